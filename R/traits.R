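# Trait assignment: orchestrates the three trait-defining contrasts
# (fire survival, fast growth, post-fire environment affinity) with the
# sample-selection, viability and effect-size filters, per horizon, and
# unions the horizons into a trait catalogue.

#' Restrict lab samples to cores that experienced an ecologically meaningful burn
#'
#' Burned cores are retained only if their maximum thermocouple temperature
#' exceeded `threshold_C` (strictly); for every retained burned core the
#' unburned control core from the same site is retained as well. Everything
#' else is dropped. Cores are site x treatment units: the decision applies to
#' all horizons and timepoints of the core.
#'
#' @param samples lab sample metadata.
#' @param threshold_C temperature threshold, degrees C (default 50).
#' @return the retained subset of `samples`.
#' @export
select_burn_exposed <- function(samples, threshold_C = 50) {
  lab <- samples[samples$timepoint != "field", , drop = FALSE]
  burned <- lab$treatment != "unburned"
  if (any(burned & is.na(lab$max_temp_C)))
    stop("burned core(s) with missing max_temp_C: ",
         paste(unique(lab$sample_id[burned & is.na(lab$max_temp_C)]), collapse = ", "))
  keep_burned <- burned & lab$max_temp_C > threshold_C
  hot_sites <- unique(lab$site_id[keep_burned])
  keep <- keep_burned | (!burned & lab$site_id %in% hot_sites)
  lab[keep, , drop = FALSE]
}

#' RNA:DNA viability filter
#'
#' For each taxon, the ratio of its mean RNA relative abundance to its mean
#' DNA relative abundance across the burned, burn-exposed 24-h samples. Taxa
#' with ratio >= 1 are considered viable (the boundary is kept); taxa absent
#' from the RNA libraries have ratio 0 and are excluded. This screens out
#' relic DNA from cells killed by the fire.
#'
#' @param dna,rna 24-h [count_table]s sharing sample identifiers (paired
#'   libraries from the same cores).
#' @param burned_ids sample ids of the retained burned cores to aggregate
#'   over (see [select_burn_exposed]).
#' @return character vector of viable taxon ids.
#' @export
viability_filter <- function(dna, rna, burned_ids) {
  burned_ids <- intersect(burned_ids, colnames(dna))
  if (length(burned_ids) == 0) stop("no burned samples in the DNA table")
  missing_rna <- setdiff(burned_ids, colnames(rna))
  if (length(missing_rna))
    stop("no paired RNA library for burned core(s): ",
         paste(missing_rna, collapse = ", "))
  dna_rel <- relative_abundance(dna[, burned_ids, drop = FALSE])
  rna_rel_all <- relative_abundance(rna[, burned_ids, drop = FALSE])
  rna_rel <- matrix(0, nrow(dna), length(burned_ids),
                    dimnames = dimnames(dna_rel))
  shared <- intersect(rownames(dna), rownames(rna))
  rna_rel[shared, ] <- rna_rel_all[shared, ]
  dna_mean <- rowMeans(dna_rel)
  rna_mean <- rowMeans(rna_rel)
  rownames(dna)[rna_mean >= dna_mean]    # 0/0 counts as viable (never called anyway)
}

#' Effect-size floor on significant positive responders
#'
#' Removes statistically significant but small positive responses: the
#' threshold is mean(log2fc) - sd(log2fc) over the supplied results (the
#' significant positive responders of one experiment x horizon), and results
#' below it are dropped. With fewer than two results, or when all effects are
#' equal (sd 0; the threshold equals the mean and >= passes), nothing is
#' removed.
#'
#' @param results data.frame with a `log2fc` column.
#' @return the retained rows.
#' @export
effect_size_filter <- function(results) {
  if (nrow(results) < 2) return(results)
  threshold <- mean(results$log2fc) - stats::sd(results$log2fc)
  results[results$log2fc >= threshold, , drop = FALSE]
}

# contrast definition: which table(s), which samples, which arm is group 1
.contrast_frame <- function(contrast, tables, retained, horizon) {
  r <- retained[retained$horizon == horizon, , drop = FALSE]
  if (contrast == "survivor") {
    if (is.null(tables$dna_t24h)) stop("survivor contrast requires the 24-h DNA table")
    tab <- tables$dna_t24h
    ids <- intersect(r$sample_id[r$timepoint == "t24h"], colnames(tab))
  } else if (contrast == "fast_grower") {
    if (is.null(tables$dna_t24h) || is.null(tables$dna_t5wk))
      stop("fast_grower contrast requires the 24-h and 5-week DNA tables")
    ids24 <- intersect(r$sample_id[r$timepoint == "t24h" & r$treatment != "unburned"],
                       colnames(tables$dna_t24h))
    ids5 <- intersect(r$sample_id[r$timepoint == "t5wk" & r$treatment != "unburned"],
                      colnames(tables$dna_t5wk))
    m <- cbind(unclass(tables$dna_t24h)[, ids24, drop = FALSE],
               unclass(tables$dna_t5wk)[, ids5, drop = FALSE])
    tab <- count_table(m, "DNA")
    ids <- colnames(tab)
  } else {
    if (is.null(tables$dna_t6mo))
      stop("postfire_affinity contrast requires the 6-month DNA table")
    tab <- tables$dna_t6mo
    ids <- intersect(r$sample_id[r$timepoint == "t6mo"], colnames(tab))
  }
  grp <- if (contrast == "fast_grower")
    as.integer(ids %in% r$sample_id[r$timepoint == "t5wk"])
  else
    as.integer(r$treatment[match(ids, r$sample_id)] != "unburned")
  tab_sub <- structure(unclass(tab)[, ids, drop = FALSE],
                       kind = attr(tab, "kind"),
                       class = c("count_table", "matrix", "array"))
  # pH covariate: the site's baseline pH (its unburned control core in this
  # horizon), not the sample's own post-burn pH. Burning itself moves pH, so
  # post-burn pH is a post-treatment variable nearly collinear with the
  # contrast arm; the baseline captures the between-site pH range the
  # covariate is meant to control.
  ctrl <- r[r$treatment == "unburned", , drop = FALSE]
  base_ph <- tapply(ctrl$pH, ctrl$site_id, mean)
  site <- r$site_id[match(ids, r$sample_id)]
  ph <- unname(base_ph[site])
  ph[is.na(ph)] <- r$pH[match(ids, r$sample_id)][is.na(ph)]
  list(table = tab_sub, group = grp, pH = ph)
}

#' Run one trait-defining contrast and apply the trait filters
#'
#' Fits the beta-binomial differential-abundance model per taxon, separately
#' for organic and mineral horizons, with pH as a covariate; keeps taxa with
#' q-value below `alpha` and positive log2 fold change; for the survivor
#' contrast additionally requires passing the RNA:DNA [viability_filter];
#' applies the [effect_size_filter] per horizon; and returns the union over
#' horizons.
#'
#' Contrast arms (group 1 vs group 0):
#' \itemize{
#'   \item survivor: burned vs unburned DNA, 24 h post-burn;
#'   \item fast_grower: burned DNA at 5 weeks vs burned DNA at 24 h;
#'   \item postfire_affinity: burned vs unburned DNA after the inoculated
#'     6-month incubation.
#' }
#'
#' @param contrast one of `"survivor"`, `"fast_grower"`, `"postfire_affinity"`.
#' @param tables named list with elements `dna_t24h`, `rna_t24h`, `dna_t5wk`,
#'   `dna_t6mo` ([count_table]s; only the ones the contrast needs are required).
#' @param samples lab sample metadata.
#' @param alpha FDR cut-off on BH q-values (default 0.05, strict inequality).
#' @param temp_threshold_C burn-exposure temperature threshold.
#' @param min_prevalence prevalence floor passed to [diff_abundance].
#' @return data.frame of retained results (taxon_id, horizon, log2fc,
#'   se_log2fc, p_value, q_value) with a `"stages"` attribute recording
#'   per-horizon counts at every filter stage.
#' @export
call_trait <- function(contrast = c("survivor", "fast_grower", "postfire_affinity"),
                       tables, samples, alpha = 0.05, temp_threshold_C = 50,
                       min_prevalence = 3L) {
  contrast <- match.arg(contrast)
  retained <- select_burn_exposed(samples, temp_threshold_C)
  out <- list(); stages <- list()
  for (h in c("organic", "mineral")) {
    cf <- .contrast_frame(contrast, tables, retained, h)
    if (length(unique(cf$group)) < 2 || min(table(cf$group)) < 2) next
    res <- diff_abundance(cf$table, cf$group, pH = cf$pH,
                          min_prevalence = min_prevalence)
    n_tested <- sum(!is.na(res$p_value))
    sig <- res[!is.na(res$q_value) & res$q_value < alpha & res$log2fc > 0 &
                 res$converged, , drop = FALSE]
    n_sig <- nrow(sig)
    n_viable <- NA_integer_
    if (contrast == "survivor") {
      burned_ids <- colnames(cf$table)[cf$group == 1]
      viable <- viability_filter(tables$dna_t24h, tables$rna_t24h, burned_ids)
      sig <- sig[sig$taxon_id %in% viable, , drop = FALSE]
      n_viable <- nrow(sig)
    }
    sig <- effect_size_filter(sig)
    stages[[h]] <- c(tested = n_tested, significant = n_sig,
                     viability_passed = n_viable, effect_size_passed = nrow(sig))
    if (nrow(sig)) {
      sig$horizon <- h
      out[[h]] <- sig[c("taxon_id", "horizon", "log2fc", "se_log2fc",
                        "p_value", "q_value")]
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(taxon_id = character(), horizon = character(),
                         log2fc = numeric(), se_log2fc = numeric(),
                         p_value = numeric(), q_value = numeric())
  attr(res, "stages") <- stages
  res
}

#' Assemble per-trait results into a trait catalogue
#'
#' Traits are non-exclusive sets: a taxon significant in several contrasts
#' carries all of them. Provenance (horizon, log2 fold change, q-value) is
#' kept for every (taxon, trait) call.
#'
#' @param survivor,fast_grower,postfire_affinity results from [call_trait]
#'   (any may be `NULL` or empty).
#' @return object of class `"trait_catalogue"`: `entries` (named list, taxon
#'   id -> character vector of traits) and `provenance` (data.frame).
#' @export
build_catalogue <- function(survivor = NULL, fast_grower = NULL,
                            postfire_affinity = NULL) {
  pieces <- list(survivor = survivor, fast_grower = fast_grower,
                 postfire_affinity = postfire_affinity)
  prov <- list()
  for (trait in names(pieces)) {
    r <- pieces[[trait]]
    if (is.null(r) || nrow(r) == 0) next
    r$trait <- trait
    prov[[trait]] <- r[c("taxon_id", "trait", "horizon", "log2fc", "q_value")]
  }
  provenance <- if (length(prov))
    do.call(rbind, c(prov, list(make.row.names = FALSE)))
  else data.frame(taxon_id = character(), trait = character(),
                  horizon = character(), log2fc = numeric(), q_value = numeric())
  entries <- lapply(split(provenance$trait, provenance$taxon_id),
                    function(x) sort(unique(x)))
  structure(list(entries = entries, provenance = provenance),
            class = "trait_catalogue")
}

#' @export
print.trait_catalogue <- function(x, ...) {
  counts <- table(unlist(x$entries))
  cat("Trait catalogue:", length(x$entries), "taxa\n")
  for (tr in names(counts)) cat(sprintf("  %-18s %d\n", tr, counts[[tr]]))
  multi <- sum(lengths(x$entries) > 1)
  if (multi) cat("  (", multi, " taxa carry multiple traits)\n", sep = "")
  invisible(x)
}

#' Taxon ids carrying a given trait (or any trait)
#' @param catalogue a [build_catalogue] object.
#' @param trait a trait name, or `"any"` for the deduplicated union.
#' @return character vector of taxon ids.
#' @export
trait_taxa <- function(catalogue, trait = "any") {
  if (trait == "any") return(names(catalogue$entries))
  names(catalogue$entries)[vapply(catalogue$entries, function(x) trait %in% x,
                                  logical(1))]
}
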