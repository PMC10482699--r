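# Projection of the lab-derived trait catalogue onto field communities:
# exact-sequence taxon matching, trait abundance aggregation (relative,
# copy-number-normalized, absolute), Bray-Curtis dissimilarity to matched
# unburned sites, and severity regressions with a year interaction.

#' Match lab and field taxa by exact sequence identity
#'
#' Lab and field amplicon datasets cover the same 16S region, so taxa merge
#' by exact sequence string equality (amplicon sequence variants).
#'
#' @param lab_taxa,field_taxa taxon records (taxon_id, sequence).
#' @return list: `map` (data.frame lab_taxon_id, field_taxon_id),
#'   `n_unmatched_lab`, `match_fraction` (fraction of field taxa with a lab
#'   match).
#' @export
match_taxa <- function(lab_taxa, field_taxa) {
  for (nm in c("lab", "field")) {
    tx <- if (nm == "lab") lab_taxa else field_taxa
    dup <- duplicated(tx$sequence)
    if (any(dup))
      stop("duplicate sequences within the ", nm, " dataset: ",
           paste(tx$taxon_id[tx$sequence %in% tx$sequence[dup]], collapse = ", "))
  }
  i <- match(lab_taxa$sequence, field_taxa$sequence)
  map <- data.frame(lab_taxon_id = lab_taxa$taxon_id[!is.na(i)],
                    field_taxon_id = field_taxa$taxon_id[i[!is.na(i)]],
                    stringsAsFactors = FALSE)
  list(map = map,
       n_unmatched_lab = sum(is.na(i)),
       match_fraction = nrow(map) / nrow(field_taxa))
}

#' Copy-number-normalized relative abundances
#'
#' Divides each taxon's counts by its predicted 16S rRNA gene copy number and
#' renormalizes every sample to 1, converting gene-copy proportions into
#' approximate cell proportions.
#'
#' @param table a [count_table] (or abundance matrix).
#' @param taxa taxon records with `taxon_id` and `copy_number`; taxa absent
#'   from the records default to copy number 1 (reported via a message).
#' @return normalized relative-abundance matrix (columns sum to 1).
#' @export
copy_number_normalize <- function(table, taxa) {
  cn <- taxa$copy_number[match(rownames(table), taxa$taxon_id)]
  if (anyNA(cn)) {
    message(sum(is.na(cn)), " taxa without predicted copy number; defaulting to 1")
    cn[is.na(cn)] <- 1
  }
  if (any(cn <= 0)) stop("predicted copy numbers must be positive")
  m <- unclass(table) / cn
  attr(m, "kind") <- NULL
  sweep(m, 2L, colSums(m), "/")
}

#' Community-weighted mean predicted 16S rRNA gene copy number
#'
#' @param relabund relative-abundance vector (one sample, sums to 1) or
#'   matrix (taxa x samples).
#' @param taxa taxon records with `taxon_id` and `copy_number`.
#' @return weighted mean (scalar, or one value per sample column).
#' @export
weighted_mean_copy_number <- function(relabund, taxa) {
  if (is.matrix(relabund)) {
    cn <- taxa$copy_number[match(rownames(relabund), taxa$taxon_id)]
    return(colSums(relabund * cn))
  }
  cn <- taxa$copy_number[match(names(relabund), taxa$taxon_id)]
  sum(relabund * cn)
}

#' Absolute abundance from relative abundance and qPCR totals
#'
#' @param relabund relative abundance(s) in [0,1].
#' @param qpcr_total total 16S copies per g soil (missing gives missing).
#' @return 16S copies per g.
#' @export
absolute_abundance <- function(relabund, qpcr_total) {
  relabund * qpcr_total
}

#' Per-sample trait abundances in field data
#'
#' For every field sample and trait: the summed relative abundance of the
#' field taxa matched to lab trait taxa, the copy-number-normalized version,
#' and (where a qPCR total is available) the absolute abundance. Multi-trait
#' taxa count toward each of their traits; the `"any_trait"` aggregate counts
#' every catalogued taxon once.
#'
#' @param field a field [count_table].
#' @param catalogue a [build_catalogue] trait catalogue (from lab data).
#' @param match result of [match_taxa].
#' @param samples field sample metadata.
#' @param taxa field taxon records (for copy numbers).
#' @return data.frame: sample_id, trait, total_relative_abundance,
#'   normalized_relative_abundance, absolute_abundance, years_post_fire,
#'   burn_severity_index.
#' @export
trait_total_abundance <- function(field, catalogue, match, samples, taxa) {
  rel <- relative_abundance(field)
  norm <- copy_number_normalize(field, taxa)
  meta <- samples[match(colnames(field), samples$sample_id), ]
  traits <- c("survivor", "fast_grower", "postfire_affinity", "any_trait")
  out <- list()
  for (tr in traits) {
    lab_ids <- trait_taxa(catalogue, if (tr == "any_trait") "any" else tr)
    fld_ids <- match$map$field_taxon_id[match$map$lab_taxon_id %in% lab_ids]
    fld_ids <- intersect(fld_ids, rownames(field))
    tot <- if (length(fld_ids)) colSums(rel[fld_ids, , drop = FALSE]) else
      stats::setNames(rep(0, ncol(field)), colnames(field))
    nrm <- if (length(fld_ids)) colSums(norm[fld_ids, , drop = FALSE]) else tot
    out[[tr]] <- data.frame(
      sample_id = colnames(field), trait = tr,
      total_relative_abundance = unname(tot),
      normalized_relative_abundance = unname(nrm),
      absolute_abundance = unname(absolute_abundance(tot, meta$qpcr_total_copies_per_g)),
      years_post_fire = meta$years_post_fire,
      burn_severity_index = meta$burn_severity_index,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Mean Bray-Curtis dissimilarity of each burned field sample to matched unburned sites
#'
#' Dissimilarities are computed on relative abundances (removing library-size
#' effects); for each burned sample the mean is taken over all unburned
#' samples of the same vegetation community, soil horizon and year stratum.
#'
#' @param field a field [count_table].
#' @param samples field sample metadata (treatment, vegetation, horizon,
#'   years_post_fire).
#' @return data.frame: sample_id, mean_bray_curtis, n_unburned_matched.
#' @export
bray_curtis_to_unburned <- function(field, samples) {
  meta <- samples[match(colnames(field), samples$sample_id), ]
  stratum <- interaction(meta$vegetation, meta$horizon, meta$years_post_fire,
                         drop = TRUE)
  burned <- meta$treatment != "unburned"
  need <- unique(stratum[burned])
  have <- unique(stratum[!burned])
  missing <- setdiff(as.character(need), as.character(have))
  if (length(missing))
    stop("no matched unburned samples for stratum(s): ",
         paste(missing, collapse = "; "))
  d <- as.matrix(vegan::vegdist(t(relative_abundance(field)), method = "bray"))
  res <- lapply(which(burned), function(i) {
    j <- which(!burned & stratum == stratum[i])
    data.frame(sample_id = meta$sample_id[i],
               mean_bray_curtis = mean(d[i, j]),
               n_unburned_matched = length(j), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Regress trait abundance on burn severity with a years-post-fire interaction
#'
#' Ordinary least squares of a trait's abundance on the severity index, year
#' group (categorical: 1 or 5 years post-fire) and their interaction. If the
#' interaction is not significant at `interaction_alpha` it is dropped and
#' the additive model reported, following the analysis convention for the
#' field severity gradient.
#'
#' @param records rows of [trait_total_abundance] for a single trait (burned
#'   and unburned samples; unburned enter at severity 0).
#' @param response column to model (default total relative abundance).
#' @param predictor continuous predictor column (default the burn severity
#'   index; any column such as a dissimilarity can be supplied).
#' @param interaction_alpha threshold for dropping the interaction.
#' @return object of class `"severity_fit"`: per-year intercepts and slopes,
#'   interaction p, whether it was dropped, adjusted R-squared, overall F
#'   p-value and the underlying `lm` fit.
#' @export
severity_regression <- function(records,
                                response = "total_relative_abundance",
                                predictor = "burn_severity_index",
                                interaction_alpha = 0.05) {
  df <- data.frame(y = records[[response]], x = records[[predictor]],
                   year = factor(records$years_post_fire))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$year)) < 2)
    stop("both year groups must be represented")
  if (nrow(df) < 8) stop("at least 8 samples required")
  full <- stats::lm(y ~ x * year, data = df)
  cf <- stats::coef(full)
  if (anyNA(cf))
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  int_term <- grep(":", names(cf), value = TRUE)
  int_p <- stats::summary.lm(full)$coefficients[int_term, "Pr(>|t|)"]
  dropped <- int_p >= interaction_alpha
  fit <- if (dropped) stats::lm(y ~ x + year, data = df) else full
  sm <- stats::summary.lm(fit)
  cf <- stats::coef(fit)
  yrs <- levels(df$year)
  year_eff <- stats::setNames(numeric(length(yrs)), yrs)
  slope_eff <- stats::setNames(rep(cf[["x"]], length(yrs)), yrs)
  for (yl in yrs[-1]) {
    year_eff[yl] <- cf[[paste0("year", yl)]]
    if (!dropped) slope_eff[yl] <- cf[["x"]] + cf[[paste0("x:year", yl)]]
  }
  fstat <- sm$fstatistic
  structure(list(
    trait = if (!is.null(records$trait)) records$trait[1] else NA_character_,
    intercepts = cf[["(Intercept)"]] + year_eff,
    slopes = slope_eff,
    interaction_p = unname(int_p),
    interaction_dropped = dropped,
    r2_adjusted = sm$adj.r.squared,
    overall_p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(df), model = fit), class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat("Severity regression", if (!is.na(x$trait)) paste0("[", x$trait, "]"), "\n")
  for (yl in names(x$slopes))
    cat(sprintf("  %s yr post-fire: y = %.3g + %.3g x\n",
                yl, x$intercepts[[yl]], x$slopes[[yl]]))
  cat(sprintf("  interaction p = %.3g (%s) | adj R^2 = %.3f | overall p = %.3g | n = %d\n",
              x$interaction_p,
              if (x$interaction_dropped) "dropped" else "retained",
              x$r2_adjusted, x$overall_p, x$n))
  invisible(x)
}
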