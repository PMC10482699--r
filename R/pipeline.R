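# Config-driven orchestration: simulate -> traits -> decay -> field, all
# reading and writing the package's standard file formats under one output
# directory, so a whole analysis is reproducible from a single YAML config.
# A thin command-line wrapper over these functions ships in inst/cli/.

.pipeline_files <- c(
  dna_t24h = "dna_t24h.tsv", rna_t24h = "rna_t24h.tsv",
  dna_t5wk = "dna_t5wk.tsv", dna_t6mo = "dna_t6mo.tsv",
  samples = "samples.csv", taxa_fasta = "taxa.fasta",
  copy_numbers = "copy_numbers.tsv", flux = "flux.csv",
  flux_samples = "flux_samples.csv",
  field_counts = "field_counts.tsv", field_samples = "field_samples.csv",
  field_taxa_fasta = "field_taxa.fasta",
  field_copy_numbers = "field_copy_numbers.tsv",
  ground_truth = "ground_truth.json",
  catalogue = "trait_catalogue.csv", catalogue_fasta = "trait_taxa.fasta",
  decay_fits = "decay_fits.csv", decay_comparisons = "decay_comparisons.csv",
  trait_abundance = "trait_abundance.csv",
  severity_models = "severity_models.csv",
  run_log = "run_log.txt")

#' Read a pipeline configuration from YAML
#'
#' Missing analysis thresholds take their defaults (FDR 0.05, burn-exposure
#' temperature 50 C, interaction drop at p 0.05, constrained decay fits with
#' 5 restarts). The `sim` section is passed to [sim_config]; `seed` at the
#' top level seeds the simulation subcommand.
#'
#' @param path YAML file path.
#' @return a named list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(alpha_fdr = 0.05, temp_threshold_C = 50,
                   interaction_alpha = 0.05,
                   decay = list(constrain_total = TRUE, restarts = 5),
                   sim = list(), out_dir = "firetraits_out")
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$decay))
    if (is.null(cfg$decay[[nm]])) cfg$decay[[nm]] <- defaults$decay[[nm]]
  if (cfg$alpha_fdr <= 0 || cfg$alpha_fdr >= 1) stop("alpha_fdr must lie in (0,1)")
  if (cfg$interaction_alpha <= 0 || cfg$interaction_alpha >= 1)
    stop("interaction_alpha must lie in (0,1)")
  cfg$config_path <- normalizePath(path)
  structure(cfg, class = "pipeline_config")
}

.out_path <- function(config, key) {
  file.path(config$out_dir, .pipeline_files[[key]])
}

.log_lines <- function(config, lines) {
  con <- file(.out_path(config, "run_log"), open = "a")
  on.exit(close(con))
  hash <- unname(tools::md5sum(config$config_path))
  writeLines(sprintf("[firetraits %s | config %s] %s",
                     as.character(utils::packageVersion("firetraits")),
                     substr(hash, 1, 8), lines), con)
}

.write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, na = "")
}

.write_copy_tsv <- function(taxa, path) {
  utils::write.table(data.frame(taxon_id = taxa$taxon_id,
                                copy_number = taxa$copy_number),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a full dataset to disk
#'
#' Writes the lab count tables (24-h DNA and RNA, 5-week and 6-month DNA),
#' sample metadata, taxa (FASTA plus copy-number TSV), flux series, the field
#' dataset and a machine-readable ground-truth JSON into `config$out_dir`
#' (created if absent). Re-running with the same config reproduces identical
#' files.
#'
#' @param config a [read_pipeline_config] result, or any list with `seed`,
#'   `out_dir` and an optional `sim` list of [sim_config] overrides.
#' @return invisibly, the named vector of written paths.
#' @export
run_simulate <- function(config) {
  if (is.null(config$seed)) stop("config must provide a seed")
  sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- generate_lab_dataset(sc)
  flux <- generate_flux_dataset(sc)
  fld <- generate_field_dataset(sc, lab$taxa, lab$truth)

  for (k in c("dna_t24h", "rna_t24h", "dna_t5wk", "dna_t6mo"))
    write_count_table(lab[[k]], .out_path(config, k))
  .write_samples_csv(lab$samples, .out_path(config, "samples"))
  write_taxa_fasta(lab$taxa, .out_path(config, "taxa_fasta"))
  .write_copy_tsv(lab$taxa, .out_path(config, "copy_numbers"))
  flux_long <- do.call(rbind, lapply(names(flux$series), function(id)
    data.frame(sample_id = id, flux$series[[id]])))
  utils::write.csv(flux_long, .out_path(config, "flux"), row.names = FALSE)
  utils::write.csv(flux$samples, .out_path(config, "flux_samples"), row.names = FALSE)
  write_count_table(fld$table, .out_path(config, "field_counts"))
  .write_samples_csv(fld$samples, .out_path(config, "field_samples"))
  write_taxa_fasta(fld$taxa, .out_path(config, "field_taxa_fasta"))
  .write_copy_tsv(fld$taxa, .out_path(config, "field_copy_numbers"))
  truth <- list(traits = lab$truth$traits, dead_taxa = lab$truth$dead_taxa,
                true_log2fc = lab$truth$true_log2fc, decay = flux$truth,
                field_slopes = fld$slopes)
  jsonlite::write_json(truth, .out_path(config, "ground_truth"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (inherits(config, "pipeline_config"))
    .log_lines(config, sprintf(
      "simulate: %d lab samples, %d flux series, %d field samples",
      nrow(lab$samples), length(flux$series), nrow(fld$samples)))
  invisible(vapply(names(.pipeline_files)[1:14], function(k)
    .out_path(config, k), character(1)))
}

# read the lab tables a trait run needs
.read_lab <- function(config) {
  list(dna_t24h = read_count_table(.out_path(config, "dna_t24h"), "DNA"),
       rna_t24h = read_count_table(.out_path(config, "rna_t24h"), "RNA"),
       dna_t5wk = read_count_table(.out_path(config, "dna_t5wk"), "DNA"),
       dna_t6mo = read_count_table(.out_path(config, "dna_t6mo"), "DNA"))
}

#' Run the three trait contrasts and write the catalogue
#'
#' @param config a [read_pipeline_config] result whose `out_dir` holds the
#'   lab tables (e.g. from [run_simulate]).
#' @return the [build_catalogue] object, invisibly.
#' @export
run_traits <- function(config) {
  tables <- .read_lab(config)
  samples <- read_sample_metadata(.out_path(config, "samples"))
  results <- list()
  for (tr in c("survivor", "fast_grower", "postfire_affinity")) {
    results[[tr]] <- call_trait(tr, tables, samples, alpha = config$alpha_fdr,
                                temp_threshold_C = config$temp_threshold_C)
    st <- attr(results[[tr]], "stages")
    if (inherits(config, "pipeline_config"))
      for (h in names(st))
        .log_lines(config, sprintf(
          "traits/%s/%s: tested=%d significant=%d viability_passed=%s effect_size_passed=%d",
          tr, h, st[[h]][["tested"]], st[[h]][["significant"]],
          st[[h]][["viability_passed"]], st[[h]][["effect_size_passed"]]))
  }
  cat <- build_catalogue(survivor = results$survivor,
                         fast_grower = results$fast_grower,
                         postfire_affinity = results$postfire_affinity)
  prov <- cat$provenance
  traits_joined <- vapply(prov$taxon_id, function(id)
    paste(cat$entries[[id]], collapse = ";"), character(1))
  utils::write.csv(
    data.frame(taxon_id = prov$taxon_id, traits = traits_joined,
               trait = prov$trait, horizon = prov$horizon,
               log2fc = prov$log2fc, q_value = prov$q_value),
    .out_path(config, "catalogue"), row.names = FALSE)
  taxa <- read_taxa_fasta(.out_path(config, "taxa_fasta"),
                          .out_path(config, "copy_numbers"))
  cat_taxa <- taxa[taxa$taxon_id %in% names(cat$entries), , drop = FALSE]
  write_taxa_fasta(cat_taxa, .out_path(config, "catalogue_fasta"))
  invisible(cat)
}

#' Fit two-pool decay models to every flux series and compare treatments
#'
#' Per-sample fit failures are recorded (converged = FALSE) and the run
#' continues. Wilcoxon comparisons of every coefficient are written for each
#' treatment pair with enough site pairs.
#'
#' @param config a [read_pipeline_config] result.
#' @return invisibly, the fit table.
#' @export
run_decay <- function(config) {
  series <- read_flux_csv(.out_path(config, "flux"))
  fits <- lapply(names(series), function(id)
    fit_two_pool(series[[id]], constrain_total = config$decay$constrain_total,
                 restarts = config$decay$restarts, sample_id = id))
  tab <- tidy_two_pool(fits)
  utils::write.csv(tab, .out_path(config, "decay_fits"), row.names = FALSE)
  fs_path <- .out_path(config, "flux_samples")
  if (file.exists(fs_path)) {
    fsamp <- utils::read.csv(fs_path, stringsAsFactors = FALSE)
    pairs <- list(c("unburned", "dry_burn"), c("unburned", "moist_burn"),
                  c("moist_burn", "dry_burn"))
    rows <- list()
    for (pr in pairs) for (co in c("M1", "M2", "k1", "k2")) {
      cmp <- compare_fits(tab, fsamp, co, pr)
      rows[[paste(pr[1], pr[2], co)]] <- data.frame(
        group_a = pr[1], group_b = pr[2], coefficient = co,
        n_pairs = cmp$n_pairs, statistic = cmp$statistic,
        p_value = cmp$p_value, mean_a = cmp$group_means[[1]],
        mean_b = cmp$group_means[[2]], sufficient = cmp$sufficient)
    }
    utils::write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                     .out_path(config, "decay_comparisons"), row.names = FALSE)
  }
  if (inherits(config, "pipeline_config"))
    .log_lines(config, sprintf("decay: %d series fitted, %d converged",
                               nrow(tab), sum(tab$converged)))
  invisible(tab)
}

#' Project the trait catalogue onto the field dataset
#'
#' Matches lab and field taxa by exact sequence, writes per-sample trait
#' abundances (relative, copy-number-normalized, absolute) and the severity
#' regression summaries per trait.
#'
#' @param config a [read_pipeline_config] result; requires the catalogue and
#'   field files in `out_dir`.
#' @return invisibly, a list with the abundance records and model fits.
#' @export
run_field <- function(config) {
  cat_csv <- utils::read.csv(.out_path(config, "catalogue"),
                             stringsAsFactors = FALSE)
  per_trait <- split(cat_csv, cat_csv$trait)
  catalogue <- build_catalogue(
    survivor = per_trait$survivor, fast_grower = per_trait$fast_grower,
    postfire_affinity = per_trait$postfire_affinity)
  lab_taxa <- read_taxa_fasta(.out_path(config, "taxa_fasta"),
                              .out_path(config, "copy_numbers"))
  field_taxa <- read_taxa_fasta(.out_path(config, "field_taxa_fasta"),
                                .out_path(config, "field_copy_numbers"))
  field <- read_count_table(.out_path(config, "field_counts"), "DNA")
  fsamples <- read_sample_metadata(.out_path(config, "field_samples"))
  if (anyNA(fsamples$burn_severity_index))
    stop("field sample(s) without burn severity index")
  mt <- match_taxa(lab_taxa, field_taxa)
  if (nrow(mt$map) == 0) warning("no lab taxa matched the field dataset")
  rec <- trait_total_abundance(field, catalogue, mt, fsamples, field_taxa)
  utils::write.csv(rec, .out_path(config, "trait_abundance"), row.names = FALSE)
  fits <- list()
  for (tr in unique(rec$trait)) {
    sub <- rec[rec$trait == tr, ]
    fit <- tryCatch(severity_regression(sub,
                                        interaction_alpha = config$interaction_alpha),
                    error = function(e) NULL)
    if (is.null(fit)) next
    for (yl in names(fit$slopes))
      fits[[paste(tr, yl)]] <- data.frame(
        trait = tr, year = yl, intercept = fit$intercepts[[yl]],
        slope = fit$slopes[[yl]], interaction_p = fit$interaction_p,
        interaction_dropped = fit$interaction_dropped,
        r2_adjusted = fit$r2_adjusted, overall_p = fit$overall_p, n = fit$n)
  }
  model_tab <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  utils::write.csv(model_tab, .out_path(config, "severity_models"),
                   row.names = FALSE)
  if (inherits(config, "pipeline_config"))
    .log_lines(config, sprintf(
      "field: match fraction %.3f (%d lab taxa unmatched), %d abundance records",
      mt$match_fraction, mt$n_unmatched_lab, nrow(rec)))
  invisible(list(abundance = rec, models = model_tab,
                 match_fraction = mt$match_fraction))
}

#' Run the whole pipeline: simulate, traits, decay, field
#' @param config a [read_pipeline_config] result (needs `seed` for the
#'   simulation stage).
#' @return invisibly, the [run_field] result.
#' @export
run_all <- function(config) {
  run_simulate(config)
  run_traits(config)
  run_decay(config)
  invisible(run_field(config))
}
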