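# Seeded synthetic lab + field datasets with known ground truth.
#
# Communities are Dirichlet-multinomial: a sample's proportions are drawn
# from Dirichlet(c * m), where m is the expected composition (baseline,
# possibly with trait taxa spiked in the contrast that defines the trait) and
# c the total concentration controlling overdispersion; counts are then
# multinomial at the sample's drawn library size. This matches the
# beta-binomial marginals assumed by the differential-abundance stage.

.TRAITS <- c("survivor", "fast_grower", "postfire_affinity")

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of the study system: 19 sites
#' of paired unburned / moist-burn / dry-burn cores, dry burns hot (>> 50 C)
#' and alkalinized (organic-horizon pH rising from about 4.5 to about 7.2),
#' moist burns cool (around 30-40 C), trait taxa spiked at log2 fold change 3
#' in their defining contrast, relic-DNA taxa whose RNA signal is depressed
#' ten-fold, treatment-specific two-pool decay coefficients set to the
#' lab-study treatment means, and a field severity gradient whose fast-grower
#' enrichment is strong one year post-fire and nearly gone at five years.
#'
#' @param seed integer seed; mandatory, drives all generation.
#' @param n_sites number of paired-core sites.
#' @param n_taxa community richness of the lab pool.
#' @param library_size_mean mean per-sample read depth (Poisson-drawn).
#' @param base_concentration total Dirichlet concentration (per-taxon
#'   concentration is `base_concentration / n_taxa`; 50 gives realistic
#'   overdispersion).
#' @param n_survivors,n_fastgrowers,n_affinity counts of spiked trait taxa
#'   (disjoint sets).
#' @param n_relic taxa spiked in burned-sample DNA but flagged dead (RNA
#'   depressed); decoys for the viability filter.
#' @param spike_log2fc named vector: spike size per trait, log2 units.
#' @param rna_viability_ratio_dead multiplier on dead-taxon RNA signal, [0,1).
#' @param rna_activity_boost multiplier on the RNA signal of live survivor
#'   taxa in burned samples (>= 1): active cells are ribosome-rich, so their
#'   rRNA:rRNA-gene ratio sits clearly above 1 rather than at the boundary.
#' @param burn_ph_shift_mean mean pH rise in dry-burned organic horizons.
#' @param temp_dry_mean_C,temp_dry_sd_C,temp_moist_mean_C,temp_moist_sd_C
#'   thermocouple maxima by burn type.
#' @param decay_params_by_treatment named list of c(M1, k1, k2) per treatment;
#'   requires M1 in (0,1) and k1 > k2 > 0.
#' @param decay_param_cv between-sample coefficient of variation of decay
#'   parameters around treatment means.
#' @param flux_noise_cv multiplicative lognormal noise CV on fluxes.
#' @param severity_slope_y1,severity_slope_y5 named vectors: increase in
#'   expected trait-group total relative abundance per severity unit, by year.
#' @param field_match_fraction fraction of field taxa that are exact-sequence
#'   matches of lab taxa.
#' @param n_field_burned_per_stratum,n_field_unburned_per_stratum field
#'   samples per vegetation x horizon x year stratum.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_sites = 19L,
                       n_taxa = 120L,
                       library_size_mean = 30000L,
                       base_concentration = 50,
                       n_survivors = 8L, n_fastgrowers = 12L, n_affinity = 8L,
                       n_relic = 4L,
                       spike_log2fc = c(survivor = 3, fast_grower = 3,
                                        postfire_affinity = 3),
                       rna_viability_ratio_dead = 0.1,
                       rna_activity_boost = 2,
                       burn_ph_shift_mean = 2.7,
                       temp_dry_mean_C = 300, temp_dry_sd_C = 150,
                       temp_moist_mean_C = 30, temp_moist_sd_C = 6,
                       decay_params_by_treatment = list(
                         unburned   = c(M1 = 0.096, k1 = 0.0036, k2 = 0.0013),
                         moist_burn = c(M1 = 0.027, k1 = 0.16,   k2 = 0.0017),
                         dry_burn   = c(M1 = 0.027, k1 = 0.16,   k2 = 0.00098)),
                       decay_param_cv = 0.1,
                       flux_noise_cv = 0.05,
                       severity_slope_y1 = c(survivor = 0.008,
                                             fast_grower = 0.035,
                                             postfire_affinity = 0.010),
                       severity_slope_y5 = c(survivor = 0.008,
                                             fast_grower = 0.003,
                                             postfire_affinity = 0.004),
                       field_match_fraction = 0.8,
                       n_field_burned_per_stratum = 4L,
                       n_field_unburned_per_stratum = 2L) {
  if (missing(seed)) stop("'seed' is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (cfg$n_survivors + cfg$n_fastgrowers + cfg$n_affinity + cfg$n_relic > cfg$n_taxa)
    stop("spiked taxa (incl. relic decoys) exceed n_taxa")
  if (!all(.TRAITS %in% names(cfg$spike_log2fc)))
    stop("spike_log2fc must name all of: ", paste(.TRAITS, collapse = ", "))
  if (any(cfg$spike_log2fc < 0)) stop("spike_log2fc must be >= 0")
  if (cfg$rna_viability_ratio_dead < 0 || cfg$rna_viability_ratio_dead >= 1)
    stop("rna_viability_ratio_dead must lie in [0, 1)")
  if (cfg$rna_activity_boost < 1) stop("rna_activity_boost must be >= 1")
  for (tr in c("unburned", "moist_burn", "dry_burn")) {
    p <- cfg$decay_params_by_treatment[[tr]]
    if (is.null(p)) stop("decay parameters missing for treatment: ", tr)
    if (p[["M1"]] <= 0 || p[["M1"]] >= 1) stop(tr, ": M1 must lie in (0,1)")
    if (!(p[["k1"]] > p[["k2"]] && p[["k2"]] > 0))
      stop(tr, ": need k1 > k2 > 0 (label-switching guard)")
  }
  if (cfg$flux_noise_cv < 0) stop("flux_noise_cv must be >= 0")
  if (cfg$field_match_fraction <= 0 || cfg$field_match_fraction > 1)
    stop("field_match_fraction must lie in (0, 1]")
  if (cfg$n_field_burned_per_stratum < 1 || cfg$n_field_unburned_per_stratum < 1)
    stop("every field stratum needs burned and matched unburned samples")
  structure(cfg, class = "sim_config")
}

# one Dirichlet draw
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Dirichlet-multinomial sample: expected proportions m, concentration c
.rdm <- function(m, conc, size) {
  p <- .rdirichlet(conc * m)
  drop(stats::rmultinom(1, size, p))
}

.random_seqs <- function(n, len = 250L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate the full laboratory experiment with known ground truth
#'
#' Per site: one unburned, one moist-burn and one dry-burn core, each with an
#' organic and a mineral horizon, sampled at 24 h (DNA and RNA), 5 weeks
#' (DNA) and 6 months (DNA; the separate autoclaved-and-inoculated affinity
#' incubation). Survivor taxa are spiked in burned 24-h (and 5-week) samples,
#' fast growers in burned 5-week samples relative to burned 24-h, and
#' affinity taxa in burned 6-month samples; relic decoys are spiked in burned
#' DNA but carry depressed RNA. Because the 6-month incubation is seeded from
#' autoclaved soil, survivor and fast-grower spikes do not carry into it.
#'
#' @param config a [sim_config].
#' @return list: `dna_t24h`, `rna_t24h`, `dna_t5wk`, `dna_t6mo`
#'   ([count_table]s), `samples` (metadata data.frame), `taxa` (taxon
#'   records with sequences and predicted copy numbers), `truth` (trait
#'   labels, spiked log2 fold changes, dead taxa).
#' @export
generate_lab_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_taxa
  taxon_ids <- sprintf("asv%03d", seq_len(nt))

  idx <- sample(nt, config$n_survivors + config$n_fastgrowers +
                  config$n_affinity + config$n_relic)
  survivors <- taxon_ids[idx[seq_len(config$n_survivors)]]
  fastgrowers <- taxon_ids[idx[config$n_survivors + seq_len(config$n_fastgrowers)]]
  affinity <- taxon_ids[idx[config$n_survivors + config$n_fastgrowers +
                              seq_len(config$n_affinity)]]
  relic <- taxon_ids[idx[config$n_survivors + config$n_fastgrowers +
                           config$n_affinity + seq_len(config$n_relic)]]

  copy_number <- 1 + stats::rexp(nt, rate = 1)
  copy_number[taxon_ids %in% fastgrowers] <- 1 + stats::rexp(config$n_fastgrowers, rate = 0.25)
  copy_number <- pmin(copy_number, 15)
  taxa <- data.frame(taxon_id = taxon_ids, sequence = .random_seqs(nt),
                     copy_number = copy_number, stringsAsFactors = FALSE)

  base <- rep(1 / nt, nt)
  names(base) <- taxon_ids
  s <- config$spike_log2fc
  spike <- function(m, ids, l2fc) {
    m[ids] <- m[ids] * 2^l2fc
    m / sum(m)
  }
  # expected DNA composition per (burned?, timepoint)
  mean_comp <- function(burned, timepoint) {
    m <- base
    if (burned && timepoint %in% c("t24h", "t5wk")) {
      m <- spike(m, survivors, s[["survivor"]])
      m <- spike(m, relic, s[["survivor"]])    # relic decoys mimic survivors in DNA
    }
    if (burned && timepoint == "t5wk") m <- spike(m, fastgrowers, s[["fast_grower"]])
    if (burned && timepoint == "t6mo") m <- spike(m, affinity, s[["postfire_affinity"]])
    m
  }

  treatments <- c("unburned", "moist_burn", "dry_burn")
  horizons <- c("organic", "mineral")
  timepoints <- c("t24h", "t5wk", "t6mo")
  conc <- config$base_concentration

  samples <- list()
  dna_cols <- list(t24h = list(), t5wk = list(), t6mo = list())
  rna_cols <- list()

  for (site in seq_len(config$n_sites)) {
    site_id <- sprintf("S%02d", site)
    temp <- c(unburned = NA_real_,
              moist_burn = min(max(stats::rnorm(1, config$temp_moist_mean_C,
                                                config$temp_moist_sd_C), 15), 49),
              dry_burn = max(stats::rnorm(1, config$temp_dry_mean_C,
                                          config$temp_dry_sd_C), 25))
    ph_base <- c(organic = stats::rnorm(1, 4.5, 0.7),
                 mineral = stats::rnorm(1, 5.0, 0.5))
    for (tr in treatments) for (h in horizons) {
      shift <- switch(tr, unburned = 0,
                      moist_burn = 0.2,
                      dry_burn = stats::rnorm(1, config$burn_ph_shift_mean, 0.5) *
                        if (h == "organic") 1 else 0.5)
      ph <- ph_base[[h]] + shift
      for (tp in timepoints) {
        sid <- sprintf("%s_%s_%s_%s", site_id, tr, h, tp)
        burned <- tr != "unburned"
        m <- mean_comp(burned, tp)
        size <- stats::rpois(1, config$library_size_mean)
        dna_cols[[tp]][[sid]] <- .rdm(m, conc, size)
        if (tp == "t24h") {
          m_rna <- m
          if (burned) {
            m_rna[relic] <- m_rna[relic] * config$rna_viability_ratio_dead
            m_rna[survivors] <- m_rna[survivors] * config$rna_activity_boost
            m_rna <- m_rna / sum(m_rna)
          }
          rna_cols[[sid]] <- .rdm(m_rna, conc, stats::rpois(1, config$library_size_mean))
        }
        samples[[sid]] <- data.frame(
          sample_id = sid, site_id = site_id, treatment = tr, horizon = h,
          timepoint = tp,
          inoculation = if (tp == "t6mo") "autoclaved_inoculated" else "none",
          pH = round(ph + stats::rnorm(1, 0, 0.1), 2),
          max_temp_C = temp[[tr]], vegetation = "jack_pine",
          years_post_fire = NA_real_, burn_severity_index = NA_real_,
          qpcr_total_copies_per_g = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }

  as_table <- function(cols, kind) {
    m <- do.call(cbind, cols)
    rownames(m) <- taxon_ids
    count_table(m, kind)
  }
  trait_of_taxon <- c(
    stats::setNames(rep("survivor", length(survivors)), survivors),
    stats::setNames(rep("fast_grower", length(fastgrowers)), fastgrowers),
    stats::setNames(rep("postfire_affinity", length(affinity)), affinity))
  truth <- list(
    traits = split(names(trait_of_taxon), unname(trait_of_taxon)),
    true_log2fc = data.frame(
      taxon_id = c(survivors, fastgrowers, affinity),
      contrast = rep(.TRAITS, c(length(survivors), length(fastgrowers),
                                length(affinity))),
      log2fc = rep(unname(s[.TRAITS]), c(length(survivors), length(fastgrowers),
                                         length(affinity))),
      stringsAsFactors = FALSE),
    dead_taxa = relic)
  list(dna_t24h = as_table(dna_cols$t24h, "DNA"),
       rna_t24h = as_table(rna_cols, "RNA"),
       dna_t5wk = as_table(dna_cols$t5wk, "DNA"),
       dna_t6mo = as_table(dna_cols$t6mo, "DNA"),
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       taxa = taxa, truth = truth)
}

#' Generate CO2 flux series from treatment-specific two-pool kinetics
#'
#' One series per site x treatment incubation. The true flux at time t is the
#' analytic two-pool flux (see [two_pool_flux]), with per-sample decay
#' parameters jittered around the treatment means and multiplicative
#' lognormal observation noise of coefficient of variation `flux_noise_cv`
#' (mean-one, so the expected flux equals the analytic curve).
#'
#' @param config a [sim_config].
#' @param design `"5wk"` (daily sampling, days 0-35) or `"6mo"` (tapering
#'   schedule out to day 180).
#' @return list: `series` (named list of data.frames time/flux), `truth`
#'   (per-sample true M1, k1, k2), `samples` (sample_id, site_id, treatment).
#' @export
generate_flux_dataset <- function(config, design = c("5wk", "6mo")) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  set.seed(config$seed + 1L)
  times <- if (design == "5wk") 0:35
           else c(0:7, seq(9, 21, 2), seq(24, 60, 3), seq(67, 180, 7))
  cv <- config$flux_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  pcv <- config$decay_param_cv
  psd <- sqrt(log(1 + pcv^2))

  series <- list(); truth <- list(); samples <- list()
  for (site in seq_len(config$n_sites)) for (tr in names(config$decay_params_by_treatment)) {
    p <- config$decay_params_by_treatment[[tr]]
    M1 <- stats::plogis(stats::qlogis(p[["M1"]]) + stats::rnorm(1, 0, pcv))
    k1 <- p[["k1"]] * stats::rlnorm(1, -psd^2 / 2, psd)
    k2 <- p[["k2"]] * stats::rlnorm(1, -psd^2 / 2, psd)
    if (k2 >= k1) k2 <- k1 * 0.5    # preserve label ordering under jitter
    sid <- sprintf("S%02d_%s_incub", site, tr)
    f <- two_pool_flux(M1, k1, k2, times)
    if (cv > 0) f <- f * stats::rlnorm(length(f), -sdlog^2 / 2, sdlog)
    series[[sid]] <- data.frame(time = times, flux = f)
    truth[[sid]] <- data.frame(sample_id = sid, treatment = tr, M1 = M1,
                               k1 = k1, k2 = k2, stringsAsFactors = FALSE)
    samples[[sid]] <- data.frame(sample_id = sid, site_id = sprintf("S%02d", site),
                                 treatment = tr, stringsAsFactors = FALSE)
  }
  list(series = series,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))))
}

#' Generate a field dataset across a burn-severity gradient
#'
#' Field communities share the lab taxon pool (exact sequences) plus
#' field-only taxa so that a known fraction of field taxa has a lab match.
#' The expected total relative abundance of each trait group rises linearly
#' with burn severity, with year-specific slopes; every vegetation x horizon
#' x year stratum includes matched unburned (severity 0) samples.
#'
#' @param config a [sim_config].
#' @param lab_taxa taxon records from [generate_lab_dataset].
#' @param truth ground truth from [generate_lab_dataset].
#' @return list: `table` ([count_table]), `samples` (field metadata),
#'   `taxa` (field taxon records incl. field-only taxa), `slopes` (the
#'   generating slopes by trait and year).
#' @export
generate_field_dataset <- function(config, lab_taxa, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_lab <- nrow(lab_taxa)
  n_extra <- round(n_lab * (1 - config$field_match_fraction) /
                     config$field_match_fraction)
  extra <- if (n_extra > 0)
    data.frame(taxon_id = sprintf("fld%03d", seq_len(n_extra)),
               sequence = .random_seqs(n_extra),
               copy_number = pmin(1 + stats::rexp(n_extra, 1), 15),
               stringsAsFactors = FALSE)
  else NULL
  taxa <- rbind(lab_taxa[c("taxon_id", "sequence", "copy_number")], extra)
  nt <- nrow(taxa)
  base <- stats::setNames(rep(1 / nt, nt), taxa$taxon_id)

  groups <- truth$traits
  slopes <- list(`1` = config$severity_slope_y1, `5` = config$severity_slope_y5)

  comp_at <- function(severity, year) {
    m <- base
    tgt <- vapply(.TRAITS, function(g) {
      sum(base[groups[[g]]]) + slopes[[as.character(year)]][[g]] * severity
    }, numeric(1))
    if (sum(tgt) >= 0.9) stop("trait targets exceed 90% of the community")
    others <- setdiff(names(m), unlist(groups))
    for (g in .TRAITS) m[groups[[g]]] <- base[groups[[g]]] *
        tgt[[g]] / sum(base[groups[[g]]])
    m[others] <- base[others] * (1 - sum(tgt)) /
      (1 - sum(vapply(.TRAITS, function(g) sum(base[groups[[g]]]), numeric(1))))
    m
  }

  veg <- c("jack_pine", "black_spruce", "aspen")
  cols <- list(); samples <- list(); i <- 0L
  for (year in c(1, 5)) for (v in veg) for (h in c("organic", "mineral")) {
    sev <- c(stats::runif(config$n_field_burned_per_stratum, 0.5, 5),
             rep(0, config$n_field_unburned_per_stratum))
    for (sv in sev) {
      i <- i + 1L
      sid <- sprintf("FLD%03d", i)
      m <- comp_at(sv, year)
      cols[[sid]] <- .rdm(m, config$base_concentration,
                          stats::rpois(1, config$library_size_mean))
      samples[[sid]] <- data.frame(
        sample_id = sid, site_id = sprintf("FS%03d", i),
        treatment = if (sv > 0) "dry_burn" else "unburned",
        horizon = h, timepoint = "field", inoculation = "none",
        pH = round(stats::rnorm(1, 5 + 0.3 * sv, 0.5), 2),
        max_temp_C = NA_real_, vegetation = v, years_post_fire = year,
        burn_severity_index = round(sv, 3),
        qpcr_total_copies_per_g = 10^(9 - 0.1 * sv) * stats::rlnorm(1, 0, 0.3),
        stringsAsFactors = FALSE)
    }
  }
  mmat <- do.call(cbind, cols)
  rownames(mmat) <- taxa$taxon_id
  list(table = count_table(mmat, "DNA"),
       samples = do.call(rbind, c(samples, list(make.row.names = FALSE))),
       taxa = taxa, slopes = slopes)
}
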