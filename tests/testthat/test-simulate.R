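test_that("config validation fires before any generation", {
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(1, n_taxa = 10, n_survivors = 5, n_fastgrowers = 5,
                          n_affinity = 5), "exceed")
  expect_error(sim_config(1, decay_params_by_treatment = list(
    unburned = c(M1 = 0.1, k1 = 0.001, k2 = 0.002),
    moist_burn = c(M1 = 0.1, k1 = 0.01, k2 = 0.001),
    dry_burn = c(M1 = 0.1, k1 = 0.01, k2 = 0.001))), "k1 > k2")
  expect_error(sim_config(1, flux_noise_cv = -0.1), "flux_noise_cv")
  expect_error(sim_config(1, rna_viability_ratio_dead = 1), "viability")
})

test_that("identical seeds reproduce identical datasets", {
  cfg <- sim_config(seed = 3, n_sites = 4, n_taxa = 40, n_survivors = 4,
                    n_fastgrowers = 5, n_affinity = 4, n_relic = 2)
  a <- generate_lab_dataset(cfg)
  b <- generate_lab_dataset(cfg)
  expect_identical(a, b)
  fa <- generate_flux_dataset(cfg)
  fb <- generate_flux_dataset(cfg)
  expect_identical(fa, fb)
  ga <- generate_field_dataset(cfg, a$taxa, a$truth)
  gb <- generate_field_dataset(cfg, b$taxa, b$truth)
  expect_identical(ga, gb)
  # and a different seed changes the draw
  c2 <- generate_lab_dataset(sim_config(seed = 4, n_sites = 4, n_taxa = 40,
                                        n_survivors = 4, n_fastgrowers = 5,
                                        n_affinity = 4, n_relic = 2))
  expect_false(identical(unclass(a$dna_t24h), unclass(c2$dna_t24h)))
})

test_that("lab dataset has the designed structure", {
  lab <- lab_fixture()
  s <- lab$samples
  expect_equal(nrow(s), 19 * 3 * 2 * 3)  # sites x treatments x horizons x timepoints
  expect_true(all(colSums(unclass(lab$dna_t24h)) > 0))
  # dry burns hot, moist burns cool
  expect_true(all(s$max_temp_C[s$treatment == "moist_burn"] < 50))
  expect_true(mean(s$max_temp_C[s$treatment == "dry_burn"] > 50) > 0.7)
  # RNA table pairs the 24-h DNA samples
  expect_setequal(colnames(lab$rna_t24h),
                  s$sample_id[s$timepoint == "t24h"])
  # trait sets disjoint and sized as configured
  tr <- lab$truth$traits
  expect_equal(lengths(tr[c("survivor", "fast_grower", "postfire_affinity")]),
               c(survivor = 8, fast_grower = 12, postfire_affinity = 8))
  expect_equal(anyDuplicated(unlist(tr)), 0)
})

test_that("null spike leaves trait taxa balanced across contrast arms", {
  cfg <- sim_config(seed = 6, n_sites = 12, n_taxa = 60,
                    spike_log2fc = c(survivor = 0, fast_grower = 0,
                                     postfire_affinity = 0))
  lab <- generate_lab_dataset(cfg)
  s <- lab$samples
  rel <- relative_abundance(lab$dna_t24h)
  burned <- s$sample_id[s$timepoint == "t24h" & s$treatment != "unburned"]
  ctrl <- s$sample_id[s$timepoint == "t24h" & s$treatment == "unburned"]
  fg <- lab$truth$traits$survivor
  ratio <- log2(mean(rel[fg, burned]) / mean(rel[fg, ctrl]))
  expect_lt(abs(ratio), 0.3)
})

test_that("spiked fast growers show the generating fold change empirically", {
  cfg <- sim_config(seed = 9, n_taxa = 200, n_fastgrowers = 10,
                    library_size_mean = 50000,
                    spike_log2fc = c(survivor = 3, fast_grower = 3,
                                     postfire_affinity = 3))
  lab <- generate_lab_dataset(cfg)
  s <- lab$samples
  burned5 <- s$sample_id[s$timepoint == "t5wk" & s$treatment != "unburned"]
  burned24 <- s$sample_id[s$timepoint == "t24h" & s$treatment != "unburned"]
  fg <- lab$truth$traits$fast_grower
  r5 <- relative_abundance(lab$dna_t5wk)[fg, burned5]
  r24 <- relative_abundance(lab$dna_t24h)[fg, burned24]
  # spikes renormalize the whole composition; compare against the realized
  # mean-model ratio rather than the nominal 2^3
  expect_lt(abs(log2(mean(r5) / mean(r24)) - 3) , 0.45)
})

test_that("noiseless flux series equal the analytic two-pool curve", {
  cfg <- sim_config(seed = 2, n_sites = 3, flux_noise_cv = 0, decay_param_cv = 0)
  fx <- generate_flux_dataset(cfg)
  tr <- fx$truth
  for (id in names(fx$series)) {
    p <- tr[tr$sample_id == id, ]
    s <- fx$series[[id]]
    expect_equal(s$flux, two_pool_flux(p$M1, p$k1, p$k2, s$time), tolerance = 1e-12)
  }
  # flux at t = 0 is M1 k1 + M2 k2
  p <- tr[1, ]
  expect_equal(fx$series[[p$sample_id]]$flux[1], p$M1 * p$k1 + (1 - p$M1) * p$k2)
})

test_that("integrated flux matches quadrature of the analytic curve", {
  M1 <- 0.096; k1 <- 0.0036; k2 <- 0.0013
  closed <- cumulative_mineralized(M1, k1, k2, 35)
  quad <- integrate(function(t) two_pool_flux(M1, k1, k2, t), 0, 35,
                    rel.tol = 1e-10)$value
  expect_equal(closed, quad, tolerance = 1e-8)
})

test_that("field dataset hits the designed lab-match fraction and strata", {
  cfg <- sim_config(seed = 5, n_sites = 4, n_taxa = 40, n_survivors = 4,
                    n_fastgrowers = 5, n_affinity = 4, n_relic = 2)
  lab <- generate_lab_dataset(cfg)
  fld <- generate_field_dataset(cfg, lab$taxa, lab$truth)
  mt <- match_taxa(lab$taxa, fld$taxa)
  expect_equal(mt$match_fraction, 0.8)
  # full-overlap variant
  cfg1 <- sim_config(seed = 5, n_sites = 4, n_taxa = 40, n_survivors = 4,
                     n_fastgrowers = 5, n_affinity = 4, n_relic = 2,
                     field_match_fraction = 1)
  fld1 <- generate_field_dataset(cfg1, lab$taxa, lab$truth)
  expect_equal(match_taxa(lab$taxa, fld1$taxa)$match_fraction, 1)
  # every burned stratum has matched unburned samples at severity 0
  s <- fld$samples
  strat <- interaction(s$vegetation, s$horizon, s$years_post_fire)
  for (st in unique(strat[s$treatment != "unburned"]))
    expect_true(any(s$treatment == "unburned" & strat == st &
                      s$burn_severity_index == 0))
})

test_that("trait-group abundance rises with severity at the configured slope", {
  cfg <- sim_config(seed = 12)
  lab <- generate_lab_dataset(cfg)
  fld <- generate_field_dataset(cfg, lab$taxa, lab$truth)
  rel <- relative_abundance(fld$table)
  s <- fld$samples
  y1 <- s$years_post_fire == 1
  fg <- lab$truth$traits$fast_grower
  tot <- colSums(rel[fg, , drop = FALSE])
  slope <- coef(lm(tot[y1] ~ s$burn_severity_index[y1]))[[2]]
  expect_lt(abs(slope - cfg$severity_slope_y1[["fast_grower"]]), 0.012)
})
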