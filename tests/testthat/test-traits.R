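make_core_meta <- function(temps) {
  # one site per named burned core plus its control, organic horizon, t24h
  rows <- lapply(names(temps), function(core) {
    site <- paste0("site_", core)
    rbind(
      data.frame(sample_id = core, site_id = site, treatment = "dry_burn",
                 horizon = "organic", timepoint = "t24h", inoculation = "none",
                 pH = 5, max_temp_C = temps[[core]], vegetation = "pine",
                 years_post_fire = NA_real_, burn_severity_index = NA_real_,
                 qpcr_total_copies_per_g = NA_real_),
      data.frame(sample_id = paste0(core, "_ctrl"), site_id = site,
                 treatment = "unburned", horizon = "organic",
                 timepoint = "t24h", inoculation = "none", pH = 5,
                 max_temp_C = NA_real_, vegetation = "pine",
                 years_post_fire = NA_real_, burn_severity_index = NA_real_,
                 qpcr_total_copies_per_g = NA_real_))
  })
  do.call(rbind, rows)
}

test_that("burn-exposure selection keeps hot cores and their controls", {
  meta <- make_core_meta(c(coreA = 45, coreB = 600))
  kept <- select_burn_exposed(meta)
  expect_setequal(kept$sample_id, c("coreB", "coreB_ctrl"))
  # exactly 50 C is excluded: the threshold is strict
  meta50 <- make_core_meta(c(coreC = 50))
  expect_equal(nrow(select_burn_exposed(meta50)), 0)
  # missing temperature on a burned core is an error
  metaNA <- make_core_meta(c(coreD = NA_real_))
  expect_error(select_burn_exposed(metaNA), "missing max_temp_C")
})

test_that("cool moist burns are excluded wholesale", {
  lab <- lab_fixture()
  kept <- select_burn_exposed(lab$samples)
  expect_equal(sum(kept$treatment == "moist_burn"), 0)
  expect_gt(sum(kept$treatment == "dry_burn"), 0)
})

test_that("viability ratio keeps the boundary and excludes relic signals", {
  taxa <- c("a", "b", "c")
  dna <- count_table(cmat(c(20L, 20L, 40L, 40L, 40L, 40L),
                          taxa, c("s1", "s2")), "DNA")
  # a: RNA == DNA relabund (ratio 1, kept); b: DNA (0.02,0.04)-like halved in
  # RNA (ratio 0.5, dropped); c: absent from RNA (ratio 0, dropped)
  rna <- count_table(cmat(c(20L, 20L, 20L, 20L, 0L, 0L),
                          taxa, c("s1", "s2")), "RNA")
  # relabund DNA: a = .2, b = .4, c = .4 ; RNA: a = .5, b = .5, c = 0
  viable <- viability_filter(dna, rna, c("s1", "s2"))
  expect_true("a" %in% viable)
  expect_false("c" %in% viable)
  # hand-computed ratio-0.5 case on dedicated table
  dna2 <- count_table(cmat(c(2L, 4L, 98L, 96L), c("x", "rest"),
                           c("s1", "s2")), "DNA")
  rna2 <- count_table(cmat(c(1L, 2L, 99L, 98L), c("x", "rest"),
                           c("s1", "s2")), "RNA")
  expect_false("x" %in% viability_filter(dna2, rna2, c("s1", "s2")))
  # missing paired RNA library is an error
  expect_error(viability_filter(dna, rna[, "s1", drop = FALSE], c("s1", "s2")),
               "paired RNA")
})

test_that("effect-size floor drops responses below mean minus sd", {
  res <- data.frame(taxon_id = letters[1:5], log2fc = 1:5)
  kept <- effect_size_filter(res)
  expect_equal(kept$log2fc, 2:5)         # threshold 3 - sqrt(2.5) = 1.4189
  same <- data.frame(taxon_id = letters[1:4], log2fc = rep(2, 4))
  expect_equal(nrow(effect_size_filter(same)), 4)
  one <- data.frame(taxon_id = "a", log2fc = 0.1)
  expect_identical(effect_size_filter(one), one)
  # monotone: output rows are always a subset of input rows
  set.seed(2)
  for (i in 1:10) {
    r <- data.frame(taxon_id = seq_len(8), log2fc = rnorm(8, 2))
    expect_true(all(effect_size_filter(r)$taxon_id %in% r$taxon_id))
  }
})

test_that("trait contrasts recover spiked taxa and respect the filters", {
  lab <- lab_fixture()
  tabs <- lab[c("dna_t24h", "rna_t24h", "dna_t5wk", "dna_t6mo")]
  truth <- lab$truth$traits
  res <- lapply(c(survivor = "survivor", fast_grower = "fast_grower",
                  postfire_affinity = "postfire_affinity"),
                function(tr) call_trait(tr, tabs, lab$samples))
  # deterministic: rerun matches
  expect_identical(res$survivor,
                   call_trait("survivor", tabs, lab$samples))
  for (tr in names(res)) {
    called <- unique(res[[tr]]$taxon_id)
    tp <- length(intersect(called, truth[[tr]]))
    expect_gte(tp / length(truth[[tr]]), 0.6)
    expect_gte(tp / max(1, length(called)), 0.8)
  }
  # relic decoys are DNA-enriched but dead: never called as survivors
  expect_length(intersect(res$survivor$taxon_id, lab$truth$dead_taxa), 0)
  # every call passed the significance gate
  for (tr in names(res))
    expect_true(all(res[[tr]]$q_value < 0.05 & res[[tr]]$log2fc > 0))
  # catalogue union keeps per-trait provenance and multi-trait entries
  cat <- build_catalogue(res$survivor, res$fast_grower, res$postfire_affinity)
  expect_true(all(lengths(cat$entries) >= 1))
  expect_setequal(unique(cat$provenance$trait),
                  names(res)[vapply(res, nrow, 1L) > 0])
  expect_setequal(trait_taxa(cat, "fast_grower"), unique(res$fast_grower$taxon_id))
})

test_that("catalogue assembly unions traits per taxon", {
  a <- data.frame(taxon_id = "t1", horizon = "organic", log2fc = 2,
                  se_log2fc = 0.1, p_value = 0.001, q_value = 0.01)
  b <- data.frame(taxon_id = c("t1", "t2"), horizon = "mineral",
                  log2fc = c(3, 2.5), se_log2fc = 0.1, p_value = 0.001,
                  q_value = 0.01)
  cat <- build_catalogue(survivor = a, fast_grower = b)
  expect_setequal(cat$entries$t1, c("fast_grower", "survivor"))
  expect_identical(cat$entries$t2, "fast_grower")
  empty <- build_catalogue()
  expect_length(empty$entries, 0)
})

test_that("missing required tables fail with the contrast named", {
  lab <- lab_fixture()
  tabs <- lab[c("dna_t24h", "rna_t24h")]
  expect_error(call_trait("fast_grower", tabs, lab$samples), "fast_grower")
  expect_error(call_trait("postfire_affinity", tabs, lab$samples),
               "postfire_affinity")
})
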