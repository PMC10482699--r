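test_that("taxon matching is exact on sequences and flags duplicates", {
  lab <- data.frame(taxon_id = c("l1", "l2"),
                    sequence = c(strrep("ACGT", 62), strrep("GCTA", 62)))
  fld <- data.frame(taxon_id = c("f1", "f2"),
                    sequence = c(strrep("ACGT", 62),
                                 sub("^G", "T", strrep("GCTA", 62))))
  mt <- match_taxa(lab, fld)
  expect_equal(mt$map$field_taxon_id, "f1")      # one-mismatch stays unmatched
  expect_equal(mt$n_unmatched_lab, 1)
  expect_equal(mt$match_fraction, 0.5)
  dup <- rbind(lab, data.frame(taxon_id = "l3", sequence = lab$sequence[1]))
  expect_error(match_taxa(dup, fld), "duplicate sequences")
})

test_that("copy-number normalization converts gene to cell proportions", {
  ct <- count_table(cmat(c(10L, 30L), c("a", "b"), "s1"), "DNA")
  taxa <- data.frame(taxon_id = c("a", "b"), copy_number = c(1, 3))
  expect_equal(unname(copy_number_normalize(ct, taxa)[, 1]), c(0.5, 0.5))
  # equal copies: identity on relative abundances
  taxa$copy_number <- c(2, 2)
  expect_equal(copy_number_normalize(ct, taxa), relative_abundance(ct))
  # single taxon is always 1
  ct1 <- count_table(cmat(5L, "a", "s1"), "DNA")
  expect_equal(unname(copy_number_normalize(ct1, taxa[1, ])[, 1]), 1)
  taxa$copy_number <- c(0, 3)
  expect_error(copy_number_normalize(ct, taxa), "positive")
})

test_that("community-weighted mean copy number is the abundance-weighted mean", {
  taxa <- data.frame(taxon_id = c("a", "b"), copy_number = c(1, 3))
  expect_equal(weighted_mean_copy_number(c(a = 0.5, b = 0.5), taxa), 2)
  taxa3 <- data.frame(taxon_id = c("a", "b"), copy_number = c(3, 3))
  expect_equal(weighted_mean_copy_number(c(a = 0.25, b = 0.75), taxa3), 3)
  expect_equal(weighted_mean_copy_number(c(a = 1), data.frame(
    taxon_id = "a", copy_number = 4.2)), 4.2)
})

test_that("absolute abundance scales by the qPCR total", {
  expect_equal(absolute_abundance(0.25, 1e8), 2.5e7)
  expect_equal(absolute_abundance(0, 1e8), 0)
  expect_true(is.na(absolute_abundance(0.25, NA)))
})

test_that("bray-curtis behaves as a dissimilarity on compositions", {
  taxa <- c("a", "b", "c")
  mk_samples <- function(ids, tr) data.frame(
    sample_id = ids, site_id = ids, treatment = tr, horizon = "organic",
    timepoint = "field", inoculation = "none", pH = 5, max_temp_C = NA,
    vegetation = "pine", years_post_fire = 1,
    burn_severity_index = ifelse(tr == "unburned", 0, 3),
    qpcr_total_copies_per_g = NA)
  # columns: b1 = (2,2,0); u1 = (0,2,2) the hand case (BC 0.5); u2 identical
  # to b1 (BC 0); mean 0.25
  ct <- count_table(cmat(c(2L, 0L, 2L, 2L, 2L, 2L, 0L, 2L, 0L), taxa,
                         c("b1", "u1", "u2")), "DNA")
  s <- rbind(mk_samples("b1", "dry_burn"), mk_samples(c("u1", "u2"), "unburned"))
  bc <- bray_curtis_to_unburned(ct, s)
  expect_equal(bc$mean_bray_curtis, 0.25)
  # disjoint supports -> 1
  ct2 <- count_table(cmat(c(5L, 0L, 3L, 0L, 0L, 7L), taxa, c("b1", "u1")), "DNA")
  s2 <- rbind(mk_samples("b1", "dry_burn"), mk_samples("u1", "unburned"))
  expect_equal(bray_curtis_to_unburned(ct2, s2)$mean_bray_curtis, 1)
  # missing stratum errors with the stratum listed
  s3 <- s2; s3$years_post_fire[2] <- 5
  expect_error(bray_curtis_to_unburned(ct2, s3), "stratum")
})

test_that("the dissimilarity backend agrees with the metric definition", {
  set.seed(31)
  for (i in 1:15) {
    x <- rgamma(8, 1); x <- x / sum(x)
    y <- rgamma(8, 1); y <- y / sum(y)
    d <- unname(as.matrix(vegan::vegdist(rbind(x, y), "bray"))[1, 2])
    expect_equal(d, bc_oracle(x, y), tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
  }
  x <- c(0.2, 0.3, 0.5)
  expect_equal(unname(as.matrix(vegan::vegdist(rbind(x, x), "bray"))[1, 2]), 0)
})

test_that("trait totals use set semantics for multi-trait taxa", {
  ct <- count_table(cmat(c(10L, 90L), c("f_multi", "f_rest"), "s1"), "DNA")
  catalogue <- build_catalogue(
    survivor = data.frame(taxon_id = "lab1", horizon = "organic", log2fc = 2,
                          se_log2fc = 0.1, p_value = 1e-4, q_value = 1e-3),
    fast_grower = data.frame(taxon_id = "lab1", horizon = "organic", log2fc = 3,
                             se_log2fc = 0.1, p_value = 1e-4, q_value = 1e-3))
  match <- list(map = data.frame(lab_taxon_id = "lab1", field_taxon_id = "f_multi"))
  samples <- data.frame(sample_id = "s1", years_post_fire = 1,
                        burn_severity_index = 2, qpcr_total_copies_per_g = 1e8)
  taxa <- data.frame(taxon_id = c("f_multi", "f_rest"), copy_number = c(2, 2))
  rec <- trait_total_abundance(ct, catalogue, match, samples, taxa)
  get <- function(tr) rec$total_relative_abundance[rec$trait == tr]
  expect_equal(get("survivor"), 0.1)
  expect_equal(get("fast_grower"), 0.1)
  expect_equal(get("any_trait"), 0.1)            # counted once, not twice
  expect_equal(get("postfire_affinity"), 0)
  expect_equal(rec$absolute_abundance[rec$trait == "survivor"], 0.1 * 1e8)
})

test_that("severity regression recovers exact printed-line fixtures", {
  x <- rep(seq(0.1, 0.9, length.out = 8), 2)
  year <- rep(c(1, 5), each = 8)
  y <- ifelse(year == 1, -0.34 + 0.53 * x, -0.04 + 0.10 * x)
  rec <- data.frame(trait = "any_trait", total_relative_abundance = y,
                    burn_severity_index = x, years_post_fire = year)
  # R warns "essentially perfect fit" on exact data; that is the point here
  fit <- suppressWarnings(severity_regression(rec))
  expect_false(fit$interaction_dropped)
  expect_equal(unname(fit$intercepts[["1"]]), -0.34, tolerance = 1e-8)
  expect_equal(unname(fit$slopes[["1"]]), 0.53, tolerance = 1e-8)
  expect_equal(unname(fit$intercepts[["5"]]), -0.04, tolerance = 1e-8)
  expect_equal(unname(fit$slopes[["5"]]), 0.10, tolerance = 1e-8)
})

test_that("severity regression drops a null interaction and flags degeneracy", {
  set.seed(14)
  x <- runif(40, 0, 5); year <- rep(c(1, 5), 20)
  rec <- data.frame(trait = "survivor",
                    total_relative_abundance = 0.05 + rnorm(40, 0, 1e-4),
                    burn_severity_index = x, years_post_fire = year)
  fit <- severity_regression(rec)
  expect_true(fit$interaction_dropped)
  expect_lt(max(abs(fit$slopes)), 1e-4)
  # collinear predictor (constant within the model) is a named error
  rec$burn_severity_index <- ifelse(year == 1, 1, 2)
  expect_error(severity_regression(rec), "collinear")
  expect_error(severity_regression(rec[rec$years_post_fire == 1, ]),
               "both year groups")
})

test_that("interaction calibration matches the generating year contrast", {
  # equal slopes across years: interaction should usually be dropped;
  # strongly different slopes: retained
  drop_eq <- 0; keep_diff <- 0; nseed <- 6
  for (seed in seq_len(nseed)) {
    cfg_eq <- sim_config(seed = seed, n_sites = 4, n_taxa = 60,
                         severity_slope_y5 = c(survivor = 0.008,
                                               fast_grower = 0.035,
                                               postfire_affinity = 0.010))
    lab <- generate_lab_dataset(cfg_eq)
    fld <- generate_field_dataset(cfg_eq, lab$taxa, lab$truth)
    rel <- relative_abundance(fld$table)
    fg <- lab$truth$traits$fast_grower
    rec <- data.frame(trait = "fast_grower",
                      total_relative_abundance = colSums(rel[fg, , drop = FALSE]),
                      burn_severity_index = fld$samples$burn_severity_index,
                      years_post_fire = fld$samples$years_post_fire)
    drop_eq <- drop_eq + severity_regression(rec)$interaction_dropped

    cfg_diff <- sim_config(seed = seed, n_sites = 4, n_taxa = 60)
    lab2 <- generate_lab_dataset(cfg_diff)
    fld2 <- generate_field_dataset(cfg_diff, lab2$taxa, lab2$truth)
    rel2 <- relative_abundance(fld2$table)
    fg2 <- lab2$truth$traits$fast_grower
    rec2 <- data.frame(trait = "fast_grower",
                       total_relative_abundance = colSums(rel2[fg2, , drop = FALSE]),
                       burn_severity_index = fld2$samples$burn_severity_index,
                       years_post_fire = fld2$samples$years_post_fire)
    keep_diff <- keep_diff + !severity_regression(rec2)$interaction_dropped
  }
  expect_gte(drop_eq, nseed - 1)
  expect_gte(keep_diff, nseed - 1)
})
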