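test_that("cohort simulation is reproducible and honours the design", {
  cfg <- small_cohort_config(seed = 21)
  s1 <- simulate_cohort(cfg, bayes_mc = 0)
  s2 <- simulate_cohort(cfg, bayes_mc = 0)
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(as.data.frame(s1$metadata), as.data.frame(s2$metadata))
  expect_true(ape::all.equal.phylo(s1$tree, s2$tree))
  md <- s1$metadata
  expect_equal(nrow(md), 2 * (20 + 8))
  expect_equal(sum(md$set == "discovery"), 40)
  expect_equal(sum(md$group == "case"), 28)
  # pairing invariants hold by construction and pass validation
  expect_s3_class(sample_metadata(as.data.frame(md)), "sample_metadata")
  # truth lists exactly the spiked genera
  expect_setequal(s1$truth$spiked$genus,
                  c(cfg$case_enriched$genus, cfg$control_enriched$genus))
  # tree covers all genera with positive branch lengths
  expect_setequal(s1$tree$tip.label, colnames(s1$table))
  expect_true(all(s1$tree$edge.length >= 0))
})

test_that("per-sample depths track the configured mean", {
  sim <- simulate_cohort(cohort_config(seed = 5, n_genera = 80), bayes_mc = 0)
  d <- sample_depths(sim$table)
  expect_equal(length(d), 196)
  expect_lt(abs(mean(d) / 63218 - 1), 0.05)
})

test_that("spiked genera shift in the stated direction", {
  ok <- vapply(1:6, function(s) {
    sim <- simulate_cohort(small_cohort_config(seed = 400 + s), bayes_mc = 0)
    ra <- relative_abundance(sim$table)
    case <- sim$metadata$group == "case"
    all(vapply(seq_len(nrow(sim$truth$spiked)), function(i) {
      g <- sim$truth$spiked$genus[i]
      d <- mean(ra[case, g]) - mean(ra[!case, g])
      (d > 0) == (sim$truth$spiked$direction[i] == "case")
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 5 / 6)
})

test_that("pair effect induces within-pair correlation, and only then", {
  icc_of <- function(pair_sd, seed) {
    sim <- simulate_cohort(
      null_cohort_config(seed = seed, n_genera = 40, pair_effect_sd = pair_sd),
      bayes_mc = 0)
    la <- log(relative_abundance(sim$table) + 1e-6)
    pid <- sim$metadata$pair_id
    mean(vapply(seq(2, 40, 2), function(j) {
      a <- la[seq(1, nrow(la), 2), j]; b <- la[seq(2, nrow(la), 2), j]
      stats::cor(a, b)
    }, numeric(1)))
  }
  expect_gt(icc_of(0.8, 3), 0.15)
  expect_lt(abs(icc_of(0, 3)), 0.1)
})

test_that("clinical coupling hits its Spearman targets on average", {
  cfg <- cohort_config(seed = 1)
  tc <- cfg$taxon_clinical_corr
  res <- vapply(1:6, function(s) {
    sim <- simulate_cohort(cohort_config(seed = 500 + s), bayes_mc = 0)
    ra <- relative_abundance(sim$table)
    vapply(seq_len(nrow(tc)), function(i)
      spearman_cor(ra[, tc$genus[i]], sim$metadata[[tc$index[i]]])$rho,
      numeric(1))
  }, numeric(nrow(tc)))
  expect_true(all(abs(rowMeans(res) - tc$rho) < 0.08))
})

test_that("infeasible couplings and malformed configs are rejected", {
  expect_error(cohort_config(taxon_clinical_corr = data.frame(
    genus = "Eisenbergiella", index = "FGB", rho = 1.2)), "rho")
  expect_error(cohort_config(taxon_clinical_corr = data.frame(
    genus = c("Eisenbergiella", "Tyzzerella_4", "Parabacteroides"),
    index = "FGB", rho = c(0.9, 0.9, 0.9))), "infeasible")
  expect_error(cohort_config(n_genera = 10), "n_genera")
})

test_that("Bayes AUC estimate: null, separable limit, and stability", {
  null_ba <- estimate_bayes_auc(null_cohort_config(n_genera = 40),
                                n_mc = 10000, seed = 1)
  expect_lt(abs(null_ba$auc - 0.5), 0.02)
  # an extreme spike on a near-noiseless genus approaches separability
  sep <- cohort_config(n_genera = 40, genus_sd = 0.05, pair_effect_sd = 0,
                       case_enriched = data.frame(genus = "Eisenbergiella",
                                                  rank = 3L, log2fc = 10),
                       control_enriched = data.frame(genus = character(),
                                                     rank = integer(),
                                                     log2fc = numeric()),
                       taxon_clinical_corr = data.frame(genus = character(),
                                                        index = character(),
                                                        rho = numeric()))
  expect_gt(estimate_bayes_auc(sep, n_mc = 10000, seed = 2)$auc, 0.99)
  # self-consistency across seeds within Monte-Carlo error
  b1 <- estimate_bayes_auc(small_cohort_config(), n_mc = 10000, seed = 3)
  b2 <- estimate_bayes_auc(small_cohort_config(), n_mc = 10000, seed = 4)
  expect_lt(abs(b1$auc - b2$auc), 4 * (b1$se + b2$se) + 0.01)
  expect_error(estimate_bayes_auc(small_cohort_config(), n_mc = 100),
               "10,000")
})
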