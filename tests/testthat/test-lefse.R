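test_that("Kruskal-Wallis: hand rank oracle, ties, and degenerate input", {
  out <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$H, 3.857143, tolerance = 1e-6)  # hand rank arithmetic
  expect_equal(out$p, stats::pchisq(out$H, 1, lower.tail = FALSE))
  # tie-corrected H agrees with the stats oracle
  set.seed(3)
  for (i in 1:20) {
    v <- sample(1:5, 14, replace = TRUE)
    g <- rep(c("a", "b"), 7)
    ref <- stats::kruskal.test(v, factor(g))
    mine <- kruskal_wallis(v, g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))$p, 1)
})

test_that("Kruskal-Wallis null p-values are approximately uniform", {
  set.seed(9)
  ps <- replicate(500, kruskal_wallis(stats::rnorm(60),
                                      rep(c("a", "b"), 30))$p)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 1e-3)
})

test_that("LDA effect size: nulls score ~0, strong spikes clear the cutoff", {
  set.seed(1)
  n <- 40
  g <- rep(c("case", "control"), each = n / 2)
  # a constant feature scores exactly 0 (floored log10)
  X <- cbind(flat = rep(2.5e5, n),
             matrix(stats::runif(n * 3, 2e5, 3e5), n, 3))
  colnames(X)[2:4] <- paste0("f", 1:3)
  rownames(X) <- paste0("s", 1:n)
  X <- X / rowSums(X) * 1e6
  X[, "flat"] <- 2.5e5  # keep it exactly constant after rescaling
  es <- lda_effect_size(X, g, seed = 5)
  expect_equal(es$lda_score[es$feature_id == "flat"], 0)
  # one feature at ~1e5 vs ~1e3 per million: significant, right direction
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    spike <- ifelse(g == "case", 1e5, 1e3) * stats::runif(n, 0.8, 1.2)
    M <- cbind(spike = spike, matrix(2.2e5, n, 4))
    M <- M / rowSums(M) * 1e6
    colnames(M) <- c("spike", paste0("f", 1:4))
    rownames(M) <- paste0("s", 1:n)
    es2 <- lda_effect_size(M, g, seed = s)
    es2$lda_score[1] >= 2 && es2$enriched_group[1] == "case"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("lefse combines the screen and the score with both cutoffs", {
  sim <- simulate_cohort(small_cohort_config(seed = 2), bayes_mc = 0)
  disc <- sim$metadata$set == "discovery"
  tb <- otu_table(unclass(sim$table)[disc, , drop = FALSE])
  res <- lefse(tb, sim$metadata$group[disc], seed = 4)
  expect_s3_class(res, "effect_size_result")
  expect_true(all(res$kw_p < 0.05))
  expect_identical(res$significant, res$kw_p < 0.05 & res$lda_score >= 2)
  expect_true(!is.unsorted(rev(abs(res$lda_score))))
  # enrichment direction matches the raw mean difference on significant hits
  ra <- relative_abundance(tb)
  for (i in which(res$significant)) {
    f <- res$feature_id[i]
    d <- mean(ra[sim$metadata$group[disc] == "case", f]) -
         mean(ra[sim$metadata$group[disc] == "control", f])
    expect_equal(res$enriched_group[i], if (d >= 0) "case" else "control")
  }
  # spiked genera are recovered with the right direction (small cohort:
  # n = 20/20, so power is partial; paper-scale recovery is tested in
  # test-acceptance.R)
  truth <- sim$truth$spiked
  hit <- res[res$significant & res$feature_id %in% truth$genus, ]
  expect_gte(nrow(hit), 3)
  expect_identical(hit$enriched_group,
                   truth$direction[match(hit$feature_id, truth$genus)])
  # empty table -> empty result
  e <- lefse(otu_table(matrix(integer(0), 2, 0,
                              dimnames = list(c("s1", "s2"), character(0)))),
             c("case", "control"))
  expect_equal(nrow(e), 0)
})

test_that("lefse scores are seed-reproducible and scale-invariant", {
  sim <- simulate_cohort(small_cohort_config(seed = 6), bayes_mc = 0)
  disc <- sim$metadata$set == "discovery"
  tb <- otu_table(unclass(sim$table)[disc, , drop = FALSE])
  g <- sim$metadata$group[disc]
  r1 <- lefse(tb, g, seed = 42)
  r2 <- lefse(tb, g, seed = 42)
  expect_identical(r1, r2)
  # multiplying one sample's counts by 10 changes nothing after rescaling
  m <- unclass(tb); m[3, ] <- m[3, ] * 10L
  r3 <- lefse(otu_table(m), g, seed = 42)
  expect_equal(r3$lda_score, r1$lda_score, tolerance = 1e-9)
})

test_that("lefse false-positive rate on null data stays near nominal", {
  set.seed(31)
  frac <- vapply(1:20, function(s) {
    tb <- make_lognormal_counts(40, 40, rho = 0, depth = 30000, seed = 100 + s)
    g <- rep(c("case", "control"), 20)
    res <- lefse(tb, g, seed = s)
    sum(res$significant) / 40
  }, numeric(1))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 2 * se + 1e-9)
})
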