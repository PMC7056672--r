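# Shared fixture builders; everything is generated in code, no data files.

make_table <- function(n_samples, n_features, lambda = 8, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  m <- withr_seed(matrix(stats::rpois(n_samples * n_features, lambda),
                         n_samples, n_features))
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("f", seq_len(n_features)))
  otu_table(m)
}

# tiny metadata block: n pairs, case/control, one clinical column
make_metadata <- function(n_pairs, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = paste0("s", seq_len(2 * n_pairs)),
             group = rep(c("case", "control"), n_pairs),
             pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), each = 2),
             set = "discovery",
             FGB = stats::rnorm(2 * n_pairs, 4.7, 0.3),
             stringsAsFactors = FALSE)
}

# log-normal compositional counts with an optional planted basis correlation
# between features 1 and 2 (used by the SparCC tests)
make_lognormal_counts <- function(n, d, rho = 0, depth = 50000, seed = 1,
                                  mu_sd = 1) {
  set.seed(seed)
  mu <- stats::rnorm(d, 0, mu_sd)
  L <- matrix(stats::rnorm(n * d), n, d)
  if (rho != 0) L[, 2] <- rho * L[, 1] + sqrt(1 - rho^2) * L[, 2]
  lam <- sweep(L, 2, mu, "+")
  comp <- exp(lam)
  comp <- comp / rowSums(comp)
  cnt <- t(vapply(seq_len(n), function(i)
    as.integer(stats::rmultinom(1, depth, comp[i, ])), integer(d)))
  dimnames(cnt) <- list(paste0("s", seq_len(n)), paste0("f", seq_len(d)))
  otu_table(cnt)
}

# small simulated cohort used by several module tests (fast: 60 genera)
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(
    n_pairs_discovery = 20, n_pairs_validation = 8, n_genera = 60,
    depth_mean = 60000, seed = seed,
    case_enriched = data.frame(genus = c("Eisenbergiella", "Tyzzerella_4"),
                               rank = c(8L, 12L), log2fc = 1),
    control_enriched = data.frame(
      genus = c("Parabacteroides", "Dialister", "Megasphaera", "Parasutterella"),
      rank = c(6L, 10L, 14L, 18L), log2fc = 1),
    taxon_clinical_corr = data.frame(genus = "Eisenbergiella", index = "FGB",
                                     rho = 0.19),
    ...)
}
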