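#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square p-value (`k - 1` df; 1 df for the usual
#' two-group screen).  An all-tied input returns `H = 0`, `p = 1` by
#' convention rather than erroring, so constant features flow through the
#' differential-abundance screen harmlessly.
#'
#' @param values numeric vector (one feature across samples).
#' @param groups group labels, 2+ levels, each non-empty.
#' @return list `(H, p)`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # H = 3.857
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  if (any(table(g) == 0)) abort_validation("every group must be non-empty")
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(z) length(z) * (mean(z) - (N + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(list(H = 0, p = 1))  # all values identical
  H <- H / corr
  list(H = H, p = stats::pchisq(H, df = nlevels(g) - 1, lower.tail = FALSE))
}

#' Bootstrapped LDA effect size per feature
#'
#' The effect-size half of the LEfSe procedure, restricted to two classes
#' (no subclass stage).  Inputs must already be scaled so each sample sums
#' to 1e6 (counts-per-million); the score cutoff of 2 is only meaningful on
#' that scale.  Per bootstrap round a fraction of each class is resampled,
#' a ridge-regularized linear discriminant is fitted on the standardized
#' features, the discriminant direction is rescaled to unit norm in the raw
#' feature space, and the per-feature effect is
#' `|0.5 * (w_f * (proj_case - proj_control) + (mean_case_f - mean_control_f))|`,
#' i.e. the average of the discriminant-projected and raw group-mean
#' differences.  The final score is `log10(max(mean effect, 1))`, flooring
#' null features at 0 instead of -Inf.
#'
#' @param X samples x features matrix, each row summing to 1e6.
#' @param groups `"case"`/`"control"` labels.
#' @param n_boot bootstrap rounds (default 30).
#' @param subsample_fraction per-class subsampling fraction (default 2/3).
#' @param seed integer seed (scores are reproducible bit-for-bit from it).
#' @return data.frame: `feature_id`, `lda_score`, `enriched_group`.
#' @export
lda_effect_size <- function(X, groups, n_boot = 30, subsample_fraction = 2 / 3,
                            seed = NULL) {
  X <- as.matrix(X)
  case <- as_case_logical(groups)
  idx1 <- which(case); idx0 <- which(!case)
  n1 <- max(2L, floor(length(idx1) * subsample_fraction))
  n0 <- max(2L, floor(length(idx0) * subsample_fraction))
  eff <- matrix(NA_real_, n_boot, ncol(X))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      s1 <- idx1[sample.int(length(idx1), n1)]
      s0 <- idx0[sample.int(length(idx0), n0)]
      Xi <- X[c(s1, s0), , drop = FALSE]
      yi <- rep(c(TRUE, FALSE), c(n1, n0))
      fit <- fit_lda(Xi, yi, allow_collinear = TRUE)
      # back to raw feature space, unit-norm direction
      w_raw <- fit$weights / fit$scale
      nrm <- sqrt(sum(w_raw^2))
      if (nrm == 0) { eff[b, ] <- 0; next }
      w_raw <- w_raw / nrm
      m1 <- colMeans(X[s1, , drop = FALSE])
      m0 <- colMeans(X[s0, , drop = FALSE])
      dproj <- sum(w_raw * (m1 - m0))
      eff[b, ] <- abs(0.5 * (w_raw * dproj + (m1 - m0)))
    }
  })
  mean_eff <- colMeans(eff)
  m1 <- colMeans(X[case, , drop = FALSE])
  m0 <- colMeans(X[!case, , drop = FALSE])
  data.frame(feature_id = colnames(X),
             lda_score = log10(pmax(mean_eff, 1)),
             enriched_group = ifelse(m1 >= m0, "case", "control"),
             stringsAsFactors = FALSE)
}

#' LEfSe-style differential-abundance scoring
#'
#' Two-group biomarker discovery for taxa or pathway tables: a per-feature
#' Kruskal-Wallis screen at `p_cutoff`, then a bootstrapped LDA effect size
#' on the survivors, with `significant = (kw_p < p_cutoff) & (lda_score >=
#' lda_cutoff)`.  Input counts are rescaled internally to per-million.
#'
#' @param table an [otu_table()] (or any samples x features count/abundance
#'   matrix) aggregated to the rank of interest.
#' @param groups `"case"`/`"control"` labels aligned with the rows, or a
#'   [sample_metadata()] matched by sample id.
#' @param p_cutoff Kruskal-Wallis screen cutoff (default 0.05).
#' @param lda_cutoff log10 effect-size cutoff (default 2.0).
#' @param n_boot,subsample_fraction passed to [lda_effect_size()].
#' @param seed integer seed.
#' @return data.frame of class `effect_size_result` with one row per
#'   screen-passing feature, sorted by decreasing `|lda_score|`:
#'   `feature_id`, `kw_p`, `lda_score`, `enriched_group`, `significant`.
#'   Empty (zero-row) when nothing passes the screen.
#' @export
lefse <- function(table, groups, p_cutoff = 0.05, lda_cutoff = 2.0,
                  n_boot = 30, subsample_fraction = 2 / 3, seed = NULL) {
  if (inherits(groups, "sample_metadata"))
    groups <- groups$group[match(rownames(table), groups$sample_id)]
  X <- relative_abundance(table, scale = 1e6)
  empty <- data.frame(feature_id = character(), kw_p = numeric(),
                      lda_score = numeric(), enriched_group = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("effect_size_result", "data.frame")
  if (ncol(X) == 0 || nrow(X) == 0) return(empty)
  kw_p <- apply(X, 2L, function(v) kruskal_wallis(v, groups)$p)
  keep <- which(kw_p < p_cutoff)
  if (!length(keep)) return(empty)
  es <- lda_effect_size(X[, keep, drop = FALSE], groups, n_boot,
                        subsample_fraction, seed)
  out <- data.frame(feature_id = es$feature_id, kw_p = kw_p[keep],
                    lda_score = es$lda_score,
                    enriched_group = es$enriched_group,
                    significant = kw_p[keep] < p_cutoff & es$lda_score >= lda_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$lda_score)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("effect_size_result", "data.frame")
  out
}
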