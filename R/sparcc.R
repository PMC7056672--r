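#' SparCC compositional correlations
#'
#' Infers basis (absolute-abundance) correlations from relative-abundance
#' count data, following the sparse compositional correlation algorithm:
#' per Dirichlet resample of each sample's composition (counts + pseudocount
#' 1), the log-ratio variance matrix `t_ij = var(log x_i / x_j)` is computed
#' and the basis variances are solved from the sparsity-approximated linear
#' system; the most correlated pair above `exclusion_threshold` is then
#' iteratively removed from the system and the solution refined, up to
#' `n_iterations` rounds or `max_excluded_fraction` of all pairs.  The
#' reported correlation matrix is the element-wise median over resamples,
#' clipped to `[-1, 1]`.
#'
#' @param table an [otu_table()] (samples x features), >= 4 features.
#' @param n_iterations exclusion iterations per resample (default 20).
#' @param exclusion_threshold |correlation| above which a pair may be
#'   excluded from the basis-variance system (default 0.1).
#' @param max_excluded_fraction cap on the excluded share of pairs
#'   (default 0.3).
#' @param n_dirichlet_resamples posterior composition draws (default 20).
#' @param seed integer seed.
#' @return list of class `sparcc_result`: `feature_ids`, `corr` (symmetric,
#'   unit diagonal), `pvals` (`NULL` until [sparcc_pvalues()]),
#'   `n_iterations`, `n_resamples`.  Features whose basis variance could
#'   not be resolved are reported in `flagged` with `NA` rows.
#' @export
sparcc_correlations <- function(table, n_iterations = 20,
                                exclusion_threshold = 0.1,
                                max_excluded_fraction = 0.3,
                                n_dirichlet_resamples = 20, seed = NULL) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  d <- ncol(m)
  if (d < 4) abort_validation("SparCC needs at least 4 features")
  cors <- array(NA_real_, c(d, d, n_dirichlet_resamples))
  with_seed(seed, {
    for (r in seq_len(n_dirichlet_resamples)) {
      frac <- dirichlet_fractions(m + 1)
      cors[, , r] <- sparcc_one(log(frac), n_iterations,
                                exclusion_threshold, max_excluded_fraction)
    }
  })
  corr <- apply(cors, c(1, 2), stats::median, na.rm = TRUE)
  corr[!is.finite(corr)] <- NA_real_
  corr <- pmin(pmax(corr, -1), 1)
  diag(corr) <- 1
  dimnames(corr) <- list(colnames(m), colnames(m))
  flagged <- colnames(m)[apply(corr, 1L, function(z) anyNA(z))]
  structure(list(feature_ids = colnames(m), corr = corr, pvals = NULL,
                 n_iterations = n_iterations,
                 n_resamples = n_dirichlet_resamples, flagged = flagged),
            class = "sparcc_result")
}

# Internal: one Dirichlet draw of per-sample compositions (rows of `alpha`).
dirichlet_fractions <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
  g / rowSums(g)
}

# Internal: basis correlations from one log-composition matrix.
# L: samples x features log fractions.
sparcc_one <- function(L, n_iterations, exclusion_threshold,
                       max_excluded_fraction) {
  d <- ncol(L)
  V <- stats::cov(L)
  tmat <- outer(diag(V), diag(V), "+") - 2 * V  # var(log x_i/x_j)
  incl <- matrix(TRUE, d, d); diag(incl) <- FALSE
  n_pairs <- d * (d - 1) / 2
  max_excl <- floor(max_excluded_fraction * n_pairs)
  solve_basis <- function() {
    A <- diag(rowSums(incl)) + incl
    ti <- rowSums(tmat * incl)
    omega <- tryCatch(solve(A, ti), error = function(e) rep(NA_real_, d))
    omega[omega <= 0] <- NA_real_
    rho <- (outer(omega, omega, "+") - tmat) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    rho
  }
  rho <- solve_basis()
  excluded <- 0L
  for (it in seq_len(n_iterations)) {
    cand <- abs(rho)
    cand[!incl | !upper.tri(cand)] <- -Inf
    cand[is.na(cand)] <- -Inf
    top <- which.max(cand)
    if (!is.finite(cand[top]) || cand[top] <= exclusion_threshold) break
    if (excluded >= max_excl) break
    ij <- arrayInd(top, dim(cand))
    incl[ij[1], ij[2]] <- incl[ij[2], ij[1]] <- FALSE
    excluded <- excluded + 1L
    rho <- solve_basis()
  }
  rho
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Two-sided pseudo p-values against a permutation null: each bootstrap
#' round resamples the samples with replacement and independently permutes
#' every feature column (destroying all real association while keeping the
#' marginals), recomputes the SparCC correlation, and the p-value per pair
#' is `(1 + #{|r_null| >= |r_obs|}) / (1 + n_bootstraps)`.
#'
#' @param table the same [otu_table()] the observed result came from.
#' @param observed a [sparcc_correlations()] result.
#' @param n_bootstraps null resamples (>= 20 enforced; default 100).
#' @param n_dirichlet_resamples composition draws inside each null round
#'   (default 5; the null is an ensemble, so fewer inner draws suffice).
#' @param seed integer seed.
#' @return the `sparcc_result` with `pvals` filled in (symmetric, `NA`
#'   diagonal).
#' @export
sparcc_pvalues <- function(table, observed, n_bootstraps = 100,
                           n_dirichlet_resamples = 5, seed = NULL) {
  if (n_bootstraps < 20) abort_validation("need n_bootstraps >= 20")
  m <- unclass(table)
  storage.mode(m) <- "double"
  d <- ncol(m)
  stopifnot(identical(colnames(m), observed$feature_ids))
  robs <- abs(observed$corr)
  count <- matrix(0, d, d)
  with_seed(seed, {
    for (b in seq_len(n_bootstraps)) {
      mb <- m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
      for (j in seq_len(d)) mb[, j] <- mb[sample.int(nrow(mb)), j]
      rownames(mb) <- sprintf("boot_%d", seq_len(nrow(mb)))
      rb <- sparcc_correlations(otu_table(mb), observed$n_iterations,
                                n_dirichlet_resamples = n_dirichlet_resamples,
                                seed = NULL)$corr
      count <- count + (abs(rb) >= robs)
    }
  })
  p <- (1 + count) / (1 + n_bootstraps)
  p <- (p + t(p)) / 2  # count is symmetric up to NA handling; make it exact
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed$corr)
  observed$pvals <- p
  observed$n_bootstraps <- n_bootstraps
  observed
}

#' Build a co-occurrence / co-exclusion edge list
#'
#' @param result a [sparcc_result] with p-values.
#' @param rho_cutoff minimum `|rho|` for an edge (default 0.3).
#' @param p_cutoff maximum p (default 0.05).
#' @return data.frame: `feature_a`, `feature_b`, `rho`, `p`, `sign`
#'   (`"co-occurring"` for positive rho, `"co-excluding"` for negative).
#' @export
build_network <- function(result, rho_cutoff = 0.3, p_cutoff = 0.05) {
  if (is.null(result$pvals)) abort_validation("run sparcc_pvalues() first")
  d <- length(result$feature_ids)
  rows <- list()
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    rho <- result$corr[i, j]; p <- result$pvals[i, j]
    if (is.na(rho) || is.na(p)) next
    if (abs(rho) >= rho_cutoff && p < p_cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_a = result$feature_ids[i], feature_b = result$feature_ids[j],
        rho = rho, p = p,
        sign = if (rho > 0) "co-occurring" else "co-excluding",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(feature_a = character(), feature_b = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
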