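#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected rho computed as the Pearson correlation of mid-ranks, with
#' a two-sided p-value from the `t = rho * sqrt((n-2)/(1-rho^2))`
#' approximation.  Pairs with a missing value in either vector are dropped
#' first (pairwise-complete).
#'
#' @param x,y paired numeric vectors.
#' @return list `(rho, p, n_used)`; `rho = NA` (flagged, with `p = NA`)
#'   when either vector is constant after missing-value removal.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort_validation("need >= 4 complete pairs for Spearman correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_used = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0, n_used = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n_used = n)
}

#' Feature-by-clinical-index Spearman correlation grid
#'
#' All pairwise Spearman correlations between feature abundances (typically
#' relative abundances of the differential genera) and clinical indices,
#' with pairwise-complete missing-value handling.  Unadjusted p-values are
#' reported alongside Benjamini-Hochberg q-values across the whole grid.
#'
#' @param features numeric matrix, samples x features (rownames = sample
#'   ids), or an [otu_table()] (converted to relative abundance).
#' @param indices data.frame of clinical values with a `sample_id` column
#'   (e.g. a [sample_metadata()]), or a numeric matrix with sample rownames.
#' @param index_vars which index columns to use (default: clinical columns).
#' @return long data.frame of class `correlation_grid`: `feature_id`,
#'   `index_name`, `rho`, `p`, `q`, `n_used`; one row per cell, `NA` rho
#'   flagged for constant inputs.
#' @export
correlation_grid <- function(features, indices, index_vars = NULL) {
  if (inherits(features, "otu_table")) features <- relative_abundance(features)
  features <- as.matrix(features)
  if (is.data.frame(indices)) {
    if (is.null(index_vars))
      index_vars <- if (inherits(indices, "sample_metadata"))
        clinical_vars(indices) else
        names(indices)[vapply(indices, is.numeric, logical(1))]
    idm <- as.matrix(indices[index_vars])
    rownames(idm) <- indices$sample_id
  } else {
    idm <- as.matrix(indices)
    if (is.null(index_vars)) index_vars <- colnames(idm)
    idm <- idm[, index_vars, drop = FALSE]
  }
  shared <- intersect(rownames(features), rownames(idm))
  if (!length(shared)) abort_validation("no overlapping samples between tables")
  features <- features[shared, , drop = FALSE]
  idm <- idm[shared, , drop = FALSE]
  grid <- expand.grid(feature_id = colnames(features), index_name = index_vars,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(f, v) {
    unlist(spearman_cor(features[, f], idm[, v]))
  }, grid$feature_id, grid$index_name)
  grid$rho <- res["rho", ]
  grid$p <- res["p", ]
  grid$q <- stats::p.adjust(grid$p, method = "BH")
  grid$n_used <- as.integer(res["n_used", ])
  class(grid) <- c("correlation_grid", "data.frame")
  grid
}
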