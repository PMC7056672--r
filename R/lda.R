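#' Fit a two-class linear discriminant
#'
#' Classic Fisher/Gaussian LDA with pooled within-class covariance.  Features
#' are standardized internally (stored in the model and re-applied at
#' prediction time); a ridge term `1e-6 * trace(S)` is always added to the
#' pooled covariance diagonal for numerical stability.  Exactly collinear
#' inputs (e.g. duplicated columns) are rejected by default, since their
#' weights are meaningless, unless `allow_collinear = TRUE` (used by the
#' effect-size bootstrap, where compositional tables are collinear by
#' construction and the ridge is the documented remedy).
#'
#' @param X numeric matrix, samples x features.
#' @param y labels coercible to `"case"`/`"control"` (logical `TRUE` =
#'   case is also accepted).  Both classes must be present.
#' @param ridge ridge multiplier on `trace(S)` (default 1e-6).
#' @param allow_collinear keep going on rank-deficient pooled scatter.
#' @return list of class `lda_model`: `features`, `center`, `scale`,
#'   `weights` (on the standardized scale), `intercept`; `predict()` returns
#'   discriminant scores, positive score = case.
#' @export
fit_lda <- function(X, y, ridge = 1e-6, allow_collinear = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  case <- as_case_logical(y)
  if (!any(case) || all(case)) abort_validation("both classes must be present")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  m1 <- colMeans(Z[case, , drop = FALSE])
  m0 <- colMeans(Z[!case, , drop = FALSE])
  S <- (crossprod(sweep(Z[case, , drop = FALSE], 2L, m1)) +
        crossprod(sweep(Z[!case, , drop = FALSE], 2L, m0))) / (nrow(Z) - 2)
  if (!allow_collinear) {
    qr_rank <- qr(S, tol = 1e-10)$rank
    if (qr_rank < ncol(S)) {
      dup <- which(duplicated(t(X)))
      hint <- if (length(dup))
        sprintf(" (duplicated column(s): %s)",
                paste(colnames(X)[dup], collapse = ", ")) else ""
      abort_validation(paste0("pooled covariance is singular; collinear features", hint))
    }
  }
  Sr <- S + diag(ridge * sum(diag(S)), ncol(S))
  w <- tryCatch(solve(Sr, m1 - m0),
                error = function(e) abort_validation(
                  "pooled covariance singular even after ridge"))
  b <- -sum(w * (m1 + m0)) / 2
  structure(list(features = colnames(X), center = ctr, scale = scl,
                 weights = as.numeric(w), intercept = b),
            class = "lda_model")
}

# Internal: normalize labels to logical "is case".
as_case_logical <- function(y) {
  if (is.logical(y)) return(y)
  y <- as.character(y)
  if (!all(y %in% c("case", "control")))
    abort_validation("labels must be 'case'/'control' (or logical)")
  y == "case"
}

#' Discriminant scores from a fitted LDA
#' @param object an `lda_model` from [fit_lda()].
#' @param newdata matrix with (at least) the model's feature columns.
#' @param ... unused.
#' @return numeric score vector; positive = classified as case.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) {
    if (!all(object$features %in% colnames(X)) && ncol(X) != length(object$weights))
      abort_validation(sprintf("missing feature(s): %s",
        paste(setdiff(object$features, colnames(X)), collapse = ", ")))
    if (all(object$features %in% colnames(X)))
      X <- X[, object$features, drop = FALSE]
  }
  Z <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  as.numeric(Z %*% object$weights + object$intercept)
}
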