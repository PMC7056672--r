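#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC by Mann-Whitney concordant-pair counting (ties count 1/2), 95 % CI by
#' the DeLong placement-variance method, the full ROC curve, and accuracy /
#' sensitivity / specificity at an operating threshold (Youden-optimal on
#' the curve unless one is supplied; prediction rule: score >= threshold =>
#' case).
#'
#' @param scores numeric classifier scores (larger = more case-like).
#' @param labels `"case"`/`"control"` (or logical case indicator).
#' @param threshold optional frozen operating threshold; default Youden.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`, `curve`
#'   (data.frame `fpr`, `tpr`, `threshold`, starting (0,0) and ending
#'   (1,1)), `threshold`, `accuracy`, `sensitivity`, `specificity`.
#' @export
roc_auc_ci <- function(scores, labels, threshold = NULL, conf_level = 0.95) {
  case <- as_case_logical(labels)
  if (!any(case) || all(case)) abort_validation("both classes must be present")
  x <- scores[case]; y <- scores[!case]
  n1 <- length(x); n0 <- length(y)
  # placements: V10_i = P-hat(x_i > Y), V01_j = P-hat(X > y_j)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
             (if (n0 > 1) stats::var(v01) / n0 else 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(var_auc)
  thr_grid <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr_grid, function(t) mean(x >= t), numeric(1))
  fpr <- vapply(thr_grid, function(t) mean(y >= t), numeric(1))
  curve <- data.frame(fpr = fpr, tpr = tpr, threshold = thr_grid)
  if (is.null(threshold)) {
    best <- which.max(curve$tpr - curve$fpr)
    threshold <- if (is.finite(curve$threshold[best])) curve$threshold[best]
                 else max(scores) + 1
  }
  pred_case <- scores >= threshold
  structure(list(auc = auc,
                 ci_low = max(0, min(ci[1], auc)),
                 ci_high = min(1, max(ci[2], auc)),
                 curve = curve, threshold = threshold,
                 accuracy = mean(pred_case == case),
                 sensitivity = mean(pred_case[case]),
                 specificity = mean(!pred_case[!case])),
            class = "roc_result")
}

#' Leave-one-out cross-validated performance of a feature subset
#'
#' For every sample, a two-class LDA is fitted on the remaining samples
#' using `feature_subset` and the held-out sample is scored; AUC (pair
#' counting) and accuracy (sign rule) are computed over the `n` held-out
#' scores.  Deterministic — no seed involved.  Class means and scatter are
#' downdated per fold rather than refitted, so the loop is O(n d^2).
#'
#' @param X numeric matrix, samples x features.
#' @param y `"case"`/`"control"` labels (or logical).
#' @param feature_subset columns to use (default all).
#' @param ridge ridge multiplier (see [fit_lda()]).
#' @return list `(auc, accuracy, scores)`.
#' @export
loocv_performance <- function(X, y, feature_subset = colnames(X), ridge = 1e-6) {
  case <- as_case_logical(y)
  Xs <- as.matrix(X[, feature_subset, drop = FALSE])
  storage.mode(Xs) <- "double"
  n <- nrow(Xs); d <- ncol(Xs)
  if (n < 10) abort_validation("LOOCV needs n >= 10")
  # global standardization (a fixed affine map; LDA scores are invariant to it)
  ctr <- colMeans(Xs); scl <- apply(Xs, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(Xs, 2L, ctr), 2L, scl, "/")
  n1 <- sum(case); n0 <- n - n1
  if (n1 < 2 || n0 < 2) abort_validation("each class needs >= 2 samples for LOOCV")
  sum1 <- colSums(Z[case, , drop = FALSE])
  sum0 <- colSums(Z[!case, , drop = FALSE])
  m1 <- sum1 / n1; m0 <- sum0 / n0
  S1 <- crossprod(sweep(Z[case, , drop = FALSE], 2L, m1))
  S0 <- crossprod(sweep(Z[!case, , drop = FALSE], 2L, m0))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    zi <- Z[i, ]
    if (case[i]) {
      if (n1 - 1 < 2) { scores[i] <- NA_real_; next }  # class would vanish/degenerate
      m1i <- (sum1 - zi) / (n1 - 1)
      dev <- zi - m1
      S1i <- S1 - (n1 / (n1 - 1)) * tcrossprod(dev)
      S0i <- S0; m0i <- m0; n1i <- n1 - 1; n0i <- n0
    } else {
      if (n0 - 1 < 2) { scores[i] <- NA_real_; next }
      m0i <- (sum0 - zi) / (n0 - 1)
      dev <- zi - m0
      S0i <- S0 - (n0 / (n0 - 1)) * tcrossprod(dev)
      S1i <- S1; m1i <- m1; n0i <- n0 - 1; n1i <- n1
    }
    S <- (S1i + S0i) / (n1i + n0i - 2)
    Sr <- S + diag(ridge * sum(diag(S)), d)
    w <- tryCatch(solve(Sr, m1i - m0i), error = function(e) NULL)
    if (is.null(w)) { scores[i] <- NA_real_; next }
    scores[i] <- sum(w * zi) - sum(w * (m1i + m0i)) / 2
  }
  ok <- is.finite(scores)
  if (!all(ok)) warning(sprintf("%d LOOCV fold(s) skipped", sum(!ok)))
  roc <- roc_auc_ci(scores[ok], case[ok], threshold = 0)
  list(auc = roc$auc, accuracy = mean((scores[ok] >= 0) == case[ok]),
       scores = stats::setNames(scores, rownames(Xs)))
}

#' Greedy forward feature selection with a LOOCV-scored LDA
#'
#' Mirrors the sequential model-building procedure: the single candidate
#' with the best leave-one-out performance enters first; in every later
#' round each remaining candidate is evaluated joined to the current set and
#' the best joins; the returned model is the prefix of that trajectory with
#' the globally best LOOCV performance.  "Performance" is LOOCV AUC with
#' accuracy as tie-break by default (`metric = "accuracy"` swaps the
#' order); remaining ties go to fewer features, then candidate order.
#'
#' @param X samples x features matrix (all candidates present as columns).
#' @param y `"case"`/`"control"` labels.
#' @param candidates candidate feature names (default all columns).
#' @param max_features search depth cap (default 10).
#' @param metric `"auc"` (default) or `"accuracy"` as the primary criterion.
#' @param ridge ridge multiplier for the internal LDA fits.
#' @return list of class `classifier_model`: `selected_features` (ordered),
#'   `lda` (the [fit_lda()] refit on the full data), `score_threshold`
#'   (Youden point of the in-sample discovery scores), `trajectory`
#'   (per-round data.frame: round, feature added, LOOCV auc and accuracy),
#'   `loocv_auc`, `loocv_accuracy`.
#' @export
forward_select <- function(X, y, candidates = colnames(X), max_features = 10,
                           metric = c("auc", "accuracy"), ridge = 1e-6) {
  metric <- match.arg(metric)
  if (!length(candidates)) abort_validation("candidate list is empty")
  if (max_features < 1) abort_validation("max_features must be >= 1")
  missing <- setdiff(candidates, colnames(X))
  if (length(missing))
    abort_validation(sprintf("candidate(s) not in X: %s",
                             paste(missing, collapse = ", ")))
  key <- function(perf) if (metric == "auc") c(perf$auc, perf$accuracy)
                        else c(perf$accuracy, perf$auc)
  selected <- character(0)
  remaining <- candidates
  traj <- data.frame(round = integer(), feature = character(),
                     auc = numeric(), accuracy = numeric(),
                     stringsAsFactors = FALSE)
  for (round in seq_len(min(max_features, length(candidates)))) {
    best <- NULL; best_key <- c(-Inf, -Inf); best_feat <- NA_character_
    for (f in remaining) {
      perf <- loocv_performance(X, y, c(selected, f), ridge = ridge)
      k <- key(perf)
      if (k[1] > best_key[1] + 1e-12 ||
          (abs(k[1] - best_key[1]) <= 1e-12 && k[2] > best_key[2] + 1e-12)) {
        best <- perf; best_key <- k; best_feat <- f
      }
    }
    selected <- c(selected, best_feat)
    remaining <- setdiff(remaining, best_feat)
    traj <- rbind(traj, data.frame(round = round, feature = best_feat,
                                   auc = best$auc, accuracy = best$accuracy,
                                   stringsAsFactors = FALSE))
  }
  prim <- if (metric == "auc") traj$auc else traj$accuracy
  best_len <- which.max(prim)  # first maximum = fewest features on ties
  feats <- traj$feature[seq_len(best_len)]
  lda <- fit_lda(X[, feats, drop = FALSE], y, ridge = ridge,
                 allow_collinear = TRUE)
  scores <- predict(lda, X[, feats, drop = FALSE])
  roc <- roc_auc_ci(scores, y)
  structure(list(selected_features = feats, lda = lda,
                 score_threshold = roc$threshold, trajectory = traj,
                 loocv_auc = traj$auc[best_len],
                 loocv_accuracy = traj$accuracy[best_len]),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %d feature(s) [%s], LOOCV AUC %.3f\n",
              length(x$selected_features),
              paste(x$selected_features, collapse = ", "), x$loocv_auc))
  invisible(x)
}

#' Evaluate a frozen classifier on an external validation set
#'
#' Applies the stored weights and operating threshold with no refitting.
#'
#' @param model a [forward_select()] model.
#' @param X_val samples x features matrix covering the selected features.
#' @param y_val validation labels.
#' @return a [roc_auc_ci()] result at the frozen threshold.
#' @export
evaluate_external <- function(model, X_val, y_val) {
  missing <- setdiff(model$selected_features, colnames(X_val))
  if (length(missing))
    abort_validation(sprintf("validation table is missing feature(s): %s",
                             paste(missing, collapse = ", ")))
  scores <- predict(model$lda, X_val[, model$selected_features, drop = FALSE])
  roc_auc_ci(scores, y_val, threshold = model$score_threshold)
}

#' Combined vs genus-only vs clinical-only models
#'
#' Runs [forward_select()] under three candidate pools and reports discovery
#' (LOOCV) and external-validation performance side by side.
#'
#' @param X,y discovery matrix and labels.
#' @param X_val,y_val validation matrix and labels.
#' @param genus_candidates,clinical_candidates column names of the two pools.
#' @param max_features,metric passed to [forward_select()].
#' @return list with elements `combined`, `genus_only`, `clinical_only`,
#'   each a list `(model, discovery, validation)` where the latter two are
#'   [roc_auc_ci()] results.
#' @export
compare_models <- function(X, y, X_val, y_val, genus_candidates,
                           clinical_candidates, max_features = 10,
                           metric = "auc") {
  pools <- list(combined = c(genus_candidates, clinical_candidates),
                genus_only = genus_candidates,
                clinical_only = clinical_candidates)
  lapply(pools, function(pool) {
    model <- forward_select(X, y, pool, max_features, metric)
    disc <- roc_auc_ci(predict(model$lda,
                               X[, model$selected_features, drop = FALSE]),
                       y, threshold = model$score_threshold)
    list(model = model, discovery = disc,
         validation = evaluate_external(model, X_val, y_val))
  })
}

#' Assemble a classifier design matrix from a table and metadata
#'
#' Genus candidates are relative abundances, log10-transformed with a
#' pseudo-fraction (`log10(p + 1e-6)`), restricted to genera present in at
#' least `min_prevalence` of the given samples; clinical candidates are
#' taken from the metadata as-is.
#'
#' @param table an [otu_table()] (post-rarefaction genus table).
#' @param metadata a [sample_metadata()].
#' @param clinical which clinical columns to include (default all).
#' @param min_prevalence presence fraction cutoff for genera (default 0.1).
#' @param pseudo_fraction added before log10 (default 1e-6).
#' @return list `(X, y, genus_candidates, clinical_candidates, sample_ids)`.
#' @export
design_matrix <- function(table, metadata, clinical = NULL,
                          min_prevalence = 0.1, pseudo_fraction = 1e-6) {
  ids <- intersect(rownames(table), metadata$sample_id)
  if (!length(ids)) abort_validation("no samples shared by table and metadata")
  ra <- relative_abundance(table)[ids, , drop = FALSE]
  keep <- colMeans(ra > 0) >= min_prevalence
  G <- log10(ra[, keep, drop = FALSE] + pseudo_fraction)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (is.null(clinical)) clinical <- clinical_vars(metadata)
  C <- as.matrix(as.data.frame(md)[clinical])
  rownames(C) <- ids
  list(X = cbind(G, C), y = md$group,
       genus_candidates = colnames(G), clinical_candidates = clinical,
       sample_ids = ids)
}
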