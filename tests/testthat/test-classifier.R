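test_that("fit_lda matches the hand pooled-covariance solution", {
  # 2-feature toy with hand-computable pooled covariance
  X <- rbind(c(1, 0), c(2, 1), c(3, 1), c(5, 2), c(6, 3), c(7, 3))
  colnames(X) <- c("a", "b"); rownames(X) <- paste0("s", 1:6)
  y <- rep(c("control", "case"), each = 3)
  fit <- fit_lda(X, y)
  # hand solution in the standardized space fit_lda works in
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  m1 <- colMeans(Z[4:6, ]); m0 <- colMeans(Z[1:3, ])
  S <- (crossprod(sweep(Z[4:6, ], 2, m1)) +
        crossprod(sweep(Z[1:3, ], 2, m0))) / 4
  w <- solve(S + diag(1e-6 * sum(diag(S)), 2), m1 - m0)
  expect_equal(fit$weights, unname(as.numeric(w)), tolerance = 1e-8)
  # positive score toward the case mean
  expect_gt(predict(fit, X)[5], 0)
  expect_lt(predict(fit, X)[2], 0)
  # one feature, class means +-1: weight sign points at the case mean
  X1 <- matrix(c(-1.1, -0.9, -1, 0.9, 1.1, 1), 6, 1,
               dimnames = list(paste0("s", 1:6), "f"))
  expect_gt(fit_lda(X1, y)$weights, 0)
  # duplicated feature columns are rejected
  expect_error(fit_lda(cbind(X, a2 = X[, 1]), y), "singular|collinear")
  expect_error(fit_lda(X, rep("case", 6)), "both classes")
})

test_that("roc_auc_ci: pair counting, ties, and the DeLong interval", {
  # hand pair-count oracle: labels (1,1,0,0), scores (.9,.4,.6,.1) -> 3/4
  roc <- roc_auc_ci(c(0.9, 0.4, 0.6, 0.1), c("case", "case", "control", "control"))
  expect_equal(roc$auc, 0.75)
  expect_equal(roc_auc_ci(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc_ci(rep(2, 6), rep(c("case", "control"), 3))$auc, 0.5)
  expect_true(roc$ci_low <= roc$auc && roc$auc <= roc$ci_high)
  expect_equal(roc$curve$fpr[1], 0); expect_equal(roc$curve$tpr[1], 0)
  expect_equal(utils::tail(roc$curve$fpr, 1), 1)
  expect_true(!is.unsorted(roc$curve$fpr))
  # AUC invariant under strictly monotone transform of scores
  set.seed(2)
  s <- stats::rnorm(60); y <- rep(c("case", "control"), 30)
  expect_equal(roc_auc_ci(exp(s), y)$auc, roc_auc_ci(s, y)$auc)
  # DeLong CI width shrinks with n (56 vs 140, validation vs discovery scale)
  width <- function(n, seed) {
    set.seed(seed)
    y <- rep(c("case", "control"), n / 2)
    s <- stats::rnorm(n) + (y == "case")
    r <- roc_auc_ci(s, y); r$ci_high - r$ci_low
  }
  w56 <- mean(vapply(1:10, function(i) width(56, i), numeric(1)))
  w140 <- mean(vapply(1:10, function(i) width(140, 100 + i), numeric(1)))
  expect_lt(w140, w56)
  expect_error(roc_auc_ci(1:4, rep("case", 4)), "both classes")
})

test_that("LOOCV performance: separable, null, and guard rails", {
  set.seed(5)
  y <- rep(c("case", "control"), each = 10)
  X <- cbind(sep = c(stats::rnorm(10, 5), stats::rnorm(10, -5)),
             noise = stats::rnorm(20))
  rownames(X) <- paste0("s", 1:20)
  expect_equal(loocv_performance(X, y, "sep")$auc, 1)
  # pure noise at n = 140: centred near 0.5.  Pooled LOOCV scores of a null
  # feature are high-variance by construction (the fitted direction flips
  # sign across folds), so the band is on the mean over seeds.
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    Xn <- matrix(stats::rnorm(140), 140, 1, dimnames = list(NULL, "f"))
    loocv_performance(Xn, rep(c("case", "control"), 70))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.6)
  expect_error(loocv_performance(X[1:8, ], y[1:8]), "n >= 10")
})

test_that("forward selection finds the informative feature and is deterministic", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    y <- rep(c("case", "control"), n / 2)
    X <- matrix(stats::rnorm(n * 21), n, 21,
                dimnames = list(paste0("s", 1:n),
                                c("signal", paste0("noise", 1:20))))
    X[, "signal"] <- X[, "signal"] + 2 * (y == "case")
    forward_select(X, y, max_features = 3)$selected_features[1]
  }, character(1))
  expect_gte(mean(picks == "signal"), 0.95)
  # deterministic given X, y and candidate order
  set.seed(1)
  n <- 40
  y <- rep(c("case", "control"), n / 2)
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:6)))
  X[, 1] <- X[, 1] + 1.5 * (y == "case")
  m1 <- forward_select(X, y, max_features = 4)
  m2 <- forward_select(X, y, max_features = 4)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_identical(m1$trajectory, m2$trajectory)
  # greedy guarantee: final LOOCV AUC >= every single-candidate round-1 AUC
  round1 <- vapply(colnames(X), function(f)
    loocv_performance(X, y, f)$auc, numeric(1))
  expect_gte(m1$loocv_auc + 1e-12, max(round1))
  expect_error(forward_select(X, y, character(0)), "empty")
  expect_error(forward_select(X, y, max_features = 0), "max_features")
})

test_that("external evaluation freezes the model and detects broken signal", {
  set.seed(8)
  gen <- function(n) {
    y <- rep(c("case", "control"), n / 2)
    X <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
    X[, 1] <- X[, 1] + 1.5 * (y == "case")
    list(X = X, y = y)
  }
  tr <- gen(80); va <- gen(60)
  model <- forward_select(tr$X, tr$y, max_features = 3)
  roc <- evaluate_external(model, va$X, va$y)
  expect_gt(roc$auc, 0.7)
  # shuffled validation labels -> chance performance
  set.seed(9)
  roc0 <- evaluate_external(model, va$X, sample(va$y))
  expect_lt(abs(roc0$auc - 0.5), 0.2)
  expect_error(evaluate_external(model, va$X[, -1, drop = FALSE], va$y),
               "missing feature")
})

test_that("compare_models reports the three candidate pools side by side", {
  set.seed(12)
  gen <- function(n, seed) {
    set.seed(seed)
    y <- rep(c("case", "control"), n / 2)
    X <- cbind(g1 = stats::rnorm(n) + 1.2 * (y == "case"),
               g2 = stats::rnorm(n),
               c1 = stats::rnorm(n) + 1.2 * (y == "case"),
               c2 = stats::rnorm(n))
    rownames(X) <- paste0("s", 1:n)
    list(X = X, y = y)
  }
  tr <- gen(80, 1); va <- gen(60, 2)
  out <- compare_models(tr$X, tr$y, va$X, va$y,
                        genus_candidates = c("g1", "g2"),
                        clinical_candidates = c("c1", "c2"), max_features = 3)
  expect_named(out, c("combined", "genus_only", "clinical_only"))
  for (b in out) {
    expect_s3_class(b$model, "classifier_model")
    expect_true(b$validation$auc >= 0 && b$validation$auc <= 1)
  }
  expect_false("c1" %in% out$genus_only$model$selected_features)
  expect_false("g1" %in% out$clinical_only$model$selected_features)
})
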