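#' Beta-diversity distance matrix
#'
#' Four community dissimilarities over the samples of a count table:
#' \describe{
#'   \item{jaccard}{on presence/absence, `1 - |A intersect B| / |A union B|`.}
#'   \item{bray_curtis}{`sum |x - y| / sum (x + y)` on counts.}
#'   \item{unweighted_unifrac}{unique branch length / total branch length
#'     observed in either sample, on a rooted tree over the features.}
#'   \item{weighted_unifrac}{`sum_l b_l |p_A(l) - p_B(l)|` over branches,
#'     with `p` the per-sample proportion of reads descending from branch
#'     `l`; `normalized = TRUE` divides by `sum_l b_l (p_A(l) + p_B(l))`,
#'     bounding the metric to `[0, 1]`.}
#' }
#'
#' @param table an [otu_table()] (conventionally rarefied first).
#' @param metric one of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree rooted [ape::phylo] tree whose tips cover every feature of
#'   `table`; required for the UniFrac metrics.
#' @param normalized normalized weighted UniFrac variant (default off).
#' @return a [distance_matrix_obj()].
#' @export
distance_matrix <- function(table,
                            metric = c("bray_curtis", "jaccard",
                                       "unweighted_unifrac", "weighted_unifrac"),
                            tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  m <- unclass(table)
  storage.mode(m) <- "double"
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric %in% c("jaccard", "bray_curtis")) {
    bin <- m > 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (metric == "jaccard") {
        un <- sum(bin[i, ] | bin[j, ])
        d[i, j] <- if (un == 0) 0 else 1 - sum(bin[i, ] & bin[j, ]) / un
      } else {
        tot <- sum(m[i, ] + m[j, ])
        d[i, j] <- if (tot == 0) 0 else sum(abs(m[i, ] - m[j, ])) / tot
      }
      d[j, i] <- d[i, j]
    }
    return(distance_matrix_obj(d))
  }
  if (is.null(tree)) abort_validation("UniFrac metrics require a tree")
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    abort_validation(sprintf("tree is missing feature(s): %s",
                             paste(missing, collapse = ", ")))
  bp <- branch_proportions(m, tree)
  b <- bp$lengths
  P <- bp$prop  # samples x branches, proportion of reads under each branch
  pres <- P > 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (metric == "unweighted_unifrac") {
      either <- pres[i, ] | pres[j, ]
      shared <- pres[i, ] & pres[j, ]
      tot <- sum(b[either])
      d[i, j] <- if (tot == 0) 0 else sum(b[either & !shared]) / tot
    } else {
      num <- sum(b * abs(P[i, ] - P[j, ]))
      if (normalized) {
        den <- sum(b * (P[i, ] + P[j, ]))
        d[i, j] <- if (den == 0) 0 else num / den
      } else d[i, j] <- num
    }
    d[j, i] <- d[i, j]
  }
  distance_matrix_obj(d)
}

# Internal: for each branch (edge) of a rooted tree, the per-sample
# proportion of reads whose features descend from it, plus branch lengths.
branch_proportions <- function(m, tree) {
  prop_tips <- m / pmax(rowSums(m), 1)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nrow(m), nnode)
  tip_idx <- match(tree$tip.label, colnames(m))
  present <- which(!is.na(tip_idx))  # tips absent from the table contribute zero
  acc[, present] <- prop_tips[, tip_idx[present], drop = FALSE]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    acc[, parent] <- acc[, parent] + acc[, child]
  }
  list(lengths = ord$edge.length, prop = acc[, ord$edge[, 2], drop = FALSE])
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix: double-center
#' `-d^2 / 2`, eigendecompose, use the axes with positive eigenvalues.
#' Negative eigenvalues (non-Euclidean distances) are reported but excluded
#' from the coordinates.
#'
#' @param dm a [distance_matrix_obj()].
#' @param k number of axes to return (default `min(n - 1, positive axes)`).
#' @return list of class `pcoa_result`: `coordinates` (samples x k),
#'   `eigenvalues` (all, descending), `proportion_explained` (share of the
#'   positive-eigenvalue total per returned axis).
#' @export
pcoa <- function(dm, k = NULL) {
  d <- unclass(dm)
  n <- nrow(d)
  if (!is.null(k)) stopifnot(k >= 1, k <= n - 1)
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev[1], 0) * 1e-9)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  coords <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = ev[pos[seq_len(k)]] / sum(ev[pos])),
            class = "pcoa_result")
}

#' PERMANOVA (permutational multivariate ANOVA on a distance matrix)
#'
#' One-factor pseudo-F from within/between sums of squared distances
#' (`SS_total = sum d_ij^2 / n`, `SS_within = sum_g sum_{ij in g} d_ij^2 /
#' n_g`), with a permutation p-value that includes the observed statistic in
#' numerator and denominator, guaranteeing `p >= 1/(n_permutations + 1)`.
#'
#' @param dm a [distance_matrix_obj()].
#' @param groups factor-like group labels aligned with the matrix rows (2+
#'   levels, each with >= 2 samples).
#' @param n_permutations label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param strata optional blocking vector (e.g. matched-pair ids): labels
#'   are then permuted only within blocks.  Default free permutation.
#' @return list of class `permanova_result`: `pseudo_F`, `p`, `R2`,
#'   `n_permutations`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = NULL,
                      strata = NULL) {
  d2 <- unclass(dm)^2
  g <- factor(groups)
  n <- nrow(d2)
  stopifnot(length(g) == n)
  if (nlevels(g) < 2) abort_validation("PERMANOVA needs at least two groups")
  if (min(table(g)) < 2) abort_validation("each group needs >= 2 samples")
  a <- nlevels(g)
  sst <- sum(d2) / (2 * n)
  ssw_of <- function(gi) {
    s <- 0
    for (lev in levels(gi)) {
      idx <- which(gi == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(gi) {
    ssw <- ssw_of(gi)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  F_obs <- f_of(g)
  perm_F <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      idx <- if (is.null(strata)) sample.int(n) else {
        out <- seq_len(n)
        for (s in unique(strata)) {
          w <- which(strata == s)
          out[w] <- w[sample.int(length(w))]
        }
        out
      }
      f_of(g[idx])
    }, numeric(1))
  })
  ssw <- ssw_of(g)
  structure(list(pseudo_F = F_obs,
                 p = (1 + sum(perm_F >= F_obs)) / (1 + n_permutations),
                 R2 = (sst - ssw) / sst,
                 n_permutations = n_permutations),
            class = "permanova_result")
}
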