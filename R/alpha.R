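#' Alpha-diversity indices for one sample
#'
#' Computes the seven within-sample indices used throughout the package:
#' observed richness, Chao1, ACE (rare/abundant cut at `rare_threshold`
#' reads), Shannon (log base 2 by default, so entropy is in bits), Simpson
#' diversity (1 - sum p_i^2), dominance (sum p_i^2) and Heip's evenness
#' `(2^H - 1)/(S - 1)`.
#'
#' Estimator details: Chao1 is the classic `S + F1^2 / (2 F2)` when
#' doubletons exist, switching to the bias-corrected `S + F1 (F1 - 1) / 2`
#' only when `F2 = 0`; ACE follows the standard abundance-based coverage
#' estimator, returning `NA` (flagged undefined) when the rare-class sample
#' coverage is zero (all rare features are singletons).
#'
#' @param counts non-negative integer vector of feature counts (one sample).
#' @param rare_threshold ACE rare/abundant boundary (default 10 reads).
#' @param base logarithm base for Shannon; 2 (bits, default) or `exp(1)`.
#' @return one-row data.frame with columns `observed`, `chao1`, `ace`,
#'   `shannon`, `simpson`, `heip_e`, `dominance`.
#' @export
#' @examples
#' alpha_indices(c(10, 5, 2, 1, 1))  # Chao1 = 5 + 4/2 = 7
alpha_indices <- function(counts, rare_threshold = 10, base = 2) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || all(counts == 0))
    abort_validation("alpha_indices needs a non-negative vector with a positive total")
  x <- counts[counts > 0]
  S <- length(x)
  N <- sum(x)
  p <- x / N
  F1 <- sum(x == 1)
  F2 <- sum(x == 2)
  chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
  # ACE
  rare <- x <= rare_threshold
  S_rare <- sum(rare); S_abund <- S - S_rare
  N_rare <- sum(x[rare])
  if (S_rare == 0) {
    ace <- S
  } else {
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      ace <- NA_real_  # undefined: every rare feature is a singleton
    } else {
      i <- seq_len(rare_threshold)
      Fi <- vapply(i, function(k) sum(x == k), numeric(1))
      gamma2 <- if (N_rare > 1)
        max(S_rare / C_ace * sum(i * (i - 1) * Fi) / (N_rare * (N_rare - 1)) - 1, 0)
      else 0
      ace <- S_abund + S_rare / C_ace + F1 / C_ace * gamma2
    }
  }
  shannon <- -sum(p * log(p, base = base))
  simpson <- 1 - sum(p^2)
  heip <- if (S > 1) (base^shannon - 1) / (S - 1) else NA_real_
  data.frame(observed = S, chao1 = chao1, ace = ace, shannon = shannon,
             simpson = simpson, heip_e = heip, dominance = sum(p^2))
}

#' Alpha diversity for every sample of a table
#'
#' @param table an [otu_table()] (typically already rarefied).
#' @inheritParams alpha_indices
#' @return data.frame with `sample_id` plus the seven index columns.
#' @export
alpha_diversity <- function(table, rare_threshold = 10, base = 2) {
  recs <- lapply(seq_len(nrow(table)), function(i)
    alpha_indices(unclass(table)[i, ], rare_threshold, base))
  out <- do.call(rbind, recs)
  cbind(data.frame(sample_id = rownames(table), stringsAsFactors = FALSE), out)
}

#' Compare alpha indices between case and control
#'
#' Two-tailed unpaired Welch t-test per index, the convention used for
#' figure-level alpha comparisons in two-group 16S studies.
#'
#' @param records output of [alpha_diversity()].
#' @param groups character vector (`"case"`/`"control"`) aligned with
#'   `records$sample_id`, or a [sample_metadata()] to be matched by id.
#' @return data.frame: index, group means, t statistic, two-sided p,
#'   direction (`"case>control"` / `"control>case"` / `"equal"`).
#' @export
compare_alpha <- function(records, groups) {
  if (inherits(groups, "sample_metadata"))
    groups <- groups$group[match(records$sample_id, groups$sample_id)]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(records))
  if (min(table(factor(groups, c("case", "control")))) < 2)
    abort_validation("each group needs at least 2 samples for a t-test")
  idx <- setdiff(names(records), "sample_id")
  rows <- lapply(idx, function(v) {
    a <- records[[v]][groups == "case"]
    b <- records[[v]][groups == "control"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(index = v, mean_case = mean(a), mean_control = mean(b),
                        t = NA_real_, p = NA_real_, direction = NA_character_))
    if (stats::sd(c(a, b)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    data.frame(index = v, mean_case = mean(a), mean_control = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               direction = if (mean(a) > mean(b)) "case>control"
                           else if (mean(a) < mean(b)) "control>case" else "equal")
  })
  do.call(rbind, rows)
}

#' Rarefaction curve (expected observed richness per depth)
#'
#' Analytic hypergeometric expectation
#' `E[S_d] = sum_f (1 - choose(N - n_f, d) / choose(N, d))`, optionally
#' accompanied by a Monte-Carlo mean over `reps` random subsamples.  The
#' analytic curve is monotone non-decreasing in depth by construction.
#'
#' @param table an [otu_table()].
#' @param depths ascending integer grid of subsampling depths.
#' @param reps Monte-Carlo replicates (0 = analytic only).
#' @param seed seed for the Monte-Carlo part.
#' @return long data.frame: `sample_id`, `depth`, `expected_observed`, and
#'   `mc_observed` when `reps > 0`.  Depths exceeding a sample's total give
#'   `NA` for that sample.
#' @export
rarefaction_curve <- function(table, depths, reps = 0, seed = NULL) {
  stopifnot(!is.unsorted(depths), all(depths >= 1))
  m <- unclass(table)
  grid <- expand.grid(sample_id = rownames(m), depth = depths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$expected_observed <- NA_real_
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]; N <- sum(r); r <- r[r > 0]
    for (d in depths) {
      if (d > N) next
      # P(feature f unseen in d draws) = choose(N - n_f, d)/choose(N, d)
      lp <- lchoose(N - r, d) - lchoose(N, d)
      lp[N - r < d] <- -Inf
      grid$expected_observed[grid$sample_id == rownames(m)[i] & grid$depth == d] <-
        sum(1 - exp(lp))
    }
  }
  if (reps > 0) {
    grid$mc_observed <- NA_real_
    with_seed(seed, {
      for (i in seq_len(nrow(m))) {
        r <- m[i, ]; N <- sum(r)
        reads <- rep.int(seq_along(r), r)
        for (d in depths) {
          if (d > N) next
          obs <- vapply(seq_len(reps), function(k)
            length(unique(reads[sample.int(N, d)])), numeric(1))
          grid$mc_observed[grid$sample_id == rownames(m)[i] & grid$depth == d] <-
            mean(obs)
        }
      }
    })
  }
  grid
}
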