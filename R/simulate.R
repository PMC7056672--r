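#' Configuration for the synthetic GDM cohort generator
#'
#' Describes a matched case-control 16S cohort with the design of the study
#' this package replays: `n_pairs_discovery + n_pairs_validation` matched
#' pairs (one case, one control each; defaults 70 + 28 = 98 pairs, 196
#' samples), genus-level taxa on a log-normal rank-abundance backbone,
#' group effects on designated "spiked" genera (defaults: 3 case-enriched
#' and 9 control-enriched genera at 2-fold change), a shared within-pair
#' log-abundance shift, per-sample read depths log-normal around
#' `depth_mean`, group-specific Gaussian clinical indices (defaults
#' approximate the published cohort's early-pregnancy values, e.g. fasting
#' glucose 4.63 vs 4.89 mmol/L), and Gaussian-copula rank coupling between
#' designated genera and clinical indices at target Spearman rho
#' (defaults in the reported +/-0.17..0.23 band).
#'
#' @param n_pairs_discovery,n_pairs_validation matched pairs per set
#'   (defaults 70 and 28).
#' @param n_genera number of genera (default 150; must exceed the number of
#'   spiked genera).
#' @param depth_mean mean reads per sample (default 63,218).
#' @param depth_dispersion log-scale SD of the depth distribution
#'   (default 0.25).
#' @param abundance_decay log rank-abundance slope: baseline log mean of
#'   genus `g` is `-abundance_decay * g` (default 0.08, giving a dominant
#'   genus near 8 % relative abundance and a long rare tail).
#' @param genus_sd per-genus log-abundance SD (default 0.9, scalar or
#'   length `n_genera`).
#' @param pair_effect_sd SD of the per-pair, per-genus log shift shared by
#'   the two members of a matched pair (default 0.3).
#' @param case_enriched data.frame `genus` (index or name), `log2fc`;
#'   default 3 genera at log2fc 1.
#' @param control_enriched likewise; default 9 genera at log2fc 1.
#' @param clinical_block data.frame `index`, `mean_control`, `sd_control`,
#'   `mean_case`, `sd_case` (defaults: Gaussian approximations of the
#'   published Table-1 clinical battery).
#' @param taxon_clinical_corr data.frame `genus`, `index`, `rho`: target
#'   Spearman correlations, coupled via a Gaussian copula on ranks.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs_discovery = 70, n_pairs_validation = 28,
                          n_genera = 150, depth_mean = 63218,
                          depth_dispersion = 0.25, abundance_decay = 0.08,
                          genus_sd = 0.9, pair_effect_sd = 0.3,
                          case_enriched = NULL, control_enriched = NULL,
                          clinical_block = NULL, taxon_clinical_corr = NULL,
                          seed = 1L) {
  if (is.null(case_enriched))
    case_enriched <- data.frame(
      genus = c("Eisenbergiella", "Tyzzerella_4", "Lachnospiraceae_NK4A136_group"),
      rank = c(12L, 18L, 24L), log2fc = 1.0, stringsAsFactors = FALSE)
  if (is.null(control_enriched))
    control_enriched <- data.frame(
      genus = c("Parabacteroides", "Parasutterella", "Megasphaera", "Dialister",
                "Ruminococcaceae_UCG_005", "Ruminococcaceae_UCG_002",
                "Ruminococcaceae_UCG_003", "Eubacterium_xylanophilum_group",
                "Eubacterium_eligens_group"),
      rank = c(9L, 15L, 21L, 27L, 30L, 33L, 36L, 39L, 42L),
      log2fc = 1.0, stringsAsFactors = FALSE)
  if (is.null(clinical_block)) clinical_block <- default_clinical_block()
  if (is.null(taxon_clinical_corr))
    taxon_clinical_corr <- data.frame(
      genus = c("Eisenbergiella", "Tyzzerella_4", "Parabacteroides",
                "Parasutterella", "Ruminococcaceae_UCG_002", "Dialister"),
      index = c("FGB", "FGB", "FGB", "FGB", "FGB", "INS"),
      rho = c(0.19, 0.19, -0.20, -0.18, -0.17, -0.23),
      stringsAsFactors = FALSE)
  cfg <- list(n_pairs_discovery = n_pairs_discovery,
              n_pairs_validation = n_pairs_validation,
              n_genera = n_genera, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              abundance_decay = abundance_decay,
              genus_sd = rep_len(genus_sd, n_genera),
              pair_effect_sd = pair_effect_sd,
              case_enriched = case_enriched,
              control_enriched = control_enriched,
              clinical_block = clinical_block,
              taxon_clinical_corr = taxon_clinical_corr,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

default_clinical_block <- function() {
  data.frame(
    index        = c("FGB", "GGT", "BMI", "SBP", "DBP", "TG", "INS", "hsCRP"),
    mean_control = c(4.63, 11.5, 20.83, 114.82, 74.30, 1.36, 51, 2.0),
    sd_control   = c(0.28, 5.5, 2.65, 9.57, 8.39, 0.42, 28, 1.5),
    mean_case    = c(4.89, 14.5, 22.79, 119.17, 76.87, 1.66, 68, 3.0),
    sd_case      = c(0.45, 7.5, 3.01, 10.09, 8.61, 0.60, 33, 2.0),
    stringsAsFactors = FALSE)
}

validate_cohort_config <- function(cfg) {
  spikes <- rbind(cfg$case_enriched[c("genus", "rank", "log2fc")],
                  cfg$control_enriched[c("genus", "rank", "log2fc")])
  if (!all(is.finite(spikes$log2fc)))
    abort_validation("spiked fold changes must be finite")
  if (nrow(spikes) >= cfg$n_genera)
    abort_validation("n_genera must exceed the number of spiked genera")
  if (anyDuplicated(spikes$rank) || anyDuplicated(spikes$genus))
    abort_validation("spiked genera must be distinct")
  if (any(abs(cfg$taxon_clinical_corr$rho) >= 1))
    abort_validation("target |rho| must be < 1")
  copula_loadings(cfg)  # errors if infeasible
  invisible(cfg)
}

# Internal: Gaussian-copula loadings that hit the target *cohort-level*
# Spearman correlations.  The target is converted to a latent Pearson
# correlation (rho_P = 2 sin(pi rho_S / 6)); because both the genus latent
# and the clinical index may carry a case/control mean shift, part of the
# cohort-level correlation comes from that shared shift and only the
# remainder is supplied by the copula loading b:
#   rho_P * sd(c) = s_bar * b + a * dm/2,
# with a the genus's standardized half-shift, dm the clinical case-control
# mean difference and s_bar the average within-group SD.  Errors when the
# loadings of one index are jointly infeasible (sum b^2 >= 1).
copula_loadings <- function(cfg) {
  tc <- cfg$taxon_clinical_corr
  spikes <- rbind(
    if (nrow(cfg$case_enriched)) cbind(cfg$case_enriched, dir = 1) else NULL,
    if (nrow(cfg$control_enriched)) cbind(cfg$control_enriched, dir = -1) else NULL)
  blk <- cfg$clinical_block
  out <- vector("list", nrow(blk))
  names(out) <- blk$index
  for (k in seq_len(nrow(blk))) {
    cc <- tc[tc$index == blk$index[k], , drop = FALSE]
    if (!nrow(cc)) { out[[k]] <- cc; next }
    dm <- blk$mean_case[k] - blk$mean_control[k]
    s_bar <- (blk$sd_case[k] + blk$sd_control[k]) / 2
    sd_c <- sqrt(s_bar^2 + dm^2 / 4)
    b <- numeric(nrow(cc))
    for (j in seq_len(nrow(cc))) {
      a <- 0
      if (!is.null(spikes) && cc$genus[j] %in% spikes$genus) {
        sp <- spikes[match(cc$genus[j], spikes$genus), ]
        delta <- sp$dir * log(2) * sp$log2fc
        s_lat <- sqrt(cfg$genus_sd[sp$rank]^2 + cfg$pair_effect_sd^2)
        a <- (delta / 2) / sqrt(s_lat^2 + delta^2 / 4)
      }
      rho_p <- 2 * sin(pi * cc$rho[j] / 6)
      # loading applies to the genus's within-group residual (variance
      # 1 - a^2 of the cohort-level score), keeping group marginals exact
      b[j] <- (rho_p * sd_c - a * dm / 2) / (s_bar * sqrt(1 - a^2))
    }
    if (sum(b^2) >= 1)
      abort_validation(sprintf(
        "infeasible rank coupling for index '%s' (joint loading >= 1)",
        blk$index[k]))
    cc$loading <- b
    out[[k]] <- cc
  }
  out
}

#' Null cohort configuration
#'
#' All fold changes zero, identical clinical blocks in both groups, no
#' taxon-clinical coupling: every downstream test should reject at its
#' nominal rate only.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a [cohort_config()].
#' @export
null_cohort_config <- function(...) {
  blk <- default_clinical_block()
  blk$mean_case <- blk$mean_control
  blk$sd_case <- blk$sd_control
  ce <- data.frame(genus = character(), rank = integer(), log2fc = numeric())
  cohort_config(case_enriched = ce, control_enriched = ce,
                clinical_block = blk,
                taxon_clinical_corr = data.frame(genus = character(),
                                                 index = character(),
                                                 rho = numeric()), ...)
}

#' Prediction-replica cohort configuration
#'
#' The stated world for the classifier exercise: 70 + 28 matched pairs,
#' exactly 5 informative genera (control-enriched, log2fc 0.8, named after
#' the published model's genera) and 2 informative clinical indices
#' (fasting glucose and GGT at their published group levels); every other
#' clinical index is null and no rank coupling is imposed, so the planted
#' signal is exactly the 7 model features.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a [cohort_config()].
#' @export
paper_replica_config <- function(...) {
  blk <- default_clinical_block()
  informative <- blk$index %in% c("FGB", "GGT")
  blk$mean_case[!informative] <- blk$mean_control[!informative]
  blk$sd_case[!informative] <- blk$sd_control[!informative]
  cohort_config(
    case_enriched = data.frame(genus = character(), rank = integer(),
                               log2fc = numeric()),
    control_enriched = data.frame(
      genus = c("Parabacteroides", "Ruminococcus_2", "Ruminococcaceae_UCG_014",
                "Alloprevotella", "uncultured_Ruminococcaceae"),
      rank = c(10L, 16L, 22L, 28L, 34L), log2fc = 0.8,
      stringsAsFactors = FALSE),
    clinical_block = blk,
    taxon_clinical_corr = data.frame(genus = character(), index = character(),
                                     rho = numeric()),
    ...)
}

#' Simulate a matched case-control 16S cohort
#'
#' Generative model: per genus `g` a baseline log abundance
#' `mu_g = -abundance_decay * g`; per matched pair a shared shift
#' `N(0, pair_effect_sd)` per genus; cases additionally get
#' `+log(2) * log2fc` on case-enriched and `-log(2) * log2fc` on
#' control-enriched genera; per-sample noise `N(0, genus_sd)`.  The latent
#' log abundances are soft-maxed into compositions and counts drawn
#' multinomially at a log-normal per-sample depth.  Clinical indices are
#' group-specific Gaussians whose latent normal scores are mixed with the
#' normal scores of designated genera (Gaussian copula, Pearson loading
#' `2 sin(pi rho / 6)`) to hit the target Spearman correlations without
#' distorting the marginals.  The genus tree is a random coalescent
#' ([ape::rcoal()]).
#'
#' @param config a [cohort_config()].
#' @param bayes_mc Monte-Carlo draws per group for the ground-truth
#'   discriminability estimate stored in `truth` (0 skips it; default
#'   20,000).
#' @return list of class `simulated_cohort`: `table` ([otu_table()],
#'   genus-level), `taxonomy`, `tree`, `metadata` ([sample_metadata()]),
#'   and `truth` (spiked genera with directions, latent compositions, and
#'   the [estimate_bayes_auc()] value when requested).
#' @export
simulate_cohort <- function(config, bayes_mc = 20000) {
  cfg <- config
  n_pairs <- cfg$n_pairs_discovery + cfg$n_pairs_validation
  G <- cfg$n_genera
  genus_ids <- paste0("Genus_", sprintf("%03d", seq_len(G)))
  spikes <- rbind(
    if (nrow(cfg$case_enriched)) cbind(cfg$case_enriched, dir = 1) else NULL,
    if (nrow(cfg$control_enriched)) cbind(cfg$control_enriched, dir = -1) else NULL)
  if (!is.null(spikes) && nrow(spikes)) genus_ids[spikes$rank] <- spikes$genus
  n <- 2L * n_pairs
  pair_id <- rep(sprintf("P%03d", seq_len(n_pairs)), each = 2L)
  group <- rep(c("case", "control"), n_pairs)
  set <- rep(c(rep("discovery", cfg$n_pairs_discovery),
               rep("validation", cfg$n_pairs_validation)), each = 2L)
  sample_id <- paste0(ifelse(group == "case", "GDM_", "CTR_"),
                      sprintf("%03d", rep(seq_len(n_pairs), each = 2L)))
  mu <- -cfg$abundance_decay * seq_len(G)
  delta <- numeric(G)
  if (!is.null(spikes) && nrow(spikes))
    delta[spikes$rank] <- spikes$dir * log(2) * spikes$log2fc
  res <- with_seed(cfg$seed, {
    pair_shift <- matrix(stats::rnorm(n_pairs * G, 0, cfg$pair_effect_sd),
                         n_pairs, G)
    eps <- matrix(stats::rnorm(n * G), n, G) *
      matrix(cfg$genus_sd, n, G, byrow = TRUE)
    lambda <- matrix(mu, n, G, byrow = TRUE) +
      pair_shift[rep(seq_len(n_pairs), each = 2L), , drop = FALSE] + eps +
      outer(group == "case", delta)
    comp <- exp(lambda - apply(lambda, 1L, max))
    comp <- comp / rowSums(comp)
    depth <- round(stats::rlnorm(n, log(cfg$depth_mean) -
                                 cfg$depth_dispersion^2 / 2,
                                 cfg$depth_dispersion))
    counts <- t(vapply(seq_len(n), function(i)
      as.integer(stats::rmultinom(1L, depth[i], comp[i, ])), integer(G)))
    # clinical block with copula coupling to genus latents
    zg <- apply(lambda, 2L, function(v) stats::qnorm((rank(v) - 0.5) / n))
    blk <- cfg$clinical_block
    loadings <- copula_loadings(cfg)
    clin <- matrix(NA_real_, n, nrow(blk),
                   dimnames = list(sample_id, blk$index))
    for (k in seq_len(nrow(blk))) {
      cc <- loadings[[blk$index[k]]]
      b <- cc$loading
      zc <- stats::rnorm(n) * sqrt(max(1 - sum(b^2), 0))
      if (nrow(cc)) {
        gi <- match(cc$genus, genus_ids)
        if (anyNA(gi))
          abort_validation(sprintf("coupled genus not in cohort: %s",
                                   paste(cc$genus[is.na(gi)], collapse = ", ")))
        # couple to the *within-structure* normal score (group shift removed):
        # the shift's own contribution is already accounted for in the loading
        zg_w <- zg[, gi, drop = FALSE]
        for (jj in seq_along(gi)) {
          sh <- stats::ave(zg_w[, jj], group)
          zg_w[, jj] <- (zg_w[, jj] - sh) / max(stats::sd(zg_w[, jj] - sh), 1e-12)
        }
        zc <- zc + as.numeric(zg_w %*% b)
      }
      is_case <- group == "case"
      clin[, k] <- ifelse(is_case,
                          blk$mean_case[k] + blk$sd_case[k] * zc,
                          blk$mean_control[k] + blk$sd_control[k] * zc)
    }
    tree <- ape::rcoal(G, tip.label = genus_ids)
    list(counts = counts, comp = comp, clin = clin, tree = tree)
  })
  dimnames(res$counts) <- list(sample_id, genus_ids)
  dimnames(res$comp) <- list(sample_id, genus_ids)
  md <- data.frame(sample_id = sample_id, group = group, pair_id = pair_id,
                   set = set, stringsAsFactors = FALSE)
  md <- cbind(md, as.data.frame(res$clin))
  truth <- list(
    spiked = if (!is.null(spikes) && nrow(spikes))
      data.frame(genus = spikes$genus,
                 direction = ifelse(spikes$dir > 0, "case", "control"),
                 log2fc = spikes$log2fc, stringsAsFactors = FALSE)
    else data.frame(genus = character(), direction = character(),
                    log2fc = numeric()),
    latent_composition = res$comp,
    bayes_auc = if (bayes_mc > 0)
      estimate_bayes_auc(cfg, n_mc = bayes_mc,
                         seed = derive_seed(cfg$seed, "bayes_auc"))
    else NULL)
  structure(list(table = otu_table(res$counts),
                 taxonomy = synthetic_taxonomy(genus_ids),
                 tree = res$tree,
                 metadata = sample_metadata(md),
                 truth = truth),
            class = "simulated_cohort")
}

# Internal: plausible 7-rank lineages for synthetic genera.  Named
# differential genera get their real phylum; filler genera cycle over the
# dominant gut phyla.  Purely cosmetic.
synthetic_taxonomy <- function(genus_ids) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")
  known <- c(Eisenbergiella = "Firmicutes", Tyzzerella_4 = "Firmicutes",
             Lachnospiraceae_NK4A136_group = "Firmicutes",
             Parabacteroides = "Bacteroidetes", Parasutterella = "Proteobacteria",
             Megasphaera = "Firmicutes", Dialister = "Firmicutes",
             Ruminococcaceae_UCG_005 = "Firmicutes",
             Ruminococcaceae_UCG_002 = "Firmicutes",
             Ruminococcaceae_UCG_003 = "Firmicutes",
             Eubacterium_xylanophilum_group = "Firmicutes",
             Eubacterium_eligens_group = "Firmicutes",
             Ruminococcus_2 = "Firmicutes", Ruminococcaceae_UCG_014 = "Firmicutes",
             Alloprevotella = "Bacteroidetes",
             uncultured_Ruminococcaceae = "Firmicutes")
  ph <- ifelse(genus_ids %in% names(known), known[genus_ids],
               phyla[(seq_along(genus_ids) - 1L) %% length(phyla) + 1L])
  lin <- sprintf("k__Bacteria;p__%s;c__%s_c;o__%s_o;f__%s_f;g__%s;unassigned",
                 ph, ph, ph, genus_ids, genus_ids)
  taxonomy_map(stats::setNames(lin, genus_ids))
}

#' Ground-truth discriminability of a cohort configuration
#'
#' Monte-Carlo estimate of the AUC a classifier with oracle knowledge of the
#' signal block (the spiked genera plus the clinical indices) can attain on
#' *observed* data from this generator — the yardstick the trained
#' classifier's validation AUC is compared against.  Two independent large
#' cohort draws are taken from the full generative model (latent log-normal
#' abundances, compositional normalization, binomial read sampling at
#' log-normal depth, coupled clinical Gaussians); the group-conditional
#' Gaussian likelihood ratio on the block (log10 relative abundance with
#' pseudo-fraction 1e-6, plus clinical values) is fitted on the first draw
#' and its AUC measured on the second.  Unlike a latent-space calculation
#' this includes the sequencing observation noise, so it is an attainable
#' ceiling rather than an idealized one.
#'
#' @param config a [cohort_config()].
#' @param n_mc draws per group for each of the fit and evaluation cohorts
#'   (>= 10,000).
#' @param seed integer seed.
#' @return list of class `bayes_auc_estimate`: `auc`, `se` (Hanley-McNeil
#'   standard error at `n_mc` per group), `n_mc`.
#' @export
estimate_bayes_auc <- function(config, n_mc = 20000, seed = NULL) {
  if (n_mc < 10000) abort_validation("need n_mc >= 10,000")
  cfg <- config
  validate_cohort_config(cfg)
  spikes <- rbind(
    if (nrow(cfg$case_enriched)) cbind(cfg$case_enriched, dir = 1) else NULL,
    if (nrow(cfg$control_enriched)) cbind(cfg$control_enriched, dir = -1) else NULL)
  blk <- cfg$clinical_block
  k_g <- if (is.null(spikes)) 0L else nrow(spikes)
  k_c <- nrow(blk)
  G <- cfg$n_genera
  mu <- -cfg$abundance_decay * seq_len(G)
  s_tot <- sqrt(cfg$genus_sd^2 + cfg$pair_effect_sd^2)  # latent SD incl. pair term
  delta <- numeric(G)
  if (k_g) delta[spikes$rank] <- spikes$dir * log(2) * spikes$log2fc
  loadings <- copula_loadings(cfg)
  with_seed(seed, {
    draw_block <- function(n, is_case) {
      lam <- matrix(stats::rnorm(n * G), n, G) *
        matrix(s_tot, n, G, byrow = TRUE) +
        matrix(mu, n, G, byrow = TRUE)
      if (is_case) lam <- sweep(lam, 2L, delta, "+")
      p <- exp(lam - apply(lam, 1L, max))
      p <- p / rowSums(p)
      depth <- round(stats::rlnorm(n, log(cfg$depth_mean) -
                                   cfg$depth_dispersion^2 / 2,
                                   cfg$depth_dispersion))
      X <- matrix(NA_real_, n, k_g + k_c)
      if (k_g) {
        for (j in seq_len(k_g)) {
          cnt <- stats::rbinom(n, depth, p[, spikes$rank[j]])
          X[, j] <- log10(cnt / depth + 1e-6)
        }
      }
      for (k in seq_len(k_c)) {
        cc <- loadings[[blk$index[k]]]
        b <- cc$loading
        zc <- stats::rnorm(n) * sqrt(max(1 - sum(b^2), 0))
        if (!is.null(b) && length(b)) {
          gi <- match(cc$genus, spikes$genus)
          drop <- is.na(gi)  # coupled to a non-spiked genus: noise w.r.t. group
          if (any(drop)) zc <- zc + stats::rnorm(n) * sqrt(sum(b[drop]^2))
          gi <- gi[!drop]; bb <- b[!drop]
          if (length(gi)) {
            zw <- sweep(sweep(lam[, spikes$rank[gi], drop = FALSE], 2L,
                              mu[spikes$rank[gi]] +
                                if (is_case) delta[spikes$rank[gi]] else 0),
                        2L, s_tot[spikes$rank[gi]], "/")
            zc <- zc + as.numeric(zw %*% bb)
          }
        }
        X[, k_g + k] <- if (is_case) blk$mean_case[k] + blk$sd_case[k] * zc
                        else blk$mean_control[k] + blk$sd_control[k] * zc
      }
      X
    }
    T1 <- draw_block(n_mc, TRUE);  T0 <- draw_block(n_mc, FALSE)
    E1 <- draw_block(n_mc, TRUE);  E0 <- draw_block(n_mc, FALSE)
    ridge <- function(S) S + diag(1e-9 * max(sum(diag(S)), 1), ncol(S))
    m1 <- colMeans(T1); m0 <- colMeans(T0)
    S1 <- ridge(stats::cov(T1)); S0 <- ridge(stats::cov(T0))
    mahal <- function(X, m, S) {
      L <- chol(S)
      Zc <- forwardsolve(t(L), t(X) - m)
      colSums(Zc^2) + 2 * sum(log(diag(L)))
    }
    llr <- function(X) 0.5 * (mahal(X, m0, S0) - mahal(X, m1, S1))
    auc <- rank_auc(llr(E1), llr(E0))
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_mc - 1) * (q1 - auc^2) +
                (n_mc - 1) * (q2 - auc^2)) / (as.numeric(n_mc)^2))
    structure(list(auc = auc, se = se, n_mc = n_mc),
              class = "bayes_auc_estimate")
  })
}

# Internal: Mann-Whitney AUC via ranks, without the outer matrix.
rank_auc <- function(s1, s0) {
  r <- rank(c(s1, s0))
  n1 <- length(s1); n0 <- length(s0)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}
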