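#' Pipeline configuration
#'
#' One structure drives the full study replica.  Inputs are either file
#' paths (`otu`, `taxonomy`, `metadata`, `tree`) or a [cohort_config()] in
#' `simulate`.  Stage defaults match the replicated study's stated
#' parameters: OTU filter < 0.005 % of total reads, rarefaction to 36,000
#' reads, the four distances, LEfSe cutoffs p < 0.05 / LDA score >= 2.
#'
#' @param simulate optional [cohort_config()]; takes precedence over paths.
#' @param otu,taxonomy,metadata,tree input file paths (TSV / newick).
#' @param min_fraction rare-OTU filter fraction (default 5e-5).
#' @param rarefaction_depth reads per sample after rarefaction
#'   (default 36,000).
#' @param metrics beta-diversity metrics to run.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param lefse_p_cutoff,lefse_lda_cutoff LEfSe cutoffs (0.05, 2).
#' @param sparcc list of [sparcc_correlations()] /[sparcc_pvalues()]
#'   settings.
#' @param clinical_candidates clinical indices offered to the classifier
#'   (default: all metadata clinical columns).
#' @param max_genus_candidates cap on genus candidates (most abundant
#'   prevalence-passing genera; default 30, keeps the greedy search
#'   tractable).
#' @param max_features forward-selection depth (default 10).
#' @param seed global seed, fanned out per stage via [derive_seed()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, otu = NULL, taxonomy = NULL,
                            metadata = NULL, tree = NULL,
                            min_fraction = 5e-5, rarefaction_depth = 36000,
                            metrics = c("jaccard", "bray_curtis",
                                        "unweighted_unifrac", "weighted_unifrac"),
                            n_permutations = 999,
                            lefse_p_cutoff = 0.05, lefse_lda_cutoff = 2,
                            sparcc = list(), clinical_candidates = NULL,
                            max_genus_candidates = 30, max_features = 10,
                            seed = 1L) {
  structure(list(simulate = simulate, otu = otu, taxonomy = taxonomy,
                 metadata = metadata, tree = tree,
                 min_fraction = min_fraction,
                 rarefaction_depth = rarefaction_depth, metrics = metrics,
                 n_permutations = n_permutations,
                 lefse_p_cutoff = lefse_p_cutoff,
                 lefse_lda_cutoff = lefse_lda_cutoff, sparcc = sparcc,
                 clinical_candidates = clinical_candidates,
                 max_genus_candidates = max_genus_candidates,
                 max_features = max_features, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full case-control analysis pipeline
#'
#' filter -> rarefy -> genus aggregation -> alpha diversity (+ group
#' t-tests) -> beta diversity (+ PCoA, PERMANOVA) -> LEfSe -> SparCC
#' network on the differential genera -> clinical correlation grid ->
#' forward-selection LDA classifier trained on the discovery set and
#' frozen-model evaluation on the validation set.  Every stage writes plain
#' TSV/JSON into `out_dir`; `manifest.json` records the config hash, the
#' derived per-stage seeds and row counts (plus runtimes, which are the
#' only non-deterministic values and are confined to the manifest).  A
#' stage failure aborts with the stage name; earlier outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  manifest <- list(config_hash = fnv1a_hash(jsonlite::toJSON(
    config[setdiff(names(config), "simulate")], auto_unbox = TRUE,
    digits = NA, null = "null", force = TRUE)),
    seed = config$seed, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seed = derive_seed(config$seed, name),
                                     runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  inputs <- t_stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate, bayes_mc = 0)
      write_otu_table(sim$table, file.path(out_dir, "otu.tsv"))
      write_taxonomy(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
      write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv"))
      write_tree(sim$tree, file.path(out_dir, "tree.nwk"))
      jsonlite::write_json(sim$truth$spiked, file.path(out_dir, "truth.json"),
                           digits = NA)
      sim[c("table", "taxonomy", "tree", "metadata")]
    } else {
      list(table = read_otu_table(config$otu),
           taxonomy = if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy),
           tree = if (!is.null(config$tree)) read_tree(config$tree),
           metadata = read_metadata(config$metadata))
    }
  })

  filtered <- t_stage("filter", filter_rare_otus(inputs$table, config$min_fraction))
  rare <- t_stage("rarefy", rarefy(filtered, config$rarefaction_depth,
                                   seed = derive_seed(config$seed, "rarefy")))
  genus <- t_stage("aggregate", {
    g <- if (!is.null(inputs$taxonomy))
      aggregate_to_rank(rare, inputs$taxonomy, "genus") else rare
    write_otu_table(g, file.path(out_dir, "genus.tsv"))
    g
  })
  md <- inputs$metadata
  md <- md[match(rownames(rare), md$sample_id), , drop = FALSE]
  disc <- if ("set" %in% names(md)) md$set == "discovery" else rep(TRUE, nrow(md))

  stages$alpha <- t_stage("alpha", {
    div <- alpha_diversity(rare)
    write_tsv(div, file.path(out_dir, "alpha_diversity.tsv"))
    cmp <- compare_alpha(div[disc, , drop = FALSE], md$group[disc])
    write_tsv(cmp, file.path(out_dir, "alpha_comparison.tsv"))
    list(per_sample = div, comparison = cmp)
  })

  stages$beta <- t_stage("beta", {
    out <- list()
    for (metric in config$metrics) {
      dm <- distance_matrix(rare, metric, tree = inputs$tree,
                            normalized = metric == "weighted_unifrac")
      write_distance_matrix(dm, file.path(out_dir, paste0("dist_", metric, ".tsv")))
      pc <- pcoa(dm, k = min(2L, nrow(dm) - 1L))
      write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                           pc$coordinates, check.names = FALSE),
                file.path(out_dir, paste0("pcoa_", metric, ".tsv")))
      pm <- permanova(distance_matrix_obj(unclass(dm)[disc, disc]),
                      md$group[disc], config$n_permutations,
                      seed = derive_seed(config$seed, paste0("permanova_", metric)))
      out[[metric]] <- list(dm = dm, pcoa = pc, permanova = pm)
    }
    perm_df <- do.call(rbind, lapply(names(out), function(mt)
      data.frame(metric = mt, pseudo_F = out[[mt]]$permanova$pseudo_F,
                 R2 = out[[mt]]$permanova$R2, p = out[[mt]]$permanova$p,
                 n_permutations = out[[mt]]$permanova$n_permutations)))
    write_tsv(perm_df, file.path(out_dir, "permanova.tsv"))
    out
  })

  stages$lefse <- t_stage("lefse", {
    res <- lefse(otu_table(unclass(genus)[disc, , drop = FALSE]),
                 md$group[disc], config$lefse_p_cutoff, config$lefse_lda_cutoff,
                 seed = derive_seed(config$seed, "lefse"))
    write_tsv(as.data.frame(res), file.path(out_dir, "lefse.tsv"))
    res
  })

  diff_genera <- stages$lefse$feature_id[stages$lefse$significant]
  stages$network <- t_stage("sparcc", {
    if (length(diff_genera) < 4) {
      writeLines("feature_a\tfeature_b\trho\tp\tsign",
                 file.path(out_dir, "network_edges.tsv"))
      NULL
    } else {
      sub <- otu_table(unclass(genus)[disc, diff_genera, drop = FALSE])
      sp <- do.call(sparcc_correlations,
                    c(list(table = sub,
                           seed = derive_seed(config$seed, "sparcc")),
                      config$sparcc[intersect(names(config$sparcc),
                        c("n_iterations", "exclusion_threshold",
                          "max_excluded_fraction", "n_dirichlet_resamples"))]))
      sp <- do.call(sparcc_pvalues,
                    c(list(table = sub, observed = sp,
                           seed = derive_seed(config$seed, "sparcc_boot")),
                      config$sparcc[intersect(names(config$sparcc),
                                              "n_bootstraps")]))
      edges <- build_network(sp)
      write_tsv(edges, file.path(out_dir, "network_edges.tsv"))
      list(sparcc = sp, edges = edges)
    }
  })

  stages$correlation <- t_stage("correlate", {
    feats <- if (length(diff_genera)) diff_genera else colnames(genus)
    grid <- correlation_grid(
      relative_abundance(genus)[disc, feats, drop = FALSE],
      md[disc, , drop = FALSE])
    write_tsv(as.data.frame(grid), file.path(out_dir, "clinical_correlation.tsv"))
    grid
  })

  stages$classifier <- t_stage("classifier", {
    dm <- design_matrix(genus, md, clinical = config$clinical_candidates)
    take <- md$set[match(dm$sample_ids, md$sample_id)] == "discovery"
    gc <- dm$genus_candidates
    if (length(gc) > config$max_genus_candidates) {
      ab <- colMeans(relative_abundance(genus)[dm$sample_ids[take], gc, drop = FALSE])
      gc <- names(sort(ab, decreasing = TRUE))[seq_len(config$max_genus_candidates)]
    }
    model <- forward_select(dm$X[take, , drop = FALSE], dm$y[take],
                            candidates = c(gc, dm$clinical_candidates),
                            max_features = config$max_features)
    val <- evaluate_external(model, dm$X[!take, , drop = FALSE], dm$y[!take])
    disc_roc <- roc_auc_ci(predict(model$lda,
                                   dm$X[take, model$selected_features, drop = FALSE]),
                           dm$y[take], threshold = model$score_threshold)
    jsonlite::write_json(list(
      selected_features = model$selected_features,
      center = model$lda$center, scale = model$lda$scale,
      weights = model$lda$weights, intercept = model$lda$intercept,
      score_threshold = model$score_threshold,
      trajectory = model$trajectory),
      file.path(out_dir, "model.json"), digits = NA)
    write_tsv(data.frame(
      set = c("discovery", "validation"),
      auc = c(disc_roc$auc, val$auc),
      ci_low = c(disc_roc$ci_low, val$ci_low),
      ci_high = c(disc_roc$ci_high, val$ci_high),
      accuracy = c(disc_roc$accuracy, val$accuracy),
      sensitivity = c(disc_roc$sensitivity, val$sensitivity),
      specificity = c(disc_roc$specificity, val$specificity)),
      file.path(out_dir, "classifier_performance.tsv"))
    list(model = model, discovery = disc_roc, validation = val)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stages)
}
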