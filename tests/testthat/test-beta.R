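test_that("Jaccard and Bray-Curtis match vegan and handle edge cases", {
  skip_if_not_installed("vegan")
  for (i in 1:8) {
    tb <- make_table(6, 10, seed = i)
    m <- unclass(tb)
    expect_equal(unclass(distance_matrix(tb, "bray_curtis")),
                 as.matrix(vegan::vegdist(m, "bray")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unclass(distance_matrix(tb, "jaccard")),
                 as.matrix(vegan::vegdist(m, "jaccard", binary = TRUE)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  m <- rbind(s1 = c(3L, 2L, 0L), s2 = c(3L, 2L, 0L), s3 = c(0L, 0L, 9L))
  colnames(m) <- c("a", "b", "c")
  for (metric in c("jaccard", "bray_curtis")) {
    d <- unclass(distance_matrix(otu_table(m), metric))
    expect_equal(d["s1", "s2"], 0)   # identical samples
    expect_equal(d["s1", "s3"], 1)   # disjoint feature sets
  }
})

test_that("UniFrac reproduces the hand branch walk on a 3-tip tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  m <- rbind(s1 = c(A = 1L, B = 0L, C = 0L), s2 = c(A = 0L, B = 0L, C = 1L))
  tb <- otu_table(m)
  expect_equal(distance_matrix(tb, "unweighted_unifrac", tree = tr)[1, 2], 1)
  # weighted: |1-0|*1 (A) + |1-0|*1 (AB stem) + |0-1|*2 (C) = 4
  expect_equal(distance_matrix(tb, "weighted_unifrac", tree = tr)[1, 2], 4)
  # normalized variant: 4 / (1*1 + 1*1 + 2*1) = 1
  expect_equal(distance_matrix(tb, "weighted_unifrac", tree = tr,
                               normalized = TRUE)[1, 2], 1)
  expect_error(distance_matrix(otu_table(cbind(m, D = c(1L, 1L))),
                               "unweighted_unifrac", tree = tr),
               "missing feature\\(s\\): D")
  expect_error(distance_matrix(tb, "weighted_unifrac"), "require a tree")
})

test_that("UniFrac agrees with the phyloseq implementation on random data", {
  skip_if_not_installed("phyloseq")
  set.seed(42)
  ntip <- 12
  tr <- ape::rtree(ntip, tip.label = paste0("f", 1:ntip))
  tb <- make_table(5, ntip, seed = 9)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(unclass(tb)), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  for (spec in list(list("unweighted_unifrac", FALSE, FALSE),
                    list("weighted_unifrac", TRUE, FALSE),
                    list("weighted_unifrac", TRUE, TRUE))) {
    mine <- unclass(distance_matrix(tb, spec[[1]], tree = tr,
                                    normalized = spec[[3]]))
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = spec[[2]],
                                       normalized = spec[[3]]))
    expect_equal(mine, ref[rownames(mine), colnames(mine)],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("unweighted UniFrac on a unit-branch star tree equals Jaccard", {
  set.seed(5)
  ntip <- 10
  star <- ape::stree(ntip, type = "star", tip.label = paste0("f", 1:ntip))
  star$edge.length <- rep(1, nrow(star$edge))
  tb <- otu_table(matrix(stats::rbinom(6 * ntip, 1, 0.5) * 3L, 6, ntip,
                         dimnames = list(paste0("s", 1:6),
                                         paste0("f", 1:ntip))))
  expect_equal(unclass(distance_matrix(tb, "unweighted_unifrac", tree = star)),
               unclass(distance_matrix(tb, "jaccard")), tolerance = 1e-12)
})

test_that("PCoA: simplex geometry, reconstruction, and the 2-point case", {
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  pc <- pcoa(distance_matrix_obj(d3))
  expect_equal(pc$eigenvalues[1], pc$eigenvalues[2], tolerance = 1e-10)
  expect_equal(as.numeric(dist(pc$coordinates)), rep(1, 3), tolerance = 1e-10)
  # Euclidean input distances are reproduced exactly in full rank
  set.seed(8)
  X <- matrix(stats::rnorm(5 * 3), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  dm <- as.matrix(dist(X))
  pc2 <- pcoa(distance_matrix_obj(dm))
  expect_equal(as.matrix(dist(pc2$coordinates)), dm,
               tolerance = 1e-8, ignore_attr = TRUE)
  # against the base-R classical scaling oracle
  ref <- stats::cmdscale(dm, k = 4, eig = TRUE)
  expect_equal(pc2$eigenvalues[1:4], ref$eig[1:4], tolerance = 1e-8)
  # two points at distance d sit at +- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc3 <- pcoa(distance_matrix_obj(d2), k = 1)
  expect_equal(sort(as.numeric(pc3$coordinates)), c(-1.5, 1.5), tolerance = 1e-10)
  expect_true(all(diff(pc2$eigenvalues) <= 1e-8))   # descending
  expect_lte(sum(pc2$proportion_explained), 1 + 1e-12)
})

test_that("PERMANOVA matches vegan's pseudo-F and the exhaustive 3+3 oracle", {
  skip_if_not_installed("vegan")
  tb <- make_table(6, 10, seed = 1)
  g <- rep(c("case", "control"), each = 3)
  dm <- distance_matrix(tb, "bray_curtis")
  pm <- permanova(dm, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(unclass(dm)) ~ g, permutations = 99)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-10)
  # exhaustive oracle: p over all choose(6,3) = 20 label splits
  f_of <- function(gi) permanova(dm, gi, n_permutations = 0, seed = 1)$pseudo_F
  splits <- utils::combn(6, 3)
  f_all <- apply(splits, 2, function(idx) {
    gi <- rep("control", 6); gi[idx] <- "case"; f_of(gi)
  })
  p_exact <- mean(f_all >= f_of(g) - 1e-12)
  pm2 <- permanova(dm, g, n_permutations = 999, seed = 7)
  expect_lt(abs(pm2$p - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 999) + 1e-3)
})

test_that("PERMANOVA saturates, is order-invariant, and validates input", {
  set.seed(31)
  # two far-separated clusters (10+10, so no random permutation can
  # reproduce the split): minimum attainable p at 999 permutations
  m <- rbind(matrix(c(100L, 0L), 10, 2, byrow = TRUE),
             matrix(c(0L, 100L), 10, 2, byrow = TRUE))
  m <- m + matrix(sample(0:3, 40, TRUE), 20, 2)
  dimnames(m) <- list(paste0("s", 1:20), c("a", "b"))
  dm <- distance_matrix(otu_table(m), "bray_curtis")
  g <- rep(c("case", "control"), each = 10)
  pm <- permanova(dm, g, n_permutations = 999, seed = 3)
  expect_equal(pm$p, 1 / 1000)
  # pseudo-F invariant to sample reordering
  ord <- sample(20)
  pm2 <- permanova(distance_matrix_obj(unclass(dm)[ord, ord]), g[ord],
                   n_permutations = 9, seed = 1)
  expect_equal(pm2$pseudo_F, pm$pseudo_F, tolerance = 1e-12)
  expect_error(permanova(dm, rep("case", 20), 99), "at least two groups")
  expect_error(permanova(dm, c("case", rep("control", 19)), 99), ">= 2 samples")
  # stratified (within-pair) permutation runs and is valid
  strata <- rep(1:10, each = 2)
  pm3 <- permanova(dm, rep(c("case", "control"), 10), 99, seed = 2,
                   strata = strata)
  expect_gte(pm3$p, 1 / 100)
})
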