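#' Read a rooted phylogenetic tree (newick)
#'
#' Thin validating wrapper around [ape::read.tree()].  Leaf labels must be
#' unique; every branch needs a finite non-negative length.  Trees written
#' without some branch lengths are either rejected (`strict = TRUE`) or
#' patched with length 0 and a warning.
#'
#' @param path newick file.
#' @param strict reject missing branch lengths instead of defaulting to 0.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, strict = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort_validation(sprintf("'%s': not a parseable newick tree", path))
  if (anyDuplicated(tr$tip.label))
    abort_validation("tree has duplicated leaf labels")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(NA_real_, nrow(tr$edge))
  miss <- !is.finite(tr$edge.length)
  if (any(miss)) {
    if (strict) abort_validation("tree has branches without a finite length")
    warning(sprintf("%d branch length(s) missing; defaulting to 0", sum(miss)))
    tr$edge.length[miss] <- 0
  }
  if (any(tr$edge.length < 0))
    abort_validation("tree has negative branch lengths")
  tr
}

#' Write a tree as newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct a distance matrix object
#'
#' Symmetric non-negative pairwise dissimilarities with a zero diagonal,
#' labeled by sample id.
#'
#' @param d square numeric matrix with dimnames.
#' @return a `distance_matrix` (numeric matrix with class attribute).
#' @export
distance_matrix_obj <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    abort_validation("distance matrix must be square")
  if (is.null(rownames(d))) abort_validation("distance matrix needs sample ids")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10, check.attributes = FALSE)))
    abort_validation("distance matrix not symmetric")
  if (any(!is.finite(d)) || any(d < -1e-12))
    abort_validation("distances must be finite and non-negative")
  if (any(abs(diag(d)) > 1e-12))
    abort_validation("distance matrix diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  colnames(d) <- rownames(d)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Read / write a square labeled distance matrix (TSV)
#' @param path file path.
#' @return a [distance_matrix_obj()].
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE,
                                   comment.char = "", fileEncoding = "UTF-8"))
  distance_matrix_obj(m)
}

#' @rdname read_distance_matrix
#' @param dm a `distance_matrix`.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), unclass(dm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
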