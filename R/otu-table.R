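#' Construct an OTU count table
#'
#' The package's central container: a non-negative integer matrix of read
#' counts with samples as rows and features (OTUs or aggregated taxa) as
#' columns.  Row and column names are the sample and feature identifiers and
#' must be unique and non-empty.
#'
#' @param counts numeric matrix (samples x features) of non-negative whole
#'   numbers.  Dimnames may be supplied here or via `sample_ids` /
#'   `feature_ids`.
#' @param sample_ids,feature_ids optional character vectors overriding the
#'   matrix dimnames.
#' @return an `otu_table` object (integer matrix with class attribute).
#' @export
#' @examples
#' tb <- otu_table(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))))
#' sample_depths(tb)
otu_table <- function(counts, sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(feature_ids)) colnames(counts) <- feature_ids
  storage.mode(counts) <- "double"
  validate_otu_counts(counts)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

validate_otu_counts <- function(counts) {
  if (is.null(rownames(counts)) || (ncol(counts) > 0 && is.null(colnames(counts))))
    abort_validation("OTU table needs sample (row) and feature (column) ids")
  if (anyDuplicated(rownames(counts)))
    abort_validation(sprintf("duplicated sample id: '%s'",
                             rownames(counts)[duplicated(rownames(counts))][1]))
  if (anyDuplicated(colnames(counts)))
    abort_validation(sprintf("duplicated feature id: '%s'",
                             colnames(counts)[duplicated(colnames(counts))][1]))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    abort_validation(sprintf(
      "invalid count at sample '%s', feature '%s': %s (must be a non-negative integer)",
      rownames(counts)[i[1]], colnames(counts)[i[2]], counts[bad[1]]))
  }
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d features, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Per-sample sequencing depth (row sums)
#' @param table an [otu_table()].
#' @return named numeric vector of read totals per sample.
#' @export
sample_depths <- function(table) {
  rowSums(unclass(table))
}

#' Relative abundances
#'
#' @param table an [otu_table()].
#' @param scale total each sample is scaled to (1 for proportions, 1e6 for
#'   the counts-per-million convention used by the effect-size scorer).
#' @return numeric matrix, each row summing to `scale` (all-zero samples
#'   stay zero).
#' @export
relative_abundance <- function(table, scale = 1) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  depth <- rowSums(m)
  depth[depth == 0] <- 1
  m / depth * scale
}

#' Read an OTU table from TSV
#'
#' Strict reader: tab-separated, first column holds ids, remaining cells must
#' be non-negative whole numbers.  A leading `"#OTU ID"`-style header cell is
#' tolerated.  Nothing is silently coerced; offending cells are reported with
#' their row/column address.
#'
#' @param path file path.
#' @param orientation `"samples-as-rows"` (default) or `"features-as-rows"`
#'   (the common QIIME layout); the returned table is always samples x
#'   features.  Auto-detection is deliberately not offered: silent
#'   transposition is a classic microbiome-pipeline bug.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path,
                           orientation = c("samples-as-rows", "features-as-rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#(?!OTU)", lines, perl = TRUE)]  # comments, keep "#OTU ID"
  if (length(lines) < 2)
    abort_validation(sprintf("'%s': need a header line and at least one data line", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_hdr <- length(cells[[1]])
  if (ncol_hdr < 2)
    abort_validation(sprintf("'%s' line 1: malformed header (no tab found)", path))
  col_ids <- cells[[1]][-1]
  row_ids <- vapply(cells[-1], `[[`, "", 1L)
  mat <- matrix(NA_real_, length(row_ids), length(col_ids),
                dimnames = list(row_ids, col_ids))
  for (i in seq_along(row_ids)) {
    v <- cells[[i + 1L]]
    if (length(v) != ncol_hdr)
      abort_validation(sprintf("'%s' line %d: %d fields, header has %d",
                               path, i + 1L, length(v), ncol_hdr))
    num <- suppressWarnings(as.numeric(v[-1]))
    bad <- which(is.na(num))
    if (length(bad))
      abort_validation(sprintf("'%s' row '%s', column '%s': non-numeric cell '%s'",
                               path, row_ids[i], col_ids[bad[1]], v[bad[1] + 1L]))
    mat[i, ] <- num
  }
  if (orientation == "features-as-rows") mat <- t(mat)
  otu_table(mat)
}

#' Write an OTU table as TSV
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @param orientation layout to write (see [read_otu_table()]).
#' @return `path`, invisibly.  Round-trips bit-exactly through
#'   [read_otu_table()].
#' @export
write_otu_table <- function(table, path,
                            orientation = c("samples-as-rows", "features-as-rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  first <- "#OTU ID"
  if (orientation == "features-as-rows") m <- t(m)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(first, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a taxonomy map
#'
#' Two-column TSV `feature_id <TAB> lineage`, lineage being semicolon- (or
#' pipe-) separated rank labels kingdom..genus(..species).  Unassigned ranks
#' may be empty or `"unassigned"`.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id` and `kingdom`..`species`
#'   (class `taxonomy_map`); unassigned ranks are `NA`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    abort_validation(sprintf("'%s': expected feature_id<TAB>lineage", path))
  taxonomy_map(stats::setNames(df[[2]], df[[1]]))
}

#' Build a taxonomy map from lineage strings
#'
#' @param lineages named character vector, names = feature ids, values =
#'   semicolon-separated lineages (`k__...;p__...;...;g__...`).
#' @return a `taxonomy_map` data.frame.
#' @export
taxonomy_map <- function(lineages) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if (is.null(names(lineages)) || anyDuplicated(names(lineages)))
    abort_validation("taxonomy lineages need unique feature-id names")
  parts <- strsplit(as.character(lineages), "[;|]")
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == "" | tolower(p) == "unassigned"] <- NA_character_
    length(p) <- 7L
    p
  }, character(7)))
  colnames(mat) <- ranks
  out <- data.frame(feature_id = names(lineages), mat,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_map`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  lin <- apply(taxonomy[ranks], 1L, function(r) {
    r[is.na(r)] <- "unassigned"
    paste(r, collapse = ";")
  })
  write_tsv(data.frame(feature_id = taxonomy$feature_id, lineage = lin), path)
}
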