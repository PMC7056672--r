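#' Construct sample metadata
#'
#' Per-sample design information for a matched case-control cohort: group
#' label, optional matched-pair id, discovery/validation set assignment and
#' any number of numeric clinical indices.  Missing clinical values are kept
#' as `NA` (flagged, never imputed or zeroed at this layer).
#'
#' Invariants enforced: exactly two group levels named `case`/`control`;
#' every used `pair_id` pairs exactly one case with one control; set
#' assignment is constant within a pair.
#'
#' @param df data.frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`), optionally `pair_id`, `set`
#'   (`"discovery"`/`"validation"`), plus numeric clinical columns.
#' @param clinical_vars character vector naming the clinical columns; by
#'   default every column other than the design columns.
#' @return a `sample_metadata` data.frame with attribute `clinical_vars`.
#' @export
sample_metadata <- function(df, clinical_vars = NULL) {
  stopifnot(is.data.frame(df))
  design <- c("sample_id", "group", "pair_id", "set")
  if (!all(c("sample_id", "group") %in% names(df)))
    abort_validation("metadata needs 'sample_id' and 'group' columns")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    abort_validation(sprintf("duplicated sample id '%s' in metadata",
                             df$sample_id[duplicated(df$sample_id)][1]))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    abort_validation(sprintf("unknown group level '%s' (expected case/control)", bad[1]))
  if ("set" %in% names(df)) {
    bad <- setdiff(unique(df$set), c("discovery", "validation"))
    if (length(bad))
      abort_validation(sprintf("unknown set level '%s'", bad[1]))
  }
  if ("pair_id" %in% names(df)) {
    used <- !is.na(df$pair_id) & df$pair_id != ""
    for (p in unique(df$pair_id[used])) {
      g <- df$group[used & df$pair_id == p]
      if (length(g) != 2L || sort(g)[1] != "case" || sort(g)[2] != "control")
        abort_validation(sprintf(
          "pair '%s' must contain exactly one case and one control", p))
      if ("set" %in% names(df) &&
          length(unique(df$set[used & df$pair_id == p])) != 1L)
        abort_validation(sprintf("pair '%s' split across sets", p))
    }
  }
  if (is.null(clinical_vars)) clinical_vars <- setdiff(names(df), design)
  for (v in clinical_vars) {
    if (!is.numeric(df[[v]]))
      abort_validation(sprintf("clinical column '%s' is not numeric", v))
  }
  structure(df, class = c("sample_metadata", "data.frame"),
            clinical_vars = clinical_vars)
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("sample_metadata: %d samples (%d case / %d control), %d clinical indices\n",
              nrow(x), sum(x$group == "case"), sum(x$group == "control"),
              length(attr(x, "clinical_vars"))))
  invisible(x)
}

#' Clinical variable names of a metadata object
#' @param metadata a [sample_metadata()].
#' @return character vector.
#' @export
clinical_vars <- function(metadata) attr(metadata, "clinical_vars")

#' Read sample metadata from TSV
#'
#' Tab-separated with header; `NA` (the single accepted missing token) marks
#' missing clinical values.  Non-numeric tokens in a declared clinical
#' column are a validation error naming the cell, not a silent `NA`.
#'
#' @param path file path.
#' @param clinical_vars optional declaration of which columns are clinical;
#'   default: every column beyond the design columns.
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path, clinical_vars = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (is.null(clinical_vars))
    clinical_vars <- setdiff(names(df), c("sample_id", "group", "pair_id", "set"))
  for (v in clinical_vars) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(is.na(raw) | raw == "NA" | raw == ""))
    if (length(bad))
      abort_validation(sprintf("'%s' row '%s', column '%s': non-numeric value '%s'",
                               path, df$sample_id[bad[1]], v, raw[bad[1]]))
    df[[v]] <- num
  }
  sample_metadata(df, clinical_vars)
}

#' Write sample metadata as TSV
#' @param metadata a [sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write_tsv(as.data.frame(metadata), path)
}
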