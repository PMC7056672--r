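#' Discard rare features
#'
#' Removes every feature whose total count across all samples is strictly
#' below `min_fraction` of the table's grand total (the classic "< 0.005 %
#' of all sequences" OTU filter; note the strict inequality — a feature
#' sitting exactly on the threshold is kept).
#'
#' @param table an [otu_table()].
#' @param min_fraction fraction of the grand total in `[0, 1)`;
#'   default `5e-5` (= 0.005 %).
#' @return filtered [otu_table()] (sample set unchanged) with attribute
#'   `removed_features` listing the discarded feature ids.
#' @export
filter_rare_otus <- function(table, min_fraction = 5e-5) {
  stopifnot(min_fraction >= 0, min_fraction < 1)
  totals <- colSums(unclass(table))
  cut <- min_fraction * sum(as.numeric(totals))
  drop <- totals < cut
  out <- otu_table(unclass(table)[, !drop, drop = FALSE])
  attr(out, "removed_features") <- colnames(table)[drop]
  out
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (multivariate hypergeometric).  Samples with fewer than `depth` reads are
#' dropped with a warning, never scaled.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (default 36,000).
#' @param seed integer seed; the operation is reproducible from it.
#' @return rarefied [otu_table()]; every retained row sums to `depth`.
#'   Attribute `dropped_samples` lists samples below depth.
#' @export
rarefy <- function(table, depth = 36000, seed = NULL) {
  stopifnot(depth > 0, depth == round(depth))
  m <- unclass(table)
  keep <- rowSums(m) >= depth
  if (!any(keep)) abort_validation(sprintf("no sample has >= %d reads", depth))
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) below rarefaction depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(m)[!keep], collapse = ", ")))
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(m, 1L, function(r) {
      if (sum(r) == depth) return(as.integer(r))
      reads <- rep.int(seq_along(r), r)
      tabulate(reads[sample.int(length(reads), depth)], nbins = length(r))
    }))
  })
  dimnames(out) <- dimnames(m)
  res <- otu_table(out)
  attr(res, "dropped_samples") <- rownames(table)[!keep]
  res
}

#' Aggregate features to a taxonomic rank
#'
#' Sums counts over features sharing the same lineage down to `rank`.
#' Features missing from the taxonomy, or unassigned at `rank`, are pooled
#' into a single `"unassigned@<rank>"` feature so the grand total is
#' conserved exactly.
#'
#' @param table an [otu_table()].
#' @param taxonomy a [taxonomy_map()] covering the table's features.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @param label `"rank"` to name output features by the rank label alone
#'   (e.g. the genus name), `"lineage"` for the full prefix.
#' @return aggregated [otu_table()].
#' @export
aggregate_to_rank <- function(table, taxonomy,
                              rank = c("genus", "family", "order", "class", "phylum"),
                              label = c("rank", "lineage")) {
  rank <- match.arg(rank)
  label <- match.arg(label)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  upto <- seq_len(match(rank, ranks))
  idx <- match(colnames(table), taxonomy$feature_id)
  key <- vapply(seq_along(idx), function(j) {
    if (is.na(idx[j])) return(NA_character_)
    lin <- unlist(taxonomy[idx[j], ranks[upto]], use.names = FALSE)
    if (is.na(lin[length(upto)])) return(NA_character_)
    if (label == "rank") lin[length(upto)] else paste(lin, collapse = ";")
  }, character(1))
  key[is.na(key)] <- paste0("unassigned@", rank)
  m <- unclass(table)
  groups <- factor(key, levels = unique(key))
  agg <- t(rowsum(t(m), groups))
  colnames(agg) <- levels(groups)
  otu_table(agg)
}
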