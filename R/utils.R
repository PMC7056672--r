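#' Run code with a temporary RNG seed
#'
#' Sets the given seed, runs `code`, and restores the caller's RNG state
#' afterwards, so package functions never clobber the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one pipeline seed to named stages: the stage name
#' is hashed with a 31-ary polynomial rolling hash and folded into the global
#' seed modulo 2^31 - 1, so every stage gets an independent, reproducible
#' stream and the result always fits a 32-bit R integer.
#'
#' @param seed global integer seed.
#' @param stage character stage name, e.g. `"rarefy"`.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "rarefy")
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  as.integer((as.numeric(seed) %% m + h) %% m)
}

# Internal: stop with a consistent error class for validation failures.
abort_validation <- function(msg, class = "microgdm_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Internal: 31-ary polynomial rolling hash of a character scalar, returned
# as hex.  Used for config fingerprints in pipeline manifests (avoids an
# external digest dependency; not cryptographic).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# Internal: write a data.frame as plain TSV (no quoting surprises).
write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
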