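# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the session stream.
#' A `NULL` seed evaluates `expr` under the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a base seed, kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

col_sds <- function(x) {
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = nrow(x)))^2) / (nrow(x) - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Write a table as TSV with a '#'-prefixed metadata header
#'
#' Output tables carry their provenance (parameters, seeds) as
#' `# key=value` lines before the header row. No timestamps are written, so
#' reruns at the same seed are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param meta named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15, trim = TRUE)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path file path.
#' @return data.frame with a `"meta"` attribute holding the parsed
#'   `# key=value` header lines as a named character vector.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- character(0)
  if (any(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    eq <- regexpr("=", kv, fixed = TRUE)
    meta <- stats::setNames(substring(kv, eq + 1L), substring(kv, 1L, eq - 1L))
  }
  df <- utils::read.table(text = lines[!hdr], sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
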