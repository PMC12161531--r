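#' Cells-by-markers intensity matrix
#'
#' The central container for single-cell CyTOF data: a numeric matrix of
#' per-cell, per-marker ion counts (raw, non-negative) or transformed
#' intensities, together with a per-cell sample label and the panel that maps
#' markers to roles.
#'
#' @param values numeric cells x markers matrix with column names matching
#'   the panel's marker names. Raw matrices must be non-negative.
#' @param panel a [panel_config()].
#' @param sample_label per-cell character/factor vector (recycled if length 1).
#' @param transformed logical; `TRUE` once intensities are no longer raw
#'   counts (arcsinh/normalized values may be negative).
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(values, panel, sample_label = "sample1",
                          transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stopf("marker_matrix needs at least one cell")
  if (is.null(colnames(values)))
    stopf("marker_matrix values must have marker column names")
  stopifnot(inherits(panel, "panel_config"))
  miss <- setdiff(colnames(values), panel$channels$marker_name)
  if (length(miss))
    stopf("columns absent from panel: %s", paste(miss, collapse = ", "))
  if (!transformed && any(values < 0))
    stopf("raw marker_matrix has negative entries")
  if (length(sample_label) == 1L) sample_label <- rep(sample_label, nrow(values))
  if (length(sample_label) != nrow(values))
    stopf("sample_label length (%d) != number of cells (%d)",
          length(sample_label), nrow(values))
  structure(list(values = values, panel = panel,
                 sample_label = as.character(sample_label),
                 transformed = transformed),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d cells x %d markers (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "transformed" else "raw"))
  tab <- table(x$sample_label)
  cat("  samples:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Subset a marker matrix by cells and/or markers
#'
#' @param m a [marker_matrix()].
#' @param cells logical/integer cell index (default all).
#' @param markers character vector of marker names (default all).
#' @return a `marker_matrix` (panel is carried over unchanged).
#' @export
subset_cells <- function(m, cells = NULL, markers = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  v <- m$values
  lab <- m$sample_label
  if (!is.null(cells)) {
    v <- v[cells, , drop = FALSE]
    lab <- lab[cells]
  }
  if (!is.null(markers)) v <- v[, markers, drop = FALSE]
  if (nrow(v) < 1L) stopf("subset leaves no cells")
  marker_matrix(v, m$panel, lab, transformed = m$transformed)
}

# Extract marker columns of given roles as a plain matrix.
role_values <- function(m, role) {
  keep <- intersect(colnames(m$values), panel_markers(m$panel, role))
  m$values[, keep, drop = FALSE]
}
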