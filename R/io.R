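#' Read a cells-by-markers matrix from FCS or delimited text
#'
#' Accepts either an FCS 3.0/3.1 file (the CyTOF container format; events are
#' assumed already de-barcoded and bead/viability gated upstream) or a
#' delimited text table with a header row. Channels are mapped to the panel's
#' marker names; file channels absent from the panel are kept with role
#' `ignore`. Event order is preserved.
#'
#' @param path path to an `.fcs` file or a TSV/CSV table.
#' @param panel a [panel_config()]. For text input, a column matching
#'   `panel$sample_key` supplies the per-cell sample label.
#' @param sample_label label used when the file carries none.
#' @return a [marker_matrix()].
#' @export
read_marker_matrix <- function(path, panel, sample_label = "sample1") {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (is_fcs_file(path)) {
    raw <- read_fcs(path)
    mat <- raw$data
    # map channel ids to marker names where the panel knows them
    idx <- match(colnames(mat), panel$channels$channel_id)
    known <- !is.na(idx)
    colnames(mat)[known] <- panel$channels$marker_name[idx[known]]
  } else {
    df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!nrow(df)) stopf("'%s' contains no events", path)
    if (panel$sample_key %in% names(df)) {
      sample_label <- as.character(df[[panel$sample_key]])
      df[[panel$sample_key]] <- NULL
    }
    mat <- as.matrix(df)
    storage.mode(mat) <- "double"
  }
  panel <- extend_panel_ignore(panel, colnames(mat))
  check_core_histones(panel)
  marker_matrix(mat, panel, sample_label)
}

# Columns present in the data but not the panel are appended with role ignore.
extend_panel_ignore <- function(panel, marker_names) {
  extra <- setdiff(marker_names, panel$channels$marker_name)
  if (!length(extra)) return(panel)
  panel$channels <- rbind(panel$channels,
                          data.frame(channel_id = extra, marker_name = extra,
                                     role = "ignore", stringsAsFactors = FALSE))
  panel
}

guess_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  first <- lines[!grepl("^#", lines)][1]
  if (is.na(first) || grepl("\t", first)) "\t" else ","
}

#' Write a marker matrix as TSV (with sample label column)
#'
#' @param m a [marker_matrix()].
#' @param path output path.
#' @param meta named list of metadata written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, meta = list()) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- data.frame(sample = m$sample_label, check.names = FALSE)
  names(df) <- m$panel$sample_key
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  write_tsv_meta(df, path, meta)
}

#' Read a cells-by-genes expression matrix
#'
#' Supports a dense delimited table (header = gene names, optional first
#' column of cell names) or a MatrixMarket triplet file with `<path>.rows`
#' and `<path>.cols` sidecar files naming cells and genes.
#'
#' @param path path to the matrix file.
#' @return numeric cells x genes matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (!file.size(path)) stopf("'%s' is empty: not a valid expression matrix", path)
  first <- readLines(path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    mm <- as.matrix(Matrix::readMM(path))
    storage.mode(mm) <- "double"
    rows_f <- paste0(path, ".rows"); cols_f <- paste0(path, ".cols")
    if (file.exists(rows_f)) {
      rn <- readLines(rows_f)
      if (length(rn) != nrow(mm))
        stopf("row sidecar has %d names but matrix has %d rows", length(rn), nrow(mm))
      rownames(mm) <- rn
    }
    if (file.exists(cols_f)) {
      cn <- readLines(cols_f)
      if (length(cn) != ncol(mm))
        stopf("column sidecar has %d names but matrix has %d columns", length(cn), ncol(mm))
      colnames(mm) <- cn
    }
    return(mm)
  }
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stopf("'%s' has a header but no cells", path)
  if (!is.numeric(df[[1]])) {
    rn <- df[[1]]; df <- df[, -1, drop = FALSE]; rownames(df) <- rn
  }
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  mat
}

#' Write an expression matrix (dense TSV or MatrixMarket triplet)
#'
#' @param x cells x genes matrix.
#' @param path output path; a `.mtx` extension selects MatrixMarket with
#'   `.rows`/`.cols` sidecars, anything else a dense TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  if (grepl("\\.mtx$", path)) {
    nz <- which(x != 0, arr.ind = TRUE)
    Matrix::writeMM(Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2],
                                         x = x[nz], dims = dim(x)), path)
    writeLines(rownames(x) %||% paste0("cell", seq_len(nrow(x))), paste0(path, ".rows"))
    writeLines(colnames(x) %||% paste0("gene", seq_len(ncol(x))), paste0(path, ".cols"))
  } else {
    df <- data.frame(cell = rownames(x) %||% paste0("cell", seq_len(nrow(x))),
                     as.data.frame(x, check.names = FALSE), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
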