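# Minimal FCS 3.0/3.1 support.
#
# Only what the pipeline needs: list-mode (`$MODE L`) float or integer data,
# one data segment, little- or big-endian. The writer emits float32
# little-endian FCS 3.0 and exists mainly so fixtures and exports round-trip
# through the same code path users' acquisition software produces. The FCS
# dialect/version exported by vendor software is not assumed beyond 3.0/3.1.

is_fcs_file <- function(path) {
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 3L))
  identical(magic, "FCS")
}

#' Read an FCS 3.0/3.1 file
#'
#' @param path file path.
#' @return list with `data` (events x channels numeric matrix, columns named
#'   by `$PnN`) and `keywords` (named character vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("'%s' is not an FCS 3.0/3.1 file (header '%s')", path, version)
  off <- function(i) as.numeric(trimws(substr(header, 11 + 8 * (i - 1), 10 + 8 * i)))
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", text_end - text_beg + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[c(FALSE, TRUE)], trimws(parts[c(TRUE, FALSE)]))

  if (data_beg == 0) data_beg <- as.numeric(kw[["$BEGINDATA"]])
  if (data_end == 0) data_end <- as.numeric(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (grepl("^1", byteord)) "little" else "big"
  bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])

  seek(con, data_beg)
  n_values <- n_par * n_tot
  vals <- switch(dtype,
    "F" = readBin(con, "double", n_values, size = 4L, endian = endian),
    "D" = readBin(con, "double", n_values, size = 8L, endian = endian),
    "I" = readBin(con, "integer", n_values, size = bits %/% 8L,
                  signed = FALSE, endian = endian),
    stopf("unsupported $DATATYPE '%s' in '%s'", dtype, path))
  data <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(data) <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), character(1))
  list(data = data, keywords = kw)
}

#' Write a matrix as FCS 3.0 (float32, little-endian)
#'
#' @param x events x channels numeric matrix with channel column names.
#' @param path output path.
#' @param extra_keywords named character vector merged into the TEXT segment.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, extra_keywords = character(0)) {
  x <- as.matrix(x)
  n_tot <- nrow(x); n_par <- ncol(x)
  ch <- colnames(x) %||% sprintf("P%d", seq_len(n_par))
  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
          "$NEXTDATA" = "0")
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- ch[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(max(1, ceiling(max(x[, i], 0))),
                                      scientific = FALSE)
  }
  kw <- c(kw, extra_keywords)

  data_len <- 4L * n_par * n_tot
  # iterate: TEXT holds BEGINDATA/ENDDATA whose width can shift the layout
  text_beg <- 58L
  data_beg <- 0L
  for (pass in 1:3) {
    kw["$BEGINDATA"] <- as.character(data_beg)
    kw["$ENDDATA"] <- as.character(if (data_beg > 0) data_beg + data_len - 1L else 0L)
    text <- paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
    text_end <- text_beg + nchar(text, type = "bytes") - 1L
    data_beg_new <- text_end + 1L
    if (data_beg_new == data_beg) break
    data_beg <- data_beg_new
  }
  data_end <- data_beg + data_len - 1L
  pad8 <- function(n) formatC(n, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad8(text_beg), pad8(text_end),
                   if (data_end <= 99999999) paste0(pad8(data_beg), pad8(data_end))
                   else paste0(pad8(0), pad8(0)),
                   pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}
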