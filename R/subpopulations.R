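# Bimodal subpopulation analyses: 'WT-like' vs 'extreme' cells, contrast
# tables, and binned mean curves for non-linear marker relationships.

#' 'WT-like' fraction of a mutant population
#'
#' Operationalizes "overlapping with the reference distribution" as
#' membership in the central `coverage` quantile interval of the reference
#' marker values (default central 99%): mutant cells inside the interval are
#' 'WT-like', the rest 'extreme'.
#'
#' @param test marker values of the mutant cells.
#' @param reference marker values of the reference (WT) cells.
#' @param coverage central coverage of the reference interval, in (0, 1]
#'   (default 0.99).
#' @param marker marker name carried in the result (optional).
#' @return object of class `bimodal_split`: `reference_interval` (low,
#'   high), `wt_like_fraction`, `assignment` (per-test-cell factor
#'   `wt_like`/`extreme`).
#' @export
wt_like_fraction <- function(test, reference, coverage = 0.99, marker = NA_character_) {
  if (!length(test) || !length(reference)) stopf("empty input vector")
  if (coverage <= 0 || coverage > 1) stopf("coverage must be in (0, 1]")
  lo <- (1 - coverage) / 2
  interval <- unname(stats::quantile(reference, c(lo, 1 - lo)))
  inside <- test >= interval[1] & test <= interval[2]
  structure(list(marker = marker,
                 reference_interval = c(low = interval[1], high = interval[2]),
                 coverage = coverage,
                 wt_like_fraction = mean(inside),
                 assignment = factor(ifelse(inside, "wt_like", "extreme"),
                                     levels = c("wt_like", "extreme"))),
            class = "bimodal_split")
}

#' @export
print.bimodal_split <- function(x, ...) {
  cat(sprintf("bimodal_split%s: %.1f%% 'WT-like' (reference interval [%.3f, %.3f], coverage %g)\n",
              if (is.na(x$marker)) "" else sprintf(" (%s)", x$marker),
              100 * x$wt_like_fraction, x$reference_interval[1],
              x$reference_interval[2], x$coverage))
  invisible(x)
}

boot_se <- function(x, n_boot, seed) {
  with_seed(seed, {
    stats::sd(vapply(seq_len(n_boot), function(b)
      mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
  })
}

#' Subpopulation contrast table
#'
#' Per-marker differences of means between the 'extreme' and 'WT-like'
#' subpopulations of a split (and each versus an optional reference cell
#' set), with bootstrap standard errors.
#'
#' @param nm a `normalized_matrix` (or plain matrix) of the mutant cells,
#'   rows aligned with `split$assignment`.
#' @param split a [wt_like_fraction()] result.
#' @param reference_cells optional matrix of reference-population cells over
#'   the same markers.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame with one row per marker: `diff_extreme_wtlike` and its
#'   `se`, plus (with reference cells) `diff_extreme_ref`, `diff_wtlike_ref`
#'   and their SEs.
#' @export
subpopulation_contrast <- function(nm, split, reference_cells = NULL,
                                   n_boot = 1000L, seed = 1L) {
  x <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  stopifnot(inherits(split, "bimodal_split"),
            nrow(x) == length(split$assignment))
  wt <- x[split$assignment == "wt_like", , drop = FALSE]
  ex <- x[split$assignment == "extreme", , drop = FALSE]
  if (!nrow(wt) || !nrow(ex)) stopf("a subpopulation is empty")
  if (nrow(wt) < 10L || nrow(ex) < 10L)
    warnf("subpopulation smaller than 10 cells; bootstrap SEs will be noisy")
  se_diff <- function(a, b, k) sqrt(boot_se(a, n_boot, child_seed(seed, k))^2 +
                                    boot_se(b, n_boot, child_seed(seed, k + 1L))^2)
  out <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
    row <- data.frame(marker = colnames(x)[j],
                      diff_extreme_wtlike = mean(ex[, j]) - mean(wt[, j]),
                      se_extreme_wtlike = se_diff(ex[, j], wt[, j], 2L * j),
                      stringsAsFactors = FALSE)
    if (!is.null(reference_cells)) {
      rf <- as.matrix(reference_cells)[, colnames(x)[j]]
      row$diff_extreme_ref <- mean(ex[, j]) - mean(rf)
      row$se_extreme_ref <- se_diff(ex[, j], rf, 1000L + 2L * j)
      row$diff_wtlike_ref <- mean(wt[, j]) - mean(rf)
      row$se_wtlike_ref <- se_diff(wt[, j], rf, 2000L + 2L * j)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Binned mean curve of one marker against another
#'
#' Bins cells into `n_bins` equal-width bins over the x marker's range and
#' reports the mean, SEM (sd/sqrt(count)) and count of the y marker per bin.
#' Bins with fewer than `min_count` cells are masked (NA means). This is the
#' analysis behind bell-shaped mark-factor relationships (e.g., BCL6 levels
#' binned by H3K27me3).
#'
#' @param x,y equal-length numeric marker vectors.
#' @param n_bins number of equal-width bins (default 20).
#' @param min_count minimum cells per unmasked bin (default 50).
#' @return object of class `binned_curve`: data.frame-like list with
#'   `bin_edges`, `bin_mids`, `bin_means`, `bin_sems`, `bin_counts`,
#'   `masked`.
#' @export
binned_mean_curve <- function(x, y, n_bins = 20L, min_count = 50L) {
  stopifnot(length(x) == length(y), n_bins >= 2L)
  rng <- range(x)
  if (diff(rng) == 0) stopf("zero x range: all cells fall in one bin")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  means <- sems <- rep(NA_real_, n_bins)
  for (b in which(counts > 0L)) {
    yb <- y[bin == b]
    means[b] <- mean(yb)
    sems[b] <- if (length(yb) > 1L) stats::sd(yb) / sqrt(length(yb)) else 0
  }
  masked <- counts < min_count
  means[masked] <- NA_real_
  sems[masked] <- NA_real_
  structure(list(bin_edges = edges, bin_mids = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                 bin_means = means, bin_sems = sems, bin_counts = counts,
                 masked = masked, n = length(x)),
            class = "binned_curve")
}

#' @export
print.binned_curve <- function(x, ...) {
  cat(sprintf("binned_curve: %d bins over [%.3f, %.3f], %d cells (%d bins masked)\n",
              length(x$bin_counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n, sum(x$masked)))
  invisible(x)
}

#' @export
as.data.frame.binned_curve <- function(x, ...) {
  data.frame(bin_mid = x$bin_mids, mean = x$bin_means, sem = x$bin_sems,
             count = x$bin_counts, masked = x$masked)
}

#' Sign changes in the first differences of a binned curve
#'
#' A bell-shaped relationship rises then falls: exactly one sign change in
#' the first differences of the unmasked bin means.
#'
#' @param curve a [binned_mean_curve()] result.
#' @return number of sign changes.
#' @export
curve_sign_changes <- function(curve) {
  m <- curve$bin_means[!is.na(curve$bin_means)]
  if (length(m) < 3L) return(0L)
  s <- sign(diff(m))
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Pairwise mean-difference table across sample groups
#'
#' Per (group pair, marker): difference of means with a bootstrap standard
#' error — the numbers behind mean-difference heatmaps of mutant lines
#' versus a reference.
#'
#' @param nm a `normalized_matrix`.
#' @param pairs list of 2-element character vectors `c(group_a, group_b)`;
#'   differences are `mean(a) - mean(b)`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `group_a`, `group_b`, `marker`, `diff`,
#'   `se`.
#' @export
mean_difference_heatmap <- function(nm, pairs, n_boot = 1000L, seed = 1L) {
  x <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  lab <- if (inherits(nm, "normalized_matrix")) nm$sample_label
         else stopf("mean_difference_heatmap needs a normalized_matrix")
  if (length(pairs) && !is.list(pairs)) pairs <- list(pairs)
  out <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    for (g in pr) if (!any(lab == g)) stopf("unknown group '%s'", g)
    a <- x[lab == pr[1], , drop = FALSE]
    b <- x[lab == pr[2], , drop = FALSE]
    out[[k]] <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      data.frame(group_a = pr[1], group_b = pr[2], marker = colnames(x)[j],
                 diff = mean(a[, j]) - mean(b[, j]),
                 se = sqrt(boot_se(a[, j], n_boot, child_seed(seed, 10L * k + 2L * j))^2 +
                           boot_se(b[, j], n_boot, child_seed(seed, 10L * k + 2L * j + 1L))^2),
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
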