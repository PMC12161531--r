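#' Embed cells with UMAP across a parameter grid
#'
#' Jointly embeds all populations (optionally equal-subsampled) once per
#' parameter combination. Marker exclusion supports sensitivity analyses
#' such as removing H3K27me2/3 before embedding.
#'
#' @param nm a [standardize()] result (`normalized_matrix`).
#' @param n_neighbors,min_dist vectors defining the parameter grid
#'   (defaults `c(15, 30, 50, 100)` x `c(0.1, 0.3, 0.5)`).
#' @param exclude_markers markers left out of the embedding.
#' @param equal_subsample subsample populations to the smallest population
#'   size before embedding (default TRUE) so density artifacts do not
#'   confound area measures.
#' @param seed integer seed (fixed per setting).
#' @param n_threads threads passed to uwot (default 1 for determinism).
#' @return list of `embedding` objects: fields `coords` (cells x 2),
#'   `sample_label`, `params` (n_neighbors, min_dist, seed, excluded_markers).
#' @export
embed_cells <- function(nm, n_neighbors = c(15, 30, 50, 100),
                        min_dist = c(0.1, 0.3, 0.5),
                        exclude_markers = character(0),
                        equal_subsample = TRUE, seed = 1L, n_threads = 1L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  x <- nm$values[, setdiff(colnames(nm$values), exclude_markers), drop = FALSE]
  if (ncol(x) < 2L) stopf("need >= 2 markers after exclusions")
  lab <- nm$sample_label
  if (equal_subsample) {
    tab <- table(lab)
    n_min <- min(tab)
    keep <- with_seed(child_seed(seed, 999L), {
      unlist(lapply(names(tab), function(s) {
        idx <- which(lab == s)
        if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
      }))
    })
    keep <- sort(keep)
    x <- x[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  grid <- expand.grid(n_neighbors = n_neighbors, min_dist = min_dist)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    nn <- grid$n_neighbors[i]
    if (nrow(x) <= nn)
      stopf("n_neighbors=%d requires more than %d cells", nn, nrow(x))
    coords <- with_seed(child_seed(seed, i), {
      uwot::umap(x, n_neighbors = nn, min_dist = grid$min_dist[i],
                 n_threads = n_threads, n_sgd_threads = 0)
    })
    out[[i]] <- structure(
      list(coords = unname(coords), sample_label = lab,
           params = list(n_neighbors = nn, min_dist = grid$min_dist[i],
                         seed = seed, excluded_markers = exclude_markers)),
      class = "embedding")
  }
  out
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells (n_neighbors=%d, min_dist=%g)\n",
              nrow(x$coords), x$params$n_neighbors, x$params$min_dist))
  invisible(x)
}

pop_coords <- function(e, population) {
  stopifnot(inherits(e, "embedding"))
  idx <- e$sample_label == population
  if (!any(idx)) stopf("population '%s' absent from embedding", population)
  e$coords[idx, , drop = FALSE]
}

#' Gini coefficient of a non-negative vector
#'
#' Normalized mean absolute pairwise difference,
#' `sum_ij |x_i - x_j| / (2 n^2 mean)`: 0 for perfect equality, approaching 1
#' for extreme inequality. Values are shifted to non-negative before
#' computation; an all-zero vector is defined as 0.
#'
#' @param values numeric vector, length >= 2.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  if (min(values) < 0) values <- values - min(values)
  if (all(values == 0)) return(0)
  n <- length(values)
  s <- sort(values)
  # sorted-form identity of the double-sum definition
  (2 * sum(seq_len(n) * s) / (n * sum(s))) - (n + 1) / n
}

# Shoelace area of a polygon given vertex coordinates in order.
polygon_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Global area: convex-hull area of one population
#'
#' Area enclosed by the bounding convex hull of all the population's points
#' in embedding space.
#'
#' @param e an `embedding`.
#' @param population sample label.
#' @return hull area (0 with a warning for < 3 or collinear points).
#' @export
global_area <- function(e, population) {
  xy <- pop_coords(e, population)
  if (nrow(xy) < 3L) {
    warnf("global_area: fewer than 3 points, returning 0")
    return(0)
  }
  hull <- grDevices::chull(xy)
  if (length(hull) < 3L) {
    warnf("global_area: collinear points, returning 0")
    return(0)
  }
  polygon_area(xy[hull, , drop = FALSE])
}

#' Global distance: upper quantile of pairwise distances
#'
#' The `q` quantile (default 0.95) of all pairwise Euclidean distances within
#' a population. Exact for `n <= cap`; above the cap a seeded random set of
#' `n_pairs` pairs estimates the quantile.
#'
#' @param e an `embedding`.
#' @param population sample label.
#' @param q quantile in (0, 1).
#' @param cap maximum n for the exact O(n^2) computation (default 5000).
#' @param n_pairs subsampled pairs above the cap (default 2e6).
#' @param seed seed for pair subsampling.
#' @return distance quantile.
#' @export
global_distance <- function(e, population, q = 0.95, cap = 5000,
                            n_pairs = 2e6, seed = 1L) {
  if (q <= 0 || q >= 1) stopf("q must be in (0,1)")
  xy <- pop_coords(e, population)
  n <- nrow(xy)
  if (n < 2L) stopf("global_distance needs >= 2 points")
  if (n <= cap) {
    d <- stats::dist(xy)
    return(unname(stats::quantile(d, q)))
  }
  with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    ok <- i != j
    d <- sqrt(rowSums((xy[i[ok], , drop = FALSE] - xy[j[ok], , drop = FALSE])^2))
    unname(stats::quantile(d, q))
  })
}

#' Local area: occupied-grid area of one population
#'
#' Overlays a `grid_bins` x `grid_bins` grid on the joint (all-population)
#' bounding box and sums the area of grid cells containing at least
#' `min_count` points of the population. Dispersed clusters occupy more
#' cells, so this estimates the net area the population covers.
#'
#' @param e an `embedding`.
#' @param population sample label.
#' @param grid_bins grid resolution per axis (default 100).
#' @param min_count minimum points for a cell to count as occupied.
#' @return occupied area in squared embedding units (0 for a degenerate
#'   bounding box).
#' @export
local_area <- function(e, population, grid_bins = 100, min_count = 1) {
  xy <- pop_coords(e, population)
  rx <- range(e$coords[, 1]); ry <- range(e$coords[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) return(0)
  ix <- pmin(pmax(ceiling((xy[, 1] - rx[1]) / diff(rx) * grid_bins), 1L), grid_bins)
  iy <- pmin(pmax(ceiling((xy[, 2] - ry[1]) / diff(ry) * grid_bins), 1L), grid_bins)
  counts <- tabulate((iy - 1L) * grid_bins + ix, nbins = grid_bins^2)
  cell_area <- (diff(rx) / grid_bins) * (diff(ry) / grid_bins)
  sum(counts >= min_count) * cell_area
}

#' Nearest-neighbour distances within a population
#'
#' Per-point Euclidean distance to the nearest other point of the same
#' population (kd-tree search; duplicates give distance 0).
#'
#' @param e an `embedding`.
#' @param population sample label.
#' @return numeric vector of NNDs, one per point.
#' @export
nnd <- function(e, population) {
  xy <- pop_coords(e, population)
  if (nrow(xy) < 2L) stopf("nnd needs >= 2 points")
  res <- RANN::nn2(xy, xy, k = 2L)
  res$nn.dists[, 2]
}

#' Ratio of two empirical CDFs on a grid
#'
#' `ecdf_a(x) / ecdf_b(x)` evaluated on `grid`. Values below 1 mean the
#' first sample's distances are stochastically larger (more heterogeneity
#' when applied to NNDs of mutant vs reference). Grid points where the
#' denominator CDF is 0 are reported as `NA` (undefined), never 0 or Inf.
#'
#' @param nnd_a,nnd_b numeric samples (e.g., [nnd()] vectors).
#' @param grid evaluation points; default 50 points spanning the interior of
#'   the union range.
#' @return data.frame with columns `grid`, `cdf_a`, `cdf_b`, `ratio`.
#' @export
cdf_ratio <- function(nnd_a, nnd_b, grid = NULL) {
  if (!length(nnd_a) || !length(nnd_b)) stopf("cdf_ratio: empty input")
  if (is.null(grid)) {
    r <- range(c(nnd_a, nnd_b))
    grid <- seq(r[1], r[2], length.out = 52)[2:51]
  }
  fa <- stats::ecdf(nnd_a)(grid)
  fb <- stats::ecdf(nnd_b)(grid)
  ratio <- ifelse(fb == 0, NA_real_, fa / fb)
  data.frame(grid = grid, cdf_a = fa, cdf_b = fb, ratio = ratio)
}

#' Heterogeneity report over an embedding-parameter grid
#'
#' For each embedding, computes the four heterogeneity measures (global
#' convex-hull area, 95th-quantile pairwise distance, occupied-grid local
#' area, median NND) per population, their test/reference ratios, and the
#' NND CDF ratio. Per-marker Gini ratios are computed once from the marker
#' matrix (they do not depend on the embedding).
#'
#' @param embeddings list of `embedding` objects (see [embed_cells()]).
#' @param reference,test sample labels to compare; ratios are test/reference.
#' @param nm optional `normalized_matrix` for per-marker Gini ratios
#'   (computed on values shifted to non-negative per marker).
#' @param q quantile for global distance (default 0.95).
#' @param grid_bins local-area grid resolution (default 100).
#' @return object of class `heterogeneity_report`: `measures` (long
#'   data.frame of per-population values and ratios per parameter setting),
#'   `cdf_ratios` (list of [cdf_ratio()] tables), `gini` (per-marker table or
#'   NULL).
#' @export
heterogeneity_report <- function(embeddings, reference, test, nm = NULL,
                                 q = 0.95, grid_bins = 100) {
  if (inherits(embeddings, "embedding")) embeddings <- list(embeddings)
  rows <- list(); cdfs <- list()
  for (i in seq_along(embeddings)) {
    e <- embeddings[[i]]
    for (pop in c(reference, test))
      if (!any(e$sample_label == pop))
        stopf("population '%s' absent from embedding %d", pop, i)
    vals <- function(pop) {
      nv <- nnd(e, pop)
      c(global_area = global_area(e, pop),
        global_distance = global_distance(e, pop, q = q),
        local_area = local_area(e, pop, grid_bins = grid_bins),
        median_nnd = stats::median(nv))
    }
    vr <- vals(reference); vt <- vals(test)
    rows[[i]] <- data.frame(
      setting = i, n_neighbors = e$params$n_neighbors,
      min_dist = e$params$min_dist,
      measure = names(vr), reference = unname(vr), test = unname(vt),
      ratio = unname(vt / vr), stringsAsFactors = FALSE)
    cdfs[[i]] <- cdf_ratio(nnd(e, test), nnd(e, reference))
  }
  gtab <- NULL
  if (!is.null(nm)) {
    ref_idx <- nm$sample_label == reference
    test_idx <- nm$sample_label == test
    gtab <- do.call(rbind, lapply(colnames(nm$values), function(mk) {
      gr <- gini(nm$values[ref_idx, mk])
      gt <- gini(nm$values[test_idx, mk])
      data.frame(marker = mk, gini_reference = gr, gini_test = gt,
                 ratio = gt / gr, stringsAsFactors = FALSE)
    }))
  }
  structure(list(measures = do.call(rbind, rows), cdf_ratios = cdfs,
                 gini = gtab, reference = reference, test = test),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("heterogeneity_report: %s vs %s (%d parameter settings)\n",
              x$test, x$reference, length(x$cdf_ratios)))
  med <- stats::aggregate(ratio ~ measure, x$measures, stats::median)
  for (i in seq_len(nrow(med)))
    cat(sprintf("  median %s ratio: %.3f\n", med$measure[i], med$ratio[i]))
  invisible(x)
}

#' Subsampled transcriptional-heterogeneity statistic
#'
#' Per sample, draws `n_sub` cells `reps` times and records the mean pairwise
#' Euclidean distance on the expression matrix each time, giving a
#' distribution of mean distances per sample. With two samples the pooled
#' distributions are compared by Welch's unequal-variance t test.
#'
#' @param x cells x genes matrix.
#' @param labels per-cell sample labels.
#' @param n_sub cells sampled per repetition (default 300; lowered with a
#'   warning to the smallest sample size if needed).
#' @param reps repetitions (default 200).
#' @param seed integer seed.
#' @return list with `distributions` (named list of numeric vectors),
#'   `means` (per-sample mean of the distribution), and `test` (Welch t
#'   test, or NULL when degenerate or > 2 samples).
#' @export
transcriptional_heterogeneity <- function(x, labels, n_sub = 300, reps = 200,
                                          seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  samples <- unique(labels)
  if (length(samples) < 2L) stopf("need >= 2 samples to compare")
  n_min <- min(table(labels))
  if (n_sub > n_min) {
    warnf("n_sub lowered from %d to smallest sample size %d", n_sub, n_min)
    n_sub <- n_min
  }
  dists <- with_seed(seed, {
    lapply(stats::setNames(samples, samples), function(s) {
      idx <- which(labels == s)
      vapply(seq_len(reps), function(r) {
        sub <- x[sample(idx, n_sub), , drop = FALSE]
        mean(stats::dist(sub))
      }, numeric(1))
    })
  })
  test <- NULL
  if (length(samples) == 2L) {
    a <- dists[[1]]; b <- dists[[2]]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      test <- list(degenerate = TRUE,
                   reason = "zero variance in both distance distributions")
    } else {
      test <- stats::t.test(a, b, var.equal = FALSE)
    }
  }
  list(distributions = dists, means = vapply(dists, mean, numeric(1)),
       test = test)
}
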