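# Inter-modification influence networks: three complementary reconstructions
# from single-cell covariation of histone marks.

# Accept a normalized_matrix (modification columns by default), a
# marker_matrix, or a plain numeric matrix.
network_input <- function(nm, roles = "modification") {
  if (inherits(nm, "normalized_matrix")) {
    keep <- intersect(colnames(nm$values), panel_markers(nm$panel, roles))
    return(nm$values[, keep, drop = FALSE])
  }
  if (inherits(nm, "marker_matrix")) return(role_values(nm, roles))
  as.matrix(nm)
}

new_adjacency <- function(values, kind, n_iterations = NA_integer_,
                          subsample_size = NA_integer_, seed = NA_integer_,
                          meta = list()) {
  diag(values) <- 0
  structure(list(values = values, kind = kind,
                 orientation = "row = source, column = target",
                 n_iterations = n_iterations, subsample_size = subsample_size,
                 seed = seed, meta = meta),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("adjacency_matrix (%s): %d markers; row = source, column = target\n",
              x$kind, nrow(x$values)))
  if (!is.na(x$n_iterations))
    cat(sprintf("  %d iterations, subsample %d, seed %s\n",
                x$n_iterations, x$subsample_size, format(x$seed)))
  print(round(x$values, digits))
  invisible(x)
}

seeded_subsample <- function(n, size, seed, k) {
  if (size > n) {
    warnf("subsample_size %d > %d cells; using all cells", size, n)
    size <- n
  }
  with_seed(child_seed(seed, k), sample.int(n, size))
}

#' Gradient-boosting / Shapley-attribution adjacency
#'
#' For each iteration a seeded subsample of cells is drawn; each marker in
#' turn is regressed on all other markers with a gradient-boosted tree
#' ensemble (squared-error loss), and per-cell Shapley-value feature
#' attributions of the fitted model are computed on the subsample.
#' `adjacency[source, target]` is the mean over iterations of the mean
#' absolute attribution of `source` in the model for `target` (magnitudes,
#' so opposite-signed contributions cannot cancel; `signed = TRUE` averages
#' signed values instead).
#'
#' @param nm a `normalized_matrix` (modification columns used), a
#'   `marker_matrix`, or a plain cells x markers matrix.
#' @param iterations number of subsample/fit rounds (default 500; the
#'   full-scale analysis uses 10000+).
#' @param subsample_size cells per iteration (default 1000, clipped with a
#'   warning).
#' @param nrounds,max_depth,eta booster hyperparameters (defaults 100 trees,
#'   depth 4, learning rate 0.1).
#' @param signed average signed attributions instead of absolute.
#' @param seed integer seed.
#' @param roles marker roles entering the network (default modification
#'   only; factor and cell-cycle channels are excluded as in the
#'   modification-only analyses).
#' @return an `adjacency_matrix` of kind `"shap"`.
#' @export
shap_adjacency <- function(nm, iterations = 500L, subsample_size = 1000L,
                           nrounds = 100L, max_depth = 4L, eta = 0.1,
                           signed = FALSE, seed = 1L, roles = "modification") {
  x <- network_input(nm, roles)
  p <- ncol(x)
  if (p < 3L) stopf("shap_adjacency needs >= 3 marker columns")
  stopifnot(iterations >= 1L)
  acc <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  warned_const <- character(0)
  params <- list(max_depth = max_depth, eta = eta,
                 objective = "reg:squarederror", nthread = 1L)
  for (it in seq_len(iterations)) {
    idx <- seeded_subsample(nrow(x), subsample_size, seed, it)
    sub <- x[idx, , drop = FALSE]
    for (j in seq_len(p)) {
      y <- sub[, j]
      if (stats::sd(y) < 1e-12) {
        warned_const <- union(warned_const, colnames(x)[j])
        next
      }
      feats <- sub[, -j, drop = FALSE]
      dm <- xgboost::xgb.DMatrix(feats, label = y, nthread = 1L)
      bst <- xgboost::xgb.train(params = params, data = dm, nrounds = nrounds)
      contrib <- predict(bst, dm, predcontrib = TRUE)
      contrib <- contrib[, colnames(feats), drop = FALSE]  # drop bias column
      agg <- if (signed) colMeans(contrib) else colMeans(abs(contrib))
      acc[colnames(feats), j] <- acc[colnames(feats), j] + agg
    }
  }
  if (length(warned_const))
    warnf("constant target column(s) skipped (zero rows): %s",
          paste(warned_const, collapse = ", "))
  new_adjacency(acc / iterations, "shap", iterations, subsample_size, seed,
                meta = list(nrounds = nrounds, max_depth = max_depth,
                            eta = eta, signed = signed))
}

#' Ensemble Bayesian-network link probability
#'
#' Each feature is discretized into `n_bins` uniformly sized bins spanning
#' its full range. Per iteration, a seeded subsample of cells is drawn and a
#' directed acyclic graph is learned by score-based hill climbing with a BIC
#' score; `adjacency[source, target]` is the fraction of iterations whose
#' DAG contains the edge, i.e. the probability of that direct link across
#' the ensemble.
#'
#' @inheritParams shap_adjacency
#' @param n_bins number of uniform bins per feature (default 20).
#' @param max_parents parent-set cap in the structure search (default 3).
#' @return an `adjacency_matrix` of kind `"link_probability"` with entries
#'   in `[0, 1]`; `meta$failed_iterations` counts skipped structure
#'   searches, `meta$algorithm` records the search used.
#' @export
link_probability <- function(nm, n_bins = 20L, iterations = 500L,
                             subsample_size = 1000L, max_parents = 3L,
                             seed = 1L, roles = "modification") {
  x <- network_input(nm, roles)
  if (ncol(x) < 2L) stopf("link_probability needs >= 2 marker columns")
  disc <- discretize_uniform(x, n_bins)
  if (any(!disc$kept))
    warnf("zero-range feature(s) excluded: %s",
          paste(colnames(x)[!disc$kept], collapse = ", "))
  B <- disc$bins
  p <- ncol(B)
  counts <- matrix(0, p, p, dimnames = list(colnames(B), colnames(B)))
  failed <- 0L
  for (it in seq_len(iterations)) {
    idx <- seeded_subsample(nrow(B), subsample_size, seed, it)
    A <- tryCatch(hc_dag(B[idx, , drop = FALSE], n_bins, max_parents),
                  error = function(e) NULL)
    if (is.null(A)) { failed <- failed + 1L; next }
    counts <- counts + A
  }
  eff <- iterations - failed
  if (eff < 1L) stopf("all %d structure-search iterations failed", iterations)
  new_adjacency(counts / eff, "link_probability", iterations, subsample_size,
                seed, meta = list(n_bins = n_bins, max_parents = max_parents,
                                  failed_iterations = failed,
                                  algorithm = "hill-climbing, BIC score"))
}

#' Partial-correlation network
#'
#' The partial correlation of markers X and Y is the correlation of their
#' residuals after regressing each on all other markers; computed here from
#' the precision (inverse covariance) matrix, to which that definition is
#' equivalent. A singular covariance errors unless `ridge` adds a diagonal
#' regularizer.
#'
#' @inheritParams shap_adjacency
#' @param ridge non-negative ridge added to the covariance diagonal
#'   (default 0).
#' @return a symmetric `adjacency_matrix` of kind `"partial_correlation"`
#'   with entries in `[-1, 1]` and zero diagonal.
#' @export
partial_correlation <- function(nm, ridge = 0, roles = "modification") {
  x <- network_input(nm, roles)
  p <- ncol(x)
  if (nrow(x) <= p + 2L) stopf("need n_cells > n_markers + 2")
  S <- stats::cov(x) + diag(ridge, p)
  P <- tryCatch(solve(S), error = function(e)
    stopf("covariance matrix is singular; retry with the ridge argument (e.g. ridge = 1e-6)"))
  D <- diag(1 / sqrt(diag(P)))
  pc <- -D %*% P %*% D
  dimnames(pc) <- dimnames(S)
  new_adjacency(pc, "partial_correlation", meta = list(ridge = ridge))
}

#' Overlap between two network reconstructions
#'
#' Symmetrizes both adjacency matrices (mean of the two directions for
#' directed kinds; magnitudes for signed kinds), then reports the Spearman
#' rank correlation of edge scores and the overlap of the top-k edges.
#'
#' @param a,b `adjacency_matrix` objects over the same marker set.
#' @param k top-edge count for the overlap (default 5).
#' @return list with `rank_correlation`, `top_k`, `overlap` (edges in both
#'   top-k sets), `k`.
#' @export
compare_networks <- function(a, b, k = 5L) {
  stopifnot(inherits(a, "adjacency_matrix"), inherits(b, "adjacency_matrix"))
  if (!identical(colnames(a$values), colnames(b$values)))
    stopf("marker sets differ between the two networks")
  sym <- function(x) {
    v <- abs(x$values)
    v <- (v + t(v)) / 2
    v[upper.tri(v)]
  }
  ea <- sym(a); eb <- sym(b)
  nm <- outer(colnames(a$values), colnames(a$values), paste, sep = "~")
  enames <- nm[upper.tri(nm)]
  top <- function(e) enames[order(e, decreasing = TRUE)[seq_len(min(k, length(e)))]]
  ov <- intersect(top(ea), top(eb))
  list(rank_correlation = stats::cor(ea, eb, method = "spearman"),
       top_k = list(a = top(ea), b = top(eb)),
       overlap = ov, k = as.integer(k))
}
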