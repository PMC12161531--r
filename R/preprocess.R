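#' Gate cells on minimum core-histone signal
#'
#' Keeps only cells whose every core-histone channel has raw value at least
#' `min_raw` (inclusive bound). This removes debris and poorly stained
#' events before any transformation.
#'
#' @param m a raw [marker_matrix()].
#' @param min_raw inclusive minimum raw core-histone value (default 5).
#' @return gated `marker_matrix`, cell order preserved.
#' @export
gate_core_histones <- function(m, min_raw = 5) {
  stopifnot(inherits(m, "marker_matrix"))
  core <- role_values(m, "core_histone")
  if (!ncol(core)) stopf("panel has no core_histone channel to gate on")
  keep <- rowSums(core >= min_raw) == ncol(core)
  if (!any(keep))
    stopf("core-histone gate at min_raw=%g leaves no cells", min_raw)
  subset_cells(m, keep)
}

#' Arcsinh (inverse hyperbolic sine) transform
#'
#' The standard variance-stabilising transform for cytometry intensities:
#' every entry x becomes `asinh(x / cofactor)`.
#'
#' @param m a [marker_matrix()].
#' @param cofactor positive scale factor (default 5).
#' @return transformed `marker_matrix`.
#' @export
arcsinh_transform <- function(m, cofactor = 5) {
  stopifnot(inherits(m, "marker_matrix"))
  if (!is.numeric(cofactor) || cofactor <= 0)
    stopf("cofactor must be positive (got %s)", format(cofactor))
  marker_matrix(asinh(m$values / cofactor), m$panel, m$sample_label,
                transformed = TRUE)
}

#' Fit variance-minimising core-histone normalization coefficients
#'
#' Finds `(alpha, beta)` (with `gamma = 1 - alpha - beta`) minimising the sum
#' of the variances of the arcsinh-transformed core histones after dividing
#' each by `1 + alpha*H3.3 + beta*H4 + gamma*H3`. The per-cell denominator
#' tracks total histone abundance, so the division removes the multiplicative
#' systematic effect of per-cell nucleosome content.
#'
#' The feasible set is the simplex `alpha >= 0, beta >= 0, alpha + beta <= 1`
#' so all three weights are non-negative mixing coefficients and the
#' denominator stays positive for non-negative arcsinh values. Optimisation
#' is deterministic Nelder-Mead from (1/3, 1/3) with infeasible candidates
#' (outside the simplex, or denominator <= 0 for any cell) rejected by
#' penalty.
#'
#' @param m an arcsinh-transformed [marker_matrix()].
#' @param core_map named character vector mapping the three roles in the
#'   denominator to panel marker names; default
#'   `c(H3.3 = "H3.3", H4 = "H4", H3 = "H3")`.
#' @param start numeric start point `(alpha, beta)`.
#' @return object of class `normalization_fit` with fields `alpha`, `beta`,
#'   `gamma`, `objective` (post-fit sum of core variances), `pre_objective`
#'   (at the unnormalized denominator 1) and `core_map`.
#' @export
fit_normalization <- function(m, core_map = c(H3.3 = "H3.3", H4 = "H4", H3 = "H3"),
                              start = c(1/3, 1/3)) {
  stopifnot(inherits(m, "marker_matrix"))
  if (!m$transformed)
    warnf("fit_normalization expects arcsinh-transformed data")
  check_core_histones(m$panel, required = unname(core_map))
  core <- m$values[, unname(core_map), drop = FALSE]
  h33 <- core[, 1]; h4 <- core[, 2]; h3 <- core[, 3]

  pre <- sum(apply(core, 2, stats::var))
  objective <- function(p) {
    a <- p[1]; b <- p[2]; g <- 1 - a - b
    if (a < 0 || b < 0 || g < 0) return(Inf)
    d <- 1 + a * h33 + b * h4 + g * h3
    if (any(d <= 0)) return(Inf)
    sum(apply(core / d, 2, stats::var))
  }
  if (pre < 1e-12) {
    # all core columns constant: objective is 0 everywhere feasible
    a <- start[1]; b <- start[2]
    return(new_normalization_fit(a, b, objective(c(a, b)), pre, core_map))
  }
  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (!is.finite(opt$value))
    stopf("normalization optimizer failed to find a feasible point (last iterate: alpha=%.4f beta=%.4f)",
          opt$par[1], opt$par[2])
  if (opt$convergence != 0)
    stopf("normalization optimizer did not converge (last iterate: alpha=%.4f beta=%.4f, objective=%.6g)",
          opt$par[1], opt$par[2], opt$value)
  new_normalization_fit(opt$par[1], opt$par[2], opt$value, pre, core_map)
}

new_normalization_fit <- function(alpha, beta, objective, pre_objective, core_map) {
  structure(list(alpha = alpha, beta = beta, gamma = 1 - alpha - beta,
                 objective = objective, pre_objective = pre_objective,
                 core_map = core_map),
            class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("normalization_fit: alpha=%.4f beta=%.4f gamma=%.4f\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  core-variance sum: %.5g -> %.5g (%.1f%% reduction)\n",
              x$pre_objective, x$objective,
              100 * (1 - x$objective / max(x$pre_objective, .Machine$double.eps))))
  invisible(x)
}

#' Apply a fitted core-histone normalization
#'
#' Divides every column (core histones included) row-wise by
#' `1 + alpha*H3.3 + beta*H4 + gamma*H3`.
#'
#' @param m an arcsinh-transformed [marker_matrix()].
#' @param fit a [fit_normalization()] result.
#' @return normalized `marker_matrix`.
#' @export
apply_normalization <- function(m, fit) {
  stopifnot(inherits(m, "marker_matrix"), inherits(fit, "normalization_fit"))
  if (abs(fit$gamma - (1 - fit$alpha - fit$beta)) > 1e-8)
    stopf("invalid fit: gamma != 1 - alpha - beta")
  core <- m$values[, unname(fit$core_map), drop = FALSE]
  d <- 1 + fit$alpha * core[, 1] + fit$beta * core[, 2] + fit$gamma * core[, 3]
  if (any(d <= 0))
    stopf("normalization denominator <= 0 for cell(s): %s",
          paste(utils::head(which(d <= 0), 10), collapse = ", "))
  marker_matrix(m$values / d, m$panel, m$sample_label, transformed = TRUE)
}

#' Batch-wise z-standardization
#'
#' Standardizes each modification/factor column to mean 0, sd 1 within each
#' batch group (samples acquired together are scaled together). Core-histone,
#' cell-cycle and other non-analyte channels are dropped here: they have done
#' their job as normalizers.
#'
#' @param m a normalized [marker_matrix()].
#' @param batch per-cell batch grouping (default: one batch).
#' @param roles marker roles retained in the output (default modification
#'   and factor).
#' @return object of class `normalized_matrix`: fields `values` (cells x
#'   markers), `sample_label`, `panel`, `batch`, `column_means` and
#'   `column_sds` (named list per batch, for the inverse mapping).
#' @export
standardize <- function(m, batch = NULL, roles = c("modification", "factor")) {
  stopifnot(inherits(m, "marker_matrix"))
  v <- role_values(m, roles)
  if (!ncol(v)) stopf("no columns with role(s) %s", paste(roles, collapse = ", "))
  batch <- batch %||% rep("batch1", nrow(v))
  if (length(batch) != nrow(v))
    stopf("batch length (%d) != number of cells (%d)", length(batch), nrow(v))
  batch <- as.character(batch)
  mus <- list(); sds <- list()
  out <- v
  for (b in unique(batch)) {
    idx <- batch == b
    if (sum(idx) < 2L) stopf("batch '%s' has fewer than 2 cells", b)
    mu <- colMeans(v[idx, , drop = FALSE])
    sd <- col_sds(v[idx, , drop = FALSE])
    zero <- sd < 1e-12
    if (any(zero))
      stopf("zero-variance column(s) in batch '%s': %s", b,
            paste(colnames(v)[zero], collapse = ", "))
    out[idx, ] <- sweep(sweep(v[idx, , drop = FALSE], 2, mu), 2, sd, "/")
    mus[[b]] <- mu; sds[[b]] <- sd
  }
  structure(list(values = out, sample_label = m$sample_label, panel = m$panel,
                 batch = batch, column_means = mus, column_sds = sds),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d markers, %d batch group(s)\n",
              nrow(x$values), ncol(x$values), length(x$column_means)))
  invisible(x)
}

#' Invert a standardization
#'
#' @param nm a [standardize()] result.
#' @return cells x markers matrix on the pre-standardization scale.
#' @export
unstandardize <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  out <- nm$values
  for (b in names(nm$column_means)) {
    idx <- nm$batch == b
    out[idx, ] <- sweep(sweep(nm$values[idx, , drop = FALSE], 2,
                              nm$column_sds[[b]], "*"), 2,
                        nm$column_means[[b]], "+")
  }
  out
}

#' Full preprocessing pipeline
#'
#' gate -> arcsinh -> core-histone normalization -> batch-wise
#' z-standardization. Normalization coefficients are fitted per batch by
#' default (samples acquired together share a fit); `pooled = TRUE` fits one
#' global set.
#'
#' @param m a raw [marker_matrix()].
#' @param min_raw core-histone gate threshold (default 5).
#' @param cofactor arcsinh cofactor (default 5).
#' @param batch per-cell batch grouping (default: one batch).
#' @param pooled fit one normalization for all batches (default FALSE).
#' @param core_map see [fit_normalization()].
#' @return a `normalized_matrix`; the per-batch fits are attached as
#'   attribute `"fits"`, the gated arcsinh matrix as attribute `"arcsinh"`.
#' @export
preprocess <- function(m, min_raw = 5, cofactor = 5, batch = NULL,
                       pooled = FALSE, core_map = c(H3.3 = "H3.3", H4 = "H4", H3 = "H3")) {
  gated <- gate_core_histones(m, min_raw)
  batch <- batch %||% rep("batch1", nrow(gated$values))
  if (length(batch) == length(m$sample_label) && nrow(gated$values) != nrow(m$values)) {
    core <- role_values(m, "core_histone")
    batch <- batch[rowSums(core >= min_raw) == ncol(core)]
  }
  tr <- arcsinh_transform(gated, cofactor)
  norm <- tr
  fits <- list()
  if (pooled) {
    fit <- fit_normalization(tr, core_map)
    norm <- apply_normalization(tr, fit)
    fits[["pooled"]] <- fit
  } else {
    vals <- tr$values
    for (b in unique(as.character(batch))) {
      idx <- as.character(batch) == b
      sub <- marker_matrix(tr$values[idx, , drop = FALSE], tr$panel,
                           tr$sample_label[idx], transformed = TRUE)
      fit <- fit_normalization(sub, core_map)
      vals[idx, ] <- apply_normalization(sub, fit)$values
      fits[[b]] <- fit
    }
    norm <- marker_matrix(vals, tr$panel, tr$sample_label, transformed = TRUE)
  }
  out <- standardize(norm, batch)
  attr(out, "fits") <- fits
  attr(out, "arcsinh") <- tr
  out
}
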