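#' Specification for the synthetic CyTOF data generator
#'
#' The generator emulates the statistical structure the downstream pipeline
#' assumes in real histone-modification CyTOF data:
#' \itemize{
#'   \item a per-cell core-histone abundance factor `h` (log-normal) acting
#'     multiplicatively on every channel — the systematic effect that
#'     core-histone normalization divides out;
#'   \item log-scale marker intensities with a planted acyclic dependency
#'     graph among marks (ground truth for the network module);
#'   \item sample mixtures differing in dispersion (heterogeneity) and in
#'     mean shifts of chosen marks;
#'   \item an optionally bimodal mark with a tunable minor-mode fraction
#'     (the 'WT-like' subpopulation structure);
#'   \item an optional mark/factor pair with a planted non-monotone
#'     (bell-shaped) relationship.
#' }
#'
#' @param markers data.frame with columns `name`, `role`, `base_mean`,
#'   `base_sd` (log scale) and optionally `efficiency` (per-channel
#'   multiplicative detection constant, default 1).
#' @param samples data.frame with columns `label`, `dispersion_scale` (> 0)
#'   and optionally `bimodal_marker` (NA for none), `minor_mode_fraction`
#'   (in `[0,1]`), `minor_mode_shift`. Per-marker mean shifts go in
#'   `mean_shift`, a named list column (or pass a list of named vectors).
#' @param n_cells_per_sample cells drawn per sample.
#' @param histone_factor_sd log-scale sd of the per-cell core-histone factor.
#' @param dependency_graph data.frame of directed weighted edges (`source`,
#'   `target`, `weight`); must be acyclic over modification/factor markers.
#' @param bell_pair optional `list(mark=, factor=, curvature=)`: the factor's
#'   log-value gains `curvature * (mark - its base mean)^2`, giving a
#'   bell-shaped (curvature < 0) mark-factor relationship.
#' @param seed integer seed driving all draws.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(markers, samples, n_cells_per_sample = 5000,
                           histone_factor_sd = 0.4,
                           dependency_graph = NULL, bell_pair = NULL,
                           seed = 1L) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("name", "role", "base_mean", "base_sd") %in% names(markers)))
  if (is.null(markers$efficiency)) markers$efficiency <- 1
  samples <- as.data.frame(samples)
  stopifnot(all(c("label", "dispersion_scale") %in% names(samples)))
  if (is.null(samples$bimodal_marker)) samples$bimodal_marker <- NA_character_
  if (is.null(samples$minor_mode_fraction)) samples$minor_mode_fraction <- 0
  if (is.null(samples$minor_mode_shift)) samples$minor_mode_shift <- 0
  if (is.null(samples$mean_shift))
    samples$mean_shift <- replicate(nrow(samples), numeric(0), simplify = FALSE)
  stopifnot(all(samples$dispersion_scale > 0),
            all(samples$minor_mode_fraction >= 0 & samples$minor_mode_fraction <= 1),
            histone_factor_sd >= 0)
  if (!is.null(dependency_graph)) {
    dependency_graph <- as.data.frame(dependency_graph)
    stopifnot(all(c("source", "target", "weight") %in% names(dependency_graph)))
    topo_order(markers$name, dependency_graph)  # errors if cyclic
  }
  if (!is.null(bell_pair))
    stopifnot(all(c("mark", "factor", "curvature") %in% names(bell_pair)),
              all(c(bell_pair$mark, bell_pair$factor) %in% markers$name))
  structure(list(markers = markers, samples = samples,
                 n_cells_per_sample = n_cells_per_sample,
                 histone_factor_sd = histone_factor_sd,
                 dependency_graph = dependency_graph,
                 bell_pair = bell_pair, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Topological order of nodes; errors on a cycle.
topo_order <- function(nodes, edges) {
  if (is.null(edges) || !nrow(edges)) return(nodes)
  order <- character(0)
  remaining <- nodes
  ed <- edges
  while (length(remaining)) {
    has_parent <- remaining %in% ed$target
    roots <- remaining[!has_parent]
    if (!length(roots)) stopf("dependency_graph contains a cycle")
    order <- c(order, roots)
    remaining <- setdiff(remaining, roots)
    ed <- ed[!(ed$source %in% roots), , drop = FALSE]
  }
  order
}

#' Default synthetic study design
#'
#' A two-genotype design mirroring an isogenic WT / EZH2-gain-of-function
#' comparison: three core histones, eight modifications, one factor (BCL6).
#' The mutant sample has doubled dispersion, an H3K27me3 mean shift with a
#' 20% 'WT-like' minor mode sitting back at the reference level, depleted
#' H3K27me2/H3K9me2, and a bell-shaped H3K27me3-BCL6 relationship. Three
#' dependency edges (H3K27me2 -> H3K27me3, H3K9me2 -> H3K27me2,
#' H3K9ac -> H3K27ac) form the planted network ground truth.
#'
#' @param n_cells_per_sample cells per sample (default 5000).
#' @param seed integer seed.
#' @param mutant_dispersion dispersion scale of the mutant sample (default 2).
#' @param minor_mode_fraction 'WT-like' fraction of the mutant (default 0.2).
#' @return a [synthetic_spec()].
#' @export
default_synthetic_spec <- function(n_cells_per_sample = 5000, seed = 1L,
                                   mutant_dispersion = 2,
                                   minor_mode_fraction = 0.2) {
  markers <- data.frame(
    name = c("H3", "H3.3", "H4",
             "H3K27me3", "H3K27me2", "H3K27ac", "H3K9me2", "H3K9me3",
             "H3K4me1", "H3K36me3", "H3K9ac", "BCL6"),
    role = c(rep("core_histone", 3), rep("modification", 8), "factor"),
    base_mean = c(4.5, 4.2, 4.8, 3.0, 3.4, 2.8, 3.2, 2.9, 2.6, 2.7, 2.5, 2.4),
    base_sd = c(0.10, 0.10, 0.10, rep(0.35, 9)),
    efficiency = c(1.0, 0.8, 1.2, rep(1, 9)),
    stringsAsFactors = FALSE)
  samples <- data.frame(label = c("WT", "EZH2_Y646N"),
                        dispersion_scale = c(1, mutant_dispersion),
                        bimodal_marker = c(NA, "H3K27me3"),
                        minor_mode_fraction = c(0, minor_mode_fraction),
                        minor_mode_shift = c(0, -1.4),
                        stringsAsFactors = FALSE)
  samples$mean_shift <- list(
    numeric(0),
    c(H3K27me3 = 1.4, H3K27me2 = -0.8, H3K9me2 = -0.6))
  graph <- data.frame(source = c("H3K27me2", "H3K9me2", "H3K9ac"),
                      target = c("H3K27me3", "H3K27me2", "H3K27ac"),
                      weight = c(0.6, 0.45, 0.5), stringsAsFactors = FALSE)
  synthetic_spec(markers, samples,
                 n_cells_per_sample = n_cells_per_sample,
                 histone_factor_sd = 0.4, dependency_graph = graph,
                 bell_pair = list(mark = "H3K27me3", factor = "BCL6",
                                  curvature = -0.3),
                 seed = seed)
}

# Panel implied by a synthetic spec.
spec_panel <- function(spec) {
  panel_config(data.frame(channel_id = spec$markers$name,
                          marker_name = spec$markers$name,
                          role = spec$markers$role, stringsAsFactors = FALSE))
}

#' Draw one synthetic sample population
#'
#' Cells are drawn marker-by-marker in topological order of the dependency
#' graph. On the log scale each marker value is
#' `base_mean + mean_shift + sum(weight * parent value) + noise`, with noise
#' sd `base_sd * dispersion_scale`. Raw intensity is
#' `exp(value) * h * efficiency`, where `h` is the per-cell log-normal
#' core-histone factor; core-histone channels report
#' `exp(base_mean) * h * efficiency * noise`.
#'
#' @param spec a [synthetic_spec()].
#' @param sample label of the sample to draw (must be in `spec$samples`).
#' @param seed optional override of `spec$seed`.
#' @return a raw [marker_matrix()].
#' @export
generate_population <- function(spec, sample, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  si <- match(sample, spec$samples$label)
  if (is.na(si)) stopf("unknown sample label '%s'", sample)
  seed <- seed %||% child_seed(spec$seed, si)
  smp <- spec$samples[si, ]
  mk <- spec$markers
  n <- spec$n_cells_per_sample
  shift <- smp$mean_shift[[1]]

  with_seed(seed, {
    h <- exp(stats::rnorm(n, 0, spec$histone_factor_sd))
    logv <- matrix(0, n, nrow(mk), dimnames = list(NULL, mk$name))
    noncore <- mk$name[mk$role != "core_histone"]
    order_edges <- spec$dependency_graph
    if (!is.null(spec$bell_pair))  # the factor is drawn after its mark
      order_edges <- rbind(order_edges,
                           data.frame(source = spec$bell_pair$mark,
                                      target = spec$bell_pair$factor,
                                      weight = 0, stringsAsFactors = FALSE))
    for (name in topo_order(noncore, order_edges)) {
      j <- match(name, mk$name)
      sh <- if (length(shift) && name %in% names(shift)) shift[[name]] else 0
      mu <- mk$base_mean[j] + sh
      v <- mu + stats::rnorm(n, 0, mk$base_sd[j] * smp$dispersion_scale)
      g <- spec$dependency_graph
      if (!is.null(g)) {
        for (e in which(g$target == name))
          v <- v + g$weight[e] * (logv[, g$source[e]] - mk$base_mean[match(g$source[e], mk$name)])
      }
      if (!is.na(smp$bimodal_marker) && identical(name, smp$bimodal_marker) &&
          smp$minor_mode_fraction > 0) {
        minor <- stats::runif(n) < smp$minor_mode_fraction
        v[minor] <- v[minor] + smp$minor_mode_shift
      }
      if (!is.null(spec$bell_pair) && identical(name, spec$bell_pair$factor)) {
        mark <- spec$bell_pair$mark
        centered <- logv[, mark] - mk$base_mean[match(mark, mk$name)]
        v <- v + spec$bell_pair$curvature * centered^2
      }
      logv[, name] <- v
    }
    raw <- matrix(0, n, nrow(mk), dimnames = list(NULL, mk$name))
    for (j in seq_len(nrow(mk))) {
      if (mk$role[j] == "core_histone") {
        raw[, j] <- exp(mk$base_mean[j]) * h * mk$efficiency[j] *
          exp(stats::rnorm(n, 0, mk$base_sd[j]))
      } else {
        raw[, j] <- exp(logv[, j]) * h * mk$efficiency[j]
      }
    }
    marker_matrix(raw, spec_panel(spec), smp$label)
  })
}

#' Draw the full multi-sample mixture
#'
#' Concatenates [generate_population()] over all samples and shuffles cell
#' order under the spec's seed.
#'
#' @param spec a [synthetic_spec()] with at least two samples.
#' @param seed optional override of `spec$seed`.
#' @return a raw [marker_matrix()] with per-cell `sample_label`.
#' @export
generate_mixture <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  pops <- lapply(seq_len(nrow(spec$samples)), function(i)
    generate_population(spec, spec$samples$label[i], seed = child_seed(seed, i)))
  values <- do.call(rbind, lapply(pops, function(p) p$values))
  labels <- unlist(lapply(pops, function(p) p$sample_label))
  ord <- with_seed(child_seed(seed, 0L), sample.int(length(labels)))
  marker_matrix(values[ord, , drop = FALSE], spec_panel(spec), labels[ord])
}

#' Generate a synthetic cells-by-genes expression matrix
#'
#' Log-normal expression with a per-cell scale factor;
#' `dispersion_scale` multiplies the per-gene log-scale sd, so mean pairwise
#' cell-cell distance grows linearly with it.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param dispersion_scale non-negative multiplier of per-gene sd.
#' @param seed integer seed.
#' @param base_sd baseline per-gene log sd (default 0.5).
#' @param cell_factor_sd log-scale sd of the per-cell scale factor (applied
#'   on the log scale; default 0 so distances scale exactly with
#'   `dispersion_scale`).
#' @return numeric cells x genes matrix (log-scale expression).
#' @export
generate_expression <- function(n_cells, n_genes, dispersion_scale = 1,
                                seed = 1L, base_sd = 0.5, cell_factor_sd = 0) {
  stopifnot(n_cells > 0, n_genes > 0, dispersion_scale >= 0)
  with_seed(seed, {
    gene_mu <- stats::rnorm(n_genes, 2, 1)
    x <- matrix(stats::rnorm(n_cells * n_genes, 0, base_sd * dispersion_scale),
                n_cells, n_genes)
    x <- sweep(x, 2, gene_mu, "+")
    if (cell_factor_sd > 0)
      x <- x + stats::rnorm(n_cells, 0, cell_factor_sd)
    dimnames(x) <- list(paste0("cell", seq_len(n_cells)),
                        paste0("gene", seq_len(n_genes)))
    x
  })
}
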