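# Fixtures built in code; nothing is stored on disk.

tiny_panel <- function() {
  panel_config(data.frame(
    channel_id = c("c1", "c2", "c3", "c4", "c5"),
    marker_name = c("H3", "H3.3", "H4", "markA", "markB"),
    role = c("core_histone", "core_histone", "core_histone",
             "modification", "modification"),
    stringsAsFactors = FALSE))
}

tiny_matrix <- function(n = 10, seed = 1) {
  set.seed(seed)
  v <- matrix(rexp(n * 5, 1 / 50), n, 5,
              dimnames = list(NULL, c("H3", "H3.3", "H4", "markA", "markB")))
  marker_matrix(v, tiny_panel(), "s1")
}

# Planted multiplicative-factor fixture: cores and markers all proportional
# to a per-cell factor h; markers carry extra independent signal.
factor_fixture <- function(n = 500, seed = 2, marker_sd = 0.3, core_sd = 0.08) {
  set.seed(seed)
  h <- exp(rnorm(n, 0, 0.4))
  v <- cbind(H3 = 90 * h * exp(rnorm(n, 0, core_sd)),
             H3.3 = 70 * h * exp(rnorm(n, 0, core_sd)),
             H4 = 110 * h * exp(rnorm(n, 0, core_sd)),
             markA = 40 * h * exp(rnorm(n, 0, marker_sd)),
             markB = 25 * h * exp(rnorm(n, 0, marker_sd)))
  marker_matrix(v, tiny_panel(), "s1")
}

# Six-marker single-population fixture with a 3-edge planted acyclic graph
# at signal-to-noise >= 2 (weight * parent_sd / noise_sd = 2).
planted_network_spec <- function(n = 5000, seed = 5, snr = 2) {
  sd0 <- 0.35
  w <- snr  # parent sd equals noise sd, so weight = snr
  markers <- data.frame(
    name = c("H3", "H3.3", "H4", paste0("M", 1:6)),
    role = c(rep("core_histone", 3), rep("modification", 6)),
    base_mean = c(4.5, 4.2, 4.8, rep(3, 6)),
    base_sd = c(rep(0.1, 3), rep(sd0, 6)),
    stringsAsFactors = FALSE)
  samples <- data.frame(label = "only", dispersion_scale = 1,
                        stringsAsFactors = FALSE)
  samples$mean_shift <- list(numeric(0))
  graph <- data.frame(source = c("M1", "M2", "M4"),
                      target = c("M2", "M3", "M5"),
                      weight = c(w, w, w), stringsAsFactors = FALSE)
  synthetic_spec(markers, samples, n_cells_per_sample = n,
                 histone_factor_sd = 0, dependency_graph = graph, seed = seed)
}

planted_network_data <- function(n = 5000, seed = 5, snr = 2) {
  m <- generate_population(planted_network_spec(n, seed, snr), "only")
  nm <- standardize(arcsinh_transform(m))
  nm
}

# Independent markers: no dependency edges, no shared factor.
independent_network_data <- function(n = 5000, seed = 7, p = 6) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("M", 1:p)))
  x
}

# Symmetric random walk on methylation states (no acetylation branch).
symmetric_methylation_model <- function(p_move = 0.15, n_cells = 500,
                                        nucleosomes = 1e5, n_steps = 300,
                                        seed = 1) {
  states <- c("unmodified", "me1", "me2", "me3")
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  P["unmodified", "me1"] <- p_move; P["me1", "unmodified"] <- p_move
  P["me1", "me2"] <- p_move; P["me2", "me1"] <- p_move
  P["me2", "me3"] <- p_move; P["me3", "me2"] <- p_move
  diag(P) <- 1 - rowSums(P)
  markov_model(P, states, n_cells = n_cells,
               nucleosomes_per_cell = nucleosomes, n_steps = n_steps,
               seed = seed)
}

# Rank of planted (symmetrized) edges among all edges of an adjacency.
edge_percentiles <- function(adj, edges) {
  v <- abs(adj$values); v <- (v + t(v)) / 2
  scores <- v[upper.tri(v)]
  nm <- outer(rownames(v), colnames(v), function(a, b) paste(pmin(a, b), pmax(a, b)))
  enames <- nm[upper.tri(nm)]
  planted <- vapply(edges, function(e) paste(min(e), max(e)), "")
  vapply(planted, function(e) {
    s <- scores[enames == e]
    mean(scores[!(enames %in% planted)] < s)
  }, numeric(1))
}
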