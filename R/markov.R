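# Markov-chain model of H3K27 modification-state dynamics.
#
# States follow the minimal chemically sensible move set: methylation
# proceeds stepwise (unmodified <-> me1 <-> me2 <-> me3), acetylation and
# methylation are mutually exclusive (unmodified <-> ac), and non-adjacent
# jumps are disallowed (exactly zero in the transition matrix). Each cell
# carries a large pool of nucleosomes evolved independently, so the exact
# law of one step is a multinomial redistribution of state counts.

#' Default H3K27 state set
#' @return character vector of the five states.
#' @export
k27_states <- function() c("unmodified", "me1", "me2", "me3", "ac")

# Logical mask of allowed (off-diagonal) moves for the default state set.
k27_allowed_moves <- function(states = k27_states()) {
  p <- length(states)
  M <- diag(p) > 0
  dimnames(M) <- list(states, states)
  chain <- intersect(c("unmodified", "me1", "me2", "me3"), states)
  for (i in seq_len(length(chain) - 1L)) {
    M[chain[i], chain[i + 1L]] <- TRUE
    M[chain[i + 1L], chain[i]] <- TRUE
  }
  if (all(c("unmodified", "ac") %in% states)) {
    M["unmodified", "ac"] <- TRUE
    M["ac", "unmodified"] <- TRUE
  }
  M
}

#' Markov model of modification-state populations
#'
#' @param transition states x states row-stochastic matrix of per-step
#'   probabilities (row = from). Moves outside the allowed set (non-adjacent
#'   methylation jumps; ac <-> methylated without passing unmodified) must
#'   be exactly 0.
#' @param states state names (default [k27_states()]); taken from
#'   `transition` dimnames when present.
#' @param n_cells cells in the simulated population (default 5000).
#' @param nucleosomes_per_cell nucleosome pool per cell (default 3e7).
#' @param n_steps propagation steps (default 1000).
#' @param seed integer seed.
#' @return object of class `markov_model`.
#' @export
markov_model <- function(transition, states = NULL, n_cells = 5000,
                         nucleosomes_per_cell = 3e7, n_steps = 1000,
                         seed = 1L) {
  transition <- as.matrix(transition)
  states <- states %||% rownames(transition) %||% k27_states()
  stopifnot(nrow(transition) == length(states),
            ncol(transition) == length(states))
  dimnames(transition) <- list(states, states)
  if (any(transition < 0)) stopf("negative transition probabilities")
  rs <- rowSums(transition)
  if (any(abs(rs - 1) > 1e-12))
    stopf("transition rows must sum to 1 (max deviation %.3g)", max(abs(rs - 1)))
  allowed <- k27_allowed_moves(states)
  viol <- transition > 0 & !allowed
  if (any(viol))
    stopf("disallowed transition(s) non-zero: %s",
          paste(apply(which(viol, arr.ind = TRUE), 1, function(ij)
            paste0(states[ij[1]], "->", states[ij[2]])), collapse = ", "))
  if (nucleosomes_per_cell * 1 > 2^31 - 1)
    stopf("nucleosomes_per_cell exceeds representable integer counts")
  structure(list(states = states, transition = transition,
                 n_cells = as.integer(n_cells),
                 nucleosomes_per_cell = nucleosomes_per_cell,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states, %d cells x %.3g nucleosomes, %d steps\n",
              length(x$states), x$n_cells, x$nucleosomes_per_cell, x$n_steps))
  print(round(x$transition, 4))
  pi <- stationary_distribution(x)
  cat("stationary:", paste(sprintf("%s=%.3f", x$states, pi), collapse = " "), "\n")
  invisible(x)
}

#' Stationary distribution of a transition matrix
#'
#' The leading left eigenvector (eigenvalue 1), normalized to sum 1.
#'
#' @param model a `markov_model` or a row-stochastic matrix.
#' @return named probability vector.
#' @export
stationary_distribution <- function(model) {
  P <- if (inherits(model, "markov_model")) model$transition else as.matrix(model)
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

#' Calibrate a transition matrix to a target stationary distribution
#'
#' Builds the transition matrix by detailed balance on the allowed-move
#' graph: each forward move (methylation steps and acetylation) gets
#' probability `base_move`, and each reverse move gets
#' `base_move * pi_from / pi_to`, which makes the target exactly stationary.
#' The construction then validates the writer-dominance constraint — every
#' demethylation probability strictly below its methylation counterpart —
#' and the row-stochastic bounds; an infeasible target errors with the best
#' residual found.
#'
#' @param target_fractions named probability vector over the states (must
#'   sum to 1).
#' @param base_move forward (methylation/acetylation) per-step probability
#'   (default 0.2).
#' @param require_writer_dominance enforce demethylation < methylation
#'   (default TRUE).
#' @param tol stationary tolerance per state (default 0.02).
#' @param ... passed to [markov_model()] (`n_cells`, `n_steps`, ...).
#' @return a `markov_model` whose stationary distribution matches the
#'   target within `tol` per state.
#' @export
calibrate_transition <- function(target_fractions, base_move = 0.2,
                                 require_writer_dominance = TRUE,
                                 tol = 0.02, ...) {
  pi <- target_fractions
  states <- names(pi) %||% k27_states()
  names(pi) <- states
  stopifnot(abs(sum(pi) - 1) < 1e-8, all(pi > 0), base_move > 0)
  p <- length(states)
  P <- matrix(0, p, p, dimnames = list(states, states))
  forward <- list(c("unmodified", "me1"), c("me1", "me2"), c("me2", "me3"),
                  c("unmodified", "ac"))
  forward <- Filter(function(e) all(e %in% states), forward)
  for (e in forward) {
    P[e[1], e[2]] <- base_move
    P[e[2], e[1]] <- base_move * pi[[e[1]]] / pi[[e[2]]]
  }
  if (any(rowSums(P) > 1))
    stopf("infeasible target: reverse rates exceed row budget (max row sum %.3f); lower base_move",
          max(rowSums(P)))
  diag(P) <- 1 - rowSums(P)
  if (require_writer_dominance) {
    meth <- list(c("unmodified", "me1"), c("me1", "me2"), c("me2", "me3"))
    meth <- Filter(function(e) all(e %in% states), meth)
    bad <- Filter(function(e) P[e[2], e[1]] >= P[e[1], e[2]], meth)
    if (length(bad)) {
      resid <- max(abs(stationary_distribution(P) - pi))
      stopf("infeasible under demethylation < methylation: %s (best stationary residual %.3g)",
            paste(vapply(bad, function(e) paste0(e[2], "->", e[1]), ""),
                  collapse = ", "), resid)
    }
  }
  model <- markov_model(P, states, ...)
  resid <- max(abs(stationary_distribution(model) - pi))
  if (resid > tol)
    stopf("calibration residual %.3g exceeds tolerance %g", resid, tol)
  model
}

#' Default writer-dominant H3K27 target state fractions
#'
#' A steady state with methylation fractions increasing along the chain, so
#' detailed balance yields demethylation rates strictly below methylation
#' rates (writer dominance).
#' @return named probability vector.
#' @export
k27_default_target <- function() {
  c(unmodified = 0.10, me1 = 0.15, me2 = 0.25, me3 = 0.40, ac = 0.10)
}

# One exact multinomial step for all cells: counts (cells x states) -> next.
# Multinomial split via sequential conditional binomials, vectorized over
# cells (rbinom accepts per-cell sizes).
markov_step <- function(counts, P) {
  n_cells <- nrow(counts)
  p <- ncol(counts)
  out <- matrix(0, n_cells, p, dimnames = dimnames(counts))
  for (s in seq_len(p)) {
    remaining <- counts[, s]
    pleft <- 1
    dests <- which(P[s, ] > 0)
    for (k in seq_along(dests)) {
      d <- dests[k]
      if (k == length(dests)) {
        out[, d] <- out[, d] + remaining
      } else {
        pr <- min(P[s, d] / pleft, 1)
        draw <- stats::rbinom(n_cells, remaining, pr)
        out[, d] <- out[, d] + draw
        remaining <- remaining - draw
        pleft <- pleft - P[s, d]
      }
    }
  }
  out
}

#' Simulate modification-state populations
#'
#' Each cell starts from random modification fractions (uniform on the
#' probability simplex, i.e. Dirichlet(1,...,1)) converted to nucleosome
#' counts, then the count vector is propagated each step by multinomial
#' redistribution under the model's transition matrix. Nucleosome totals are
#' conserved exactly.
#'
#' @param model a [markov_model()].
#' @param record_every record fractions every this many steps (default:
#'   `max(1, n_steps / 100)`).
#' @param init optional cells x states count matrix overriding the random
#'   initial condition.
#' @param tol steady-state tolerance: maximum absolute change of the mean
#'   state fractions over the last 10 recorded steps. The default adds the
#'   multinomial noise floor `10 / sqrt(nucleosomes * n_cells)` to the
#'   full-scale tolerance 1e-4, so scaled-down runs are not flagged
#'   non-converged for pure sampling noise.
#' @return object of class `population_trajectory`: `fractions` (cells x
#'   states at the final step), `recorded` (list of fraction matrices),
#'   `step_index` (recorded steps), `converged` (see `tol`).
#' @export
simulate_markov <- function(model, record_every = NULL, init = NULL,
                            tol = NULL) {
  stopifnot(inherits(model, "markov_model"))
  p <- length(model$states)
  record_every <- record_every %||% max(1L, model$n_steps %/% 100L)
  with_seed(model$seed, {
    if (is.null(init)) {
      # Dirichlet(1,..,1) via normalized exponentials
      g <- matrix(stats::rexp(model$n_cells * p), model$n_cells, p)
      frac0 <- g / rowSums(g)
      counts <- t(apply(frac0, 1, function(f)
        stats::rmultinom(1, model$nucleosomes_per_cell, f)[, 1]))
    } else {
      counts <- as.matrix(init)
    }
    colnames(counts) <- model$states
    total <- rowSums(counts)
    recorded <- list(counts / total)
    steps_rec <- 0L
    for (t in seq_len(model$n_steps)) {
      counts <- markov_step(counts, model$transition)
      if (t %% record_every == 0L || t == model$n_steps) {
        recorded[[length(recorded) + 1L]] <- counts / total
        steps_rec <- c(steps_rec, t)
      }
    }
    if (any(rowSums(counts) != total))
      stopf("internal error: nucleosome counts not conserved")
    k <- length(recorded)
    last <- recorded[seq(max(1L, k - 10L), k)]
    deltas <- vapply(seq_len(length(last) - 1L), function(i)
      max(abs(colMeans(last[[i + 1L]]) - colMeans(last[[i]]))), numeric(1))
    tol <- tol %||%
      (1e-4 + 10 / sqrt(model$nucleosomes_per_cell * model$n_cells))
    structure(list(fractions = recorded[[k]], recorded = recorded,
                   step_index = steps_rec,
                   converged = length(deltas) > 0 && max(deltas) < tol),
              class = "population_trajectory")
  })
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("population_trajectory: %d cells, %d states, %d recorded steps (converged: %s)\n",
              nrow(x$fractions), ncol(x$fractions), length(x$step_index),
              x$converged))
  cat("final mean fractions:",
      paste(sprintf("%s=%.3f", colnames(x$fractions), colMeans(x$fractions)),
            collapse = " "), "\n")
  invisible(x)
}

#' Writer-dominance attribution asymmetry
#'
#' Repeatedly simulates the population to steady state, treats the per-cell
#' state fractions as a marker matrix, runs the Shapley-attribution network
#' on subsamples restricted to the measurable states, and records the two
#' focus entries (by default me2 -> me3 and me3 -> me2). The unmodified
#' state is excluded from the features: it is not measurable by CyTOF and
#' would make every target a deterministic function of the features through
#' the sum-to-one constraint. The last `n_snapshots` recorded stationary
#' snapshots are pooled before the fit — at stationarity each recorded step
#' is an equally valid draw of the population, so pooling sharpens the
#' attribution estimate without changing its expectation — and the
#' attribution itself is ensemble-averaged over `iterations` random
#' subsamples, mirroring the repeated-subset averaging of the full-scale
#' analysis.
#'
#' @param model a [markov_model()].
#' @param n_repeats repeats of the simulate + attribute cycle (default 500).
#' @param focus ordered state pair; the first entry of the result is
#'   attribution `focus[1] -> focus[2]` (default `c("me2", "me3")`).
#' @param features states used as markers (default all but `unmodified`).
#' @param n_snapshots stationary snapshots pooled per repeat (default 10).
#' @param iterations subsample/fit rounds per repeat (default 3).
#' @param subsample_size rows per attribution fit (default
#'   `min(pooled rows, 2000)`).
#' @param nrounds,max_depth,eta booster hyperparameters (see
#'   [shap_adjacency()]).
#' @param seed integer seed (each repeat derives its own).
#' @return object of class `asymmetry_analysis`: data.frame `draws` with
#'   per-repeat forward/reverse attributions and their difference, plus
#'   `n_nonconverged`.
#' @export
asymmetry_analysis <- function(model, n_repeats = 500L,
                               focus = c("me2", "me3"), features = NULL,
                               n_snapshots = 10L, iterations = 3L,
                               subsample_size = NULL, nrounds = 100L,
                               max_depth = 4L, eta = 0.1, seed = 1L) {
  stopifnot(inherits(model, "markov_model"))
  features <- features %||% setdiff(model$states, "unmodified")
  if (!all(focus %in% features)) stopf("focus states must be among the features")
  fwd <- rev <- numeric(n_repeats)
  nonconv <- 0L
  for (r in seq_len(n_repeats)) {
    m_r <- model
    m_r$seed <- child_seed(seed, r)
    traj <- simulate_markov(m_r)
    if (!traj$converged) nonconv <- nonconv + 1L
    k <- length(traj$recorded)
    take <- seq.int(max(1L, k - n_snapshots + 1L), k)
    x <- do.call(rbind, lapply(traj$recorded[take],
                               function(f) f[, features, drop = FALSE]))
    adj <- shap_adjacency(x, iterations = iterations,
                          subsample_size = subsample_size %||% min(nrow(x), 2000L),
                          nrounds = nrounds, max_depth = max_depth, eta = eta,
                          seed = child_seed(seed, r + n_repeats))
    fwd[r] <- adj$values[focus[1], focus[2]]
    rev[r] <- adj$values[focus[2], focus[1]]
  }
  if (nonconv > 0L)
    warnf("%d of %d repeats had non-converged trajectories", nonconv, n_repeats)
  structure(list(draws = data.frame(forward = fwd, reverse = rev,
                                    difference = fwd - rev),
                 focus = focus, n_repeats = n_repeats,
                 n_nonconverged = nonconv),
            class = "asymmetry_analysis")
}

#' @export
print.asymmetry_analysis <- function(x, ...) {
  d <- x$draws$difference
  cat(sprintf("asymmetry_analysis: %s->%s vs %s->%s over %d repeats\n",
              x$focus[1], x$focus[2], x$focus[2], x$focus[1], x$n_repeats))
  cat(sprintf("  mean difference %.4g (SE %.4g); forward larger in %.1f%% of repeats\n",
              mean(d), stats::sd(d) / sqrt(length(d)), 100 * mean(d > 0)))
  invisible(x)
}
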