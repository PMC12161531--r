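# Score-based DAG structure learning on discretized data.
#
# Hill climbing over add/delete/reverse edge moves with a BIC score for
# multinomial nodes: score(j | parents) = loglik - 0.5*log(n)*(r-1)*r^|P|,
# where r is the (fixed) bin cardinality. Used by link_probability(); the
# per-iteration DAG is discarded, only its edges are counted.

# Combined parent-configuration index for columns `parents` of bin matrix B.
parent_config_index <- function(B, parents, r) {
  if (!length(parents)) return(rep.int(1L, nrow(B)))
  idx <- B[, parents[1]] - 1L
  if (length(parents) > 1L)
    for (k in 2:length(parents)) idx <- idx * r + (B[, parents[k]] - 1L)
  idx + 1L
}

# BIC local score of node j given parent set (columns of B with r bins each).
bic_local_score <- function(B, j, parents, r) {
  n <- nrow(B)
  pc <- parent_config_index(B, parents, r)
  n_pc <- r^length(parents)
  joint <- tabulate((pc - 1L) * r + B[, j], nbins = n_pc * r)
  marg <- tabulate(pc, nbins = n_pc)
  nz <- joint > 0L
  ll <- sum(joint[nz] * log(joint[nz] / marg[(which(nz) - 1L) %/% r + 1L]))
  ll - 0.5 * log(n) * (r - 1) * n_pc
}

# TRUE if adding edge from->to creates a cycle in adjacency matrix A.
creates_cycle <- function(A, from, to) {
  # path to -> from?
  visited <- logical(nrow(A))
  stack <- to
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == from) return(TRUE)
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- c(stack, which(A[v, ] > 0))
  }
  FALSE
}

#' Hill-climbing DAG search with a BIC score on binned data
#'
#' @param B integer matrix of bin indices (cells x features), each column in
#'   `1..r`.
#' @param r bin cardinality shared by all features.
#' @param max_parents parent-set cap (default 3).
#' @param max_sweeps safety cap on improvement sweeps.
#' @return binary adjacency matrix (`A[source, target] = 1`).
#' @keywords internal
hc_dag <- function(B, r, max_parents = 3L, max_sweeps = 100L) {
  p <- ncol(B)
  A <- matrix(0L, p, p, dimnames = list(colnames(B), colnames(B)))
  cache <- new.env(parent = emptyenv())
  score_of <- function(j, parents) {
    key <- paste0(j, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bic_local_score(B, j, sort(parents), r)
      cache[[key]] <- val
    }
    val
  }
  node_score <- vapply(seq_len(p), function(j) score_of(j, integer(0)), numeric(1))

  for (sweep in seq_len(max_sweeps)) {
    best <- list(gain = 1e-9)
    for (from in seq_len(p)) for (to in seq_len(p)) {
      if (from == to) next
      parents_to <- which(A[, to] > 0)
      if (A[from, to] == 0L) {
        # add
        if (length(parents_to) < max_parents && !creates_cycle(A, from, to)) {
          gain <- score_of(to, c(parents_to, from)) - node_score[to]
          if (gain > best$gain) best <- list(gain = gain, op = "add", from = from, to = to)
        }
      } else {
        # delete
        gain <- score_of(to, setdiff(parents_to, from)) - node_score[to]
        if (gain > best$gain) best <- list(gain = gain, op = "del", from = from, to = to)
        # reverse
        parents_from <- which(A[, from] > 0)
        if (length(parents_from) < max_parents) {
          A[from, to] <- 0L
          ok <- !creates_cycle(A, to, from)
          A[from, to] <- 1L
          if (ok) {
            gain <- (score_of(to, setdiff(parents_to, from)) - node_score[to]) +
              (score_of(from, c(parents_from, to)) - node_score[from])
            if (gain > best$gain) best <- list(gain = gain, op = "rev", from = from, to = to)
          }
        }
      }
    }
    if (is.null(best$op)) break
    from <- best$from; to <- best$to
    if (best$op == "add") {
      A[from, to] <- 1L
    } else if (best$op == "del") {
      A[from, to] <- 0L
    } else {
      A[from, to] <- 0L
      A[to, from] <- 1L
      node_score[from] <- score_of(from, which(A[, from] > 0))
    }
    node_score[to] <- score_of(to, which(A[, to] > 0))
  }
  A
}

# Discretize each column into n_bins uniform bins over its own full range.
discretize_uniform <- function(x, n_bins = 20L) {
  B <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  keep <- rep(TRUE, ncol(x))
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (diff(rng) == 0) { keep[j] <- FALSE; next }
    b <- floor((x[, j] - rng[1]) / diff(rng) * n_bins) + 1L
    B[, j] <- pmin(b, n_bins)
  }
  list(bins = B[, keep, drop = FALSE], kept = keep)
}
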