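# network: three reconstructions, their oracles, and planted-edge recovery.

test_that("two-marker partial correlation equals the Pearson correlation", {
  set.seed(41)
  x <- cbind(A = rnorm(200), B = rnorm(200))
  x[, "B"] <- 0.6 * x[, "A"] + rnorm(200, sd = 0.5)
  pc <- partial_correlation(x)
  expect_equal(pc$values["A", "B"], cor(x)["A", "B"], tolerance = 1e-10)
  expect_equal(pc$values["A", "B"], pc$values["B", "A"])
  expect_equal(diag(pc$values), c(A = 0, B = 0))
})

test_that("precision-matrix partial correlation equals residual regression", {
  set.seed(42)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("M", 1:5)))
  x[, 2] <- 0.7 * x[, 1] + rnorm(n, sd = 0.5)
  x[, 3] <- 0.5 * x[, 2] + rnorm(n, sd = 0.7)
  pc <- partial_correlation(x)
  # residual-regression oracle
  oracle <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    ri <- resid(lm(x[, i] ~ x[, -c(i, j)]))
    rj <- resid(lm(x[, j] ~ x[, -c(i, j)]))
    oracle[i, j] <- oracle[j, i] <- cor(ri, rj)
  }
  expect_equal(unname(pc$values), oracle, tolerance = 1e-8)
  expect_true(all(abs(pc$values) <= 1 + 1e-12))
})

test_that("conditioning removes the indirect path of a chain", {
  set.seed(43)
  n <- 10000
  a <- rnorm(n)
  b <- 0.9 * a + rnorm(n, sd = 0.4)
  c_ <- 0.9 * b + rnorm(n, sd = 0.4)
  x <- cbind(A = a, B = b, C = c_)
  pc <- partial_correlation(x)
  expect_lt(abs(pc$values["A", "C"]), abs(pc$values["A", "B"]))
  expect_lt(abs(pc$values["A", "C"]), abs(pc$values["B", "C"]))
  # marginal correlation of A,C is large; the partial one collapses
  expect_gt(cor(a, c_), 0.5)
  expect_lt(abs(pc$values["A", "C"]), 0.1)
})

test_that("singular covariance errors unless ridge-regularized", {
  set.seed(44)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  x <- cbind(x, D = x[, "A"] + x[, "B"])  # exact collinearity
  expect_error(partial_correlation(x), "ridge")
  pc <- partial_correlation(x, ridge = 1e-6)
  expect_true(all(is.finite(pc$values)))
  expect_error(partial_correlation(x[1:4, ]), "n_cells")
})

test_that("shap adjacency ranks a planted chain edge top of its column", {
  set.seed(45)
  n <- 5000
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  x[, "B"] <- 0.9 * x[, "A"] + rnorm(n, sd = sqrt(1 - 0.81))
  adj <- shap_adjacency(x, iterations = 5, subsample_size = 1000, seed = 46)
  col_b <- adj$values[, "B"]
  expect_equal(names(which.max(col_b)), "A")
  expect_equal(unname(diag(adj$values)), rep(0, 4))
  # determinism at fixed seed, invariance to cell-row permutation
  adj2 <- shap_adjacency(x, iterations = 5, subsample_size = 1000, seed = 46)
  expect_identical(adj$values, adj2$values)
})

test_that("shap entries on independent markers stay at the permuted-null level", {
  x <- independent_network_data(n = 4000, seed = 47)
  adj <- shap_adjacency(x, iterations = 5, subsample_size = 800, seed = 48)
  # permuted-label null: independently shuffle each column
  set.seed(49)
  xp <- apply(x, 2, sample)
  colnames(xp) <- colnames(x)
  null <- shap_adjacency(xp, iterations = 5, subsample_size = 800, seed = 48)
  null_med <- median(null$values[row(null$values) != col(null$values)])
  expect_lt(max(adj$values), 5 * null_med)
})

test_that("link probability recovers dependence and stays in [0,1]", {
  set.seed(50)
  n <- 4000
  a <- rnorm(n)
  b <- a + rnorm(n, sd = 0.4)  # B a noisy function of A
  x <- cbind(A = a, B = b)
  lp <- link_probability(x, iterations = 100, subsample_size = 2000, seed = 51)
  expect_gt(lp$values["A", "B"] + lp$values["B", "A"], 0.8)
  expect_true(all(lp$values >= 0 & lp$values <= 1))

  xi <- independent_network_data(n = 4000, seed = 52, p = 4)
  lpi <- link_probability(xi, iterations = 100, subsample_size = 2000, seed = 53)
  expect_lt(max(lpi$values), 0.2)
})

test_that("link probability excludes zero-range features with a warning", {
  set.seed(54)
  x <- cbind(A = rnorm(500), B = rnorm(500), C = rep(1, 500))
  expect_warning(lp <- link_probability(x, iterations = 5,
                                        subsample_size = 400, seed = 1),
                 "zero-range")
  expect_equal(colnames(lp$values), c("A", "B"))
})

test_that("hill-climb DAG search finds strong edges and not noise", {
  set.seed(55)
  n <- 3000
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.3)
  B <- epicyto:::discretize_uniform(cbind(A = a, B = b, C = rnorm(n)), 20)$bins
  A <- epicyto:::hc_dag(B, 20)
  expect_equal(A["A", "B"] + A["B", "A"], 1L)  # adjacency found, one direction
  expect_equal(sum(A[, "C"]) + sum(A["C", ]), 0L)  # no spurious edge to noise
})

test_that("compare_networks is exact on self-comparison and errors on mismatch", {
  nm <- planted_network_data(n = 2000, seed = 56)
  pc <- partial_correlation(nm)
  self <- compare_networks(pc, pc)
  expect_equal(self$rank_correlation, 1)
  expect_equal(length(self$overlap), self$k)
  other <- partial_correlation(independent_network_data(n = 1000, p = 4))
  expect_error(compare_networks(pc, other), "marker sets")
})

test_that("all three models rank the planted edges above the 90th percentile", {
  nm <- planted_network_data(n = 5000, seed = 57)
  planted <- list(c("M1", "M2"), c("M2", "M3"), c("M4", "M5"))
  adj_s <- shap_adjacency(nm, iterations = 5, subsample_size = 1000, seed = 58)
  adj_l <- link_probability(nm, iterations = 60, subsample_size = 2500, seed = 58)
  adj_p <- partial_correlation(nm)
  for (adj in list(adj_s, adj_l, adj_p)) {
    pct <- edge_percentiles(adj, planted)
    expect_true(all(pct >= 0.9), info = adj$kind)
  }
  # the three reconstructions agree with each other
  cmp <- compare_networks(adj_s, adj_p, k = 3)
  expect_gte(length(cmp$overlap), 2)
})
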