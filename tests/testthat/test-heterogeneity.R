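# heterogeneity: closed-form oracles, brute-force equivalence, and
# geometric invariances of the four embedding measures.

make_embedding <- function(coords, labels) {
  structure(list(coords = as.matrix(coords), sample_label = labels,
                 params = list(n_neighbors = NA, min_dist = NA, seed = NA,
                               excluded_markers = character(0))),
            class = "embedding")
}

test_that("gini matches the double-sum oracle and its invariances", {
  gini_brute <- function(x) {
    if (min(x) < 0) x <- x - min(x)
    if (all(x == 0)) return(0)
    n <- length(x)
    sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
  }
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini_brute(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(rep(3.7, 10)), 0)
  expect_equal(gini(rep(0, 5)), 0)
  set.seed(21)
  for (i in 1:5) {
    x <- rexp(50)
    expect_equal(gini(x), gini_brute(x), tolerance = 1e-12)
    expect_equal(gini(10 * x), gini(x), tolerance = 1e-12)   # scale invariance
    expect_true(gini(x) >= 0 && gini(x) < 1)
  }
  # shifted-to-non-negative convention for signed input
  x <- rnorm(100)
  expect_equal(gini(x), gini_brute(x), tolerance = 1e-12)
})

test_that("convex-hull area matches closed forms and uniform sampling", {
  sq <- make_embedding(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), rep("a", 4))
  expect_equal(global_area(sq, "a"), 1.0)
  tri <- make_embedding(rbind(c(0, 0), c(1, 0), c(0, 1)), rep("a", 3))
  expect_equal(global_area(tri, "a"), 0.5)
  set.seed(22)
  unif <- make_embedding(cbind(runif(1000), runif(1000)), rep("a", 1000))
  a <- global_area(unif, "a")
  expect_gt(a, 0.9); expect_lt(a, 1.0)
  # degenerate cases return 0 with warning
  two <- make_embedding(rbind(c(0, 0), c(1, 1)), rep("a", 2))
  expect_warning(expect_equal(global_area(two, "a"), 0), "fewer than 3")
  col <- make_embedding(cbind(1:5, 2 * (1:5)), rep("a", 5))
  expect_warning(expect_equal(global_area(col, "a"), 0), "collinear")
})

test_that("nnd matches hand values and the O(n^2) oracle", {
  line <- make_embedding(cbind(c(0, 1, 3), 0), rep("a", 3))
  expect_equal(nnd(line, "a"), c(1, 1, 2))
  dup <- make_embedding(rbind(c(2, 2), c(2, 2)), rep("a", 2))
  expect_equal(nnd(dup, "a"), c(0, 0))
  set.seed(23)
  pts <- cbind(rnorm(500), rnorm(500))
  e <- make_embedding(pts, rep("a", 500))
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  expect_equal(nnd(e, "a"), unname(apply(d, 1, min)), tolerance = 1e-12)
})

test_that("global distance matches the exact pairwise oracle and scales linearly", {
  two <- make_embedding(rbind(c(0, 0), c(3, 4)), rep("a", 2))
  expect_equal(global_distance(two, "a", q = 0.95), 5)
  expect_equal(global_distance(two, "a", q = 0.05), 5)
  set.seed(24)
  pts <- cbind(rnorm(2000), rnorm(2000))
  e <- make_embedding(pts, rep("a", 2000))
  exact <- unname(quantile(dist(pts), 0.95))
  expect_equal(global_distance(e, "a"), exact)  # n below cap: exact path
  est <- global_distance(e, "a", cap = 100, n_pairs = 4e5, seed = 1)
  expect_lt(abs(est - exact) / exact, 0.02)
  e3 <- make_embedding(3 * pts, rep("a", 2000))
  expect_equal(global_distance(e3, "a"), 3 * exact, tolerance = 1e-12)
  expect_error(global_distance(e, "a", q = 1.2), "q must be")
})

test_that("occupied-grid local area behaves like an area", {
  same <- make_embedding(matrix(1, 50, 2) + 1e-9 * cbind(1:50, 1:50), rep("a", 50))
  # all points in one cell of a grid over a tiny bounding box
  a1 <- local_area(same, "a", grid_bins = 10)
  expect_gt(a1, 0)
  set.seed(25)
  # compact support: occupied area of a scaled cloud converges to x4
  r <- sqrt(runif(10000)); th <- runif(10000, 0, 2 * pi)
  base <- cbind(r * cos(th), r * sin(th))
  joint <- rbind(base, 2 * base)
  e <- make_embedding(joint, rep(c("a", "b"), each = 10000))
  ratio <- local_area(e, "b", grid_bins = 50) / local_area(e, "a", grid_bins = 50)
  expect_gt(ratio, 3); expect_lt(ratio, 5)  # scaling x2 quadruples area, +-25%
  # monotone in point count
  e_sub <- make_embedding(joint[c(1:5000, 10001:20000), ],
                          rep(c("a", "b"), c(5000, 10000)))
  expect_lte(local_area(e_sub, "a"), local_area(e, "a") + 1e-12)
})

test_that("measures are invariant to rigid motions and scale correctly", {
  set.seed(26)
  pts <- cbind(rnorm(400), rnorm(400))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(pts %*% R, 2, c(5, -3), "+")
  e1 <- make_embedding(pts, rep("a", 400))
  e2 <- make_embedding(moved, rep("a", 400))
  expect_equal(global_area(e2, "a"), global_area(e1, "a"), tolerance = 1e-9)
  expect_equal(global_distance(e2, "a"), global_distance(e1, "a"), tolerance = 1e-9)
  expect_equal(sort(nnd(e2, "a")), sort(nnd(e1, "a")), tolerance = 1e-9)
  e4 <- make_embedding(2.5 * pts, rep("a", 400))
  expect_equal(global_area(e4, "a"), 2.5^2 * global_area(e1, "a"), tolerance = 1e-9)
  expect_equal(nnd(e4, "a"), 2.5 * nnd(e1, "a"), tolerance = 1e-9)
})

test_that("cdf_ratio flags undefined points and detects stochastic dominance", {
  set.seed(27)
  a <- runif(5000); b <- runif(5000)
  same <- cdf_ratio(a, b)
  expect_true(all(abs(same$ratio[!is.na(same$ratio)] - 1) < 0.15))
  shifted <- cdf_ratio(b + 0.1, b)  # stochastically larger
  inner <- shifted$ratio[!is.na(shifted$ratio) & shifted$cdf_b < 1]
  expect_true(all(inner < 1))
  # undefined where denominator CDF is 0, not 0 or Inf
  r <- cdf_ratio(c(1, 2), c(10, 11), grid = c(0.5, 5, 12))
  expect_true(is.na(r$ratio[1]) && is.na(r$ratio[2]))
  expect_equal(r$ratio[3], 1)
  # common rescaling of samples and grid leaves the ratio unchanged
  g <- seq(0.1, 3, length.out = 20)
  r1 <- cdf_ratio(a, b, g); r2 <- cdf_ratio(7 * a, 7 * b, 7 * g)
  expect_equal(r1$ratio, r2$ratio)
  expect_error(cdf_ratio(numeric(0), b), "empty")
})

test_that("embeddings separate well-separated populations and respect exclusions", {
  set.seed(28)
  n <- 400
  x <- rbind(matrix(rnorm(n * 5), n, 5), matrix(rnorm(n * 5, mean = 8), n, 5))
  colnames(x) <- paste0("M", 1:5)
  panel <- panel_config(data.frame(channel_id = colnames(x),
                                   marker_name = colnames(x),
                                   role = "modification"))
  nm <- structure(list(values = x, sample_label = rep(c("a", "b"), each = n),
                       panel = panel, batch = rep("b1", 2 * n),
                       column_means = list(), column_sds = list()),
                  class = "normalized_matrix")
  e <- embed_cells(nm, n_neighbors = 15, min_dist = 0.1, seed = 42)[[1]]
  km <- kmeans(e$coords, 2, nstart = 5)
  agreement <- max(mean((km$cluster == 1) == (e$sample_label == "a")),
                   mean((km$cluster == 2) == (e$sample_label == "a")))
  expect_gt(agreement, 0.9)
  # determinism at fixed seed
  e2 <- embed_cells(nm, n_neighbors = 15, min_dist = 0.1, seed = 42)[[1]]
  expect_identical(e$coords, e2$coords)
  # an excluded marker has no influence: shuffling it leaves coords unchanged
  nm_shuf <- nm
  nm_shuf$values[, "M5"] <- sample(nm_shuf$values[, "M5"])
  e3 <- embed_cells(nm_shuf, n_neighbors = 15, min_dist = 0.1, seed = 42,
                    exclude_markers = "M5")[[1]]
  e4 <- embed_cells(nm, n_neighbors = 15, min_dist = 0.1, seed = 42,
                    exclude_markers = "M5")[[1]]
  expect_identical(e3$coords, e4$coords)
  expect_error(embed_cells(nm, n_neighbors = 10000, min_dist = 0.1), "n_neighbors")
})

test_that("self-comparison report gives unit ratios", {
  set.seed(29)
  coords <- cbind(rnorm(600), rnorm(600))
  e <- make_embedding(coords, rep("a", 600))
  e$sample_label <- rep("a", 600)
  rep_self <- heterogeneity_report(list(e), reference = "a", test = "a")
  expect_true(all(abs(rep_self$measures$ratio - 1) < 1e-12))
  expect_error(heterogeneity_report(list(e), reference = "a", test = "zz"),
               "absent")
})

test_that("transcriptional heterogeneity recovers a planted dispersion ratio", {
  x1 <- generate_expression(400, 150, dispersion_scale = 1, seed = 31)
  x2 <- generate_expression(400, 150, dispersion_scale = 2, seed = 32)
  x <- rbind(x1, x2)
  labels <- rep(c("wt", "mut"), each = 400)
  th <- transcriptional_heterogeneity(x, labels, n_sub = 150, reps = 100, seed = 33)
  ratio <- th$means[["mut"]] / th$means[["wt"]]
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
  expect_lt(th$test$p.value, 1e-10)
  th2 <- transcriptional_heterogeneity(x, labels, n_sub = 150, reps = 100, seed = 33)
  expect_identical(th$distributions, th2$distributions)
  # degenerate all-identical input is reported as such
  x0 <- matrix(5, 100, 20)
  expect_warning(
    th0 <- transcriptional_heterogeneity(x0, rep(c("a", "b"), each = 50),
                                         n_sub = 60, reps = 10, seed = 1),
    "lowered")
  expect_true(all(unlist(th0$distributions) == 0))
  expect_true(isTRUE(th0$test$degenerate))
  expect_error(transcriptional_heterogeneity(x0, rep("a", 100)), ">= 2 samples")
})
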