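# subpopulations: WT-like splits, contrasts, binned curves, mean-difference
# tables.

test_that("wt_like_fraction handles the boundary cases", {
  ref <- rnorm(1000)
  above <- max(ref) + 1 + abs(rnorm(500))  # entirely above the reference
  s <- wt_like_fraction(above, ref)
  expect_equal(s$wt_like_fraction, 0)
  expect_true(all(s$assignment == "extreme"))
  expect_error(wt_like_fraction(numeric(0), ref), "empty")
  expect_error(wt_like_fraction(above, ref, coverage = 0), "coverage")
  expect_error(wt_like_fraction(above, ref, coverage = 1.5), "coverage")
})

test_that("identical distributions recover the coverage as the fraction", {
  set.seed(71)
  ref <- rnorm(5000); test <- rnorm(5000)
  for (cov in c(0.9, 0.99)) {
    s <- wt_like_fraction(test, ref, coverage = cov)
    # binomial CI at n = 5000
    expect_lt(abs(s$wt_like_fraction - cov), 3 * sqrt(cov * (1 - cov) / 5000) + 0.01)
  }
  # monotone non-decreasing in coverage
  covs <- c(0.5, 0.8, 0.9, 0.99, 1)
  fr <- vapply(covs, function(cv) wt_like_fraction(test, ref, cv)$wt_like_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("the planted minor-mode fraction is recovered from the generator", {
  errs <- vapply(1:10, function(s) {
    # clean two-mode design: unit dispersion, no dependency inflow into the
    # bimodal marker, +5 sd separation (a central-99% reference interval
    # reaches 2.58 sd, so the major mode must sit well beyond it for the
    # planted fraction to be identifiable)
    spec <- default_synthetic_spec(n_cells_per_sample = 5000, seed = 70 + s,
                                   mutant_dispersion = 1,
                                   minor_mode_fraction = 0.2)
    spec$dependency_graph <-
      spec$dependency_graph[spec$dependency_graph$target != "H3K27me3", ]
    spec$samples$mean_shift[[2]] <- c(H3K27me3 = 5 * 0.35)
    spec$samples$minor_mode_shift[2] <- -5 * 0.35
    nm <- preprocess(generate_mixture(spec))
    ref <- nm$values[nm$sample_label == "WT", "H3K27me3"]
    mut <- nm$values[nm$sample_label == "EZH2_Y646N", "H3K27me3"]
    split <- wt_like_fraction(mut, ref, coverage = 0.99)
    abs(split$wt_like_fraction - 0.2)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
  expect_true(mean(errs < 0.03) >= 0.8)
})

test_that("subpopulation contrast recovers a planted shift and scales its SE", {
  set.seed(72)
  n <- 2000
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("A", "B", "C")))
  assign <- factor(rep(c("wt_like", "extreme"), each = n / 2),
                   levels = c("wt_like", "extreme"))
  x[assign == "extreme", "B"] <- x[assign == "extreme", "B"] + 1
  split <- structure(list(marker = "B", assignment = assign,
                          reference_interval = c(low = -2, high = 2),
                          coverage = 0.99, wt_like_fraction = 0.5),
                     class = "bimodal_split")
  ct <- subpopulation_contrast(x, split, n_boot = 500, seed = 73)
  expect_equal(ct$diff_extreme_wtlike[ct$marker == "B"], 1,
               tolerance = 4 * ct$se_extreme_wtlike[ct$marker == "B"])
  expect_lt(abs(ct$diff_extreme_wtlike[ct$marker == "A"]),
            4 * ct$se_extreme_wtlike[ct$marker == "A"])
  # quadrupling the subpopulation sizes shrinks the SE by ~sqrt(2)... i.e. x2
  x4 <- x[rep(1:n, 4), ]
  assign4 <- rep(assign, 4)
  split4 <- split; split4$assignment <- assign4
  ct4 <- subpopulation_contrast(x4, split4, n_boot = 500, seed = 74)
  ratio <- ct$se_extreme_wtlike[2] / ct4$se_extreme_wtlike[2]
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.5)
})

test_that("identical subpopulations show no significant contrasts", {
  set.seed(75)
  x <- matrix(rnorm(1000 * 3), 1000, 3, dimnames = list(NULL, c("A", "B", "C")))
  assign <- factor(rep(c("wt_like", "extreme"), 500),
                   levels = c("wt_like", "extreme"))
  split <- structure(list(marker = "A", assignment = assign,
                          reference_interval = c(low = -2, high = 2),
                          coverage = 0.99, wt_like_fraction = 0.5),
                     class = "bimodal_split")
  ct <- subpopulation_contrast(x, split, n_boot = 500, seed = 76)
  expect_true(all(abs(ct$diff_extreme_wtlike) < 3 * ct$se_extreme_wtlike))
})

test_that("binned means equal a group-by loop oracle and masking works", {
  set.seed(77)
  x <- runif(3000, 0, 10)
  y <- sin(x) + rnorm(3000, sd = 0.1)
  curve <- binned_mean_curve(x, y, n_bins = 12, min_count = 10)
  edges <- curve$bin_edges
  for (b in seq_len(12)) {
    inb <- x >= edges[b] & (x < edges[b + 1] | (b == 12 & x <= edges[13]))
    if (sum(inb) >= 10) {
      expect_equal(curve$bin_means[b], mean(y[inb]), tolerance = 1e-12)
      expect_equal(curve$bin_sems[b], sd(y[inb]) / sqrt(sum(inb)), tolerance = 1e-12)
    } else {
      expect_true(is.na(curve$bin_means[b]))
    }
  }
  expect_equal(sum(curve$bin_counts), 3000L)
  # constant y: flat curve with zero SEM
  flat <- binned_mean_curve(x, rep(2.5, 3000), n_bins = 5, min_count = 1)
  expect_true(all(flat$bin_means == 2.5))
  expect_true(all(flat$bin_sems == 0))
  expect_equal(curve_sign_changes(flat), 0L)
  expect_error(binned_mean_curve(rep(1, 100), rnorm(100), n_bins = 5), "zero x range")
})

test_that("a planted bell gives exactly one sign change at n = 20000", {
  set.seed(78)
  x <- rnorm(20000)
  y <- -(x - 0.2)^2 + rnorm(20000, sd = 0.5)
  curve <- binned_mean_curve(x, y, n_bins = 20, min_count = 50)
  expect_equal(curve_sign_changes(curve), 1L)
})

test_that("mean-difference tables are antisymmetric and localize planted shifts", {
  set.seed(79)
  spec <- default_synthetic_spec(n_cells_per_sample = 1500, seed = 80)
  spec$samples$mean_shift[[2]] <- c(H3K27me3 = 0.5, H3K9me3 = 0.5)
  spec$samples$bimodal_marker <- NA_character_
  spec$bell_pair <- NULL
  nm <- preprocess(generate_mixture(spec))
  # standardized scale: a planted log shift of 0.5 against base sd 0.35
  # appears at those markers only
  tab <- mean_difference_heatmap(nm, list(c("EZH2_Y646N", "WT")),
                                 n_boot = 200, seed = 81)
  hits <- tab$marker[abs(tab$diff) > 4 * tab$se]
  expect_true(all(c("H3K27me3", "H3K9me3") %in% hits))
  expect_false("H3K4me1" %in% hits)
  rev_tab <- mean_difference_heatmap(nm, list(c("WT", "EZH2_Y646N")),
                                     n_boot = 200, seed = 81)
  expect_equal(tab$diff, -rev_tab$diff)
  # group vs itself is exactly zero
  self_tab <- mean_difference_heatmap(nm, list(c("WT", "WT")), n_boot = 50)
  expect_true(all(self_tab$diff == 0))
  expect_error(mean_difference_heatmap(nm, list(c("WT", "nope"))), "unknown group")
})
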