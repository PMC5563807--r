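test_that("Dirichlet deviates: normalization, determinism, posterior mean", {
  n <- c(3, 0, 5.5, 1, 0.5, 2, 8)
  dev <- dirichlet_deviates(n, alpha0 = 0.5, nsim = 500, seed = 1)
  expect_equal(dim(dev), c(500L, 7L))
  expect_true(all(abs(rowSums(dev) - 1) < 1e-12))
  expect_true(all(dev >= 0))
  # determinism contract, and global RNG state untouched
  set.seed(99); before <- .Random.seed
  dev2 <- dirichlet_deviates(n, alpha0 = 0.5, nsim = 500, seed = 1)
  expect_identical(dev, dev2)
  expect_identical(before, .Random.seed)
  # closed-form posterior mean: (n_k + a0) / (N + K a0)
  n10 <- c(10, rep(0, 6))
  dev3 <- dirichlet_deviates(n10, alpha0 = 0.5, nsim = 40000, seed = 2)
  expect_equal(mean(dev3[, 1]), 10.5 / 13.5, tolerance = 0.005)
  # symmetric case: all-zero counts with a0 = 0.5 average to 1/K
  dev4 <- dirichlet_deviates(rep(0, 7), alpha0 = 0.5, nsim = 40000, seed = 3)
  expect_equal(unname(colMeans(dev4)), rep(1 / 7, 7), tolerance = 0.01)
  expect_error(dirichlet_deviates(rep(0, 7), alpha0 = 0), "undefined")
  expect_error(dirichlet_deviates(c(-1, 2)), "nonnegative")
  expect_error(dirichlet_deviates(c(1, 2), nsim = 0), "nsim")
})

test_that("credible intervals are equal-tailed empirical quantiles", {
  const <- matrix(0.3, nrow = 50, ncol = 3)
  ci <- credible_interval(const)
  expect_equal(unname(ci[, "low"]), rep(0.3, 3))
  expect_equal(unname(ci[, "high"]), rep(0.3, 3))
  # level = 0 limit: both bounds at the median
  dev <- dirichlet_deviates(c(2, 3, 4), nsim = 201, seed = 4)
  ci0 <- credible_interval(dev, level = 0)
  med <- apply(dev, 2, stats::median)
  expect_equal(unname(ci0[, "low"]), unname(med))
  expect_equal(unname(ci0[, "high"]), unname(med))
  expect_error(credible_interval(dev, level = 1), "level")
  expect_error(credible_interval(dev, level = -0.1), "level")
  # Beta(1/2, 1/2) oracle: K = 2 symmetric Dirichlet marginal; frozen from
  # qbeta(c(.025, .975), .5, .5) = 0.00154135, 0.99845865
  dev2 <- dirichlet_deviates(c(0, 0), alpha0 = 0.5, nsim = 50000, seed = 5)
  ci2 <- credible_interval(dev2, level = 0.95)
  expect_equal(unname(ci2[1, ]), c(0.00154135, 0.99845865), tolerance = 0.25)
  expect_lt(abs(ci2[1, "low"] - 0.00154135), 1e-3)
  expect_lt(abs(ci2[1, "high"] - 0.99845865), 1e-3)
})

test_that("interval coverage is near nominal (scaled-down check)", {
  # full-scale (5000 replicates) version lives in the acceptance suite
  pstar <- c(0.10, 0.15, 0.20, 0.15, 0.20, 0.12, 0.08)
  set.seed(31)
  reps <- 800
  cover <- matrix(FALSE, reps, 7)
  for (r in seq_len(reps)) {
    n <- as.vector(stats::rmultinom(1, 50, pstar))
    ci <- credible_interval(dirichlet_deviates(n, 0.5, nsim = 600))
    cover[r, ] <- pstar >= ci[, "low"] & pstar <= ci[, "high"]
  }
  expect_true(all(colMeans(cover) > 0.92 & colMeans(cover) < 0.98))
})

test_that("interval width shrinks as N grows at fixed proportions", {
  pstar <- c(0.10, 0.15, 0.20, 0.15, 0.20, 0.12, 0.08)
  width <- function(N) {
    ci <- credible_interval(dirichlet_deviates(pstar * N, 0.5, nsim = 2000,
                                               seed = 8))
    mean(ci[, "high"] - ci[, "low"])
  }
  expect_lt(width(1000), width(100))
  expect_lt(width(100), width(10))
})

test_that("mortality profiles carry proportions, CIs and metadata", {
  scheme <- fix_scheme()
  map <- fix_map(scheme)
  ds <- generate_dataset(simulation_spec(c("A", "B", "C"),
                                         c("Milk1", "Meat", "Milk2"),
                                         n_teeth = c(40, 40, 40), seed = 2))
  tab <- build_count_table(ds$records, map)
  prof <- mortality_profiles(tab, nsim = 400, seed = 5)
  expect_length(prof, 3L)
  p1 <- prof[[1]]
  expect_equal(sum(p1$proportions), 1)
  expect_equal(p1$N, 40)
  expect_true(all(p1$ci_low <= p1$ci_high))
  # per-context streams: adding a context never perturbs earlier ones
  prof2 <- mortality_profiles(tab[1:2, ], nsim = 400, seed = 5)
  expect_equal(prof2[[1]], prof[[1]])
  expect_equal(prof2[[2]], prof[[2]])
  # report: one row per context x class, bars sum to 100% per panel
  rep_df <- profile_report(prof)
  expect_equal(nrow(rep_df), 21L)
  sums <- tapply(rep_df$pct, rep_df$context_id, sum)
  expect_equal(as.numeric(sums), rep(100, 3))
  expect_error(profile_report(list()), "no profiles")
  expect_s3_class(plot_profiles(prof), "ggplot")
})

test_that("contexts with zero teeth are excluded with a warning", {
  tab <- structure(rbind(A = c(1, 2, 0, 0, 0, 0, 1),
                         B = rep(0, 7)),
                   N = c(A = 4L, B = 0L), class = c("count_table", "matrix"))
  colnames(tab) <- class_labels(fix_scheme())
  expect_warning(prof <- mortality_profiles(tab, nsim = 50, seed = 1),
                 "zero teeth: B")
  expect_length(prof, 1L)
})
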