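test_that("identical rows give zero inertia and no axes", {
  x <- matrix(rep(c(0.2, 0.3, 0.5), each = 6), nrow = 6)
  res <- correspondence_analysis(x)
  expect_equal(res$total_inertia, 0, tolerance = 1e-14)
  expect_equal(res$n_axes, 0L)
})

test_that("2x2 tables match the closed-form mean-square contingency", {
  set.seed(11)
  for (rep in 1:25) {
    x <- matrix(stats::rexp(4) + 0.05, 2, 2)
    p <- x / sum(x)
    r <- rowSums(p); cm <- colSums(p)
    lambda_closed <- (p[1, 1] * p[2, 2] - p[1, 2] * p[2, 1])^2 /
      (r[1] * r[2] * cm[1] * cm[2])
    res <- correspondence_analysis(x)
    expect_equal(res$n_axes, 1L)
    expect_equal(unname(res$inertia[1]), unname(lambda_closed),
                 tolerance = 1e-12)
  }
})

test_that("inertias and |coordinates| match the brute-force oracle", {
  set.seed(21)
  for (rep in 1:30) {
    x <- random_table(sample(3:8, 1), sample(3:7, 1))
    res <- correspondence_analysis(x)
    ora <- ca_oracle(x)
    expect_lt(max(abs(res$inertia - ora$inertia)), 1e-10)
    expect_lt(abs(res$total_inertia - ora$total_inertia), 1e-12)
    # per-axis sign is the only permitted discrepancy
    expect_lt(max(abs(abs(res$col_coords) - abs(ora$col_coords))), 1e-10)
    # total inertia equals the independently computed mean-square contingency
    expect_equal(sum(res$inertia), res$total_inertia, tolerance = 1e-12)
  }
})

test_that("column contributions sum to 1000 per mille per axis", {
  set.seed(33)
  for (rep in 1:10) {
    res <- correspondence_analysis(random_table(6, 5))
    expect_equal(unname(colSums(res$col_contrib)),
                 rep(1000, res$n_axes), tolerance = 1e-9)
  }
  expect_equal(sum(correspondence_analysis(random_table(9, 7))$col_mass), 1)
})

test_that("supplementary points do not alter the solution", {
  set.seed(44)
  x <- random_table(8, 7)
  res0 <- correspondence_analysis(x)
  sup <- list(ref1 = rep(1 / 7, 7),
              ref2 = c(0.5, 0.2, 0.1, 0.1, 0.05, 0.03, 0.02))
  res1 <- correspondence_analysis(x, supplementary = sup)
  expect_identical(res0$inertia, res1$inertia)
  expect_identical(res0$col_coords, res1$col_coords)
  expect_identical(res0$row_coords, res1$row_coords)
  expect_equal(rownames(res1$sup_coords), c("ref1", "ref2"))
  # centroid profile maps to the origin
  centroid <- res0$col_mass / sum(res0$col_mass)
  expect_equal(project_supplementary(res0, centroid),
               rep(0, res0$n_axes), tolerance = 1e-10)
  # vertex property: indicator of class k lands on its standard coordinates
  for (k in c(1, 4, 7)) {
    ind <- rep(0, 7); ind[k] <- 1
    expect_equal(project_supplementary(res0, ind),
                 unname(res0$std_col_coords[k, ]), tolerance = 1e-10)
  }
  expect_error(project_supplementary(res0, rep(1 / 5, 5)), "wrong length")
  expect_error(project_supplementary(res0, rep(1, 7)), "sum to 1")
})

test_that("degenerate and malformed inputs are handled", {
  expect_error(correspondence_analysis(matrix(-1, 2, 2)), "nonnegative")
  expect_error(correspondence_analysis(matrix(0, 2, 2)), "zero grand total")
  x <- random_table(5, 4)
  colnames(x) <- letters[1:4]
  x[, 2] <- 0
  expect_warning(res <- correspondence_analysis(x), "zero-mass column.*b")
  expect_equal(nrow(res$col_coords), 3L)
  # single active row: zero axes
  one <- matrix(c(0.2, 0.3, 0.5), 1)
  expect_equal(correspondence_analysis(one)$n_axes, 0L)
})

test_that("stacked deviates are deterministic blocks per context", {
  map <- fix_map()
  ds <- generate_dataset(simulation_spec(c("A", "B", "C"),
                                         c("Milk1", "Meat", "IntenseMilk"),
                                         n_teeth = c(30, 30, 30), seed = 4))
  tab <- build_count_table(ds$records, map)
  act <- stack_deviates(tab, nsim = 100, seed = 9)
  expect_equal(dim(act), c(300L, 7L))
  expect_equal(attr(act, "context"), rep(c("A", "B", "C"), each = 100))
  expect_identical(act, stack_deviates(tab, nsim = 100, seed = 9))
  # adding a context leaves existing blocks byte-identical
  act2 <- stack_deviates(tab[1:2, ], nsim = 100, seed = 9)
  expect_identical(act[1:200, ], `attr<-`(act2, "context", NULL))
  expect_error(stack_deviates(tab[0, ], nsim = 10), "empty context")
  # one context, one deviate: CA degenerates to zero axes
  single <- stack_deviates(tab[1, , drop = FALSE], nsim = 1, seed = 2)
  expect_equal(correspondence_analysis(single)$n_axes, 0L)
  # context mean profiles are the block column means
  means <- context_mean_profiles(act)
  expect_equal(unname(means["A", ]), unname(colMeans(act[1:100, ])))
})

test_that("axis orientation convention anchors F1/F2 signs", {
  map <- fix_map()
  ds <- generate_dataset(simulation_spec(sprintf("c%d", 1:8),
                                         rep(c("Milk1", "Meat"), 4),
                                         seed = 12))
  tab <- build_count_table(ds$records, map)
  act <- stack_deviates(tab, nsim = 200, seed = 12)
  res <- correspondence_analysis(act, orient_anchors = default_orientation())
  expect_gte(res$col_coords[7, 1], 0)  # >8 years nonnegative on F1
  expect_gte(res$col_coords[5, 2], 0)  # 3-6 years nonnegative on F2
  plain <- correspondence_analysis(act)
  expect_equal(plain$inertia, res$inertia)
  expect_equal(abs(plain$col_coords), abs(res$col_coords), tolerance = 1e-12)
})

test_that("axis_summary mirrors the conventional per-class table", {
  map <- fix_map()
  ds <- generate_dataset(simulation_spec(sprintf("c%d", 1:6),
                                         rep(c("Milk1", "Meat"), 3),
                                         seed = 13))
  tab <- build_count_table(ds$records, map)
  res <- correspondence_analysis(stack_deviates(tab, nsim = 200, seed = 13))
  summ <- axis_summary(res)
  expect_equal(nrow(summ), 7L)
  expect_lte(abs(sum(summ$mass_permille) - 1000), 4)  # rounding slack
  expect_lte(abs(sum(summ$ctr_F1_permille) - 1000), 4)
  expect_named(summ, c("class", "mass_permille",
                       "coord_F1", "ctr_F1_permille",
                       "coord_F2", "ctr_F2_permille",
                       "coord_F3", "ctr_F3_permille"))
  res2 <- correspondence_analysis(matrix(stats::rexp(8), 4, 2))
  expect_error(axis_summary(res2), "1 axes")
})

test_that("classify_context assigns nearest reference with tie warning", {
  refs <- rbind(R1 = c(0, 0, 1), R2 = c(1, 0, 0))
  ctx <- rbind(a = c(0, 0, 0.4), b = c(0.9, 0.1, 2), c = c(0.4, 0, 5))
  out <- classify_context(ctx, refs, axes = 1:2)
  expect_equal(out$nearest, c("R1", "R2", "R1"))
  expect_equal(out$dist_R1[1], 0)
  # context exactly at a reference
  out2 <- classify_context(rbind(z = c(1, 0)), rbind(R1 = c(0, 0),
                                                     R2 = c(1, 0)))
  expect_equal(out2$nearest, "R2")
  expect_equal(out2$dist_R2, 0)
  # equidistant pair: first-listed wins with a warning
  expect_warning(out3 <- classify_context(rbind(m = c(0.5, 0)),
                                          rbind(R1 = c(0, 0),
                                                R2 = c(1, 0))),
                 "equidistant")
  expect_equal(out3$nearest, "R1")
  expect_error(classify_context(ctx, refs, axes = 1:5), "exceed")
})

test_that("total inertia is stable across master seeds", {
  map <- fix_map()
  ds <- generate_dataset(simulation_spec(sprintf("c%02d", 1:10),
                                         rep(c("Milk1", "Meat"), 5),
                                         seed = 3))
  tab <- build_count_table(ds$records, map)
  ti <- vapply(1:5, function(s)
    correspondence_analysis(stack_deviates(tab, nsim = 2000, seed = s),
                            keep_row_coords = FALSE)$total_inertia,
    numeric(1))
  expect_lt(stats::sd(ti) / mean(ti), 0.01)
})
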