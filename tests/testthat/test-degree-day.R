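test_that("exact linear rates give the exact model", {
  T <- c(15, 20, 25, 30)
  pts <- data.frame(temperature_c = T, rate = 0.01 * (T - 10))
  m <- rate_regression(pts)
  expect_equal(m$dev_min, 10, tolerance = 1e-10)
  expect_equal(m$add, 100, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  # internal identities hold exactly
  expect_equal(m$add * m$slope, 1, tolerance = 1e-12)
  expect_equal(m$dev_min, -m$intercept / m$slope, tolerance = 1e-12)
})

test_that("degenerate regressions are refused", {
  expect_error(rate_regression(data.frame(temperature_c = c(15, 20),
                                          rate = c(0.1, 0.2))), "at least 3")
  expect_error(rate_regression(data.frame(temperature_c = c(15, 20, 25),
                                          rate = c(0.3, 0.2, 0.1))),
               "non-positive")
  expect_error(rate_regression(data.frame(temperature_c = c(15, 20, 25),
                                          rate = c(0.1, 0.2, -0.1))),
               "positive")
})

test_that("runs counting and the textbook example check out", {
  r <- runs_test(c(1, 2, 3, 4, -1, -2, -3, -4))
  expect_identical(r$runs, 2L)
  expect_identical(c(r$n_pos, r$n_neg), c(4L, 4L))
  # one-tail P(R <= 2) = 2/C(8,4) = 2/70
  expect_equal(r$one_sided_low, 2 / 70, tolerance = 1e-12)

  alt <- runs_test(rep(c(1, -1), 5))
  expect_identical(alt$runs, 10L)
  expect_lt(alt$p_value, 0.05)  # perfectly alternating: upper-tail extreme

  one_sign <- runs_test(c(1, 2, 3))
  expect_identical(one_sign$runs, 1L)
  expect_true(one_sign$uninformative)

  # zero residuals are dropped before counting
  rz <- runs_test(c(1, 0, 1, -1, 0, -1))
  expect_identical(c(rz$n_pos, rz$n_neg), c(2L, 2L))
})

test_that("exact runs p-values match brute-force enumeration", {
  set.seed(99)
  cases <- list()
  for (n in c(4, 6, 8, 10, 12)) {
    for (i in 1:6) {
      s <- sign(rnorm(n))
      if (length(unique(s)) == 2) cases[[length(cases) + 1]] <- s
    }
  }
  # plus the deliberately extreme patterns
  cases <- c(cases, list(c(1, 1, 1, 1, -1, -1, -1, -1),
                         rep(c(1, -1), 6), c(rep(1, 9), rep(-1, 3))))
  for (s in cases) {
    expect_equal(runs_test(s)$p_value, brute_force_runs_p(s),
                 tolerance = 1e-12)
  }
})

test_that("the closed-form runs distribution sums to one and matches enumeration", {
  for (n1 in 2:8) for (n2 in 2:8) {
    probs <- phormiadev:::runs_distribution(n1, n2)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("pruning is idempotent on already-linear data", {
  set.seed(4)
  T <- seq(15, 32.5, 2.5)
  pts <- data.frame(temperature_c = T,
                    rate = (T - 10.2) / 182 * exp(rnorm(length(T), 0, 0.01)))
  m0 <- rate_regression(pts)
  m1 <- prune_until_linear(pts)
  expect_identical(nrow(m1$trace), 0L)
  expect_equal(m1$add, m0$add)
  expect_equal(m1$n, m0$n)
})

test_that("the included set only shrinks and refitting the final set is a fixed point", {
  set.seed(12)
  T <- seq(12.5, 35, 2.5)
  cfg <- sim_config(temperatures = T, linear_range = c(15, 32.5))
  g <- effective_rate(T, cfg) / pmax(1e-9, T - cfg$true_dev_min)
  pts <- data.frame(temperature_c = T,
                    rate = (T - 10.2) / 182 * g *
                      exp(rnorm(length(T), 0, 0.015)))
  m <- fit_degree_day_model(pts, event = "E-A")
  expect_true(m$validated)
  included <- m$points$temperature_c[m$points$included]
  # re-running the full loop on the surviving points changes nothing
  m2 <- fit_degree_day_model(m$points[m$points$included, ], event = "E-A")
  expect_equal(sort(m2$points$temperature_c[m2$points$included]),
               sort(included))
  expect_equal(m2$add, m$add, tolerance = 1e-12)
})

test_that("zero-curvature accumulations pass validation with zero slope", {
  T <- seq(15, 32.5, 2.5)
  pts <- data.frame(temperature_c = T, rate = (T - 10.2) / 182)
  m <- validate_add_accumulation(rate_regression(pts))
  expect_true(m$validation$accepted)
  expect_equal(stats::coef(m$validation$fit)[2], c(`inc$temperature_c` = 0),
               tolerance = 1e-9)
})

test_that("a misspecified developmental minimum tilts the accumulations detectably", {
  T <- seq(15, 32.5, 2.5)
  pts <- data.frame(temperature_c = T, rate = (T - 10.2) / 182)
  m <- rate_regression(pts)
  m$dev_min <- m$dev_min + 2  # force a 2 degC error in the minimum
  v <- validate_add_accumulation(m)
  # ADD_i = D (T - dev_min - 2) is linear in T with slope -2D... i.e. +D
  expect_false(v$validation$accepted)
  expect_lt(v$validation$slope_p, 0.05)
})

test_that("calculated ADD summaries use the population SD and percent deviation", {
  vals <- c(191.2, 184.1, 181.5, 175.3, 172.8, 179.9)
  s <- summarize_add(vals, regression_add = 181.9)
  expect_equal(round(s$mean, 1), 180.8)
  expect_equal(round(s$sd_pop, 1), 6.0)
  expect_equal(s$pct_deviation, 100 * (mean(vals) - 181.9) / 181.9)
  same <- summarize_add(c(5, 5, 5))
  expect_equal(same$mean, 5)
  expect_equal(same$sd_pop, 0)
  expect_error(summarize_add(numeric(0)), "no degree-day")
})
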