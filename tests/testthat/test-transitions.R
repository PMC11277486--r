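test_that("probit t50 is the symmetry point of a symmetric design", {
  d <- data.frame(time_h = c(10, 20, 30), n_entered = c(0, 10, 20),
                  n_live = 20)
  est <- probit_t50(d)
  expect_equal(est$t50, 20, tolerance = 1e-6)
  expect_identical(est$method, "probit")
})

test_that("probit regression recovers the generating normal CDF", {
  set.seed(14)
  times <- seq(10, 30, by = 0.5)
  n <- 400
  entered <- rbinom(length(times), n, pnorm(times, mean = 20, sd = 3))
  est <- probit_t50(data.frame(time_h = times, n_entered = entered,
                               n_live = n))
  expect_equal(est$t50, 20, tolerance = 0.05)
  expect_equal(est$sd, 3, tolerance = 0.05)
  # any desired percentile through the fitted quantile function
  expect_equal(est$quantile_fn(0.5), est$t50)
  expect_gt(est$quantile_fn(0.95), est$t50)
})

test_that("probit refuses data with no transition information", {
  d <- data.frame(time_h = c(10, 20, 30), n_entered = 0, n_live = 20)
  expect_error(probit_t50(d), "no transition observed")
  d2 <- data.frame(time_h = c(10, 20), n_entered = c(20, 0), n_live = 20)
  expect_error(probit_t50(d2), "not positive")
})

test_that("the cumulative-Gaussian t50 is the fitted center", {
  x <- seq(50, 100, by = 2.5)
  y <- evaluate_curve(list(model = "cumulative_gaussian", a = 1, b = 75,
                           c = 4), x)
  fit <- fit_stage_curve(x, y, "cumulative_gaussian")
  est <- t50_from_cumulative(fit)
  expect_equal(est$t50, 75, tolerance = 1e-6)

  yr <- evaluate_curve(list(model = "reversed_cumulative_gaussian", a = 1,
                            b = 12, c = 2), seq(0, 24, 1))
  fitr <- fit_stage_curve(seq(0, 24, 1), yr, "reversed_cumulative_gaussian")
  expect_equal(t50_from_cumulative(fitr)$t50, 12, tolerance = 1e-6)

  expect_error(t50_from_cumulative(fit_stage_curve(x, y + 0, "gaussian")),
               "cumulative")
  bad <- fit; bad$converged <- FALSE
  expect_error(t50_from_cumulative(bad), "non-converged")
})

test_that("probit and cumulative routes agree on the same simulated transition", {
  cfg <- quick_config(seed = 31)
  obs <- generate_cohort(cfg)
  ser <- boundary_entered_series(obs, 25, 2)  # L1 -> L2
  e_cum <- estimate_t50(ser, route = "cumulative")
  e_pro <- estimate_t50(ser, route = "probit")
  se <- sqrt(max(e_cum$se_t50, 1e-6)^2 + max(e_pro$se_t50, 1e-6)^2)
  expect_lt(abs(e_cum$t50 - e_pro$t50), 2 * se + 1e-6)
})

test_that("t50 refuses series whose median is not bracketed", {
  ser <- data.frame(time_h = c(10, 20, 30), n_entered = c(0, 2, 6),
                    n_live = 20)
  ser$p <- ser$n_entered / ser$n_live
  expect_error(estimate_t50(ser), "never reach 50%")
})

test_that("a pure step series yields the bracket midpoint with uniform se", {
  ser <- data.frame(time_h = c(10, 20, 30, 40), n_entered = c(0, 0, 20, 20),
                    n_live = 20)
  ser$p <- ser$n_entered / ser$n_live
  est <- estimate_t50(ser)
  expect_equal(est$t50, 25)
  expect_equal(est$se_t50, 10 / sqrt(12))
  expect_true(isTRUE(est$degenerate))
})

test_that("stage durations come from subtraction of consecutive t50s", {
  mk <- function(t) structure(list(t50 = t, se_t50 = 0.5), class =
                                "transition_estimate")
  ests <- stats::setNames(lapply(c(12, 30, 75, 120, 200, 420), mk),
                          pr_boundaries())
  durs <- stage_durations(ests)
  expect_equal(durs$duration_h, c(12, 18, 45, 45, 80, 220))
  expect_equal(durs$duration_days, durs$duration_h / 24)
  # egg duration equals the first boundary's t50: same event by construction
  expect_equal(durs$duration_h[1], 12)

  # missing boundary -> missing duration, neighbors unaffected
  ests2 <- ests; ests2["L2-L3f"] <- list(NULL)
  durs2 <- stage_durations(ests2)
  expect_true(is.na(durs2$duration_h[durs2$stage == "L2"]))
  expect_true(is.na(durs2$duration_h[durs2$stage == "L3f"]))
  expect_equal(durs2$duration_h[durs2$stage == "P"], 220)

  # non-monotone sequence names the offending boundary
  ests3 <- ests; ests3[["L1-L2"]] <- mk(80)
  expect_error(stage_durations(ests3), "non-monotone")
})

test_that("durations sum to the total development time and percents to 100", {
  cfg <- noiseless_config(samples_per_stage = 60,
                          temperatures = seq(17.5, 30, 2.5))
  obs <- generate_cohort(cfg)
  for (tt in c(20, 27.5)) {
    ests <- lapply(1:6, function(k)
      estimate_t50(boundary_entered_series(obs, tt, k)))
    names(ests) <- pr_boundaries()
    durs <- stage_durations(ests)
    expect_equal(sum(durs$duration_h), ests[["P-A"]]$t50, tolerance = 1e-9)
    pct <- 100 * durs$duration_h / sum(durs$duration_h)
    expect_equal(sum(pct), 100, tolerance = 1e-9)
  }
})

test_that("t50 standard errors shrink with larger cohorts", {
  se_for <- function(n) {
    set.seed(8)
    times <- seq(12, 28, by = 2)
    entered <- rbinom(length(times), n, pnorm(times, 20, 3))
    probit_t50(data.frame(time_h = times, n_entered = entered,
                          n_live = n))$se_t50
  }
  expect_lt(se_for(800), se_for(20))
})
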