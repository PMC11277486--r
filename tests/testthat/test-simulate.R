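test_that("sampling windows scale inversely with distance above the assumed minimum", {
  # duration 16 h at a temperature twice as far above the minimum as a
  # second temperature -> the second temperature's window is 32 h
  s <- build_sampling_schedule(c("E-L1" = 16), reference_temp = 30,
                               assumed_dev_min = 10,
                               temperatures = c(20, 30))
  expect_equal(max(s$time_h[s$temperature_c == 30]), 16)
  expect_equal(max(s$time_h[s$temperature_c == 20]), 32)

  # a 10 h window divides into times 2, 4, 6, 8, 10
  s <- build_sampling_schedule(c("E-L1" = 10), reference_temp = 25,
                               assumed_dev_min = 10, temperatures = 25)
  expect_equal(s$time_h, c(2, 4, 6, 8, 10))
})

test_that("egg-hatch sampling interval at 25 degC is a few hours, as in the real design", {
  cfg <- sim_config()
  sched <- phormiadev:::default_schedule(cfg)
  d <- sched[sched$temperature_c == 25 & sched$boundary == "E-L1", ]
  interval <- diff(d$time_h)[1]
  expect_gt(interval, 1)
  expect_lt(interval, 4)
})

test_that("temperatures at or below the assumed minimum reuse the lowest scalable schedule", {
  cfg <- sim_config()
  sched <- phormiadev:::default_schedule(cfg)
  t75 <- sched$time_h[sched$temperature_c == 7.5]
  t10 <- sched$time_h[sched$temperature_c == 10]
  t125 <- sched$time_h[sched$temperature_c == 12.5]
  expect_equal(t75, t125)
  expect_equal(t10, t125)
})

test_that("schedule construction rejects invalid inputs", {
  expect_error(build_sampling_schedule(numeric(0), 25, 10, 25), "no reference")
  expect_error(build_sampling_schedule(c(E = 10), 9, 10, 25), "exceed")
  expect_error(
    build_sampling_schedule(data.frame(boundary = "E-L1", t_min = 5,
                                       t_max = 5), 25, 10, 25),
    "non-positive")
  expect_error(build_sampling_schedule(c(E = 10), 25, 10, c(8, 9)),
               "no treatment temperature")
})

test_that("cohorts are bit-reproducible and conserve individuals", {
  cfg <- quick_config(seed = 5, mortality_per_stage = 0.02)
  obs1 <- generate_cohort(cfg)
  obs2 <- generate_cohort(cfg)
  expect_identical(obs1, obs2)
  totals <- tapply(obs1$count,
                   interaction(obs1$temperature_c, obs1$time_h,
                               obs1$replicate, drop = TRUE), sum)
  expect_true(all(totals == cfg$eggs_per_cup))
})

test_that("no development occurs below the biological minimum", {
  cfg <- sim_config(temperatures = c(7.5, 10, 15, 25), seed = 2)
  obs <- generate_cohort(cfg)
  for (tt in c(7.5, 10)) {
    d <- obs[obs$temperature_c == tt, ]
    expect_equal(sum(d$count[d$stage != "E"]), 0)
  }
  # but development does proceed just above it
  d15 <- obs[obs$temperature_c == 15, ]
  expect_gt(sum(d15$count[d15$stage != "E"]), 0)
})

test_that("a noiseless cohort crosses stages exactly at the closed-form times", {
  cfg <- noiseless_config(samples_per_stage = 40,
                          temperatures = c(20, 25, 30))
  obs <- generate_cohort(cfg)
  cum_add <- cumsum(cfg$true_stage_add)
  for (tt in cfg$temperatures) {
    t_star <- 24 * cum_add[1] / (tt - cfg$true_dev_min)  # egg hatch
    d <- obs[obs$temperature_c == tt, ]
    hatched <- tapply(d$count[d$stage != "E"], d$time_h[d$stage != "E"], sum)
    times <- as.numeric(names(hatched))
    # all-or-nothing around t_star: none hatched before, all after
    expect_true(all(hatched[times < t_star - 1e-9] == 0))
    expect_true(all(hatched[times >= t_star] == cfg$eggs_per_cup))
  }
})

test_that("occupied stage is non-decreasing in time for a noiseless cohort", {
  cfg <- noiseless_config(samples_per_stage = 25, temperatures = c(17.5, 27.5))
  obs <- generate_cohort(cfg)
  stage_rank <- stats::setNames(seq_along(pr_stages()), pr_stages())
  for (tt in cfg$temperatures) {
    d <- obs[obs$temperature_c == tt & obs$count > 0 & obs$stage != "dead", ]
    occupied <- tapply(stage_rank[d$stage], d$time_h, max)
    expect_true(all(diff(occupied[order(as.numeric(names(occupied)))]) >= 0))
  }
})

test_that("median transition time scales as 1/(T - dev_min) without curvature", {
  cfg <- noiseless_config(samples_per_stage = 100)
  obs <- generate_cohort(cfg)
  ks <- c()
  for (tt in c(15, 20, 25, 30)) {
    est <- estimate_t50(boundary_entered_series(obs, tt, 6))
    ks <- c(ks, est$t50 * (tt - cfg$true_dev_min))
  }
  # thermal constant: t50 * (T - dev_min) identical across temperatures
  # within the sampling resolution
  expect_lt(diff(range(ks)) / mean(ks), 0.01)
})

test_that("mortality moves individuals to the dead class, never resurrects them", {
  cfg <- quick_config(seed = 9, mortality_per_stage = 0.1)
  obs <- generate_cohort(cfg)
  dead <- obs[obs$stage == "dead", ]
  expect_gt(sum(dead$count), 0)
  live <- obs[obs$stage != "dead", ]
  expect_true(all(tapply(live$count, interaction(live$temperature_c,
    live$time_h, live$replicate, drop = TRUE), sum) <= cfg$eggs_per_cup))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(transition_cv = 1.2))
  expect_error(sim_config(temperatures = c(20, 15)))
  expect_error(sim_config(true_stage_add = c(E = -1, L1 = 1, L2 = 1,
                                             L3f = 1, L3m = 1, P = 1)))
  expect_error(generate_cohort(sim_config(temperatures = c(15, 20)),
    schedule = data.frame(temperature_c = 25, boundary = "E-L1",
                          sample = 1, time_h = 5)),
    "absent")
})
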