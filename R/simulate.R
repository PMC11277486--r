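#' Configuration for the synthetic cohort generator
#'
#' Describes a constant-temperature destructive-sampling development study:
#' cups of eggs held at each temperature, pulled (destructively) at scheduled
#' times, every individual staged morphologically. Defaults reproduce the
#' design under which the reference *P. regina* data were collected: eleven
#' temperatures from 7.5 to 32.5 degC in 2.5 degC steps, 20 eggs per cup,
#' five sampling times per stage boundary, each replicated in four
#' incubators.
#'
#' Individual variation is placed on physiological-time thresholds: each
#' individual draws its per-stage accumulated-degree-day (ADD) requirement
#' from a normal distribution (mean `true_stage_add`, sd `transition_cv *`
#' mean, truncated above 0). This makes transition *times* normal at every
#' temperature with a spread proportional to stage duration, the structure
#' observed in real cohorts. At temperature T the realized development rate
#' is `(T - true_dev_min) * g(T)` degree-days per day. Inside `linear_range`
#' the attenuation g is 1; below it, g ramps to zero at the biological
#' minimum as `((T - biological_min)/(linear_range[1] - biological_min))`
#' raised to `curvature_strength`, so development collapses — not merely
#' slows — as T approaches the temperature where it truly ceases; above the
#' range the mirrored ramp `(1 - (T - linear_range[2])/w)^curvature_strength`
#' (w = the low-side width, standing in for the distance to the thermal
#' maximum) bends the hot end downward. `curvature_strength = 0` gives a
#' fully linear response; no development at all occurs below
#' `biological_min`.
#'
#' @param temperatures treatment temperatures, degC, strictly increasing.
#' @param true_dev_min x-intercept of the linear rate response, degC.
#' @param true_stage_add named ADD requirement (degree-days) per stage
#'   E, L1, L2, L3f, L3m, P.
#' @param transition_cv coefficient of variation of individual thresholds
#'   (0 <= cv < 1); 0 gives a deterministic cohort.
#' @param biological_min temperature below which development ceases, degC.
#' @param linear_range `(low, high)` degC bounds of the linear rate response.
#' @param curvature_strength exponent of the attenuation ramps outside
#'   `linear_range` (0 = none; 1 = linear collapse to the biological
#'   minimum).
#' @param eggs_per_cup,replicates,samples_per_stage design counts.
#' @param mortality_per_stage per-stage, per-individual death probability.
#' @param seed integer RNG seed; cohorts are bit-reproducible given the seed.
#' @param assumed_dev_min developmental minimum assumed when building the
#'   sampling schedule (the experimenter's prior, degC).
#' @param reference_temp temperature of the prior duration data, degC.
#' @param window_margin multiplicative `(lower, upper)` margins applied to
#'   prior transition times to form each boundary's sampling window,
#'   emulating schedules built from published minimum/maximum durations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(temperatures = seq(7.5, 32.5, by = 2.5),
                       true_dev_min = 10.2,
                       true_stage_add = c(E = 8.4, L1 = 12.1, L2 = 14.4,
                                          L3f = 29.3, L3m = 30.2, P = 84.9),
                       transition_cv = 0.05,
                       biological_min = 11,
                       linear_range = c(15, 32.5),
                       curvature_strength = 1,
                       eggs_per_cup = 20L,
                       replicates = 4L,
                       samples_per_stage = 5L,
                       mortality_per_stage = 0,
                       seed = 1L,
                       assumed_dev_min = 10,
                       reference_temp = 26.7,
                       window_margin = c(0.85, 1.30)) {
  stopifnot(
    length(temperatures) >= 1, !is.unsorted(temperatures, strictly = TRUE),
    all(true_stage_add > 0), length(true_stage_add) == 6,
    transition_cv >= 0, transition_cv < 1,
    length(linear_range) == 2, linear_range[1] < linear_range[2],
    eggs_per_cup >= 1, replicates >= 1, samples_per_stage >= 1,
    mortality_per_stage >= 0, mortality_per_stage < 1,
    curvature_strength >= 0,
    window_margin[1] > 0, window_margin[1] <= 1, window_margin[2] >= 1
  )
  names(true_stage_add) <- pr_stage_events()
  structure(list(
    temperatures = temperatures, true_dev_min = true_dev_min,
    true_stage_add = true_stage_add, transition_cv = transition_cv,
    biological_min = biological_min, linear_range = linear_range,
    curvature_strength = curvature_strength,
    eggs_per_cup = as.integer(eggs_per_cup),
    replicates = as.integer(replicates),
    samples_per_stage = as.integer(samples_per_stage),
    mortality_per_stage = mortality_per_stage, seed = as.integer(seed),
    assumed_dev_min = assumed_dev_min, reference_temp = reference_temp,
    window_margin = window_margin
  ), class = "sim_config")
}

#' Realized development rate of the generator, degree-days per day
#'
#' Linear `(T - true_dev_min)` within `linear_range`, multiplied outside it
#' by the curvature attenuation described in [sim_config()], and zero below
#' `biological_min` (or below `true_dev_min`).
#'
#' @param temperature degC (vectorized).
#' @param config a [sim_config()].
#' @return degree-days accumulated per day at each temperature.
#' @export
effective_rate <- function(temperature, config) {
  lo <- config$linear_range[1]; hi <- config$linear_range[2]
  w <- lo - config$biological_min
  g <- rep(1, length(temperature))
  below <- temperature < lo
  g[below] <- pmax(0, (temperature[below] - config$biological_min) / w) ^
    config$curvature_strength
  above <- temperature > hi
  g[above] <- pmax(0, 1 - (temperature[above] - hi) / w) ^
    config$curvature_strength
  r <- pmax(0, temperature - config$true_dev_min) * g
  r[temperature < config$biological_min] <- 0
  r
}

#' Build the destructive sampling schedule
#'
#' Prior transition times at a reference temperature are converted to
#' accumulated degree-hours (ADH) above an assumed developmental minimum,
#' rescaled to each treatment temperature, and each boundary's window is
#' divided into `samples_per_boundary` equally spaced sampling times:
#' `ADH = duration_ref * (reference_temp - assumed_dev_min)`, scheduled hours
#' at temperature T are `ADH / (T - assumed_dev_min)`. Temperatures at or
#' below the assumed minimum reuse the schedule of the lowest temperature
#' above it (there is no defensible way to scale thermal time below the
#' assumed zero, and development there is expected to stall anyway).
#'
#' @param reference_durations either a named numeric vector of cumulative
#'   times (hours at `reference_temp`) to the end of each boundary's
#'   transition — the window then starts at 0 — or a data.frame with columns
#'   `boundary`, `t_min`, `t_max` giving each window's bounds in hours at the
#'   reference temperature.
#' @param reference_temp degC; must exceed `assumed_dev_min`.
#' @param assumed_dev_min degC.
#' @param temperatures treatment temperatures, degC.
#' @param samples_per_boundary sampling times per boundary window (default 5).
#' @return data.frame `temperature_c`, `boundary`, `sample` (1..S), `time_h`.
#' @examples
#' # a 10 h window divided into 5 sample times -> 2, 4, 6, 8, 10 h
#' s <- build_sampling_schedule(c("E-L1" = 10), reference_temp = 25,
#'                              assumed_dev_min = 10, temperatures = 25)
#' s$time_h
#' @export
build_sampling_schedule <- function(reference_durations, reference_temp,
                                    assumed_dev_min, temperatures,
                                    samples_per_boundary = 5L) {
  if (length(reference_durations) == 0) stop("no reference durations given")
  if (reference_temp <= assumed_dev_min) {
    stop("reference_temp must exceed assumed_dev_min")
  }
  if (is.data.frame(reference_durations)) {
    win <- reference_durations
    stopifnot(all(c("boundary", "t_min", "t_max") %in% names(win)))
  } else {
    win <- data.frame(boundary = names(reference_durations),
                      t_min = 0, t_max = as.numeric(reference_durations))
  }
  if (any(win$t_max <= win$t_min) || any(win$t_max <= 0)) {
    stop("non-positive sampling window: t_max must exceed t_min and 0")
  }
  ref_k <- reference_temp - assumed_dev_min
  above <- temperatures[temperatures > assumed_dev_min]
  if (length(above) == 0) {
    stop("no treatment temperature lies above the assumed developmental ",
         "minimum (", assumed_dev_min, " degC); cannot scale the schedule")
  }
  lowest_above <- min(above)
  out <- do.call(rbind, lapply(temperatures, function(tt) {
    t_eff <- if (tt > assumed_dev_min) tt else lowest_above
    scale <- ref_k / (t_eff - assumed_dev_min)
    do.call(rbind, lapply(seq_len(nrow(win)), function(i) {
      lo <- win$t_min[i] * scale
      hi <- win$t_max[i] * scale
      data.frame(temperature_c = tt, boundary = win$boundary[i],
                 sample = seq_len(samples_per_boundary),
                 time_h = lo + seq_len(samples_per_boundary) *
                   (hi - lo) / samples_per_boundary)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Default schedule windows for a config: prior transition times taken as the
# generator's own expected cumulative times at the reference temperature,
# widened by the window margins (the min/max-style window an experimenter
# would build from published duration ranges).
default_schedule <- function(config) {
  cum_add <- cumsum(config$true_stage_add)
  t_ref <- 24 * cum_add / (config$reference_temp - config$true_dev_min)
  win <- data.frame(boundary = pr_boundaries(),
                    t_min = config$window_margin[1] * t_ref,
                    t_max = config$window_margin[2] * t_ref)
  build_sampling_schedule(win, config$reference_temp, config$assumed_dev_min,
                          config$temperatures, config$samples_per_stage)
}

# Draw n x 6 per-stage ADD thresholds, truncated normal above 0.
draw_thresholds <- function(n, config) {
  mu <- config$true_stage_add
  cv <- config$transition_cv
  if (cv == 0) {
    matrix(mu, nrow = n, ncol = 6, byrow = TRUE)
  } else {
    sapply(mu, function(m) {
      sd <- cv * m
      p0 <- stats::pnorm(0, m, sd)
      stats::qnorm(stats::runif(n, p0, 1), m, sd)
    })
  }
}

#' Generate a synthetic development cohort
#'
#' Simulates the full destructive-sampling experiment described by a
#' [sim_config()]: at every scheduled (temperature, time) one unsampled cup
#' per replicate is pulled and its `eggs_per_cup` individuals are classified
#' into stages by comparing elapsed physiological time
#' (`time/24 * effective_rate(T)`) against each individual's cumulative ADD
#' thresholds. Individuals are classified in the earlier stage until the
#' threshold is crossed, matching the morphological convention that pharate
#' larvae count as the stage they have not yet molted out of. Optional
#' mortality is an independent per-stage Bernoulli per individual; dead
#' individuals are counted in the `dead` class from the stage in which they
#' died.
#'
#' @param config a [sim_config()].
#' @param schedule optional schedule data.frame (as returned by
#'   [build_sampling_schedule()]); defaults to the config's own design.
#' @return an observation table: long data.frame with columns
#'   `temperature_c`, `time_h`, `replicate`, `stage`
#'   (E, L1, L2, L3f, L3m, P, A or `dead`) and `count`; one cup per
#'   (temperature, time, replicate), counts summing to `eggs_per_cup`.
#' @export
generate_cohort <- function(config, schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(schedule)) schedule <- default_schedule(config)
  if (!all(schedule$temperature_c %in% config$temperatures)) {
    stop("schedule references a temperature absent from the configuration")
  }

  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  classes <- c(pr_stages(), "dead")
  n <- config$eggs_per_cup
  R <- config$replicates
  U <- upper.tri(matrix(0, 6, 6), diag = TRUE) * 1  # cumsum across stages
  rows <- vector("list", 0L)
  for (tt in sort(unique(schedule$temperature_c))) {
    times <- sort(unique(schedule$time_h[schedule$temperature_c == tt]))
    nt <- length(times)
    rate <- effective_rate(tt, config)
    N <- nt * R * n                     # individuals across all cups
    cum <- draw_thresholds(N, config) %*% U
    elapsed <- rep(times, each = R * n) / 24 * rate
    stage_idx <- rowSums(cum <= elapsed) + 1L  # 1=E ... 7=A
    if (config$mortality_per_stage > 0) {
      dies <- matrix(stats::runif(N * 6) < config$mortality_per_stage,
                     nrow = N)
      any_death <- rowSums(dies) > 0
      death_stage <- ifelse(any_death, max.col(dies, ties.method = "first"),
                            Inf)
      dead <- stage_idx >= death_stage
    } else {
      dead <- rep(FALSE, N)
    }
    class_idx <- ifelse(dead, 8L, stage_idx)
    cup_time <- rep(seq_len(nt), each = R * n)
    cup_rep <- rep(rep(seq_len(R), each = n), times = nt)
    cell <- ((cup_time - 1L) * R + (cup_rep - 1L)) * 8L + class_idx
    counts <- tabulate(cell, nbins = nt * R * 8L)
    rows[[length(rows) + 1L]] <- data.frame(
      temperature_c = tt,
      time_h = rep(times, each = R * 8L),
      replicate = rep(rep(seq_len(R), each = 8L), times = nt),
      stage = rep(classes, times = nt * R),
      count = counts
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
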