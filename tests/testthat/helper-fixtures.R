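# Small simulation configs and light analysis helpers shared across tests.

# fast mid-range design: 5 temperatures, defaults otherwise
quick_config <- function(seed = 1, ...) {
  sim_config(temperatures = seq(15, 32.5, by = 2.5), seed = seed, ...)
}

# noiseless, curvature-free, densely sampled cohort for closed-form checks
noiseless_config <- function(seed = 1, samples_per_stage = 200, ...) {
  sim_config(transition_cv = 0, curvature_strength = 0, replicates = 1,
             samples_per_stage = samples_per_stage, seed = seed, ...)
}

# E-A (oviposition to adult) degree-day analysis without the full report:
# t50 of the P-A boundary per temperature -> rates -> validated model
ea_rate_points <- function(obs) {
  temps <- sort(unique(obs$temperature_c))
  rows <- lapply(temps, function(tt) {
    est <- tryCatch(estimate_t50(boundary_entered_series(obs, tt, 6)),
                    error = function(e) NULL)
    if (is.null(est)) NULL
    else data.frame(temperature_c = tt, rate = 24 / est$t50)
  })
  do.call(rbind, rows)
}

ea_model <- function(obs, alpha = 0.05) {
  fit_degree_day_model(ea_rate_points(obs), alpha = alpha, event = "E-A")
}

# independent brute-force two-sided runs-test p-value: enumerate every
# arrangement of the signs and tally the run-count distribution
brute_force_runs_p <- function(signs) {
  n <- length(signs)
  n_pos <- sum(signs > 0)
  pos_sets <- utils::combn(n, n_pos, simplify = FALSE)
  runs_of <- function(idx) {
    v <- rep(-1, n); v[idx] <- 1
    length(rle(v)$lengths)
  }
  all_runs <- vapply(pos_sets, runs_of, 0L)
  r_obs <- length(rle(sign(signs))$lengths)
  p_low <- mean(all_runs <= r_obs)
  p_high <- mean(all_runs >= r_obs)
  min(1, 2 * min(p_low, p_high))
}
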