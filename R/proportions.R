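#' Proportion-in-stage series from an observation table
#'
#' Converts long stage counts into the proportion (or percent) of live
#' sampled individuals occupying each stage at each sampling time. Replicate
#' cups at a sampling time are exchangeable units from identical incubators,
#' so they are pooled before the proportion is formed (per-cup proportions
#' averaged across replicates are available as an alternative). Dead
#' individuals are excluded from denominators.
#'
#' @param obs observation table (see [generate_cohort()] /
#'   [read_observations()]).
#' @param unit `"proportion"` (0-1) or `"percent"` (0-100).
#' @param pooled pool replicate counts before forming proportions (default)
#'   or average per-cup proportions.
#' @return data.frame `temperature_c`, `stage`, `time_h`, `y`, `n_live` with
#'   attribute `unit`.
#' @export
stage_proportions <- function(obs, unit = c("proportion", "percent"),
                              pooled = TRUE) {
  unit <- match.arg(unit)
  validate_observations(obs)
  live <- obs[obs$stage != "dead", ]
  out <- do.call(rbind, lapply(split(live, live[c("temperature_c", "time_h")],
                                     drop = TRUE), function(d) {
    if (pooled) {
      tot <- sum(d$count)
      agg <- stats::aggregate(count ~ stage, d, sum)
      p <- if (tot > 0) agg$count / tot else rep(NA_real_, nrow(agg))
      data.frame(temperature_c = d$temperature_c[1], stage = agg$stage,
                 time_h = d$time_h[1], y = p, n_live = tot)
    } else {
      per <- lapply(split(d, d$replicate), function(cup) {
        tot <- sum(cup$count)
        data.frame(stage = cup$stage,
                   p = if (tot > 0) cup$count / tot else NA_real_)
      })
      all <- do.call(rbind, per)
      agg <- stats::aggregate(p ~ stage, all, mean, na.rm = TRUE)
      data.frame(temperature_c = d$temperature_c[1], stage = agg$stage,
                 time_h = d$time_h[1], y = agg$p, n_live = sum(d$count))
    }
  }))
  out <- out[!is.na(out$y), ]
  if (unit == "percent") out$y <- 100 * out$y
  out <- out[order(out$temperature_c, out$stage, out$time_h), ]
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  out
}

#' Cumulative "entered stage" series for one boundary
#'
#' For the boundary into stage `s`, the entered proportion at a sampling time
#' is the fraction of live individuals at or past `s` — transitions are
#' monotone, so an L3 individual has necessarily entered L1 and L2. Every
#' sampling time at the temperature contributes, not just the times scheduled
#' for that boundary.
#'
#' @param obs observation table.
#' @param temperature one treatment temperature present in `obs`.
#' @param boundary one of [pr_boundaries()] (or its index 1-6).
#' @return data.frame `time_h`, `n_entered`, `n_live`, `p` (proportion),
#'   ordered by time.
#' @export
boundary_entered_series <- function(obs, temperature, boundary) {
  validate_observations(obs)
  if (is.character(boundary)) boundary <- match(boundary, pr_boundaries())
  stopifnot(!is.na(boundary), boundary >= 1, boundary <= 6)
  target <- pr_stages()[(boundary + 1L):7L]
  d <- obs[obs$temperature_c == temperature & obs$stage != "dead", ]
  if (nrow(d) == 0) stop("no observations at ", temperature, " degC")
  sp <- split(d, d$time_h)
  out <- data.frame(
    time_h = as.numeric(names(sp)),
    n_entered = vapply(sp, function(x) sum(x$count[x$stage %in% target]), 0),
    n_live = vapply(sp, function(x) sum(x$count), 0)
  )
  out <- out[out$n_live > 0, ]
  out$p <- out$n_entered / out$n_live
  out <- out[order(out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Flag extended-duration outliers
#'
#' Individuals occasionally persist in an early stage for far longer than
#' the cohort; such observations distort curve tails. A sampling time is
#' flagged for a boundary when it exceeds the fitted transition center `b`
#' by more than `m * c` while some individuals still remain in the earlier
#' stage. Flagged rows are reported; exclusion is an explicit opt-in in
#' downstream calls.
#'
#' @param series output of [boundary_entered_series()].
#' @param fit a `stage_curve_fit` (or any list with `b` and `c`) for that
#'   boundary.
#' @param m multiplier on the spread `c` (default 4).
#' @return logical vector flagging rows of `series`.
#' @export
flag_outliers <- function(series, fit, m = 4) {
  series$time_h > fit$b + m * fit$c & series$p < 1
}
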