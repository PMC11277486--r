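#' 50% transition time by probit regression
#'
#' Fits a maximum-likelihood probit model to the binary outcome "already in
#' the later stage" versus time. The fitted median `t50 = -intercept/slope`
#' estimates the time at which half the cohort has crossed the boundary; the
#' standard error follows by the delta method; `1/slope` estimates the
#' standard deviation of the underlying normal transition-time distribution.
#' Any other transition percentile is available through `quantile_fn`.
#'
#' @param counts data.frame with columns `time_h`, `n_entered` (individuals
#'   at or past the later stage) and `n_live` (live individuals sampled).
#' @return a `transition_estimate`: list with `t50`, `se_t50`, `sd` (fitted
#'   transition-time SD), `method = "probit"`, `n_times`, `quantile_fn`
#'   (function of p), and the underlying `fit`.
#' @examples
#' d <- data.frame(time_h = c(10, 20, 30), n_entered = c(0, 10, 20),
#'                 n_live = 20)
#' probit_t50(d)$t50  # 20 by symmetry
#' @export
probit_t50 <- function(counts) {
  stopifnot(all(c("time_h", "n_entered", "n_live") %in% names(counts)))
  counts <- counts[counts$n_live > 0, ]
  partial <- counts$n_entered > 0 & counts$n_entered < counts$n_live
  spans <- any(counts$n_entered == 0) &&
    any(counts$n_entered == counts$n_live)
  if (!any(partial) && !spans) {
    stop("no transition observed: counts never leave 0% or never reach ",
         "100%, and no partial time point informs the crossing")
  }
  fit <- suppressWarnings(stats::glm(
    cbind(n_entered, n_live - n_entered) ~ time_h,
    family = stats::binomial(link = "probit"), data = counts
  ))
  cf <- stats::coef(fit)
  if (!is.finite(cf["time_h"]) || cf["time_h"] <= 0) {
    stop("probit slope is not positive; the entered proportion does not ",
         "increase with time")
  }
  b0 <- cf[[1]]; b1 <- cf[[2]]
  t50 <- -b0 / b1
  V <- stats::vcov(fit)
  grad <- c(-1 / b1, b0 / b1^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  structure(list(
    t50 = t50, se_t50 = se, sd = 1 / b1, method = "probit",
    n_times = nrow(counts),
    quantile_fn = function(p) (stats::qnorm(p) - b0) / b1,
    fit = fit
  ), class = "transition_estimate")
}

#' 50% transition time from a cumulative-Gaussian fit
#'
#' The cumulative (or reversed cumulative) Gaussian crosses `a/2` exactly at
#' `x = b`, so the fitted center is the 50% transition time; its standard
#' error is read from the fit's parameter covariance.
#'
#' @param fit a converged `stage_curve_fit` with a cumulative model.
#' @return a `transition_estimate` with `method = "cumulative_gaussian"`.
#' @export
t50_from_cumulative <- function(fit) {
  stopifnot(inherits(fit, "stage_curve_fit"))
  if (!fit$model %in% c("cumulative_gaussian",
                        "reversed_cumulative_gaussian")) {
    stop("t50 is the center parameter of a cumulative form; got model '",
         fit$model, "'")
  }
  if (!isTRUE(fit$converged)) {
    stop("refusing to extract t50 from a non-converged fit")
  }
  se <- if (!is.null(fit$vcov) && "b" %in% rownames(fit$vcov)) {
    sqrt(fit$vcov["b", "b"])
  } else NA_real_
  structure(list(
    t50 = fit$b, se_t50 = se, sd = fit$c, method = "cumulative_gaussian",
    n_times = fit$n, quantile_fn = function(p) fit$b + fit$c * stats::qnorm(p),
    fit = fit
  ), class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("<transition_estimate> t50 = %.3f h (se %.3f), %s, %d times\n",
              x$t50, x$se_t50, x$method, x$n_times))
  invisible(x)
}

#' Estimate a boundary's 50% transition time from an entered-proportion series
#'
#' The degree-day pipeline's default route: truncate the series to the first
#' portion of the rise (leading zeros through the first time the cohort is
#' fully transitioned), then fit a cumulative Gaussian with the plateau fixed
#' at 100% — every live individual eventually transitions — and take
#' `t50 = b`. The median must be bracketed by the data (observed proportions
#' must cross 50%); otherwise the estimate would be an extrapolation and the
#' function refuses, which is how temperatures whose transition fell outside
#' the sampling windows drop out of downstream regressions. A series with no
#' partial time point (a pure step, as in a noiseless cohort) yields the
#' midpoint of the bracketing times with `se = gap/sqrt(12)`.
#'
#' @param series output of [boundary_entered_series()].
#' @param route `"cumulative"` (default) or `"probit"`.
#' @param require_bracket refuse when observed proportions never reach 50%
#'   (default TRUE).
#' @return a `transition_estimate`.
#' @export
estimate_t50 <- function(series, route = c("cumulative", "probit"),
                         require_bracket = TRUE) {
  route <- match.arg(route)
  stopifnot(all(c("time_h", "p", "n_entered", "n_live") %in% names(series)))
  series <- series[order(series$time_h), ]
  if (require_bracket && max(series$p) < 0.5) {
    stop("observed proportions never reach 50% (max ",
         sprintf("%.1f%%", 100 * max(series$p)),
         "); the median transition is not bracketed by the sampling times")
  }
  # first portion of the curve: drop everything after the rise is complete
  done <- which(series$p >= 1 - 1e-9)
  if (length(done)) series <- series[seq_len(min(done)), ]

  if (route == "probit") return(probit_t50(series))

  partial <- series$p > 1e-9 & series$p < 1 - 1e-9
  if (sum(partial) == 0) {
    # pure step: the crossing lies between the last 0% and first 100% time
    lo <- max(series$time_h[series$p <= 1e-9])
    hi <- min(series$time_h[series$p >= 1 - 1e-9])
    if (!is.finite(lo) || !is.finite(hi)) {
      stop("degenerate series: no information about the transition crossing")
    }
    return(structure(list(
      t50 = (lo + hi) / 2, se_t50 = (hi - lo) / sqrt(12),
      sd = 0, method = "cumulative_gaussian", n_times = nrow(series),
      degenerate = TRUE,
      quantile_fn = function(p) (lo + hi) / 2, fit = NULL
    ), class = "transition_estimate"))
  }
  # least squares needs two partial points to identify (b, c); with one, or
  # when LS wanders off the data (the wide-sigmoid local minimum), the probit
  # ML fit of the same normal CDF is used — it draws information from the
  # binomial 0/n and n/n observations that LS treats as exact
  if (sum(partial) >= 2) {
    fit <- tryCatch(
      fit_stage_curve(series$time_h, series$p, "cumulative_gaussian",
                      fix_a = 1),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$converged &&
        fit$b >= min(series$time_h) && fit$b <= max(series$time_h) &&
        fit$c <= diff(range(series$time_h)) / 2) {
      return(t50_from_cumulative(fit))
    }
  }
  probit_t50(series)
}

#' Stage durations by subtraction of 50% transition points
#'
#' Duration in a stage is the time between the 50% transition into it and
#' the 50% transition out of it; the egg stage runs from oviposition, so its
#' duration equals the first boundary's t50 (and its ADD requirement equals
#' the E-L1 transition ADD by construction). Missing boundaries give missing
#' durations — never interpolated.
#'
#' @param transitions named list (or list) of `transition_estimate`s for the
#'   six boundaries in order E-L1, L1-L2, L2-L3f, L3f-L3m, L3m-P, P-A;
#'   use `NULL` (or omit names) for boundaries that could not be estimated.
#' @return data.frame `stage`, `t50_entry_h`, `t50_exit_h`, `duration_h`,
#'   `duration_days`.
#' @export
stage_durations <- function(transitions) {
  bnames <- pr_boundaries()
  if (!is.null(names(transitions))) {
    transitions <- transitions[bnames]
  } else if (length(transitions) != 6) {
    stop("provide six boundary estimates (NULL where missing) or a named list")
  }
  t50 <- vapply(transitions, function(tr) {
    if (is.null(tr) || (is.list(tr) && is.null(tr$t50))) NA_real_ else tr$t50
  }, 0)
  if (sum(!is.na(t50)) < 2) stop("need at least two boundary estimates")
  fin <- which(!is.na(t50))
  if (any(diff(t50[fin]) <= 0)) {
    bad <- fin[which(diff(t50[fin]) <= 0)[1] + 1L]
    stop("non-monotone transition sequence: t50(", bnames[bad],
         ") does not exceed the preceding boundary's t50 — ",
         "upstream fitting failure")
  }
  entry <- c(0, t50[-6])  # egg stage starts at oviposition
  dur <- t50 - entry
  data.frame(stage = pr_stage_events(), t50_entry_h = entry,
             t50_exit_h = t50, duration_h = dur, duration_days = dur / 24)
}
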