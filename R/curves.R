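#' Gaussian-family stage-transition curves
#'
#' Proportion-in-stage time series at a constant temperature are described by
#' one of four curves in `x` (hours since oviposition):
#'
#' * `gaussian`: `y = a * exp(-1/2 * ((x - b) / c)^2)` — a stage entered and
#'   left quickly, so the occupancy profile is a bell.
#' * `modified_gaussian`: `y = a * exp(-1/2 * abs((x - b) / c)^d)` — a bell
#'   with a flat top; `d > 2` produces the plateau seen for long stages in
#'   which the whole cohort sits between transitions.
#' * `cumulative_gaussian`: `y = a/2 * (1 + erf((x - b) / (sqrt(2) * c)))` —
#'   sigmoidal rise to a plateau (entry into a terminal class, e.g. adults).
#' * `reversed_cumulative_gaussian`: `y = a/2 * (1 - erf((x - b)/(sqrt(2)*c)))`
#'   — sigmoidal fall from a plateau (exit from the egg stage).
#'
#' `a` is the amplitude/plateau in the units of `y` (proportion or percent),
#' `b` the curve center in hours (the 50% crossing for the cumulative forms),
#' `c` the spread in hours, and `d` the dimensionless shape exponent of the
#' modified form (`d = 2` recovers the plain Gaussian).
#'
#' @param params a `stage_curve_fit` or a list with elements `model`, `a`,
#'   `b`, `c` and (for the modified form) `d`.
#' @param x numeric vector of times (hours).
#' @return fitted curve values at `x`.
#' @export
evaluate_curve <- function(params, x) {
  model <- match.arg(params$model, curve_models())
  a <- params$a; b <- params$b; cc <- params$c
  switch(model,
    gaussian = a * exp(-0.5 * ((x - b) / cc)^2),
    modified_gaussian = a * exp(-0.5 * abs((x - b) / cc)^params$d),
    cumulative_gaussian = a / 2 * (1 + erf((x - b) / (sqrt(2) * cc))),
    reversed_cumulative_gaussian = a / 2 * (1 - erf((x - b) / (sqrt(2) * cc)))
  )
}

#' @rdname evaluate_curve
#' @export
curve_models <- function() {
  c("gaussian", "modified_gaussian", "cumulative_gaussian",
    "reversed_cumulative_gaussian")
}

curve_is_peaked <- function(model) {
  model %in% c("gaussian", "modified_gaussian")
}

# Moment-based starting values; a <- max(y); b at the peak (peaked forms) or
# the half-range crossing (cumulative forms); c from the half-width at
# half-maximum; d <- 2.
curve_start <- function(x, y, model) {
  a0 <- max(y)
  if (curve_is_peaked(model)) {
    b0 <- x[which.max(y)]
    half <- a0 / 2
    above <- x[y >= half]
    c0 <- (max(above) - min(above)) / 2 / sqrt(2 * log(2))
  } else {
    rising <- model == "cumulative_gaussian"
    yy <- if (rising) y else a0 - y
    half <- a0 / 2
    hi_i <- which(yy >= half)[1]
    if (is.na(hi_i)) {
      b0 <- stats::median(x); c0 <- NA_real_
    } else if (hi_i == 1L) {
      b0 <- x[1]; c0 <- NA_real_
    } else {
      lo_i <- hi_i - 1L
      # interpolate the 50% crossing; half the bracket gap is a serviceable
      # spread start for a sharp sigmoid sampled on this grid
      b0 <- x[lo_i] + (x[hi_i] - x[lo_i]) *
        (half - yy[lo_i]) / (yy[hi_i] - yy[lo_i])
      c0 <- (x[hi_i] - x[lo_i]) / 2
    }
  }
  if (!is.finite(c0) || c0 <= 0) c0 <- diff(range(x)) / 6
  list(a = a0, b = b0, c = c0, d = 2)
}

#' Fit one Gaussian-family curve to a stage-proportion series
#'
#' Bounded Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]) with
#' moment-based starting values. Bounds keep the fit in the scientifically
#' meaningful region: `a` in (0, 1.05 * scale] where scale is the unit
#' ceiling (1 for proportions, 100 for percentages), `c` in (0, range(x)],
#' `d` in (0.5, 10] — the last prevents plateau-exponent blow-up.
#'
#' @param x sampling times in hours (strictly increasing after aggregation).
#' @param y proportion (0-1) or percent (0-100) in stage at `x`; the scale is
#'   recorded but fits are scale-equivariant in `a`.
#' @param model one of [curve_models()].
#' @param fix_a optional value at which to pin the amplitude/plateau (e.g. 1
#'   or 100 for cumulative forms when every survivor eventually transitions).
#' @param start optional named list overriding the moment-based start.
#' @return an object of class `stage_curve_fit`: list with `model`, `a`, `b`,
#'   `c`, `d` (NA unless modified form), `rss`, `converged`, `n`, `vcov`
#'   (parameter covariance) and the underlying `fit`.
#' @examples
#' x <- seq(0, 96, by = 4)
#' y <- evaluate_curve(list(model = "gaussian", a = 100, b = 48, c = 6), x)
#' fit_stage_curve(x, y, "gaussian")
#' @export
fit_stage_curve <- function(x, y, model = curve_models(), fix_a = NULL,
                            start = NULL) {
  model <- match.arg(model)
  stopifnot(length(x) == length(y), !is.unsorted(x, strictly = TRUE))
  needed <- if (model == "modified_gaussian") 5L else 4L
  if (!is.null(fix_a)) needed <- needed - 1L
  if (length(x) < needed) {
    stop("need at least ", needed, " points to fit a ", model, " curve")
  }
  if (diff(range(y)) == 0) {
    stop("degenerate series: y is constant (", y[1],
         ") for every time point; no ", model, " curve can be fitted")
  }

  s0 <- curve_start(x, y, model)
  if (!is.null(start)) s0[names(start)] <- start
  # amplitude bound uses the unit ceiling (1 for proportions, 100 for
  # percentages), not the observed maximum: a series may never sample its
  # plateau
  ymax <- if (!is.null(fix_a)) fix_a
    else if (max(y) <= 1) 1
    else if (max(y) <= 100) 100
    else max(y)
  pars <- c("a", "b", "c", if (model == "modified_gaussian") "d")
  if (!is.null(fix_a)) pars <- setdiff(pars, "a")
  lower <- c(a = 1e-8, b = -Inf, c = 1e-8, d = 0.5)[pars]
  upper <- c(a = 1.05 * ymax, b = Inf, c = diff(range(x)), d = 10)[pars]
  s0$c <- min(max(s0$c, 2 * lower[["c"]]), upper[["c"]])
  if (is.null(fix_a)) s0$a <- min(s0$a, upper[["a"]])

  form <- switch(model,
    gaussian = y ~ a * exp(-0.5 * ((x - b) / c)^2),
    modified_gaussian = y ~ a * exp(-0.5 * abs((x - b) / c)^d),
    cumulative_gaussian = y ~ a / 2 * (1 + erf((x - b) / (sqrt(2) * c))),
    reversed_cumulative_gaussian =
      y ~ a / 2 * (1 - erf((x - b) / (sqrt(2) * c)))
  )
  dat <- data.frame(x = x, y = y)
  if (!is.null(fix_a)) dat$a <- fix_a

  # retry over a ladder of spread starts (the L-M gradient degenerates when
  # the starting spread is far from the sampling grid's resolution) and keep
  # the lowest-rss convergent fit
  fit <- NULL
  best_rss <- Inf
  last_err <- NULL
  for (fac in c(1, 0.5, 2, 0.25, 4, 8)) {
    s_try <- s0
    s_try$c <- min(max(s0$c * fac, 2 * lower[["c"]]), upper[["c"]])
    cand <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = s_try[pars],
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e
    )
    if (inherits(cand, "error")) {
      last_err <- cand
      next
    }
    rss <- sum(stats::resid(cand)^2)
    if (rss < best_rss) {
      fit <- cand
      best_rss <- rss
    }
    if (best_rss <= 1e-16 * max(1, sum(y^2))) break
  }
  if (is.null(fit)) {
    stop("curve fit failed for model ", model, ": ",
         conditionMessage(last_err))
  }
  cf <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv)
  out <- list(
    model = model,
    a = if (is.null(fix_a)) unname(cf["a"]) else fix_a,
    b = unname(cf["b"]),
    c = unname(cf["c"]),
    d = if (model == "modified_gaussian") unname(cf["d"]) else NA_real_,
    a_fixed = !is.null(fix_a),
    rss = sum(stats::resid(fit)^2),
    converged = converged,
    n = length(x),
    vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
    fit = fit
  )
  class(out) <- "stage_curve_fit"
  out
}

#' @export
print.stage_curve_fit <- function(x, ...) {
  cat(sprintf("<stage_curve_fit> %s: a=%.4g b=%.4g c=%.4g%s rss=%.4g%s\n",
              x$model, x$a, x$b, x$c,
              if (!is.na(x$d)) sprintf(" d=%.3g", x$d) else "",
              x$rss, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Choose between the plain and plateau-modified Gaussian for a larval stage
#'
#' Long stages hold the whole cohort between transitions, producing a plateau
#' at the maximum; short stages peak and fall. A plateau is declared when at
#' least `k` consecutive points lie within `tol` (relative) of the series
#' maximum, in which case the modified Gaussian is the appropriate occupancy
#' model.
#'
#' @param y proportions (any scale).
#' @param k minimum number of consecutive near-maximum points (default 3).
#' @param tol relative tolerance around the maximum (default 0.05).
#' @return `"modified_gaussian"` or `"gaussian"`.
#' @export
select_larval_model <- function(y, k = 3, tol = 0.05) {
  if (length(y) < k) {
    warning("fewer than k = ", k, " points; defaulting to plain gaussian")
    return("gaussian")
  }
  near <- y >= (1 - tol) * max(y)
  r <- rle(near)
  if (any(r$lengths[r$values] >= k)) "modified_gaussian" else "gaussian"
}
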