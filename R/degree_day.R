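#' Wald-Wolfowitz runs test on regression residuals
#'
#' Counts runs of residual signs ordered by temperature. Systematic curvature
#' left in a straight-line fit concentrates same-signed residuals at the ends
#' of the temperature range, producing too few runs. For `n_pos + n_neg <= 20`
#' the p-value is computed from the exact conditional distribution of the run
#' count given the sign counts; above that, the normal approximation with
#' continuity correction is used. Zero residuals are dropped before counting.
#'
#' @param residuals numeric residuals ordered by the regressor (temperature).
#' @return a `runs_test_result`: list `n_pos`, `n_neg`, `runs`, `p_value`
#'   (two-sided), `one_sided_low` (P(R <= observed), the curvature-sensitive
#'   tail) and `exact` flag. With all residuals of one sign, `runs = 1` and
#'   the result is flagged `uninformative` (no sign changes to test).
#' @examples
#' runs_test(c(1, 2, 1, -1, -2, -1))  # one sign change: runs = 2
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  if (length(s) < 2) stop("need at least 2 nonzero residuals")
  n_pos <- sum(s > 0); n_neg <- sum(s < 0)
  r <- length(rle(s)$lengths)
  n <- n_pos + n_neg

  if (n_pos == 0 || n_neg == 0) {
    return(structure(list(n_pos = n_pos, n_neg = n_neg, runs = 1L,
                          p_value = 1, one_sided_low = 1, exact = TRUE,
                          uninformative = TRUE),
                     class = "runs_test_result"))
  }

  if (n <= 20) {
    probs <- runs_distribution(n_pos, n_neg)
    lower <- sum(probs[seq_len(r - 1)])          # P(R < r)
    p_low <- lower + probs[r]                    # P(R <= r)
    p_high <- 1 - lower                          # P(R >= r)
    p <- min(1, 2 * min(p_low, p_high))
    exact <- TRUE
  } else {
    mu <- 1 + 2 * n_pos * n_neg / n
    v <- 2 * n_pos * n_neg * (2 * n_pos * n_neg - n) / (n^2 * (n - 1))
    z_low <- (r + 0.5 - mu) / sqrt(v)
    z_high <- (r - 0.5 - mu) / sqrt(v)
    p_low <- stats::pnorm(z_low)
    p_high <- stats::pnorm(z_high, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    exact <- FALSE
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, runs = as.integer(r),
                 p_value = p, one_sided_low = p_low, exact = exact,
                 uninformative = FALSE),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat(sprintf("<runs_test> R = %d (n+ = %d, n- = %d), two-sided p = %.4g%s\n",
              x$runs, x$n_pos, x$n_neg, x$p_value,
              if (isTRUE(x$uninformative)) " [uninformative]" else ""))
  invisible(x)
}

# Exact conditional distribution of the number of runs given sign counts:
# probs[r] = P(R = r), r = 1..n. P(R = 2k) = 2 C(n1-1,k-1) C(n2-1,k-1) / C(n,n1);
# P(R = 2k+1) = [C(n1-1,k) C(n2-1,k-1) + C(n1-1,k-1) C(n2-1,k)] / C(n,n1).
runs_distribution <- function(n1, n2) {
  n <- n1 + n2
  total <- choose(n, n1)
  probs <- numeric(n)
  for (r in 2:n) {
    if (r %% 2 == 0) {
      k <- r / 2
      probs[r] <- 2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / total
    } else {
      k <- (r - 1) / 2
      probs[r] <- (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
                     choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / total
    }
  }
  probs
}

new_rate_points <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temperature_c", "rate") %in% names(points)))
  if (any(points$rate <= 0)) stop("development rates must be positive")
  if (is.null(points$included)) points$included <- TRUE
  points[order(points$temperature_c), ]
}

#' Linear degree-day regression of development rate on temperature
#'
#' Ordinary least squares of rate (1/days to transition, or 1/days in stage)
#' on temperature for the currently included points. The fitted line's
#' x-intercept `-intercept/slope` is the developmental minimum and `1/slope`
#' the accumulated degree-days (ADD) required for the event.
#'
#' @param points data.frame with columns `temperature_c`, `rate` (1/days)
#'   and optionally `included` (logical).
#' @param event label for the modeled event (e.g. `"E-A"` or `"P"`).
#' @return a `degree_day_model`: list with `event`, `slope`, `intercept`,
#'   `dev_min`, `add`, `r2`, `n`, `range`, `points`, `fit`, `runs`
#'   (runs test on the rate residuals) and an empty exclusion `trace`.
#' @examples
#' pts <- data.frame(temperature_c = c(15, 20, 25, 30),
#'                   rate = 0.01 * (c(15, 20, 25, 30) - 10))
#' m <- rate_regression(pts)
#' c(m$dev_min, m$add, m$r2)  # 10, 100, 1
#' @export
rate_regression <- function(points, event = "") {
  points <- new_rate_points(points)
  inc <- points[points$included, ]
  if (nrow(inc) < 3) {
    stop("need at least 3 included rate points for a degree-day regression ",
         "(got ", nrow(inc), ")")
  }
  fit <- stats::lm(rate ~ temperature_c, data = inc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive rate-temperature slope for event '", event,
         "': no thermal response to model")
  }
  structure(list(
    event = event, slope = slope, intercept = intercept,
    dev_min = -intercept / slope, add = 1 / slope,
    # suppressed: "essentially perfect fit" on exact data is expected here
    r2 = suppressWarnings(summary(fit)$r.squared), n = nrow(inc),
    range = range(inc$temperature_c),
    points = points, fit = fit,
    runs = runs_test(stats::resid(fit)),
    trace = empty_trace(), validation = NULL, validated = FALSE
  ), class = "degree_day_model")
}

#' @export
print.degree_day_model <- function(x, ...) {
  cat(sprintf(
    "<degree_day_model> %s: dev_min = %.2f degC, ADD = %.1f, r2 = %.3f, n = %d, range %.1f-%.1f degC%s\n",
    if (nzchar(x$event)) x$event else "(unnamed)",
    x$dev_min, x$add, x$r2, x$n, x$range[1], x$range[2],
    if (isTRUE(x$validated)) " [validated]" else ""))
  if (nrow(x$trace)) {
    cat("  excluded:", paste(sprintf("%.1f degC (%s)", x$trace$temperature_c,
                                     x$trace$reason), collapse = ", "), "\n")
  }
  invisible(x)
}

empty_trace <- function() {
  data.frame(step = integer(), temperature_c = numeric(),
             reason = character(), p_value = numeric())
}

# Which endpoint (lowest or highest included temperature) to drop: the one
# with the larger |standardized residual|; ties go to the low end, where
# proximity to the biological minimum bends rates hardest.
pick_endpoint <- function(fit, temps) {
  rs <- abs(stats::rstandard(fit))
  lo <- which.min(temps); hi <- which.max(temps)
  if (rs[hi] > rs[lo]) temps[hi] else temps[lo]
}

#' Prune rate points until the regression shows no runs-test non-linearity
#'
#' Iteratively refits the rate-temperature regression, and while the runs
#' test rejects at `alpha`, removes one endpoint temperature per iteration —
#' the end whose point has the larger absolute standardized residual (the
#' non-linear region of a thermal response sits at the extremes). Stops when
#' the residual pattern is consistent with a straight line; fails, with the
#' full exclusion trace in the error, if linearity cannot be reached with at
#' least 3 points.
#'
#' @inheritParams rate_regression
#' @param alpha significance level for the runs test (default 0.05).
#' @return a `degree_day_model` whose `trace` logs each exclusion in order.
#' @export
prune_until_linear <- function(points, alpha = 0.05, event = "") {
  points <- new_rate_points(points)
  trace <- empty_trace()
  repeat {
    model <- rate_regression(points, event = event)
    model$trace <- trace
    if (model$runs$p_value >= alpha) return(model)
    if (model$n <= 3) {
      stop("cannot reach runs-test linearity for event '", event,
           "' with n >= 3; excluded so far: ",
           paste(sprintf("%.1f", trace$temperature_c), collapse = ", "))
    }
    inc <- points$included
    temps <- points$temperature_c[inc]
    drop_t <- pick_endpoint(model$fit, temps)
    points$included[points$temperature_c == drop_t] <- FALSE
    trace <- rbind(trace, data.frame(
      step = nrow(trace) + 1L, temperature_c = drop_t,
      reason = "rate_runs_test", p_value = model$runs$p_value))
  }
}

#' Validate a degree-day model by its degree-day accumulations
#'
#' A correct linear model implies that the degree-day accumulation
#' `ADD_i = duration_days_i * (T_i - dev_min)` observed at each included
#' temperature is constant: regressed on temperature it must be linear (runs
#' test) with zero slope (t-test). This check catches both residual
#' curvature and a misspecified developmental minimum (which tilts the
#' accumulations linearly in T).
#'
#' @param model a `degree_day_model`.
#' @param alpha significance level for both the slope t-test and runs test.
#' @return the model with `validation` (list: `add_values`, `fit`,
#'   `slope_p`, `runs`, `accepted`) and `validated` set.
#' @export
validate_add_accumulation <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "degree_day_model"))
  inc <- model$points[model$points$included, ]
  add_i <- (inc$temperature_c - model$dev_min) / inc$rate
  fit <- stats::lm(add_i ~ inc$temperature_c)
  res <- stats::resid(fit)
  if (max(abs(res)) < 1e-9 * max(add_i)) {
    slope_p <- 1
    runs <- NULL
    accepted <- TRUE
  } else {
    slope_p <- suppressWarnings(summary(fit)$coefficients[2, 4])
    runs <- runs_test(res)
    accepted <- slope_p >= alpha && runs$p_value >= alpha
  }
  model$validation <- list(add_values = data.frame(
    temperature_c = inc$temperature_c, add = add_i),
    fit = fit, slope_p = slope_p, runs = runs, accepted = accepted)
  model$validated <- accepted
  model
}

#' Fit a fully validated degree-day model
#'
#' The complete iterative procedure for one event: (i) regress rate on
#' temperature and prune endpoints until the runs test shows no
#' non-linearity ([prune_until_linear()]); (ii) check the zero-slope and
#' linearity assumptions on the degree-day accumulations
#' ([validate_add_accumulation()]); (iii) if validation fails, exclude the
#' endpoint with the larger absolute standardized residual in the
#' accumulation regression and repeat from (i). The final model records the
#' contiguous temperature range over which the linear degree-day assumptions
#' hold, with every exclusion logged.
#'
#' @inheritParams prune_until_linear
#' @return a validated `degree_day_model` (`validated = TRUE`).
#' @export
fit_degree_day_model <- function(points, alpha = 0.05, event = "") {
  points <- new_rate_points(points)
  trace <- empty_trace()
  repeat {
    model <- prune_until_linear(points, alpha = alpha, event = event)
    points <- model$points
    trace <- rbind(trace, model$trace)
    trace$step <- seq_len(nrow(trace))
    model$trace <- trace
    model <- validate_add_accumulation(model, alpha = alpha)
    if (model$validation$accepted) return(model)
    if (model$n <= 3) {
      stop("degree-day assumptions cannot be met for event '", event,
           "' with n >= 3; excluded so far: ",
           paste(sprintf("%.1f", trace$temperature_c), collapse = ", "))
    }
    inc <- points$included
    temps <- points$temperature_c[inc]
    reason <- if (model$validation$slope_p < alpha) "add_slope_test"
      else "add_runs_test"
    drop_t <- pick_endpoint(model$validation$fit, temps)
    points$included[points$temperature_c == drop_t] <- FALSE
    trace <- rbind(trace, data.frame(
      step = nrow(trace) + 1L, temperature_c = drop_t, reason = reason,
      p_value = min(model$validation$slope_p,
                    if (is.null(model$validation$runs)) 1
                    else model$validation$runs$p_value)))
  }
}

#' Summarize per-temperature degree-day accumulations
#'
#' The cross-temperature mean of the observed accumulations, their spread as
#' the population standard deviation (divisor n), and — when the regression
#' ADD is supplied — the percent deviation of the calculated mean from the
#' regression estimate, the consistency figure reported alongside validated
#' models.
#'
#' @param add_values per-temperature ADD accumulations (degree-days).
#' @param regression_add the model's `1/slope` ADD, for the deviation figure.
#' @return list `mean`, `sd_pop`, `n`, `pct_deviation` (NA without
#'   `regression_add`).
#' @export
summarize_add <- function(add_values, regression_add = NULL) {
  add_values <- add_values[!is.na(add_values)]
  if (length(add_values) == 0) stop("no degree-day accumulations supplied")
  m <- mean(add_values)
  sd_pop <- sqrt(sum((add_values - m)^2) / length(add_values))
  list(mean = m, sd_pop = sd_pop, n = length(add_values),
       pct_deviation = if (is.null(regression_add)) NA_real_
       else 100 * (m - regression_add) / regression_add)
}
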