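#' Published reference values for P. regina development
#'
#' Three small tables from a published 11-temperature constant-temperature
#' development study of *Phormia regina* (the study whose design the
#' simulator emulates), shipped as plain CSV for desk-scale cross-checks of
#' this package's computations:
#'
#' * `pr_reference_percent_time()` — percent of total egg-to-adult
#'   development time spent in each pre-adult stage, by measured chamber
#'   temperature (degC). The 10.4 degC row is all NA: development there did
#'   not proceed far enough to report.
#' * `pr_reference_add()` — per-temperature degree-day accumulations (ADD)
#'   for each transition event (E-L1 ... E-A, cumulative from oviposition)
#'   and stage event (E ... P, duration within stage), long format.
#'   Temperatures excluded from an event's validated linear range carry no
#'   row.
#' * `pr_reference_models()` — the corresponding validated linear
#'   degree-day regressions: developmental minimum (x-intercept, degC),
#'   regression ADD (1/slope, degree-days), r-squared, n, valid temperature
#'   range, cross-temperature calculated ADD mean, its spread (population
#'   SD), and the percent deviation of calculated vs. regression ADD.
#'
#' @return a data.frame (see above).
#' @name reference-data
NULL

read_ref <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "phormiadev",
                              mustWork = TRUE), check.names = FALSE)
}

#' @rdname reference-data
#' @export
pr_reference_percent_time <- function() {
  read_ref("reference_percent_time_in_stage.csv")
}

#' @rdname reference-data
#' @export
pr_reference_add <- function() read_ref("reference_add_by_temperature.csv")

#' @rdname reference-data
#' @export
pr_reference_models <- function() read_ref("reference_degree_day_models.csv")

#' Reconstruct development rates from published per-temperature ADD values
#'
#' A published per-temperature accumulation is
#' `ADD_i = duration_days_i * (T_i - dev_min)` with `dev_min` the event's
#' published developmental minimum, so the underlying development rates are
#' recovered exactly (up to print rounding) as
#' `rate_i = (T_i - dev_min) / ADD_i`. Feeding these rates back through
#' [rate_regression()] re-derives the published regression line from the
#' printed table alone.
#'
#' @param event one event label present in [pr_reference_add()].
#' @return data.frame `temperature_c`, `rate` suitable for
#'   [rate_regression()].
#' @export
pr_reference_rates <- function(event) {
  add <- pr_reference_add()
  models <- pr_reference_models()
  if (!event %in% models$event) {
    stop("unknown event '", event, "'; available: ",
         paste(models$event, collapse = ", "))
  }
  d <- add[add$event == event, ]
  dev_min <- models$dev_min[models$event == event]
  data.frame(temperature_c = d$temperature_c,
             rate = (d$temperature_c - dev_min) / d$add)
}
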