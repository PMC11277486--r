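#' Validate an observation table
#'
#' Checks the long stage-count schema produced by [generate_cohort()] and
#' consumed by every analysis step: columns `temperature_c`, `time_h`,
#' `replicate`, `stage`, `count`; known stage labels; non-negative integer
#' counts; non-negative times; and at most one cup per
#' (temperature, time, replicate) — sampling is destructive.
#'
#' @param obs data.frame to validate.
#' @return `obs`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_observations <- function(obs) {
  required <- c("temperature_c", "time_h", "replicate", "stage", "count")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ok_labels <- c(pr_stages(), "dead")
  bad <- which(!obs$stage %in% ok_labels)
  if (length(bad)) {
    stop("unknown stage label(s) ",
         paste(unique(obs$stage[bad]), collapse = ", "), " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; accepted labels are: ", paste(ok_labels, collapse = ", "))
  }
  bad <- which(obs$count < 0 | obs$count != round(obs$count))
  if (length(bad)) {
    stop("counts must be non-negative integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(obs$time_h < 0)) stop("sampling times must be non-negative")
  key <- interaction(obs$temperature_c, obs$time_h, obs$replicate,
                     obs$stage, drop = TRUE)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (temperature, time, replicate, stage) record: ", d,
         " — destructive sampling admits one cup per combination")
  }
  invisible(obs)
}

#' Read / write observation tables
#'
#' `read_observations()` loads stage-count data from CSV or (with the
#' `readxl` package) XLSX. The canonical schema is long — `temperature_c`,
#' `time_h`, `replicate`, `stage`, `count` — but a wide layout with one
#' column per stage label is also accepted and melted; `col_map` renames
#' non-standard column headers first (e.g.
#' `c(temp = "temperature_c", hours = "time_h")`).
#'
#' @param path file to read or write.
#' @param sheet XLSX sheet (name or index), passed to [readxl::read_excel()].
#' @param col_map optional named character vector: `c(old_name = new_name)`.
#' @return a validated observation table.
#' @export
read_observations <- function(path, sheet = 1, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    obs <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    obs <- utils::read.csv(path, check.names = FALSE)
  }
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(obs))
    names(obs)[idx[!is.na(idx)]] <- col_map[!is.na(idx)]
  }
  if (!all(c("stage", "count") %in% names(obs))) {
    stage_cols <- intersect(c(pr_stages(), "dead"), names(obs))
    if (length(stage_cols) == 0) {
      stop("cannot interpret ", path, ": no stage/count columns and no ",
           "stage-labelled columns (", paste(pr_stages(), collapse = ", "),
           ") found")
    }
    id_cols <- setdiff(names(obs), stage_cols)
    long <- do.call(rbind, lapply(stage_cols, function(s) {
      cbind(obs[id_cols], stage = s, count = obs[[s]])
    }))
    obs <- long
  }
  validate_observations(obs)
  obs
}

#' @rdname read_observations
#' @param obs observation table to write.
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Percent time in stage by temperature
#'
#' Expresses each pre-adult stage's duration as a percentage of the total
#' egg-to-adult development time at that temperature, one row per
#' temperature, with a final column-mean row computed over the complete
#' rows. Rows with a missing stage are computed over the available total
#' (their cells no longer sum against the full life cycle) and are excluded
#' from the column means.
#'
#' @param durations data.frame with columns `temperature_c`, `stage`,
#'   `duration_days` (or `duration_h`).
#' @return data.frame with `temperature` (character; last row `"Mean"`) and
#'   one column per stage E, L1, L2, L3f, L3m, P.
#' @export
percent_time_in_stage <- function(durations) {
  stopifnot(all(c("temperature_c", "stage") %in% names(durations)))
  dcol <- if ("duration_days" %in% names(durations)) "duration_days"
    else "duration_h"
  stages <- pr_stage_events()
  temps <- sort(unique(durations$temperature_c))
  mat <- matrix(NA_real_, nrow = length(temps), ncol = length(stages),
                dimnames = list(NULL, stages))
  for (i in seq_along(temps)) {
    d <- durations[durations$temperature_c == temps[i], ]
    dur <- d[[dcol]][match(stages, d$stage)]
    if (any(!is.na(dur))) {
      mat[i, ] <- 100 * dur / sum(dur, na.rm = TRUE)
    }
  }
  complete <- stats::complete.cases(mat)
  means <- if (any(complete)) colMeans(mat[complete, , drop = FALSE])
    else rep(NA_real_, length(stages))
  out <- data.frame(temperature = c(format(temps), "Mean"),
                    rbind(mat, means), check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Column means of a percent-time-in-stage table
#'
#' Utility for summarizing an externally supplied percent table (same layout
#' as [percent_time_in_stage()] without its mean row): column means over
#' complete rows, and each complete row's sum (which must be 100 up to
#' rounding).
#'
#' @param tbl data.frame whose stage columns are named E, L1, L2, L3f,
#'   L3m, P.
#' @return list `means` (named numeric), `row_sums` (per complete row).
#' @export
percent_time_summary <- function(tbl) {
  stages <- intersect(pr_stage_events(), names(tbl))
  m <- as.matrix(tbl[stages])
  complete <- stats::complete.cases(m)
  list(means = colMeans(m[complete, , drop = FALSE]),
       row_sums = rowSums(m[complete, , drop = FALSE]))
}

#' Run the full development-modeling pipeline
#'
#' Orchestrates the whole analysis over an observation table: for every
#' temperature, build cumulative entered-stage series for the six
#' boundaries, estimate 50% transition times (cumulative-Gaussian route by
#' default, probit available), derive stage durations by subtraction, then
#' fit validated degree-day models for the six cumulative transition events
#' (E-L1 ... E-A, rate = 1/days from oviposition) and the six stage-duration
#' events (E ... P, rate = 1/days in stage), and assemble the report tables.
#' Temperatures whose transitions were not bracketed by the sampling times
#' (e.g. below the biological minimum, or beyond the linear range with
#' schedules built from linear extrapolation) drop out of the regressions
#' and are listed in the log. Deterministic given the input and settings.
#'
#' @param obs observation table; alternatively supply `config` to simulate
#'   one cohort first.
#' @param config a [sim_config()], used when `obs` is NULL.
#' @param alpha significance level for the runs and zero-slope tests.
#' @param route t50 route, `"cumulative"` or `"probit"`.
#' @param fit_curves also fit the four-equation occupancy curves per
#'   (temperature, stage) for diagnostics (slower; default FALSE).
#' @return a `pr_report`: list with `transitions`, `durations`,
#'   `percent_time`, `models` (per event), `degree_day_table`, `curve_fits`
#'   (optional), `log` (skipped pieces with reasons), plus the settings.
#' @export
run_pipeline <- function(obs = NULL, config = NULL, alpha = 0.05,
                         route = c("cumulative", "probit"),
                         fit_curves = FALSE) {
  route <- match.arg(route)
  if (is.null(obs)) {
    if (is.null(config)) stop("supply an observation table or a sim_config")
    obs <- generate_cohort(config)
  }
  validate_observations(obs)
  temps <- sort(unique(obs$temperature_c))
  log <- character()

  trans_rows <- list(); dur_rows <- list()
  t50_by_temp <- list()
  for (tt in temps) {
    ests <- stats::setNames(vector("list", 6), pr_boundaries())
    for (k in 1:6) {
      est <- tryCatch({
        ser <- boundary_entered_series(obs, tt, k)
        estimate_t50(ser, route = route)
      }, error = function(e) {
        log <<- c(log, sprintf("%.1f degC %s: %s", tt, pr_boundaries()[k],
                               conditionMessage(e)))
        NULL
      })
      ests[k] <- list(est)
      if (!is.null(est)) {
        trans_rows[[length(trans_rows) + 1L]] <- data.frame(
          temperature_c = tt, boundary = pr_boundaries()[k],
          t50_h = est$t50, se_h = est$se_t50, method = est$method,
          n_times = est$n_times)
      }
    }
    t50_by_temp[[as.character(tt)]] <- ests
    if (sum(!vapply(ests, is.null, TRUE)) >= 2) {
      durs <- tryCatch(stage_durations(ests), error = function(e) {
        log <<- c(log, sprintf("%.1f degC durations: %s", tt,
                               conditionMessage(e)))
        NULL
      })
      if (!is.null(durs)) {
        dur_rows[[length(dur_rows) + 1L]] <-
          cbind(temperature_c = tt, durs)
      }
    }
  }
  transitions <- if (length(trans_rows)) do.call(rbind, trans_rows) else NULL
  durations <- if (length(dur_rows)) do.call(rbind, dur_rows) else NULL

  # degree-day models: transition events (time from oviposition) ...
  models <- list()
  for (k in 1:6) {
    ev <- pr_transition_events()[k]
    pts <- do.call(rbind, lapply(names(t50_by_temp), function(nm) {
      est <- t50_by_temp[[nm]][[k]]
      if (is.null(est)) return(NULL)
      data.frame(temperature_c = as.numeric(nm), rate = 24 / est$t50)
    }))
    models[[ev]] <- fit_event_model(pts, alpha, ev,
                                    function(msg) log <<- c(log, msg))
  }
  # ... and stage events (duration within stage)
  if (!is.null(durations)) {
    for (st in pr_stage_events()) {
      d <- durations[durations$stage == st & !is.na(durations$duration_days), ]
      pts <- if (nrow(d)) data.frame(temperature_c = d$temperature_c,
                                     rate = 1 / d$duration_days) else NULL
      models[[st]] <- fit_event_model(pts, alpha, st,
                                      function(msg) log <<- c(log, msg))
    }
  }
  models <- Filter(Negate(is.null), models)

  report <- structure(list(
    transitions = transitions,
    durations = durations,
    percent_time = if (!is.null(durations)) percent_time_in_stage(durations)
      else NULL,
    models = models,
    degree_day_table = degree_day_table(models),
    curve_fits = if (fit_curves) fit_occupancy_curves(obs, function(msg)
      log <<- c(log, msg)) else NULL,
    log = log, alpha = alpha, route = route
  ), class = "pr_report")
  report
}

fit_event_model <- function(pts, alpha, event, log_fn) {
  if (is.null(pts) || nrow(pts) < 4) {
    log_fn(sprintf("event %s: too few rate points (%d) for a validated model",
                   event, if (is.null(pts)) 0L else nrow(pts)))
    return(NULL)
  }
  tryCatch(fit_degree_day_model(pts, alpha = alpha, event = event),
           error = function(e) {
             log_fn(sprintf("event %s: %s", event, conditionMessage(e)))
             NULL
           })
}

#' Tabulate validated degree-day models
#'
#' One row per event: developmental minimum, regression ADD, r-squared, n,
#' valid temperature range, cross-temperature calculated ADD mean and
#' population SD, and the percent deviation of the calculated mean from the
#' regression ADD.
#'
#' @param models list of `degree_day_model`s (as in a `pr_report`).
#' @return data.frame, one row per event.
#' @export
degree_day_table <- function(models) {
  if (length(models) == 0) return(NULL)
  do.call(rbind, lapply(names(models), function(ev) {
    m <- models[[ev]]
    adds <- m$validation$add_values$add
    s <- summarize_add(adds, m$add)
    data.frame(event = ev,
               type = if (ev %in% pr_transition_events()) "transition"
                 else "stage",
               dev_min = m$dev_min, add = m$add, r2 = m$r2, n = m$n,
               range_min = m$range[1], range_max = m$range[2],
               calc_add_mean = s$mean, calc_add_sd = s$sd_pop,
               pct_deviation = s$pct_deviation,
               n_excluded = nrow(m$trace))
  }))
}

fit_occupancy_curves <- function(obs, log_fn) {
  props <- stage_proportions(obs, unit = "percent")
  combos <- unique(props[c("temperature_c", "stage")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    tt <- combos$temperature_c[i]; st <- combos$stage[i]
    d <- props[props$temperature_c == tt & props$stage == st, ]
    model <- if (st == "E") "reversed_cumulative_gaussian"
      else if (st == "A") "cumulative_gaussian"
      else select_larval_model(d$y)
    fit <- tryCatch(fit_stage_curve(d$time_h, d$y, model),
                    error = function(e) {
                      log_fn(sprintf("curve %.1f degC %s: %s", tt, st,
                                     conditionMessage(e)))
                      NULL
                    })
    if (!is.null(fit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_c = tt, stage = st, model = fit$model, a = fit$a,
        b = fit$b, c = fit$c, d = fit$d, rss = fit$rss,
        converged = fit$converged)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' @export
print.pr_report <- function(x, ...) {
  cat("<pr_report>\n")
  if (!is.null(x$transitions)) {
    cat(sprintf("  %d transition estimates over %d temperatures (%s route)\n",
                nrow(x$transitions), length(unique(x$transitions$temperature_c)),
                x$route))
  }
  if (!is.null(x$degree_day_table)) {
    cat("  degree-day models:\n")
    print(x$degree_day_table, digits = 4)
  }
  if (length(x$log)) {
    cat(sprintf("  %d pieces skipped (see $log)\n", length(x$log)))
  }
  invisible(x)
}
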