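#' Life-stage and event vocabulary
#'
#' Pre-adult development is tracked through seven ordered classes: egg (E),
#' first and second instar (L1, L2), feeding and post-feeding/migratory third
#' instar (L3f, L3m), pupa (P) and adult (A). Stage boundaries are the six
#' molts/eclosions between consecutive classes; "transition events" are
#' cumulative times from oviposition to entry into a stage (E-L1 ... E-A),
#' while "stage events" are the durations spent within each pre-adult stage.
#'
#' @format `pr_stages()` returns the ordered stage labels; `pr_boundaries()`
#'   the six boundary labels (`"E-L1"`, `"L1-L2"`, ...); `pr_transition_events()`
#'   the cumulative event labels (`"E-L1"`, `"E-L2"`, ..., `"E-A"`);
#'   `pr_stage_events()` the six pre-adult stage labels.
#' @name stage-vocabulary
NULL

#' @rdname stage-vocabulary
#' @export
pr_stages <- function() c("E", "L1", "L2", "L3f", "L3m", "P", "A")

#' @rdname stage-vocabulary
#' @export
pr_boundaries <- function() {
  s <- pr_stages()
  paste(s[-length(s)], s[-1], sep = "-")
}

#' @rdname stage-vocabulary
#' @export
pr_transition_events <- function() paste0("E-", pr_stages()[-1])

#' @rdname stage-vocabulary
#' @export
pr_stage_events <- function() pr_stages()[-7]

# stage index of the stage entered at boundary k (k = 1..6 -> L1..A)
boundary_target_stage <- function(k) pr_stages()[k + 1L]

#' Error function
#'
#' `erf(x) = 2 * pnorm(x * sqrt(2)) - 1`, the form in which the cumulative
#' Gaussian transition curves are written.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
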