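#' Specify a two-stage adaptive enrichment design
#'
#' A design partitions the full population into `K` biomarker-defined strata
#' with known prevalences. At the interim analysis (calendar time `t1`, the
#' day the `interim_events`-th event is observed) a selection rule keeps the
#' partitions that look beneficial; stage-2 recruitment is restricted to
#' them. Stage-1 patients without an event at `t1` may be followed for a
#' prespecified additional `tilde_offset_days` (to `t_tilde1`), and stage-2
#' follow-up stops at `t2`, the day of the `stage2_events`-th event among
#' stage-2 patients.
#'
#' @param K number of partitions (>= 2).
#' @param prevalences numeric vector of length `K`, summing to 1.
#' @param b futility threshold on the log hazard ratio scale. Partitions (or
#'   weighted partition prefixes) with stage-1 estimate above `b` do not
#'   continue.
#' @param rule `"adaptive_threshold"` keeps the largest prefix `{1..s}` whose
#'   prevalence-weighted mean stage-1 estimate is `<= b`;
#'   `"independent"` keeps every partition with stage-1 estimate `<= b`.
#' @param alpha two-sided significance level (default 0.05); each one-sided
#'   test runs at `alpha/2`.
#' @param weights inverse-normal combination weights `(w1, w2)` with
#'   `w1^2 + w2^2 = 1`; conventionally the square roots of the prespecified
#'   stagewise shares of the total number of events.
#' @param weights_are_squared set `TRUE` when `weights` are given as the
#'   event shares themselves (so the combination weights are their square
#'   roots).
#' @param interim_events number of events that triggers the interim analysis.
#' @param stage2_events number of stage-2 patient events that ends the trial.
#' @param tilde_offset_days prespecified extra follow-up (days) of stage-1
#'   patients after `t1`; 0 freezes stage-1 data at the interim.
#' @param dropped_followed_to_tilde are stage-1 patients in dropped
#'   partitions followed to `t_tilde1` (TRUE) or censored at `t1` (FALSE)?
#'
#' @return An object of class `"trial_design"`.
#' @examples
#' trial_design(K = 2, prevalences = c(0.2, 0.8), b = 0,
#'              rule = "adaptive_threshold")
#' @export
trial_design <- function(K,
                         prevalences = rep(1 / K, K),
                         b = 0,
                         rule = c("adaptive_threshold", "independent"),
                         alpha = 0.05,
                         weights = c(1, 1) / sqrt(2),
                         weights_are_squared = FALSE,
                         interim_events = NULL,
                         stage2_events = NULL,
                         tilde_offset_days = 0,
                         dropped_followed_to_tilde = FALSE) {
  rule <- match.arg(rule)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (length(prevalences) != K) stop("prevalences must have length K")
  if (any(prevalences <= 0)) stop("prevalences must be positive")
  if (abs(sum(prevalences) - 1) > 1e-9)
    stop("prevalences must sum to 1 (tolerance 1e-9)")
  if (!is.numeric(b) || length(b) != 1L) stop("b must be a single number")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(weights) != 2L || any(weights <= 0))
    stop("weights must be two positive numbers")
  if (weights_are_squared) weights <- sqrt(weights)
  if (abs(sum(weights^2) - 1) > 1e-9)
    stop("weights must satisfy w1^2 + w2^2 = 1 (tolerance 1e-9); ",
         "use weights_are_squared = TRUE for event-share weights")
  if (!is.null(interim_events) && interim_events < 1)
    stop("interim_events must be a positive integer")
  if (!is.null(stage2_events) && stage2_events < 1)
    stop("stage2_events must be a positive integer")
  if (tilde_offset_days < 0) stop("tilde_offset_days must be non-negative")
  structure(
    list(K = K, prevalences = as.numeric(prevalences), b = b, rule = rule,
         alpha = alpha, weights = as.numeric(weights),
         interim_events = interim_events, stage2_events = stage2_events,
         tilde_offset_days = tilde_offset_days,
         dropped_followed_to_tilde = isTRUE(dropped_followed_to_tilde)),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-stage adaptive enrichment design\n")
  cat(sprintf("  K = %d partitions, prevalences: %s\n", x$K,
              paste(format(x$prevalences), collapse = ", ")))
  cat(sprintf("  selection rule: %s, futility threshold b = %g\n",
              x$rule, x$b))
  cat(sprintf("  alpha = %g (two-sided), weights = (%.4f, %.4f)\n",
              x$alpha, x$weights[1], x$weights[2]))
  if (!is.null(x$interim_events))
    cat(sprintf("  interim at %d events; stage 2 until %s events\n",
                x$interim_events,
                if (is.null(x$stage2_events)) "?" else x$stage2_events))
  cat(sprintf("  stage-1 extra follow-up: %g days (dropped partitions %s)\n",
              x$tilde_offset_days,
              if (x$dropped_followed_to_tilde) "followed" else "frozen at t1"))
  invisible(x)
}

#' Calendar analysis times of a two-stage trial
#'
#' Day 0 is the start of recruitment. `t1` is the interim analysis day,
#' `t_tilde1 >= t1` the day stage-1 follow-up stops, and `t2` the day
#' stage-2 follow-up stops. `t_tilde1 > t2` is allowed with a warning: data
#' beyond `t2` are not used, so such a configuration wastes follow-up.
#'
#' @param t1,t_tilde1,t2 calendar days (non-negative reals).
#' @return An object of class `"analysis_times"`.
#' @export
analysis_times <- function(t1, t_tilde1 = t1, t2) {
  if (t1 < 0) stop("t1 must be non-negative")
  if (t_tilde1 < t1) stop("t_tilde1 must be >= t1")
  if (t2 < t1) stop("t2 must be >= t1")
  if (t_tilde1 > t2)
    warning("t_tilde1 exceeds t2; stage-1 follow-up beyond t2 is unusual")
  structure(list(t1 = t1, t_tilde1 = t_tilde1, t2 = t2),
            class = "analysis_times")
}

#' @export
print.analysis_times <- function(x, ...) {
  cat(sprintf("Analysis times (days): t1 = %g, t_tilde1 = %g, t2 = %g\n",
              x$t1, x$t_tilde1, x$t2))
  invisible(x)
}
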