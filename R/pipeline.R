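#' Calendar analysis times implied by observed subject records
#'
#' `t1` is the calendar day of the `interim_events`-th observed event among
#' all recorded events; `t2` the day of the `stage2_events`-th event among
#' subjects recruited after `t1`; `t_tilde1 = t1 + tilde_offset_days`.
#'
#' @param records subject records.
#' @param design a [trial_design()] with event counts set.
#' @return An [analysis_times()].
#' @export
compute_analysis_times <- function(records, design) {
  if (is.null(design$interim_events))
    stop("design has no interim_events; supply analysis times explicitly")
  ev <- sort(records$event_day[records$status == 1])
  if (length(ev) < design$interim_events)
    stop("fewer events than interim_events")
  t1 <- ev[design$interim_events]
  t2 <- max(records$last_followup_day)
  if (!is.null(design$stage2_events)) {
    ev2 <- sort(records$event_day[records$status == 1 &
                                    records$entry_day > t1])
    if (length(ev2) < design$stage2_events)
      stop("fewer stage-2 events than stage2_events")
    t2 <- ev2[design$stage2_events]
  }
  analysis_times(t1, t1 + design$tilde_offset_days, t2)
}

#' Run the full estimation pipeline
#'
#' Orchestrates select -> truncation bounds -> point estimates -> intervals
#' from either subject-level records (analysis times computed from the
#' design's event counts unless supplied) or per-partition summary
#' statistics (analysis-time computation skipped). With summary-level input
#' the duality intervals require the `tilde` and `stage2` blocks; when they
#' are absent the report carries the naive intervals only and says so.
#'
#' @param subjects subject records (data frame) or a CSV path; exactly one
#'   of `subjects`/`summaries` must be given.
#' @param summaries a [partition_summaries()] or a JSON path.
#' @param design a [trial_design()] or a JSON path.
#' @param times optional [analysis_times()] (subject-level input only).
#' @param out optional path; the report is also written there as JSON.
#' @return An object of class `"estimate_report"`.
#' @examples
#' \dontrun{
#' summ <- read_summaries(system.file("extdata", "table1_summaries.json",
#'                                    package = "enrichest"))
#' des <- trial_design(K = 2, prevalences = c(0.2, 0.8), b = 0,
#'                     rule = "independent")
#' run_estimate(summaries = summ, design = des)
#' }
#' @export
run_estimate <- function(subjects = NULL, summaries = NULL, design,
                         times = NULL, out = NULL) {
  if (is.null(subjects) == is.null(summaries))
    stop("supply exactly one of subjects or summaries")
  if (is.character(design)) design <- read_design(design)
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- read_subjects(subjects, design)
    else subjects <- validate_subjects(subjects, design)
    if (is.null(times)) times <- compute_analysis_times(subjects, design)
    stage1 <- subjects[subjects$entry_day <= times$t1, , drop = FALSE]
    theta1 <- vapply(seq_len(design$K), function(j)
      logrank_summary(censor_at(stage1, times$t1, j))$theta, numeric(1))
    selection <- select_partitions(theta1, design)
    summ <- if (length(selection$selected))
      all_summaries(subjects, design, times, selection)
  } else {
    if (is.character(summaries)) summaries <- read_summaries(summaries)
    if (summaries$K != design$K)
      stop("summaries have ", summaries$K, " partitions but design K = ",
           design$K)
    theta1 <- stage1_estimates(summaries)
    selection <- select_partitions(theta1, design)
    summ <- summaries
  }

  report <- structure(
    list(design = design, times = times, selection = selection,
         estimates = NULL, duality_available = FALSE, message = NULL),
    class = "estimate_report")
  if (!length(selection$selected)) {
    report$message <- "stopped at interim; no estimates"
    if (!is.null(out)) write_report(report, out)
    return(report)
  }

  sel <- selection$selected
  pe <- point_estimates(summ, selection)
  est <- data.frame(
    partition = sel,
    theta1 = theta1[sel],
    sigma2_1 = vapply(sel, function(j) summary_slot(summ, j, "stage1")$sigma2,
                      numeric(1)),
    thetaN = pe$naive,
    sigma2_N = vapply(sel, function(j) summary_slot(summ, j, "combined")$sigma2,
                      numeric(1)),
    theta2 = vapply(sel, function(j) summary_slot(summ, j, "increment")$theta,
                    numeric(1)),
    sigma2_2 = vapply(sel, function(j)
      summary_slot(summ, j, "increment")$sigma2, numeric(1)),
    umvcue = pe$umvcue,
    lower_bound = selection$bounds$lower,
    upper_bound = selection$bounds$upper
  )
  nc <- t(vapply(seq_along(sel), function(i)
    naive_ci(est$thetaN[i], est$sigma2_N[i], design$alpha, length(sel)),
    numeric(2)))
  est$naive_lower <- nc[, 1]
  est$naive_upper <- nc[, 2]

  can_duality <- all(vapply(sel, function(j)
    !is.null(summary_slot(summ, j, "stage2")), logical(1))) &&
    all(vapply(seq_len(design$K), function(j)
      !is.null(summary_slot(summ, j, "tilde")), logical(1)))
  if (can_duality) {
    di <- duality_intervals(summ, selection, design)
    est$duality_lower <- di$lower
    est$duality_upper <- di$upper
    est$lower_informative <- di$lower_informative
    est$upper_informative <- di$upper_informative
    est$adjusted_p_greater <- di$adjusted_p_greater
    est$adjusted_p_less <- di$adjusted_p_less
    report$duality_available <- TRUE
  } else {
    report$message <-
      "duality intervals unavailable: stage-1-at-t_tilde1 or stage-2-only summaries missing"
  }
  report$estimates <- est
  if (!is.null(out)) write_report(report, out)
  report
}

#' @export
print.estimate_report <- function(x, digits = 3, ...) {
  cat("Two-stage enrichment estimate report\n")
  cat(sprintf("  rule: %s, b = %g, alpha = %g\n", x$design$rule, x$design$b,
              x$design$alpha))
  if (!is.null(x$times))
    cat(sprintf("  analysis times: t1 = %.0f, t_tilde1 = %.0f, t2 = %.0f\n",
                x$times$t1, x$times$t_tilde1, x$times$t2))
  if (!length(x$selection$selected)) {
    cat("  ", x$message, "\n")
    return(invisible(x))
  }
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  Partition %d: theta1 = %s (%s), thetaN = %s (%s), theta2 = %s (%s)\n",
                e$partition[i],
                format(round(e$theta1[i], digits)),
                format(round(e$sigma2_1[i], digits)),
                format(round(e$thetaN[i], digits)),
                format(round(e$sigma2_N[i], digits)),
                format(round(e$theta2[i], digits)),
                format(round(e$sigma2_2[i], digits))))
    cat(sprintf("    bounds (l, w) = (%s, %s), UMVCUE = %s\n",
                format(round(e$lower_bound[i], digits)),
                format(round(e$upper_bound[i], digits)),
                format(round(e$umvcue[i], digits))))
    cat(sprintf("    naive CI (%s, %s)",
                format(round(e$naive_lower[i], digits)),
                format(round(e$naive_upper[i], digits))))
    if (x$duality_available)
      cat(sprintf(", duality CI (%s%s, %s%s), adj. p = %.3f / %.3f",
                  format(round(e$duality_lower[i], digits)),
                  if (e$lower_informative[i]) "" else "*",
                  format(round(e$duality_upper[i], digits)),
                  if (e$upper_informative[i]) "" else "*",
                  e$adjusted_p_greater[i], e$adjusted_p_less[i]))
    cat("\n")
  }
  if (x$duality_available)
    cat("  (* marks a non-informative bound fixed at 0 by the closed test)\n")
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' Read a simulation scenario from JSON
#'
#' Keys mirror the arguments of [simulation_scenario()].
#' @param path JSON file.
#' @return A [simulation_scenario()].
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x),
                      names(formals(simulation_scenario)))]
  do.call(simulation_scenario, args)
}

## long-format view of an operating_characteristics object
oc_tidy <- function(oc) {
  rows <- list()
  rows$sel <- data.frame(outcome = names(oc$selection_probs),
                         partition = NA_integer_, estimator = NA_character_,
                         variant = NA_character_, statistic = "selection_prob",
                         value = as.numeric(oc$selection_probs),
                         n = oc$n_reps)
  if (!is.null(oc$estimates)) {
    e <- oc$estimates
    for (v in c("naive", "naive_frozen", "umvcue", "umvcue_frozen")) {
      variant <- if (grepl("frozen", v)) "tilde_eq_t1" else "tilde_gt_t1"
      estimator <- sub("_frozen", "", v)
      for (stat in c("bias", "rmse"))
        rows[[paste(v, stat)]] <- data.frame(
          outcome = e$outcome, partition = e$partition,
          estimator = estimator, variant = variant, statistic = stat,
          value = e[[paste0(stat, "_", v)]], n = e$n)
    }
  }
  if (!is.null(oc$coverage)) {
    cv <- oc$coverage
    for (v in c("naive", "duality")) {
      rows[[paste(v, "cov")]] <- data.frame(
        outcome = cv$outcome, partition = NA_integer_, estimator = v,
        variant = "tilde_gt_t1", statistic = "coverage",
        value = cv[[paste0(v, "_cover")]], n = cv$n)
      rows[[paste(v, "tail")]] <- data.frame(
        outcome = cv$outcome, partition = NA_integer_, estimator = v,
        variant = "tilde_gt_t1", statistic = "tail_error",
        value = cv[[paste0(v, "_tail")]], n = cv$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate operating characteristics and write a tidy table
#'
#' Thin orchestration over [operating_characteristics()]: accepts a
#' scenario object or JSON path, runs the replicates, and optionally writes
#' a tidy tab-delimited table (one row per outcome x partition x estimator
#' x statistic).
#'
#' @param scenario a [simulation_scenario()] or JSON path.
#' @param n_reps replicates (>= 1).
#' @param seed base seed.
#' @param out optional TSV path.
#' @param stage1_only,intervals passed to [operating_characteristics()].
#' @return The [operating_characteristics()] object, invisibly when `out`
#'   is given.
#' @export
run_simulate <- function(scenario, n_reps, seed = 1, out = NULL,
                         stage1_only = FALSE, intervals = TRUE) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  oc <- operating_characteristics(scenario, n_reps, seed,
                                  stage1_only = stage1_only,
                                  intervals = intervals)
  if (!is.null(out)) {
    utils::write.table(oc_tidy(oc), out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(oc))
  }
  oc
}

#' Design matching the bundled synthetic fixture
#'
#' @return The [trial_design()] under which [write_fixture()] trials are
#'   generated and should be analyzed.
#' @export
fixture_design <- function() {
  trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0, rule = "independent",
               alpha = 0.05, weights = c(1, 1) / sqrt(2),
               interim_events = 60, stage2_events = 30,
               tilde_offset_days = 80)
}

#' Write a small synthetic subject-level trial
#'
#' Generates a two-partition trial of about 240 subjects with known log
#' hazard ratios (-0.5, 0.1) under [fixture_design()] and writes it as a
#' subjects CSV, for end-to-end runs without external data. Deterministic
#' in `seed`; if a draw stops at the interim the next derived seed is
#' tried, still deterministically.
#'
#' @param path CSV file to write.
#' @param seed integer seed.
#' @return The path, invisibly; the simulated trial as attribute `"trial"`.
#' @export
write_fixture <- function(path, seed = 1) {
  des <- fixture_design()
  sc <- simulation_scenario(theta = c(-0.5, 0.1), gamma = 0.5,
                            lambda_c = log(2) / 10,
                            prevalences = des$prevalences,
                            n_patients = 240, accrual_days = 365,
                            allocation = 0.5,
                            interim_events = des$interim_events,
                            stage2_events = des$stage2_events,
                            tilde_offset_days = des$tilde_offset_days,
                            rule = des$rule, b = des$b, alpha = des$alpha)
  tr <- NULL
  for (k in 0:19) {
    set.seed(seed + 1000003L * k)
    cand <- simulate_trial(sc, intervals = FALSE, return_subjects = TRUE)
    if (!cand$stopped && !cand$flagged) {
      tr <- cand
      break
    }
  }
  if (is.null(tr)) stop("could not generate a non-stopped fixture trial")
  write_subjects(tr$subjects, path)
  invisible(structure(path, trial = tr))
}
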