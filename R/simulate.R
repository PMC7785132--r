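#' Draw Weibull event times
#'
#' Inverse-transform samples from the Weibull distribution with hazard
#' `h(t) = lambda * gamma * t^(gamma - 1)`, i.e. survival
#' `S(t) = exp(-lambda * t^gamma)`: `T = (-log(U)/lambda)^(1/gamma)`.
#' The median is `(log(2)/lambda)^(1/gamma)`.
#'
#' @param n number of draws.
#' @param lambda scale parameter (> 0).
#' @param gamma shape parameter (> 0); `gamma = 1` is the exponential.
#' @return Vector of event times (days).
#' @export
weibull_times <- function(n, lambda, gamma) {
  if (lambda <= 0 || gamma <= 0) stop("lambda and gamma must be positive")
  (-log(stats::runif(n)) / lambda)^(1 / gamma)
}

#' Specify a simulated two-stage enrichment trial
#'
#' Control-arm event times are Weibull with shared shape `gamma` and scale
#' `lambda_c` in every partition (predictive, non-prognostic biomarker);
#' the experimental scale in partition `j` is `lambda_c * exp(theta[j])`,
#' so `theta[j]` is the constant log hazard ratio. Patients accrue
#' uniformly over `accrual_days`; partition membership is multinomial with
#' the design prevalences; allocation is 1:1 by independent assignment.
#' The interim is at the `interim_events`-th death, stage-2 recruitment
#' (all post-interim entrants, keeping the overall accrual rate) is
#' restricted to the selected partitions with renormalized prevalences, and
#' the trial ends at the `stage2_events`-th stage-2 death.
#'
#' @param theta log hazard ratios, length `K`.
#' @param gamma Weibull shape.
#' @param lambda_c control-arm scale (default `log(2)/20`: median 400 days
#'   at `gamma = 0.5`).
#' @param prevalences partition prevalences.
#' @param n_patients total accrual.
#' @param accrual_days accrual window (days).
#' @param allocation probability of the experimental arm.
#' @param interim_events,stage2_events event counts defining `t1` and `t2`.
#' @param tilde_offset_days extra stage-1 follow-up after `t1`.
#' @param rule,b,alpha,weights,dropped_followed_to_tilde passed to
#'   [trial_design()].
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(theta,
                                gamma = 0.5,
                                lambda_c = log(2) / 20,
                                prevalences = rep(1 / length(theta), length(theta)),
                                n_patients = 2200,
                                accrual_days = 730,
                                allocation = 0.5,
                                interim_events = 300,
                                stage2_events = 300,
                                tilde_offset_days = 250,
                                rule = "adaptive_threshold",
                                b = 0,
                                alpha = 0.05,
                                weights = c(1, 1) / sqrt(2),
                                dropped_followed_to_tilde = FALSE) {
  if (lambda_c <= 0 || gamma <= 0) stop("lambda_c and gamma must be positive")
  if (n_patients < interim_events)
    stop("n_patients must be at least interim_events")
  design <- trial_design(K = length(theta), prevalences = prevalences, b = b,
                         rule = rule, alpha = alpha, weights = weights,
                         interim_events = interim_events,
                         stage2_events = stage2_events,
                         tilde_offset_days = tilde_offset_days,
                         dropped_followed_to_tilde = dropped_followed_to_tilde)
  structure(list(theta = as.numeric(theta), gamma = gamma,
                 lambda_c = lambda_c, n_patients = as.integer(n_patients),
                 accrual_days = accrual_days, allocation = allocation,
                 design = design),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Simulation scenario: Weibull(gamma =", x$gamma, "), lambda_C =",
      format(x$lambda_c, digits = 4), "\n")
  cat("  theta:", paste(format(x$theta, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  %d patients over %g days, allocation P(exp) = %g\n",
              x$n_patients, x$accrual_days, x$allocation))
  print(x$design)
  invisible(x)
}

## snapshot of (time, status, arm) for index set idx censored at calendar
## day; subjects recruited after the analysis day are excluded
snap_at <- function(entry, death, exper, idx, day) {
  idx <- idx[entry[idx] <= day]
  data.frame(time = pmin(death[idx], day) - entry[idx],
             status = as.integer(death[idx] <= day),
             experimental = exper[idx])
}

#' Simulate one two-stage adaptive enrichment trial
#'
#' Generates a trial under `scenario` (using the current RNG state), applies
#' the selection rule at the interim, and -- unless the trial stops or
#' `stage1_only` is set -- runs the full estimation pipeline. Point
#' estimates are computed twice: with the incremental follow-up
#' (`t_tilde1 = t1 + tilde_offset_days`) and with stage-1 data frozen at
#' the interim (`t_tilde1 = t1`, the `_frozen` columns).
#'
#' @param scenario a [simulation_scenario()].
#' @param stage1_only stop after the interim selection (fast path for
#'   selection-probability studies).
#' @param intervals compute the naive and duality intervals (the duality
#'   bounds dominate the run time).
#' @param return_subjects attach the subject-level records (calendar-day
#'   format suitable for [write_subjects()]).
#' @return A list of class `"trial_result"` with elements `theta1`,
#'   `selection`, `times`, `stopped`, `flagged`, and (full runs) an
#'   `estimates` data frame with one row per selected partition.
#' @export
simulate_trial <- function(scenario, stage1_only = FALSE, intervals = TRUE,
                           return_subjects = FALSE) {
  sc <- scenario
  des <- sc$design
  K <- des$K
  n <- sc$n_patients
  entry <- stats::runif(n, 0, sc$accrual_days)
  part <- sample.int(K, n, TRUE, des$prevalences)
  exper <- stats::runif(n) < sc$allocation
  lam <- sc$lambda_c * ifelse(exper, exp(sc$theta[part]), 1)
  tev <- (-log(stats::runif(n)) / lam)^(1 / sc$gamma)
  death <- entry + tev

  t1 <- sort(death, partial = des$interim_events)[des$interim_events]
  is1 <- entry <= t1
  S1 <- V1 <- rep(NA_real_, K)
  for (j in seq_len(K)) {
    idx <- which(is1 & part == j)
    sv <- logrank_sv(pmin(death[idx], t1) - entry[idx],
                     as.integer(death[idx] <= t1), exper[idx])
    S1[j] <- sv$S
    V1[j] <- sv$V
  }
  theta1 <- S1 / V1
  selection <- select_partitions(theta1, des)
  sel <- selection$selected

  out <- list(theta_true = sc$theta, theta1 = theta1, sigma2_1 = 1 / V1,
              selection = selection, t1 = t1,
              stopped = !length(sel), flagged = FALSE)
  class(out) <- "trial_result"
  if (stage1_only || out$stopped) return(out)

  i2 <- which(!is1)
  if (length(i2) < des$stage2_events) {
    out$flagged <- TRUE
    return(out)
  }
  # enrichment: post-interim entrants come from the selected partitions only
  psel <- des$prevalences[sel] / sum(des$prevalences[sel])
  part[i2] <- sel[sample.int(length(sel), length(i2), TRUE, psel)]
  exper[i2] <- stats::runif(length(i2)) < sc$allocation
  lam2 <- sc$lambda_c * ifelse(exper[i2], exp(sc$theta[part[i2]]), 1)
  tev[i2] <- (-log(stats::runif(length(i2))) / lam2)^(1 / sc$gamma)
  death[i2] <- entry[i2] + tev[i2]
  t2 <- sort(death[i2], partial = des$stage2_events)[des$stage2_events]
  ttil <- t1 + des$tilde_offset_days
  out$times <- suppressWarnings(analysis_times(t1, ttil, t2))

  blocks <- vector("list", K)
  frozen <- vector("list", K) # combined/increment with stage-1 data at t1
  for (j in seq_len(K)) {
    b <- list(stage1 = score_summary(S1[j], V1[j]))
    idx1 <- which(is1 & part == j)
    tilde_day <- if (j %in% sel || des$dropped_followed_to_tilde) ttil else t1
    b$tilde <- if (tilde_day == t1) b$stage1 else
      logrank_summary(snap_at(entry, death, exper, idx1, tilde_day))
    if (j %in% sel) {
      idx2 <- i2[part[i2] == j]
      sn1 <- snap_at(entry, death, exper, idx1, ttil)
      sn2 <- snap_at(entry, death, exper, idx2, t2)
      b$combined <- logrank_summary(rbind(sn1, sn2))
      b$increment <- increment_summary(b$combined, b$stage1)
      b$stage2 <- logrank_summary(sn2)
      cmb0 <- logrank_summary(rbind(snap_at(entry, death, exper, idx1, t1), sn2))
      frozen[[j]] <- list(combined = cmb0,
                          increment = increment_summary(cmb0, b$stage1))
    }
    blocks[[j]] <- b
  }
  summ <- partition_summaries(blocks)
  out$summaries <- summ

  pe <- point_estimates(summ, selection)
  est <- data.frame(
    partition = sel,
    theta_true = sc$theta[sel],
    theta1 = theta1[sel],
    naive = pe$naive,
    umvcue = pe$umvcue,
    sigma2_N = vapply(sel, function(j) summary_slot(summ, j, "combined")$sigma2,
                      numeric(1)),
    naive_frozen = NA_real_, umvcue_frozen = NA_real_
  )
  for (i in seq_along(sel)) {
    j <- sel[i]
    fz <- frozen[[j]]
    est$naive_frozen[i] <- fz$combined$theta
    est$umvcue_frozen[i] <- umvcue(fz$combined$theta, 1 / V1[j],
                                   fz$increment$sigma2,
                                   lower = selection$bounds$lower[i],
                                   upper = selection$bounds$upper[i])
  }
  if (intervals) {
    nc <- t(vapply(seq_along(sel), function(i)
      naive_ci(est$naive[i], est$sigma2_N[i], des$alpha, length(sel)),
      numeric(2)))
    est$naive_lower <- nc[, 1]
    est$naive_upper <- nc[, 2]
    di <- duality_intervals(summ, selection, des)
    est$duality_lower <- di$lower
    est$duality_upper <- di$upper
    est$lower_informative <- di$lower_informative
    est$upper_informative <- di$upper_informative
    est$adjusted_p_greater <- di$adjusted_p_greater
    est$adjusted_p_less <- di$adjusted_p_less
  }
  out$estimates <- est

  if (return_subjects) {
    followup <- numeric(n)
    followup[is1] <- ifelse(part[is1] %in% sel | des$dropped_followed_to_tilde,
                            ttil, t1)
    followup[!is1] <- t2
    evt <- death <= followup
    # entrants after the end of stage-2 follow-up are never analyzed and
    # would not have been recruited; they do not appear in the records
    keep <- entry <= pmin(followup, t2)
    out$subjects <- data.frame(
      subject_id = sprintf("s%04d", seq_len(n)),
      partition = part,
      arm = ifelse(exper, "experimental", "control"),
      entry_day = entry,
      event_day = ifelse(evt, death, NA_real_),
      last_followup_day = followup,
      status = as.integer(evt)
    )[keep, ]
    rownames(out$subjects) <- NULL
  }
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Simulated trial: stage-1 estimates",
      paste(format(x$theta1, digits = 3), collapse = ", "), "\n")
  print(x$selection)
  if (!is.null(x$estimates)) {
    cat("Estimates:\n")
    print(x$estimates, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Operating characteristics of a design/estimator pair
#'
#' Simulates `n_reps` trials (replicate `r` uses seed `seed + r`, so each
#' replicate is individually reproducible) and aggregates, conditional on
#' each realized selection outcome: the selection probabilities (summing to
#' one over outcomes including the futility stop), the bias and RMSE of the
#' naive estimator and the UMVCUE -- each both with incremental follow-up
#' and with stage-1 data frozen at the interim -- and, when `intervals` is
#' set, the simultaneous coverage of the naive and duality intervals
#' together with the tail error (the probability that at least one upper
#' bound falls below the true value).
#'
#' @param scenario a [simulation_scenario()].
#' @param n_reps number of simulated trials (>= 1).
#' @param seed integer base seed.
#' @param stage1_only only run the interim (selection probabilities only).
#' @param intervals compute interval coverage (slower).
#' @return An object of class `"operating_characteristics"` with elements
#'   `selection_probs`, `estimates`, `coverage`, `n_reps`, `n_flagged`.
#' @export
operating_characteristics <- function(scenario, n_reps, seed = 1,
                                      stage1_only = FALSE, intervals = TRUE) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  outcome_of <- function(sel)
    if (!length(sel)) "stop" else paste(sel, collapse = ",")
  outcomes <- character(n_reps)
  flagged <- logical(n_reps)
  rows <- vector("list", n_reps)
  cov_rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    tr <- tryCatch(
      simulate_trial(scenario, stage1_only = stage1_only,
                     intervals = intervals),
      error = function(e) NULL)
    if (is.null(tr)) {
      # degenerate replicate (e.g. a partition without events at the
      # interim, or an unbracketable confidence bound); kept in the outcome
      # table so probabilities still sum to one, excluded from estimates
      outcomes[r] <- "error"
      next
    }
    outcomes[r] <- outcome_of(tr$selection$selected)
    flagged[r] <- tr$flagged
    if (is.null(tr$estimates)) next
    e <- tr$estimates
    rows[[r]] <- data.frame(
      outcome = outcomes[r], partition = e$partition,
      err_naive = e$naive - e$theta_true,
      err_naive_frozen = e$naive_frozen - e$theta_true,
      err_umvcue = e$umvcue - e$theta_true,
      err_umvcue_frozen = e$umvcue_frozen - e$theta_true
    )
    if (intervals) {
      cov_rows[[r]] <- data.frame(
        outcome = outcomes[r],
        naive_cover = all(e$naive_lower <= e$theta_true &
                            e$theta_true <= e$naive_upper),
        duality_cover = all(e$duality_lower <= e$theta_true &
                              e$theta_true <= e$duality_upper),
        naive_tail = any(e$naive_upper < e$theta_true),
        duality_tail = any(e$duality_upper < e$theta_true)
      )
    }
  }
  sel_tab <- table(outcomes)
  selection_probs <- as.numeric(sel_tab) / n_reps
  names(selection_probs) <- names(sel_tab)

  est <- NULL
  errs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(errs) && nrow(errs)) {
    agg <- function(v, f) stats::aggregate(
      errs[[v]], by = list(outcome = errs$outcome, partition = errs$partition),
      FUN = f)$x
    est <- stats::aggregate(errs$err_naive,
                            by = list(outcome = errs$outcome,
                                      partition = errs$partition),
                            FUN = length)
    names(est)[3] <- "n"
    for (v in c("err_naive", "err_naive_frozen", "err_umvcue",
                "err_umvcue_frozen")) {
      nm <- sub("^err_", "", v)
      est[[paste0("bias_", nm)]] <- agg(v, mean)
      est[[paste0("rmse_", nm)]] <- agg(v, function(x) sqrt(mean(x^2)))
    }
  }

  cov <- NULL
  cv <- do.call(rbind, cov_rows[!vapply(cov_rows, is.null, logical(1))])
  if (!is.null(cv) && nrow(cv)) {
    cov <- stats::aggregate(
      cv[, c("naive_cover", "duality_cover", "naive_tail", "duality_tail")],
      by = list(outcome = cv$outcome), FUN = mean)
    cov$n <- as.integer(table(cv$outcome)[cov$outcome])
  }

  structure(list(scenario = scenario, n_reps = n_reps, seed = seed,
                 selection_probs = selection_probs, estimates = est,
                 coverage = cov, n_flagged = sum(flagged)),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, digits = 4, ...) {
  cat(sprintf("Operating characteristics (%d replicates, seed %d)\n",
              x$n_reps, x$seed))
  cat("Selection probabilities:\n")
  print(round(x$selection_probs, digits))
  if (!is.null(x$estimates)) {
    cat("Conditional bias / RMSE:\n")
    print(format(x$estimates, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$coverage)) {
    cat("Simultaneous coverage and tail error:\n")
    print(format(x$coverage, digits = digits), row.names = FALSE)
  }
  if (x$n_flagged)
    cat(sprintf("%d replicate(s) flagged: stage-2 event target unreachable\n",
                x$n_flagged))
  invisible(x)
}
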