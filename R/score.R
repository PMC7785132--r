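#' Administratively censor subject records at a calendar analysis time
#'
#' Converts calendar-time subject records into a survival snapshot: each
#' subject recruited by `analysis_day` contributes
#' `observed_time = min(event_day, last_followup_day, analysis_day) - entry_day`
#' and an event indicator for whether the event happened by both the
#' analysis day and the last follow-up day. Subjects recruited after
#' `analysis_day` are excluded (not counted as censored at time zero).
#'
#' @param records subject records as returned by [read_subjects()].
#' @param analysis_day calendar day (>= 0) of the analysis.
#' @param partition optional partition index; restricts the snapshot.
#' @return A data frame with columns `time`, `status` (1 event, 0 censored)
#'   and `experimental` (logical arm indicator), one row per included
#'   subject. May have zero rows.
#' @export
censor_at <- function(records, analysis_day, partition = NULL) {
  if (analysis_day < 0) stop("analysis_day must be non-negative")
  keep <- records$entry_day <= analysis_day
  if (!is.null(partition)) keep <- keep & records$partition == partition
  r <- records[keep, , drop = FALSE]
  event_day <- ifelse(is.na(r$event_day), Inf, r$event_day)
  horizon <- pmin(r$last_followup_day, analysis_day)
  data.frame(
    time = pmin(event_day, horizon) - r$entry_day,
    status = as.integer(event_day <= horizon),
    experimental = r$arm == "experimental"
  )
}

## Core log-rank score/information computation.
## S = sum over distinct event times of (dE - d * nE/n)
## V = sum of d * (nE/n) * (nC/n) * (n - d)/(n - 1), terms with n = 1 skipped
## (hypergeometric variance with tie correction). Censored subjects at an
## event time remain in the risk set (risk set is {T >= t}).
logrank_sv <- function(time, status, experimental) {
  if (sum(status) < 1L)
    stop("insufficient events/information: snapshot has no events")
  ord <- order(time)
  tt <- time[ord]
  ss <- status[ord] == 1L
  ee <- experimental[ord]
  n <- length(tt)
  et <- tt[ss]
  ut <- unique(et) # sorted, since tt is sorted
  grp <- match(et, ut)
  d <- tabulate(grp, length(ut))
  dE <- tabulate(grp[ee[ss]], length(ut))
  nrisk <- n - findInterval(ut, tt, left.open = TRUE)
  te <- tt[ee]
  nE <- length(te) - findInterval(ut, te, left.open = TRUE)
  S <- sum(dE - d * nE / nrisk)
  keep <- nrisk > 1
  V <- sum((d * (nE / nrisk) * ((nrisk - nE) / nrisk) *
              (nrisk - d) / (nrisk - 1))[keep])
  if (!is.finite(V) || V <= 0)
    stop("insufficient events/information: log-rank information is zero")
  list(S = S, V = V)
}

#' Log-rank score statistic and Fisher information of a snapshot
#'
#' Computes the two-sample log-rank score `S` and its hypergeometric
#' information `V` for one partition's snapshot. The sign convention is
#' that `S > 0` corresponds to excess events in the experimental arm, so
#' `theta = S/V > 0` means the experimental treatment is worse and
#' `theta < 0` that it delays the event.
#'
#' @param snapshot data frame from [censor_at()] with columns `time`,
#'   `status`, `experimental`.
#' @return A [score_summary()].
#' @examples
#' snap <- data.frame(time = c(1, 2), status = c(1, 0),
#'                    experimental = c(FALSE, TRUE))
#' logrank_summary(snap) # S = -0.5, V = 0.25, theta = -2
#' @export
logrank_summary <- function(snapshot) {
  sv <- logrank_sv(snapshot$time, snapshot$status, snapshot$experimental)
  score_summary(sv$S, sv$V)
}

#' Independent increment between two analyses
#'
#' The score accumulated after the interim, `S_N - S_1`, is asymptotically
#' independent of the interim score and normal with mean
#' `theta * (V_N - V_1)` and variance `V_N - V_1`. The increment estimate
#' `theta_2 = (S_N - S_1)/(V_N - V_1)` is the unbiased post-selection
#' estimator on which the UMVCUE is built.
#'
#' @param full [score_summary()] from all data of the partition.
#' @param stage1 [score_summary()] from the stage-1 data at the interim.
#' @return A [score_summary()] of the increment.
#' @export
increment_summary <- function(full, stage1) {
  stopifnot(inherits(full, "score_summary"), inherits(stage1, "score_summary"))
  if (full$V <= stage1$V)
    stop("no incremental information: V_N must exceed V_1")
  score_summary(full$S - stage1$S, full$V - stage1$V)
}

#' Inverse-variance combination of stagewise estimates
#'
#' Combines the stage-1 estimate and the independent increment into the
#' naive estimator:
#' `theta_N = (s2 * theta1 + s1 * theta2) / (s1 + s2)` with variance
#' `sigma2_N = s1 * s2 / (s1 + s2)`, writing `s_k` for `sigma2_k`. This is
#' identical to `S_N / V_N` when the increment was formed by subtraction.
#'
#' @param theta1,sigma2_1 stage-1 estimate and variance.
#' @param theta2,sigma2_2 increment estimate and variance.
#' @return A list with `theta` and `sigma2`.
#' @examples
#' combine_estimates(-0.902, 0.191, -0.609, 0.167) # theta -0.746, sigma2 0.089
#' @export
combine_estimates <- function(theta1, sigma2_1, theta2, sigma2_2) {
  if (sigma2_1 <= 0 || sigma2_2 <= 0) stop("variances must be positive")
  list(theta = (sigma2_2 * theta1 + sigma2_1 * theta2) / (sigma2_1 + sigma2_2),
       sigma2 = sigma2_1 * sigma2_2 / (sigma2_1 + sigma2_2))
}

#' All stagewise score summaries of a two-stage trial
#'
#' Assembles, from subject-level records, every per-partition summary the
#' estimators need: the stage-1 summary at `t1` for every partition; and,
#' for each selected partition, the stage-1 summary at `t_tilde1`, the
#' combined summary (stage-1 patients censored at `t_tilde1` pooled with
#' stage-2 patients censored at `t2`), the increment, and the stage-2-only
#' summary at `t2`. Dropped partitions get their `tilde` summary at
#' `t_tilde1` only when the design follows them after the interim;
#' otherwise it is the `t1` summary.
#'
#' @param records subject records (see [read_subjects()]).
#' @param design a [trial_design()].
#' @param times an [analysis_times()].
#' @param selection a [selection_result()]; partitions outside
#'   `selection$selected` only get `stage1` and `tilde` summaries.
#' @return A [partition_summaries()].
#' @export
all_summaries <- function(records, design, times, selection) {
  K <- design$K
  sel <- selection$selected
  stage1 <- records[records$entry_day <= times$t1, , drop = FALSE]
  stage2 <- records[records$entry_day > times$t1, , drop = FALSE]
  blocks <- vector("list", K)
  for (j in seq_len(K)) {
    b <- list()
    b$stage1 <- logrank_summary(censor_at(stage1, times$t1, j))
    tilde_day <- if (j %in% sel || design$dropped_followed_to_tilde)
      times$t_tilde1 else times$t1
    b$tilde <- if (tilde_day == times$t1) b$stage1 else
      logrank_summary(censor_at(stage1, tilde_day, j))
    if (j %in% sel) {
      snapN <- rbind(censor_at(stage1, times$t_tilde1, j),
                     censor_at(stage2, times$t2, j))
      b$combined <- logrank_summary(snapN)
      b$increment <- increment_summary(b$combined, b$stage1)
      b$stage2 <- logrank_summary(censor_at(stage2, times$t2, j))
    }
    blocks[[j]] <- b
  }
  partition_summaries(blocks)
}
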