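test_that("censoring at an analysis day follows the calendar-time rules", {
  rec <- data.frame(
    subject_id = c("a", "b", "c"),
    partition = 1L,
    arm = "experimental",
    entry_day = c(100, 100, 250),
    event_day = c(150, 300, NA),
    last_followup_day = c(150, 400, 400),
    status = c(1L, 1L, 0L)
  )
  snap <- censor_at(rec, 200)
  expect_equal(nrow(snap), 2) # subject entering at day 250 excluded
  expect_equal(snap$time, c(50, 100))
  expect_equal(snap$status, c(1L, 0L))
  # last follow-up before the analysis day also censors
  rec$last_followup_day[2] <- 180
  snap2 <- censor_at(rec, 200)
  expect_equal(snap2$time[2], 80)
  expect_equal(snap2$status[2], 0L)
})

test_that("single-event snapshot reproduces the hand computation", {
  snap <- data.frame(time = c(1, 2), status = c(1L, 0L),
                     experimental = c(FALSE, TRUE))
  s <- logrank_summary(snap)
  expect_equal(s$S, -0.5)
  expect_equal(s$V, 0.25)
  expect_equal(s$theta, -2)
  expect_equal(s$sigma2, 4)
})

test_that("log-rank score and information match survival::survdiff", {
  skip_if_not_installed("survival")
  for (seed in 1:6) {
    snap <- random_snapshot(n = 40 + 10 * seed, seed = seed)
    ours <- logrank_summary(snap)
    ref <- logrank_survdiff(snap)
    expect_equal(ours$S, ref$S, tolerance = 1e-10)
    expect_equal(ours$V, ref$V, tolerance = 1e-10)
  }
  # with heavy ties (integer-day times)
  set.seed(99)
  snap <- data.frame(time = sample(1:8, 60, TRUE),
                     status = rbinom(60, 1, 0.8),
                     experimental = rep(c(TRUE, FALSE), 30))
  ours <- logrank_summary(snap)
  ref <- logrank_survdiff(snap)
  expect_equal(ours$S, ref$S, tolerance = 1e-10)
  expect_equal(ours$V, ref$V, tolerance = 1e-10)
})

test_that("degenerate snapshots are refused", {
  expect_error(logrank_summary(
    data.frame(time = c(1, 2), status = c(0L, 0L),
               experimental = c(TRUE, FALSE))),
    "insufficient events")
  # events but only one arm ever at risk -> zero information
  expect_error(logrank_summary(
    data.frame(time = c(1, 2), status = c(1L, 1L),
               experimental = c(TRUE, TRUE))),
    "insufficient events")
})

test_that("increments subtract scores and informations", {
  full <- score_summary(10, 20)
  st1 <- score_summary(4, 8)
  inc <- increment_summary(full, st1)
  expect_equal(inc$S, 6)
  expect_equal(inc$V, 12)
  expect_equal(inc$theta, 0.5)
  expect_error(increment_summary(st1, full), "no incremental information")
  expect_error(increment_summary(st1, st1), "no incremental information")
})

test_that("inverse-variance combination reproduces the worked example", {
  cmb <- combine_estimates(-0.902, 0.191, -0.609, 0.167)
  expect_equal(round(cmb$theta, 3), -0.746)
  expect_equal(round(cmb$sigma2, 3), 0.089)
  # equal variances -> simple average
  expect_equal(combine_estimates(1, 0.2, 3, 0.2)$theta, 2)
  # an infinitely noisy increment leaves the stage-1 estimate untouched
  expect_equal(combine_estimates(1.3, 0.2, 99, 1e12)$theta, 1.3,
               tolerance = 1e-9)
  # Table 1 partition 2 variance identity
  expect_equal(round(0.103 * 0.108 / (0.103 + 0.108), 3), 0.053)
})

test_that("assembled summaries are internally consistent", {
  sc <- simulation_scenario(theta = c(-0.5, 0.1), gamma = 0.5,
                            lambda_c = log(2) / 10, n_patients = 300,
                            accrual_days = 365, interim_events = 60,
                            stage2_events = 40, tilde_offset_days = 90,
                            rule = "independent", b = 0.2)
  set.seed(11)
  tr <- simulate_trial(sc, intervals = FALSE, return_subjects = TRUE)
  expect_false(tr$stopped)
  sel <- tr$selection$selected
  summ <- all_summaries(tr$subjects, sc$design, tr$times, tr$selection)

  for (j in seq_len(sc$design$K)) {
    # the simulator's internal summaries match the subject-level path
    expect_equal(summ$partitions[[j]]$stage1$S,
                 tr$summaries$partitions[[j]]$stage1$S, tolerance = 1e-9)
    if (j %in% sel) {
      expect_equal(summ$partitions[[j]]$combined$V,
                   tr$summaries$partitions[[j]]$combined$V, tolerance = 1e-9)
      st1 <- summ$partitions[[j]]$stage1
      inc <- summ$partitions[[j]]$increment
      cmb <- combine_estimates(st1$theta, st1$sigma2, inc$theta, inc$sigma2)
      # combined estimate satisfies the inverse-variance identity
      expect_equal(cmb$theta, summ$partitions[[j]]$combined$theta,
                   tolerance = 1e-9)
      expect_equal(cmb$sigma2, summ$partitions[[j]]$combined$sigma2,
                   tolerance = 1e-9)
      # information grows with follow-up
      expect_gte(summ$partitions[[j]]$tilde$V, st1$V)
    } else {
      expect_null(summ$partitions[[j]]$stage2)
      expect_null(summ$partitions[[j]]$combined)
      # dropped partitions are frozen at t1 by default
      expect_equal(summ$partitions[[j]]$tilde$theta,
                   summ$partitions[[j]]$stage1$theta)
    }
  }
})

test_that("a zero follow-up offset makes the tilde summary the stage-1 one", {
  sc <- simulation_scenario(theta = c(-0.5, 0.1), gamma = 0.5,
                            lambda_c = log(2) / 10, n_patients = 300,
                            accrual_days = 365, interim_events = 60,
                            stage2_events = 40, tilde_offset_days = 0,
                            rule = "independent", b = 0.2)
  set.seed(12)
  tr <- simulate_trial(sc, intervals = FALSE)
  j <- tr$selection$selected[1]
  expect_identical(tr$summaries$partitions[[j]]$tilde$S,
                   tr$summaries$partitions[[j]]$stage1$S)
})

test_that("stagewise estimates are approximately uncorrelated under the null", {
  sc <- simulation_scenario(theta = c(0, 0), gamma = 0.5,
                            lambda_c = log(2) / 10,
                            n_patients = 300, accrual_days = 365,
                            interim_events = 60, stage2_events = 40,
                            tilde_offset_days = 90,
                            rule = "independent", b = Inf)
  n <- 300
  th1 <- th2 <- numeric(n)
  for (r in seq_len(n)) {
    set.seed(5000 + r)
    tr <- simulate_trial(sc, intervals = FALSE)
    th1[r] <- tr$estimates$theta1[1]
    th2[r] <- with(tr$summaries$partitions[[1]], increment$theta)
  }
  expect_lt(abs(cor(th1, th2)), 3 / sqrt(n))
})
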