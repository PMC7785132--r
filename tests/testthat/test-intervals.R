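test_that("naive multiplicity-split interval matches the worked example", {
  ci <- naive_ci(-0.746, 0.089, alpha = 0.05, n_selected = 2)
  expect_equal(round(stats::qnorm(1 - 0.05 / 4), 3), 2.241)
  expect_equal(round(ci[["lower"]], 3), -1.415)
  expect_equal(round(ci[["upper"]], 3), -0.077)
  # one selected partition: the ordinary two-sided z interval
  ci1 <- naive_ci(0.2, 0.04, alpha = 0.05, n_selected = 1)
  expect_equal(ci1[["upper"]] - 0.2, 0.2 - ci1[["lower"]])
  expect_equal(round((ci1[["upper"]] - 0.2) / 0.2, 3), round(1.96, 3))
})

test_that("Sidak adjustment behaves as printed", {
  expect_equal(sidak(c(0, 0.5)), 0)
  expect_equal(sidak(0.37, m = 1), 0.37)
  expect_equal(sidak(c(0.2, 0.5, 0.9)), 1 - 0.8^3)
})

test_that("inverse-normal combination has the stated special cases", {
  expect_equal(combine_p(0.5, 0.5), 0.5)
  expect_equal(combine_p(0.123, 0.9, weights = c(1 - 1e-12, 1e-6)), 0.123,
               tolerance = 1e-4)
  expect_equal(combine_p(1, 1), 1)
  expect_equal(combine_p(0, 0), 0)
  # monotone increasing in each argument over a grid
  ps <- seq(0.02, 0.98, by = 0.08)
  for (p2 in c(0.1, 0.5, 0.9)) {
    vals <- vapply(ps, function(p1) combine_p(p1, p2), numeric(1))
    expect_true(all(diff(vals) > 0))
    vals2 <- vapply(ps, function(pp) combine_p(p2, pp), numeric(1))
    expect_true(all(diff(vals2) > 0))
  }
})

test_that("closed test equals brute-force subset enumeration", {
  set.seed(7)
  for (i in 1:25) {
    K <- sample(2:5, 1)
    theta_t <- rnorm(K, 0, 0.5)
    sd_t <- runif(K, 0.2, 0.6)
    selected <- sort(sample(seq_len(K), sample(seq_len(K), 1)))
    thetaS2 <- rnorm(K, 0, 0.5)
    sdS2 <- runif(K, 0.2, 0.6)
    des <- trial_design(K = K, prevalences = rep(1 / K, K), b = 0,
                        rule = "independent", weights = c(0.6, 0.8))
    summ <- summaries_from_numbers(
      theta1 = theta_t, sigma2_1 = sd_t^2,
      theta2 = thetaS2, sigma2_2 = sdS2^2, selected = selected,
      thetaS2 = thetaS2, sigma2_S2 = sdS2^2)
    sel <- selection_result("independent", selected,
                            data.frame(partition = selected,
                                       lower = -Inf, upper = Inf),
                            theta_t)
    for (dir in c("greater", "less")) {
      g <- closed_test(summ, sel, des, direction = dir)
      sgn <- if (dir == "greater") 1 else -1
      ref <- closed_test_brute(
        p1 = 1 - pnorm(sgn * theta_t / sd_t),
        p2 = 1 - pnorm(sgn * thetaS2 / sdS2),
        selected = selected, weights = c(0.6, 0.8), alpha = des$alpha)
      expect_equal(g$adjusted, ref$adjusted, tolerance = 1e-12)
      expect_equal(g$rejected, ref$rejected)
      # closure: rejection implies the elementary combined p is small
      elem <- vapply(seq_len(K), function(j) {
        k <- which(vapply(g$subsets, function(I) identical(I, j), logical(1)))
        g$combined[k]
      }, numeric(1))
      expect_true(all(elem[g$rejected] <= des$alpha / 2))
    }
  }
})

test_that("trivial closed-test cases behave as expected", {
  des <- trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0,
                      rule = "independent")
  # all pairwise p-values ~ 1 in the greater direction: nothing rejected
  summ <- summaries_from_numbers(c(-2, -2), c(0.1, 0.1), c(-2, -2),
                                 c(0.1, 0.1))
  sel <- selection_result("independent", 1:2,
                          data.frame(partition = 1:2, lower = -Inf,
                                     upper = Inf), c(-2, -2))
  g <- closed_test(summ, sel, des, "greater")
  expect_false(any(g$rejected))
  expect_true(all(g$adjusted >= g$combined[c(1, 2)]))
  # missing tilde summary errors
  broken <- summ
  broken$partitions[[1]]$tilde <- NULL
  expect_error(closed_test(broken, sel, des), "missing stage-1")
})

test_that("p_M is the maximum over dropped-partition intersections", {
  expect_equal(pm_plus(c(0.2, 0.3, 0.4, 0.5), selected = 1:4), 0)
  expect_equal(pm_plus(c(0.2, 0.7), selected = 1), 0.7)
  p1 <- c(0.1, 0.2, 0.62, 0.35)
  byhand <- max(p1[3], p1[4], 1 - (1 - min(p1[3], p1[4]))^2)
  expect_equal(pm_plus(p1, selected = 1:2), byhand)
  # exhaustive check against direct enumeration for K = 5
  set.seed(3)
  p <- runif(5)
  selected <- c(2, 4)
  dropped <- setdiff(1:5, selected)
  subs <- unlist(lapply(1:3, function(m)
    utils::combn(dropped, m, simplify = FALSE)), recursive = FALSE)
  ref <- max(vapply(subs, function(I) 1 - (1 - min(p[I]))^length(I),
                    numeric(1)))
  expect_equal(pm_plus(p, selected), ref)
})

test_that("all-rejected lower bounds agree with a dense grid search", {
  des <- trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0,
                      rule = "independent", weights = c(1, 1) / sqrt(2))
  # strong effects in the 'greater' signed space so both get rejected
  summ <- summaries_from_numbers(
    theta1 = c(1.2, 0.9), sigma2_1 = c(0.04, 0.05),
    theta2 = c(1.0, 0.8), sigma2_2 = c(0.05, 0.06))
  sel <- selection_result("independent", 1:2,
                          data.frame(partition = 1:2, lower = -Inf,
                                     upper = Inf), c(1.2, 0.9))
  g <- closed_test(summ, sel, des, "greater")
  expect_true(all(g$rejected))
  pm <- pm_plus(g$p1_pairwise, 1:2)
  expect_equal(pm, 0)
  for (j in 1:2) {
    ours <- lower_bound_all_rejected(j, summ, sel, des, pm)
    ref <- bound_grid_search(
      tilde_theta = c(1.2, 0.9)[j], tilde_sd = sqrt(c(0.04, 0.05)[j]),
      s2_theta = c(1.0, 0.8)[j], s2_sd = sqrt(c(0.05, 0.06)[j]),
      K = 2, n_selected = 2, pm = pm, weights = des$weights,
      alpha = des$alpha, lo = -1, hi = 2)
    expect_equal(ours, ref, tolerance = 1e-4)
    expect_gte(ours, 0)
    # duality: the bound is positive exactly because H_j was rejected
    expect_gt(ours, 0)
  }
  # the bound shrinks as alpha shrinks
  des_strict <- trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0,
                             rule = "independent", alpha = 0.01)
  expect_lt(lower_bound_all_rejected(1, summ, sel, des_strict, pm),
            lower_bound_all_rejected(1, summ, sel, des, pm))
})

test_that("mixed-case bounds fix rejected partitions at zero", {
  des <- trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0,
                      rule = "independent")
  # partition 1 clearly positive (rejected), partition 2 ambiguous
  summ <- summaries_from_numbers(
    theta1 = c(1.5, 0.1), sigma2_1 = c(0.04, 0.05),
    theta2 = c(1.3, 0.05), sigma2_2 = c(0.05, 0.06))
  sel <- selection_result("independent", 1:2,
                          data.frame(partition = 1:2, lower = -Inf,
                                     upper = Inf), c(1.5, 0.1))
  g <- closed_test(summ, sel, des, "greater")
  expect_true(g$rejected[1])
  expect_false(g$rejected[2])
  b1 <- lower_bound_mixed(1, summ, sel, des, g)
  expect_equal(as.numeric(b1), 0)
  expect_false(attr(b1, "informative"))
  b2 <- lower_bound_mixed(2, summ, sel, des, g)
  expect_true(attr(b2, "informative"))
  expect_lt(as.numeric(b2), 0.1)
  # compatibility: the informative bound must not contradict non-rejection
  expect_lte(as.numeric(b2), 0)
})

test_that("duality intervals are anti-symmetric under sign flips", {
  des <- trial_design(K = 3, prevalences = rep(1 / 3, 3), b = 0,
                      rule = "independent", weights = c(0.6, 0.8))
  set.seed(10)
  for (i in 1:8) {
    th_t <- rnorm(3, 0, 0.7)
    sd_t <- runif(3, 0.2, 0.5)
    th2 <- rnorm(3, 0, 0.7)
    sd2 <- runif(3, 0.2, 0.5)
    selected <- sort(sample(1:3, sample(1:3, 1)))
    mk <- function(sgn) summaries_from_numbers(
      theta1 = sgn * th_t, sigma2_1 = sd_t^2,
      theta2 = sgn * th2, sigma2_2 = sd2^2, selected = selected,
      thetaS2 = sgn * th2, sigma2_S2 = sd2^2)
    sel <- selection_result("independent", selected,
                            data.frame(partition = selected, lower = -Inf,
                                       upper = Inf), th_t)
    sel_neg <- selection_result("independent", selected,
                                data.frame(partition = selected, lower = -Inf,
                                           upper = Inf), -th_t)
    di <- duality_intervals(mk(1), sel, des)
    di_neg <- duality_intervals(mk(-1), sel_neg, des)
    expect_equal(di$lower, -di_neg$upper, tolerance = 1e-9)
    expect_equal(di$upper, -di_neg$lower, tolerance = 1e-9)
    both <- di$lower_informative & di$upper_informative
    expect_true(all(di$lower[both] <= di$upper[both]))
  }
})

test_that("exact-normal duality regions cover simultaneously", {
  # K = 2, independent rule, normal stagewise estimates (no survival layer)
  n <- 4000
  theta <- c(-0.2, 0.15)
  s1 <- c(0.05, 0.04)
  s2 <- c(0.06, 0.05)
  des <- trial_design(K = 2, prevalences = c(0.5, 0.5), b = 0,
                      rule = "independent")
  set.seed(4)
  covered <- logical(n)
  used <- logical(n)
  for (r in seq_len(n)) {
    th1 <- rnorm(2, theta, sqrt(s1))
    th2 <- rnorm(2, theta, sqrt(s2))
    sel <- select_partitions(th1, des)
    if (!length(sel$selected)) next
    used[r] <- TRUE
    summ <- summaries_from_numbers(th1, s1, th2, s2,
                                   selected = sel$selected)
    di <- duality_intervals(summ, sel, des)
    covered[r] <- all(di$lower <= theta[sel$selected] &
                        theta[sel$selected] <= di$upper)
  }
  cov <- mean(covered[used])
  mc_se <- sqrt(cov * (1 - cov) / sum(used))
  expect_gte(cov, 0.95 - 3 * mc_se)
})
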