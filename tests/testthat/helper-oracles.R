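# Independent oracles and small generators used across the test files.
# Everything here is written directly from the defining formulas / by brute
# force, independently of the package implementation it checks.

# Quadrature oracle for the Rao-Blackwell estimate: integrate the truncated
# normal conditional density of theta1 given thetaN (mean thetaN, sd
# s1/sqrt(s1+s2)) and recover theta2 = ((s1+s2)*thetaN - s2*theta1)/s1.
umvcue_quadrature <- function(theta_n, s1, s2, l, w) {
  sdc <- s1 / sqrt(s1 + s2)
  # E[theta2 | .] = thetaN - (s2/s1) * sdc * E[z | a < z <= b] on the
  # standardized scale. The truncated-normal mean is integrated after the
  # shift u = z - a, whose integrand exp(-a*u - u^2/2) is O(1) at u = 0
  # even when the interval sits many SDs into a tail.
  trunc_mean <- function(a, b) {
    if (a == -Inf && b == Inf) return(0)
    if (a == -Inf) return(-trunc_mean(-b, Inf))
    g <- function(u) exp(-a * u - u^2 / 2)
    i0 <- stats::integrate(g, 0, b - a, rel.tol = 1e-12)$value
    i1 <- stats::integrate(function(u) u * g(u), 0, b - a,
                           rel.tol = 1e-12)$value
    a + i1 / i0
  }
  a <- (l - theta_n) / sdc
  b <- (w - theta_n) / sdc
  theta_n - (s2 / s1) * sdc * trunc_mean(a, b)
}

# Log-rank (S, V) through survival::survdiff, the established routine.
logrank_survdiff <- function(snapshot) {
  sd <- survival::survdiff(
    survival::Surv(time, status) ~ experimental, data = snapshot)
  # group 2 is experimental = TRUE (factor level order FALSE < TRUE)
  list(S = sd$obs[2] - sd$exp[2], V = sd$var[2, 2])
}

# Random but reproducible survival snapshot with events in both arms.
random_snapshot <- function(n = 40, seed = 1) {
  set.seed(seed)
  data.frame(
    time = round(rexp(n, 1 / 50), 2),
    status = rbinom(n, 1, 0.7),
    experimental = rep(c(FALSE, TRUE), length.out = n)
  )
}

# Brute-force "largest s" scan of the adaptive threshold rule.
adaptive_scan <- function(theta1, prev, b) {
  s <- 0L
  for (m in seq_along(theta1)) {
    if (sum(prev[1:m] * theta1[1:m]) / sum(prev[1:m]) <= b) s <- m
  }
  s
}

# Build a partition_summaries object straight from numbers; tilde defaults
# to stage 1 (the exact-normal, t_tilde1 = t1 regime).
summaries_from_numbers <- function(theta1, sigma2_1, theta2, sigma2_2,
                                   selected = seq_along(theta1),
                                   thetaS2 = theta2, sigma2_S2 = sigma2_2,
                                   theta_tilde = theta1,
                                   sigma2_tilde = sigma2_1) {
  K <- length(theta1)
  blocks <- lapply(seq_len(K), function(j) {
    bl <- list(stage1 = score_summary(theta1[j] / sigma2_1[j], 1 / sigma2_1[j]),
               tilde = score_summary(theta_tilde[j] / sigma2_tilde[j],
                                     1 / sigma2_tilde[j]))
    if (j %in% selected) {
      bl$increment <- score_summary(theta2[j] / sigma2_2[j], 1 / sigma2_2[j])
      bl$combined <- score_summary(bl$stage1$S + bl$increment$S,
                                   bl$stage1$V + bl$increment$V)
      bl$stage2 <- score_summary(thetaS2[j] / sigma2_S2[j], 1 / sigma2_S2[j])
    }
    bl
  })
  partition_summaries(blocks)
}

# Independent closed-test recomputation by explicit subset enumeration,
# straight from the formulas (Sidak within stage, inverse-normal across).
closed_test_brute <- function(p1, p2, selected, weights, alpha) {
  K <- length(p1)
  combn_all <- unlist(lapply(seq_len(K), function(m)
    utils::combn(K, m, simplify = FALSE)), recursive = FALSE)
  comb <- vapply(combn_all, function(I) {
    I2 <- intersect(I, selected)
    p1I <- 1 - (1 - min(p1[I]))^length(I)
    p2I <- if (length(I2)) 1 - (1 - min(p2[I2]))^length(I2) else 1
    p1I <- min(max(p1I, 1e-15), 1 - 1e-15)
    p2I <- min(max(p2I, 1e-15), 1 - 1e-15)
    1 - pnorm(weights[1] * qnorm(1 - p1I) + weights[2] * qnorm(1 - p2I))
  }, numeric(1))
  adjusted <- vapply(seq_len(K), function(j)
    max(comb[vapply(combn_all, function(I) j %in% I, logical(1))]),
    numeric(1))
  list(adjusted = adjusted, rejected = adjusted <= alpha / 2)
}

# Dense grid search for sup{v : C(v) <= alpha/2} of the all-rejected lower
# bound (Eq.-(4)-type elementary bound), independent of the root finder.
bound_grid_search <- function(tilde_theta, tilde_sd, s2_theta, s2_sd,
                              K, n_selected, pm, weights, alpha,
                              lo, hi, step = 1e-5) {
  v <- seq(lo, hi, by = step)
  p1 <- 1 - pnorm((tilde_theta - v) / tilde_sd)
  p2 <- 1 - pnorm((s2_theta - v) / s2_sd)
  a <- pmin(pmax(pmax(pm, 1 - (1 - p1)^K), 1e-15), 1 - 1e-15)
  b <- pmin(pmax(1 - (1 - p2)^n_selected, 1e-15), 1 - 1e-15)
  C <- 1 - pnorm(weights[1] * qnorm(1 - a) + weights[2] * qnorm(1 - b))
  max(0, v[max(which(C <= alpha / 2))])
}

table1_path <- function() {
  system.file("extdata", "table1_summaries.json", package = "enrichest")
}
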