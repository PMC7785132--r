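#' Naive multiplicity-split confidence interval
#'
#' Symmetric normal interval for the naive estimator that splits the
#' two-sided level equally over the selected partitions:
#' `theta_N +/- z[alpha/(2|S|)] * sigma_N`. It accounts for multiplicity
#' but not for the subpopulation selection.
#'
#' @param theta_n,sigma2_n naive estimate and its variance.
#' @param alpha two-sided level.
#' @param n_selected number of selected partitions `|S|`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' naive_ci(-0.746, 0.089, 0.05, 2) # (-1.415, -0.077)
#' @export
naive_ci <- function(theta_n, sigma2_n, alpha = 0.05, n_selected = 1) {
  if (n_selected < 1) stop("n_selected must be at least 1")
  if (sigma2_n <= 0) stop("sigma2_n must be positive")
  z <- stats::qnorm(1 - alpha / (2 * n_selected))
  c(lower = theta_n - z * sqrt(sigma2_n), upper = theta_n + z * sqrt(sigma2_n))
}

#' Sidak-adjusted intersection p-value
#'
#' For an intersection of `m` hypotheses tested on disjoint data, the
#' adjusted p-value `1 - (1 - min(p))^m` has exact size under independence.
#'
#' @param p_values component p-values of the intersection.
#' @param m number of components (defaults to `length(p_values)`).
#' @return A single p-value.
#' @export
sidak <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be at least 1")
  1 - (1 - min(p_values))^m
}

#' Weighted inverse-normal combination of stagewise p-values
#'
#' `C(p1, p2) = 1 - Phi(w1 * qnorm(1 - p1) + w2 * qnorm(1 - p2))` with
#' prespecified weights satisfying `w1^2 + w2^2 = 1`. Inputs at 0 or 1 are
#' clamped to `eps` before the normal inverse; when both inputs sit at the
#' same extreme the combination is defined as that extreme.
#'
#' @param p1,p2 stagewise p-values.
#' @param weights numeric of length 2 with `w1^2 + w2^2 = 1`.
#' @param eps clamping epsilon.
#' @return The combined p-value.
#' @export
combine_p <- function(p1, p2, weights = c(1, 1) / sqrt(2), eps = 1e-15) {
  if (abs(sum(weights^2) - 1) > 1e-9) stop("weights must satisfy w1^2 + w2^2 = 1")
  if (p1 >= 1 - eps && p2 >= 1 - eps) return(1)
  if (p1 <= eps && p2 <= eps) return(0)
  p1 <- min(max(p1, eps), 1 - eps)
  p2 <- min(max(p2, eps), 1 - eps)
  1 - stats::pnorm(weights[1] * stats::qnorm(1 - p1) +
                     weights[2] * stats::qnorm(1 - p2))
}

## all nonempty subsets of 1..K, as integer vectors
all_subsets <- function(K) {
  if (K > 15) stop("closed testing supports at most K = 15 partitions")
  lapply(seq_len(2^K - 1), function(m) which(bitwAnd(m, 2^(0:(K - 1))) > 0))
}

## Extract the statistics hypothesis testing needs from the summaries:
## theta-tilde and its SD for every partition, stage-2-only theta and SD for
## the selected partitions. `sign = -1` negates the estimates (used to turn
## upper-bound problems into lower-bound problems for delta = -theta).
testing_stats <- function(summaries, selection, sign = 1) {
  K <- summaries$K
  tilde_theta <- tilde_sd <- s2_theta <- s2_sd <- rep(NA_real_, K)
  for (j in seq_len(K)) {
    td <- summary_slot(summaries, j, "tilde")
    if (is.null(td)) stop("missing stage-1 (tilde) summary for partition ", j)
    tilde_theta[j] <- sign * td$theta
    tilde_sd[j] <- sqrt(td$sigma2)
  }
  for (j in selection$selected) {
    s2 <- summary_slot(summaries, j, "stage2")
    if (is.null(s2)) stop("missing stage-2-only summary for partition ", j)
    s2_theta[j] <- sign * s2$theta
    s2_sd[j] <- sqrt(s2$sigma2)
  }
  list(K = K, tilde_theta = tilde_theta, tilde_sd = tilde_sd,
       s2_theta = s2_theta, s2_sd = s2_sd)
}

## closed test on pre-extracted signed stats (one-sided, "greater" in the
## signed space); returns the full intersection grid
closed_test_stats <- function(st, selected, alpha, weights) {
  K <- st$K
  p1 <- 1 - stats::pnorm(st$tilde_theta / st$tilde_sd)
  p2 <- rep(NA_real_, K)
  p2[selected] <- 1 - stats::pnorm(st$s2_theta[selected] / st$s2_sd[selected])
  subsets <- all_subsets(K)
  p1I <- p2I <- comb <- numeric(length(subsets))
  for (k in seq_along(subsets)) {
    I <- subsets[[k]]
    I2 <- intersect(I, selected)
    p1I[k] <- sidak(p1[I])
    p2I[k] <- if (length(I2)) sidak(p2[I2]) else 1
    comb[k] <- combine_p(p1I[k], p2I[k], weights)
  }
  adjusted <- vapply(seq_len(K), function(j)
    max(comb[vapply(subsets, function(I) j %in% I, logical(1))]), numeric(1))
  structure(
    list(alpha = alpha, subsets = subsets, p1_pairwise = p1, p2_pairwise = p2,
         p1I = p1I, p2I = p2I, combined = comb, adjusted = adjusted,
         rejected = adjusted <= alpha / 2, selected = selected, K = K,
         weights = weights),
    class = "hypothesis_grid")
}

#' Closed test over all intersection hypotheses
#'
#' Tests every intersection `H_I` of the elementary hypotheses
#' `H_j: theta_j = 0` one-sidedly, combining a stage-1 Sidak-adjusted
#' p-value (over `I`, from the stage-1 summaries at `t_tilde1` or `t1`)
#' with a stage-2 Sidak-adjusted p-value (over `I` intersected with the
#' selected set, 1 if that is empty) through the weighted inverse-normal
#' rule. The adjusted p-value of partition `j` is the maximum combined
#' p-value over the intersections containing `j`; `theta_j > 0`
#' (direction `"greater"`) is concluded when it is at most `alpha/2`.
#'
#' @param summaries a [partition_summaries()] with `tilde` for every
#'   partition and `stage2` for every selected partition.
#' @param selection a [selection_result()].
#' @param design a [trial_design()].
#' @param direction `"greater"` tests against `theta_j > 0`, `"less"`
#'   against `theta_j < 0` (sign-flipped pairwise p-values).
#' @return An object of class `"hypothesis_grid"` with the pairwise and
#'   intersection p-values, the combined p-values, per-partition adjusted
#'   p-values and rejection flags.
#' @export
closed_test <- function(summaries, selection, design,
                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  st <- testing_stats(summaries, selection,
                      sign = if (direction == "greater") 1 else -1)
  g <- closed_test_stats(st, selection$selected, design$alpha, design$weights)
  g$direction <- direction
  g
}

#' @export
print.hypothesis_grid <- function(x, ...) {
  cat(sprintf("Closed test (%s direction), alpha/2 = %g\n",
              if (is.null(x$direction)) "signed" else x$direction, x$alpha / 2))
  for (j in seq_len(x$K))
    cat(sprintf("  H%d: adjusted p = %.4f%s\n", j, x$adjusted[j],
                if (x$rejected[j]) " (rejected)" else ""))
  invisible(x)
}

#' Maximum stage-1 p-value over intersections of dropped partitions
#'
#' `p_M` is the maximum Sidak-adjusted stage-1 p-value over all nonempty
#' subsets of the dropped partitions; it enters the all-rejected lower
#' bound. It is 0 when every partition was selected.
#'
#' @param stage1_pairwise stage-1 pairwise p-values, length `K`.
#' @param selected indices of the selected partitions.
#' @return A single p-value.
#' @export
pm_plus <- function(stage1_pairwise, selected) {
  K <- length(stage1_pairwise)
  dropped <- setdiff(seq_len(K), selected)
  if (!length(dropped)) return(0)
  subs <- all_subsets(length(dropped))
  max(vapply(subs, function(ii) sidak(stage1_pairwise[dropped[ii]]),
             numeric(1)))
}

## find sup{v : f(v) <= 0} for increasing f, by bisection to 1e-6;
## initial bracket center +/- 10*scale, expanded once to +/- 20*scale
sup_root <- function(f, center, scale, tol = 1e-6) {
  lo <- center - 10 * scale
  hi <- center + 10 * scale
  if (f(lo) > 0) {
    lo <- center - 20 * scale
    if (f(lo) > 0) stop("cannot bracket confidence bound within 20 SDs")
  }
  if (f(hi) < 0) {
    hi <- center + 20 * scale
    if (f(hi) < 0) stop("cannot bracket confidence bound within 20 SDs")
  }
  stats::uniroot(f, lower = lo, upper = hi, tol = tol)$root
}

## generalized pairwise p-values under a shift v of coordinate j
gen_p1 <- function(st, j, v) 1 - stats::pnorm((st$tilde_theta[j] - v) / st$tilde_sd[j])
gen_p2 <- function(st, j, v) 1 - stats::pnorm((st$s2_theta[j] - v) / st$s2_sd[j])

#' Lower confidence bound when every selected partition is rejected
#'
#' When the closed test concludes `theta_j > 0` for all selected
#' partitions, the lower bound for partition `j` is
#' `max(0, sup{v : C(max(p_M, 1 - (1 - p1_j(v))^K),
#' 1 - (1 - p2_j(v))^{|S|}) <= alpha/2})`, where `p1_j(v)` and `p2_j(v)`
#' are the stagewise pairwise p-values of the shifted null
#' `theta_j = v`. The combined p-value is increasing in `v`, so the
#' supremum is the root of `C(v) = alpha/2`.
#'
#' @param j partition index (must be selected).
#' @inheritParams closed_test
#' @param pm the dropped-partition maximum p-value from [pm_plus()].
#' @return The lower bound (never negative).
#' @export
lower_bound_all_rejected <- function(j, summaries, selection, design, pm) {
  st <- testing_stats(summaries, selection)
  bound_all_rejected(st, j, length(selection$selected), design, pm)
}

bound_all_rejected <- function(st, j, n_selected, design, pm) {
  a2 <- design$alpha / 2
  K <- st$K
  f <- function(v)
    combine_p(max(pm, 1 - (1 - gen_p1(st, j, v))^K),
              1 - (1 - gen_p2(st, j, v))^n_selected,
              design$weights) - a2
  max(0, sup_root(f, st$tilde_theta[j], st$tilde_sd[j]))
}

#' Lower confidence bound in the mixed-conclusion case
#'
#' When not every selected partition is rejected, a rejected partition's
#' lower bound is fixed at 0 (non-informative), while a non-rejected
#' partition `j` gets `min` over the intersections `I` containing `j` of
#' the bound `sup{v : C(p1_I(j, v), p2_I(j, v)) <= alpha/2}` -- taken as
#' `+Inf` for intersections the observed data already reject -- where the
#' generalized intersection p-values are evaluated under the parameter
#' vector with `v` in coordinate `j` and 0 elsewhere.
#'
#' @param j partition index (must be selected).
#' @inheritParams closed_test
#' @param grid the [closed_test()] result in the same direction.
#' @return The lower bound, with attribute `informative`.
#' @export
lower_bound_mixed <- function(j, summaries, selection, design, grid) {
  st <- testing_stats(summaries, selection)
  bound_mixed(st, j, selection$selected, design, grid)
}

bound_mixed <- function(st, j, selected, design, grid) {
  a2 <- design$alpha / 2
  if (grid$rejected[j])
    return(structure(0, informative = FALSE))
  best <- Inf
  for (k in seq_along(grid$subsets)) {
    I <- grid$subsets[[k]]
    if (!(j %in% I)) next
    if (grid$combined[k] < a2) next # theta_{j,L}^I = +Inf
    I2 <- intersect(I, selected)
    f <- function(v) {
      p1 <- vapply(I, function(i) gen_p1(st, i, if (i == j) v else 0),
                   numeric(1))
      p1I <- sidak(p1)
      p2I <- if (length(I2))
        sidak(vapply(I2, function(i) gen_p2(st, i, if (i == j) v else 0),
                     numeric(1)))
      else 1
      combine_p(p1I, p2I, design$weights) - a2
    }
    best <- min(best, sup_root(f, st$tilde_theta[j], st$tilde_sd[j]))
  }
  structure(best, informative = TRUE)
}

## one direction of the duality machinery, in signed space (sign = +1 gives
## lower bounds for theta; sign = -1 gives lower bounds for delta = -theta,
## i.e. negated upper bounds for theta)
duality_side <- function(summaries, selection, design, sign) {
  st <- testing_stats(summaries, selection, sign = sign)
  sel <- selection$selected
  grid <- closed_test_stats(st, sel, design$alpha, design$weights)
  if (all(grid$rejected[sel])) {
    pm <- pm_plus(grid$p1_pairwise, sel)
    bounds <- vapply(sel, function(j)
      bound_all_rejected(st, j, length(sel), design, pm), numeric(1))
    informative <- rep(TRUE, length(sel))
  } else {
    res <- lapply(sel, function(j) bound_mixed(st, j, sel, design, grid))
    bounds <- vapply(res, as.numeric, numeric(1))
    informative <- vapply(res, function(b) attr(b, "informative"), logical(1))
  }
  list(bounds = bounds, informative = informative,
       adjusted = grid$adjusted[sel], rejected = grid$rejected[sel])
}

#' Simultaneous duality confidence intervals
#'
#' Confidence intervals for the selected partitions obtained by inverting
#' the family of shifted-null closed tests (test-inversion duality), so
#' that the intervals are compatible with the trial's hypothesis testing
#' and have simultaneous coverage at least `1 - alpha`. Lower bounds come
#' from the `theta_j > 0` direction; upper bounds are obtained by negating
#' every estimate, computing lower bounds for `delta = -theta`, and
#' negating the result. In mixed-conclusion cases the bound of a rejected
#' partition is fixed at 0 and flagged non-informative.
#'
#' @inheritParams closed_test
#' @return A data frame with one row per selected partition: `partition`,
#'   `lower`, `upper`, `lower_informative`, `upper_informative`,
#'   `adjusted_p_greater`, `adjusted_p_less`.
#' @export
duality_intervals <- function(summaries, selection, design) {
  if (!length(selection$selected)) stop("selection is empty (futility stop)")
  lo <- duality_side(summaries, selection, design, sign = 1)
  up <- duality_side(summaries, selection, design, sign = -1)
  data.frame(
    partition = selection$selected,
    lower = lo$bounds,
    upper = -up$bounds,
    lower_informative = lo$informative,
    upper_informative = up$informative,
    adjusted_p_greater = lo$adjusted,
    adjusted_p_less = up$adjusted
  )
}
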