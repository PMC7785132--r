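#' Selection result
#'
#' Records which partitions continue to stage 2 and, per selected partition,
#' the truncation interval `(l_j, w_j]` of stage-1 estimates consistent with
#' the observed selection given the other partitions' estimates. An empty
#' `selected` set encodes a futility stop.
#'
#' @param rule `"adaptive_threshold"` or `"independent"`.
#' @param selected integer vector of selected partition indices (possibly
#'   empty).
#' @param bounds data frame with columns `partition`, `lower`, `upper`, one
#'   row per selected partition; `lower` may be `-Inf`, `upper` `+Inf`.
#' @param theta1 stage-1 estimates the selection was based on (length `K`).
#' @return An object of class `"selection_result"`.
#' @export
selection_result <- function(rule, selected, bounds, theta1) {
  selected <- as.integer(selected)
  if (length(selected)) {
    if (!identical(bounds$partition, selected))
      stop("bounds must have one row per selected partition, in order")
    th <- theta1[selected]
    if (any(th <= bounds$lower) || any(th > bounds$upper + 1e-12))
      stop("observed stage-1 estimate outside its truncation interval")
  }
  structure(list(rule = rule, selected = selected, bounds = bounds,
                 theta1 = theta1),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (!length(x$selected)) {
    cat(sprintf("Selection (%s): stopped at interim for futility\n", x$rule))
    return(invisible(x))
  }
  cat(sprintf("Selection (%s): partitions {%s}\n", x$rule,
              paste(x$selected, collapse = ", ")))
  for (i in seq_along(x$selected))
    cat(sprintf("  partition %d: theta1 = %.4f, bounds (l, w) = (%s, %s)\n",
                x$selected[i], x$theta1[x$selected[i]],
                format(x$bounds$lower[i], digits = 4),
                format(x$bounds$upper[i], digits = 4)))
  invisible(x)
}

#' Adaptive threshold selection rule
#'
#' Continues with the largest prefix subpopulation `{1..s}` whose
#' prevalence-weighted mean stage-1 estimate satisfies
#' `sum(p[1:s] * theta1[1:s]) / sum(p[1:s]) <= b`. Assumes the partitions
#' are ordered by expected benefit (threshold-ordered biomarker). Boundary
#' equality selects, as the inequality is non-strict.
#'
#' @param theta1 stage-1 log hazard ratio estimates, length `K`.
#' @param prevalences partition prevalences, summing to 1.
#' @param b futility threshold.
#' @return The number of selected partitions `s` in `0..K`; 0 means stop.
#' @examples
#' select_adaptive_threshold(c(-0.902, -0.419), c(0.2, 0.8), 0) # 2
#' @export
select_adaptive_threshold <- function(theta1, prevalences, b) {
  if (abs(sum(prevalences) - 1) > 1e-9) stop("prevalences must sum to 1")
  wmean <- cumsum(prevalences * theta1) / cumsum(prevalences)
  ok <- which(wmean <= b)
  if (length(ok)) max(ok) else 0L
}

#' Independent selection rule
#'
#' Every partition whose stage-1 estimate is at most `b` continues to
#' stage 2, independently of the other partitions.
#'
#' @inheritParams select_adaptive_threshold
#' @return Integer vector of selected partition indices (possibly empty).
#' @export
select_independent <- function(theta1, b) {
  which(theta1 <= b)
}

#' Truncation bounds under the adaptive threshold rule
#'
#' For selected partition `j` (with `s` partitions selected out of `K`), the
#' stage-1 estimate is consistent with the observed selection exactly when
#' it lies in `(l_j, w_j]`:
#' `w_j = (P_s * b - sum_{i <= s, i != j} p_i * theta1_i) / p_j` (the sum is
#' zero when `s = 1`), and `l_j` is the maximum over `m = s+1, ..., K` of
#' the analogous expression with `P_m`, `-Inf` when all partitions are
#' selected. `P_m` denotes the cumulative prevalence `p_1 + ... + p_m`.
#'
#' @inheritParams select_adaptive_threshold
#' @param s number of selected partitions (1..K).
#' @param j index of the partition whose bounds are sought (`j <= s`).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' bounds_adaptive(c(-0.902, -0.419), c(0.2, 0.8), b = 0, s = 2, j = 1)
#' @export
bounds_adaptive <- function(theta1, prevalences, b, s, j) {
  K <- length(theta1)
  if (s < 1 || s > K || j > s) stop("need 1 <= j <= s <= K")
  pcum <- cumsum(prevalences)
  bound_at <- function(m) {
    others <- setdiff(seq_len(m), j)
    (pcum[m] * b - sum(prevalences[others] * theta1[others])) / prevalences[j]
  }
  w <- bound_at(s)
  l <- if (s == K) -Inf else max(vapply((s + 1):K, bound_at, numeric(1)))
  c(lower = l, upper = w)
}

#' Truncation bounds under the independent rule
#'
#' Selection of a partition depends only on its own estimate, so every
#' selected partition has bounds `(-Inf, b]`.
#'
#' @param b futility threshold.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bounds_independent <- function(b) {
  c(lower = -Inf, upper = b)
}

#' Apply a design's selection rule to stage-1 estimates
#'
#' Runs the configured rule and attaches the per-partition truncation
#' bounds required by the UMVCUE.
#'
#' @param theta1 stage-1 log hazard ratio estimates, length `K`.
#' @param design a [trial_design()].
#' @return A [selection_result()].
#' @export
select_partitions <- function(theta1, design) {
  if (length(theta1) != design$K) stop("theta1 must have length K")
  if (design$rule == "adaptive_threshold") {
    s <- select_adaptive_threshold(theta1, design$prevalences, design$b)
    selected <- seq_len(s)
    bounds <- do.call(rbind, lapply(selected, function(j)
      bounds_adaptive(theta1, design$prevalences, design$b, s, j)))
  } else {
    selected <- select_independent(theta1, design$b)
    bounds <- do.call(rbind, lapply(selected, function(j)
      bounds_independent(design$b)))
  }
  bounds <- if (length(selected))
    data.frame(partition = as.integer(selected),
               lower = bounds[, "lower"], upper = bounds[, "upper"])
  else
    data.frame(partition = integer(), lower = numeric(), upper = numeric())
  selection_result(design$rule, selected, bounds, theta1)
}
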