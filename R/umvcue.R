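## log-scale Mills-type evaluation of (phi(gl) - phi(gw)) / (Phi(gl) - Phi(gw))
## for a one-sided truncation. For upper-only truncation (l = -Inf) the ratio
## is -phi(gw)/Phi(-gw); for lower-only (w = +Inf) it is phi(gl)/Phi(gl)...
## both computed as exp(log phi - log Phi) so they stay finite for |g| >> 6.
mills_upper <- function(gw) {
  # -phi(gw) / (1 - Phi(gw)); stable for any gw
  -exp(stats::dnorm(gw, log = TRUE) -
         stats::pnorm(gw, lower.tail = FALSE, log.p = TRUE))
}
mills_lower <- function(gl) {
  exp(stats::dnorm(gl, log = TRUE) - stats::pnorm(gl, log.p = TRUE))
}

#' Conditionally unbiased point estimate after selection (UMVCUE)
#'
#' Rao-Blackwell estimate of the log hazard ratio in a selected partition:
#' the expectation of the unbiased increment estimator given the combined
#' estimate and the selection event `l < theta1 <= w`,
#' \deqn{\hat\theta_U = \hat\theta_N - \frac{\sigma_2^2}
#'   {\sqrt{\sigma_1^2+\sigma_2^2}}\,
#'   \frac{\phi(g(l))-\phi(g(w))}{\Phi(g(l))-\Phi(g(w))},\qquad
#'   g(x) = \frac{\sqrt{\sigma_1^2+\sigma_2^2}}{\sigma_1^2}
#'   (\hat\theta_N - x).}
#' With both bounds infinite the estimate equals the naive one. One-sided
#' truncations are evaluated on the log scale so that extreme bounds do not
#' underflow; if a two-sided truncation is numerically degenerate the naive
#' estimate is returned with a `"degenerate"` attribute and a warning.
#'
#' @param theta_n naive (combined) estimate.
#' @param sigma2_1 variance of the stage-1 estimate used for selection.
#' @param sigma2_2 variance of the increment estimate.
#' @param lower,upper truncation bounds `l < w` from the selection rule
#'   (`-Inf` / `+Inf` allowed).
#' @return The conditionally unbiased estimate (a single number).
#' @examples
#' umvcue(-0.362, 0.103, 0.108, upper = 0.226) # -0.359
#' umvcue(-0.362, 0.103, 0.108, upper = 0)     # -0.335
#' @export
umvcue <- function(theta_n, sigma2_1, sigma2_2, lower = -Inf, upper = Inf) {
  if (sigma2_1 <= 0 || sigma2_2 <= 0) stop("variances must be positive")
  if (!(lower < upper)) stop("need lower < upper")
  if (lower == -Inf && upper == Inf) return(theta_n)
  pre <- sigma2_2 / sqrt(sigma2_1 + sigma2_2)
  g <- function(x) sqrt(sigma2_1 + sigma2_2) / sigma2_1 * (theta_n - x)
  if (lower == -Inf) return(theta_n - pre * mills_upper(g(upper)))
  if (upper == Inf) return(theta_n - pre * mills_lower(g(lower)))
  gl <- g(lower)
  gw <- g(upper) # gl > gw since g is decreasing
  num <- stats::dnorm(gl) - stats::dnorm(gw)
  den <- stats::pnorm(gl) - stats::pnorm(gw)
  if (den < 1e-300) {
    # both bounds many conditional SDs from theta_n on the same side
    if (abs(gl) > 6 && abs(gw) > 6 && sign(gl) == sign(gw)) {
      # Mills-ratio asymptotics: the truncated mass piles at the endpoint
      # nearer to theta_n, so the correction ratio tends to -g(nearer bound)
      gstar <- if (gw > 0) gw else gl
      return(theta_n + pre * gstar)
    }
    warning("degenerate truncation interval; returning the naive estimate")
    return(structure(theta_n, degenerate = TRUE))
  }
  theta_n - pre * num / den
}

#' Naive and UMVCUE point estimates for the selected partitions
#'
#' Applies [umvcue()] partition by partition, pairing each selected
#' partition's combined estimate and increment variance with its truncation
#' bounds.
#'
#' @param summaries a [partition_summaries()] with `combined` and
#'   `increment` present for every selected partition.
#' @param selection a [selection_result()] with nonempty selection.
#' @return A data frame with columns `partition`, `naive`, `umvcue`,
#'   `correction` (`umvcue - naive`).
#' @export
point_estimates <- function(summaries, selection) {
  if (!length(selection$selected))
    stop("selection is empty (futility stop); no estimates are defined")
  rows <- lapply(seq_along(selection$selected), function(i) {
    j <- selection$selected[i]
    comb <- summary_slot(summaries, j, "combined")
    s1 <- summary_slot(summaries, j, "stage1")
    inc <- summary_slot(summaries, j, "increment")
    if (is.null(comb) || is.null(inc))
      stop("missing combined/increment summary for partition ", j)
    u <- umvcue(comb$theta, s1$sigma2, inc$sigma2,
                lower = selection$bounds$lower[i],
                upper = selection$bounds$upper[i])
    data.frame(partition = j, naive = comb$theta, umvcue = as.numeric(u),
               correction = as.numeric(u) - comb$theta)
  })
  do.call(rbind, rows)
}
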