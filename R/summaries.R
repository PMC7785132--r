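#' Score statistic summary
#'
#' Container for a (score `S`, Fisher information `V`) pair from a log-rank
#' analysis of one partition at one analysis time. The derived estimate is
#' `theta = S/V` (asymptotically normal with variance `sigma2 = 1/V`),
#' positive values indicating excess events under the experimental arm,
#' i.e. the experimental treatment is worse.
#'
#' @param S score statistic.
#' @param V Fisher information (must be positive).
#' @return An object of class `"score_summary"` with elements `S`, `V`,
#'   `theta`, `sigma2`.
#' @export
score_summary <- function(S, V) {
  if (!is.finite(S)) stop("score S must be finite")
  if (!is.finite(V) || V <= 0) stop("information V must be positive")
  structure(list(S = S, V = V, theta = S / V, sigma2 = 1 / V),
            class = "score_summary")
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("score summary: S = %.4f, V = %.4f, theta = %.4f (sigma2 = %.4f)\n",
              x$S, x$V, x$theta, x$sigma2))
  invisible(x)
}

## build a score_summary from (theta, sigma2) instead of (S, V)
summary_from_theta <- function(theta, sigma2) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  score_summary(S = theta / sigma2, V = 1 / sigma2)
}

#' Per-partition stagewise summaries
#'
#' Collects, for each partition, the score summaries that the estimation
#' machinery consumes:
#' \describe{
#'   \item{stage1}{stage-1 patients censored at `t1` (drives selection).}
#'   \item{tilde}{stage-1 patients censored at `t_tilde1` (or `t1` for
#'     dropped partitions that are not followed); used for stage-1
#'     p-values.}
#'   \item{combined}{all patients of a selected partition, stage-1 at
#'     `t_tilde1` pooled with stage-2 at `t2`; the naive estimate.}
#'   \item{increment}{combined minus stage1 (independent increment).}
#'   \item{stage2}{stage-2 patients only, censored at `t2`; used for
#'     stage-2 p-values.}
#' }
#' Entries that are undefined for a partition (e.g. stage-2 data of a
#' dropped partition) are `NULL`.
#'
#' @param blocks list of length `K`; each element a list with any of the
#'   components above, each either `NULL` or a [score_summary()].
#' @return An object of class `"partition_summaries"`.
#' @export
partition_summaries <- function(blocks) {
  slots <- c("stage1", "tilde", "combined", "increment", "stage2")
  if (length(blocks) == 0L) stop("no partitions")
  blocks <- lapply(blocks, function(bl) {
    bl <- bl[intersect(names(bl), slots)]
    for (nm in names(bl)) {
      if (!is.null(bl[[nm]]) && !inherits(bl[[nm]], "score_summary"))
        stop("component '", nm, "' is not a score_summary")
    }
    bl[slots[!(slots %in% names(bl))]] <- list(NULL)
    bl[slots]
  })
  structure(list(K = length(blocks), partitions = blocks),
            class = "partition_summaries")
}

## pull one component for one partition, or NULL
summary_slot <- function(x, j, slot) {
  stopifnot(inherits(x, "partition_summaries"))
  x$partitions[[j]][[slot]]
}

#' @export
print.partition_summaries <- function(x, digits = 4, ...) {
  cat(sprintf("Partition summaries (K = %d)\n", x$K))
  slots <- c("stage1", "tilde", "combined", "increment", "stage2")
  for (j in seq_len(x$K)) {
    cat(sprintf("  partition %d:", j))
    for (s in slots) {
      b <- x$partitions[[j]][[s]]
      if (!is.null(b))
        cat(sprintf(" %s %.3f (%.3f)", s, b$theta, b$sigma2))
    }
    cat("\n")
  }
  invisible(x)
}

## stage-1 estimates across partitions (vector used by selection rules)
stage1_estimates <- function(x) {
  vapply(x$partitions, function(b) b$stage1$theta, numeric(1))
}
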