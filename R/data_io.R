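#' Read subject-level trial records
#'
#' Reads a delimited (CSV) file with one row per enrolled subject and
#' columns `subject_id`, `partition`, `arm`, `entry_day`, `event_day`,
#' `last_followup_day`, `status`. Times are calendar days with day 0 the
#' start of recruitment. `event_day` is empty for censored subjects
#' (`status = 0`); `status = 1` marks an event at `event_day`. Every record
#' is validated: partitions must lie in `1..K`, arms must be `control` or
#' `experimental`, and event/follow-up days must not precede entry.
#'
#' @param path file to read.
#' @param design a [trial_design()] supplying `K`.
#' @return A data frame of validated records, with a `stage` column derived
#'   later by the analysis (stage 1 iff `entry_day <= t1`).
#' @export
read_subjects <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_subjects(df, design)
}

#' Validate subject records against the design
#'
#' @param df data frame of subject records.
#' @param design a [trial_design()].
#' @return The validated data frame (invisibly usable).
#' @export
validate_subjects <- function(df, design) {
  needed <- c("subject_id", "partition", "arm", "entry_day", "event_day",
              "last_followup_day", "status")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$partition <- as.integer(df$partition)
  df$event_day <- as.numeric(df$event_day)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$partition) || r$partition < 1 || r$partition > design$K)
      stop(sprintf("row %d: partition out of range (1..%d)", i, design$K))
    if (!(r$arm %in% c("control", "experimental")))
      stop(sprintf("row %d: field 'arm' must be control or experimental", i))
    if (is.na(r$entry_day) || r$entry_day < 0)
      stop(sprintf("row %d: field 'entry_day' must be a non-negative day", i))
    if (is.na(r$last_followup_day) || r$last_followup_day < r$entry_day)
      stop(sprintf("row %d: field 'last_followup_day' precedes entry_day", i))
    if (!(r$status %in% c(0, 1)))
      stop(sprintf("row %d: field 'status' must be 0 or 1", i))
    if (r$status == 1 && is.na(r$event_day))
      stop(sprintf("row %d: field 'event_day' required when status = 1", i))
    if (r$status == 0 && !is.na(r$event_day))
      stop(sprintf("row %d: field 'event_day' present but status = 0", i))
    if (!is.na(r$event_day) && r$event_day < r$entry_day)
      stop(sprintf("row %d: field 'event_day' precedes entry_day", i))
  }
  df
}

#' Write subject-level trial records
#'
#' Inverse of [read_subjects()]; numeric fields are written at full
#' precision so read/write round-trips are lossless.
#'
#' @param df subject records.
#' @param path file to write.
#' @export
write_subjects <- function(df, path) {
  out <- df
  for (cn in c("entry_day", "event_day", "last_followup_day"))
    out[[cn]] <- vapply(out[[cn]], function(x)
      if (is.na(x)) "" else format(x, digits = 15), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## keys used in the summary JSON, per block
.summary_keys <- list(
  stage1 = c(theta = "theta1", sigma2 = "sigma2_1", V = "V1"),
  tilde = c(theta = "theta1_tilde", sigma2 = "sigma2_1_tilde", V = "V1_tilde"),
  combined = c(theta = "thetaN", sigma2 = "sigma2_N", V = "VN"),
  increment = c(theta = "theta2", sigma2 = "sigma2_2", V = "V2"),
  stage2 = c(theta = "thetaS2", sigma2 = "sigma2_S2", V = "VS2")
)

#' Read per-partition summary statistics
#'
#' Reads a JSON file with a `partitions` array, one object per partition,
#' keyed by the conventional symbols: `theta1`/`sigma2_1` (stage 1 at
#' `t1`), `theta1_tilde`/`sigma2_1_tilde` (stage-1 patients at `t_tilde1`),
#' `thetaN`/`sigma2_N` (all data), `theta2`/`sigma2_2` (increment), and
#' `thetaS2`/`sigma2_S2` (stage-2 patients only). Informations may be given
#' instead of variances (`V1`, `VN`, ... with `V = 1/sigma2`). Blocks that
#' are absent stay absent -- they are not imputed as zero -- except that a
#' missing `combined` (or `increment`) block is completed from the other
#' two via the independent-increment identity `S_N = S_1 + S_2`,
#' `V_N = V_1 + V_2`.
#'
#' @param path JSON file.
#' @return A [partition_summaries()].
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  parts <- if (!is.null(x$partitions)) x$partitions else x
  if (length(parts) == 0L) stop("no partitions in summary file")
  blocks <- lapply(parts, function(p) {
    bl <- list()
    for (slot in names(.summary_keys)) {
      k <- .summary_keys[[slot]]
      th <- p[[k[["theta"]]]]
      s2 <- p[[k[["sigma2"]]]]
      vv <- p[[k[["V"]]]]
      if (is.null(s2) && !is.null(vv)) {
        if (vv <= 0) stop("non-positive information in block '", slot, "'")
        s2 <- 1 / vv
      }
      if (!is.null(th) && !is.null(s2)) {
        if (s2 <= 0) stop("non-positive variance in block '", slot, "'")
        bl[[slot]] <- summary_from_theta(th, s2)
      }
    }
    if (is.null(bl$combined) && !is.null(bl$stage1) && !is.null(bl$increment))
      bl$combined <- score_summary(bl$stage1$S + bl$increment$S,
                                   bl$stage1$V + bl$increment$V)
    if (is.null(bl$increment) && !is.null(bl$stage1) && !is.null(bl$combined))
      bl$increment <- increment_summary(bl$combined, bl$stage1)
    bl
  })
  partition_summaries(blocks)
}

#' Write per-partition summary statistics
#'
#' Inverse of [read_summaries()]; writes variances (not informations) at
#' full precision.
#'
#' @param summaries a [partition_summaries()].
#' @param path JSON file to write.
#' @export
write_summaries <- function(summaries, path) {
  parts <- lapply(summaries$partitions, function(bl) {
    out <- list()
    for (slot in names(.summary_keys)) {
      b <- bl[[slot]]
      if (is.null(b)) next
      k <- .summary_keys[[slot]]
      out[[k[["theta"]]]] <- b$theta
      out[[k[["sigma2"]]]] <- b$sigma2
    }
    out
  })
  jsonlite::write_json(list(partitions = parts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an estimate report
#'
#' Serializes an [run_estimate()] report to JSON: the design echo, analysis
#' times, selection with truncation bounds, and per selected partition the
#' naive estimate and UMVCUE, both confidence intervals with
#' informativeness flags, and the adjusted p-values. A futility-stop report
#' states `"stopped at interim; no estimates"`.
#'
#' @param report an `estimate_report`.
#' @param path JSON file to write.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "estimate_report"))
  x <- list(
    design = unclass(report$design),
    times = if (is.null(report$times)) NULL else unclass(report$times),
    selection = list(rule = report$selection$rule,
                     selected = report$selection$selected,
                     bounds = report$selection$bounds,
                     theta1 = report$selection$theta1)
  )
  if (!length(report$selection$selected)) {
    x$message <- "stopped at interim; no estimates"
  } else {
    x$estimates <- report$estimates
    x$duality_available <- report$duality_available
  }
  ok <- tryCatch({
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    TRUE
  }, error = function(e) stop("cannot write report to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read an estimate report written by [write_report()]
#'
#' @param path JSON file.
#' @return An `estimate_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- x$design
  opt <- function(v) if (is.null(v) || !length(v) || all(is.na(v))) NULL else v
  design <- trial_design(K = des$K, prevalences = des$prevalences, b = des$b,
                         rule = des$rule, alpha = des$alpha,
                         weights = des$weights,
                         interim_events = opt(des$interim_events),
                         stage2_events = opt(des$stage2_events),
                         tilde_offset_days = des$tilde_offset_days,
                         dropped_followed_to_tilde = des$dropped_followed_to_tilde)
  renum <- function(df) {
    # infinite bounds travel through JSON as "Inf"/"-Inf" strings
    for (cn in setdiff(names(df), "partition"))
      if (is.character(df[[cn]])) df[[cn]] <- as.numeric(df[[cn]])
    df
  }
  sel <- x$selection
  bounds <- renum(as.data.frame(sel$bounds))
  if (!nrow(bounds))
    bounds <- data.frame(partition = integer(), lower = numeric(),
                         upper = numeric())
  selection <- selection_result(sel$rule, sel$selected %||% integer(0),
                                bounds, sel$theta1)
  times <- if (!is.null(opt(x$times$t1)))
    analysis_times(x$times$t1, x$times$t_tilde1, x$times$t2)
  structure(list(design = design, times = times, selection = selection,
                 estimates = if (is.null(x$estimates)) NULL else
                   renum(as.data.frame(x$estimates)),
                 duality_available = isTRUE(x$duality_available),
                 message = x$message),
            class = "estimate_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a design configuration
#' @param design a [trial_design()].
#' @param path JSON file to write.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design configuration written by [write_design()]
#' @param path JSON file.
#' @return A [trial_design()].
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_design(K = x$K, prevalences = x$prevalences, b = x$b, rule = x$rule,
               alpha = x$alpha %||% 0.05,
               weights = x$weights %||% (c(1, 1) / sqrt(2)),
               weights_are_squared = isTRUE(x$weights_are_squared),
               interim_events = x$interim_events,
               stage2_events = x$stage2_events,
               tilde_offset_days = x$tilde_offset_days %||% 0,
               dropped_followed_to_tilde = isTRUE(x$dropped_followed_to_tilde))
}
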