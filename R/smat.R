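#' Mean gray value of an image frame
#'
#' The field-level intensity readout used by SMAT: the arithmetic mean of
#' pixel intensities over the whole frame (the default, matching a
#' low-magnification field measurement) or over an optional mask.
#'
#' @param frame A numeric matrix of non-negative pixel intensities.
#' @param mask Optional logical matrix of the same dimensions selecting
#'   the pixels to average.
#' @return A scalar mean intensity.
#' @examples
#' mean_gray_value(matrix(7, 4, 4))
#' @export
mean_gray_value <- function(frame, mask = NULL) {
  stopifnot(is.matrix(frame) || is.array(frame))
  if (length(frame) == 0) stop("empty frame")
  if (is.null(mask)) return(mean(frame))
  stopifnot(identical(dim(mask), dim(frame)))
  if (!any(mask)) stop("empty mask")
  mean(frame[mask])
}

trace_cols <- c("condition", "replicate", "field", "time_min", "value")

check_trace_table <- function(traces) {
  stopifnot(is.data.frame(traces))
  miss <- setdiff(trace_cols, names(traces))
  if (length(miss)) stop("trace table missing columns: ",
                         paste(miss, collapse = ", "))
  invisible(traces)
}

trace_id <- function(traces) {
  interaction(traces$condition, traces$replicate, traces$field, drop = TRUE)
}

#' Normalize an intensity trace to its first timepoint
#'
#' Divides every value of a single field trace by its value at the first
#' (post-wash reference) timepoint, so the output starts at exactly 1.
#'
#' @param trace A data frame with columns `time_min` and `value` for one
#'   field trace, ordered by time (extra metadata columns are preserved).
#' @return The same data frame with `value` replaced by the ratio to the
#'   first timepoint.
#' @examples
#' normalize_trace(data.frame(time_min = 0:2, value = c(10, 5, 2.5)))
#' @export
normalize_trace <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time_min", "value") %in% names(trace)))
  trace <- trace[order(trace$time_min), , drop = FALSE]
  v0 <- trace$value[1]
  if (!is.finite(v0) || v0 <= 0) {
    where <- paste(c(
      if ("condition" %in% names(trace)) paste0("condition ", trace$condition[1]),
      if ("field" %in% names(trace)) paste0("field ", trace$field[1])),
      collapse = ", ")
    stop("cannot normalize: reference value at first timepoint is ", v0,
         if (nzchar(where)) paste0(" (", where, ")") else "")
  }
  trace$value <- trace$value / v0
  trace
}

#' Normalize every trace in a long trace table
#'
#' Applies [normalize_trace()] independently to each
#' condition x replicate x field trace of a long-format table.
#'
#' @param traces Data frame with columns `condition`, `replicate`,
#'   `field`, `time_min`, `value`.
#' @return The table with each trace normalized to its first timepoint.
#' @export
normalize_traces <- function(traces) {
  check_trace_table(traces)
  parts <- split(traces, trace_id(traces))
  out <- do.call(rbind, lapply(parts, normalize_trace))
  rownames(out) <- NULL
  out
}

#' Aggregate normalized traces into a condition decay curve
#'
#' Pointwise ratiometric mean and standard error of the mean across the
#' replicate x field traces of one condition — the quantity plotted in a
#' SMAT decay figure.
#'
#' @param traces Long table of normalized traces for a single condition
#'   (>= 2 traces on identical time grids).
#' @return A data frame with columns `condition`, `time_min`, `mean`,
#'   `sem`, `n`.
#' @export
aggregate_condition <- function(traces) {
  check_trace_table(traces)
  if (length(unique(traces$condition)) != 1)
    stop("aggregate_condition expects a single condition")
  ids <- trace_id(traces)
  if (nlevels(ids) < 2) stop("need at least 2 traces to aggregate")
  grids <- lapply(split(traces$time_min, ids), sort)
  if (length(unique(lapply(grids, as.numeric))) != 1)
    stop("traces have mismatched time grids")
  tp <- sort(unique(traces$time_min))
  M <- vapply(split(traces, ids), function(tr) {
    tr$value[order(tr$time_min)]
  }, numeric(length(tp)))
  n <- ncol(M)
  data.frame(condition = traces$condition[1], time_min = tp,
             mean = rowMeans(M),
             sem = apply(M, 1, stats::sd) / sqrt(n),
             n = n)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-timepoint comparison of decay curves against a reference condition
#'
#' Fits a two-way ANOVA (factors: condition and time; each normalized
#' field trace contributes one observation per timepoint) and then, in
#' the style of Prism's posttests, compares every non-reference condition
#' to the reference at each timepoint using the pooled residual variance,
#' Bonferroni-correcting the p-values across timepoints. Stars follow the
#' usual convention (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @param traces Long table of normalized traces covering >= 2 conditions
#'   on a common time grid.
#' @param reference Name of the reference condition.
#' @return An object of class `condition_comparison`: a list with the
#'   per-timepoint `table` (condition, time_min, diff, p, p_adj, stars),
#'   the `anova` table, and the `reference` label.
#' @export
compare_conditions <- function(traces, reference) {
  check_trace_table(traces)
  conds <- unique(as.character(traces$condition))
  if (!(reference %in% conds)) stop("reference condition not present: ", reference)
  if (length(conds) < 2) stop("need at least 2 conditions to compare")
  for (cn in conds) {
    sub <- traces[traces$condition == cn, ]
    if (nlevels(droplevels(trace_id(sub))) < 2)
      stop("condition ", cn, " has fewer than 2 traces")
  }
  tp <- sort(unique(traces$time_min))
  d <- data.frame(value = traces$value,
                  condition = factor(traces$condition),
                  time = factor(traces$time_min, levels = tp))
  fit <- if (length(tp) > 1) {
    stats::aov(value ~ condition * time, data = d)
  } else {
    stats::aov(value ~ condition, data = d)  # degenerate single-frame design
  }
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]

  rows <- list()
  for (cn in setdiff(conds, reference)) {
    for (t in tp) {
      v1 <- d$value[d$condition == cn & d$time == t]
      v0 <- d$value[d$condition == reference & d$time == t]
      diffm <- mean(v1) - mean(v0)
      sed <- sqrt(mse * (1 / length(v1) + 1 / length(v0)))
      p <- if (diffm == 0) 1
           else if (sed == 0 || dfres <= 0) 0
           else 2 * stats::pt(-abs(diffm / sed), dfres)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cn, time_min = t, diff = diffm, p = p)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- pmin(1, tab$p * length(tp))
  tab$stars <- significance_stars(tab$p_adj)
  rownames(tab) <- NULL
  structure(list(table = tab, anova = an, reference = reference,
                 n_timepoints = length(tp)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Per-timepoint comparisons vs reference '", x$reference,
      "' (Bonferroni over ", x$n_timepoints, " timepoints)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Pre/post analysis around a media switch
#'
#' Splits the traces at `switch_time`, compares conditions separately in
#' the two windows, and re-expresses the post-switch window relative to
#' each trace's value at the switch frame (a fresh ratiometric reference),
#' because curves have typically already decayed substantially by the
#' time the media are swapped.
#'
#' @inheritParams compare_conditions
#' @param switch_time Time (min) of the media switch; must coincide with
#'   a grid timepoint inside the observed range.
#' @return A list with elements `pre` and `post`, each a
#'   `condition_comparison` (`pre` is `NULL` when the switch is at the
#'   first timepoint, in which case `post` equals a plain comparison).
#' @export
segment_switch_analysis <- function(traces, switch_time, reference) {
  check_trace_table(traces)
  tp <- sort(unique(traces$time_min))
  if (switch_time < tp[1] || switch_time > tp[length(tp)])
    stop("switch_time ", switch_time, " lies outside the time grid")
  hit <- which(abs(tp - switch_time) < 1e-9)
  if (!length(hit)) stop("switch_time must coincide with a grid timepoint")
  ts <- tp[hit[1]]

  post_raw <- traces[traces$time_min >= ts, , drop = FALSE]
  post <- do.call(rbind, lapply(split(post_raw, trace_id(post_raw)), function(tr) {
    tr <- tr[order(tr$time_min), , drop = FALSE]
    tr$value <- tr$value / tr$value[1]
    tr
  }))
  rownames(post) <- NULL
  post_cmp <- compare_conditions(post, reference)

  pre_cmp <- NULL
  if (ts > tp[1]) {
    pre <- traces[traces$time_min <= ts, , drop = FALSE]
    pre_cmp <- compare_conditions(pre, reference)
  }
  list(pre = pre_cmp, post = post_cmp)
}

#' Convert an image series into an intensity trace
#'
#' Computes the per-frame mean gray value of a time-lapse image series,
#' with optional constant background subtraction (useful for synthetic
#' stacks rendered over a dim detached-probe background; the assay's
#' standard raw measurement uses none).
#'
#' @param frames List of numeric matrices, one per timepoint (time order).
#' @param times Acquisition times (min), same length as `frames`.
#' @param condition,replicate,field Metadata carried into the trace.
#' @param background Constant background level to subtract from each mean
#'   (default 0 = raw mean gray value), or `"auto"` to estimate it as the
#'   25th intensity percentile of the first frame.
#' @return A one-trace data frame with the standard trace columns.
#' @export
image_series_trace <- function(frames, times, condition, replicate = 1L,
                               field = 1L, background = 0) {
  stopifnot(length(frames) == length(times))
  if (identical(background, "auto"))
    background <- stats::quantile(frames[[1]], 0.25, names = FALSE)
  vals <- vapply(frames, mean_gray_value, numeric(1)) - background
  vals <- pmax(vals, 0)
  data.frame(condition = condition, replicate = replicate, field = field,
             time_min = as.numeric(times), value = vals)
}
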