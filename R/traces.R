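#' Construct a trace set
#'
#' Single-particle traces (e.g. from kymograph trace detection) as sequences
#' of (time, position) points. Trace detection itself is not part of this
#' package; traces enter as tabular input, and exclusion of ambiguous traces
#' (crossings, merging) is the caller's responsibility.
#'
#' @param traces Either a list of data frames with columns `time_s` and
#'   `position_um`, or one long data frame with an additional `trace` id
#'   column.
#' @return A `trace_set` (list of per-trace data frames).
#' @export
trace_set <- function(traces) {
  if (is.data.frame(traces)) {
    stopifnot(all(c("trace", "time_s", "position_um") %in% names(traces)))
    traces <- lapply(split(traces, traces$trace),
                     function(d) d[c("time_s", "position_um")])
  }
  for (i in seq_along(traces)) {
    d <- traces[[i]]
    if (!all(c("time_s", "position_um") %in% names(d)))
      stop("trace ", i, " lacks time_s/position_um columns")
    if (nrow(d) < 2L) stop("trace ", i, " has fewer than 2 points")
    if (is.unsorted(d$time_s, strictly = TRUE))
      stop("times must be strictly increasing within trace ", i)
  }
  structure(unname(traces), class = "trace_set")
}

#' Trace velocity statistics
#'
#' Per-trace velocity is the slope of the least-squares line of position
#' against time over the full trace; the summary is the median velocity
#' across traces and the standard error of the mean (s.d. across traces
#' divided by sqrt(N)). Minus-end-directed traces simply yield negative
#' velocities.
#'
#' @param traces A [trace_set()] (or anything it accepts).
#' @return A list with `median_velocity` (um/s), `sem` (um/s), `n`, and the
#'   per-trace `velocities`.
#' @examples
#' tr <- trace_set(list(data.frame(time_s = c(0, 10), position_um = c(0, 1.2))))
#' trace_velocities(tr)$median_velocity  # 0.12 um/s
#' @export
trace_velocities <- function(traces) {
  if (!inherits(traces, "trace_set")) traces <- trace_set(traces)
  v <- vapply(traces, function(d) {
    span <- diff(range(d$time_s))
    if (span <= 0) stop("degenerate trace: zero time span")
    tc <- d$time_s - mean(d$time_s)
    sum(tc * (d$position_um - mean(d$position_um))) / sum(tc^2)
  }, numeric(1))
  list(median_velocity = stats::median(v),
       sem = stats::sd(v) / sqrt(length(v)),
       n = length(v),
       velocities = v)
}
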