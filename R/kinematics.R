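#' Kinematic analysis of a selected segment of an event
#'
#' Over a user-selected sub-window of one event, integrates acceleration
#' to velocity and velocity to displacement (cumulative trapezoidal rule,
#' starting from rest: v = 0 and s = 0 at the segment start) and derives
#' the absolute-value channel of each quantity per sample.  Minima, maxima
#' and means are reported for all twelve quantity-by-component
#' combinations (acceleration/velocity/displacement x x/y/z/abs).
#'
#' The segment is half-open, 0-based: samples `start_idx` to
#' `end_idx - 1`.  The start-at-rest assumption is appropriate for
#' segments beginning before movement onset; no detrending or drift
#' correction is applied inside the segment.
#'
#' @param event Data frame of one event's samples (see [get_event()]).
#' @param start_idx,end_idx Half-open 0-based segment bounds;
#'   `0 <= start_idx < end_idx <= nrow(event)`.  Defaults select the whole
#'   event.
#' @param dt Sample period in seconds (1 / sampling rate).
#' @return An object of class `segment_analysis`: list with `t` (segment
#'   time axis, seconds from segment start), `acceleration`, `velocity`,
#'   `displacement` (each a data frame with columns `x`, `y`, `z`, `abs`)
#'   and `summary` (data frame with `quantity`, `component`, `min`, `max`,
#'   `mean`).
#' @export
#' @examples
#' ev <- data.frame(ax = rep(2, 1000), ay = 0, az = 0)
#' sa <- analyze_segment(ev, dt = 1e-3)
#' tail(sa$velocity$x, 1)       # ~2 m/s after 1 s at 2 m/s^2
#' tail(sa$displacement$x, 1)   # ~1 m   (s = a t^2 / 2)
analyze_segment <- function(event, start_idx = 0L,
                            end_idx = nrow(event), dt) {
  a_full <- .axes_matrix(event)
  n <- nrow(a_full)
  if (start_idx < 0 || end_idx > n || start_idx >= end_idx)
    stop(sprintf("invalid segment [%d, %d) for an event of %d samples",
                 start_idx, end_idx, n))
  a <- a_full[(start_idx + 1):end_idx, , drop = FALSE]
  m <- nrow(a)
  tt <- (seq_len(m) - 1) * dt
  v <- if (m > 1) pracma::cumtrapz(tt, a) else matrix(0, 1, 3)
  s <- if (m > 1) pracma::cumtrapz(tt, v) else matrix(0, 1, 3)
  channelize <- function(x) data.frame(x = x[, 1], y = x[, 2], z = x[, 3],
                                       abs = sqrt(rowSums(x^2)))
  acc <- channelize(a); vel <- channelize(v); dis <- channelize(s)
  smry <- do.call(rbind, lapply(
    list(acceleration = acc, velocity = vel, displacement = dis),
    function(q) data.frame(component = names(q),
                           min = vapply(q, min, 0),
                           max = vapply(q, max, 0),
                           mean = vapply(q, mean, 0))))
  smry <- data.frame(quantity = rep(c("acceleration", "velocity",
                                      "displacement"), each = 4),
                     smry, row.names = NULL)
  structure(list(t = tt, acceleration = acc, velocity = vel,
                 displacement = dis, summary = smry,
                 start_idx = as.integer(start_idx),
                 end_idx = as.integer(end_idx), dt = dt),
            class = "segment_analysis")
}

#' @export
print.segment_analysis <- function(x, ...) {
  cat(sprintf("<segment_analysis> samples [%d, %d), dt = %g s\n",
              x$start_idx, x$end_idx, x$dt))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
plot.segment_analysis <- function(x, component = "abs", ...) {
  old <- par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(par(old))
  plot(x$t, x$acceleration[[component]], type = "l", xlab = "",
       ylab = "acceleration [m/s²]", ...)
  plot(x$t, x$velocity[[component]], type = "l", xlab = "",
       ylab = "velocity [m/s]", ...)
  plot(x$t, x$displacement[[component]], type = "l", xlab = "time [s]",
       ylab = "displacement [m]", ...)
  invisible(x)
}

#' Peak acceleration of one event
#'
#' The maximum of the chosen acceleration component over the event's
#' samples.  The default component is the absolute value, the only
#' rotation-invariant choice; the signal is expected to be
#' offset-calibrated first so the peak reflects movement, not orientation.
#'
#' @param event Data frame of one event's samples.
#' @param component `"abs"` (default), `"x"`, `"y"` or `"z"`.
#' @return Peak acceleration in m/s^2.
#' @export
event_peak <- function(event, component = c("abs", "x", "y", "z")) {
  component <- match.arg(component)
  a <- .axes_matrix(event)
  if (nrow(a) == 0L) stop("cannot compute the peak of an empty event")
  ch <- switch(component,
               abs = sqrt(rowSums(a^2)),
               x = a[, 1], y = a[, 2], z = a[, 3])
  max(ch)
}

#' Per-event peak accelerations of a whole recording
#'
#' Computes [event_peak()] for every event.  Refuses uncalibrated
#' recordings unless `force = TRUE`, because peaks on a signal still
#' containing gravity measure sensor orientation rather than movement
#' (see [calibrate_recording()]).
#'
#' @param rec A [recording()].
#' @param component Passed to [event_peak()].
#' @param force Compute peaks even if `rec` is not marked calibrated.
#' @return Data frame with columns `block_id`, `event_id`, `peak`.
#' @export
recording_peaks <- function(rec, component = "abs", force = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (!isTRUE(rec$meta$calibrated) && !force)
    stop("recording is not offset-calibrated; peaks would measure ",
         "orientation, not movement. Run calibrate_recording() first or ",
         "pass force = TRUE.")
  ev <- list_events(rec)
  if (nrow(ev) == 0L)
    return(data.frame(block_id = integer(), event_id = integer(),
                      peak = numeric()))
  ev$peak <- vapply(seq_len(nrow(ev)), function(i)
    event_peak(get_event(rec, ev$block_id[i], ev$event_id[i]), component),
    0)
  ev[, c("block_id", "event_id", "peak")]
}

#' Per-block summary of event peak accelerations
#'
#' For each block, the mean and sample standard deviation (n - 1
#' convention) of the per-event peaks — the summary behind block-wise
#' learning curves.  SD is `NA` for single-event blocks.
#'
#' @param x A [recording()] (calibrated, or `force = TRUE`) or a data
#'   frame of peaks as returned by [recording_peaks()].
#' @param component,force Passed to [recording_peaks()] when `x` is a
#'   recording.
#' @return An object of class `block_stats`: data frame with columns
#'   `block_id`, `n_events`, `mean_peak`, `sd_peak`, carrying the
#'   per-event peak table as attribute `"peaks"`.
#' @export
#' @examples
#' bs <- block_stats(data.frame(block_id = 0, event_id = 0:2,
#'                              peak = c(1, 2, 3)))
#' bs$mean_peak  # 2
#' bs$sd_peak    # 1
block_stats <- function(x, component = "abs", force = FALSE) {
  peaks <- if (inherits(x, "recording"))
    recording_peaks(x, component = component, force = force)
  else as.data.frame(x)
  stopifnot(all(c("block_id", "peak") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("no events to summarise")
  out <- do.call(rbind, lapply(split(peaks, peaks$block_id), function(p)
    data.frame(block_id = p$block_id[1],
               n_events = nrow(p),
               mean_peak = mean(p$peak),
               sd_peak = if (nrow(p) > 1) sd(p$peak) else NA_real_)))
  out <- out[order(out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peaks") <- peaks
  class(out) <- c("block_stats", "data.frame")
  out
}

#' @export
print.block_stats <- function(x, ...) {
  cat("Peak acceleration by block [m/s²]:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (nrow(x) >= 2 && x$mean_peak[1] > 0)
    cat(sprintf("last vs first block: %+.1f%%\n", percent_change(x)))
  invisible(x)
}

#' @export
plot.block_stats <- function(x, ...) {
  ylim <- range(c(x$mean_peak - x$sd_peak, x$mean_peak + x$sd_peak),
                na.rm = TRUE)
  plot(x$block_id + 1, x$mean_peak, type = "b", pch = 19, ylim = ylim,
       xlab = "block", ylab = "mean peak acceleration [m/s²]", ...)
  ok <- !is.na(x$sd_peak)
  arrows(x$block_id[ok] + 1, x$mean_peak[ok] - x$sd_peak[ok],
         x$block_id[ok] + 1, x$mean_peak[ok] + x$sd_peak[ok],
         angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Percent change of mean peak acceleration, last vs first block
#'
#' `(last - first) / first * 100`, the index used to quantify change in
#' ballistic performance across a session: positive values mean the last
#' block's mean peak exceeds the first's.
#'
#' @param first A [block_stats()] table (then the change from its first to
#'   its last row is returned), a single-block stats row, or a plain
#'   numeric mean.
#' @param last Single-block stats row or numeric mean; ignored when
#'   `first` is a multi-row table.
#' @return Percent change (numeric scalar).
#' @export
#' @examples
#' percent_change(2.00, 3.05)  # +52.5
percent_change <- function(first, last = NULL) {
  pick <- function(x, i) {
    if (inherits(x, "data.frame")) x$mean_peak[i] else as.numeric(x)
  }
  if (is.null(last)) {
    stopifnot(inherits(first, "data.frame"), nrow(first) >= 2)
    last_v <- pick(first, nrow(first))
    first_v <- pick(first, 1L)
  } else {
    first_v <- pick(first, 1L)
    last_v <- pick(last, nrow_or_one(last))
  }
  if (!is.finite(first_v) || first_v <= 0)
    stop("baseline (first block) mean peak must be positive, got ", first_v)
  (last_v - first_v) / first_v * 100
}

nrow_or_one <- function(x) if (inherits(x, "data.frame")) nrow(x) else 1L

#' Export block statistics and per-event peaks as TSV
#'
#' Writes `<base>.blocks.tsv` (block_id, n_events, mean_peak, sd_peak) and
#' `<base>.peaks.tsv` (block_id, event_id, peak), six-decimal fixed
#' notation, for further statistical analysis outside R.
#'
#' @param stats A [block_stats()] object.
#' @param basepath Base path (without suffix) of the two files.
#' @return Invisibly, a named character vector of the two paths.
#' @export
export_stats <- function(stats, basepath) {
  paths <- c(blocks = paste0(basepath, ".blocks.tsv"),
             peaks = paste0(basepath, ".peaks.tsv"))
  b <- as.data.frame(stats)
  b$mean_peak <- sprintf("%.6f", b$mean_peak)
  b$sd_peak <- ifelse(is.na(b$sd_peak), "NA", sprintf("%.6f", b$sd_peak))
  write.table(b, paths["blocks"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  p <- attr(stats, "peaks")
  if (is.null(p))
    p <- data.frame(block_id = integer(), event_id = integer(),
                    peak = numeric())
  p$peak <- sprintf("%.6f", p$peak)
  write.table(p, paths["peaks"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
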