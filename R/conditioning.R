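#' Estimate per-axis sensor offsets from a static window
#'
#' Automatic offset calibration: on a window in which the sensor is known
#' to be at rest, the per-axis mean acceleration is the constant bias to
#' remove.  Gravity handling is explicit — if `gravity_axis` names an axis,
#' one g (9.81 m/s^2) is preserved on that axis, i.e. the offset there is
#' `mean - g0`; with `gravity_axis = "none"` all axes are driven to zero
#' mean, which removes the gravity component along with the bias.
#'
#' @param series Data frame or matrix with acceleration columns
#'   `ax`, `ay`, `az` (m/s^2), assumed static over its whole extent.
#' @param gravity_axis `"none"` (default), `"x"`, `"y"` or `"z"`.
#' @param sampling_rate_hz Sampling rate of `series`, used to enforce the
#'   minimum window length of 0.5 s.
#' @return An object of class `offset_estimate`: list with `offset`
#'   (named 3-vector, m/s^2), `gravity_axis` and `window` (index range
#'   used).
#' @seealso [apply_offset()], [calibrate_recording()]
#' @export
#' @examples
#' s <- data.frame(ax = rep(0.1, 600), ay = rep(-0.2, 600),
#'                 az = rep(9.91, 600))
#' estimate_offset(s, gravity_axis = "z", sampling_rate_hz = 1000)$offset
estimate_offset <- function(series, gravity_axis = "none",
                            sampling_rate_hz = 1000) {
  a <- .axes_matrix(series)
  n <- nrow(a)
  if (n < 0.5 * sampling_rate_hz)
    stop(sprintf(paste("calibration window too short: %d samples < 0.5 s",
                       "at %g Hz (%d samples)"),
                 n, sampling_rate_hz, ceiling(0.5 * sampling_rate_hz)))
  offset <- colMeans(a)
  g <- .gravity_vector(gravity_axis)
  offset <- offset - g
  names(offset) <- c("x", "y", "z")
  structure(list(offset = offset, gravity_axis = gravity_axis,
                 window = c(1L, n)),
            class = "offset_estimate")
}

#' @export
print.offset_estimate <- function(x, ...) {
  cat(sprintf("<offset_estimate> (%.4g, %.4g, %.4g) m/s^2, gravity on %s\n",
              x$offset[1], x$offset[2], x$offset[3], x$gravity_axis))
  invisible(x)
}

#' Subtract an estimated offset from an acceleration series
#'
#' @param series Data frame or matrix with columns `ax`, `ay`, `az`.
#' @param est An [estimate_offset()] result, or a plain numeric 3-vector.
#' @return `series` with the offset removed per axis (same type/columns).
#' @export
apply_offset <- function(series, est) {
  offset <- if (inherits(est, "offset_estimate")) est$offset else est
  stopifnot(length(offset) == 3)
  if (is.matrix(series)) {
    series - matrix(offset, nrow(series), 3, byrow = TRUE)
  } else {
    for (i in 1:3) series[[.axis_cols[i]]] <- series[[.axis_cols[i]]] - offset[i]
    series
  }
}

.axes_matrix <- function(series) {
  if (is.matrix(series)) {
    stopifnot(ncol(series) == 3)
    return(series)
  }
  missing_cols <- setdiff(.axis_cols, names(series))
  if (length(missing_cols))
    stop("series lacks acceleration columns: ",
         paste(missing_cols, collapse = ", "))
  as.matrix(series[, .axis_cols])
}

#' First-order high-pass filter for drift removal
#'
#' Applies a first-order Butterworth high-pass (a first-order recursive
#' filter) independently to each axis.  A constant (DC) input decays to
#' zero; frequencies well above the cutoff pass essentially unchanged.
#' Typical use is removal of slow MEMS baseline drift with a cutoff far
#' below movement frequencies (default hardware setting: 0.1 Hz).
#'
#' @param series Data frame or matrix with columns `ax`, `ay`, `az`, or a
#'   plain numeric vector (single channel).
#' @param cutoff_hz Cutoff frequency, 0 < cutoff < Nyquist.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Filtered series, same shape as the input.
#' @export
highpass <- function(series, cutoff_hz, sampling_rate_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2)
    stop(sprintf("cutoff_hz must lie in (0, %g) Hz, got %g",
                 sampling_rate_hz / 2, cutoff_hz))
  flt <- signal::butter(1, cutoff_hz / (sampling_rate_hz / 2), type = "high")
  apply_channel <- function(x) as.numeric(signal::filter(flt, x))
  if (is.numeric(series) && is.null(dim(series)))
    return(apply_channel(series))
  if (is.matrix(series))
    return(apply(series, 2, apply_channel))
  for (col in .axis_cols) series[[col]] <- apply_channel(series[[col]])
  series
}

#' Per-sample acceleration magnitude
#'
#' The absolute value channel `sqrt(ax^2 + ay^2 + az^2)` — the
#' rotation-invariant quantity displayed alongside the three axis channels
#' and used by default for peak detection.
#'
#' @param series Data frame or matrix with columns `ax`, `ay`, `az`.
#' @return Numeric vector of magnitudes, in m/s^2.
#' @export
#' @examples
#' magnitude(data.frame(ax = 6.94, ay = 6.94, az = 0))  # ~9.81 (1 g)
magnitude <- function(series) {
  a <- .axes_matrix(series)
  sqrt(rowSums(a^2))
}

#' Saturate readings beyond the sensor's full scale
#'
#' Values outside +/- `range_g` * 9.81 m/s^2 are clipped to the rail and
#' flagged, mirroring what the physical sensor would report; nothing is
#' dropped.
#'
#' @param series Data frame or matrix with columns `ax`, `ay`, `az`.
#' @param range_g Full-scale range in g (2, 4 or 8).
#' @return `series` clipped, with attribute `"clipped"`: logical vector
#'   marking samples where any axis saturated.
#' @export
clip_range <- function(series, range_g = 8) {
  if (!range_g %in% c(2, 4, 8))
    stop("range_g must be one of 2, 4 or 8")
  rail <- range_g * G0
  a <- .axes_matrix(series)
  clipped_mat <- abs(a) > rail
  a <- pmin(pmax(a, -rail), rail)
  if (is.matrix(series)) {
    out <- a
  } else {
    out <- series
    for (i in 1:3) out[[.axis_cols[i]]] <- a[, i]
  }
  attr(out, "clipped") <- apply(clipped_mat, 1, any)
  out
}

#' Offset-calibrate a whole recording
#'
#' Estimates a single per-axis offset from the pooled pre-movement windows
#' of all events (the first `static_window_s` seconds after each trigger,
#' during which the subject has not yet reacted to the cue) and subtracts
#' it from every sample.  With the default `gravity_axis = "none"` every
#' axis is driven to zero mean on the static window, which removes the
#' static gravity component together with the sensor bias — the
#' preparation peak detection requires, so that peaks measure movement
#' rather than orientation.  Naming a `gravity_axis` instead preserves
#' 1 g on that axis (see [estimate_offset()]), useful when the physical
#' gravity reading itself is of interest.  The recording is marked
#' calibrated; peak-extraction functions refuse uncalibrated recordings
#' unless forced.
#'
#' @param rec A [recording()].
#' @param gravity_axis `"none"` (default; removes gravity and bias), or
#'   the axis on which 1 g should be preserved.
#' @param static_window_s Length of the per-event static window in
#'   seconds; the pooled window must reach 0.5 s in total.
#' @return The calibrated [recording()] with `meta$calibrated = TRUE` and
#'   the estimate stored in `meta$offset_estimate`.
#' @export
calibrate_recording <- function(rec, gravity_axis = "none",
                                static_window_s = 0.1) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$meta$hardware$sampling_rate_hz
  n_win <- max(1L, as.integer(round(static_window_s * fs)))
  ev <- list_events(rec)
  if (nrow(ev) == 0L) stop("cannot calibrate an empty recording")
  d <- rec$data
  key <- paste(d$block_id, d$event_id)
  # index within event: position since the event's first sample
  idx_in_event <- sequence(rle(key)$lengths)
  static <- d[idx_in_event <= n_win, , drop = FALSE]
  # the pooled pre-movement window must still satisfy the 0.5 s minimum
  est <- estimate_offset(static, gravity_axis = gravity_axis,
                         sampling_rate_hz = fs)
  rec$data <- apply_offset(rec$data, est)
  rec$meta$calibrated <- TRUE
  rec$meta$offset_estimate <- est
  rec
}
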