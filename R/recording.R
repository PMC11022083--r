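#' Hardware configuration of the acquisition device
#'
#' Describes the sensor and board settings that govern a recording: the
#' accelerometer full scale (in g), the sampling rate, the optional on-board
#' first-order high-pass filter, the cue beep duration and the trigger edge
#' for externally triggered acquisition.
#'
#' @param range_g Full-scale acceleration range in g; one of 2, 4 or 8.
#' @param sampling_rate_hz Sampling rate in Hz, between 4 and 4000.
#' @param highpass_enabled Logical; whether the high-pass stage is applied.
#' @param highpass_cutoff_hz High-pass cutoff frequency in Hz (used only
#'   when `highpass_enabled` is `TRUE`).
#' @param beep_duration_ms Duration of the acoustic cue in milliseconds.
#' @param trigger_edge `"rising"` or `"falling"`; which edge of the external
#'   trigger input starts an event.
#' @return An object of class `hardware_config` (a named list).
#' @export
#' @examples
#' hardware_config(range_g = 8, sampling_rate_hz = 1000)
hardware_config <- function(range_g = 8,
                            sampling_rate_hz = 1000,
                            highpass_enabled = FALSE,
                            highpass_cutoff_hz = 0.1,
                            beep_duration_ms = 100,
                            trigger_edge = c("rising", "falling")) {
  trigger_edge <- match.arg(trigger_edge)
  if (!range_g %in% c(2, 4, 8))
    stop("range_g must be one of 2, 4 or 8 (g), got ", range_g)
  if (sampling_rate_hz < 4 || sampling_rate_hz > 4000)
    stop("sampling_rate_hz must lie in [4, 4000] Hz, got ", sampling_rate_hz)
  if (highpass_enabled &&
      (highpass_cutoff_hz <= 0 || highpass_cutoff_hz >= sampling_rate_hz / 2))
    stop("highpass_cutoff_hz must lie in (0, sampling_rate_hz/2)")
  structure(list(range_g = as.numeric(range_g),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 highpass_enabled = isTRUE(highpass_enabled),
                 highpass_cutoff_hz = as.numeric(highpass_cutoff_hz),
                 beep_duration_ms = as.numeric(beep_duration_ms),
                 trigger_edge = trigger_edge),
            class = "hardware_config")
}

#' Assemble a recording from a sample table
#'
#' A recording is the in-memory form of one acquisition session: an ordered
#' table of samples, each tagged with its `sample_id`, `block_id` and
#' `event_id`, plus wall-clock timestamps and metadata (subject fields,
#' hardware and protocol configuration).  Samples are stored as a single
#' data frame rather than nested event objects; events and blocks are
#' addressed through their ID columns (see [get_event()], [get_block()]).
#'
#' The sample table must contain columns `sample_id`, `block_id`,
#' `event_id`, `t` (seconds since recording start) and `ax`, `ay`, `az`
#' (acceleration in m/s^2).  Optional columns `raw_x`, `raw_y`, `raw_z`
#' (integer sensor counts) and `temperature` (degrees C) are kept when
#' present and omitted from files when absent.
#'
#' @param data Data frame of samples as described above.
#' @param hardware A [hardware_config()].
#' @param protocol A [protocol_config()] or `NULL` for recordings not
#'   produced by the protocol engine.
#' @param subject Named character vector or list of free-text subject fields.
#' @param timestamps Data frame with columns `sample_id`, `time` (ISO-8601
#'   wall-clock string with millisecond precision) and `marker` (`""`,
#'   `"break"` or `"delay"`); generated from `start_time` when `NULL`.
#' @param start_time Wall-clock time of the first sample, used to synthesise
#'   timestamps when `timestamps` is `NULL`.
#' @param created Creation timestamp string stored in the metadata.
#' @param calibrated Logical; whether the acceleration columns have already
#'   been offset-calibrated (see [calibrate_recording()]).
#' @return An object of class `recording`: a list with elements `data`,
#'   `timestamps` and `meta`.
#' @seealso [write_recording()], [read_recording()], [validate_recording()]
#' @export
recording <- function(data,
                      hardware = hardware_config(),
                      protocol = NULL,
                      subject = character(),
                      timestamps = NULL,
                      start_time = "2000-01-01T00:00:00.000",
                      created = start_time,
                      calibrated = FALSE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(.required_cols, names(data))
  if (length(missing_cols))
    stop("sample table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  data <- data[, intersect(.data_cols, names(data)), drop = FALSE]
  rownames(data) <- NULL
  for (col in intersect(c("sample_id", "block_id", "event_id",
                          "raw_x", "raw_y", "raw_z"), names(data)))
    data[[col]] <- as.integer(data[[col]])
  if (is.null(timestamps))
    timestamps <- .make_timestamps(data, start_time)
  timestamps <- as.data.frame(timestamps)
  rownames(timestamps) <- NULL
  meta <- list(
    subject = as.list(subject),
    n_blocks = if (nrow(data)) length(unique(data$block_id)) else 0L,
    n_events = if (nrow(data))
      nrow(unique(data[, c("block_id", "event_id")])) else 0L,
    hardware = hardware,
    protocol = protocol,
    created = created,
    calibrated = isTRUE(calibrated)
  )
  structure(list(data = data, timestamps = timestamps, meta = meta),
            class = "recording")
}

# Wall-clock stamps: start_time + t, ISO-8601 with ms. The first sample of
# every block after the first is marked "break" (it follows the inter-block
# pause); all other samples carry an empty marker.
.make_timestamps <- function(data, start_time) {
  n <- nrow(data)
  if (n == 0L)
    return(data.frame(sample_id = integer(), time = character(),
                      marker = character(), stringsAsFactors = FALSE))
  t0 <- as.POSIXct(start_time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (is.na(t0)) stop("start_time must be ISO-8601, got ", start_time)
  stamp <- format(t0 + data$t, "%Y-%m-%dT%H:%M:%OS3")
  marker <- character(n)
  new_block <- c(FALSE, diff(data$block_id) != 0)
  marker[new_block] <- "break"
  data.frame(sample_id = data$sample_id, time = stamp, marker = marker,
             stringsAsFactors = FALSE)
}

#' @export
print.recording <- function(x, ...) {
  m <- x$meta
  cat("<recording>", m$n_blocks, "block(s),", m$n_events, "event(s),",
      nrow(x$data), "samples\n")
  cat("  sampling rate:", m$hardware$sampling_rate_hz, "Hz, range +/-",
      m$hardware$range_g, "g\n")
  if (!is.null(m$protocol))
    cat("  protocol:", m$protocol$mode, "\n")
  cat("  calibrated:", m$calibrated, "\n")
  invisible(x)
}

#' @export
summary.recording <- function(object, ...) {
  d <- object$data
  ev <- if (nrow(d))
    aggregate(sample_id ~ block_id + event_id, d, length) else NULL
  cat("Recording with", object$meta$n_blocks, "block(s) and",
      object$meta$n_events, "event(s)\n")
  if (nrow(d)) {
    cat("Samples per event:",
        paste(range(ev$sample_id), collapse = "-"), "\n")
    cat("Duration (sample clock):", max(d$t) - min(d$t), "s\n")
    amag <- magnitude(d)
    cat("Acceleration magnitude [m/s^2]: min", signif(min(amag), 4),
        " mean", signif(mean(amag), 4), " max", signif(max(amag), 4), "\n")
  }
  invisible(object)
}

#' Extract one event or one block from a recording
#'
#' @param rec A [recording()].
#' @param block_id,event_id Zero-based IDs; `event_id` is scoped within its
#'   block.
#' @return A data frame of the event's (or block's) samples.
#' @export
get_event <- function(rec, block_id, event_id) {
  stopifnot(inherits(rec, "recording"))
  out <- rec$data[rec$data$block_id == block_id &
                  rec$data$event_id == event_id, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no samples for block ", block_id, ", event ", event_id)
  rownames(out) <- NULL
  out
}

#' @rdname get_event
#' @export
get_block <- function(rec, block_id) {
  stopifnot(inherits(rec, "recording"))
  out <- rec$data[rec$data$block_id == block_id, , drop = FALSE]
  if (nrow(out) == 0L) stop("no samples for block ", block_id)
  rownames(out) <- NULL
  out
}

#' List the (block_id, event_id) pairs present in a recording
#' @param rec A [recording()].
#' @return Data frame with columns `block_id`, `event_id`, `n_samples`.
#' @export
list_events <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  d <- rec$data
  if (!nrow(d))
    return(data.frame(block_id = integer(), event_id = integer(),
                      n_samples = integer()))
  out <- aggregate(list(n_samples = d$sample_id),
                   by = list(block_id = d$block_id, event_id = d$event_id),
                   FUN = length)
  out <- out[order(out$block_id, out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
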