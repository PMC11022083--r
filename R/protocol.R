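#' Stimulation-protocol configuration
#'
#' Describes one acquisition protocol in any of the three modes the
#' acquisition software supports:
#'
#' * `"acoustic"` — the subject is cued by a buzzer beep at a fixed
#'   stimulation rate (given in millihertz); each beep triggers the
#'   recording of one event.  Blocks of `block_duration_s` seconds are
#'   repeated `repetitions` times, separated by breaks of `pause_s`
#'   seconds.
#' * `"external_trigger"` — an edge on the external trigger input starts
#'   each event; `event_samples` samples are recorded per trigger.
#' * `"free_running"` — continuous acquisition for `block_duration_s`
#'   seconds, stored as a single event.
#'
#' @param mode One of `"acoustic"`, `"external_trigger"`, `"free_running"`.
#' @param stim_rate_mHz Acoustic stimulation (beep) rate in millihertz;
#'   500 mHz means one cue every 2 s.
#' @param block_duration_s Block duration in seconds (also the total
#'   duration in free-running mode).
#' @param pause_s Break between consecutive blocks, in seconds.
#' @param repetitions Number of blocks.
#' @param event_samples Samples recorded per trigger (event length).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param trigger_edge `"rising"` or `"falling"` (metadata in simulation).
#' @param beep_on_trigger Whether a cue beep accompanies each trigger.
#' @return An object of class `protocol_config`.
#' @export
#' @examples
#' # the reference protocol: 6 blocks of 30 one-second events, 60 s breaks
#' reference_protocol()
protocol_config <- function(mode = c("acoustic", "external_trigger",
                                     "free_running"),
                            stim_rate_mHz = 500,
                            block_duration_s = 60,
                            pause_s = 60,
                            repetitions = 6,
                            event_samples = 1000,
                            sampling_rate_hz = 1000,
                            trigger_edge = c("rising", "falling"),
                            beep_on_trigger = TRUE) {
  mode <- match.arg(mode)
  trigger_edge <- match.arg(trigger_edge)
  if (event_samples < 1) stop("event_samples must be >= 1")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (sampling_rate_hz < 4 || sampling_rate_hz > 4000)
    stop("sampling_rate_hz must lie in [4, 4000] Hz")
  if (mode == "acoustic") {
    if (stim_rate_mHz <= 0)
      stop("stim_rate_mHz must be > 0 in acoustic mode")
    event_dur <- event_samples / sampling_rate_hz
    isi <- 1000 / stim_rate_mHz
    if (event_dur > isi)
      stop(sprintf(paste("events overlap: event duration %.3f s exceeds the",
                         "inter-stimulus interval %.3f s"), event_dur, isi))
  }
  structure(list(mode = mode,
                 stim_rate_mHz = as.numeric(stim_rate_mHz),
                 block_duration_s = as.numeric(block_duration_s),
                 pause_s = as.numeric(pause_s),
                 repetitions = as.integer(repetitions),
                 event_samples = as.integer(event_samples),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 trigger_edge = trigger_edge,
                 beep_on_trigger = isTRUE(beep_on_trigger)),
            class = "protocol_config")
}

#' @rdname protocol_config
#' @export
reference_protocol <- function() {
  protocol_config(mode = "acoustic", stim_rate_mHz = 500,
                  block_duration_s = 60, pause_s = 60, repetitions = 6,
                  event_samples = 1000, sampling_rate_hz = 1000)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>", x$mode, "\n")
  if (x$mode == "acoustic")
    cat(sprintf("  %g mHz stimulation, %g s blocks x %d, %g s pauses\n",
                x$stim_rate_mHz, x$block_duration_s, x$repetitions,
                x$pause_s))
  cat(sprintf("  %d samples/event at %g Hz\n", x$event_samples,
              x$sampling_rate_hz))
  invisible(x)
}

#' Number of events fitting in one acoustic-mode block
#'
#' With a stimulation rate of `stim_rate_mHz` millihertz and the first cue
#' at the block start, `floor(block_duration_s * stim_rate_mHz / 1000)`
#' cued events fit in a block (the final partial inter-stimulus interval
#' yields no cue).
#'
#' @param cfg An acoustic-mode [protocol_config()].
#' @return Integer event count per block.
#' @export
#' @examples
#' events_per_block(reference_protocol())  # 30
events_per_block <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (cfg$mode != "acoustic")
    stop("events_per_block is defined for acoustic mode only, got mode '",
         cfg$mode, "'")
  as.integer(floor(cfg$block_duration_s * cfg$stim_rate_mHz / 1000))
}

#' Build the trigger schedule of an acoustic protocol
#'
#' Lays the protocol out on the experiment clock: block `b` (0-based)
#' starts at `b * (block_duration_s + pause_s)` seconds, and within a block
#' cues fire every `1000 / stim_rate_mHz` seconds starting at the block
#' start.
#'
#' @param cfg An acoustic-mode [protocol_config()].
#' @return A data frame of class `trigger_schedule` with columns
#'   `block_id`, `event_id` (both 0-based) and `trigger_time_s`.
#' @export
#' @examples
#' sched <- build_schedule(reference_protocol())
#' nrow(sched)                  # 180
#' sched$trigger_time_s[31]     # block 1 starts at 120 s
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "protocol_config"))
  n_ev <- events_per_block(cfg)
  isi <- 1000 / cfg$stim_rate_mHz
  block_starts <- (seq_len(cfg$repetitions) - 1) *
    (cfg$block_duration_s + cfg$pause_s)
  out <- data.frame(
    block_id = rep(seq_len(cfg$repetitions) - 1L, each = n_ev),
    event_id = rep(seq_len(n_ev) - 1L, times = cfg$repetitions),
    trigger_time_s = rep(block_starts, each = n_ev) +
      rep((seq_len(n_ev) - 1) * isi, times = cfg$repetitions))
  class(out) <- c("trigger_schedule", "data.frame")
  out
}

#' Built-in movement-signal sources for simulated acquisition
#'
#' A source is a function `f(t)` mapping a numeric vector of times (seconds
#' on the experiment clock) to an `length(t) x 3` matrix of acceleration in
#' m/s^2.  Sources may use the R random number generator; the protocol
#' runners seed it once, so a run is reproducible given its seed.
#'
#' `source_silent()` returns rest under gravity along `gravity_axis` plus
#' optional white noise and a constant per-axis offset — the signal of a
#' sensor lying still.
#'
#' @param gravity_axis `"none"`, `"x"`, `"y"` or `"z"`; axis aligned with
#'   gravity.
#' @param noise A [noise_model()].
#' @return A function `f(t)` as described above.
#' @export
source_silent <- function(gravity_axis = "z", noise = noise_model(sd = 0)) {
  g <- .gravity_vector(gravity_axis)
  function(t) {
    n <- length(t)
    matrix(g, n, 3, byrow = TRUE) +
      matrix(noise$offset, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, 0, noise$sd), n, 3)
  }
}

.gravity_vector <- function(gravity_axis) {
  switch(gravity_axis,
         none = c(0, 0, 0),
         x = c(G0, 0, 0),
         y = c(0, G0, 0),
         z = c(0, 0, G0),
         stop("gravity_axis must be one of none, x, y, z"))
}

# Assemble a recording from per-event trigger times and a source.
.record_events <- function(schedule, cfg, source, hardware, subject) {
  n_ev <- nrow(schedule)
  n_per <- cfg$event_samples
  dt <- 1 / cfg$sampling_rate_hz
  rel <- (seq_len(n_per) - 1) * dt
  t_all <- rep(schedule$trigger_time_s, each = n_per) + rep(rel, n_ev)
  acc <- source(t_all)
  if (!is.matrix(acc) || nrow(acc) != length(t_all) || ncol(acc) != 3)
    stop("source must return a length(t) x 3 acceleration matrix")
  data <- data.frame(
    sample_id = seq_len(n_ev * n_per) - 1L,
    block_id = rep(schedule$block_id, each = n_per),
    event_id = rep(schedule$event_id, each = n_per),
    t = t_all, ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
  recording(data, hardware = hardware, protocol = cfg, subject = subject)
}

#' Run a protocol against a simulated movement source
#'
#' Executes an acoustic-mode or free-running protocol on a movement-signal
#' source (see [source_silent()]), producing a [recording()].  Schedules
#' depend only on the configuration; the seed affects only the source's
#' noise, so the same seed reproduces the identical recording.
#'
#' @param cfg A [protocol_config()].
#' @param source A source function `f(t)` returning an `n x 3` matrix.
#' @param seed Integer seed for the source's random numbers.
#' @param hardware A [hardware_config()]; its sampling rate is taken from
#'   `cfg`.
#' @param subject Subject metadata passed to [recording()].
#' @return A [recording()].
#' @export
#' @examples
#' rec <- run_protocol(protocol_config("acoustic", stim_rate_mHz = 1000,
#'                                     block_duration_s = 2, pause_s = 1,
#'                                     repetitions = 2, event_samples = 10,
#'                                     sampling_rate_hz = 100),
#'                     source_silent(), seed = 1)
#' rec$meta$n_events  # 2 blocks x 2 events
run_protocol <- function(cfg, source = source_silent(), seed = 1,
                         hardware = NULL, subject = character()) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (is.null(hardware))
    hardware <- hardware_config(sampling_rate_hz = cfg$sampling_rate_hz)
  set.seed(seed)
  if (cfg$mode == "acoustic") {
    schedule <- build_schedule(cfg)
  } else if (cfg$mode == "free_running") {
    n <- as.integer(round(cfg$block_duration_s * cfg$sampling_rate_hz))
    cfg$event_samples <- n
    schedule <- data.frame(block_id = 0L, event_id = 0L, trigger_time_s = 0)
  } else {
    stop("use external_trigger_run() for external-trigger protocols")
  }
  .record_events(schedule, cfg, source, hardware, subject)
}

#' Run an externally triggered acquisition
#'
#' One event of `cfg$event_samples` samples is recorded per supplied
#' trigger time, all in a single block (an external-trigger session has no
#' block structure of its own).
#'
#' @param cfg An external-trigger [protocol_config()].
#' @param trigger_times Sorted numeric vector of trigger times in seconds.
#' @param source,seed,hardware,subject As in [run_protocol()].
#' @return A [recording()]; empty (zero events) for an empty trigger list.
#' @export
external_trigger_run <- function(cfg, trigger_times,
                                 source = source_silent(), seed = 1,
                                 hardware = NULL, subject = character()) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (cfg$mode != "external_trigger")
    stop("cfg$mode must be 'external_trigger', got '", cfg$mode, "'")
  if (is.unsorted(trigger_times, strictly = TRUE) && length(trigger_times) > 1)
    stop("trigger_times must be strictly increasing")
  event_dur <- cfg$event_samples / cfg$sampling_rate_hz
  if (length(trigger_times) > 1 && any(diff(trigger_times) < event_dur))
    stop(sprintf("overlapping triggers: spacing below the %.3f s event duration",
                 event_dur))
  if (is.null(hardware))
    hardware <- hardware_config(sampling_rate_hz = cfg$sampling_rate_hz,
                                trigger_edge = cfg$trigger_edge)
  set.seed(seed)
  if (length(trigger_times) == 0) {
    rec <- recording(data.frame(sample_id = integer(), block_id = integer(),
                                event_id = integer(), t = numeric(),
                                ax = numeric(), ay = numeric(),
                                az = numeric()),
                     hardware = hardware, protocol = NULL, subject = subject)
    return(rec)
  }
  schedule <- data.frame(block_id = 0L,
                         event_id = seq_along(trigger_times) - 1L,
                         trigger_time_s = as.numeric(trigger_times))
  cfg_noblock <- cfg
  .record_events(schedule, cfg_noblock, source, hardware, subject)
}
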