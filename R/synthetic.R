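#' Sensor noise and bias model for simulated signals
#'
#' White Gaussian noise per axis plus a constant per-axis offset — the two
#' imperfections the conditioning module is designed to handle.  The
#' default noise SD of 0.02 m/s^2 reflects a low-noise MEMS accelerometer
#' sampled at 1 kHz.
#'
#' @param sd Noise standard deviation, m/s^2 (scalar, applied per axis).
#' @param offset Numeric 3-vector of constant per-axis bias, m/s^2.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.02, offset = c(0, 0, 0)) {
  stopifnot(sd >= 0, length(offset) == 3)
  structure(list(sd = as.numeric(sd), offset = as.numeric(offset)),
            class = "noise_model")
}

#' Orientation sequence for static gravity recordings
#'
#' Describes a sequence of sensor placements as single-plane tilts: in
#' each segment, gravity lies in the plane spanned by `from` and `to`, at
#' `angle_deg` degrees from the `from` axis.  `angle_deg = 0` puts the
#' `from` axis vertical (reading 1 g); `angle_deg = 45` splits gravity
#' equally between the two axes (each reading 9.81/sqrt(2) = 6.94 m/s^2).
#'
#' `orientation("z")` is shorthand for a single segment with the named
#' axis vertical.
#'
#' @param from,to Axis names (`"x"`, `"y"`, `"z"`); `from` may also be a
#'   vector for multi-segment sequences.
#' @param angle_deg Tilt angle(s) in degrees, in `[0, 360)`.
#' @param hold_s Hold duration(s) of each segment, seconds.
#' @return An object of class `orientation`: data frame with columns
#'   `from`, `to`, `angle_deg`, `hold_s`.
#' @export
#' @examples
#' # each axis vertical in turn, then the 45 degree x/z placement
#' orientation(from = c("x", "y", "z", "x"), to = c("z", "z", "x", "z"),
#'             angle_deg = c(0, 0, 0, 45), hold_s = 1)
orientation <- function(from, to = "x", angle_deg = 0, hold_s = 1) {
  axes <- c("x", "y", "z")
  stopifnot(all(from %in% axes), all(to %in% axes))
  out <- data.frame(from = from, to = to, angle_deg = angle_deg,
                    hold_s = hold_s, stringsAsFactors = FALSE)
  if (any(out$from == out$to & out$angle_deg %% 360 != 0))
    stop("tilt plane is degenerate: from == to with a non-zero angle")
  if (any(out$angle_deg < 0 | out$angle_deg >= 360))
    stop("angles must lie in [0, 360) degrees")
  if (any(out$hold_s <= 0)) stop("hold durations must be positive")
  class(out) <- c("orientation", "data.frame")
  out
}

# Gravity reading (sensor frame) for one tilt segment.
.tilt_gravity <- function(from, to, angle_deg) {
  g <- c(x = 0, y = 0, z = 0)
  theta <- angle_deg * pi / 180
  g[from] <- G0 * cos(theta)
  g[to] <- g[to] + G0 * sin(theta)
  unname(g)
}

#' Simulate a static recording under a sequence of sensor orientations
#'
#' The sensor sits still while being placed in each orientation in turn;
#' the signal is the gravity vector projected onto the sensor axes, plus
#' the noise model's offset and white noise.  The noiseless magnitude is
#' exactly 1 g (9.81 m/s^2) at every sample regardless of orientation.
#'
#' @param ori An [orientation()] sequence.
#' @param fs Sampling rate, Hz.
#' @param noise A [noise_model()]; use `noise_model(sd = 0)` for a clean
#'   signal.
#' @param seed Integer seed for the noise.
#' @return Data frame with columns `t`, `ax`, `ay`, `az` (one row per
#'   sample).
#' @seealso [static_recording()] for a full [recording()] wrapper.
#' @export
#' @examples
#' s <- static_signal(orientation("z"), fs = 100, noise = noise_model(0))
#' s$az[1]          # 9.81
#' s45 <- static_signal(orientation("x", "z", 45), fs = 100,
#'                      noise = noise_model(0))
#' c(s45$ax[1], s45$az[1])  # both 6.94
static_signal <- function(ori, fs = 1000, noise = noise_model(), seed = 1) {
  stopifnot(inherits(ori, "orientation"))
  set.seed(seed)
  seg <- lapply(seq_len(nrow(ori)), function(i) {
    n <- as.integer(round(ori$hold_s[i] * fs))
    g <- .tilt_gravity(ori$from[i], ori$to[i], ori$angle_deg[i])
    matrix(g, n, 3, byrow = TRUE)
  })
  a <- do.call(rbind, seg)
  n <- nrow(a)
  a <- a + matrix(noise$offset, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, 0, noise$sd), n, 3)
  data.frame(t = (seq_len(n) - 1) / fs, ax = a[, 1], ay = a[, 2],
             az = a[, 3])
}

#' @rdname static_signal
#' @param duration_s Total duration when `ori` has a single segment whose
#'   hold time should be overridden; `NULL` keeps the orientation's own
#'   hold times.
#' @return `static_recording()` returns the signal wrapped as a
#'   free-running single-event [recording()].
#' @export
static_recording <- function(ori, fs = 1000, noise = noise_model(),
                             seed = 1, duration_s = NULL) {
  if (!is.null(duration_s)) {
    stopifnot(nrow(ori) == 1L)
    ori$hold_s <- duration_s
  }
  s <- static_signal(ori, fs = fs, noise = noise, seed = seed)
  data <- data.frame(sample_id = seq_len(nrow(s)) - 1L, block_id = 0L,
                     event_id = 0L, t = s$t, ax = s$ax, ay = s$ay,
                     az = s$az)
  recording(data, hardware = hardware_config(sampling_rate_hz = fs))
}

#' Biphasic ballistic movement pulse
#'
#' Model of the acceleration trace of a single cued ballistic movement
#' (e.g. a thumb flick): silence during the reaction time after the
#' trigger, then a smooth accelerate-then-brake pulse shaped as the
#' derivative of a Gaussian, truncated at +/- 3 sigma (so
#' `duration = 6 sigma`).  The pulse is scaled so the programmed `peak` is
#' the exact maximum of the continuous |a|; because the truncation is
#' symmetric, the velocity integral returns exactly to zero at the pulse
#' end while the displacement integral stays positive — the limb stops in
#' a new position.
#'
#' @param peak Programmed peak acceleration, m/s^2 (> 0; 0 gives silence).
#' @param duration Pulse duration in seconds.
#' @param onset_delay Reaction time between trigger and movement onset,
#'   seconds.
#' @param event_duration_s Length of the returned series, seconds.
#' @param fs Sampling rate, Hz.
#' @param direction Unit 3-vector of the movement direction in the sensor
#'   frame (normalised internally).
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise.
#' @return Data frame with columns `t` (seconds from the trigger), `ax`,
#'   `ay`, `az`.
#' @export
#' @examples
#' ev <- flick_signal(peak = 5, noise = noise_model(0))
#' max(magnitude(ev))  # 5 (up to sample discretisation)
flick_signal <- function(peak, duration = 0.15, onset_delay = 0.15,
                         event_duration_s = 1, fs = 1000,
                         direction = c(1, 0, 0), noise = noise_model(),
                         seed = 1) {
  if (peak < 0) stop("peak must be >= 0")
  if (onset_delay + duration > event_duration_s)
    stop(sprintf(paste("movement (onset %g s + duration %g s) does not fit",
                       "in the %g s event window"),
                 onset_delay, duration, event_duration_s))
  set.seed(seed)
  n <- as.integer(round(event_duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  a1 <- .flick_profile(t, peak, duration, onset_delay)
  direction <- direction / sqrt(sum(direction^2))
  a <- outer(a1, direction)
  a <- a + matrix(noise$offset, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, 0, noise$sd), n, 3)
  data.frame(t = t, ax = a[, 1], ay = a[, 2], az = a[, 3])
}

# Derivative-of-Gaussian pulse on [onset, onset + duration], zero outside,
# scaled to a continuous-time peak |a| of `peak` (attained at tc +/- sigma).
.flick_profile <- function(t, peak, duration, onset_delay) {
  sigma <- duration / 6
  tc <- onset_delay + duration / 2
  u <- (t - tc) / sigma
  active <- t >= onset_delay & t <= onset_delay + duration
  out <- numeric(length(t))
  out[active] <- peak * exp(0.5) * (-u[active]) * exp(-u[active]^2 / 2)
  out
}

#' Simulate a multi-block ballistic-movement experiment
#'
#' Generates a complete protocol recording in which each cued event
#' contains one biphasic movement pulse.  The true (noiseless) peak of
#' event `j` in block `b` is
#' `base_peak * block_trend[b] * (1 + e)`, `e ~ N(0, event_cv)` — a
#' per-block multiplier models practice-related change in ballistic
#' performance across blocks, and the coefficient of variation models
#' event-to-event behavioural variability.  Gravity is projected onto
#' `gravity_axis` and the noise model's offset and white noise are added,
#' so the recording must be offset-calibrated (gravity axis named) before
#' peak extraction, exactly as with a real sensor.
#'
#' @param cfg An acoustic-mode [protocol_config()]; defaults to
#'   [reference_protocol()] (6 blocks x 30 events of 1000 samples at
#'   1 kHz, 60 s breaks).
#' @param base_peak Baseline true peak acceleration, m/s^2.
#' @param block_trend Numeric vector of per-block multipliers, length
#'   `cfg$repetitions`.
#' @param event_cv Coefficient of variation of per-event true peaks.
#' @param noise A [noise_model()].
#' @param seed Integer seed (drives event peaks and sensor noise).
#' @param gravity_axis Axis carrying gravity (`"none"`, `"x"`, `"y"`,
#'   `"z"`).
#' @param direction Movement direction in the sensor frame.
#' @param onset_delay,flick_duration Pulse timing, seconds.
#' @return A [recording()] with attribute `"true_peaks"`: data frame of
#'   the programmed per-event peaks.
#' @export
#' @examples
#' cfg <- protocol_config("acoustic", stim_rate_mHz = 1000,
#'                        block_duration_s = 5, pause_s = 1,
#'                        repetitions = 2, event_samples = 100,
#'                        sampling_rate_hz = 100)
#' rec <- learning_experiment(cfg, block_trend = c(1, 1.5),
#'                            event_cv = 0, noise = noise_model(0))
#' rec$meta$n_events  # 10
learning_experiment <- function(cfg = reference_protocol(),
                                base_peak = 2,
                                block_trend = seq(1, 1.525,
                                                  length.out = cfg$repetitions),
                                event_cv = 0.05,
                                noise = noise_model(),
                                seed = 1,
                                gravity_axis = "z",
                                direction = c(1, 0, 0),
                                onset_delay = 0.15,
                                flick_duration = 0.15) {
  stopifnot(inherits(cfg, "protocol_config"), cfg$mode == "acoustic")
  if (length(block_trend) != cfg$repetitions)
    stop("block_trend must have one multiplier per block (",
         cfg$repetitions, "), got ", length(block_trend))
  set.seed(seed)
  sched <- build_schedule(cfg)
  fs <- cfg$sampling_rate_hz
  n_per <- cfg$event_samples
  event_duration_s <- n_per / fs
  g <- .gravity_vector(gravity_axis)
  direction <- direction / sqrt(sum(direction^2))
  rel_t <- (seq_len(n_per) - 1) / fs
  profile_unit <- .flick_profile(rel_t, 1, flick_duration, onset_delay)

  true_peak <- base_peak * block_trend[sched$block_id + 1L] *
    (1 + rnorm(nrow(sched), 0, event_cv))
  if (any(true_peak <= 0))
    stop("event_cv produced a non-positive true peak; reduce event_cv")

  n_total <- nrow(sched) * n_per
  a <- outer(as.vector(outer(profile_unit, true_peak)), direction)
  a <- a + matrix(g + noise$offset, n_total, 3, byrow = TRUE) +
    matrix(rnorm(3 * n_total, 0, noise$sd), n_total, 3)
  data <- data.frame(
    sample_id = seq_len(n_total) - 1L,
    block_id = rep(sched$block_id, each = n_per),
    event_id = rep(sched$event_id, each = n_per),
    t = rep(sched$trigger_time_s, each = n_per) + rep(rel_t, nrow(sched)),
    ax = a[, 1], ay = a[, 2], az = a[, 3])
  rec <- recording(data, protocol = cfg,
                   hardware = hardware_config(sampling_rate_hz = fs))
  attr(rec, "true_peaks") <- data.frame(block_id = sched$block_id,
                                        event_id = sched$event_id,
                                        peak = true_peak)
  rec
}
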