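# Shared fixtures: small in-code recordings for format and pipeline tests.

# A minimal valid sample table: n_blocks x n_events x n_per samples at fs Hz.
make_sample_table <- function(n_blocks = 1, n_events = 1, n_per = 3,
                              fs = 100, with_raw = FALSE, with_temp = FALSE) {
  n <- n_blocks * n_events * n_per
  d <- data.frame(
    sample_id = seq_len(n) - 1L,
    block_id = rep(seq_len(n_blocks) - 1L, each = n_events * n_per),
    event_id = rep(rep(seq_len(n_events) - 1L, each = n_per), n_blocks),
    t = (seq_len(n) - 1) / fs,
    ax = rnorm(n), ay = rnorm(n), az = rnorm(n))
  if (with_raw) {
    d$raw_x <- sample.int(4096, n, replace = TRUE)
    d$raw_y <- sample.int(4096, n, replace = TRUE)
    d$raw_z <- sample.int(4096, n, replace = TRUE)
  }
  if (with_temp) d$temperature <- runif(n, 20, 30)
  d
}

make_recording <- function(n_blocks = 1, n_events = 1, n_per = 3,
                           fs = 100, ...) {
  recording(make_sample_table(n_blocks, n_events, n_per, fs, ...),
            hardware = hardware_config(sampling_rate_hz = fs),
            subject = c(id = "s01", hand = "right"))
}

# Random valid recording with random optional columns and metadata,
# for round-trip property tests.
random_recording <- function() {
  nb <- sample(1:3, 1); ne <- sample(1:3, 1); np <- sample(2:12, 1)
  rec <- make_recording(nb, ne, np, fs = sample(c(50, 100, 250), 1),
                        with_raw = runif(1) < 0.5,
                        with_temp = runif(1) < 0.5)
  rec
}

# A tiny acoustic protocol that runs in milliseconds.
small_protocol <- function(repetitions = 2, event_samples = 20,
                           sampling_rate_hz = 100) {
  protocol_config("acoustic", stim_rate_mHz = 1000, block_duration_s = 3,
                  pause_s = 2, repetitions = repetitions,
                  event_samples = event_samples,
                  sampling_rate_hz = sampling_rate_hz)
}
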