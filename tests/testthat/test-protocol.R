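test_that("events_per_block floors rate x duration", {
  expect_equal(events_per_block(reference_protocol()), 30L)
  expect_equal(events_per_block(
    protocol_config("acoustic", stim_rate_mHz = 500, block_duration_s = 1,
                    pause_s = 0, repetitions = 1, event_samples = 4,
                    sampling_rate_hz = 100)), 0L)
  expect_equal(events_per_block(
    protocol_config("acoustic", stim_rate_mHz = 1000,
                    block_duration_s = 45, pause_s = 0, repetitions = 1,
                    event_samples = 100, sampling_rate_hz = 100)), 45L)
  expect_error(events_per_block(
    protocol_config("free_running", sampling_rate_hz = 100)),
    "acoustic mode only")
})

test_that("config invariants reject overlapping events and bad rates", {
  expect_error(protocol_config("acoustic", stim_rate_mHz = 2000,
                               event_samples = 1000,
                               sampling_rate_hz = 1000),
               "events overlap")
  expect_error(protocol_config("acoustic", stim_rate_mHz = 0),
               "stim_rate_mHz")
  expect_error(protocol_config("acoustic", sampling_rate_hz = 5000),
               "sampling_rate_hz")
  expect_error(hardware_config(range_g = 3), "range_g")
})

test_that("reference schedule: 180 entries, block 1 at 120 s, 2 s spacing", {
  sched <- build_schedule(reference_protocol())
  expect_equal(nrow(sched), 180L)
  expect_equal(sched$trigger_time_s[sched$block_id == 1][1], 120)
  within <- diff(sched$trigger_time_s[sched$block_id == 0])
  expect_equal(within, rep(2, 29))
  # single repetition: no pause anywhere in the schedule
  one <- build_schedule(protocol_config("acoustic", stim_rate_mHz = 500,
                                        block_duration_s = 60, pause_s = 60,
                                        repetitions = 1))
  expect_equal(max(one$trigger_time_s), 58)
})

test_that("schedule times are strictly increasing for random valid configs", {
  set.seed(11)
  for (i in 1:25) {
    fs <- sample(c(50, 100, 200), 1)
    rate <- sample(c(250, 500, 1000, 2000), 1)
    n_samp <- sample.int(floor(1000 / rate * fs), 1)
    cfg <- protocol_config("acoustic", stim_rate_mHz = rate,
                           block_duration_s = sample(5:30, 1),
                           pause_s = sample(0:10, 1),
                           repetitions = sample(1:4, 1),
                           event_samples = n_samp, sampling_rate_hz = fs)
    sched <- build_schedule(cfg)
    expect_equal(nrow(sched), cfg$repetitions * events_per_block(cfg))
    if (nrow(sched) > 1)
      expect_true(all(diff(sched$trigger_time_s) > 0))
  }
})

test_that("run_protocol produces the scheduled block/event/sample structure", {
  cfg <- small_protocol()
  rec <- run_protocol(cfg, source_silent(), seed = 3)
  expect_equal(rec$meta$n_blocks, 2L)
  expect_equal(rec$meta$n_events, 6L)       # 2 blocks x 3 events
  expect_equal(nrow(rec$data), 6L * 20L)
  expect_equal(nrow(validate_recording(rec)), 0L)
  # last sample sits at the closed-form position inside the protocol span
  isi <- 1000 / cfg$stim_rate_mHz
  expected_last <- (cfg$repetitions - 1) *
    (cfg$block_duration_s + cfg$pause_s) +
    (events_per_block(cfg) - 1) * isi +
    (cfg$event_samples - 1) / cfg$sampling_rate_hz
  expect_equal(max(rec$data$t), expected_last)
  # and the whole session fits the nominal duration reps*block+(reps-1)*pause
  expect_lte(max(rec$data$t),
             cfg$repetitions * cfg$block_duration_s +
               (cfg$repetitions - 1) * cfg$pause_s)
})

test_that("same seed reproduces the identical recording", {
  cfg <- small_protocol()
  r1 <- run_protocol(cfg, source_silent(noise = noise_model(0.1)), seed = 9)
  r2 <- run_protocol(cfg, source_silent(noise = noise_model(0.1)), seed = 9)
  expect_identical(r1$data, r2$data)
  r3 <- run_protocol(cfg, source_silent(noise = noise_model(0.1)), seed = 10)
  expect_false(identical(r3$data, r1$data))
})

test_that("free-running mode records one continuous event", {
  cfg <- protocol_config("free_running", block_duration_s = 2,
                         sampling_rate_hz = 100, event_samples = 1)
  rec <- run_protocol(cfg, source_silent(), seed = 1)
  expect_equal(rec$meta$n_events, 1L)
  expect_equal(nrow(rec$data), 200L)
})

test_that("external triggers yield one event each and reject overlaps", {
  cfg <- protocol_config("external_trigger", event_samples = 10,
                         sampling_rate_hz = 100)
  rec <- external_trigger_run(cfg, c(0, 0.5, 2), source_silent(), seed = 1)
  expect_equal(rec$meta$n_events, 3L)
  expect_equal(nrow(rec$data), 30L)
  empty <- external_trigger_run(cfg, numeric(), source_silent(), seed = 1)
  expect_equal(nrow(empty$data), 0L)
  expect_error(external_trigger_run(cfg, c(0, 0.05), source_silent()),
               "overlapping triggers")
  expect_error(external_trigger_run(reference_protocol(), c(0, 5)),
               "external_trigger")
})
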