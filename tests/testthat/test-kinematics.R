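# Independent oracle for the integration route: trapezoid on a 10x finer
# grid, evaluated from the continuous-time acceleration function, then
# subsampled to the analysis endpoint.
fine_grid_integral <- function(a_fun, T, dt, refine = 10) {
  tt <- seq(0, T, by = dt / refine)
  a <- a_fun(tt)
  v <- pracma::cumtrapz(tt, a)
  s <- pracma::cumtrapz(tt, as.numeric(v))
  c(v_end = tail(as.numeric(v), 1), s_end = tail(as.numeric(s), 1))
}

test_that("constant acceleration integrates to v = aT and s = aT^2/2", {
  ev <- data.frame(ax = rep(2, 1000), ay = 0, az = 0)
  sa <- analyze_segment(ev, dt = 1e-3)
  expect_lt(abs(tail(sa$velocity$x, 1) - 2 * 0.999), 1e-3)
  expect_lt(abs(tail(sa$displacement$x, 1) - 0.5 * 2 * 0.999^2), 1e-3)
  expect_equal(sa$velocity$x[1], 0)
  expect_equal(sa$displacement$x[1], 0)
  zero <- analyze_segment(data.frame(ax = numeric(50), ay = 0, az = 0),
                          dt = 0.01)
  expect_true(all(zero$velocity$abs == 0))
  expect_true(all(zero$displacement$abs == 0))
})

test_that("sinusoidal acceleration matches its closed-form integrals", {
  dt <- 1e-3
  t <- seq(0, 1 - dt, by = dt)
  ev <- data.frame(ax = sin(2 * pi * t), ay = 0, az = 0)
  sa <- analyze_segment(ev, dt = dt)
  # v(t) = (1 - cos(2 pi t)) / (2 pi): ~0 after a full period, peak 1/pi
  expect_lt(abs(tail(sa$velocity$x, 1) -
                  (1 - cos(2 * pi * (1 - dt))) / (2 * pi)), 2e-3)
  expect_lt(abs(max(sa$velocity$x) - 1 / pi), 1e-3)
})

test_that("trapezoid agrees with a 10x fine-grid oracle for smooth signals", {
  dt <- 1e-2
  T <- 2 - dt
  a_fun <- function(t) 3 * exp(-t) * sin(5 * t)
  t <- seq(0, T, by = dt)
  sa <- analyze_segment(data.frame(ax = a_fun(t), ay = 0, az = 0), dt = dt)
  oracle <- fine_grid_integral(a_fun, T, dt)
  # composite-trapezoid error bound: T * dt^2 / 12 * max|a''|;
  # here |a''| <= 3 * (1 + 5)^2 = 108
  bound <- T * dt^2 / 12 * 108
  expect_lt(abs(tail(sa$velocity$x, 1) - oracle["v_end"]), bound)
  expect_lt(abs(tail(sa$displacement$x, 1) - oracle["s_end"]), T * bound)
  # degree-1 (linear) acceleration is integrated to velocity exactly
  lin <- analyze_segment(data.frame(ax = 2 + 3 * t, ay = 0, az = 0), dt = dt)
  expect_equal(tail(lin$velocity$x, 1), 2 * T + 1.5 * T^2, tolerance = 1e-12)
})

test_that("segment selection is half-open, 0-based, and rejects bad bounds", {
  ev <- data.frame(ax = 1:10, ay = 0, az = 0)
  sa <- analyze_segment(ev, start_idx = 2, end_idx = 5, dt = 0.1)
  expect_equal(sa$acceleration$x, c(3, 4, 5))
  expect_error(analyze_segment(ev, 5, 5, dt = 0.1), "invalid segment")
  expect_error(analyze_segment(ev, -1, 5, dt = 0.1), "invalid segment")
  expect_error(analyze_segment(ev, 0, 11, dt = 0.1), "invalid segment")
})

test_that("summary covers all 12 quantity-component combinations", {
  ev <- data.frame(ax = rnorm(20), ay = rnorm(20), az = rnorm(20))
  sa <- analyze_segment(ev, dt = 0.01)
  expect_equal(nrow(sa$summary), 12)
  expect_setequal(unique(sa$summary$quantity),
                  c("acceleration", "velocity", "displacement"))
  expect_setequal(unique(sa$summary$component), c("x", "y", "z", "abs"))
  row <- sa$summary[sa$summary$quantity == "acceleration" &
                      sa$summary$component == "x", ]
  expect_equal(row$min, min(ev$ax))
  expect_equal(row$max, max(ev$ax))
  expect_equal(row$mean, mean(ev$ax))
})

test_that("event_peak takes the component maximum; abs dominates axes", {
  ev <- data.frame(ax = c(0.1, 3.2, 1.0), ay = 0, az = 0)
  expect_equal(event_peak(ev), 3.2)
  expect_equal(event_peak(data.frame(ax = 0, ay = 0, az = 0)[rep(1, 5), ]), 0)
  expect_error(event_peak(ev[0, ]), "empty event")
  set.seed(3)
  for (i in 1:20) {
    ev <- data.frame(ax = rnorm(30), ay = rnorm(30), az = rnorm(30))
    pabs <- event_peak(ev, "abs")
    expect_gte(pabs, event_peak(ev, "x"))
    expect_gte(pabs, event_peak(ev, "y"))
    expect_gte(pabs, event_peak(ev, "z"))
  }
})

test_that("block_stats uses the n-1 SD convention and flags n=1", {
  bs <- block_stats(data.frame(block_id = 0L, event_id = 0:2,
                               peak = c(1, 2, 3)))
  expect_equal(bs$mean_peak, 2)
  expect_equal(bs$sd_peak, 1)
  one <- block_stats(data.frame(block_id = 0L, event_id = 0L, peak = 2.5))
  expect_equal(one$mean_peak, 2.5)
  expect_true(is.na(one$sd_peak))
})

test_that("block mean of iid peaks stays within the CLT band", {
  set.seed(21)
  peaks <- data.frame(block_id = 0L, event_id = 0:29,
                      peak = rnorm(30, 3, 0.2))
  bs <- block_stats(peaks)
  expect_lt(abs(bs$mean_peak - 3), 4 * 0.2 / sqrt(30))
})

test_that("percent_change arithmetic and scale invariance", {
  expect_equal(percent_change(2.00, 3.05), 52.5)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(2.00, 1.748), -12.6)
  expect_error(percent_change(0, 1), "positive")
  # invariant under common rescaling of all accelerations
  set.seed(2)
  p <- data.frame(block_id = rep(0:2, each = 5), event_id = rep(0:4, 3),
                  peak = runif(15, 1, 4))
  p2 <- transform(p, peak = peak * 7.3)
  expect_equal(percent_change(block_stats(p2)),
               percent_change(block_stats(p)), tolerance = 1e-12)
})

test_that("export_stats writes re-readable block and peak tables", {
  p <- data.frame(block_id = rep(0:5, each = 3), event_id = rep(0:2, 6),
                  peak = runif(18, 1, 4))
  bs <- block_stats(p)
  base <- tempfile()
  paths <- export_stats(bs, base)
  blocks <- read.delim(paths["blocks"])
  expect_equal(nrow(blocks), 6)
  expect_equal(blocks$mean_peak, bs$mean_peak, tolerance = 1e-6)
  peaks <- read.delim(paths["peaks"])
  expect_equal(nrow(peaks), 18)
  expect_equal(peaks$peak, p$peak, tolerance = 1e-6)
})
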