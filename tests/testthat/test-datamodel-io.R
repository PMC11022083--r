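test_that("recording construction derives counts and enforces columns", {
  rec <- make_recording(2, 3, 4)
  expect_s3_class(rec, "recording")
  expect_equal(rec$meta$n_blocks, 2L)
  expect_equal(rec$meta$n_events, 6L)
  expect_equal(nrow(rec$timestamps), 24L)
  expect_error(recording(data.frame(ax = 1)), "missing required columns")
})

test_that("write_recording produces three files with one row per sample", {
  rec <- make_recording(1, 1, 3)
  base <- tempfile()
  paths <- write_recording(rec, base)
  expect_true(all(file.exists(paths)))
  data_lines <- readLines(paths["data"])
  body <- data_lines[!grepl("^#", data_lines)]
  expect_length(body, 1 + 3)   # header + samples
  time_body <- grep("^#", readLines(paths["time"]), invert = TRUE,
                    value = TRUE)
  expect_length(time_body, 1 + 3)
})

test_that("an empty recording writes valid header-only files", {
  empty <- recording(make_sample_table(1, 1, 1)[0, ])
  base <- tempfile()
  paths <- write_recording(empty, base)
  body <- grep("^#", readLines(paths["data"]), invert = TRUE, value = TRUE)
  expect_length(body, 1)
  rec2 <- read_recording(base)
  expect_equal(nrow(rec2$data), 0L)
  expect_equal(rec2$meta$n_blocks, 0L)
})

test_that("write/read round trip is the exact identity across random recordings", {
  set.seed(42)
  for (i in 1:100) {
    rec <- random_recording()
    base <- tempfile()
    write_recording(rec, base)
    rec2 <- read_recording(base)
    expect_identical(rec2$data, rec$data)
    expect_identical(rec2$timestamps, rec$timestamps)
    expect_equal(rec2$meta, rec$meta)
    unlink(paste0(base, c(".data.tsv", ".time.tsv", ".meta.txt")))
  }
})

test_that("optional columns stay absent instead of becoming zeros", {
  rec <- make_recording(1, 1, 5, with_raw = FALSE, with_temp = FALSE)
  base <- tempfile()
  write_recording(rec, base)
  rec2 <- read_recording(base)
  expect_false(any(c("raw_x", "raw_y", "raw_z", "temperature") %in%
                     names(rec2$data)))
  rec3 <- make_recording(1, 1, 5, with_raw = TRUE, with_temp = TRUE)
  base3 <- tempfile()
  write_recording(rec3, base3)
  expect_true(all(c("raw_x", "temperature") %in%
                    names(read_recording(base3)$data)))
})

test_that("parser reports malformed rows with their line number", {
  rec <- make_recording(1, 1, 4)
  base <- tempfile()
  paths <- write_recording(rec, base)
  lines <- readLines(paths["data"])
  lines[4] <- paste(strsplit(lines[4], "\t")[[1]][1:3], collapse = "\t")
  writeLines(lines, paths["data"])
  expect_error(read_recording(base), "line 4")

  paths <- write_recording(rec, base)
  lines <- readLines(paths["data"])
  lines[5] <- sub("^2\t", "notanumber\t", lines[5])
  writeLines(lines, paths["data"])
  expect_error(read_recording(base), "cannot parse")
})

test_that("reader rejects sample_id gaps and missing files", {
  rec <- make_recording(1, 1, 5)
  base <- tempfile()
  paths <- write_recording(rec, base)
  lines <- readLines(paths["data"])
  writeLines(lines[-4], paths["data"])  # drop one sample row
  expect_error(read_recording(base), "sample_id not contiguous")
  unlink(paths["meta"])
  expect_error(read_recording(base), "missing recording file")
})

test_that("validate_recording reports violations without raising", {
  rec <- make_recording(2, 2, 5)
  expect_s3_class(validate_recording(rec), "validation_report")
  expect_equal(nrow(validate_recording(rec)), 0L)

  bad <- rec
  bad$data$sample_id[3] <- 99L   # gap
  rep <- validate_recording(bad)
  expect_gt(nrow(rep), 0)
  expect_true(any(grepl("contiguous", rep$message)))

  bad2 <- rec
  bad2$data$block_id <- rev(bad2$data$block_id)  # decreasing blocks
  rep2 <- validate_recording(bad2)
  expect_true(any(rep2$scope == "block"))

  # event shorter than the governing protocol specifies
  cfg <- small_protocol(repetitions = 1, event_samples = 5,
                        sampling_rate_hz = 100)
  rec3 <- run_protocol(cfg, source_silent(), seed = 1)
  rec3$data <- rec3$data[-nrow(rec3$data), ]
  rec3$timestamps <- rec3$timestamps[-nrow(rec3$timestamps), ]
  rec3$meta$n_events <- length(unique(paste(rec3$data$block_id,
                                            rec3$data$event_id)))
  rep3 <- validate_recording(rec3)
  expect_true(any(grepl("samples, protocol specifies", rep3$message)))
})

test_that("writing an invalid recording names the offending scope", {
  rec <- make_recording(1, 1, 4)
  rec$data$sample_id[2] <- 7L
  expect_error(write_recording(rec, tempfile()), "invalid recording")
})

test_that("event and block accessors slice by 0-based IDs", {
  rec <- make_recording(2, 3, 4)
  ev <- get_event(rec, 1, 2)
  expect_equal(nrow(ev), 4)
  expect_true(all(ev$block_id == 1 & ev$event_id == 2))
  expect_equal(nrow(get_block(rec, 0)), 12)
  expect_error(get_event(rec, 5, 0), "no samples")
  le <- list_events(rec)
  expect_equal(nrow(le), 6)
  expect_equal(le$n_samples, rep(4L, 6))
})

test_that("export_csv flattens the sample table", {
  rec <- make_recording(1, 2, 3)
  path <- tempfile(fileext = ".csv")
  export_csv(rec, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 6)
  expect_equal(names(d)[1:4], c("sample_id", "block_id", "event_id", "t"))
})
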