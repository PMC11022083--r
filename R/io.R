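#' Write a recording to the three-file on-disk layout
#'
#' A recording is stored as three plain-text files sharing a base path:
#'
#' * `<base>.data.tsv` — the sample table, tab-separated with a one-line
#'   header: `sample_id`, `block_id`, `event_id`, `t` (s), `ax`, `ay`, `az`
#'   (m/s^2), then `raw_x`, `raw_y`, `raw_z` (sensor counts) and
#'   `temperature` (degrees C) when present.  Lines starting with `#` are
#'   comments.
#' * `<base>.time.tsv` — one wall-clock timestamp per sample: `sample_id`,
#'   `time` (ISO-8601 with millisecond precision) and `marker` (`""`,
#'   `"break"` or `"delay"`), so inter-block breaks and trigger delays are
#'   visible in real time even though the sample clock `t` is continuous.
#' * `<base>.meta.txt` — flat `key=value` metadata: subject fields
#'   (`subject.*`), block/event counts, hardware configuration
#'   (`hardware.*`) and, for protocol recordings, the protocol
#'   configuration (`protocol.*`).
#'
#' Floating-point columns are written with 17 significant digits so that
#' [read_recording()] reproduces the recording exactly (double-precision
#' round trip).
#'
#' @param rec A valid [recording()]; invariants are checked first and the
#'   first violation aborts the write.
#' @param basepath Base path (without suffix) for the three files.
#' @return Invisibly, a named character vector of the three file paths
#'   (`data`, `time`, `meta`).
#' @seealso [read_recording()], [export_csv()]
#' @export
write_recording <- function(rec, basepath) {
  stopifnot(inherits(rec, "recording"))
  .assert_valid(rec)
  paths <- c(data = paste0(basepath, ".data.tsv"),
             time = paste0(basepath, ".time.tsv"),
             meta = paste0(basepath, ".meta.txt"))
  dir <- dirname(basepath)
  if (!dir.exists(dir))
    stop("directory does not exist: ", dir)

  d <- rec$data
  num_cols <- setdiff(names(d), c("sample_id", "block_id", "event_id"))
  out <- d
  for (col in num_cols) out[[col]] <- sprintf("%.17g", d[[col]])
  con <- file(paths["data"], "w")
  writeLines(c("# limbkin recording: sample table",
               paste(names(out), collapse = "\t")), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  close(con)

  con <- file(paths["time"], "w")
  writeLines(c("# limbkin recording: wall-clock timestamps",
               "sample_id\ttime\tmarker"), con)
  if (nrow(rec$timestamps))
    write.table(rec$timestamps, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  close(con)

  writeLines(.serialize_meta(rec$meta), paths["meta"])
  invisible(paths)
}

.serialize_meta <- function(m) {
  kv <- function(key, value) paste0(key, "=", value)
  num <- function(x) sprintf("%.17g", x)
  lines <- c("# limbkin recording: metadata",
             kv("format", "limbkin-recording-v1"),
             kv("created", m$created),
             kv("calibrated", m$calibrated),
             kv("n_blocks", m$n_blocks),
             kv("n_events", m$n_events))
  for (key in names(m$subject))
    lines <- c(lines, kv(paste0("subject.", key), m$subject[[key]]))
  h <- m$hardware
  lines <- c(lines,
             kv("hardware.range_g", num(h$range_g)),
             kv("hardware.sampling_rate_hz", num(h$sampling_rate_hz)),
             kv("hardware.highpass_enabled", h$highpass_enabled),
             kv("hardware.highpass_cutoff_hz", num(h$highpass_cutoff_hz)),
             kv("hardware.beep_duration_ms", num(h$beep_duration_ms)),
             kv("hardware.trigger_edge", h$trigger_edge))
  p <- m$protocol
  if (!is.null(p)) {
    lines <- c(lines,
               kv("protocol.mode", p$mode),
               kv("protocol.stim_rate_mHz", num(p$stim_rate_mHz)),
               kv("protocol.block_duration_s", num(p$block_duration_s)),
               kv("protocol.pause_s", num(p$pause_s)),
               kv("protocol.repetitions", p$repetitions),
               kv("protocol.event_samples", p$event_samples),
               kv("protocol.sampling_rate_hz", num(p$sampling_rate_hz)),
               kv("protocol.trigger_edge", p$trigger_edge),
               kv("protocol.beep_on_trigger", p$beep_on_trigger))
  }
  lines
}

#' Read a recording from the three-file layout
#'
#' Inverse of [write_recording()]: reconstructs the [recording()] object,
#' including metadata, from `<base>.data.tsv`, `<base>.time.tsv` and
#' `<base>.meta.txt`.  Optional columns absent from the data file (raw
#' counts, temperature) stay absent in the result rather than being filled
#' with zeros.  After parsing, the recording is validated and the first
#' invariant violation (for example a gap in `sample_id`) raises an error.
#'
#' @param basepath Base path (without suffix) of the three files.
#' @return A [recording()].
#' @export
read_recording <- function(basepath) {
  paths <- c(data = paste0(basepath, ".data.tsv"),
             time = paste0(basepath, ".time.tsv"),
             meta = paste0(basepath, ".meta.txt"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing recording file(s): ", paste(missing, collapse = ", "))

  d <- .read_tsv(paths["data"],
                 integer_cols = c("sample_id", "block_id", "event_id",
                                  "raw_x", "raw_y", "raw_z"))
  unknown <- setdiff(names(d), .data_cols)
  if (length(unknown))
    stop("unknown column(s) in ", paths["data"], ": ",
         paste(unknown, collapse = ", "))
  missing_cols <- setdiff(.required_cols, names(d))
  if (length(missing_cols))
    stop("missing required column(s) in ", paths["data"], ": ",
         paste(missing_cols, collapse = ", "))

  ts <- .read_tsv(paths["time"], integer_cols = "sample_id",
                  character_cols = c("time", "marker"))
  ts$marker[is.na(ts$marker)] <- ""

  m <- .parse_meta(paths["meta"])
  rec <- recording(d, hardware = m$hardware, protocol = m$protocol,
                   subject = m$subject, timestamps = ts,
                   created = m$created, calibrated = m$calibrated)
  rep <- validate_recording(rec)
  if (nrow(rep))
    stop("invalid recording in ", basepath, ": [", rep$scope[1], " ",
         rep$id[1], "] ", rep$message[1], call. = FALSE)
  if (!identical(as.integer(m$n_blocks), as.integer(rec$meta$n_blocks)) ||
      !identical(as.integer(m$n_events), as.integer(rec$meta$n_events)))
    stop("metadata block/event counts disagree with the data file in ",
         basepath)
  rec
}

# Tab-separated reader with '#' comments and per-line diagnostics.
.read_tsv <- function(path, integer_cols = character(),
                      character_cols = character()) {
  lines <- readLines(path)
  content <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(content)) stop("no header line in ", path)
  n_fields <- count.fields(textConnection(lines[content]), sep = "\t",
                           quote = "", comment.char = "")
  bad <- which(n_fields != n_fields[1])
  if (length(bad))
    stop("malformed row in ", path, " at line ", content[bad[1]],
         ": expected ", n_fields[1], " fields, found ", n_fields[bad[1]])
  d <- read.delim(text = lines[content], sep = "\t", quote = "",
                  comment.char = "", header = TRUE,
                  stringsAsFactors = FALSE, colClasses = "character")
  for (col in names(d)) {
    if (col %in% character_cols) next
    val <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(val) & !is.na(d[[col]]) & d[[col]] != "NA")
    if (length(bad))
      stop("malformed row in ", path, " at data row ", bad[1],
           ": cannot parse ", col, " value '", d[[col]][bad[1]], "'")
    d[[col]] <- if (col %in% integer_cols) as.integer(val) else val
  }
  d
}

.parse_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0))
    stop("malformed metadata line in ", path, ": ", lines[which(eq < 0)[1]])
  keys <- substr(lines, 1, eq - 1)
  vals <- substring(lines, eq + 1)
  kv <- stats::setNames(as.list(vals), keys)
  get <- function(key, default = NULL) {
    if (is.null(kv[[key]])) default else kv[[key]]
  }
  num <- function(key, default) as.numeric(get(key, default))
  lgl <- function(key, default) as.logical(get(key, default))

  subject_keys <- grep("^subject\\.", keys, value = TRUE)
  subject <- stats::setNames(as.list(unlist(kv[subject_keys])),
                             sub("^subject\\.", "", subject_keys))

  hardware <- hardware_config(
    range_g = num("hardware.range_g", 8),
    sampling_rate_hz = num("hardware.sampling_rate_hz", 1000),
    highpass_enabled = lgl("hardware.highpass_enabled", FALSE),
    highpass_cutoff_hz = num("hardware.highpass_cutoff_hz", 0.1),
    beep_duration_ms = num("hardware.beep_duration_ms", 100),
    trigger_edge = get("hardware.trigger_edge", "rising"))

  protocol <- NULL
  if (!is.null(kv[["protocol.mode"]])) {
    protocol <- protocol_config(
      mode = get("protocol.mode"),
      stim_rate_mHz = num("protocol.stim_rate_mHz", 500),
      block_duration_s = num("protocol.block_duration_s", 60),
      pause_s = num("protocol.pause_s", 60),
      repetitions = as.integer(num("protocol.repetitions", 1)),
      event_samples = as.integer(num("protocol.event_samples", 1000)),
      sampling_rate_hz = num("protocol.sampling_rate_hz", 1000),
      trigger_edge = get("protocol.trigger_edge", "rising"),
      beep_on_trigger = lgl("protocol.beep_on_trigger", TRUE))
  }

  list(subject = subject, hardware = hardware, protocol = protocol,
       created = get("created", NA_character_),
       calibrated = lgl("calibrated", FALSE),
       n_blocks = num("n_blocks", NA), n_events = num("n_events", NA))
}

#' Export the sample table as a single CSV
#'
#' Flattens a recording's sample table to one comma-separated file for
#' third-party tools; metadata and timestamps are not included.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  write.csv(rec$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
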