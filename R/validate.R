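#' Check a recording against the data-model invariants
#'
#' Runs every structural invariant of the sample/event/block model and
#' returns all violations found; it never raises on content problems, so it
#' can be used to triage damaged files.  The invariants checked are:
#' globally 0-based, contiguous, strictly increasing `sample_id`;
#' non-decreasing `block_id` with 0-based contiguous values; `event_id`
#' 0-based and contiguous within each block, with event samples stored
#' contiguously; timestamp rows matching sample rows one-to-one; metadata
#' block/event counts agreeing with the data table; and, for protocol-mode
#' recordings, event sample counts equal to the configured `event_samples`
#' and events per block equal to [events_per_block()].
#'
#' @param rec A [recording()].
#' @return A data frame of class `validation_report` with columns `scope`
#'   (`"sample"`, `"event"`, `"block"`, `"timestamps"` or `"meta"`), `id`
#'   (the first offending ID, as a string) and `message`.  Zero rows means
#'   the recording is valid.
#' @export
#' @examples
#' rec <- static_recording(orientation("z"), duration_s = 0.1)
#' nrow(validate_recording(rec)) == 0
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  d <- rec$data
  v <- list()
  add <- function(scope, id, message)
    v[[length(v) + 1L]] <<- data.frame(scope = scope, id = as.character(id),
                                       message = message,
                                       stringsAsFactors = FALSE)

  if (nrow(d)) {
    if (d$sample_id[1] != 0L)
      add("sample", d$sample_id[1], "first sample_id is not 0")
    bad <- which(diff(d$sample_id) != 1L)
    if (length(bad))
      add("sample", d$sample_id[bad[1] + 1L],
          sprintf("sample_id not contiguous after sample %d",
                  d$sample_id[bad[1]]))
    if (any(d$block_id < 0L) || any(d$event_id < 0L))
      add("sample", d$sample_id[which(d$block_id < 0L | d$event_id < 0L)[1]],
          "negative block_id or event_id")

    bad <- which(diff(d$block_id) < 0L)
    if (length(bad))
      add("block", d$block_id[bad[1] + 1L],
          sprintf("block_id decreases at sample %d", d$sample_id[bad[1] + 1L]))
    blocks <- unique(d$block_id)
    if (!identical(sort(blocks), seq_along(blocks) - 1L))
      add("block", blocks[1], "block_id values are not 0-based contiguous")

    # events must be stored contiguously and be 0-based contiguous per block
    key <- paste(d$block_id, d$event_id, sep = "/")
    runs <- rle(key)
    if (anyDuplicated(runs$values))
      add("event", runs$values[duplicated(runs$values)][1],
          "samples of one event are not stored contiguously")
    for (b in blocks) {
      ev <- unique(d$event_id[d$block_id == b])
      if (!identical(sort(ev), seq_along(ev) - 1L)) {
        add("event", paste0(b, "/", ev[1]),
            sprintf("event_id values in block %d are not 0-based contiguous", b))
        break
      }
    }
  }

  ts <- rec$timestamps
  if (nrow(ts) != nrow(d))
    add("timestamps", nrow(ts),
        sprintf("timestamp rows (%d) != sample rows (%d)", nrow(ts), nrow(d)))
  else if (nrow(ts) && !identical(as.integer(ts$sample_id), d$sample_id))
    add("timestamps", ts$sample_id[which(ts$sample_id != d$sample_id)[1]],
        "timestamp sample_id column does not match the data table")

  m <- rec$meta
  n_blocks <- if (nrow(d)) length(unique(d$block_id)) else 0L
  n_events <- if (nrow(d)) nrow(unique(d[, c("block_id", "event_id")])) else 0L
  if (!identical(as.integer(m$n_blocks), n_blocks))
    add("meta", m$n_blocks,
        sprintf("meta n_blocks (%s) != blocks in data (%d)", m$n_blocks, n_blocks))
  if (!identical(as.integer(m$n_events), n_events))
    add("meta", m$n_events,
        sprintf("meta n_events (%s) != events in data (%d)", m$n_events, n_events))

  cfg <- m$protocol
  if (!is.null(cfg) && nrow(d)) {
    ev <- list_events(rec)
    bad <- which(ev$n_samples != cfg$event_samples)
    if (length(bad))
      add("event", paste0(ev$block_id[bad[1]], "/", ev$event_id[bad[1]]),
          sprintf("event has %d samples, protocol specifies %d",
                  ev$n_samples[bad[1]], cfg$event_samples))
    if (cfg$mode == "acoustic") {
      per_block <- table(ev$block_id)
      expected <- events_per_block(cfg)
      bad <- which(as.integer(per_block) != expected)
      if (length(bad))
        add("block", names(per_block)[bad[1]],
            sprintf("block has %d events, protocol specifies %d",
                    as.integer(per_block)[bad[1]], expected))
    }
  }

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(scope = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("recording valid: no invariant violations\n")
  } else {
    cat(nrow(x), "invariant violation(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s %s] %s\n", x$scope[i], x$id[i], x$message[i]))
  }
  invisible(x)
}

# Stop with the first violation; used by writers and pipeline entry points.
.assert_valid <- function(rec) {
  rep <- validate_recording(rec)
  if (nrow(rep))
    stop("invalid recording: [", rep$scope[1], " ", rep$id[1], "] ",
         rep$message[1], call. = FALSE)
  invisible(rec)
}
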