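# Event-log data model: time-stamped device state changes at 1-ms resolution.

EVENT_COLUMNS <- c("time_ms", "event_type", "location", "magnitude")

#' Construct an event log
#'
#' An event log is the primary record of an automated behavior session: a
#' time-ordered sequence of state changes ("on"/"off") at named device
#' channels (odor-port IR beam, odor valves, water valves, lick sensor, TTL
#' lines), each stamped with integer milliseconds since the start of the
#' recording and an analog magnitude (0 is allowed, e.g. for digital lines).
#'
#' Events are stored sorted by `time_ms`; ties are broken by `location` and
#' then by event type with "off" preceding "on", so that a zero-length gap
#' between two bouts at the same channel remains representable.
#'
#' @param events Data frame with columns `time_ms` (non-negative integer
#'   milliseconds), `event_type` (`"on"` or `"off"`), `location` (non-empty
#'   channel identifier) and `magnitude` (numeric). May be `NULL` or empty.
#' @param meta Named list of free-form header metadata (animal id, assay id,
#'   seed, ...). Values are coerced to single character strings.
#' @return An object of class `event_log`: a list with elements `events`
#'   (sorted data frame) and `meta`.
#' @examples
#' ev <- data.frame(
#'   time_ms = c(5L, 8L), event_type = c("on", "off"),
#'   location = "odor_port_ir", magnitude = 1
#' )
#' log <- event_log(ev, meta = list(animal = "m01"))
#' n_events(log)
#' @export
event_log <- function(events = NULL, meta = list()) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- data.frame(
      time_ms = integer(), event_type = character(),
      location = character(), magnitude = double(),
      stringsAsFactors = FALSE
    )
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0L) {
    stop_olf("event data frame lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  events <- events[EVENT_COLUMNS]
  validate_events(events)
  events$time_ms <- as.integer(round(events$time_ms))
  events$event_type <- as.character(events$event_type)
  events$location <- as.character(events$location)
  events$magnitude <- as.double(events$magnitude)
  events <- sort_events(events)
  if (length(meta) > 0L && is.null(names(meta))) {
    stop_olf("meta entries must be named")
  }
  meta <- lapply(meta, function(v) paste(as.character(v), collapse = " "))
  structure(list(events = events, meta = meta), class = "event_log")
}

validate_events <- function(events) {
  t <- events$time_ms
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_olf("event times must be finite and non-negative",
             class = "olf_validation_error")
  }
  if (any(abs(t - round(t)) > 0)) {
    stop_olf("event times must be integer milliseconds (1-ms quantization)",
             class = "olf_validation_error")
  }
  if (!all(events$event_type %in% c("on", "off"))) {
    stop_olf("event_type must be \"on\" or \"off\"",
             class = "olf_validation_error")
  }
  loc <- as.character(events$location)
  if (any(is.na(loc) | !nzchar(loc))) {
    stop_olf("location must be a non-empty string",
             class = "olf_validation_error")
  }
  if (any(!is.finite(events$magnitude))) {
    stop_olf("magnitude must be finite", class = "olf_validation_error")
  }
  invisible(events)
}

sort_events <- function(events) {
  # off before on at identical (time, location)
  ord <- order(events$time_ms, events$location, events$event_type != "off")
  ev <- events[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log: %d events, %d channel(s)>\n",
              nrow(x$events), length(unique(x$events$location))))
  if (length(x$meta) > 0L) {
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                       collapse = ", "), "\n")
  }
  if (nrow(x$events) > 0L) {
    print(utils::head(x$events, 10L))
    if (nrow(x$events) > 10L) cat("...\n")
  }
  invisible(x)
}

#' Number of events in a log
#' @param log An `event_log`.
#' @return Integer count of events.
#' @export
n_events <- function(log) {
  stopifnot(inherits(log, "event_log"))
  nrow(log$events)
}

#' Parse an event log from text
#'
#' Reads the plain-text event-log dialect: optional leading `#`-prefixed
#' metadata lines of the form `# key=value`, a mandatory header line
#' `time_ms,event_type,location,magnitude`, then one comma-separated row per
#' event. UTF-8, LF line endings.
#'
#' @param text Either a single string containing the whole log or a
#'   character vector of lines.
#' @return An `event_log`.
#' @seealso [write_event_log()], [read_event_log()]
#' @export
parse_event_log <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- sub("\r$", "", lines)

  meta <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n && grepl("^#", lines[i])) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0L) {
      key <- trimws(substr(kv, 1L, eq - 1L))
      val <- trimws(substr(kv, eq + 1L, nchar(kv)))
      if (nzchar(key)) meta[[key]] <- val
    }
    i <- i + 1L
  }
  if (i > n || !nzchar(trimws(lines[i]))) {
    stop_olf("missing header line (line ", i, ")", class = "olf_parse_error")
  }
  header <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
  if (!identical(header, EVENT_COLUMNS)) {
    stop_olf("line ", i, ": header must be \"",
             paste(EVENT_COLUMNS, collapse = ","), "\"",
             class = "olf_parse_error")
  }
  i <- i + 1L

  rows <- lines[seq.int(i, length.out = max(0L, n - i + 1L))]
  keep <- nzchar(trimws(rows))
  row_lines <- which(keep) + i - 1L
  rows <- rows[keep]

  if (length(rows) == 0L) {
    return(event_log(NULL, meta = meta))
  }

  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad) > 0L) {
    stop_olf("line ", row_lines[bad[1]], ": expected 4 comma-separated fields",
             class = "olf_parse_error")
  }
  m <- matrix(trimws(unlist(parts)), ncol = 4L, byrow = TRUE)

  t_chr <- m[, 1]
  bad_t <- which(!grepl("^[0-9]+$", t_chr))
  if (length(bad_t) > 0L) {
    stop_olf("line ", row_lines[bad_t[1]],
             ": time_ms must be a non-negative integer (got \"",
             t_chr[bad_t[1]], "\")", class = "olf_validation_error")
  }
  type <- m[, 2]
  bad_type <- which(!type %in% c("on", "off"))
  if (length(bad_type) > 0L) {
    stop_olf("line ", row_lines[bad_type[1]],
             ": event_type must be \"on\" or \"off\" (got \"",
             type[bad_type[1]], "\")", class = "olf_validation_error")
  }
  mag <- suppressWarnings(as.double(m[, 4]))
  bad_mag <- which(!is.finite(mag))
  if (length(bad_mag) > 0L) {
    stop_olf("line ", row_lines[bad_mag[1]], ": magnitude must be numeric",
             class = "olf_parse_error")
  }
  events <- data.frame(
    time_ms = as.integer(t_chr), event_type = type,
    location = m[, 3], magnitude = mag, stringsAsFactors = FALSE
  )
  event_log(events, meta = meta)
}

#' Read an event log from a file
#' @param path Path to an event-log text file.
#' @return An `event_log`.
#' @export
read_event_log <- function(path) {
  parse_event_log(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Serialize an event log
#'
#' Emits the same dialect [parse_event_log()] reads; `parse(write(x))`
#' reproduces the event sequence exactly (magnitudes are printed with at
#' most 6 significant digits, so inputs already at that precision
#' round-trip bit-exactly).
#'
#' @param log An `event_log`.
#' @param path Optional file path. If supplied, the text is written there
#'   (UTF-8, LF) and the path is returned invisibly.
#' @return The log text as a single string, or the path invisibly.
#' @export
write_event_log <- function(log, path = NULL) {
  stopifnot(inherits(log, "event_log"))
  meta_lines <- if (length(log$meta) > 0L) {
    paste0("# ", names(log$meta), "=", unlist(log$meta))
  } else {
    character()
  }
  ev <- log$events
  body <- if (nrow(ev) > 0L) {
    paste(ev$time_ms, ev$event_type, ev$location,
          format_magnitude(ev$magnitude), sep = ",")
  } else {
    character()
  }
  lines <- c(meta_lines, paste(EVENT_COLUMNS, collapse = ","), body)
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) {
    return(text)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  invisible(path)
}

format_magnitude <- function(x) {
  vapply(x, function(v) format(signif(v, 6L), trim = TRUE, scientific = NA),
         character(1))
}

#' Pair on/off events into investigation intervals
#'
#' Matches each "on" event at `location` to the next "off" at the same
#' location, producing closed bouts (e.g. nose-poke intervals from an IR
#' beam channel). Degenerate sequences are resolved deterministically:
#' a second "on" while the channel is already on is a hardware glitch (an
#' IR beam cannot re-break while broken) and is discarded; an "off" with no
#' preceding "on" is discarded; a trailing unmatched "on" is closed at the
#' last event time in the whole log (recording stopped while the animal was
#' still in the port). A warning reports the number of discarded events.
#'
#' @param log An `event_log`.
#' @param location Channel identifier to pair events at.
#' @return Data frame with columns `location`, `start_ms`, `end_ms`,
#'   `duration_ms`, carrying attribute `n_discarded` (integer count of
#'   dropped glitch events).
#' @examples
#' ev <- data.frame(
#'   time_ms = c(5L, 8L, 20L, 26L), event_type = c("on", "off", "on", "off"),
#'   location = "odor_port_ir", magnitude = 1
#' )
#' pair_events(event_log(ev), "odor_port_ir")
#' @export
pair_events <- function(log, location) {
  stopifnot(inherits(log, "event_log"))
  ev <- log$events[log$events$location == location, , drop = FALSE]
  starts <- integer(0)
  ends <- integer(0)
  open_at <- NA_integer_
  discarded <- 0L
  for (i in seq_len(nrow(ev))) {
    t <- ev$time_ms[i]
    if (ev$event_type[i] == "on") {
      if (is.na(open_at)) {
        open_at <- t
      } else {
        discarded <- discarded + 1L  # on-while-on glitch
      }
    } else {
      if (is.na(open_at)) {
        discarded <- discarded + 1L  # off with no open bout
      } else {
        starts <- c(starts, open_at)
        ends <- c(ends, t)
        open_at <- NA_integer_
      }
    }
  }
  if (!is.na(open_at)) {
    log_end <- max(log$events$time_ms)
    starts <- c(starts, open_at)
    ends <- c(ends, max(open_at, log_end))
  }
  if (discarded > 0L) {
    warning(sprintf("pair_events: discarded %d unmatched event(s) at %s",
                    discarded, location),
            call. = FALSE)
  }
  out <- data.frame(
    location = rep(location, length(starts)),
    start_ms = starts, end_ms = ends,
    duration_ms = ends - starts,
    stringsAsFactors = FALSE
  )
  attr(out, "n_discarded") <- discarded
  out
}

stop_olf <- function(..., class = "olf_error", call = sys.call(-1)) {
  stop(structure(
    class = c(class, "olf_error", "error", "condition"),
    list(message = paste0(...), call = call)
  ))
}
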