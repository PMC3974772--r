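# Independent brute-force oracles and random fixture generators. These are
# deliberately written differently from the package implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force on/off pairing: walk the (time-ordered) event sequence for one
# location with an explicit open/closed state.
oracle_pair <- function(times, types, log_end) {
  open <- NA
  out_s <- c()
  out_e <- c()
  dropped <- 0L
  for (i in seq_along(times)) {
    if (types[i] == "on") {
      if (is.na(open)) open <- times[i] else dropped <- dropped + 1L
    } else {
      if (is.na(open)) {
        dropped <- dropped + 1L
      } else {
        out_s <- c(out_s, open)
        out_e <- c(out_e, times[i])
        open <- NA
      }
    }
  }
  if (!is.na(open)) {
    out_s <- c(out_s, open)
    out_e <- c(out_e, max(open, log_end))
  }
  list(start = out_s, end = out_e, dropped = dropped)
}

# Millisecond-grid counting oracle for interval/window overlap under
# half-open [start, end) semantics.
oracle_investigation <- function(pokes, window) {
  if (nrow(pokes) == 0L) return(0)
  total <- 0L
  for (i in seq_len(nrow(pokes))) {
    ms <- seq.int(pokes$start_ms[i], pokes$end_ms[i] - 1L,
                  length.out = max(0L, pokes$end_ms[i] - pokes$start_ms[i]))
    if (length(ms) > 0L) {
      total <- total + sum(ms >= window[1] & ms < window[2])
    }
  }
  total
}

# Random well-formed event log with magnitudes already at <= 6 significant
# digits (so serialization round-trips exactly).
random_event_log <- function(n_events, n_locations = 3L, t_max = 10000L) {
  locs <- paste0("chan_", seq_len(n_locations))
  data_ev <- data.frame(
    time_ms = sample.int(t_max, n_events, replace = TRUE) - 1L,
    event_type = sample(c("on", "off"), n_events, replace = TRUE),
    location = sample(locs, n_events, replace = TRUE),
    magnitude = signif(stats::runif(n_events, 0, 10), 4L),
    stringsAsFactors = FALSE
  )
  event_log(data_ev, meta = list(source = "random", n = n_events))
}

default_concs <- function() 2e-6 * 10^seq(-1.5, 1.5, 0.5)
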