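# Event-log parsing, serialization and interval pairing.

test_that("parsing handles headers, metadata and empty bodies", {
  txt <- "# animal_id=m01\n# seed=7\ntime_ms,event_type,location,magnitude\n"
  log <- parse_event_log(txt)
  expect_equal(n_events(log), 0L)
  expect_equal(log$meta$animal_id, "m01")
  expect_equal(log$meta$seed, "7")

  # ten rows forming five on/off pairs at the nose-poke channel
  t_on <- c(100L, 900L, 2500L, 4000L, 7000L)
  t_off <- t_on + c(300L, 150L, 600L, 90L, 1200L)
  rows <- paste0(
    c(rbind(t_on, t_off)), ",",
    rep(c("on", "off"), 5L), ",odor_port_ir,1"
  )
  log10 <- parse_event_log(c("time_ms,event_type,location,magnitude", rows))
  expect_equal(n_events(log10), 10L)
  iv <- pair_events(log10, "odor_port_ir")
  expect_equal(nrow(iv), 5L)
  expect_equal(iv$start_ms, t_on)
  expect_equal(iv$duration_ms, c(300L, 150L, 600L, 90L, 1200L))
})

test_that("malformed input is rejected with the offending line number", {
  hdr <- "time_ms,event_type,location,magnitude"
  expect_error(parse_event_log(c(hdr, "5,on,port")), "line 2",
               class = "olf_parse_error")
  expect_error(parse_event_log(c(hdr, "5,on,port,1", "-3,off,port,1")),
               "line 3", class = "olf_validation_error")
  expect_error(parse_event_log(c(hdr, "5.5,on,port,1")),
               "non-negative integer", class = "olf_validation_error")
  expect_error(parse_event_log(c(hdr, "5,blink,port,1")),
               class = "olf_validation_error")
  expect_error(parse_event_log("# only=meta"), class = "olf_parse_error")
})

test_that("event ordering breaks time ties with off before on", {
  ev <- data.frame(
    time_ms = c(10L, 10L, 5L), event_type = c("on", "off", "on"),
    location = "lick_ir", magnitude = 0
  )
  log <- event_log(ev)
  expect_equal(log$events$time_ms, c(5L, 10L, 10L))
  expect_equal(log$events$event_type, c("on", "off", "on"))
  # the zero-length gap stays pairable with no discards
  iv <- pair_events(log, "lick_ir")
  expect_equal(iv$start_ms, c(5L, 10L))
  expect_equal(attr(iv, "n_discarded"), 0L)
})

test_that("serialization round-trips: parse o write and write o parse", {
  ev <- data.frame(time_ms = 0L, event_type = "on", location = "lick_ir",
                   magnitude = 1.0)
  one <- event_log(ev)
  txt <- write_event_log(one)
  expect_equal(length(strsplit(txt, "\n")[[1]]), 2L)  # header + 1 row
  expect_identical(parse_event_log(txt)$events, one$events)

  empty_txt <- write_event_log(event_log(NULL, meta = list(a = "b")))
  rt <- parse_event_log(empty_txt)
  expect_equal(n_events(rt), 0L)
  expect_equal(rt$meta$a, "b")

  set.seed(401)
  for (i in 1:30) {
    log <- random_event_log(sample(c(1L, 10L, 500L), 1L))
    txt <- write_event_log(log)
    back <- parse_event_log(txt)
    expect_identical(back$events, log$events)
    # write o parse is the identity on the serialized form
    expect_identical(write_event_log(back), txt)
  }
})

test_that("file I/O preserves the log", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(402)
  log <- random_event_log(120L)
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_identical(back$events, log$events)
  expect_equal(back$meta$source, "random")
})

test_that("pairing resolves degenerate sequences per the state machine", {
  mk <- function(t, ty, loc = "odor_port_ir") {
    event_log(data.frame(time_ms = t, event_type = ty, location = loc,
                         magnitude = 1))
  }
  iv <- pair_events(mk(c(5L, 8L), c("on", "off")), "odor_port_ir")
  expect_equal(iv[, c("start_ms", "end_ms", "duration_ms")],
               data.frame(start_ms = 5L, end_ms = 8L, duration_ms = 3L))

  # on-while-on: keep the first on, discard the glitch
  expect_warning(
    iv2 <- pair_events(mk(c(5L, 9L, 12L), c("on", "on", "off")),
                       "odor_port_ir"),
    "discarded 1"
  )
  expect_equal(iv2$start_ms, 5L)
  expect_equal(iv2$end_ms, 12L)

  # leading off is dropped
  expect_warning(
    iv3 <- pair_events(mk(c(2L, 5L, 8L), c("off", "on", "off")),
                       "odor_port_ir"),
    "discarded 1"
  )
  expect_equal(iv3$start_ms, 5L)

  # trailing open bout closes at the last event time of the whole log
  log4 <- event_log(data.frame(
    time_ms = c(5L, 900L), event_type = c("on", "off"),
    location = c("odor_port_ir", "ttl_out"), magnitude = 1
  ))
  iv4 <- pair_events(log4, "odor_port_ir")
  expect_equal(iv4$end_ms, 900L)
})

test_that("pairing agrees with the brute-force oracle on random logs", {
  set.seed(403)
  for (i in 1:200) {
    log <- random_event_log(sample.int(50L, 1L), n_locations = 2L)
    loc <- sample(unique(log$events$location), 1L)
    suppressWarnings(iv <- pair_events(log, loc))
    sel <- log$events[log$events$location == loc, ]
    want <- oracle_pair(sel$time_ms, sel$event_type,
                        max(log$events$time_ms))
    expect_equal(iv$start_ms, as.integer(want$start %||% integer(0)))
    expect_equal(iv$end_ms, as.integer(want$end %||% integer(0)))
    expect_equal(attr(iv, "n_discarded"), want$dropped)
    # intervals never overlap and never exceed the log time span
    if (nrow(iv) > 1L) {
      expect_true(all(iv$start_ms[-1] >= iv$end_ms[-nrow(iv)]))
    }
    expect_lte(sum(iv$duration_ms),
               max(log$events$time_ms) - min(log$events$time_ms))
  }
})
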