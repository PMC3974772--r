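# Behavioral statistics: investigation, NPI, dNPI, success rates,
# preference indices and the JND threshold.

test_that("investigation duration clips pokes to the session window", {
  w <- c(0, 60000)
  none <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  expect_equal(investigation_duration(none, w), 0)

  straddle <- data.frame(start_ms = -1000, end_ms = 2000)
  expect_equal(investigation_duration(straddle, w), 2000)

  outside <- data.frame(start_ms = 70000, end_ms = 71000)
  expect_equal(investigation_duration(outside, w), 0)

  set.seed(21)
  for (i in 1:50) {
    n <- sample.int(12L, 1L)
    s <- sort(sample.int(5000L, n))
    pokes <- data.frame(start_ms = s,
                        end_ms = s + sample.int(800L, n, replace = TRUE))
    win <- sort(sample.int(6000L, 2L)) - 500L
    expect_equal(investigation_duration(pokes, win),
                 oracle_investigation(pokes, win))
  }
})

test_that("basal activity is the arithmetic mean of background sessions", {
  expect_equal(basal_activity(rep(3000, 8)), 3000)
  expect_equal(basal_activity(c(1000, 2000)), 1500)
  set.seed(22)
  for (i in 1:20) {
    x <- runif(sample.int(10L, 1L), 0, 60000)
    expect_equal(basal_activity(x), sum(x) / length(x))
  }
  expect_error(basal_activity(numeric(0)))
})

test_that("NPI normalizes to the basal mean and flags excluded animals", {
  expect_equal(npi(3000, 3000), 100)
  expect_equal(npi(6000, 3000), 200)
  durations <- c(1200, 4000, 800, 2000)
  basal <- basal_activity(durations)
  expect_equal(mean(npi(durations, basal)), 100)  # algebraic identity
  expect_error(npi(1000, 0), class = "olf_animal_excluded")
})

test_that("dNPI is the successive-session difference", {
  expect_equal(delta_npi(c(100, 100, 100)), c(0, 0))
  expect_equal(delta_npi(c(100, 250, 120)), c(150, -130))
  expect_error(delta_npi(100))
})

test_that("success rates follow their count definitions and invariants", {
  expect_equal(success_rate_two_choice(choice_counts(30, 30, 60)), 1)
  expect_equal(success_rate_two_choice(choice_counts(15, 15, 60)), 0.5)
  expect_equal(success_rate_two_choice(choice_counts(20, 25, 60)), 0.75)
  expect_error(success_rate_two_choice(choice_counts(0, 0, 0)),
               class = "olf_undefined_rate")
  expect_error(choice_counts(40, 30, 60))

  expect_equal(success_rate_gonogo(gonogo_counts(30, 0, 0, 30)), 1)
  # licking every trial on a balanced sequence is forced to chance
  expect_equal(success_rate_gonogo(gonogo_counts(30, 0, 30, 0)), 0.5)
  expect_equal(success_rate_gonogo(gonogo_counts(25, 5, 10, 20)), 0.75)
  expect_error(success_rate_gonogo(gonogo_counts(0, 0, 0, 0)),
               class = "olf_undefined_rate")

  # rates are bounded and order-free: random count splits
  set.seed(23)
  for (i in 1:50) {
    n <- 60L
    caa <- sample.int(30L, 1L); cbb <- sample.int(30L, 1L)
    sr <- success_rate_two_choice(choice_counts(caa, cbb, n))
    expect_gte(sr, 0); expect_lte(sr, 1)
    k <- sample.int(n, 4L)
    sr2 <- success_rate_gonogo(gonogo_counts(k[1], k[2], k[3], k[4]))
    expect_gte(sr2, 0); expect_lte(sr2, 1)
  }
})

test_that("attraction and aversion indices are NPI contrasts", {
  series <- c(rep(100, 7), 100, 300, 40, 35, 30)  # MO x8 then odor x4
  expect_equal(attraction_index(series, 9), 200)
  expect_equal(aversion_index(series, 10), 60)
  flat <- rep(100, 12)
  expect_equal(attraction_index(flat, 9), 0)
  expect_equal(aversion_index(flat, 10), 0)
  expect_error(attraction_index(series, 1))
  expect_error(aversion_index(series, 2))
})

test_that("three-chamber indices normalize to control-zone time", {
  expect_equal(three_chamber_indices(300, 300),
               list(attraction = 0, aversion = 0))
  expect_equal(three_chamber_indices(450, 300),
               list(attraction = 0.5, aversion = -0.5))
  expect_error(three_chamber_indices(300, 0),
               class = "olf_animal_excluded")
})

test_that("JND threshold detects a shifted column and controls the null", {
  concs <- 10^seq(-7, -4, length.out = 6)
  zero <- matrix(0, nrow = 6, ncol = 6)
  expect_true(is.na(jnd_threshold(zero, concs)$threshold_sv))

  # one concentration with a strong real effect among exactly-null columns
  set.seed(31)
  m <- matrix(rnorm(8 * 6, 0, 10), nrow = 8)
  m <- sweep(m, 2L, colMeans(m))  # null columns carry zero mean exactly
  m[, 4] <- m[, 4] + 120
  j <- jnd_threshold(m, concs)
  expect_equal(j$threshold_sv, concs[4])
  # raw p value matches the reference t-test implementation
  expect_equal(j$p_values[4], t.test(m[, 4], mu = 0)$p.value)

  # threshold is non-increasing as alpha grows on a monotone effect ramp
  set.seed(32)
  ramp <- sapply(seq(0, 25, length.out = 6),
                 function(mu) rnorm(10, mu, 8))
  prev <- Inf
  for (alpha in c(0.001, 0.01, 0.05, 0.2)) {
    th <- jnd_threshold(ramp, concs, alpha = alpha)$threshold_sv
    th <- if (is.na(th)) Inf else th
    expect_lte(th, prev)
    prev <- th
  }

  # degenerate variance: constant non-zero column is decisive evidence
  m2 <- zero
  m2[, 2] <- 50
  expect_equal(jnd_threshold(m2, concs)$threshold_sv, concs[2])
})

test_that("session metrics tie the pipeline together", {
  sched <- build_cross_habituation("AA", n_air = 4L, n_s1 = 2L)
  # hand-built log: constant 5 s investigation in every air session,
  # 15 s in the first odor session, 5 s in the second
  inv_s <- c(5, 5, 5, 5, 15, 5) * 1000
  on <- sched$onset_ms + 1000
  ev <- data.frame(
    time_ms = as.integer(c(on, on + inv_s)),
    event_type = rep(c("on", "off"), each = 6L),
    location = "odor_port_ir", magnitude = 1
  )
  log <- event_log(ev)
  sm <- session_metrics(log, sched)
  expect_equal(attr(sm, "basal_ms"), 5000)
  expect_equal(sm$npi_percent, c(100, 100, 100, 100, 300, 100))
  expect_equal(sm$delta_npi_percent, c(NA, 0, 0, 0, 200, -200))
  expect_equal(mean(sm$npi_percent[sm$stimulus == "air"]), 100)

  # last_k basal option
  sm2 <- session_metrics(log, sched, basal_sessions = "last_k", k = 2L)
  expect_equal(attr(sm2, "basal_ms"), 5000)

  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_table(sm, path)
  back <- read_metrics_table(path)
  expect_equal(back$npi_percent, sm$npi_percent)

  # an animal that never pokes is excluded, not silently scored
  quiet <- event_log(data.frame(time_ms = 0L, event_type = "on",
                                location = "ttl_out", magnitude = 1))
  expect_error(session_metrics(quiet, sched),
               class = "olf_animal_excluded")
})
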