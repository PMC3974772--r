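# Generative virtual mouse: log validity, determinism, and the behavioral
# structure (habituation, dis-habituation, valence, operant learning) the
# analyses assume.

test_that("simulated logs are valid, pairable and deterministic", {
  sched <- build_cross_habituation("HXH", "HXO", n_s2 = 2L)
  p <- virtual_mouse_params()
  log1 <- simulate_habituation_assay(p, sched, seed = 5)
  log2 <- simulate_habituation_assay(p, sched, seed = 5)
  expect_identical(write_event_log(log1), write_event_log(log2))
  log3 <- simulate_habituation_assay(p, sched, seed = 6)
  expect_false(identical(write_event_log(log1), write_event_log(log3)))

  # 1-ms quantization and round-trip validity
  expect_true(is.integer(log1$events$time_ms))
  back <- parse_event_log(write_event_log(log1))
  expect_identical(back$events, log1$events)

  # nose-poke channel pairs with zero discards
  iv <- pair_events(log1, "odor_port_ir")
  expect_equal(attr(iv, "n_discarded"), 0L)
  expect_true(all(iv$duration_ms >= 1))
  expect_true(all(iv$start_ms[-1] >= iv$end_ms[-nrow(iv)]))

  # odor valve and TTL markers present
  expect_true(any(log1$events$location == "odor_valve_HXH"))
  expect_true(any(log1$events$location == "ttl_out"))
})

test_that("a blind, indifferent mouse treats odor sessions like air", {
  # eta = 0: odor sessions share the air rate; NPI close to 100 on average
  sched <- build_cross_habituation("AA", n_air = 8L, n_s1 = 4L)
  p0 <- virtual_mouse_params(eta = 0)
  odor_npi <- unlist(lapply(1:60, function(r) {
    log <- simulate_habituation_assay(p0, sched, seed = 3000 + r)
    sm <- session_metrics(log, sched)
    sm$npi_percent[sm$stimulus == "AA"]
  }))
  # small positive bias (~6%) is expected from the ratio normalization
  expect_lt(abs(mean(odor_npi) - 100), 15)
})

test_that("expected session rates encode habituation and similarity", {
  p <- virtual_mouse_params()
  conc <- 2e-3  # far above the ground-truth threshold: p_detect ~ 1

  # repeated identical stimulus: first session strongly elevated, then a
  # non-increasing decay back toward baseline (habituation monotonicity)
  sched <- build_cross_habituation("AA", n_air = 2L, n_s1 = 4L,
                                   conc_s1 = conc)
  mult <- olfactr:::session_rate_multipliers(p, sched)
  odor_mult <- mult[3:6]
  expect_gt(odor_mult[1], 3)
  expect_true(all(diff(odor_mult) < 0))
  expect_lt(odor_mult[4], 1.1)

  # indistinguishable S2 (D = 0) elicits no dis-habituation at the switch
  psame <- virtual_mouse_params(similarity = c("S1:S2" = 0))
  sw <- build_cross_habituation("S1", "S2", n_air = 2L, n_s1 = 3L,
                                n_s2 = 2L, conc_s1 = conc, conc_s2 = conc)
  msw <- olfactr:::session_rate_multipliers(psame, sw)
  expect_equal(msw[6], 1, tolerance = 1e-9)  # first S2 session flat
  # while a fully distinct S2 (D = 1) dis-habituates
  pdiff <- virtual_mouse_params(similarity = c("S1:S2" = 1))
  mdiff <- olfactr:::session_rate_multipliers(pdiff, sw)
  expect_gt(mdiff[6], 3)

  # sub-threshold concentrations are undetectable hence not novel
  faint <- build_cross_habituation("AA", n_air = 2L, n_s1 = 1L,
                                   conc_s1 = 2e-9)
  expect_lt(olfactr:::session_rate_multipliers(p, faint)[3], 1.01)
})

test_that("habituation shows in simulated investigation means", {
  conc <- 2e-3
  sched <- build_cross_habituation("AA", n_air = 2L, n_s1 = 3L,
                                   conc_s1 = conc)
  p <- virtual_mouse_params()
  inv <- t(sapply(1:120, function(r) {
    log <- simulate_habituation_assay(p, sched, seed = 4000 + r)
    pokes <- pair_events(log, "odor_port_ir")
    vapply(which(sched$stimulus == "AA"), function(i) {
      investigation_duration(
        pokes, c(sched$onset_ms[i], sched$onset_ms[i] + sched$duration_ms[i])
      )
    }, numeric(1))
  }))
  means <- colMeans(inv)
  expect_gt(means[1], 2 * means[2])
  expect_gt(means[2], means[3] * 0.8)
})

test_that("valence drives the preference indices in opposite directions", {
  conc <- 2e-3
  sched <- build_preference_assay("odorX", n_mo = 4L, n_odor = 3L,
                                  conc = conc)
  run_idx <- function(valence, seeds) {
    p <- virtual_mouse_params(valence = c(odorX = valence))
    sapply(seeds, function(s) {
      log <- simulate_habituation_assay(p, sched, seed = s)
      sm <- session_metrics(log, sched)
      c(att = attraction_index(sm$npi_percent, 5L),
        ave = aversion_index(sm$npi_percent, 6L))
    })
  }
  pos <- run_idx(+0.8, 5000 + 1:80)
  neg <- run_idx(-0.8, 5000 + 1:80)
  # attractive odor: strong first-session attraction, no aversion
  expect_gt(mean(pos["att", ]), 100)
  # aversive odor: investigation suppressed below baseline from session 2
  expect_gt(mean(neg["ave", ]), 20)
  expect_lt(mean(neg["ave", ]) * -1, mean(pos["att", ]))
  # matched positive vs negative valence push the indices apart
  expect_gt(mean(pos["att", ]) - mean(neg["att", ]) +
              mean(neg["ave", ]) - mean(pos["ave", ]), 0)
})

test_that("operant simulators sit at chance when blind and learn when not", {
  p <- virtual_mouse_params()
  # undetectable concentration: SR ~ 0.5 over 600 trials
  correct <- unlist(lapply(1:10, function(i) {
    tr <- build_two_choice_session("AA", "HPH", seed = 600 + i)
    cc <- simulate_two_choice(p, tr, 1e-12, seed = 700 + i,
                              start_trial = 1000L)
    attr(cc, "trial_correct")
  }))
  sr0 <- mean(correct)
  expect_lt(abs(sr0 - 0.5), 2.58 * sqrt(0.25 / 600))  # 99% binomial CI

  # trained animal at high concentration approaches the asymptote
  correct_hi <- unlist(lapply(1:10, function(i) {
    tr <- build_two_choice_session("AA", "HPH", seed = 800 + i)
    cc <- simulate_two_choice(p, tr, 2e-3, seed = 900 + i,
                              start_trial = 1000L)
    attr(cc, "trial_correct")
  }))
  expect_gt(mean(correct_hi), 0.9)

  # expected SR is non-increasing as concentration decreases
  pc <- sapply(default_concs(), function(cc) {
    olfactr:::operant_p_correct(p, 1000L, cc)
  })
  expect_true(all(diff(pc) >= 0))

  # naive animal starts near chance even on a detectable odor
  expect_lt(olfactr:::operant_p_correct(p, 1L, 2e-3), 0.55)

  # go/no-go counts add up and reach high SR when trained
  tr <- build_gonogo_session("AA", "MO", seed = 42)
  gg <- simulate_gonogo(p, tr, 2e-3, seed = 43, start_trial = 1000L)
  expect_equal(gg$p_cs_plus + gg$np_cs_plus, 30)
  expect_equal(gg$p_cs_minus + gg$np_cs_minus, 30)
  expect_gt(success_rate_gonogo(gg), 0.85)
})

test_that("cohorts are reproducible, stable under growth, and variable", {
  sched <- build_cross_habituation("AA", n_air = 3L, n_s1 = 2L)
  p <- virtual_mouse_params()
  c1 <- simulate_cohort(3L, p, sched, seed = 10)
  c2 <- simulate_cohort(3L, p, sched, seed = 10)
  expect_identical(lapply(c1, write_event_log),
                   lapply(c2, write_event_log))
  # enlarging the cohort leaves earlier animals untouched
  c3 <- simulate_cohort(5L, p, sched, seed = 10)
  expect_identical(write_event_log(c3[[2]]), write_event_log(c1[[2]]))
  # per-animal basal activity varies when the spread is positive
  basals <- vapply(simulate_cohort(6L, p, sched, seed = 11), function(lg) {
    attr(session_metrics(lg, sched), "basal_ms")
  }, numeric(1))
  expect_gt(stats::sd(basals), 0)
})

test_that("ground truth serializes alongside simulated cohorts", {
  p <- virtual_mouse_params(valence = c(AA = 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(p, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$detect$a, 2e-6)
  expect_equal(gt$rho, 0.25)
  expect_equal(gt$valence$AA, 0.2)
})
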