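# Generative virtual mouse: Poisson nose-poke bouts with habituation,
# detection-gated novelty responses, valence effects and operant learning.
# Produces event logs with the statistical structure the analysis modules
# assume, so the whole pipeline is testable without animals.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters of the virtual mouse
#'
#' The simulated animal investigates the odor port in bouts arriving as a
#' Poisson process. Its session rate is the baseline rate times a
#' multiplier capturing novelty-driven dis-habituation (gated by a
#' ground-truth detection psychometric), stimulus-specific habituation,
#' and odor valence; operant choices follow an exponential learning curve
#' scaled by detectability.
#'
#' The behavioral rate constants are not reported quantities anywhere;
#' the defaults (4 bouts/min, 800-ms mean bouts) are plausibility choices
#' for a mouse investigating a novel port and are fully configurable.
#'
#' @param lambda_base_per_min Baseline poke-bout rate during background
#'   sessions (bouts/min, default 4).
#' @param bout_mean_ms Mean bout duration (ms, default 800; exponential).
#' @param rho Per-repeat habituation multiplier on the novelty response,
#'   in (0, 1]. The default 0.25 makes habituation essentially complete
#'   after a single exposure, matching the observed assay phenomenology
#'   (interest returns to background by the second presentation of the
#'   same stimulus).
#' @param eta Novelty gain: a fully novel, fully detectable stimulus
#'   multiplies the bout rate by `1 + eta` on first presentation
#'   (default 3, putting first-odor NPI around 400%).
#' @param detect Ground-truth detection psychometric
#'   (`psychometric_params` with `g = 0`); `weibull_psychometric(c, detect)`
#'   is the probability the animal detects concentration `c`.
#' @param valence Named numeric vector mapping odor id to valence in
#'   \[-1, 1\] (0 = neutral; negative = aversive). Unlisted odors are
#'   neutral.
#' @param similarity Named numeric vector mapping `"odor1:odor2"`
#'   (alphabetical order) to perceptual dissimilarity D in \[0, 1\]
#'   (0 = indistinguishable). Unlisted distinct pairs default to 1;
#'   an odor vs itself is always 0.
#' @param intensity_dissimilarity D assigned to the same odor at a
#'   different concentration (default 1: a detectable intensity step is
#'   treated as fully novel, which makes the ascending threshold series'
#'   expected dNPI proportional to the detection probability).
#' @param learn_tau Operant learning time constant in trials (default 30).
#' @param learn_asymptote Asymptotic per-trial accuracy on a fully
#'   detectable odor pair, in (0.5, 1\] (default 0.95).
#' @param seed Default seed used by the simulators when none is passed.
#' @return Object of class `virtual_mouse_params`.
#' @export
virtual_mouse_params <- function(lambda_base_per_min = 4,
                                 bout_mean_ms = 800,
                                 rho = 0.25,
                                 eta = 3,
                                 detect = psychometric_params(
                                   A = 1, b = 1.5, a = 2e-6, g = 0),
                                 valence = NULL,
                                 similarity = NULL,
                                 intensity_dissimilarity = 1,
                                 learn_tau = 30,
                                 learn_asymptote = 0.95,
                                 seed = NULL) {
  if (lambda_base_per_min <= 0) stop_olf("lambda_base_per_min must be > 0")
  if (bout_mean_ms <= 0) stop_olf("bout_mean_ms must be > 0")
  if (rho <= 0 || rho > 1) stop_olf("rho must be in (0, 1]")
  if (eta < 0) stop_olf("eta must be >= 0")
  stopifnot(inherits(detect, "psychometric_params"))
  if (detect$g != 0) stop_olf("ground-truth detection curve must have g = 0")
  if (!is.null(valence) && any(abs(valence) > 1)) {
    stop_olf("valence must lie in [-1, 1]")
  }
  if (!is.null(similarity) &&
      (any(similarity < 0) || any(similarity > 1))) {
    stop_olf("similarity values must lie in [0, 1]")
  }
  if (learn_tau <= 0) stop_olf("learn_tau must be > 0")
  if (learn_asymptote <= 0.5 || learn_asymptote > 1) {
    stop_olf("learn_asymptote must be in (0.5, 1]")
  }
  structure(
    list(lambda_base_per_min = lambda_base_per_min,
         bout_mean_ms = bout_mean_ms, rho = rho, eta = eta,
         detect = detect, valence = valence, similarity = similarity,
         intensity_dissimilarity = intensity_dissimilarity,
         learn_tau = learn_tau, learn_asymptote = learn_asymptote,
         seed = seed),
    class = "virtual_mouse_params"
  )
}

p_detect <- function(params, concentration_sv) {
  if (concentration_sv <= 0) return(0)
  weibull_psychometric(concentration_sv, params$detect)
}

# Perceptual dissimilarity between two stimuli (name + concentration).
stimulus_dissimilarity <- function(params, name_a, name_b,
                                   conc_a, conc_b) {
  if (name_a == name_b) {
    if (isTRUE(all.equal(conc_a, conc_b))) return(0)
    return(params$intensity_dissimilarity)
  }
  key <- paste(sort(c(name_a, name_b)), collapse = ":")
  d <- params$similarity[key]
  if (is.null(params$similarity) || is.na(d)) 1 else unname(d)
}

# Expected bout-rate multipliers, one per schedule session. Deterministic:
# this is the model's mean structure, reused by tests as an oracle.
session_rate_multipliers <- function(params, schedule) {
  n <- nrow(schedule)
  mult <- numeric(n)
  exposures <- integer(0)
  d_cache <- numeric(0)
  prev <- NULL  # list(name, conc, is_bg)
  for (i in seq_len(n)) {
    stim <- schedule$stimulus[i]
    conc <- schedule$concentration_sv[i]
    if (conc <= 0) {
      mult[i] <- 1
      prev <- list(name = stim, conc = 0, is_bg = TRUE)
      next
    }
    key <- paste0(stim, "@", signif(conc, 8))
    k <- exposures[key]
    k <- if (is.na(k) || is.null(k)) 0L else unname(k)
    p <- p_detect(params, conc)
    if (k == 0L) {
      d_eff <- if (is.null(prev) || prev$is_bg) 1 else {
        stimulus_dissimilarity(params, prev$name, stim, prev$conc, conc)
      }
      d_cache[key] <- d_eff
    } else {
      d_eff <- d_cache[key]
    }
    novelty <- p * d_eff * params$rho^k
    v <- unname(params$valence[stim] %||% 0)
    if (is.na(v)) v <- 0
    m <- if (k == 0L) {
      1 + params$eta * novelty * (1 + abs(v))
    } else {
      base <- 1 + params$eta * novelty
      if (v < 0) base * (1 + v * p) else base
    }
    mult[i] <- max(m, 0.02)
    exposures[key] <- k + 1L
    prev <- list(name = stim, conc = conc, is_bg = FALSE)
  }
  mult
}

#' Simulate a habituation-family assay
#'
#' Generates a 1-ms-resolution event log for one virtual animal running a
#' schedule. Poke bouts arrive as a Poisson process whose rate during each
#' session is `lambda_base * M`, where the multiplier `M` encodes
#' detection-gated novelty (dis-habituation), per-repeat habituation decay
#' `rho`, cross-transfer of habituation between similar stimuli, and
#' valence (aversive odors suppress investigation below baseline from
#' their second presentation on). Between sessions the rate is the
#' baseline. Bout durations are exponential; overlapping bouts are merged
#' so the log pairs cleanly into intervals.
#'
#' The log contains the nose-poke channel (`odor_port_ir`), an odor-valve
#' channel per odor session (magnitude = delivered s.v. fraction) and a
#' `ttl_out` marker per session.
#'
#' @param params A `virtual_mouse_params`.
#' @param schedule An `assay_schedule`.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param animal_id Identifier written to the log header.
#' @return An `event_log`.
#' @export
simulate_habituation_assay <- function(params, schedule,
                                       seed = params$seed,
                                       animal_id = "virtual") {
  stopifnot(inherits(params, "virtual_mouse_params"),
            inherits(schedule, "assay_schedule"))
  mult <- session_rate_multipliers(params, schedule)
  n <- nrow(schedule)
  log_end <- schedule$onset_ms[n] + schedule$duration_ms[n] + 60000

  # piecewise-constant rate segments: sessions and the gaps between them
  seg_start <- numeric(0); seg_end <- numeric(0); seg_mult <- numeric(0)
  cursor <- 0
  for (i in seq_len(n)) {
    on <- schedule$onset_ms[i]
    off <- on + schedule$duration_ms[i]
    if (on > cursor) {
      seg_start <- c(seg_start, cursor); seg_end <- c(seg_end, on)
      seg_mult <- c(seg_mult, 1)
    }
    seg_start <- c(seg_start, on); seg_end <- c(seg_end, off)
    seg_mult <- c(seg_mult, mult[i])
    cursor <- off
  }
  if (cursor < log_end) {
    seg_start <- c(seg_start, cursor); seg_end <- c(seg_end, log_end)
    seg_mult <- c(seg_mult, 1)
  }

  rate_ms <- params$lambda_base_per_min / 60000
  bouts <- with_preserved_seed(seed, {
    starts <- numeric(0); durs <- numeric(0)
    for (j in seq_along(seg_start)) {
      len <- seg_end[j] - seg_start[j]
      nb <- stats::rpois(1L, rate_ms * seg_mult[j] * len)
      if (nb > 0L) {
        starts <- c(starts, seg_start[j] + stats::runif(nb) * len)
        durs <- c(durs, stats::rexp(nb, rate = 1 / params$bout_mean_ms))
      }
    }
    list(starts = starts, durs = durs)
  })

  s <- as.integer(round(bouts$starts))
  e <- s + pmax(1L, as.integer(round(bouts$durs)))
  keep <- s < log_end
  s <- s[keep]; e <- pmin(e[keep], as.integer(log_end))
  if (length(s) > 0L) {
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    ms <- integer(0); me <- integer(0)
    cs <- s[1]; ce <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= ce) {
        ce <- max(ce, e[i])
      } else {
        ms <- c(ms, cs); me <- c(me, ce)
        cs <- s[i]; ce <- e[i]
      }
    }
    ms <- c(ms, cs); me <- c(me, ce)
  } else {
    ms <- integer(0); me <- integer(0)
  }

  port <- data.frame(
    time_ms = c(ms, me),
    event_type = rep(c("on", "off"), c(length(ms), length(me))),
    location = "odor_port_ir",
    magnitude = 1,
    stringsAsFactors = FALSE
  )
  is_odor <- schedule$concentration_sv > 0
  valves <- data.frame(
    time_ms = c(schedule$onset_ms[is_odor],
                schedule$onset_ms[is_odor] + schedule$duration_ms[is_odor]),
    event_type = rep(c("on", "off"), each = sum(is_odor)),
    location = rep(paste0("odor_valve_", schedule$stimulus[is_odor]), 2L),
    magnitude = rep(schedule$concentration_sv[is_odor], 2L),
    stringsAsFactors = FALSE
  )
  ttl <- data.frame(
    time_ms = c(schedule$onset_ms, schedule$onset_ms + schedule$duration_ms),
    event_type = rep(c("on", "off"), each = n),
    location = "ttl_out",
    magnitude = 1,
    stringsAsFactors = FALSE
  )
  event_log(
    rbind(port, valves, ttl),
    meta = list(
      animal_id = animal_id,
      paradigm = attr(schedule, "paradigm") %||% "habituation",
      seed = if (is.null(seed)) "NA" else seed
    )
  )
}

# Per-trial accuracy after t trials of training, scaled by detectability.
operant_p_correct <- function(params, trial_index, concentration_sv) {
  acc <- 0.5 + (params$learn_asymptote - 0.5) *
    (1 - exp(-trial_index / params$learn_tau))
  0.5 + (acc - 0.5) * p_detect(params, concentration_sv)
}

#' Simulate a two-choice session
#'
#' Each trial the animal pokes one water port; the probability of the
#' correct port is `0.5 + (acc_t - 0.5) * p_detect(c)` where `acc_t`
#' follows an exponential learning curve in the cumulative trial count.
#' At undetectable concentrations performance sits at the 50% chance
#' floor regardless of training.
#'
#' @param params A `virtual_mouse_params`.
#' @param trials A `trial_sequence` from [build_two_choice_session()].
#' @param concentration_sv Delivered concentration (s.v. fraction).
#' @param seed Integer seed (defaults to `params$seed`).
#' @param start_trial Cumulative training trial count at session start
#'   (1 = naive animal; large values emulate a trained animal).
#' @return A `choice_counts`; attribute `trial_correct` holds the
#'   per-trial outcome vector.
#' @export
simulate_two_choice <- function(params, trials, concentration_sv,
                                seed = params$seed, start_trial = 1L) {
  stopifnot(inherits(params, "virtual_mouse_params"),
            inherits(trials, "trial_sequence"))
  n <- nrow(trials)
  t_idx <- start_trial + seq_len(n) - 1L
  p_corr <- operant_p_correct(params, t_idx, concentration_sv)
  correct <- with_preserved_seed(seed, stats::rbinom(n, 1L, p_corr) == 1L)
  is_a <- trials$correct_response == "port_L"
  out <- choice_counts(
    p_aa = sum(correct & is_a),
    p_bb = sum(correct & !is_a),
    p_total = n
  )
  attr(out, "trial_correct") <- correct
  out
}

#' Simulate a Go/No-Go session
#'
#' Same learning and detection structure as [simulate_two_choice()]; a
#' correct trial is a lick on CS+ (hit) or a withheld lick on CS-
#' (correct rejection), so chance-level responding gives SR = 0.5 on a
#' balanced sequence.
#'
#' @inheritParams simulate_two_choice
#' @param trials A `trial_sequence` from [build_gonogo_session()].
#' @return A `gonogo_counts`; attribute `trial_correct` as above.
#' @export
simulate_gonogo <- function(params, trials, concentration_sv,
                            seed = params$seed, start_trial = 1L) {
  stopifnot(inherits(params, "virtual_mouse_params"),
            inherits(trials, "trial_sequence"))
  n <- nrow(trials)
  t_idx <- start_trial + seq_len(n) - 1L
  p_corr <- operant_p_correct(params, t_idx, concentration_sv)
  correct <- with_preserved_seed(seed, stats::rbinom(n, 1L, p_corr) == 1L)
  is_go <- trials$correct_response == "go"
  out <- gonogo_counts(
    p_cs_plus = sum(is_go & correct),
    np_cs_plus = sum(is_go & !correct),
    p_cs_minus = sum(!is_go & !correct),
    np_cs_minus = sum(!is_go & correct)
  )
  attr(out, "trial_correct") <- correct
  out
}

# Deterministic per-animal seed stream: depends only on (master seed, i),
# so growing the cohort never reshuffles earlier animals.
derive_animal_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) * 48271 + i * 104729) %% 2147483647)
}

#' Simulate a cohort of virtual mice
#'
#' Runs [simulate_habituation_assay()] for `n_animals` independent
#' animals. Per-animal seeds are derived deterministically from the master
#' seed (counter style), so the same master seed always reproduces the
#' same logs and enlarging the cohort leaves existing animals unchanged.
#' Individual differences in baseline activity are modelled as a
#' log-normal multiplier on the baseline bout rate.
#'
#' @param n_animals Cohort size (>= 1).
#' @param params Shared `virtual_mouse_params`.
#' @param schedule Shared `assay_schedule`.
#' @param seed Master seed.
#' @param lambda_sdlog Log-normal sd of the per-animal baseline-rate
#'   multiplier (default 0.25; 0 for identical animals).
#' @return Named list of `event_log` (`animal_01`, `animal_02`, ...).
#' @export
simulate_cohort <- function(n_animals, params, schedule, seed,
                            lambda_sdlog = 0.25) {
  if (n_animals < 1L) stop_olf("n_animals must be >= 1")
  stopifnot(inherits(params, "virtual_mouse_params"))
  logs <- lapply(seq_len(n_animals), function(i) {
    seed_i <- derive_animal_seed(seed, i)
    lam_mult <- with_preserved_seed(seed_i, {
      if (lambda_sdlog > 0) stats::rlnorm(1L, 0, lambda_sdlog) else 1
    })
    params_i <- params
    params_i$lambda_base_per_min <- params$lambda_base_per_min * lam_mult
    simulate_habituation_assay(
      params_i, schedule, seed = derive_animal_seed(seed_i, 1L),
      animal_id = sprintf("animal_%02d", i)
    )
  })
  names(logs) <- sprintf("animal_%02d", seq_len(n_animals))
  logs
}

#' Write the generative ground truth as JSON
#'
#' Records the simulator parameters (including the ground-truth detection
#' threshold) alongside simulated data, for parameter-recovery checks.
#'
#' @param params A `virtual_mouse_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(params, path) {
  stopifnot(inherits(params, "virtual_mouse_params"))
  payload <- unclass(params)
  payload$detect <- unclass(payload$detect)
  payload$valence <- as.list(payload$valence)
  payload$similarity <- as.list(payload$similarity)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
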