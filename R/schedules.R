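# Assay schedules: ordered stimulus sessions for habituation-family assays
# and pseudorandom trial sequences for operant (two-choice, Go/No-Go)
# paradigms.

#' Construct an assay schedule
#'
#' A schedule is an ordered list of stimulus sessions. Each session presents
#' one stimulus ("air", "MO" or an odor name) at a saturated-vapor fraction
#' for a fixed window; onsets are strictly increasing and sessions do not
#' overlap. The habituation-family assays use 60-s stimuli at 240-s
#' onset-to-onset spacing (1 min odor, 3 min clean air between).
#'
#' @param stimulus Character vector of stimulus ids.
#' @param concentration_sv Saturated-vapor fractions (0 for air/solvent).
#' @param onset_ms Session onsets in ms; strictly increasing.
#' @param duration_ms Session durations in ms (> 0); recycled.
#' @param paradigm Paradigm tag, one of `"cross_habituation"`,
#'   `"threshold"`, `"preference"`, `"habituation"`.
#' @param inter_onset_ms Nominal onset-to-onset spacing recorded with the
#'   schedule (informational).
#' @return Data frame of class `assay_schedule` with columns `index`,
#'   `stimulus`, `concentration_sv`, `onset_ms`, `duration_ms`.
#' @export
assay_schedule <- function(stimulus, concentration_sv, onset_ms,
                           duration_ms = 60000,
                           paradigm = "habituation",
                           inter_onset_ms = 240000) {
  n <- length(stimulus)
  duration_ms <- rep_len(duration_ms, n)
  concentration_sv <- rep_len(concentration_sv, n)
  if (n > 0L) {
    if (any(duration_ms <= 0)) stop_olf("session duration must be > 0")
    if (any(concentration_sv < 0)) stop_olf("concentration must be >= 0")
    if (any(diff(onset_ms) <= 0)) {
      stop_olf("session onsets must be strictly increasing")
    }
    if (any(onset_ms[-1] < (onset_ms + duration_ms)[-n])) {
      stop_olf("sessions must not overlap")
    }
  }
  out <- data.frame(
    index = seq_len(n), stimulus = as.character(stimulus),
    concentration_sv = as.numeric(concentration_sv),
    onset_ms = as.numeric(onset_ms), duration_ms = as.numeric(duration_ms),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("assay_schedule", "data.frame"),
            paradigm = paradigm, inter_onset_ms = inter_onset_ms)
}

#' Cross-habituation / dis-habituation schedule
#'
#' The canonical sequence: a block of background sessions (air or mineral
#' oil) to habituate port investigation, a block of a first odor S1, and
#' optionally a block of a second odor S2. Dis-habituation at the S1 onset
#' reads out detection; the response at the S2 switch reads out perceptual
#' similarity between S1 and S2 (cross-habituation).
#'
#' @param s1 First odor id.
#' @param s2 Optional second odor id (`NULL` for plain
#'   habituation/dis-habituation).
#' @param n_air Number of background sessions (default 8).
#' @param n_s1 Number of S1 sessions (default 5).
#' @param n_s2 Number of S2 sessions (default 5 when `s2` given).
#' @param conc_s1,conc_s2 Delivered concentrations in s.v. fraction
#'   (default 2.5e-3, a 1:1000 vial at 100/400 ml/min flows).
#' @param background Background stimulus label, `"air"` or `"MO"`.
#' @param stim_duration_ms Stimulus window (default 60 000 ms).
#' @param inter_onset_ms Onset-to-onset spacing (default 240 000 ms).
#' @param paradigm Paradigm tag recorded on the schedule.
#' @return An `assay_schedule`.
#' @examples
#' sched <- build_cross_habituation("HXH", "HXO")
#' nrow(sched)  # 8 air + 5 + 5
#' @export
build_cross_habituation <- function(s1, s2 = NULL, n_air = 8L, n_s1 = 5L,
                                    n_s2 = if (is.null(s2)) 0L else 5L,
                                    conc_s1 = 2.5e-3, conc_s2 = 2.5e-3,
                                    background = "air",
                                    stim_duration_ms = 60000,
                                    inter_onset_ms = 240000,
                                    paradigm = "cross_habituation") {
  if (n_air < 0L) stop_olf("n_air must be >= 0")
  if (n_s1 < 1L) stop_olf("n_s1 must be >= 1")
  if (n_s2 > 0L && is.null(s2)) stop_olf("n_s2 > 0 requires s2")
  if (stim_duration_ms <= 0) stop_olf("stimulus duration must be > 0")
  if (stim_duration_ms > inter_onset_ms) {
    stop_olf("stimulus duration must fit within the inter-onset interval")
  }
  stim <- c(rep(background, n_air), rep(s1, n_s1),
            if (n_s2 > 0L) rep(s2, n_s2))
  conc <- c(rep(0, n_air), rep(conc_s1, n_s1),
            if (n_s2 > 0L) rep(conc_s2, n_s2))
  onset <- (seq_along(stim) - 1) * inter_onset_ms
  assay_schedule(stim, conc, onset, stim_duration_ms,
                 paradigm = paradigm, inter_onset_ms = inter_onset_ms)
}

#' Detection-threshold schedule
#'
#' Background habituation followed by probes of one odor at strictly
#' ascending concentrations (one dis-habituation probe per concentration by
#' default). The ascending order means each probe asks whether the animal
#' notices an intensity increase over what it has habituated to.
#'
#' @param odor Odor id.
#' @param concentrations_sv Strictly increasing vector of probe
#'   concentrations (> 0, s.v. fraction).
#' @param n_air Background sessions (default 8).
#' @param reps_per_conc Sessions per concentration (default 1).
#' @inheritParams build_cross_habituation
#' @return An `assay_schedule` with paradigm `"threshold"`.
#' @export
build_threshold_series <- function(odor, concentrations_sv, n_air = 8L,
                                   reps_per_conc = 1L,
                                   background = "air",
                                   stim_duration_ms = 60000,
                                   inter_onset_ms = 240000) {
  if (length(concentrations_sv) > 0L) {
    if (any(concentrations_sv <= 0)) {
      stop_olf("probe concentrations must be > 0")
    }
    if (any(diff(concentrations_sv) <= 0)) {
      stop_olf("probe concentrations must be strictly increasing")
    }
  }
  if (reps_per_conc < 1L) stop_olf("reps_per_conc must be >= 1")
  stim <- c(rep(background, n_air),
            rep(odor, length(concentrations_sv) * reps_per_conc))
  conc <- c(rep(0, n_air), rep(concentrations_sv, each = reps_per_conc))
  onset <- (seq_along(stim) - 1) * inter_onset_ms
  assay_schedule(stim, conc, onset, stim_duration_ms,
                 paradigm = "threshold", inter_onset_ms = inter_onset_ms)
}

#' Innate odor-preference schedule
#'
#' Mineral-oil background sessions followed by repeated presentations of a
#' test odor; the attraction index compares the first odor session with the
#' last background session and the aversion index the second odor session
#' with the last background session.
#'
#' @param odor Test odor id.
#' @param n_mo Mineral-oil background sessions (default 8).
#' @param n_odor Test-odor sessions (default 5; at least 2 for the aversion
#'   index to be defined).
#' @param conc Delivered concentration in s.v. fraction.
#' @inheritParams build_cross_habituation
#' @return An `assay_schedule` with paradigm `"preference"`.
#' @export
build_preference_assay <- function(odor, n_mo = 8L, n_odor = 5L,
                                   conc = 2.5e-3,
                                   stim_duration_ms = 60000,
                                   inter_onset_ms = 240000) {
  build_cross_habituation(
    s1 = odor, s2 = NULL, n_air = n_mo, n_s1 = n_odor, n_s2 = 0L,
    conc_s1 = conc, background = "MO",
    stim_duration_ms = stim_duration_ms, inter_onset_ms = inter_onset_ms,
    paradigm = "preference"
  )
}

#' Pseudorandom operant trial sequence
#'
#' Builds the trial order for a two-choice session: each odor appears
#' exactly `n_per_odor` times, in a seeded pseudorandom order constrained to
#' at most `max_run` consecutive trials of the same odor (preventing
#' degenerate single-side blocks). `odor_a` maps to the left water port and
#' `odor_b` to the right.
#'
#' @param odor_a,odor_b Odor ids.
#' @param n_per_odor Presentations per odor (default 30).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param max_run Maximum run of identical consecutive odors (default 3).
#' @param reward_volume_ul Water reward per correct trial (default 5).
#' @return Data frame of class `trial_sequence` with columns `trial`,
#'   `odor`, `correct_response`; attributes `paradigm`, `reward_volume_ul`.
#' @export
build_two_choice_session <- function(odor_a, odor_b, n_per_odor = 30L,
                                     seed = NULL, max_run = 3L,
                                     reward_volume_ul = 5) {
  odors <- sample_constrained_sequence(c(odor_a, odor_b), n_per_odor,
                                       seed, max_run)
  resp <- ifelse(odors == odor_a, "port_L", "port_R")
  structure(
    data.frame(trial = seq_along(odors), odor = odors,
               correct_response = resp, stringsAsFactors = FALSE),
    class = c("trial_sequence", "data.frame"),
    paradigm = "two_choice", reward_volume_ul = reward_volume_ul,
    seed = seed
  )
}

#' Pseudorandom Go/No-Go trial sequence
#'
#' As [build_two_choice_session()] but labelling trials `"go"` (CS+, lick
#' for water reward) and `"no_go"` (CS-, withhold licking).
#'
#' @param cs_plus Rewarded odor id (CS+).
#' @param cs_minus Unrewarded/punished odor id (CS-).
#' @inheritParams build_two_choice_session
#' @return A `trial_sequence` with paradigm `"gonogo"`.
#' @export
build_gonogo_session <- function(cs_plus, cs_minus, n_per_odor = 30L,
                                 seed = NULL, max_run = 3L,
                                 reward_volume_ul = 5) {
  odors <- sample_constrained_sequence(c(cs_plus, cs_minus), n_per_odor,
                                       seed, max_run)
  resp <- ifelse(odors == cs_plus, "go", "no_go")
  structure(
    data.frame(trial = seq_along(odors), odor = odors,
               correct_response = resp, stringsAsFactors = FALSE),
    class = c("trial_sequence", "data.frame"),
    paradigm = "gonogo", reward_volume_ul = reward_volume_ul,
    seed = seed
  )
}

# Draw a balanced sequence of the two odors with no run longer than
# max_run. Sequential sampling weighted by remaining counts; on the rare
# dead end (only the run-blocked odor remains) the draw restarts.
sample_constrained_sequence <- function(odors, n_per_odor, seed, max_run) {
  stopifnot(length(odors) == 2L)
  if (odors[1] == odors[2]) {
    stop_olf("the two odors must differ")
  }
  if (n_per_odor < 1L) stop_olf("n_per_odor must be >= 1")
  if (max_run < 1L) stop_olf("max_run must be >= 1")
  with_preserved_seed(seed, {
    repeat {
      remaining <- c(n_per_odor, n_per_odor)
      seq_out <- character(2L * n_per_odor)
      run_len <- 0L
      last <- 0L
      ok <- TRUE
      for (i in seq_along(seq_out)) {
        eligible <- which(remaining > 0L)
        if (last > 0L && run_len >= max_run) {
          eligible <- setdiff(eligible, last)
        }
        if (length(eligible) == 0L) {
          ok <- FALSE
          break
        }
        pick <- if (length(eligible) == 1L) eligible else {
          sample(eligible, 1L, prob = remaining[eligible])
        }
        seq_out[i] <- odors[pick]
        remaining[pick] <- remaining[pick] - 1L
        run_len <- if (pick == last) run_len + 1L else 1L
        last <- pick
      }
      if (ok && max(rle(seq_out)$lengths) <= max_run) {
        return(seq_out)
      }
    }
  })
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# state; a NULL seed uses (and advances) the current stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Serialize / read schedules and trial sequences as JSON
#'
#' @param x An `assay_schedule` or `trial_sequence`.
#' @param path JSON file path.
#' @return `path` invisibly (writers); the reconstructed object (readers).
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "assay_schedule"))
  payload <- list(
    paradigm = attr(x, "paradigm"),
    inter_onset_ms = attr(x, "inter_onset_ms"),
    sessions = as.data.frame(unclass(x))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- p$sessions
  assay_schedule(s$stimulus, s$concentration_sv, s$onset_ms, s$duration_ms,
                 paradigm = p$paradigm, inter_onset_ms = p$inter_onset_ms)
}

#' @rdname write_schedule
#' @export
write_trials <- function(x, path) {
  stopifnot(inherits(x, "trial_sequence"))
  payload <- list(
    paradigm = attr(x, "paradigm"),
    reward_volume_ul = attr(x, "reward_volume_ul"),
    trials = as.data.frame(unclass(x))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_trials <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- p$trials
  structure(
    data.frame(trial = tr$trial, odor = tr$odor,
               correct_response = tr$correct_response,
               stringsAsFactors = FALSE),
    class = c("trial_sequence", "data.frame"),
    paradigm = p$paradigm, reward_volume_ul = p$reward_volume_ul
  )
}
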