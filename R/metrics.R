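# Behavioral statistics: investigation durations, normalized port
# investigation (NPI), session-to-session differences (dNPI), operant
# success rates, preference indices and the just-noticeable-difference
# threshold.

#' Total investigation time within a stimulus window
#'
#' Sums the overlap of nose-poke intervals with a session window. Window
#' semantics are half-open `[onset, offset)`; pokes straddling an edge are
#' clipped, not counted whole.
#'
#' @param pokes Data frame of intervals as returned by [pair_events()]
#'   (columns `start_ms`, `end_ms`).
#' @param window Numeric length-2 vector `c(onset_ms, offset_ms)`.
#' @return Investigation duration in ms.
#' @export
investigation_duration <- function(pokes, window) {
  if (length(window) != 2L || window[2] < window[1]) {
    stop_olf("window must be c(onset_ms, offset_ms) with offset >= onset")
  }
  if (nrow(pokes) == 0L) return(0)
  lo <- pmax(pokes$start_ms, window[1])
  hi <- pmin(pokes$end_ms, window[2])
  sum(pmax(0, hi - lo))
}

#' Basal port-seeking activity
#'
#' Arithmetic mean investigation duration over the background (air or
#' mineral-oil) sessions; the normalization constant for NPI, controlling
#' for individual differences in baseline activity.
#'
#' @param air_session_durations_ms Non-empty numeric vector of per-session
#'   investigation durations during background sessions.
#' @return Mean duration in ms.
#' @export
basal_activity <- function(air_session_durations_ms) {
  if (length(air_session_durations_ms) == 0L) {
    stop_olf("no background sessions supplied")
  }
  mean(air_session_durations_ms)
}

#' Normalized port investigation (NPI)
#'
#' `100 * duration / basal`, in percent. By construction the mean NPI over
#' the background sessions used to compute `basal` is exactly 100%. An
#' animal that never investigated during the background block
#' (`basal = 0`) has an undefined normalization and is excluded: a classed
#' error `olf_animal_excluded` is signalled.
#'
#' @param duration_ms Session investigation duration (ms).
#' @param basal_ms Basal activity from [basal_activity()] (ms, > 0).
#' @return NPI in percent (vectorized over `duration_ms`).
#' @export
npi <- function(duration_ms, basal_ms) {
  if (!is.finite(basal_ms) || basal_ms < 0) {
    stop_olf("basal_ms must be a non-negative number")
  }
  if (basal_ms == 0) {
    stop_olf("animal never investigated during background sessions; ",
             "NPI undefined", class = "olf_animal_excluded")
  }
  100 * duration_ms / basal_ms
}

#' Session-to-session NPI differences (dNPI)
#'
#' `dNPI[i] = NPI[i] - NPI[i-1]`. Approximately zero for repeated identical
#' stimuli once the animal has habituated; a positive value at a stimulus
#' switch quantifies dis-habituation, i.e. perceived novelty.
#'
#' @param npi_sequence NPI values for consecutive sessions (length >= 2).
#' @return Vector of differences, length `length(npi_sequence) - 1`.
#' @export
delta_npi <- function(npi_sequence) {
  if (length(npi_sequence) < 2L) {
    stop_olf("need at least 2 sessions to difference")
  }
  diff(npi_sequence)
}

#' Two-choice trial counts
#'
#' @param p_aa Pokes into water port A upon odor A.
#' @param p_bb Pokes into water port B upon odor B.
#' @param p_total Total water-port pokes.
#' @return Object of class `choice_counts`.
#' @export
choice_counts <- function(p_aa, p_bb, p_total) {
  if (any(c(p_aa, p_bb, p_total) < 0)) stop_olf("counts must be >= 0")
  if (p_aa + p_bb > p_total) {
    stop_olf("correct pokes cannot exceed total pokes")
  }
  structure(list(p_aa = p_aa, p_bb = p_bb, p_total = p_total),
            class = "choice_counts")
}

#' Go/No-Go trial counts
#'
#' @param p_cs_plus Licks on CS+ trials (hits).
#' @param np_cs_plus Withheld licks on CS+ trials (misses).
#' @param p_cs_minus Licks on CS- trials (false alarms).
#' @param np_cs_minus Withheld licks on CS- trials (correct rejections).
#' @return Object of class `gonogo_counts`.
#' @export
gonogo_counts <- function(p_cs_plus, np_cs_plus, p_cs_minus, np_cs_minus) {
  counts <- c(p_cs_plus, np_cs_plus, p_cs_minus, np_cs_minus)
  if (any(counts < 0)) stop_olf("counts must be >= 0")
  structure(list(p_cs_plus = p_cs_plus, np_cs_plus = np_cs_plus,
                 p_cs_minus = p_cs_minus, np_cs_minus = np_cs_minus),
            class = "gonogo_counts")
}

#' Two-choice success rate
#'
#' `SR = (P_AA + P_BB) / P_total`: the fraction of water-port pokes that
#' were on the port matching the delivered odor. Chance level is 0.5.
#'
#' @param counts A `choice_counts`.
#' @return Success rate in \[0, 1\].
#' @export
success_rate_two_choice <- function(counts) {
  stopifnot(inherits(counts, "choice_counts"))
  if (counts$p_total == 0) {
    stop_olf("no trials; success rate undefined",
             class = "olf_undefined_rate")
  }
  (counts$p_aa + counts$p_bb) / counts$p_total
}

#' Go/No-Go success rate
#'
#' `SR = (P_CS+ + NP_CS-) / (P_CS+ + NP_CS+ + P_CS- + NP_CS-)`: hits plus
#' correct rejections over all trials. An animal licking on every trial
#' scores exactly 0.5 when CS+ and CS- are balanced.
#'
#' @param counts A `gonogo_counts`.
#' @return Success rate in \[0, 1\].
#' @export
success_rate_gonogo <- function(counts) {
  stopifnot(inherits(counts, "gonogo_counts"))
  total <- counts$p_cs_plus + counts$np_cs_plus +
    counts$p_cs_minus + counts$np_cs_minus
  if (total == 0) {
    stop_olf("no trials; success rate undefined",
             class = "olf_undefined_rate")
  }
  (counts$p_cs_plus + counts$np_cs_minus) / total
}

#' Attraction index
#'
#' NPI of the first test-odor session minus NPI of the last background
#' (mineral-oil) session: how much the odor's first presentation raised
#' port investigation above the habituated baseline. Positive = attraction.
#'
#' @param npi_series NPI values for the whole assay, in session order.
#' @param first_odor_session_idx Index of the first test-odor session
#'   (the background block must precede it).
#' @return Index in NPI percentage points.
#' @export
attraction_index <- function(npi_series, first_odor_session_idx) {
  i <- first_odor_session_idx
  if (i < 2L || i > length(npi_series)) {
    stop_olf("first odor session must be preceded by a background block")
  }
  npi_series[i] - npi_series[i - 1L]
}

#' Aversion index
#'
#' NPI of the last background session minus NPI of the *second* test-odor
#' session. Aversion shows from the second presentation onward (the first
#' is confounded by novelty-driven investigation); suppression of port
#' investigation below baseline gives a positive index, so attraction and
#' aversion indices are both bigger-is-stronger.
#'
#' @param npi_series NPI values for the whole assay, in session order.
#' @param second_odor_session_idx Index of the second test-odor session
#'   (so the odor block has at least 2 sessions and a background session
#'   sits two positions before it).
#' @return Index in NPI percentage points; positive = aversion.
#' @export
aversion_index <- function(npi_series, second_odor_session_idx) {
  i <- second_odor_session_idx
  if (i < 3L || i > length(npi_series)) {
    stop_olf("need >= 2 odor sessions preceded by a background block")
  }
  npi_series[i - 2L] - npi_series[i]
}

#' Three-chamber preference indices
#'
#' Zone-time based indices for the classic three-chamber assay:
#' `attraction = (test - control) / control` and `aversion = -attraction`.
#' An animal that never entered the control zone cannot be normalized and
#' is excluded (classed error `olf_animal_excluded`).
#'
#' @param time_test_zone_s Time spent in the test-odor zone (s).
#' @param time_control_zone_s Time spent in the control zone (s, > 0).
#' @return List with `attraction` and `aversion`.
#' @export
three_chamber_indices <- function(time_test_zone_s, time_control_zone_s) {
  if (any(c(time_test_zone_s, time_control_zone_s) < 0)) {
    stop_olf("zone times must be >= 0")
  }
  if (time_control_zone_s == 0) {
    stop_olf("animal never entered the control zone; indices undefined",
             class = "olf_animal_excluded")
  }
  att <- (time_test_zone_s - time_control_zone_s) / time_control_zone_s
  list(attraction = att, aversion = -att)
}

#' Just-noticeable-difference threshold from dNPI
#'
#' For each probe concentration, tests whether the across-animal dNPI
#' (odor session minus the preceding session, so the within-animal control
#' is already subtracted) differs from zero by a paired t-test. The JND is
#' the smallest concentration significant at `alpha` after multiplicity
#' adjustment across the concentration series (Holm by default; with 7
#' probes, unadjusted per-test 0.05 would false-alarm on ~30% of null
#' cohorts).
#'
#' @param delta_npi_matrix Numeric matrix, animals x concentrations, of
#'   dNPI at each probe.
#' @param concentrations_sv Ascending probe concentrations (one per
#'   column).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()];
#'   `"none"` reproduces raw per-concentration p values.
#' @return List with `threshold_sv` (smallest significant concentration,
#'   or `NA` if none), `p_values` (raw), `p_adjusted`, `alpha`, `method`.
#' @export
jnd_threshold <- function(delta_npi_matrix, concentrations_sv,
                          alpha = 0.05, p_adjust = "holm") {
  m <- as.matrix(delta_npi_matrix)
  if (nrow(m) < 2L) stop_olf("need at least 2 animals")
  if (ncol(m) != length(concentrations_sv)) {
    stop_olf("one concentration per matrix column required")
  }
  if (any(diff(concentrations_sv) <= 0)) {
    stop_olf("concentrations must be strictly ascending")
  }
  if (!alpha > 0 || !alpha < 1) stop_olf("alpha must be in (0, 1)")
  p <- apply(m, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2L) return(NA_real_)
    if (stats::sd(col) == 0) {
      # degenerate variance: an exactly constant zero column carries no
      # evidence (p = 1); a constant non-zero shift is unambiguous
      return(if (all(col == 0)) 1 else 0)
    }
    stats::t.test(col, mu = 0)$p.value
  })
  p_adj <- stats::p.adjust(p, method = p_adjust)
  sig <- which(!is.na(p_adj) & p_adj <= alpha)
  list(
    threshold_sv = if (length(sig) > 0L) concentrations_sv[min(sig)]
                   else NA_real_,
    p_values = unname(p), p_adjusted = unname(p_adj),
    alpha = alpha, method = p_adjust
  )
}

#' Per-session metrics from an event log and its schedule
#'
#' Pairs the nose-poke channel into bouts, tallies investigation inside
#' each session window, computes the basal activity from the background
#' sessions, and derives NPI and dNPI per session.
#'
#' @param log An `event_log`.
#' @param schedule The `assay_schedule` the log was recorded under.
#' @param port_location Nose-poke IR channel (default `"odor_port_ir"`).
#' @param basal_stimuli Stimulus labels counted as background
#'   (default `c("air", "MO")`).
#' @param basal_sessions `"all"` (default) uses every background session;
#'   `"last_k"` uses only the final `k` of them.
#' @param k Number of background sessions for `basal_sessions = "last_k"`.
#' @return Data frame of class `session_metrics` with columns
#'   `session_index`, `stimulus`, `concentration_sv`, `investigation_ms`,
#'   `npi_percent`, `delta_npi_percent` (NA for the first session);
#'   attribute `basal_ms`.
#' @export
session_metrics <- function(log, schedule, port_location = "odor_port_ir",
                            basal_stimuli = c("air", "MO"),
                            basal_sessions = c("all", "last_k"), k = 4L) {
  stopifnot(inherits(log, "event_log"), inherits(schedule, "assay_schedule"))
  basal_sessions <- match.arg(basal_sessions)
  pokes <- pair_events(log, port_location)
  inv <- vapply(seq_len(nrow(schedule)), function(i) {
    investigation_duration(
      pokes, c(schedule$onset_ms[i],
               schedule$onset_ms[i] + schedule$duration_ms[i])
    )
  }, numeric(1))
  is_bg <- schedule$stimulus %in% basal_stimuli
  bg_idx <- which(is_bg)
  if (basal_sessions == "last_k" && length(bg_idx) > k) {
    bg_idx <- utils::tail(bg_idx, k)
  }
  if (length(bg_idx) == 0L) {
    stop_olf("schedule has no background sessions; basal undefined")
  }
  basal <- basal_activity(inv[bg_idx])
  npi_pct <- npi(inv, basal)
  out <- data.frame(
    session_index = schedule$index, stimulus = schedule$stimulus,
    concentration_sv = schedule$concentration_sv,
    investigation_ms = inv, npi_percent = npi_pct,
    delta_npi_percent = c(NA_real_, delta_npi(npi_pct)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("session_metrics", "data.frame"),
            basal_ms = basal)
}

#' Write a per-animal session metrics table as TSV
#' @param metrics A `session_metrics` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  utils::write.table(as.data.frame(metrics), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a session metrics table written by [write_metrics_table()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_metrics_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Probe dNPI matrix for a cohort on a threshold series
#'
#' Runs [session_metrics()] on every animal's log and extracts, for each
#' probe concentration, the NPI change at the *entry into that
#' concentration's block* (the first session at a new concentration).
#' Two comparators are supported. `"air"` (default) references the probe
#' NPI to the air-block baseline, which is 100% by construction:
#' `dNPI = NPI(probe) - 100`. Because the baseline is exact this halves
#' the sampling variance of the successive-session difference and is
#' unaffected by residual elevation in the session before the probe.
#' `"previous"` is the literal successive-session difference
#' `NPI(probe) - NPI(preceding session)`; with a single session per
#' concentration, consecutive elevated probes then partially cancel, so
#' this comparator is best combined with `reps_per_conc >= 2` (the
#' pre-switch session is then a re-habituated one).
#'
#' @param logs List of `event_log`, one per animal.
#' @param schedule The shared `assay_schedule` (paradigm `"threshold"`).
#' @param baseline Comparator for the probe dNPI, `"air"` or
#'   `"previous"`.
#' @param ... Passed to [session_metrics()].
#' @return Numeric matrix animals x concentrations with the ascending
#'   probe concentrations as an attribute `concentrations_sv`.
#' @export
cohort_dnpi_matrix <- function(logs, schedule,
                               baseline = c("air", "previous"), ...) {
  baseline <- match.arg(baseline)
  conc <- schedule$concentration_sv
  stim <- schedule$stimulus
  block_entry <- conc > 0 &
    (seq_along(conc) == 1L |
       conc != c(NA, conc[-length(conc)]) |
       stim != c(NA, stim[-length(stim)]))
  probe_idx <- which(block_entry)
  if (length(probe_idx) == 0L) stop_olf("schedule has no odor probes")
  concs <- conc[probe_idx]
  m <- t(vapply(logs, function(log) {
    sm <- session_metrics(log, schedule, ...)
    if (baseline == "air") {
      sm$npi_percent[probe_idx] - 100
    } else {
      sm$delta_npi_percent[probe_idx]
    }
  }, numeric(length(probe_idx))))
  dimnames(m) <- list(NULL, signif(concs, 6))
  attr(m, "concentrations_sv") <- concs
  m
}

#' Estimate an odor detection threshold from a cohort
#'
#' The full habituation/dis-habituation threshold pipeline: per-animal
#' session metrics, probe dNPI matrix, Weibull psychometric fit to the
#' cohort-mean dNPI against concentration (floor `g = 0`), and the
#' JND-style smallest statistically detectable concentration.
#'
#' @param logs List of `event_log`, one per animal.
#' @param schedule The shared threshold-series `assay_schedule`.
#' @param alpha Significance level for the JND test.
#' @param p_adjust Multiplicity adjustment for the JND test.
#' @param baseline dNPI comparator used for the *curve fit*, see
#'   [cohort_dnpi_matrix()]. The JND significance test always uses the
#'   successive-session difference, which is exactly mean-zero under the
#'   null hypothesis (the air-baseline variant carries a small positive
#'   ratio-estimator bias that would inflate its false-alarm rate).
#' @param ... Passed to [session_metrics()].
#' @return List with `fit` (a `psychometric_fit`; `fit$params$a` is the
#'   threshold), `jnd` (from [jnd_threshold()]), `dnpi_matrix` (the fit
#'   comparator), `mean_dnpi`, `concentrations_sv`.
#' @export
estimate_detection_threshold <- function(logs, schedule, alpha = 0.05,
                                         p_adjust = "holm",
                                         baseline = c("air", "previous"),
                                         ...) {
  baseline <- match.arg(baseline)
  m <- cohort_dnpi_matrix(logs, schedule, baseline = baseline, ...)
  concs <- attr(m, "concentrations_sv")
  mean_dnpi <- colMeans(m)
  fit <- fit_psychometric(concs, mean_dnpi, g_fixed = 0)
  m_succ <- if (baseline == "previous") m else {
    cohort_dnpi_matrix(logs, schedule, baseline = "previous", ...)
  }
  jnd <- jnd_threshold(m_succ, concs, alpha = alpha, p_adjust = p_adjust)
  list(fit = fit, jnd = jnd, dnpi_matrix = m, mean_dnpi = mean_dnpi,
       concentrations_sv = concs)
}
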