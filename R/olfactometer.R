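# Virtual olfactometer: flow/dilution arithmetic, constant-total-flow valve
# logic, and synthesized photo-ionization detector (PID) traces.

#' Describe an odorant vial
#'
#' An odor source is a vial of odorant diluted (v/v) in an inert solvent.
#' Air flowing over the headspace picks up odor vapor; under the ideal
#' (Raoult-type) headspace assumption the vapor-phase concentration is the
#' liquid volume fraction times the odorant's saturated vapor concentration.
#'
#' @param name Odor identifier, e.g. `"AA"` (amyl acetate).
#' @param liquid_dilution Volume fraction of odorant in solvent, in (0, 1].
#' @param vapor_pressure_mmHg Vapor pressure of the pure odorant in mmHg
#'   (controls how fast the delivery line clears after valve close).
#' @param solvent `"mineral_oil"` (default) or `"water"` (for highly polar
#'   compounds).
#' @return An object of class `odor_spec`.
#' @export
odor_spec <- function(name, liquid_dilution, vapor_pressure_mmHg,
                      solvent = c("mineral_oil", "water")) {
  solvent <- match.arg(solvent)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_olf("odor name must be a non-empty string")
  }
  if (!is.numeric(liquid_dilution) || length(liquid_dilution) != 1L ||
      !is.finite(liquid_dilution) ||
      liquid_dilution <= 0 || liquid_dilution > 1) {
    stop_olf("liquid_dilution must be in (0, 1]")
  }
  if (!is.numeric(vapor_pressure_mmHg) || length(vapor_pressure_mmHg) != 1L ||
      !is.finite(vapor_pressure_mmHg) || vapor_pressure_mmHg <= 0) {
    stop_olf("vapor_pressure_mmHg must be > 0")
  }
  structure(
    list(name = name, liquid_dilution = liquid_dilution,
         vapor_pressure_mmHg = vapor_pressure_mmHg, solvent = solvent),
    class = "odor_spec"
  )
}

#' Default odor panel
#'
#' Four commonly used odorants spanning a wide volatility range:
#' isoamylamine (IAMM, 51.1 mmHg), 2-hexanone (HXO, 12 mmHg), amyl acetate
#' (AA, 4 mmHg) and heptanal (HPH, 3 mmHg).
#'
#' @param liquid_dilution Liquid dilution applied to every vial
#'   (default 1e-3, i.e. 1:1000 v/v).
#' @return Named list of `odor_spec` objects.
#' @export
default_odor_panel <- function(liquid_dilution = 1e-3) {
  vp <- c(IAMM = 51.1, HXO = 12, AA = 4, HPH = 3)
  specs <- lapply(names(vp), function(nm) {
    odor_spec(nm, liquid_dilution, vp[[nm]])
  })
  names(specs) <- names(vp)
  specs
}

#' Olfactometer flow configuration
#'
#' The air supply is split into a carrier line (mass-flow controlled,
#' 0-1000 ml/min), one fixed-speed odor line (100 ml/min) and one variable
#' speed odor line (1-99 ml/min) per odor bank. Two banks of four vials
#' each allow binary mixtures. The carrier setpoint here is the constant
#' *total* flow the device maintains: whenever odor lines open, the carrier
#' drops by the same amount.
#'
#' @param carrier_setpoint_ml_min Total flow setpoint in ml/min (0-1000).
#' @param fixed_line_ml_min Fixed-speed odor line flow (default 100).
#' @param variable_line_min_ml_min,variable_line_max_ml_min Range of each
#'   bank's variable-speed line when open (defaults 1 and 99).
#' @param n_banks Number of odor banks (default 2).
#' @param vials_per_bank Vials per bank (default 4).
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(carrier_setpoint_ml_min = 1000,
                        fixed_line_ml_min = 100,
                        variable_line_min_ml_min = 1,
                        variable_line_max_ml_min = 99,
                        n_banks = 2L,
                        vials_per_bank = 4L) {
  if (carrier_setpoint_ml_min < 0 || carrier_setpoint_ml_min > 1000) {
    stop_olf("carrier setpoint must be within the controller range 0-1000 ml/min")
  }
  if (fixed_line_ml_min < 0) stop_olf("fixed line flow must be >= 0")
  if (variable_line_min_ml_min < 0 ||
      variable_line_max_ml_min < variable_line_min_ml_min) {
    stop_olf("variable line range must satisfy 0 <= min <= max")
  }
  n_banks <- as.integer(n_banks)
  vials_per_bank <- as.integer(vials_per_bank)
  if (n_banks < 1L || vials_per_bank < 1L) {
    stop_olf("n_banks and vials_per_bank must be >= 1")
  }
  structure(
    list(carrier_setpoint_ml_min = carrier_setpoint_ml_min,
         fixed_line_ml_min = fixed_line_ml_min,
         variable_line_min_ml_min = variable_line_min_ml_min,
         variable_line_max_ml_min = variable_line_max_ml_min,
         n_banks = n_banks, vials_per_bank = vials_per_bank),
    class = "flow_config"
  )
}

#' Airborne dilution of an odor
#'
#' Final saturated-vapor (s.v.) fraction delivered when an odor line at
#' `odor_flow_ml_min` joins a total air stream of `total_flow_ml_min`:
#' `liquid_dilution * odor_flow / total_flow`, under the headspace
#' equilibrium assumption. A 1:10 vial at 100 ml/min into 400 ml/min total
#' gives 2.5e-2 s.v.; a 1:10^7 vial gives 2.5e-8 s.v.
#'
#' @param spec An `odor_spec`, or a bare numeric liquid dilution in (0, 1].
#' @param odor_flow_ml_min Odor line flow in ml/min (> 0).
#' @param total_flow_ml_min Total delivered flow in ml/min (>= odor flow).
#' @return Saturated-vapor fraction (dimensionless).
#' @examples
#' airborne_dilution(0.1, 100, 400)   # 0.025
#' @export
airborne_dilution <- function(spec, odor_flow_ml_min, total_flow_ml_min) {
  dil <- if (inherits(spec, "odor_spec")) spec$liquid_dilution else spec
  if (!is.numeric(dil) || length(dil) != 1L || dil <= 0 || dil > 1) {
    stop_olf("liquid dilution must be in (0, 1]")
  }
  if (total_flow_ml_min <= 0) {
    stop_olf("total flow must be > 0", class = "olf_domain_error")
  }
  if (odor_flow_ml_min <= 0) {
    stop_olf("odor flow must be > 0", class = "olf_domain_error")
  }
  if (odor_flow_ml_min > total_flow_ml_min) {
    stop_olf("odor flow exceeds total flow", class = "olf_domain_error")
  }
  dil * odor_flow_ml_min / total_flow_ml_min
}

#' Carrier flow under the constant-total-flow rule
#'
#' When odor valves open, the carrier stream drops by the summed odor-line
#' flow so that total flow stays at the setpoint (eliminating mechanical
#' stimulation artifacts at odor onset). At 1000 ml/min setpoint, a single
#' 100 ml/min odor pulse brings the carrier to 900 ml/min; with all valves
#' shut the carrier returns to the setpoint.
#'
#' @param total_setpoint_ml_min Constant total flow setpoint.
#' @param open_odor_flows_ml_min Numeric vector of currently open odor-line
#'   flows (possibly empty).
#' @return Carrier flow in ml/min.
#' @export
carrier_flow <- function(total_setpoint_ml_min,
                         open_odor_flows_ml_min = numeric(0)) {
  if (total_setpoint_ml_min < 0) stop_olf("setpoint must be >= 0")
  s <- sum(open_odor_flows_ml_min)
  if (any(open_odor_flows_ml_min < 0)) {
    stop_olf("odor flows must be >= 0", class = "olf_domain_error")
  }
  if (s > total_setpoint_ml_min) {
    stop_olf("summed odor flow exceeds the total setpoint",
             class = "olf_domain_error")
  }
  total_setpoint_ml_min - s
}

#' Maximal combined flow from the variable-speed odor banks
#'
#' @param config A `flow_config`.
#' @return ml/min; 198 for the default two banks at 99 ml/min each.
#' @export
max_combined_bank_flow <- function(config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  config$n_banks * config$variable_line_max_ml_min
}

#' Number of binary odor mixtures
#'
#' With one odor drawn from each of two banks, `vials_per_bank^2` distinct
#' binary mixtures can be formed (16 for the default 2 x 4 layout).
#'
#' @param config A `flow_config` with exactly two banks.
#' @return Integer count of mixtures.
#' @export
count_binary_mixtures <- function(config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  if (config$n_banks != 2L) {
    stop_olf("binary mixtures require exactly 2 banks",
             class = "olf_domain_error")
  }
  config$vials_per_bank^2L
}

#' Construct a valve timeline
#'
#' @param odor Character vector of odor ids.
#' @param onset_ms,offset_ms Valve open/close times (ms); `offset > onset`.
#' @param flow_ml_min Odor-line flow while open.
#' @return Data frame of class `valve_timeline`.
#' @export
valve_timeline <- function(odor = character(), onset_ms = numeric(),
                           offset_ms = numeric(), flow_ml_min = numeric()) {
  n <- length(odor)
  stopifnot(length(onset_ms) == n, length(offset_ms) == n,
            length(flow_ml_min) == n)
  if (n > 0L) {
    if (any(offset_ms <= onset_ms)) stop_olf("offset_ms must exceed onset_ms")
    if (any(onset_ms < 0)) stop_olf("onset_ms must be >= 0")
    if (any(flow_ml_min <= 0)) stop_olf("flow_ml_min must be > 0")
  }
  structure(
    data.frame(odor = as.character(odor), onset_ms = as.numeric(onset_ms),
               offset_ms = as.numeric(offset_ms),
               flow_ml_min = as.numeric(flow_ml_min),
               stringsAsFactors = FALSE),
    class = c("valve_timeline", "data.frame")
  )
}

#' @rdname valve_timeline
#' @param x A `valve_timeline`.
#' @param path JSON file path.
#' @export
write_valve_timeline <- function(x, path) {
  jsonlite::write_json(as.data.frame(unclass(x)), path, digits = NA)
  invisible(path)
}

#' @rdname valve_timeline
#' @export
read_valve_timeline <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  valve_timeline(d$odor, d$onset_ms, d$offset_ms, d$flow_ml_min)
}

# Line-clearance time constant in seconds: inversely proportional to vapor
# pressure (volatile odors clear faster), clipped so that 10 s after valve
# close every odor has decayed below 1% of plateau (exp(-10/2.1) ~ 0.9%).
tau_clear_s <- function(vapor_pressure_mmHg, coef = 8,
                        range_s = c(0.2, 2.1)) {
  pmin(pmax(coef / vapor_pressure_mmHg, range_s[1]), range_s[2])
}

#' Simulate a PID concentration trace
#'
#' Synthesizes the photo-ionization detector signal an odor timeline would
#' produce: while a valve is open the signal rises with first-order kinetics
#' (time constant `tau_rise_s`) toward a plateau equal to
#' `gain * airborne_dilution(spec, flow, total setpoint)`; after valve close
#' it decays exponentially with an odor-specific clearance constant that
#' decreases with vapor pressure. Overlapping pulses superpose linearly and
#' no vial depletion is modelled (repeated pulses reach identical plateaus).
#'
#' @param timeline A `valve_timeline`.
#' @param specs Named list of `odor_spec` covering every odor id used.
#' @param config A `flow_config`; its carrier setpoint is the constant total
#'   flow into which odors dilute.
#' @param dt_ms Sampling interval in ms (>= 1; default 10).
#' @param gains Named numeric vector of per-odor PID gains in detector units
#'   per s.v. fraction (default 1 for every odor; real photo-ionization
#'   efficiencies are odor-specific and uncalibrated here).
#' @param duration_ms Trace length; defaults to the last offset + 15 s.
#' @param tau_rise_s Rise time constant in seconds (default 0.2).
#' @return Object of class `pid_trace`: list with `dt_ms`, `samples`
#'   (non-negative detector signal), `time_s`.
#' @export
simulate_pid_trace <- function(timeline, specs, config = flow_config(),
                               dt_ms = 10, gains = NULL,
                               duration_ms = NULL, tau_rise_s = 0.2) {
  stopifnot(inherits(timeline, "valve_timeline"))
  if (dt_ms < 1) stop_olf("dt_ms must be >= 1")
  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(timeline) > 0L) max(timeline$offset_ms) + 15000
                   else 1000
  }
  t_ms <- seq(0, duration_ms, by = dt_ms)
  signal <- numeric(length(t_ms))
  for (i in seq_len(nrow(timeline))) {
    id <- timeline$odor[i]
    if (!id %in% names(specs)) {
      stop_olf("unknown odor id: ", id, class = "olf_domain_error")
    }
    spec <- specs[[id]]
    gain <- if (!is.null(gains) && id %in% names(gains)) gains[[id]] else 1
    plateau <- gain * airborne_dilution(
      spec, timeline$flow_ml_min[i], config$carrier_setpoint_ml_min
    )
    tr <- tau_rise_s * 1000
    tc <- tau_clear_s(spec$vapor_pressure_mmHg) * 1000
    on <- timeline$onset_ms[i]
    off <- timeline$offset_ms[i]
    rise <- t_ms >= on & t_ms < off
    decay <- t_ms >= off
    signal[rise] <- signal[rise] + plateau * (1 - exp(-(t_ms[rise] - on) / tr))
    s_off <- plateau * (1 - exp(-(off - on) / tr))
    signal[decay] <- signal[decay] + s_off * exp(-(t_ms[decay] - off) / tc)
  }
  structure(
    list(dt_ms = dt_ms, samples = signal, time_s = t_ms / 1000),
    class = "pid_trace"
  )
}

#' Flow profile over a timeline
#'
#' Evaluates odor, carrier and total flow at sample times under the
#' constant-total-flow rule; the total column is constant by construction.
#'
#' @param timeline A `valve_timeline`.
#' @param config A `flow_config`.
#' @param times_ms Sample times in ms.
#' @return Data frame with `time_ms`, `odor_flow_ml_min`,
#'   `carrier_flow_ml_min`, `total_flow_ml_min`.
#' @export
flow_profile <- function(timeline, config = flow_config(), times_ms) {
  odor_flow <- vapply(times_ms, function(t) {
    open <- timeline$onset_ms <= t & t < timeline$offset_ms
    sum(timeline$flow_ml_min[open])
  }, numeric(1))
  carrier <- vapply(odor_flow, function(f) {
    carrier_flow(config$carrier_setpoint_ml_min, f)
  }, numeric(1))
  data.frame(
    time_ms = times_ms, odor_flow_ml_min = odor_flow,
    carrier_flow_ml_min = carrier,
    total_flow_ml_min = odor_flow + carrier
  )
}

#' Write a PID trace as two-column TSV
#' @param trace A `pid_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pid_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pid_trace"))
  utils::write.table(
    data.frame(time_s = trace$time_s, signal = trace$samples),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
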