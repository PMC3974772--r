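---
title: "Models and methods behind olfactr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind olfactr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactr)
```

# Scope

`olfactr` implements the computational core of an automated,
olfactometer-driven behavior rig for rodents: the event-log data model the
rig records, the flow/dilution physics of odor delivery, the schedule
builders for habituation-family and operant assays, the behavioral
statistics those assays produce, Weibull psychometric threshold
estimation, and a generative virtual mouse that lets every analysis be
exercised end-to-end without animal data. Hardware control, video
tracking, and live-animal data are out of scope.

# The olfactometer model

## Dilution arithmetic

Odorants are diluted v/v in mineral oil (or water) inside a vial whose
headspace equilibrates with air. Under the ideal-solution assumption, air
leaving the vial carries the odor at `liquid_dilution` times saturation.
Joining an odor line at flow $f_o$ to a total stream $f_t$ gives the
delivered concentration in saturated-vapor (s.v.) fraction:

$$c = d_\text{liquid} \cdot \frac{f_o}{f_t}.$$

A 1:10 vial at 100 ml/min into 400 ml/min total therefore delivers
$2.5\times10^{-2}$ s.v., and a $1{:}10^7$ vial $2.5\times10^{-8}$ s.v.
The headspace assumption is the standard operating approximation for
flow-dilution olfactometers; deviations from Raoult's law for strongly
non-ideal odorant/solvent pairs are not modelled.

## Constant total flow

Whenever odor valves open, the carrier mass-flow setpoint is reduced by
the summed odor-line flow, so total flow at the animal is constant
(`carrier_flow()`). This reproduces the rig's anti-artifact logic: odor
onset causes no mechanical (pressure/flow) transient, which matters
because olfactory neurons also respond to mechanical stimulation. The
default configuration has a 0–1000 ml/min carrier, one 100 ml/min fixed
line, and two 1–99 ml/min variable bank lines over 2 × 4 vials, giving a
maximal bank contribution of 198 ml/min and 16 binary mixtures.

## Synthesized PID traces

`simulate_pid_trace()` produces the signal a photo-ionization detector
would report. Kinetics are first order: rise toward
`gain × airborne_dilution` with $\tau_\text{rise} = 0.2$ s (rise speed is
treated as concentration- and odor-independent, consistent with observed
rapid onsets), and exponential clearance after valve close with

$$\tau_\text{clear} = \mathrm{clip}\!\left(\frac{8}{p_\text{vap}\,
[\text{mmHg}]},\; 0.2\,\text{s},\; 2.1\,\text{s}\right),$$

so more volatile odors clear faster. The coefficient gives amyl acetate
(4 mmHg) $\tau \approx 2$ s; the 2.1 s ceiling guarantees every odor
decays below 1% of plateau within 10 s of valve close
($e^{-10/2.1} \approx 0.9\%$), the cleanliness criterion automated
assays rely on. Pulses superpose linearly and no vial depletion is
modelled (repeated pulses measure identical plateaus, as real vials do
over typical session counts). Per-odor PID gains default to 1: real
photo-ionization efficiencies are odor-specific but uncalibrated here,
so absolute trace units are arbitrary.

# The event log

The rig records one row per state change — `time_ms, event_type,
location, magnitude` — at 1-ms resolution. The package fixes a concrete
text dialect (UTF-8, LF, `#`-prefixed `key=value` header lines) since
only the logical four-column structure is canonical. Design choices:

* Times are integer milliseconds from log start; wall-clock dates belong
  in the metadata header, not the event stream.
* At identical timestamps, "off" sorts before "on", keeping zero-length
  gaps representable.
* `pair_events()` matches each "on" to the next "off" at the same
  channel. A second "on" while on is a hardware glitch (an IR beam
  cannot re-break while broken) and is discarded with a warning, as is
  an "off" with no open bout. A trailing open bout is closed at the last
  event time of the log (recording stopped mid-poke).

Pairing is verified against an independent brute-force state-machine
oracle on random logs, and serialization round-trips exactly for
magnitudes at ≤ 6 significant digits.

# Assay schedules

Habituation-family assays use 60-s stimulus sessions at 240-s
onset-to-onset spacing. The phrase "one minute stimulus at four minute
intervals" is ambiguous between onset spacing and gap; onset spacing was
chosen (1 min odor + 3 min clean air) and both are configurable. The
cross-habituation layout is background ×8, S1 ×5, optional S2 block; the
threshold series is background ×8 followed by strictly ascending
concentration blocks; the preference assay is mineral-oil background
followed by repeated test-odor sessions.

Operant sequences (two-choice, Go/No-Go) are balanced pseudorandom
orders of 30 trials per odor, seeded, with at most 3 consecutive
same-odor trials — the run cap prevents degenerate single-side blocks
that would confound side bias with learning.

# Behavioral statistics

* **Investigation** is the summed overlap of nose-poke bouts with the
  session window, half-open `[onset, offset)`; straddling pokes are
  clipped, not counted whole.
* **NPI** (normalized port investigation) is
  $100 \times$ session investigation / mean background investigation.
  The mean NPI over the background block is exactly 100% by
  construction — an identity the tests assert. An animal with zero
  background investigation cannot be normalized and is excluded via a
  classed condition rather than silently scored.
* **ΔNPI** is the successive-session NPI difference: ≈ 0 for repeated
  identical stimuli after habituation, positive at a perceived stimulus
  change.
* **Success rates**: two-choice $SR = (P_{AA} + P_{BB})/P_\text{total}$;
  Go/No-Go $SR = (P_{CS+} + NP_{CS-}) / \text{total}$ (hits plus correct
  rejections; the only combination of the four counts with a 50% chance
  floor). Both are permutation-invariant in trial order and bounded in
  [0, 1].
* **Preference**: attraction index = NPI(first odor session) − NPI(last
  background session); aversion index = NPI(last background session) −
  NPI(second odor session). Aversion is read from the second
  presentation because the first is confounded by novelty-driven
  investigation; the sign conventions make both indices
  bigger-is-stronger. Three-chamber zone times are normalized to the
  control chamber, with control-zone-absent animals excluded.

## The JND threshold and its multiplicity correction

For the detection-threshold series, each probe concentration's ΔNPI
(probe session minus preceding session — the within-animal control is
built into the difference) is tested against zero with a t-test across
animals; the just-noticeable difference is the smallest significant
concentration. Testing 7 concentrations at a raw per-test α = 0.05
would false-alarm on roughly 30% of null cohorts, so the p values are
Holm-adjusted across the series by default; `p_adjust = "none"`
reproduces the raw per-concentration p values. With Holm, simulated
null cohorts (novelty gain set to zero) report no detectable
concentration in ≥ 95% of replicates, i.e. the procedure is calibrated.

## Two ΔNPI comparators in the threshold pipeline

The pipeline computes the per-concentration response two ways, for two
different jobs:

* For the **curve fit**, the probe NPI is referenced to the air-block
  baseline, which is exactly 100 by the normalization identity:
  `dNPI = NPI − 100`. This has two advantages over the literal
  successive-session difference: the expected value is directly
  proportional to the detection probability (successive differencing of
  an ascending series telescopes into *increments* of the psychometric
  function — a peaked curve that no saturating Weibull fits), and the
  sampling variance is roughly halved because one of the two terms is
  exact.
* For the **JND significance test**, the successive-session difference
  is kept: it is exactly mean-zero under the null hypothesis, whereas
  the ratio-normalized baseline comparator carries a small positive
  Jensen-type bias ($E[1/\bar{B}] > 1/E[\bar{B}]$, ≈ +6% with 8
  background sessions) that measurably inflates the false-alarm rate.

Both comparators are exposed via `cohort_dnpi_matrix(baseline =)`.

# Weibull psychometric fitting

The psychometric function is the standard Weibull form

$$\psi(x) = g + (A - g)\left(1 - e^{-(x/a)^b}\right),$$

with $A$ the ceiling, $b$ the steepness, $a$ the threshold (the fitted
threshold *is* $a$; no alternative criterion level is used), and $g$ the
floor held fixed at the paradigm's chance level — 0.5 for Go/No-Go
success rates, 0 for habituation-family responses. No lapse-rate
parameter is modelled. Fitting is nonlinear least squares on the linear
concentration scale (concentrations are log-spaced by design, but the
function is evaluated on linear $x$):

* positivity of $b$, $a$ and $A > g$ is enforced by an unconstrained
  log reparameterization;
* initialization is data-driven ($A_0 = \max y$, $b_0 = 1$, $a_0$ = the
  half-rise point interpolated on $\log_{10} x$) with two deterministic
  jittered restarts ($b_0 \times 2, a_0/5$ and $b_0/2, a_0 \times 5$);
* each start is polished BFGS → Nelder–Mead → BFGS; the simplex stage's
  convergence verdict is kept;
* a fit is reported `converged = FALSE` when the optimizer fails, the
  responses are flat at/below the floor (threshold unidentifiable), or
  the fitted $a$ lands more than 4 decades outside the sampled range —
  never a silent fallback.

Noiseless synthetic curves are recovered to relative error below
$10^{-6}$, and the fit is scale-equivariant: scaling all concentrations
by $c$ scales $\hat{a}$ by $c$ and leaves $\hat{A}, \hat{b}$ unchanged.

# The virtual mouse

The generator produces event logs with the statistical structure the
analyses assume — it is a stated model, not a fit to any dataset.

**Bout process.** Nose pokes arrive as a Poisson process at
`lambda_base` (default 4 bouts/min) with exponential bout durations
(mean 800 ms), merged if overlapping and written at 1-ms resolution.
These two rate constants are nowhere reported for real animals; the
defaults are plausibility choices, exposed as parameters, and none of
the package's statistics depend on their particular values (NPI
normalizes them away).

**Session rate multipliers.** During a session with stimulus $s$ at
concentration $c$ the rate is multiplied by $M$:

* detection is gated by a ground-truth Weibull psychometric
  $p_\text{det}(c)$ (defaults $A=1$, $b=1.5$, $a = 2\times10^{-6}$ s.v.,
  $g=0$);
* on first exposure, $M = 1 + \eta \, p_\text{det}(c)\, D \,(1 + |v|)$,
  where $D \in [0,1]$ is the perceptual dissimilarity to the stimulus
  the animal last habituated to (0 = indistinguishable; unlisted
  distinct pairs default to 1; background air/MO counts as fully
  dissimilar from any odor), $\eta$ is the novelty gain (default 3,
  putting first-exposure NPI near 400%), and $v \in [-1,1]$ the odor's
  valence;
* on the $k$-th repeat, the novelty term decays as $\rho^k$. The
  default $\rho = 0.25$ encodes the observed phenomenology that
  investigation returns to near background by the second presentation
  of the same stimulus;
* aversive odors ($v<0$) additionally multiply the rate by
  $1 + v\,p_\text{det}(c)$ from the second exposure onward, pushing
  investigation below baseline — which is exactly why the aversion
  index reads the second presentation;
* a same odor at a different concentration is treated as a new stimulus
  with dissimilarity `intensity_dissimilarity` (default 1: a detectable
  intensity step is fully novel). This choice makes the expected
  air-referenced ΔNPI of an ascending threshold series proportional to
  $p_\text{det}(c)$, which is what licenses fitting it with the same
  Weibull family.

Habituation is stimulus-specific with cross-transfer through $D$; that
transfer is precisely what makes the cross-habituation ΔNPI a
similarity readout ($D=0$ pairs produce no dis-habituation at the
switch).

**Operant model.** Per-trial accuracy follows
$acc_t = 0.5 + (A_\infty - 0.5)(1 - e^{-t/\tau})$ (defaults
$A_\infty = 0.95$, $\tau = 30$ trials) scaled by detectability:
$P(\text{correct}) = 0.5 + (acc_t - 0.5)\,p_\text{det}(c)$. Undetectable
odors pin performance to the 50% floor regardless of training.

**Cohorts.** Per-animal seeds derive deterministically from the master
seed, so cohorts are reproducible and enlarging a cohort never
reshuffles existing animals. Between-animal variability is a log-normal
multiplier (sd(log) = 0.25) on the baseline rate.

**What a green test does not establish.** The generator reproduces the
*structure* real assays assume (Poisson-like bouts, rapid habituation,
detection-gated novelty, valence suppression, exponential learning), not
any real animal's rates, thresholds or variability. Live-animal headline
numbers (detection thresholds of $6.6\times10^{-6}$ and
$1.9\times10^{-6}$ s.v. order) are properties of mice, not of this code,
and are deliberately not asserted anywhere; the pipeline is validated by
parameter recovery against its own ground truth instead.

# Numerical and degenerate-input choices

* Event times are validated as non-negative integers; parse errors name
  the offending line.
* `npi()` with a zero basal and three-chamber indices with zero control
  time raise an `olf_animal_excluded` condition (matching the practice
  of excluding such animals rather than imputing).
* `jnd_threshold()` with a zero-variance column: an exactly-zero column
  carries no evidence (p = 1); an exactly-constant non-zero shift is
  treated as decisive (p = 0). A spec-style "always p = 1" reading would
  make a noiseless known effect undetectable, which contradicts the
  procedure's purpose.
* The recovery experiment in the acceptance tests is a stochastic
  property: measured over 20 master seeds at the design size (12
  animals, 7 half-decade concentrations around $a^* = 2\times10^{-6}$),
  the fitted threshold lands within ±50% of truth in ~85% of
  replicates; the suite pins one a-priori seed.
* Simulations in the test suite are scaled (tens to a few hundred
  replicates instead of thousands) to keep the default run inside CI
  budgets; the bounds asserted leave margin for the reduced replicate
  counts.

# Known limitations

* The headspace model ignores non-ideal solution behavior, tubing
  dead-volume and adsorption; PID gains are arbitrary per-odor
  constants.
* The virtual mouse has no spatial component (no trajectory, zone or
  velocity readouts); three-chamber zone times are consumed as a table,
  never generated.
* Closed-loop paradigms (trial logic driven by live animal state) are
  not simulated; schedules are consumed open-loop.
* The operant simulator models per-trial correctness only, not lick
  timing, reaction times or satiation.
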