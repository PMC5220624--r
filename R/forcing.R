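# Forcing: compression waveform, force-to-pressure coupling, PLR gravity.

# Pa per mmHg
MMHG_PA <- 133.322

# Force->pressure coupling (mmHg per N) calibrated once so that steady-state
# cardiac output under the reference protocol (400 N half-sinusoids, 100/min,
# 50% duty, thoracic pump factor 0.75, no leg raising) equals the reference
# 1.30 L/min; see calibrate_force_coupling().  The split between the
# intrathoracic and mediastinal sources is not identifiable from a single
# flow anchor, so both share one coefficient (ratio 1).
DEFAULT_K_LUNG <- 0.0545444539
DEFAULT_K_MED <- 0.0545444539

#' Define the compression and leg-raising protocol
#'
#' Bundles the chest-compression waveform, the force-to-pressure coupling
#' and the passive leg raising (PLR) maneuver into a single protocol object
#' consumed by [simulate_cpr()].
#'
#' @param amplitude Peak compression force (N). The reference protocol uses
#'   400 N, clinically equivalent to about 5 cm of sternal displacement.
#' @param frequency Compression rate (per minute).
#' @param duty_cycle Fraction of each cycle spent compressing; the waveform
#'   is a half-sinusoid over the compression fraction and zero during the
#'   restoring phase.
#' @param k_lung Intrathoracic pressure per unit force (mmHg/N), acting on
#'   all chest compartments C1--C8.
#' @param k_med Mediastinal pressure per unit force (mmHg/N), acting fully
#'   on the ventricles and scaled by the thoracic pump factor elsewhere in
#'   the chest (never on the peripheral pulmonary vessels C4, C5).
#' @param force_gate_threshold Force (N) above which the coronary bed is
#'   pinched shut; effectively "any compression at all".
#' @param plr_angle_deg Leg elevation angle above horizontal, degrees in
#'   \[0, 90\]. 0 disables the maneuver.
#' @param plr_start Time (s) at which the legs are raised.
#' @param plr_ramp Duration (s) of a linear ramp of the gravitational
#'   pressure from 0 to its full value; 0 means an instantaneous step.
#' @return An object of class `cpr_protocol`.
#' @export
#' @examples
#' proto <- cpr_protocol(plr_angle_deg = 90)
#' compression_force(c(0, 0.15, 0.45), proto)
cpr_protocol <- function(amplitude = 400,
                         frequency = 100,
                         duty_cycle = 0.5,
                         k_lung = DEFAULT_K_LUNG,
                         k_med = DEFAULT_K_MED,
                         force_gate_threshold = 1e-9,
                         plr_angle_deg = 0,
                         plr_start = 20,
                         plr_ramp = 0) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (frequency <= 0) stop("frequency must be positive")
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("duty_cycle must lie strictly between 0 and 1")
  if (k_lung < 0 || k_med < 0) stop("pressure couplings must be non-negative")
  if (plr_angle_deg < 0 || plr_angle_deg > 90)
    stop("plr_angle_deg must lie in [0, 90], got ", format(plr_angle_deg))
  if (plr_start < 0) stop("plr_start must be non-negative")
  if (plr_ramp < 0) stop("plr_ramp must be non-negative")
  structure(
    list(amplitude = amplitude, frequency = frequency,
         duty_cycle = duty_cycle, k_lung = k_lung, k_med = k_med,
         force_gate_threshold = force_gate_threshold,
         plr_angle_deg = plr_angle_deg, plr_start = plr_start,
         plr_ramp = plr_ramp),
    class = "cpr_protocol")
}

#' Instantaneous chest-compression force
#'
#' Non-overlapping half-sinusoids: within each cycle of length
#' `60/frequency` seconds the force is `A sin(pi t / t_on)` for the
#' compression fraction `t_on = duty_cycle * period` and zero for the rest.
#'
#' @param t Time(s), seconds; vectorised.
#' @param protocol A [cpr_protocol()].
#' @return Force in newtons, same length as `t`.
#' @export
compression_force <- function(t, protocol) {
  period <- 60 / protocol$frequency
  t_on <- protocol$duty_cycle * period
  tau <- t - floor(t / period) * period
  ifelse(tau < t_on, protocol$amplitude * sin(pi * tau / t_on), 0)
}

#' Map compression force to intrathoracic and mediastinal pressures
#'
#' Both pressure sources are proportional to the applied force; the
#' coefficients are calibrated jointly against the reference cardiac output
#' (see [calibrate_force_coupling()]).
#'
#' @param force Force (N), vectorised.
#' @param protocol A [cpr_protocol()].
#' @return List with components `p_lung` and `p_m` (mmHg).
#' @export
force_to_pressures <- function(force, protocol) {
  list(p_lung = protocol$k_lung * force, p_m = protocol$k_med * force)
}

#' Gravitational pressure from passive leg raising
#'
#' Treats the blood in the raised legs as a uniform column of length
#' `leg_length`, with its centre of gravity at the mid-point, so that the
#' hydrostatic pressure at the hip is \eqn{\rho g (l/2) \sin\alpha},
#' converted from Pa to mmHg. The same pressure is applied to the femoral
#' arterial and venous compartments. Zero before `plr_start`; ramped
#' linearly over `plr_ramp` seconds if a ramp is configured.
#'
#' @param t Time(s), seconds; vectorised.
#' @param protocol A [cpr_protocol()].
#' @param params A [cpr_parameters()] (supplies `rho`, `g`, `leg_length`).
#' @return Pressure in mmHg, same length as `t`.
#' @export
#' @examples
#' p <- cpr_parameters()
#' plr_pressure(25, cpr_protocol(plr_angle_deg = 90), p)  # ~30.8 mmHg
plr_pressure <- function(t, protocol, params) {
  full <- plr_pressure_magnitude(protocol, params)
  if (protocol$plr_ramp > 0) {
    frac <- pmin(1, pmax(0, (t - protocol$plr_start) / protocol$plr_ramp))
  } else {
    frac <- as.numeric(t >= protocol$plr_start)
  }
  full * frac
}

# Steady gravitational pressure (mmHg) for the configured angle.
plr_pressure_magnitude <- function(protocol, params) {
  params$rho * params$g * (params$leg_length / 2) *
    sin(protocol$plr_angle_deg * pi / 180) / MMHG_PA
}

#' Calibrate the force-to-pressure coupling against a cardiac output anchor
#'
#' The magnitude of the pressure generated per newton of compression force
#' is not identifiable from the network parameters alone; it is fixed by
#' requiring that the simulated steady-state cardiac output under a
#' reference protocol matches a known value (default: 1.30 L/min at
#' thoracic pump factor 0.75, no leg raising). A one-dimensional root
#' search over a common scale factor is performed with the
#' mediastinal/intrathoracic ratio held fixed.
#'
#' @param params A [cpr_parameters()]; its `tpf` defines the reference
#'   condition.
#' @param protocol A [cpr_protocol()]; its waveform settings are kept, only
#'   `k_lung`/`k_med` are replaced during the search.
#' @param target_co Target steady-state cardiac output (L/min).
#' @param ratio Fixed ratio `k_med / k_lung`.
#' @param duration Simulation length (s) per evaluation.
#' @param window Averaging window (s) for cardiac output.
#' @param dt Integration step (s).
#' @param tol Relative tolerance on the achieved cardiac output.
#' @param k_range Search bracket for `k_lung` (mmHg/N).
#' @return List with `k_lung`, `k_med`, `achieved_co` (L/min) and
#'   `target_co`.
#' @export
calibrate_force_coupling <- function(params, protocol = cpr_protocol(),
                                     target_co = 1.30, ratio = 1,
                                     duration = 20, window = c(10, 20),
                                     dt = 0.001, tol = 0.01,
                                     k_range = c(1e-4, 1)) {
  if (target_co <= 0) stop("target_co must be positive")
  co_at <- function(k) {
    proto <- protocol
    proto$k_lung <- k
    proto$k_med <- ratio * k
    proto$plr_angle_deg <- 0
    tr <- simulate_cpr(params, proto, dt = dt, duration = duration)
    summarize_window(tr, window)$co
  }
  lo <- co_at(k_range[1])
  hi <- co_at(k_range[2])
  if (target_co < lo || target_co > hi)
    stop(sprintf(
      "target CO %.3f L/min outside achievable range [%.3f, %.3f] over k in [%g, %g]",
      target_co, lo, hi, k_range[1], k_range[2]))
  # CO grows monotonically with the coupling scale; bisect on log-k.
  f <- function(logk) co_at(exp(logk)) - target_co
  root <- stats::uniroot(f, lower = log(k_range[1]), upper = log(k_range[2]),
                         tol = 1e-4)
  k <- exp(root$root)
  achieved <- co_at(k)
  if (abs(achieved - target_co) / target_co > tol)
    warning(sprintf("calibration achieved CO %.4f vs target %.4f L/min",
                    achieved, target_co))
  list(k_lung = k, k_med = ratio * k, achieved_co = achieved,
       target_co = target_co)
}
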