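# Windowed summary metrics and before/after-PLR comparison.

#' Summarise a trace over a steady-state window
#'
#' Reduces a [simulate_cpr()] trace to the standard CPR hemodynamic
#' quantities, averaged over a time window that should span an integer
#' number of compression cycles and lie past the initial transient:
#'
#' * `co` — cardiac output: mean aortic-valve flow, L/min;
#' * `cpp` — coronary perfusion pressure: mean aortic minus right-atrial
#'   pressure restricted to the restoring (zero-force) phase, mmHg;
#' * `q_heart` — mean coronary flow, mL/s;
#' * `q_head` — mean flow through the head vascular bed, mL/s;
#' * `v_legs` — mean femoral arterial + venous volume, mL;
#' * `v_abdomen` — mean abdominal aorta + inferior vena cava volume, mL;
#' * `p_ppv_mean` — mean peripheral pulmonary venous pressure, mmHg (the
#'   oedema-safety quantity).
#'
#' @param trace A `cpr_trace`.
#' @param window Numeric length 2: start and end of the window (s).
#' @return An object of class `cpr_metrics` (a named list of the above
#'   plus `window`).
#' @export
summarize_window <- function(trace, window) {
  stopifnot(inherits(trace, "cpr_trace"), length(window) == 2L)
  if (window[2] <= window[1]) stop("window end must exceed its start")
  if (window[2] > max(trace$time) + 1e-9)
    stop("window [", window[1], ", ", window[2], "] extends beyond the trace")
  period <- 60 / trace$protocol$frequency
  if (diff(window) < period - 1e-9)
    stop("window must cover at least one compression cycle (",
         format(period), " s)")
  idx <- trace$time >= window[1] & trace$time <= window[2]
  restoring <- idx & trace$force <= trace$protocol$force_gate_threshold
  structure(
    list(
      co = 60 * mean(trace$flows[idx, "C7_C8"]),
      cpp = mean(trace$pressures[restoring, 8] - trace$pressures[restoring, 1]),
      q_heart = 1000 * mean(trace$flows[idx, "C8_C1"]),
      q_head = 1000 * mean(trace$flows[idx, "C9_C10"]),
      v_legs = 1000 * mean(trace$volumes[idx, 12] + trace$volumes[idx, 13]),
      v_abdomen = 1000 * mean(trace$volumes[idx, 11] + trace$volumes[idx, 14]),
      p_ppv_mean = mean(trace$pressures[idx, 5]),
      window = window),
    class = "cpr_metrics")
}

#' @export
print.cpr_metrics <- function(x, ...) {
  cat(sprintf("window [%g, %g] s:\n", x$window[1], x$window[2]))
  cat(sprintf("  CO      %7.3f L/min   CPP    %7.2f mmHg\n", x$co, x$cpp))
  cat(sprintf("  Q_heart %7.2f mL/s    Q_head %7.2f mL/s\n",
              x$q_heart, x$q_head))
  cat(sprintf("  V_legs  %7.1f mL      V_abd  %7.1f mL\n",
              x$v_legs, x$v_abdomen))
  cat(sprintf("  P_ppv   %7.2f mmHg\n", x$p_ppv_mean))
  invisible(x)
}

# metrics whose percent change is reported
COMPARED_METRICS <- c("co", "cpp", "q_heart", "q_head",
                      "v_legs", "v_abdomen", "p_ppv_mean")

#' Compare hemodynamics before and after passive leg raising
#'
#' Runs one simulation in which the legs are raised mid-run (at
#' `protocol$plr_start`), summarises a pre-PLR and a post-PLR window, and
#' reports the percent change of each metric,
#' \eqn{(after - before)/before \times 100}.
#'
#' @param params A [cpr_parameters()].
#' @param protocol A [cpr_protocol()]; `plr_start` must fall between the
#'   two windows.
#' @param dt,duration,record_every Passed to [simulate_cpr()].
#' @param before,after Averaging windows (s), by default the last 10 s
#'   before and the final 10 s after the maneuver.
#' @param keep_trace Keep the full trace in the result (`$trace`)?
#' @return An object of class `plr_comparison`: list with `before`, `after`
#'   (both `cpr_metrics`), `pct_change` (named numeric; `NA` where the
#'   before value is 0), `tpf`, `angle_deg`, and optionally `trace`.
#' @export
#' @examples
#' \donttest{
#' cmp <- compare_plr(cpr_parameters(tpf = 0.75),
#'                    cpr_protocol(plr_angle_deg = 90))
#' cmp$pct_change["co"]
#' }
compare_plr <- function(params, protocol, dt = 0.001, duration = 40,
                        record_every = 1L, before = c(10, 20),
                        after = c(30, 40), keep_trace = FALSE) {
  if (protocol$plr_start < before[2] || protocol$plr_start > after[1])
    stop("plr_start must lie between the 'before' and 'after' windows")
  if (after[2] > duration)
    stop("'after' window extends beyond the simulation duration")
  trace <- simulate_cpr(params, protocol, dt = dt, duration = duration,
                        record_every = record_every)
  b <- summarize_window(trace, before)
  a <- summarize_window(trace, after)
  pct <- vapply(COMPARED_METRICS, function(k) {
    if (abs(b[[k]]) < .Machine$double.eps) NA_real_
    else (a[[k]] - b[[k]]) / b[[k]] * 100
  }, numeric(1))
  res <- list(before = b, after = a, pct_change = pct,
              tpf = params$tpf, angle_deg = protocol$plr_angle_deg)
  if (keep_trace) res$trace <- trace
  structure(res, class = "plr_comparison")
}

#' @export
print.plr_comparison <- function(x, ...) {
  cat(sprintf("PLR comparison (tpf = %.2f, angle = %g deg)\n",
              x$tpf, x$angle_deg))
  tab <- data.frame(before = unlist(x$before[COMPARED_METRICS]),
                    after = unlist(x$after[COMPARED_METRICS]),
                    pct_change = x$pct_change)
  print(round(tab, 2))
  invisible(x)
}

#' Blood volume transferred out of the legs by the maneuver
#'
#' @param comparison A [compare_plr()] result.
#' @return List with `transferred_ml` (mL moved from the femoral
#'   compartments to the upper body) and `fraction_pct` (percent of the
#'   pre-maneuver leg volume).
#' @export
leg_volume_transfer <- function(comparison) {
  stopifnot(inherits(comparison, "plr_comparison"))
  v0 <- comparison$before$v_legs
  if (v0 <= 0) stop("pre-maneuver leg volume is zero; fraction undefined")
  moved <- v0 - comparison$after$v_legs
  list(transferred_ml = moved, fraction_pct = moved / v0 * 100)
}

#' Pulmonary oedema safety check
#'
#' The mean peripheral pulmonary venous pressure approximates pulmonary
#' capillary pressure; values below the plasma colloid osmotic pressure
#' (about 25--30 mmHg) are taken as oedema-safe. The default threshold is
#' the conservative end of that band.
#'
#' @param trace A `cpr_trace`.
#' @param window Averaging window (s).
#' @param threshold Colloid osmotic pressure threshold (mmHg).
#' @return List with `p_ppv_mean` (mmHg), `threshold`, and logical `safe`.
#' @export
edema_check <- function(trace, window, threshold = 25) {
  m <- summarize_window(trace, window)
  list(p_ppv_mean = m$p_ppv_mean, threshold = threshold,
       safe = m$p_ppv_mean < threshold)
}
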