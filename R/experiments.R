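# Scripted experiments: TPF sweep, angle sweep, oedema grid, summary table,
# PETCO2 bridge.

sweep_core <- function(axis_name, axis_values, make_run, ...) {
  if (is.unsorted(axis_values, strictly = TRUE))
    stop(axis_name, " values must be strictly increasing")
  results <- lapply(axis_values, make_run)
  rows <- lapply(seq_along(axis_values), function(i) {
    cmp <- results[[i]]
    tv <- leg_volume_transfer(cmp)
    data.frame(axis = axis_values[i],
               co_before = cmp$before$co, co_after = cmp$after$co,
               cpp_change = cmp$pct_change[["cpp"]],
               co_change = cmp$pct_change[["co"]],
               q_heart_change = cmp$pct_change[["q_heart"]],
               q_head_change = cmp$pct_change[["q_head"]],
               transferred_ml = tv$transferred_ml,
               transfer_fraction_pct = tv$fraction_pct,
               p_ppv_after = cmp$after$p_ppv_mean)
  })
  tab <- do.call(rbind, rows)
  names(tab)[1] <- axis_name
  structure(list(axis = axis_name, values = axis_values,
                 results = results, table = tab),
            class = "cpr_sweep")
}

#' Sweep the thoracic pump factor
#'
#' Runs the before/after-PLR comparison at each thoracic pump factor with a
#' fixed leg elevation angle, tracing how the benefit of the maneuver
#' depends on the compression mechanism (cardiac vs thoracic pump).
#'
#' @param tpfs Thoracic pump factors, strictly increasing, within \[0, 1\].
#' @param angle_deg Leg elevation angle (degrees).
#' @param protocol Base [cpr_protocol()]; its `plr_angle_deg` is replaced.
#' @param ... Passed to [compare_plr()] (e.g. `dt`, `record_every`).
#' @return A `cpr_sweep`: list with `axis`, `values`, per-point
#'   [compare_plr()] `results`, and a `table` of percent-change curves and
#'   transfer volumes.
#' @export
tpf_sweep <- function(tpfs, angle_deg = 90, protocol = cpr_protocol(), ...) {
  if (any(tpfs < 0 | tpfs > 1)) stop("tpfs must lie within [0, 1]")
  protocol$plr_angle_deg <- angle_deg
  sweep_core("tpf", tpfs,
             function(v) compare_plr(cpr_parameters(tpf = v), protocol, ...))
}

#' Sweep the leg elevation angle
#'
#' Runs the before/after-PLR comparison at each elevation angle with a
#' fixed thoracic pump factor.
#'
#' @param angles_deg Angles (degrees), strictly increasing, within
#'   \[0, 90\].
#' @param tpf Thoracic pump factor.
#' @param protocol Base [cpr_protocol()].
#' @param ... Passed to [compare_plr()].
#' @return A `cpr_sweep` (see [tpf_sweep()]).
#' @export
angle_sweep <- function(angles_deg, tpf = 0.75, protocol = cpr_protocol(),
                        ...) {
  if (any(angles_deg < 0 | angles_deg > 90))
    stop("angles_deg must lie within [0, 90]")
  params <- cpr_parameters(tpf = tpf)
  sweep_core("angle_deg", angles_deg, function(v) {
    proto <- protocol
    proto$plr_angle_deg <- v
    compare_plr(params, proto, ...)
  })
}

#' @export
print.cpr_sweep <- function(x, ...) {
  cat(sprintf("PLR sweep over %s (%d points)\n", x$axis, length(x$values)))
  print(round(x$table, 2))
  invisible(x)
}

#' @export
as.data.frame.cpr_sweep <- function(x, ...) x$table

#' Plot percent-change curves of a sweep
#'
#' @param x A `cpr_sweep`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cpr_sweep <- function(x, ...) {
  cols <- c("cpp_change", "co_change", "q_heart_change", "q_head_change")
  graphics::matplot(x$table[[x$axis]], as.matrix(x$table[cols]), type = "b",
                    pch = 1:4, lty = 1, xlab = x$axis,
                    ylab = "change with PLR (%)", ...)
  graphics::legend("topright", legend = c("CPP", "CO", "Q_heart", "Q_head"),
                   pch = 1:4, col = 1:4, bty = "n")
  invisible(x)
}

#' Pulmonary oedema screening grid
#'
#' Mean peripheral pulmonary venous pressure over the post-PLR window for
#' every combination of thoracic pump factor and elevation angle, screened
#' against the colloid-osmotic threshold.
#'
#' @param tpfs Thoracic pump factors.
#' @param angles_deg Elevation angles (degrees).
#' @param threshold Colloid osmotic pressure threshold (mmHg).
#' @param protocol Base [cpr_protocol()].
#' @param window Post-PLR averaging window (s).
#' @param ... Passed to [simulate_cpr()].
#' @return Data frame with columns `tpf`, `angle_deg`, `p_ppv_mean`,
#'   `safe`; the maximum pressure over the grid is attached as attribute
#'   `max_p_ppv`.
#' @export
edema_grid <- function(tpfs, angles_deg, threshold = 25,
                       protocol = cpr_protocol(), window = c(30, 40), ...) {
  grid <- expand.grid(tpf = tpfs, angle_deg = angles_deg)
  vals <- mapply(function(tpf, ang) {
    proto <- protocol
    proto$plr_angle_deg <- ang
    tr <- simulate_cpr(cpr_parameters(tpf = tpf), proto,
                       duration = window[2], ...)
    edema_check(tr, window, threshold)$p_ppv_mean
  }, grid$tpf, grid$angle_deg)
  grid$p_ppv_mean <- vals
  grid$safe <- vals < threshold
  attr(grid, "max_p_ppv") <- max(vals)
  grid
}

#' Linear bridge between cardiac output and end-tidal CO2 changes
#'
#' End-tidal CO2 is a noninvasive surrogate for cardiac output during CPR;
#' the published linear relation is `y = 0.33 x + 0.13` with `x` the
#' percent change in cardiac output and `y` the percent change in end-tidal
#' CO2 (stated for decreases and applied with the same coefficients to
#' increases). The model itself contains no gas exchange, so this bridge is
#' the only route from simulated flows to the clinically measured quantity.
#'
#' @param co_change_pct Percent change in cardiac output.
#' @return Percent change in end-tidal CO2.
#' @seealso [co_change_from_petco2()] for the inverse.
#' @export
#' @examples
#' petco2_from_co_change(0)      # intercept 0.13
#' co_change_from_petco2(7)      # about 20.8
petco2_from_co_change <- function(co_change_pct) {
  0.33 * co_change_pct + 0.13
}

#' @rdname petco2_from_co_change
#' @param petco2_change_pct Percent change in end-tidal CO2.
#' @export
co_change_from_petco2 <- function(petco2_change_pct) {
  (petco2_change_pct - 0.13) / 0.33
}

# Published comparison values for the PLR effect at TPF 0, 0.5, 1 (90 deg):
# CO in L/min, Q_heart and Q_head in mL/s, percent increase with PLR.
reference_table3 <- function() {
  data.frame(
    metric = rep(c("co", "q_heart", "q_head"), each = 3),
    tpf = rep(c(0, 0.5, 1), times = 3),
    ref_before = c(2.0, 1.5, 1.1, 1.9, 1.4, 0.8, 6.9, 5.8, 4.8),
    ref_after = c(2.2, 1.7, 1.1, 2.1, 1.6, 0.8, 7.6, 6.6, 5.2),
    ref_change_pct = c(10, 15, 0, 10, 17, 0, 10, 14, 9)
  )
}

#' Simulated counterpart of the published three-pump-regime table
#'
#' Re-simulates the PLR comparison at thoracic pump factors 0, 0.5 and 1
#' (angle 90 degrees) and lays the simulated before/after/percent-change
#' values for CO, Q_heart and Q_head alongside the published reference
#' values, with absolute and relative deviations. Deviations are reported,
#' not asserted.
#'
#' @param protocol Base [cpr_protocol()].
#' @param ... Passed to [compare_plr()].
#' @param sweep Optionally, a precomputed `cpr_sweep` over tpf
#'   `c(0, 0.5, 1)` at 90 degrees to avoid re-simulation.
#' @return Data frame: `metric`, `tpf`, simulated `before`/`after`/
#'   `change_pct`, reference values, and deviations.
#' @export
reproduce_table3 <- function(protocol = cpr_protocol(), ..., sweep = NULL) {
  if (is.null(sweep))
    sweep <- tpf_sweep(c(0, 0.5, 1), angle_deg = 90, protocol = protocol, ...)
  if (!identical(as.numeric(sweep$values), c(0, 0.5, 1)))
    stop("sweep must cover tpf = 0, 0.5, 1")
  ref <- reference_table3()
  sim <- do.call(rbind, lapply(seq_along(sweep$values), function(i) {
    cmp <- sweep$results[[i]]
    data.frame(
      metric = c("co", "q_heart", "q_head"),
      tpf = sweep$values[i],
      before = c(cmp$before$co, cmp$before$q_heart, cmp$before$q_head),
      after = c(cmp$after$co, cmp$after$q_heart, cmp$after$q_head),
      change_pct = cmp$pct_change[c("co", "q_heart", "q_head")])
  }))
  out <- merge(sim, ref, by = c("metric", "tpf"), sort = FALSE)
  out$dev_before_rel <- (out$before - out$ref_before) / out$ref_before
  out$dev_change_pp <- out$change_pct - out$ref_change_pct
  out[order(out$metric, out$tpf), ]
}
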