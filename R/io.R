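# Trace/summary export and test fixtures.

#' Write a simulation trace to CSV
#'
#' Comma-separated, header row, one row per recorded step, times in seconds
#' with six decimals; columns as in [as.data.frame.cpr_trace()].
#'
#' @param trace A `cpr_trace`.
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$t <- round(df$t, 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a PLR comparison summary as JSON
#'
#' All windowed metrics, percent changes, the transferred leg volume, a
#' configuration echo and provenance fields (package version, step size,
#' calibration constants, configuration fingerprint).
#'
#' @param comparison A [compare_plr()] result.
#' @param path Output path.
#' @param dt Step size used (s), echoed into provenance.
#' @export
write_summary_json <- function(comparison, path, dt = 0.001) {
  stopifnot(inherits(comparison, "plr_comparison"))
  tv <- leg_volume_transfer(comparison)
  strip <- function(m) m[COMPARED_METRICS]
  doc <- list(
    tpf = comparison$tpf,
    plr_angle_deg = comparison$angle_deg,
    before = strip(comparison$before),
    after = strip(comparison$after),
    pct_change = as.list(comparison$pct_change),
    transferred_ml = tv$transferred_ml,
    transfer_fraction_pct = tv$fraction_pct,
    provenance = list(
      package = "cprplr",
      version = as.character(utils::packageVersion("cprplr")),
      dt = dt,
      k_lung = DEFAULT_K_LUNG,
      k_med = DEFAULT_K_MED,
      config_fingerprint = config_fingerprint(default_config())
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Miniature fixtures with known dynamics
#'
#' Small systems used as integrator oracles and fast test protocols:
#'
#' * `"two-compartment-loop"` — two equal RC compartments exchanging volume
#'   through one resistance: the pressure difference relaxes exponentially
#'   with the closed-form time constant \eqn{\tau = R C_1 C_2/(C_1+C_2)}.
#' * `"no-valves-loop"` — three valveless compartments in a ring starting
#'   at uniform pressure: the exact solution is constant.
#' * `"reference-short"` — the reference parameters and protocol cut to
#'   12 s, long enough to reach the periodic steady state.
#'
#' @param kind Fixture name.
#' @return For the analytic loops, a list with `rhs(t, y)`, `y0`, and the
#'   closed-form quantities (`tau`, `equilibrium`); for the short protocol,
#'   a list with `params`, `protocol`, `dt`, `duration`.
#' @export
make_fixture <- function(kind = c("two-compartment-loop", "no-valves-loop",
                                  "reference-short")) {
  kind <- match.arg(kind)
  switch(kind,
    "two-compartment-loop" = {
      R <- 100
      C <- c(0.01, 0.01)
      y0 <- c(0.75, 0.25)
      list(
        kind = kind, R = R, C = C, y0 = y0,
        tau = R * prod(C) / sum(C),
        equilibrium = rep(sum(y0) / 2, 2),
        rhs = function(t, y) {
          q <- (y[1] / C[1] - y[2] / C[2]) / R
          c(-q, q)
        },
        # closed-form pressure difference at time t
        dp = function(t) (y0[1] / C[1] - y0[2] / C[2]) *
          exp(-t / (R * prod(C) / sum(C)))
      )
    },
    "no-valves-loop" = {
      R <- c(10, 20, 30)
      C <- c(0.01, 0.02, 0.03)
      P <- 5
      y0 <- P * C
      list(
        kind = kind, R = R, C = C, y0 = y0,
        rhs = function(t, y) {
          p <- y / C
          q <- (p - p[c(2, 3, 1)]) / R  # edge i: i -> i+1 (ring)
          q[c(3, 1, 2)] - q
        }
      )
    },
    "reference-short" = list(
      kind = kind,
      params = cpr_parameters(tpf = 0.75),
      protocol = cpr_protocol(),
      dt = 0.001,
      duration = 12
    )
  )
}
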