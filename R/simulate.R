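# Pressures, valve-gated flows, volume ODE right-hand side, and the
# fixed-step integrator.

#' Compartment pressures from volumes and external pressure sources
#'
#' The pressure of compartment *i* is the closed-form
#' \deqn{P_i = P_0 + (V_i - V_{0,i})/C_i + \ell_i P_{lung} + m_i P_M + s_i P_{PLR}}
#' where \eqn{\ell_i} is 1 for chest compartments, \eqn{m_i} is 1 for the
#' ventricles, the thoracic pump factor for the other chest compartments
#' outside the lung parenchyma and 0 elsewhere, and \eqn{s_i} is 1 for the
#' femoral compartments. This is the time-integral of the incremental
#' pressure update \eqn{\Delta P_i = \Delta V_i / C_i + \ldots} from the
#' zero-forcing arrest equilibrium, so integrating volumes alone loses
#' nothing and cannot drift.
#'
#' @param V Volumes (L): a length-14 vector, or an n x 14 matrix of states
#'   (one row per time point).
#' @param params A [cpr_parameters()].
#' @param p_lung,p_m,p_plr External pressures (mmHg): scalars, or vectors of
#'   length n when `V` is a matrix.
#' @return Pressures (mmHg), same shape as `V`.
#' @export
compute_pressures <- function(V, params, p_lung = 0, p_m = 0, p_plr = 0) {
  comp <- params$compartments
  m <- mediastinal_weights(params)
  lung <- comp$lung_coupling
  plr <- comp$plr_coupling
  if (is.matrix(V)) {
    if (ncol(V) != nrow(comp))
      stop("V has ", ncol(V), " columns but the model has ",
           nrow(comp), " compartments")
    n <- nrow(V)
    elastic <- sweep(sweep(V, 2, comp$V0), 2, comp$C, "/")
    params$P0 + elastic +
      outer(rep_len(p_lung, n), lung) +
      outer(rep_len(p_m, n), m) +
      outer(rep_len(p_plr, n), plr)
  } else {
    if (length(V) != nrow(comp))
      stop("V has length ", length(V), " but the model has ",
           nrow(comp), " compartments")
    params$P0 + (V - comp$V0) / comp$C + lung * p_lung + m * p_m + plr * p_plr
  }
}

#' Valve-gated flows along every network edge
#'
#' Resistive edges carry signed flow \eqn{\Delta P / R}; valve edges are
#' ideal diodes, \eqn{\max(0, \Delta P / R)}. The coronary edge additionally
#' conducts only while the chest is not being compressed: during the
#' compression phase the coronary resistance is effectively infinite and
#' the flow is exactly zero.
#'
#' @param P Pressures (mmHg): length-14 vector or n x 14 matrix.
#' @param params A [cpr_parameters()].
#' @param force Instantaneous compression force (N): scalar, or length-n
#'   vector for the matrix case.
#' @param gate_threshold Force above which the coronary edge is shut (N).
#' @return Flows (L/s) along the directed edges, named as in
#'   `params$edges$name`: a vector, or an n x 17 matrix.
#' @export
compute_flows <- function(P, params, force = 0, gate_threshold = 1e-9) {
  ed <- params$edges
  if (is.matrix(P)) {
    dp <- P[, ed$from, drop = FALSE] - P[, ed$to, drop = FALSE]
    q <- sweep(dp, 2, ed$R, "/")
    vi <- which(ed$valve)
    q[, vi] <- pmax(q[, vi, drop = FALSE], 0)
    gi <- which(ed$gated)
    q[rep_len(force, nrow(P)) > gate_threshold, gi] <- 0
    colnames(q) <- ed$name
    q
  } else {
    q <- (P[ed$from] - P[ed$to]) / ed$R
    q[ed$valve] <- pmax(q[ed$valve], 0)
    if (force[1L] > gate_threshold) q[ed$gated] <- 0
    names(q) <- ed$name
    q
  }
}

# Signed incidence matrix (compartments x edges): +1 inflow, -1 outflow.
# Each edge appears exactly once with each sign, so colSums are zero and
# total volume is conserved identically.
incidence_matrix <- function(params) {
  ed <- params$edges
  n <- nrow(params$compartments)
  M <- matrix(0, n, nrow(ed))
  M[cbind(ed$from, seq_len(nrow(ed)))] <- -1
  M[cbind(ed$to, seq_len(nrow(ed)))] <- M[cbind(ed$to, seq_len(nrow(ed)))] + 1
  rownames(M) <- params$compartments$id
  colnames(M) <- ed$name
  M
}

#' Time derivative of the volume state
#'
#' Net inflow minus outflow per compartment at time `t`, composing
#' [compression_force()], [force_to_pressures()], [plr_pressure()],
#' [compute_pressures()] and [compute_flows()]. The sum over compartments is
#' exactly zero: the loop is closed.
#'
#' @param t Time (s).
#' @param V Volumes (L), length 14.
#' @param params A [cpr_parameters()].
#' @param protocol A [cpr_protocol()].
#' @return dV/dt (L/s), length 14.
#' @export
cpr_derivatives <- function(t, V, params, protocol) {
  f <- compression_force(t, protocol)
  fp <- force_to_pressures(f, protocol)
  pp <- plr_pressure(t, protocol, params)
  P <- compute_pressures(V, params, fp$p_lung, fp$p_m, pp)
  q <- compute_flows(P, params, f, protocol$force_gate_threshold)
  as.vector(incidence_matrix(params) %*% q)
}

#' Fixed-step explicit integration of an ODE system
#'
#' Classic fourth-order Runge--Kutta (or forward Euler) with a constant
#' step. Diode discontinuities in the right-hand side are evaluated
#' directly inside the stages without event detection, as appropriate at
#' millisecond steps.
#'
#' @param rhs Function `(t, y) -> dy/dt`.
#' @param y0 Initial state (numeric vector, optionally named).
#' @param dt Step size (s), > 0.
#' @param duration Total integration time (s).
#' @param record_every Record every k-th step (the initial state is always
#'   recorded).
#' @param method `"rk4"` or `"euler"`.
#' @return List with `time` (length m) and `states` (m x length(y0) matrix).
#' @export
integrate_fixed_step <- function(rhs, y0, dt, duration, record_every = 1L,
                                 method = c("rk4", "euler")) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive")
  if (duration < dt) stop("duration must cover at least one step")
  record_every <- as.integer(record_every)
  nstep <- as.integer(round(duration / dt))
  nrec <- nstep %/% record_every + 1L
  states <- matrix(NA_real_, nrec, length(y0))
  colnames(states) <- names(y0)
  times <- numeric(nrec)
  states[1L, ] <- y0
  y <- as.numeric(y0)
  j <- 2L
  half <- dt / 2
  sixth <- dt / 6
  for (i in seq_len(nstep)) {
    t <- (i - 1L) * dt
    if (method == "rk4") {
      k1 <- rhs(t, y)
      k2 <- rhs(t + half, y + half * k1)
      k3 <- rhs(t + half, y + half * k2)
      k4 <- rhs(t + dt, y + dt * k3)
      y <- y + sixth * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      y <- y + dt * rhs(t, y)
    }
    if (!all(is.finite(y))) {
      bad <- which(!is.finite(y))[1L]
      nm <- if (is.null(names(y0))) as.character(bad) else names(y0)[bad]
      stop(sprintf("non-finite state in component %s at t = %.4f s", nm, i * dt))
    }
    if (i %% record_every == 0L) {
      states[j, ] <- y
      times[j] <- i * dt
      j <- j + 1L
    }
  }
  list(time = times, states = states)
}

# Fast closure form of the model right-hand side used by the main
# simulation loop; algebraically identical to cpr_derivatives() (asserted
# in the test suite) but avoids per-call data-frame access.
build_rhs <- function(params, protocol) {
  comp <- params$compartments
  Cv <- comp$C
  V0 <- comp$V0
  lungv <- comp$lung_coupling
  mv <- mediastinal_weights(params)
  plrv <- comp$plr_coupling
  P0 <- params$P0
  ed <- params$edges
  efrom <- ed$from
  eto <- ed$to
  Re <- ed$R
  valve_idx <- which(ed$valve)
  gate_idx <- which(ed$gated)
  M <- incidence_matrix(params)
  kl <- protocol$k_lung
  km <- protocol$k_med
  A <- protocol$amplitude
  period <- 60 / protocol$frequency
  t_on <- protocol$duty_cycle * period
  gate <- protocol$force_gate_threshold
  pplr_full <- plr_pressure_magnitude(protocol, params)
  plr_start <- protocol$plr_start
  plr_ramp <- protocol$plr_ramp

  function(t, V) {
    tau <- t - floor(t / period) * period
    f <- if (tau < t_on) A * sin(pi * tau / t_on) else 0
    pp <- if (plr_ramp > 0) {
      pplr_full * min(1, max(0, (t - plr_start) / plr_ramp))
    } else if (t >= plr_start) pplr_full else 0
    P <- P0 + (V - V0) / Cv + lungv * (kl * f) + mv * (km * f) + plrv * pp
    q <- (P[efrom] - P[eto]) / Re
    q[valve_idx] <- pmax(q[valve_idx], 0)
    if (f > gate) q[gate_idx] <- 0
    as.vector(M %*% q)
  }
}

#' Simulate the CPR circulation model
#'
#' Integrates the 14 volume ODEs under the given compression/PLR protocol
#' with a fixed-step fourth-order Runge--Kutta scheme (the reference solver
#' configuration: 1 ms step, 40 s horizon) and reconstructs pressures,
#' edge flows and the applied forcings at every recorded step.
#'
#' @param params A [cpr_parameters()].
#' @param protocol A [cpr_protocol()].
#' @param dt Step size (s).
#' @param duration Simulated time (s).
#' @param record_every Record every k-th step; 1 keeps the full millisecond
#'   trace.
#' @param method `"rk4"` (default) or `"euler"` (the incremental update
#'   scheme, kept as a cross-check).
#' @return An object of class `cpr_trace`: list with `time` (s), `volumes`
#'   (L, matrix), `pressures` (mmHg, matrix), `flows` (L/s, matrix with one
#'   column per directed edge), `force` (N), `p_lung`, `p_m`, `p_plr`
#'   (mmHg), plus the `params`, `protocol`, `dt`, `record_every` and
#'   `method` that produced it.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_cpr(cpr_parameters(tpf = 0.75),
#'                    cpr_protocol(plr_angle_deg = 90),
#'                    duration = 40)
#' summarize_window(tr, c(10, 20))
#' }
simulate_cpr <- function(params, protocol = cpr_protocol(), dt = 0.001,
                         duration = 40, record_every = 1L,
                         method = c("rk4", "euler")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "cpr_parameters"),
            inherits(protocol, "cpr_protocol"))
  rhs <- build_rhs(params, protocol)
  y0 <- params$compartments$V0
  names(y0) <- params$compartments$id
  sol <- integrate_fixed_step(rhs, y0, dt, duration,
                              record_every = record_every, method = method)
  tt <- sol$time
  force <- compression_force(tt, protocol)
  fp <- force_to_pressures(force, protocol)
  pp <- plr_pressure(tt, protocol, params)
  P <- compute_pressures(sol$states, params, fp$p_lung, fp$p_m, pp)
  colnames(P) <- params$compartments$id
  q <- compute_flows(P, params, force, protocol$force_gate_threshold)
  structure(
    list(time = tt, volumes = sol$states, pressures = P, flows = q,
         force = force, p_lung = fp$p_lung, p_m = fp$p_m, p_plr = pp,
         params = params, protocol = protocol, dt = dt,
         record_every = as.integer(record_every), method = method),
    class = "cpr_trace")
}

#' @export
print.cpr_trace <- function(x, ...) {
  cat(sprintf("CPR simulation trace: %.1f s at dt = %g s (%s), %d samples\n",
              max(x$time), x$dt, x$method, length(x$time)))
  cat(sprintf("  tpf = %.2f, PLR angle = %g deg (start %g s)\n",
              x$params$tpf, x$protocol$plr_angle_deg, x$protocol$plr_start))
  invisible(x)
}

#' Coerce a simulation trace to a data frame
#'
#' One row per recorded step with columns `t`, `V_C1..V_C14` (L),
#' `P_C1..P_C14` (mmHg), `q_<edge>` (L/s), `force` (N), `p_lung`, `p_m`,
#' `p_plr` (mmHg).
#'
#' @param x A `cpr_trace`.
#' @param ... Unused.
#' @export
as.data.frame.cpr_trace <- function(x, ...) {
  V <- x$volumes
  colnames(V) <- paste0("V_", x$params$compartments$id)
  P <- x$pressures
  colnames(P) <- paste0("P_", x$params$compartments$id)
  q <- x$flows
  colnames(q) <- paste0("q_", x$params$edges$name)
  data.frame(t = x$time, V, P, q, force = x$force, p_lung = x$p_lung,
             p_m = x$p_m, p_plr = x$p_plr)
}

#' Plot a simulation trace
#'
#' Three stacked panels: compression force, regional blood volumes (legs
#' and abdomen), and aortic-valve flow.
#'
#' @param x A `cpr_trace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpr_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$force, type = "l", xlab = "time (s)",
                 ylab = "force (N)", ...)
  vl <- 1000 * (x$volumes[, 12] + x$volumes[, 13])
  va <- 1000 * (x$volumes[, 11] + x$volumes[, 14])
  graphics::plot(x$time, va, type = "l", col = "darkred",
                 ylim = range(c(va, vl)), xlab = "time (s)",
                 ylab = "volume (mL)")
  graphics::lines(x$time, vl, col = "navy")
  graphics::legend("right", legend = c("abdomen", "legs"), lty = 1,
                   col = c("darkred", "navy"), bty = "n")
  graphics::plot(x$time, 60 * x$flows[, "C7_C8"], type = "l",
                 xlab = "time (s)", ylab = "aortic flow (L/min)")
  invisible(x)
}
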