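# Shared simulation cache: the full-length reference runs are reused by
# several test files, so each (tpf, angle) condition is simulated once.

sim_cache <- new.env(parent = emptyenv())

# Full 40-s PLR comparison at the default calibrated protocol.
cached_cmp <- function(tpf, angle) {
  key <- sprintf("cmp_%g_%g", tpf, angle)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- compare_plr(
      cpr_parameters(tpf = tpf),
      cpr_protocol(plr_angle_deg = angle),
      keep_trace = (tpf == 0.75 && angle == 90))
  }
  sim_cache[[key]]
}

# Short (12 s) reference run without PLR, for property tests.
cached_short_trace <- function() {
  if (is.null(sim_cache$short)) {
    fx <- make_fixture("reference-short")
    sim_cache$short <- simulate_cpr(fx$params, fx$protocol, dt = fx$dt,
                                    duration = fx$duration)
  }
  sim_cache$short
}

# Same run integrated with the explicit (incremental-update) Euler scheme.
cached_euler_short <- function() {
  if (is.null(sim_cache$short_euler)) {
    fx <- make_fixture("reference-short")
    sim_cache$short_euler <- simulate_cpr(fx$params, fx$protocol,
                                          dt = fx$dt,
                                          duration = fx$duration,
                                          method = "euler")
  }
  sim_cache$short_euler
}
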