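# Structured run configuration: YAML serialization and validation.

#' Default run configuration
#'
#' The configuration equivalent of the reference setup: Table-of-reference
#' compartment values, 400 N half-sinusoid compressions at 100/min with 50%
#' duty cycle, calibrated force couplings, no leg raising, 40 s at a 1 ms
#' step, comparison windows \[10, 20\] and \[30, 40\] s.
#'
#' @return An object of class `cpr_config` (a nested named list with
#'   sections `model`, `forcing`, `plr` and `run`).
#' @export
default_config <- function() {
  comp <- compartment_table()
  structure(list(
    model = list(
      tpf = 0.75,
      epsilon_R = 1,
      P0 = 7,
      rho = 1060,
      g = 9.8,
      leg_length = 0.79,
      peripherals = list(Rh = 5520, Rht = 10780, Rs = 1800, Rl = 8520,
                         Rpc = 105),
      compartments = lapply(seq_len(nrow(comp)), function(i)
        as.list(comp[i, , drop = FALSE]))
    ),
    forcing = list(
      amplitude = 400,
      frequency = 100,
      duty_cycle = 0.5,
      k_lung = DEFAULT_K_LUNG,
      k_med = DEFAULT_K_MED,
      force_gate_threshold = 1e-9
    ),
    plr = list(angle_deg = 0, start = 20, ramp = 0),
    run = list(dt = 0.001, duration = 40, record_every = 1L,
               window_before = c(10, 20), window_after = c(30, 40))
  ), class = "cpr_config")
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[key]]) && !is.null(names(base[[key]])) &&
        key != "compartments") {
      if (!is.list(user[[key]]))
        stop("configuration key ", here, " must be a mapping")
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  m <- cfg$model
  if (m$tpf < 0 || m$tpf > 1)
    stop("model.tpf must lie in [0, 1], got ", format(m$tpf))
  if (m$epsilon_R <= 0) stop("model.epsilon_R must be positive")
  p <- cfg$plr
  if (p$angle_deg < 0 || p$angle_deg > 90)
    stop("plr.angle_deg must lie in [0, 90], got ", format(p$angle_deg))
  r <- cfg$run
  if (r$dt <= 0) stop("run.dt must be positive")
  period <- 60 / cfg$forcing$frequency
  if (abs(period / r$dt - round(period / r$dt)) > 1e-9)
    stop("run.dt must divide the compression period (", format(period),
         " s) evenly")
  for (w in list(r$window_before, r$window_after)) {
    if (length(w) != 2L || w[1] >= w[2])
      stop("run windows must be increasing pairs of times")
    if (w[2] > r$duration)
      stop("run window [", w[1], ", ", w[2],
           "] extends beyond run.duration = ", r$duration)
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take their reference defaults; unknown keys are
#' rejected with the offending key named. An empty file yields the full
#' default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated `cpr_config`.
#' @seealso [default_config()], [save_config()], [config_to_model()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    if (!is.list(user)) stop("configuration must be a YAML mapping")
    cfg <- merge_config(unclass(cfg), user)
    class(cfg) <- "cpr_config"
  }
  validate_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg A `cpr_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cpr_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg A `cpr_config`.
#' @return List with `params` ([cpr_parameters()]), `protocol`
#'   ([cpr_protocol()]), `dt`, `duration`, `record_every`,
#'   `window_before`, `window_after`.
#' @export
config_to_model <- function(cfg) {
  validate_config(cfg)
  m <- cfg$model
  comp <- do.call(rbind, lapply(m$compartments, function(row)
    as.data.frame(row, stringsAsFactors = FALSE)))
  params <- cpr_parameters(
    tpf = m$tpf, epsilon_R = m$epsilon_R, P0 = m$P0, rho = m$rho, g = m$g,
    leg_length = m$leg_length, compartments = comp,
    peripherals = m$peripherals)
  f <- cfg$forcing
  protocol <- cpr_protocol(
    amplitude = f$amplitude, frequency = f$frequency,
    duty_cycle = f$duty_cycle, k_lung = f$k_lung, k_med = f$k_med,
    force_gate_threshold = f$force_gate_threshold,
    plr_angle_deg = cfg$plr$angle_deg, plr_start = cfg$plr$start,
    plr_ramp = cfg$plr$ramp)
  list(params = params, protocol = protocol, dt = cfg$run$dt,
       duration = cfg$run$duration, record_every = cfg$run$record_every,
       window_before = cfg$run$window_before,
       window_after = cfg$run$window_after)
}

# 32-bit FNV-1a over the deparsed configuration; a dependency-free
# fingerprint for provenance logging.  The xor only touches the low byte
# and the 32-bit modular product is split into 16-bit halves so every step
# stays exact in double arithmetic.
config_fingerprint <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
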