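# Model parameters: the 14-compartment closed-loop network.

#' Compartment definitions of the circulation network
#'
#' Returns the fourteen lumped vascular compartments with their outflow
#' resistances, capacitances and initial (cardiac-arrest) volumes, together
#' with the coupling classes that determine which external pressure sources
#' act on each compartment:
#'
#' * `lung_coupling` — chest compartments (C1--C8) receive the intrathoracic
#'   pressure generated by chest compression;
#' * `mediastinal_mode` — the mediastinal compression pressure acts fully on
#'   the ventricles (C2, C7), scaled by the thoracic pump factor on the
#'   remaining chest compartments except the peripheral pulmonary vessels
#'   (C4, C5), which are shielded deep inside the lungs;
#' * `plr_coupling` — the femoral compartments (C12, C13) receive the
#'   gravitational pressure when the legs are raised.
#'
#' @return A data frame with one row per compartment: `id`, `name`, `R_out`
#'   (outflow resistance, mmHg·s/L; zero for the atria where outflow into
#'   the ventricle is essentially unresisted), `C` (capacitance, L/mmHg),
#'   `V0` (initial volume, L), `valve_out` (outflow is one-way), `region`,
#'   `lung_coupling`, `mediastinal_mode`, `plr_coupling`.
#' @seealso [cpr_parameters()]
#' @export
#' @examples
#' compartment_table()
compartment_table <- function() {
  data.frame(
    id = paste0("C", 1:14),
    name = c(
      "Right atrium and intrathoracic great veins",
      "Right ventricle",
      "Large pulmonary arteries",
      "Peripheral pulmonary arteries",
      "Peripheral pulmonary veins",
      "Central pulmonary veins and left atrium",
      "Left ventricle",
      "Thoracic aorta",
      "Carotid arteries",
      "Jugular veins",
      "Abdominal aorta",
      "Femoral arteries",
      "Femoral veins",
      "Inferior vena cava"
    ),
    R_out = c(0, 5, 10, 10, 5, 0, 5, 10, 60, 30, 25, 360, 180, 25),
    C = c(0.00950, 0.016, 0.0042, 0.00042, 0.00128, 0.0128, 0.0080,
          0.00080, 0.00020, 0.01200, 0.00040, 0.00020, 0.00470, 0.02340),
    V0 = c(0.367, 0.150, 0.109, 0.160, 0.300, 0.250, 0.150, 0.078,
           0.132, 0.216, 0.114, 0.133, 0.267, 1.930),
    valve_out = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                  FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    region = c(rep("chest", 8), "head", "head", "abdomen",
               "legs", "legs", "abdomen"),
    lung_coupling = c(rep(1, 8), rep(0, 6)),
    mediastinal_mode = c("tpf_scaled", "full", "tpf_scaled", "none", "none",
                         "tpf_scaled", "full", "tpf_scaled", rep("none", 6)),
    plr_coupling = c(rep(0, 11), 1, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Assemble the full model parameter set
#'
#' Builds the complete parameterisation of the closed-loop network: the
#' fourteen compartments, the five peripheral bed resistances, the thoracic
#' pump factor, and the physical constants used by the leg-raising pressure.
#' Defaults reproduce the published reference values for an average adult
#' (175 cm, 70 kg, leg length 0.79 m, total blood volume 4.36 L).
#'
#' The printed outflow resistance of the atria (C1, C6) is zero —
#' atrioventricular filling is nearly unresisted — which would make the
#' valve flows singular; a small finite `epsilon_R` is substituted there to
#' keep the network well-posed at millisecond time steps.
#'
#' @param tpf Thoracic pump factor in \[0, 1\]: the fraction of the
#'   mediastinal compression pressure transmitted to the non-ventricular
#'   chest compartments. 0 is a pure cardiac pump (open chest, thin thorax),
#'   1 a pure thoracic pump (emphysema, deep thorax).
#' @param epsilon_R Resistance (mmHg·s/L) substituted where the printed
#'   outflow resistance is zero.
#' @param P0 Uniform initial pressure offset (mmHg); the mean circulatory
#'   filling pressure of the arrest state, at which the network is in true
#'   equilibrium.
#' @param rho Blood density (kg/m^3).
#' @param g Gravitational acceleration (N/kg).
#' @param leg_length Length of the blood column in the legs (m).
#' @param compartments Compartment table, by default [compartment_table()].
#'   Override to run reduced or perturbed networks.
#' @param peripherals Named list of peripheral resistances (mmHg·s/L):
#'   `Rh` (head), `Rht` (coronary, phase-gated), `Rs` (splanchnic),
#'   `Rl` (legs), `Rpc` (pulmonary capillary bed).
#' @return An object of class `cpr_parameters`: a list with elements
#'   `compartments`, `peripherals`, `tpf`, `rho`, `g`, `leg_length`,
#'   `epsilon_R`, `P0`, and `edges` (the directed edge table of the
#'   network, see Details).
#'
#' @details The network topology is fixed: blood flows
#' C1 (right atrium) \eqn{\to} C2 (right ventricle) \eqn{\to} C3--C5
#' (pulmonary arteries, capillary bed `Rpc`, veins) \eqn{\to} C6 (left
#' atrium) \eqn{\to} C7 (left ventricle) \eqn{\to} C8 (thoracic aorta),
#' which feeds the head (C9, `Rh`, C10, back to C1), the abdomen
#' (C11), the legs (C12, `Rl`, C13), and the splanchnic bed (`Rs` into
#' C14); C13 and C14 return to C1. The coronary bed connects C8 to C1
#' through `Rht` and only conducts while the chest is not being compressed.
#' Inter-compartment flow between X and Y uses the upstream compartment's
#' outflow resistance `R_out(X)`; the valves (tricuspid, pulmonary, mitral,
#' aortic, jugular, femoral-venous) are ideal diodes.
#' @export
#' @examples
#' p <- cpr_parameters(tpf = 0.75)
#' sum(p$compartments$V0)  # whole blood volume, 4.36 L
cpr_parameters <- function(tpf = 0.75,
                           epsilon_R = 1,
                           P0 = 7,
                           rho = 1060,
                           g = 9.8,
                           leg_length = 0.79,
                           compartments = compartment_table(),
                           peripherals = list(Rh = 5520, Rht = 10780,
                                              Rs = 1800, Rl = 8520,
                                              Rpc = 105)) {
  stopifnot(is.data.frame(compartments))
  required <- c("id", "name", "R_out", "C", "V0", "valve_out", "region",
                "lung_coupling", "mediastinal_mode", "plr_coupling")
  missing <- setdiff(required, names(compartments))
  if (length(missing) > 0L)
    stop("compartment table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(tpf) || length(tpf) != 1L || is.na(tpf) ||
      tpf < 0 || tpf > 1)
    stop("tpf must be a single number in [0, 1], got ", format(tpf))
  if (any(compartments$C <= 0))
    stop("all capacitances must be strictly positive")
  if (any(compartments$V0 <= 0))
    stop("all initial volumes must be strictly positive")
  if (any(compartments$R_out < 0))
    stop("outflow resistances must be non-negative")
  if (!all(vapply(peripherals[c("Rh", "Rht", "Rs", "Rl", "Rpc")],
                  function(r) is.numeric(r) && r > 0, logical(1))))
    stop("peripheral resistances Rh, Rht, Rs, Rl, Rpc must be positive")
  if (epsilon_R <= 0) stop("epsilon_R must be strictly positive")

  params <- structure(
    list(compartments = compartments,
         peripherals = peripherals,
         tpf = tpf,
         rho = rho,
         g = g,
         leg_length = leg_length,
         epsilon_R = epsilon_R,
         P0 = P0),
    class = "cpr_parameters")
  params$edges <- build_edge_table(params)
  params
}

# Directed edge list of the standard 14-compartment loop.  Flow X -> Y uses
# the upstream compartment's outflow resistance except through the named
# peripheral beds; `gated` marks the coronary edge, conducting only while
# the compression force is zero.
build_edge_table <- function(params) {
  comp <- params$compartments
  if (nrow(comp) != 14L || !identical(comp$id, paste0("C", 1:14)))
    stop("the standard topology requires compartments C1..C14 in order")
  r_eff <- ifelse(comp$R_out == 0, params$epsilon_R, comp$R_out)
  per <- params$peripherals
  edges <- data.frame(
    name = c("C1_C2", "C2_C3", "C3_C4", "C4_C5", "C5_C6", "C6_C7", "C7_C8",
             "C8_C9", "C9_C10", "C10_C1", "C8_C11", "C11_C12", "C12_C13",
             "C13_C14", "C11_C14", "C14_C1", "C8_C1"),
    from = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 8L, 11L, 12L,
             13L, 11L, 14L, 8L),
    to = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 1L, 11L, 12L, 13L,
           14L, 14L, 1L, 1L),
    R = c(r_eff[1], r_eff[2], r_eff[3], per$Rpc, r_eff[5], r_eff[6],
          r_eff[7], r_eff[8], per$Rh, r_eff[10], r_eff[8], r_eff[11],
          per$Rl, r_eff[13], per$Rs, r_eff[14], per$Rht),
    valve = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
              TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    gated = c(rep(FALSE, 16L), TRUE),
    stringsAsFactors = FALSE
  )
  edges
}

# Per-compartment mediastinal coupling weights for a given tpf.
mediastinal_weights <- function(params) {
  mode <- params$compartments$mediastinal_mode
  ifelse(mode == "full", 1, ifelse(mode == "tpf_scaled", params$tpf, 0))
}

#' @export
print.cpr_parameters <- function(x, ...) {
  cat("14-compartment closed-loop CPR model parameters\n")
  cat(sprintf("  thoracic pump factor: %.2f\n", x$tpf))
  cat(sprintf("  whole blood volume:   %.3f L\n", sum(x$compartments$V0)))
  cat(sprintf("  initial pressure P0:  %.1f mmHg\n", x$P0))
  cat(sprintf("  peripheral R (mmHg.s/L): Rh=%g Rht=%g Rs=%g Rl=%g Rpc=%g\n",
              x$peripherals$Rh, x$peripherals$Rht, x$peripherals$Rs,
              x$peripherals$Rl, x$peripherals$Rpc))
  invisible(x)
}
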