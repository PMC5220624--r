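test_that("pressures reduce to P0 at the arrest equilibrium", {
  p <- cpr_parameters(P0 = 7)
  V0 <- p$compartments$V0
  expect_equal(unname(compute_pressures(V0, p)), rep(7, 14))
})

test_that("mediastinal pressure reaches compartments according to tpf", {
  V0 <- compartment_table()$V0
  # pure cardiac pump: only the ventricles feel the mediastinal squeeze
  p0 <- cpr_parameters(tpf = 0)
  P <- compute_pressures(V0, p0, p_lung = 0, p_m = 50)
  expect_equal(which(abs(P - p0$P0) > 1e-12), c(2, 7))
  expect_equal(P[c(2, 7)], rep(p0$P0 + 50, 2))
  # pure thoracic pump: all chest compartments except those deep in the
  # lungs (C4, C5)
  p1 <- cpr_parameters(tpf = 1)
  P <- compute_pressures(V0, p1, p_lung = 0, p_m = 50)
  expect_equal(which(abs(P - p1$P0) > 1e-12), c(1, 2, 3, 6, 7, 8))
  # intermediate tpf scales the non-ventricular chest compartments
  ph <- cpr_parameters(tpf = 0.4)
  P <- compute_pressures(V0, ph, p_lung = 0, p_m = 50)
  expect_equal(P[1] - ph$P0, 0.4 * 50)
  expect_equal(P[2] - ph$P0, 50)
  # intrathoracic pressure acts on every chest compartment including C4, C5
  P <- compute_pressures(V0, ph, p_lung = 10, p_m = 0)
  expect_equal(unname(P - ph$P0), c(rep(10, 8), rep(0, 6)))
  # PLR pressure acts on the femoral compartments only
  P <- compute_pressures(V0, ph, p_plr = 30)
  expect_equal(which(abs(P - ph$P0) > 1e-12), c(12, 13))
})

test_that("valves block reverse flow and uniform pressure yields no flow", {
  p <- cpr_parameters()
  P <- rep(10, 14)
  expect_equal(unname(compute_flows(P, p)), rep(0, 17))
  # reverse-bias the femoral venous valve: P_C13 < P_C14
  P <- rep(10, 14); P[13] <- 5; P[14] <- 9
  q <- compute_flows(P, p)
  expect_equal(q[["C13_C14"]], 0)
  # forward bias passes dP/R
  P[13] <- 12
  q <- compute_flows(P, p)
  expect_equal(q[["C13_C14"]], (12 - 9) / 180)
})

test_that("coronary flow is gated off whenever the chest is compressed", {
  p <- cpr_parameters()
  P <- rep(10, 14); P[8] <- 40  # strong aorta-to-atrium gradient
  q_rest <- compute_flows(P, p, force = 0)
  expect_equal(q_rest[["C8_C1"]], (40 - 10) / 10780)
  q_comp <- compute_flows(P, p, force = 400)
  expect_equal(q_comp[["C8_C1"]], 0)
  # reverse gradient never produces backward coronary flow
  P[8] <- 1
  expect_equal(compute_flows(P, p, force = 0)[["C8_C1"]], 0)
})

test_that("matrix and vector forms of pressures and flows agree", {
  p <- cpr_parameters(tpf = 0.6)
  set.seed(42)
  V <- matrix(rep(p$compartments$V0, each = 5), 5) *
    matrix(runif(70, 0.9, 1.1), 5)
  pl <- runif(5, 0, 20); pm <- runif(5, 0, 20); pp <- c(0, 0, 10, 10, 30)
  f <- c(0, 400, 0, 123, 0)
  P <- compute_pressures(V, p, pl, pm, pp)
  q <- compute_flows(P, p, f)
  for (i in 1:5) {
    expect_equal(unname(P[i, ]),
                 unname(compute_pressures(V[i, ], p, pl[i], pm[i], pp[i])))
    expect_equal(unname(q[i, ]), unname(compute_flows(P[i, ], p, f[i])))
  }
})

test_that("derivatives conserve volume and vanish at equilibrium", {
  p <- cpr_parameters(tpf = 0.75)
  proto <- cpr_protocol()
  set.seed(7)
  for (i in 1:10) {
    V <- p$compartments$V0 * runif(14, 0.7, 1.3)
    t <- runif(1, 0, 40)
    dV <- cpr_derivatives(t, V, p, proto)
    expect_equal(sum(dV), 0, tolerance = 1e-12)
  }
  # arrest equilibrium with no forcing is a fixed point
  quiet <- cpr_protocol(amplitude = 0, plr_angle_deg = 0)
  dV <- cpr_derivatives(5, p$compartments$V0, p, quiet)
  expect_equal(dV, rep(0, 14))
})

test_that("thoracic aorta balance matches a hand-written flow budget", {
  p <- cpr_parameters(tpf = 0.75)
  proto <- cpr_protocol()
  t_peak <- 0.15  # peak compression
  set.seed(11)
  V <- p$compartments$V0 * runif(14, 0.85, 1.15)
  f <- compression_force(t_peak, proto)
  P <- compute_pressures(V, p, proto$k_lung * f, proto$k_med * f, 0)
  # inflow through the aortic valve; outflow to carotid and abdominal
  # branches through the aorta's outflow resistance; coronary edge is shut
  # during compression
  expected <- max(0, (P[7] - P[8]) / 5) - (P[8] - P[9]) / 10 -
    (P[8] - P[11]) / 10
  dV <- cpr_derivatives(t_peak, V, p, proto)
  expect_equal(dV[8], expected)
  expect_true(is.finite(dV[8]))
})

test_that("the fast integrator right-hand side equals the composed one", {
  p <- cpr_parameters(tpf = 0.3)
  proto <- cpr_protocol(plr_angle_deg = 60, plr_start = 2)
  rhs <- cprplr:::build_rhs(p, proto)
  set.seed(99)
  for (t in c(0, 0.07, 0.15, 0.31, 2.5, 3.001)) {
    V <- p$compartments$V0 * runif(14, 0.8, 1.2)
    expect_equal(rhs(t, V), cpr_derivatives(t, V, p, proto),
                 tolerance = 1e-12)
  }
})
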