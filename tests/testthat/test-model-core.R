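test_that("steady-state gate matches the sigmoid oracle and its limits", {
  expect_equal(gate_steady_state(-40, -40, -6), 0.5)
  expect_equal(gate_steady_state(-48, -48, 5), 0.5)
  # hand-evaluated sigmoid: V = -34, Vx = -40, sx = -6 -> 1/(1 + e^-1)
  expect_equal(gate_steady_state(-34, -40, -6), 0.731058578630005,
               tolerance = 1e-12)
  expect_equal(gate_steady_state(-1e3, -40, 5), 1, tolerance = 1e-12)
  expect_equal(gate_steady_state(1e3, -40, 5), 0, tolerance = 1e-12)
  v <- seq(-100, 30, by = 1)
  act <- gate_steady_state(v, -40, -6)
  expect_true(all(diff(act) > 0))             # strictly monotone, bounded
  expect_true(all(act > 0 & act < 1))
  expect_error(gate_steady_state(-40, -40, 0), "non-zero")
})

test_that("gating time constant is bell-shaped, symmetric, maximal at midpoint", {
  expect_equal(gate_time_constant(-48, 10000, -48, 5), 10000)
  # hand evaluation at 10 mV above midpoint with tau_h_bar = 10 s
  expect_equal(gate_time_constant(-38, 10000, -48, 5), 6480.54273663885,
               tolerance = 1e-10)
  for (d in c(1, 5, 12))
    expect_equal(gate_time_constant(-48 + d, 10000, -48, 5),
                 gate_time_constant(-48 - d, 10000, -48, 5))
  expect_error(gate_time_constant(-40, -1, -48, 5), "positive")
  expect_error(gate_time_constant(-40, 10, -48, 0), "non-zero")
})

test_that("current breakdown agrees with an independent term-by-term evaluation", {
  p <- test_params()
  s <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = 0.1, ca_tot = 1.5, l = 0.7)
  cur <- compute_currents(s, p)
  # frozen values from an independent high-precision evaluation of the
  # current equations at this state
  expect_equal(cur$INaP, -15.8869104880915, tolerance = 1e-12)
  expect_equal(cur$INa, -0.151397595635233, tolerance = 1e-12)
  expect_equal(cur$IK, 0.0168, tolerance = 1e-12)
  expect_equal(cur$IL, 27.0, tolerance = 1e-12)
  expect_equal(cur$ICa, -1.58869104880915, tolerance = 1e-12)
  expect_equal(cur$ICAN, -29.7619047619048, tolerance = 1e-12)
  expect_equal(cur$Ih, 0)
  expect_equal(cur$total, -20.3721038944407, tolerance = 1e-10)
})

test_that("each current vanishes with its conductance and is linear in it", {
  s <- model_state(V = -45, h = 0.6, n = 0.2, ca_i = 0.3, ca_tot = 1.5, l = 0.5)
  p0 <- test_params(gNaP = 0)
  expect_equal(compute_currents(s, p0)$INaP, 0)
  for (g in c("gNaP", "gNa", "gK", "gL", "gCAN", "gCa")) {
    args1 <- stats::setNames(list(1.3), g)
    args2 <- stats::setNames(list(2.6), g)
    c1 <- compute_currents(s, do.call(test_params, args1))[[sub("g", "I", g)]]
    c2 <- compute_currents(s, do.call(test_params, args2))[[sub("g", "I", g)]]
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
})

test_that("I_CAN is half-activated at the calcium half-activation constant", {
  p <- test_params()
  s <- model_state(V = -30, h = 0.5, n = 0.1, ca_i = p$KCAN, ca_tot = 3, l = 0.5)
  expect_equal(compute_currents(s, p)$ICAN,
               0.5 * p$gCAN * (-30 - p$VNaP), tolerance = 1e-12)
})

test_that("as-printed membrane mode reduces to the ohmic-IK equation", {
  p <- model_parameters(spiking_mode = "as_printed")
  s <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = 0.1, ca_tot = 1.5, l = 0.7)
  cur <- compute_currents(s, p)
  expect_equal(cur$INa, 0)
  expect_equal(cur$IL, 0)
  expect_equal(cur$IK, p$gK * (-50 - p$VK), tolerance = 1e-12)
})

test_that("calcium fluxes match their closed forms and sign conventions", {
  p <- test_params()
  s <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = 0.1, ca_tot = 1.5, l = 0.7)
  flx <- calcium_fluxes(s, p, ICa = -1.58869104880915)
  expect_equal(flx$ca_er, 7.56756756756757, tolerance = 1e-12)
  expect_equal(flx$J_ER_in, 82.1656459459459, tolerance = 1e-10)
  expect_equal(flx$J_ER_out, 80.0, tolerance = 1e-12)
  expect_equal(flx$J_PM_in, 0.0873780076845033, tolerance = 1e-12)
  expect_equal(flx$J_PM_out, 0.2, tolerance = 1e-12)
  # zero ER gradient -> zero ER flux
  s2 <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = 0.2,
                    ca_tot = 0.2 + p$sigma * 0.2, l = 0.7)
  expect_equal(calcium_fluxes(s2, p, 0)$J_ER_in, 0, tolerance = 1e-12)
  # SERCA half-activation
  sK <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = p$KSERCA, ca_tot = 2, l = 0.5)
  expect_equal(calcium_fluxes(sK, p, 0)$J_ER_out, p$VSERCA / 2, tolerance = 1e-12)
  # no voltage-gated calcium current -> no plasma-membrane influx
  expect_equal(calcium_fluxes(s, p, 0)$J_PM_in, 0)
  # negative derived ER calcium is an invalid state
  expect_error(
    calcium_fluxes(model_state(-50, 0.4, 0.1, ca_i = 0.5, ca_tot = 0.5, l = 0.5),
                   p, 0), NA)
  bad <- c(V = -50, h = 0.4, n = 0.1, ca_i = 2, ca_tot = 0.5, l = 0.5)
  expect_error(calcium_fluxes(bad, p, 0), "ER calcium")
})

test_that("right-hand side matches an independent full evaluation", {
  p <- test_params()
  s <- model_state(V = -50, h = 0.4, n = 0.1, ca_i = 0.1, ca_tot = 1.5, l = 0.7)
  d <- model_rhs(0, s, p)
  expect_equal(unname(d["V"]), 0.970100185449555, tolerance = 1e-10)
  expect_equal(unname(d["h"]), 2.02674676832455e-05, tolerance = 1e-10)
  expect_equal(unname(d["n"]), -0.0657630818637942, tolerance = 1e-10)
  expect_equal(unname(d["ca_i"]), -1.98552558071328e-05, tolerance = 1e-9)
  expect_equal(unname(d["ca_tot"]), -4.69258301314570e-05, tolerance = 1e-9)
  expect_equal(unname(d["l"]), 2.5e-05, tolerance = 1e-12)
})

test_that("gate equations are at rest at their fixed points", {
  p <- test_params()
  V <- -52
  s <- model_state(V = V, h = gate_steady_state(V, p$vh, p$sh),
                   n = gate_steady_state(V, p$vn, p$sn),
                   ca_i = 0.1, ca_tot = 1.5,
                   l = p$Kd / (0.1 + p$Kd))
  d <- model_rhs(0, s, p)
  expect_equal(unname(d["h"]), 0, tolerance = 1e-14)
  expect_equal(unname(d["n"]), 0, tolerance = 1e-14)
  expect_equal(unname(d["l"]), 0, tolerance = 1e-14)
})

test_that("closed plasma membrane conserves total calcium exactly in the RHS", {
  p <- test_params()
  p$alpha <- 0
  p$VPMCA <- 0
  s <- model_state(V = -30, h = 0.2, n = 0.4, ca_i = 0.6, ca_tot = 2, l = 0.3)
  expect_identical(unname(model_rhs(0, s, p)["ca_tot"]), 0)
})

test_that("all-zero conductances leave only the applied current", {
  p <- test_params(gNaP = 0, gNa = 0, gK = 0, gL = 0, gCAN = 0, gCa = 0, gh = 0)
  s <- model_state(V = -55, h = 0.5, n = 0.5, ca_i = 0.1, ca_tot = 1.5, l = 0.5)
  expect_equal(unname(model_rhs(0, s, p, I_app = 21)["V"]), 1, tolerance = 1e-12)
  expect_equal(unname(model_rhs(0, s, p)["V"]), 0, tolerance = 1e-12)
})

test_that("non-finite states are rejected with the offending component named", {
  p <- test_params()
  s <- c(V = NaN, h = 0.5, n = 0.5, ca_i = 0.1, ca_tot = 1.5, l = 0.5)
  expect_error(model_rhs(0, s, p), "V")
})

test_that("compiled and reference right-hand sides agree along a trajectory", {
  # spike-free configuration: fast-subsystem trajectories amplify rounding
  # differences, so the cross-check uses the smooth calcium-driven dynamics
  p <- test_params(gNa = 0, gK = 0, gNaP = 0)
  tr_c <- simulate(p, duration_s = 10, discard_s = 0, dt_out_ms = 5)
  tr_r <- simulate(p, duration_s = 10, discard_s = 0, dt_out_ms = 5,
                   engine = "R")
  expect_equal(tr_c$V_mV, tr_r$V_mV, tolerance = 1e-6)
  expect_equal(tr_c$ca_i, tr_r$ca_i, tolerance = 1e-6)
  expect_equal(tr_c$ca_tot, tr_r$ca_tot, tolerance = 1e-6)
})
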