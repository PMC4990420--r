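test_that("default initial state satisfies the state invariants", {
  p <- test_params()
  s <- default_initial_state(p)
  expect_s3_class(s, "model_state")
  expect_equal(s[["V"]], -60)
  # gates start at their V = -60 fixed points
  d <- model_rhs(0, s, p, clamp = TRUE)
  expect_equal(unname(d["h"]), 0, tolerance = 1e-14)
  expect_equal(unname(d["n"]), 0, tolerance = 1e-14)
  expect_equal(unname(d["l"]), 0, tolerance = 1e-14)
  expect_equal((s[["ca_tot"]] - s[["ca_i"]]) / p$sigma, 10, tolerance = 1e-12)
})

test_that("a passive membrane relaxes to its leak reversal and stays there", {
  p <- test_params(gNaP = 0, gNa = 0, gK = 0, gCAN = 0, gCa = 0)
  tr <- simulate(p, duration_s = 16, discard_s = 6)
  expect_lt(diff(range(tr$V_mV)), 1e-6)
  expect_equal(tr$V_mV[1], p$VL, tolerance = 1e-4)
})

test_that("with every conductance zero the potential stays at its start", {
  p <- test_params(gNaP = 0, gNa = 0, gK = 0, gL = 0, gCAN = 0, gCa = 0)
  tr <- simulate(p, duration_s = 10, discard_s = 6)
  expect_equal(tr$V_mV, rep(-60, length(tr$V_mV)), tolerance = 1e-6)
})

test_that("simulation is deterministic and drops the requested transient", {
  p <- test_params()
  tr1 <- simulate(p, duration_s = 16, keep_states = FALSE)
  tr2 <- simulate(p, duration_s = 16, keep_states = FALSE)
  expect_identical(tr1$V_mV, tr2$V_mV)
  expect_equal(tr1$t_s[1], 0)
  expect_equal(tr1$t_s[nrow(tr1)], 10, tolerance = 1e-9)
  dt <- diff(tr1$t_s)
  expect_lt(diff(range(dt)), 1e-9)
  expect_true(all(is.finite(tr1$V_mV)))
})

test_that("gate variables remain inside [0, 1] along a bursting trajectory", {
  tr <- simulate(test_params(), duration_s = 26)
  for (g in c("h", "n", "l")) {
    expect_gte(min(tr[[g]]), 0)
    expect_lte(max(tr[[g]]), 1)
  }
  expect_gte(min(tr$ca_i), 0)
  expect_gte(min((tr$ca_tot - tr$ca_i)), 0)
})

test_that("total calcium is conserved over a minute with the membrane closed", {
  p <- test_params()
  p$alpha <- 0
  p$VPMCA <- 0
  tr <- simulate(p, duration_s = 66, discard_s = 0, dt_out_ms = 5)
  expect_lt(diff(range(tr$ca_tot)), 1e-8)
})

test_that("duration must exceed the discarded transient", {
  expect_error(simulate(test_params(), duration_s = 4, discard_s = 6),
               "transient")
  expect_error(simulate(test_params(), duration_s = 10, dt_out_ms = 0),
               "dt_out_ms")
})

test_that("voltage clamp: zero conductances give zero current at any step", {
  p <- test_params(gNaP = 0, gNa = 0, gK = 0, gL = 0, gCAN = 0, gCa = 0)
  for (v in c(-100, -50, 0, 30))
    expect_equal(voltage_clamp_current(p, v), 0, tolerance = 1e-9)
})

test_that("voltage clamp: a pure leak cell reverses at its leak potential", {
  p <- test_params(gNaP = 0, gNa = 0, gK = 0, gCAN = 0, gCa = 0)
  expect_equal(voltage_clamp_current(p, p$VL), 0, tolerance = 1e-9)
  expect_gt(voltage_clamp_current(p, p$VL + 10), 0)
  expect_lt(voltage_clamp_current(p, p$VL - 10), 0)
})

test_that("clamped inactivation relaxes with the predicted time constant", {
  p <- test_params()
  V_hold <- -40
  tau_pred <- gate_time_constant(V_hold, p$tau_h_bar, p$vh, p$sh)
  s0 <- default_initial_state(p)          # h at its V = -60 fixed point
  y0 <- as.numeric(s0)[1:6]
  names(y0) <- c("V", "h", "n", "ca_i", "ca_tot", "l")
  y0["V"] <- V_hold
  times <- seq(0, 2.5 * tau_pred, by = 20)
  out <- prebotsim:::.integrate(y0, times, p, I_app = 0, clamp = TRUE,
                                rtol = 1e-10, atol = 1e-12,
                                engine = "compiled")
  hinf <- gate_steady_state(V_hold, p$vh, p$sh)
  frac <- (out[, "h"] - hinf) / (y0[["h"]] - hinf)
  tau_meas <- stats::approx(frac, times, xout = exp(-1))$y
  expect_lt(abs(tau_meas - tau_pred) / tau_pred, 0.02)
})

test_that("the steady-state I-V relation rises monotonically when depolarized", {
  iv <- iv_curve(test_params())
  dep <- iv$V_mV >= 0
  expect_true(all(diff(iv$I_pA[dep]) > 0))
})

test_that("trace construction enforces uniform finite sampling", {
  expect_error(trace(c(0, 1, 1.5), c(1, 2, 3)), "uniform")
  expect_error(trace(c(0, 1, 0.5), c(1, 2, 3)), "increasing")
  expect_error(trace(c(0, 1, 2), c(1, NA, 3)), "finite")
  tr <- trace(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
  expect_s3_class(tr, "trace")
  expect_equal(trace_dt(tr), 0.1)
})

test_that("trace CSV round trip preserves data and scalar metadata", {
  tr <- simulate(test_params(), duration_s = 7, dt_out_ms = 5)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$V_mV, tr$V_mV, tolerance = 1e-9)
  expect_equal(back$ca_i, tr$ca_i, tolerance = 1e-9)
  meta <- attr(back, "meta")
  expect_equal(meta[["parameters.gNaP"]], 2.5)
  expect_equal(meta[["I_app"]], 0)
  unlink(c(path, paste0(path, ".meta")))
})

test_that("simulations from a perturbed start reach the same regime", {
  p <- test_params()                         # reference plateau configuration
  lab0 <- classify_discharge(simulate(p, keep_states = FALSE))$label
  for (dv in c(-5, 5)) {
    s <- default_initial_state(p)
    s2 <- model_state(V = s[["V"]] + dv, h = s[["h"]], n = s[["n"]],
                      ca_i = s[["ca_i"]], ca_tot = s[["ca_tot"]],
                      l = s[["l"]], sigma = p$sigma)
    expect_identical(
      classify_discharge(simulate(p, init = s2, keep_states = FALSE))$label,
      lab0)
  }
})
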