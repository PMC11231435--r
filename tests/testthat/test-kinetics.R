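test_that("the slow gate is half-activated at V = -50 + delta_x", {
  for (dx in c(-4, -2, 0, 3))
    expect_equal(x_inf(-50 + dx, dx), 0.5)
  expect_equal(x_inf(-60, 0), 1 / (1 + exp(1.5)), tolerance = 1e-12)
  expect_equal(x_inf(-60, 0), 0.182425523806356, tolerance = 1e-10)
  # sigmoid limits and monotonicity
  expect_lt(x_inf(-200, 0), 1e-9)
  expect_gt(x_inf(200, 0), 1 - 1e-9)
  V <- seq(-90, 30, by = 1)
  expect_true(all(diff(x_inf(V, -4)) > 0))
  expect_error(x_inf(NaN), "finite")
})

test_that("gating steady states and time constants are well-behaved", {
  V <- seq(-90, 40, by = 0.5)
  for (f in list(m_inf, h_inf, n_inf, y_inf, sigma_h)) {
    v <- f(V)
    expect_true(all(v >= 0 & v <= 1))
  }
  for (f in list(tau_h, tau_n, tau_y))
    expect_true(all(f(V) > 0))
  # h-current activates as voltage drops below about -50 mV
  expect_gt(sigma_h(-70), 0.7)
  expect_lt(sigma_h(-40), 0.1)
  expect_equal(sigma_h(-63), 0.5)
})

test_that("currents vanish with their driving forces and gates", {
  p <- sin_params()
  s <- sin_state(V = p$EL, Ca = 0.5, params = p)
  expect_equal(unname(currents(s, p)["I_leak"]), 0)
  s2 <- sin_state(V = -40, Ca = 0, params = p)
  expect_equal(unname(currents(s2, p)["I_KCa"]), 0)
  s3 <- sin_state(V = -40, x = 0, Ca = 0.5, params = p)
  expect_equal(unname(currents(s3, p)["I_T"]), 0)
})

test_that("the right-hand side respects its relaxation structure", {
  p <- sin_params(delta_Ca = -30, delta_x = -4)
  s <- sin_state(V = -48, Ca = 0.7, params = p)
  # x at its steady state has zero drift
  expect_equal(unname(sin_rhs(s, p)["x"]), 0)
  # rho scales the calcium equation: rho -> 0 freezes Ca
  p0 <- p; p0$rho <- 0
  expect_equal(unname(sin_rhs(s, p0)["Ca"]), 0)
  # calcium relaxes monotonically toward its influx balance at frozen V, x
  target <- p$Kc * s[["x"]] * (p$ECa - s[["V"]] + p$delta_Ca)
  for (Ca in c(0.1, 0.5 * target, target, 2 * target)) {
    st <- sin_state(V = -48, Ca = Ca, params = p)
    drift <- unname(sin_rhs(st, p)["Ca"])
    expect_equal(sign(drift), sign(target - Ca), tolerance = 1e-12)
  }
  expect_error(sin_rhs(s, p, I_syn_total = NaN), "finite")
})

test_that("full-system equilibria are roots of the vector field", {
  # equilibria located by the dissection module's scalar reduction must be
  # genuine roots of the full right-hand side; cross-check the residual
  # with an independent multidimensional Newton refinement
  for (dca in c(-20, 0, 60)) {
    p <- sin_params(delta_Ca = dca, delta_x = -4)
    eqs <- sinet:::full_equilibria(p, perturbation())
    expect_gt(nrow(eqs), 0)
    for (i in seq_len(nrow(eqs))) {
      st <- sin_state(V = eqs$V[i], x = eqs$x[i], Ca = eqs$Ca[i],
                      params = p)
      expect_lt(max(abs(sin_rhs(st, p))), 1e-8)
      # independent refinement: damped Newton from a perturbed start
      z <- unclass(st) * (1 + 1e-4)
      for (k in 1:40) {
        fz <- sinet:::sin_rhs_raw(
          c(V = z[[1]], h = z[[2]], n = z[[3]], y = z[[4]], x = z[[5]],
            Ca = z[[6]]), p)
        J <- sinet:::numeric_jacobian(function(u)
          sinet:::sin_rhs_raw(c(V = u[[1]], h = u[[2]], n = u[[3]],
                                y = u[[4]], x = u[[5]], Ca = u[[6]]), p),
          z)
        z <- z - 0.8 * solve(J, fz)
      }
      expect_lt(max(abs(z - unclass(st))), 1e-4)
    }
  }
})

test_that("parameter and state validation enforces the model's box", {
  expect_error(sin_params(rho = 0.5), "rho")
  expect_error(sin_params(tau_x = -1), "tau_x")
  expect_error(sin_params(gK = -0.1), "gK")
  expect_error(sin_state(V = -50, h = 1.5), "gating")
  expect_error(sin_state(V = -50, Ca = -1), "Ca")
  expect_error(solver_options(rtol = 0), "tolerances")
})
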