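test_that("the hyperpolarized corner of the slow plane is quiescent", {
  p <- sin_params(delta_x = -4)
  ms <- fast_attractor(Ca = 1.5, x = 0.05, params = p)
  expect_true(any(ms$equilibria$stable))
  expect_null(ms$orbit)
  # equilibria re-checked against the full right-hand side with the slow
  # derivatives ignored
  for (i in seq_len(nrow(ms$equilibria))) {
    V <- ms$equilibria$V[i]
    st <- sin_state(V = V, x = 0.05, Ca = 1.5, params = p)
    r <- sin_rhs(st, p, freeze_slow = TRUE)
    expect_lt(max(abs(r[c("V", "h", "n", "y")])), 1e-8)
  }
})

test_that("orbit averages agree with brute-force time averages", {
  p <- sin_params(delta_x = -4)
  orb <- sinet:::fast_orbit(Ca = 0.4, x = 0.8, params = p,
                            pert = perturbation())
  expect_false(is.null(orb))
  # independent long-run time average from a fresh simulation
  opts <- solver_options(duration = 60e3, dt_out = 0.5, rtol = 1e-8,
                         atol = 1e-10)
  tr <- simulate_cell(p, init = sin_state(V = -45, x = 0.8, Ca = 0.4,
                                          params = p),
                      opts = opts, freeze_slow = TRUE)
  keep <- tr[, "time"] >= 30e3
  expect_equal(orb$V_mean, mean(tr[keep, "V"]), tolerance = 0.1)
})

test_that("the SNIC boundary separates spiking from quiescence", {
  p <- sin_params(delta_x = -4)
  sn <- snic_curve(p, Ca_grid = c(0.5, 0.9))
  expect_true(all(is.finite(sn$x)))
  for (i in 1:2) {
    above <- sinet:::fast_orbit(sn$Ca[i], sn$x[i] + 0.01, p,
                                perturbation())
    below <- sinet:::fast_orbit(sn$Ca[i], sn$x[i] - 0.01, p,
                                perturbation())
    expect_false(is.null(above))
    expect_true(is.null(below))
  }
  # orbit period grows monotonically approaching the boundary from above
  Ts <- vapply(c(0.2, 0.1, 0.05, 0.02), function(dx)
    sinet:::fast_orbit(sn$Ca[1], sn$x[1] + dx, p, perturbation())$T,
    numeric(1))
  expect_true(all(diff(Ts) > 0))
})

test_that("applied current deforms the slow-plane geometry as expected", {
  p <- sin_params(delta_x = -4)
  lower_knee <- function(pert) {
    xn <- sinet:::x_nullcline(p, pert, seq(-85, -25, by = 0.25))
    tp <- which(diff(sign(diff(xn$Ca))) != 0) + 1L
    xn$Ca[tp[1]]
  }
  k0 <- lower_knee(perturbation())
  expect_gt(lower_knee(perturbation(Iapp = 0.05)), k0)   # rightward
  expect_lt(lower_knee(perturbation(Iapp = -0.05)), k0)  # leftward
  # positive applied current expands the spiking side of the SNIC curve
  sn0 <- snic_curve(p, Ca_grid = c(0.5, 0.9))
  snp <- snic_curve(p, Ca_grid = c(0.5, 0.9),
                    pert = perturbation(Iapp = 0.1))
  expect_true(all(snp$x < sn0$x))
})

test_that("hysteresis overlap of the averaged and equilibrium branches
           appears at delta_x = 0 and is absent at delta_x = -4", {
  overlap <- function(dx) {
    p <- sin_params(delta_x = dx)
    nc <- slow_nullclines(p, Ca_grid = seq(0.2, 1.0, by = 0.1))
    up <- nc$x_null[nc$x_null$stable & nc$x_null$x > 0.4, ]
    if (!nrow(up) || !nrow(nc$x_avg)) return(0)
    lo <- max(min(up$Ca), min(nc$x_avg$Ca))
    hi <- min(max(up$Ca), max(nc$x_avg$Ca))
    max(hi - lo, 0)
  }
  expect_gt(overlap(0), 0.005)
  expect_equal(overlap(-4), 0)
})
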