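test_that("the release sigmoid is centred on the synaptic threshold", {
  expect_equal(f_inf(20, k = 1, theta_syn = 20), 0.5)
  expect_equal(f_inf(0, k = 0.5, theta_syn = 0), 0.5)
  expect_gt(f_inf(21, k = 50, theta_syn = 20), 0.999999)
  expect_lt(f_inf(-200, k = 1, theta_syn = 20), 1e-20)
  expect_error(f_inf(Inf), "finite")
})

test_that("gate kinetics reach their closed-form steady states", {
  # alpha kinetics under constant full drive approach alpha/(alpha+beta)
  sp <- synapse_spec("alpha", alpha = 0.01, beta = 0.001, k = 50)
  w <- pulse_fixture(100, widths = 20000, gaps = 10)
  run <- simulate_gate(sp, w, duration = 20000)
  expect_equal(unname(run[nrow(run), "S"]), 0.01 / 0.011, tolerance = 1e-3)
  # logistic: S = 0 is invariant at zero floor; the nonzero steady state
  # under full drive is 1 - beta/alpha
  spl <- synapse_spec("logistic", alpha = 0.05, beta = 0.005, S0 = 0,
                      k = 50)
  expect_equal(gate_rhs(spl, 0, V_pre = 40), 0)
  run2 <- simulate_gate(spl, w, duration = 20000, init = 0.01)
  expect_equal(unname(run2[nrow(run2), "S"]), 0.9, tolerance = 1e-3)
})

test_that("synaptic and gap currents follow their algebraic forms", {
  sp <- synapse_spec("alpha", g_syn = 0.5, E_rev = -80)
  expect_equal(syn_current(sp, 0.3, V_post = -80), 0)
  expect_equal(syn_current(sp, 0, V_post = 0), 0)
  sp2 <- synapse_spec("alpha", g_syn = 0.5, E_rev = -80, power = 2)
  expect_equal(syn_current(sp2, 0.5, V_post = 0),
               0.5 * syn_current(sp, 0.5, V_post = 0))
  expect_equal(gap_current(0.1, -50, -50), 0)
  expect_equal(gap_current(0.1, -40, -60), -gap_current(0.1, -60, -40))
  expect_equal(gap_current(0, -40, -60), 0)
})

test_that("gate trajectories match piecewise-analytic oracles to 1e-6", {
  w <- pulse_fixture(c(100, 100), widths = 800, gaps = 1200, V_base = -60)
  # segment ends: 1200 (gap), 2000 (pulse), 3200 (gap), 4000 (pulse)
  probe_t <- c(1200, 2000, 3200, 4000)
  k <- 50; th <- 20                       # near-Heaviside drive
  # alpha kinetics: exponential segments
  sp <- synapse_spec("alpha", alpha = 0.02, beta = 0.002, k = k,
                     theta_syn = th)
  run <- simulate_gate(sp, w, duration = 4200, dt_out = 1)
  S <- 0; t0 <- 0
  segs <- list(c(0, 1200, 0), c(1200, 2000, 1), c(2000, 3200, 0),
               c(3200, 4000, 1))
  for (seg in segs) {
    S <- oracle_alpha(S, seg[3], 0.02, 0.002, seg[2] - seg[1])
    got <- run[run[, "time"] == seg[2], "S"]
    expect_equal(unname(got), S, tolerance = 1e-6)
  }
  # logistic: Riccati/exponential segments (zero spontaneous floor)
  spl <- synapse_spec("logistic", alpha = 0.05, beta = 0.004, S0 = 0,
                      k = k, theta_syn = th)
  runl <- simulate_gate(spl, w, duration = 4200, dt_out = 1, init = 0.05)
  S <- 0.05
  for (seg in segs) {
    S <- oracle_logistic(S, seg[3], 0.05, 0.004, seg[2] - seg[1])
    got <- runl[runl[, "time"] == seg[2], "g1"]
    expect_equal(unname(got), S, tolerance = 1e-6)
  }
  # dynamic: alpha-form gate times slow first-order modulation
  spd <- synapse_spec("dynamic", alpha = 0.02, beta = 0.002,
                      tau_M = 1500, k = k, theta_syn = th)
  rund <- simulate_gate(spd, w, duration = 4200, dt_out = 1)
  S <- 0; M <- 0
  for (seg in segs) {
    S <- oracle_alpha(S, seg[3], 0.02, 0.002, seg[2] - seg[1])
    M <- oracle_modulation(M, seg[3], 1500, seg[2] - seg[1])
    got <- rund[rund[, "time"] == seg[2], c("g1", "g2")]
    expect_equal(unname(got[[1]]), S, tolerance = 1e-6)
    expect_equal(unname(got[[2]]), M, tolerance = 1e-6)
  }
  # cascade: brute-force fixed-step integration as the oracle
  spc <- synapse_spec("cascade", alpha = 0.02, beta = 0.002, n_stages = 2,
                      k = k, theta_syn = th)
  runc <- simulate_gate(spc, w, duration = 4000, dt_out = 1)
  orc <- rk4_gate(spc, w, 4000, c(0, 0), dt = 0.05)
  for (tt in probe_t) {
    got <- runc[runc[, "time"] == tt, "g2"]
    want <- orc$S[orc$time == tt, 2]
    expect_equal(unname(got), want, tolerance = 1e-5)
  }
})

test_that("fast alpha kinetics approach the threshold-modulation limit", {
  w <- pulse_fixture(c(100, 100, 100), widths = 400, gaps = 600)
  sp <- synapse_spec("alpha", alpha = 2, beta = 0.4, k = 50)
  run <- simulate_gate(sp, w, dt_out = 1)
  ftm <- f_inf(run[, "V_pre"], 50, 20) * 2 / 2.4  # saturates at a/(a+b)
  # away from switching transients the fast gate tracks the scaled step
  mid <- run[, "time"] %in% c(500, 850, 1500, 1850, 2500, 2850)
  expect_lt(max(abs(run[mid, "S"] - ftm[mid])), 0.01)
})

test_that("higher-order kinetics smooth within-burst ripple", {
  # a bursty train: five short pulses in quick succession
  w <- pulse_fixture(rep(100, 5), widths = 60, gaps = 140)
  ripple <- vapply(1:3, function(ns) {
    sp <- synapse_spec("cascade", alpha = 0.05, beta = 0.005,
                       n_stages = ns, k = 50)
    run <- simulate_gate(sp, w, duration = 1200, dt_out = 1)
    burst <- run[run[, "time"] >= 200 & run[, "time"] <= 1100, "S"]
    d <- diff(burst)
    sum(abs(d)) - abs(sum(d))      # ripple beyond the net drift
  }, numeric(1))
  expect_true(all(diff(ripple) < 0))
})

test_that("closely spaced pulses summate", {
  sp <- synapse_spec("alpha", alpha = 0.01, beta = 0.001, k = 50)
  w <- pulse_fixture(c(100, 100), widths = 300, gaps = 500)  # gap < 1/beta
  run <- simulate_gate(sp, w, duration = 2000, dt_out = 1)
  onset1 <- run[run[, "time"] == 500, "S"]
  onset2 <- run[run[, "time"] == 1300, "S"]
  expect_gt(onset2, onset1)
  # an empty pulse list leaves the gate at rest
  w0 <- pulse_fixture()
  run0 <- simulate_gate(sp, w0)
  expect_true(all(run0[, "S"] < 1e-9))
})

test_that("synapse specifications are validated", {
  expect_error(synapse_spec("alpha", beta = 0), "rate")
  expect_error(synapse_spec("logistic", S0 = 0.1), "S0")
  expect_error(synapse_spec("ftm", k = 100), "k")
  expect_error(synapse_spec("cascade", n_stages = 5), "n_stages")
  expect_error(gate_rhs(synapse_spec("alpha"), c(0.1, 0.2), V_pre = 0),
               "wrong length")
})
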