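test_that("simulation is deterministic and respects the trivial limits", {
  p <- sin_params(delta_Ca = -30, delta_x = -4)
  tr0 <- simulate_cell(p, opts = solver_options(duration = 0))
  expect_equal(nrow(tr0), 1L)
  expect_equal(unname(tr0[1, "V"]), -55)
  o <- solver_options(duration = 20e3)
  tr1 <- simulate_cell(p, opts = o)
  tr2 <- simulate_cell(p, opts = o)
  expect_identical(unclass(tr1)[, ], unclass(tr2)[, ])
})

test_that("gating variables stay inside the unit box along trajectories", {
  cases <- list(sin_params(),                       # endogenous burster
                sin_params(delta_Ca = -60),         # tonic spiker
                sin_params(delta_Ca = -20, delta_x = -4),
                sin_params(delta_Ca = 105, delta_x = -4))
  for (p in cases) {
    tr <- simulate_cell(p, opts = solver_options(duration = 60e3))
    g <- tr[, c("h", "n", "y", "x")]
    expect_gt(min(g), -1e-6)
    expect_lt(max(g), 1 + 1e-6)
    expect_gt(min(tr[, "Ca"]), -1e-9)
  }
})

test_that("spike detection finds interpolated threshold crossings", {
  t <- seq(0, 5000, by = 1)
  V <- ifelse(t %% 500 < 25, 20, -55)
  st <- spike_times(t, V)
  expect_equal(length(st), 10L)
  expect_true(all(diff(st) > 400))
  expect_length(spike_times(t, rep(-60, length(t))), 0L)
  # refractory lockout suppresses double counting on noisy crossings
  V2 <- -55 + 50 * (t %% 500 < 25) - 3 * (t %% 2 == 0)
  expect_equal(length(spike_times(t, V2)), 10L)
})

test_that("the pulse-release protocol reduces to a free run at zero drive", {
  p <- sin_params(delta_Ca = -20, delta_x = -4)
  opts <- solver_options(duration = 10e3)
  r <- inhibitory_pulse_protocol(p, g_syn = 0, pulse_duration = 5000,
                                 settle = 10e3, post = 20e3, opts = opts)
  free <- simulate_cell(p, opts = solver_options(duration = 35e3))
  idx <- seq_len(nrow(r$trace))
  expect_equal(r$trace[idx, "V"], free[idx, "V"], tolerance = 1e-5)
  expect_error(inhibitory_pulse_protocol(p, pulse_duration = 0),
               "pulse_duration")
})
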