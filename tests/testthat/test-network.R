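test_that("network simulation is deterministic", {
  cfg <- hco_config(g_syn = 0.047)
  cfg$opts <- solver_options(duration = 30e3, dt_out = 2, rtol = 1e-7,
                             atol = 1e-9)
  tr1 <- simulate_network(cfg)
  tr2 <- simulate_network(cfg)
  expect_identical(unclass(tr1)[, ], unclass(tr2)[, ])
})

test_that("the decoupled network reproduces isolated-cell dynamics", {
  cell <- sin_params(delta_Ca = -20, delta_x = -4)   # settles to rest
  syn0 <- synapse_spec("logistic", g_syn = 0, S0 = 1e-3)
  cfg <- suppressWarnings(network_config(cell, cell, syn0, syn0))
  cfg$opts <- solver_options(duration = 50e3, dt_out = 1, rtol = 1e-8,
                             atol = 1e-10)
  net <- simulate_network(cfg)
  iso <- simulate_cell(cell, opts = cfg$opts)
  # transient spikes amplify adaptive-step differences between the 20- and
  # 6-dimensional integrations; agreement is at the solver-accuracy scale
  expect_lt(max(abs(net[, "V1"] - iso[, "V"])), 0.05)
  expect_lt(max(abs(net[, "V2"] - iso[, "V"])), 0.05)
  # a spiking cell: compare the emitted spike trains
  cellt <- sin_params(delta_Ca = -60, delta_x = -4)
  cfg2 <- suppressWarnings(network_config(cellt, cellt, syn0, syn0))
  cfg2$opts <- cfg$opts
  net2 <- simulate_network(cfg2)
  iso2 <- simulate_cell(cellt, opts = cfg$opts)
  st_net <- spike_times(net2[, "time"], net2[, "V1"])
  st_iso <- spike_times(iso2[, "time"], iso2[, "V"])
  expect_equal(length(st_net), length(st_iso))
  expect_lt(max(abs(st_net - st_iso)), 5)
})

test_that("a symmetric half-center oscillator has exchange symmetry", {
  cfg <- preset("hco_quiescent", ignite = FALSE)
  cfg$opts <- solver_options(duration = 60e3, dt_out = 2, rtol = 1e-7,
                             atol = 1e-9)
  ini <- antiphase_init(cfg)
  cfg$init <- ini
  trA <- simulate_network(cfg)
  cfg$init <- list(cell1 = ini$cell2, cell2 = ini$cell1,
                   S12 = ini$S21, S21 = ini$S12)
  trB <- simulate_network(cfg)
  expect_lt(max(abs(trA[, "V1"] - trB[, "V2"])), 1e-3)
  expect_lt(max(abs(trA[, "V2"] - trB[, "V1"])), 1e-3)
})

test_that("burst metrics recover constructed periods and phase lags", {
  t <- 0:200000
  spikes <- function(offset)
    ifelse((t - offset) %% 20000 >= 0 & (t - offset) %% 20000 < 3000 &
             t %% 300 < 20, 30, -55)
  trace <- cbind(time = t, V1 = spikes(0), V2 = spikes(0))
  m0 <- burst_metrics(trace, window = 180000)
  expect_equal(m0$phase_lag, 0, tolerance = 0.01)
  expect_equal(m0$period, 20000, tolerance = 0.01)
  trace2 <- cbind(time = t, V1 = spikes(0), V2 = spikes(10000))
  m5 <- burst_metrics(trace2, window = 180000)
  expect_equal(m5$phase_lag, 0.5, tolerance = 0.01)
  expect_gt(m5$cell1[["duty"]], 0)
  expect_lt(m5$cell1[["duty"]], 1)
  # too few bursts is an explicit error, not a guess
  short <- cbind(time = 0:30000, V1 = spikes(0)[1:30001],
                 V2 = spikes(0)[1:30001])
  expect_error(burst_metrics(short, window = 30000), "insufficient")
})

test_that("the preset registry carries the published parameter sets", {
  expect_equal(preset("hco_quiescent", ignite = FALSE)$syn12$g_syn, 0.047)
  expect_equal(preset("hco_quiescent_weak", ignite = FALSE)$syn12$g_syn,
               0.027)
  expect_equal(preset("hco_tonic", ignite = FALSE)$syn21$alpha, 0.03)
  expect_equal(preset("winner_strong", ignite = FALSE)$syn21$g_syn, 0.8)
  expect_equal(preset("ei_tonic_pair", ignite = FALSE)$gap$g_elec, 4e-3)
  expect_equal(preset("ei_diverse", ignite = FALSE)$cell2$delta_Ca, 60)
  expect_equal(preset("ei_quiescent_pair", ignite = FALSE)$syn12$g_syn,
               0.045)
  expect_error(preset("no_such_preset"), "valid names")
  expect_setequal(preset_names(),
                  c("hco_quiescent_weak", "hco_quiescent",
                    "hco_tonic_weak", "hco_tonic", "winner_strong",
                    "winner_weak", "ei_uncoupled", "ei_exc_only",
                    "ei_weak", "ei_balanced", "ei_diverse",
                    "ei_quiescent_pair_weak", "ei_quiescent_pair",
                    "ei_tonic_pair"))
})

test_that("synapse gate states remain in the unit box during network runs", {
  cfg <- preset("hco_quiescent", ignite = FALSE)
  cfg$init <- list(S12 = 0.5, S21 = 0.5)
  cfg$opts <- solver_options(duration = 60e3, dt_out = 2, rtol = 1e-7,
                             atol = 1e-9)
  tr <- simulate_network(cfg)
  g <- tr[, c("s12_1", "s21_1")]
  expect_gt(min(g), -1e-6)
  expect_lt(max(g), 1 + 1e-6)
})
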