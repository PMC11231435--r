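test_that("synthetic traces with known regimes are labelled correctly", {
  expect_equal(classify_trace(synthetic_trace("quiescent"))$label,
               "quiescent")
  expect_equal(classify_trace(synthetic_trace("tonic"))$label, "tonic")
  expect_equal(classify_trace(synthetic_trace("bursting"))$label,
               "bursting")
  expect_equal(classify_trace(synthetic_trace("subthreshold"))$label,
               "subthreshold")
})

test_that("classification refuses windows that are too short", {
  short <- cbind(time = 0:50000, V = rep(-60, 50001))
  expect_error(classify_trace(short), "too short")
})

test_that("every finite trace maps to exactly one label", {
  set.seed(42)
  labels <- c("tonic", "bursting", "quiescent", "subthreshold")
  for (i in 1:12) {
    t <- 0:110000
    kind <- sample(labels, 1)
    V <- synthetic_trace(kind)[, "V"] + stats::rnorm(length(t), 0, 0.05)
    lab <- classify_trace(cbind(time = t, V = V))$label
    expect_true(lab %in% labels)
  }
})

test_that("run-length encoding compresses sweep label sequences", {
  # degenerate constant-label sweep reduces to a single run
  p <- sin_params(delta_Ca = -60, delta_x = -4)
  r <- transition_routes(p, delta_x_levels = -4,
                         delta_Ca = c(-70, -60, -50),
                         opts = scan_opts, copts = scan_copts)
  expect_equal(r[["dx=-4"]], "tonic")
})

test_that("scans cache per-node labels and resume from the cache", {
  cache <- tempfile("scan-cache")
  p <- sin_params()
  d1 <- scan_diagram(p, delta_Ca = c(-60, 0), delta_x = 0,
                     opts = scan_opts, copts = scan_copts, cache = cache)
  expect_equal(as.vector(d1$labels), c("tonic", "bursting"))
  # poison the true computation: cached labels must be used verbatim
  d2 <- scan_diagram(p, delta_Ca = c(-60, 0), delta_x = 0,
                     opts = solver_options(duration = 1), cache = cache)
  expect_equal(as.vector(d2$labels), c("tonic", "bursting"))
})
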