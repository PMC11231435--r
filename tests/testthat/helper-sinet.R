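# shared fixtures and oracles for the test suite

# study conditions used by the regime scans: long runs so slow transients
# near regime boundaries settle before classification
scan_opts <- solver_options(duration = 400e3, rtol = 1e-7, atol = 1e-9)
scan_copts <- classifier_options(transient = 250e3, window = 140e3)

label_at <- function(delta_Ca, delta_x, params = sin_params(),
                     opts = scan_opts, copts = scan_copts) {
  params$delta_Ca <- delta_Ca
  params$delta_x <- delta_x
  classify_trace(simulate_cell(params, opts = opts), copts)$label
}

# synthetic voltage traces with known regime labels
synthetic_trace <- function(kind, t_end = 110e3) {
  t <- 0:t_end
  V <- switch(kind,
    quiescent = rep(-60, length(t)),
    tonic = ifelse(t %% 400 < 20, 30, -50),
    bursting = ifelse(t %% 10000 < 2000 & t %% 200 < 20, 30, -55),
    subthreshold = -55 + 3 * sin(2 * pi * t / 5000))
  cbind(time = t, V = V)
}

# closed-form gate trajectories under piecewise-constant drive f
# (exponential segments for first-order kinetics, a logistic/Riccati
# segment for the logistic synapse with zero floor)
oracle_alpha <- function(S0, f, alpha, beta, t) {
  rate <- alpha * f + beta
  Sinf <- alpha * f / rate
  Sinf + (S0 - Sinf) * exp(-rate * t)
}

oracle_logistic <- function(S0, f, alpha, beta, t) {
  a <- alpha * f
  r <- a - beta
  if (f == 0) return(S0 * exp(-beta * t))
  if (abs(r) < 1e-14) return(S0 / (1 + a * S0 * t))
  K <- r / a
  K / (1 + ((K - S0) / S0) * exp(-r * t))
}

oracle_modulation <- function(M0, f, tau_M, t) {
  f + (M0 - f) * exp(-t / tau_M)
}

# brute-force fixed-step RK4 for gate kinetics (used where no closed form
# is convenient, e.g. the cascade)
rk4_gate <- function(spec, waveform, t_end, init, dt = 0.02) {
  n <- ceiling(t_end / dt)
  S <- init
  out_t <- seq(0, n) * dt
  out <- matrix(NA_real_, n + 1L, length(init))
  out[1L, ] <- S
  for (i in seq_len(n)) {
    t0 <- (i - 1L) * dt
    f <- function(tt, s) gate_rhs(spec, s, waveform_at(waveform, tt))
    k1 <- f(t0, S)
    k2 <- f(t0 + dt / 2, S + dt / 2 * k1)
    k3 <- f(t0 + dt / 2, S + dt / 2 * k2)
    k4 <- f(t0 + dt, S + dt * k3)
    S <- S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- S
  }
  list(time = out_t, S = out)
}
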