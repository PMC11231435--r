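#' Frequency response of a synapse driven by a live presynaptic cell
#'
#' Implements the ramped-frequency protocol: a presynaptic swim interneuron
#' is driven from quiescence into progressively faster tonic spiking by
#' slowly ramping its \code{delta_Ca} downward; per presynaptic spike the
#' instantaneous frequency (1000/ISI, in Hz) and the time-average of the
#' synaptic gate over that interspike interval are recorded. The resulting
#' curve characterizes the synapse as a frequency filter; the logistic kind
#' acts as a high-pass with an interior inflection, while the dynamic kind
#' is close to linear.
#'
#' The ramp must be slow relative to the interspike intervals: a rate guard
#' rejects ramps steeper than 0.001 mV of delta_Ca per model unit.
#'
#' @param spec a \code{\link{synapse_spec}}.
#' @param presyn_params presynaptic cell parameters; the default
#'   (\code{delta_x = -4}) cell is quiescent at the ramp start and spikes
#'   tonically beyond about 0.5 Hz once \code{delta_Ca} passes its spiking
#'   threshold.
#' @param dca_start,dca_end ramp endpoints for \code{delta_Ca} (mV).
#' @param ramp_duration ramp length (model units).
#' @param settle pre-ramp settling time at \code{dca_start}.
#' @param opts solver options (duration derived from the protocol).
#' @return An object of class \code{frequency_response}: data frame with
#'   per-spike \code{frequency} (Hz) and \code{S_mean}, plus attributes
#'   \code{half_activation} (lowest frequency at which \code{S_mean} first
#'   reaches half its curve maximum, linearly interpolated) and
#'   \code{inflection} (frequency of the sign change of the smoothed second
#'   difference).
#' @examples
#' \donttest{
#' sp <- synapse_spec("logistic", alpha = 0.05, beta = 0.0051)
#' fr <- frequency_response(sp, ramp_duration = 2e5)
#' attr(fr, "half_activation")
#' }
#' @export
frequency_response <- function(spec,
                               presyn_params = sin_params(delta_x = -4,
                                                          delta_Ca = -20),
                               dca_start = presyn_params$delta_Ca,
                               dca_end = -160, ramp_duration = 1e6,
                               settle = 2e4,
                               opts = solver_options(dt_out = 2,
                                                     rtol = 1e-7,
                                                     atol = 1e-9)) {
  rate <- abs(dca_end - dca_start) / ramp_duration
  if (rate > 1e-3)
    stop("ramp too fast (", signif(rate, 3),
         " mV per model unit): must not exceed 1e-3", call. = FALSE)
  run <- run_cellgate(spec, presyn_params, dca_start, dca_end,
                      settle, settle + ramp_duration, opts)
  st <- spike_times(run$time, run$V)
  if (length(st) < 3L)
    stop("presynaptic cell produced fewer than 3 spikes; no curve",
         call. = FALSE)
  S <- run$S
  freq <- 1000 / diff(st)
  cs <- c(0, cumsum(S))
  j <- findInterval(st, run$time)         # sample index at each spike
  j0 <- j[-length(j)]; j1 <- j[-1]
  Smean <- (cs[j1 + 1L] - cs[j0 + 1L]) / pmax(j1 - j0, 1L)
  ord <- order(freq)
  out <- data.frame(frequency = freq[ord], S_mean = Smean[ord])
  out <- out[is.finite(out$frequency) & is.finite(out$S_mean), ]
  structure(out, class = c("frequency_response", "data.frame"),
            half_activation = half_activation_freq(out),
            inflection = inflection_freq(out), kind = spec$kind)
}

# joint integration of the presynaptic cell and the full gate bank via the
# compiled cell+gates model; returns time, V and the requested kind's S
run_cellgate <- function(spec, p, dca0, dca1, t0r, t1r, opts) {
  duration <- t1r + 0.2 * (t1r - t0r)   # hold the final level briefly
  cp <- cell_parms_vec(p)
  cp[17] <- dca0                        # ramp starts from dca_start
  parms <- c(cp,
             0, -80, 0, 1, dca1, t0r, t1r,
             spec$k, spec$theta_syn,
             if (spec$kind == "alpha") c(spec$alpha[1], spec$beta[1])
             else c(0.01, 0.001),
             if (spec$kind == "cascade") c(spec$alpha[1], spec$beta[1])
             else c(0.01, 0.001),
             if (spec$kind == "cascade") spec$n_stages else 2,
             if (spec$kind == "dynamic") c(spec$alpha[1], spec$beta[1])
             else c(0.01, 0.001),
             spec$tau_M,
             if (spec$kind == "logistic") c(spec$alpha[1], spec$beta[1],
                                            spec$S0)
             else c(0.05, 0.0051, 1e-3))
  init <- sin_state(params = p)
  s0l <- max(parms[length(parms)], 1e-4)
  y0 <- c(unclass(init), Sa = 0, Sc1 = 0, Sc2 = 0, Sc3 = 0, Sd = 0,
          Md = 0, Sl = s0l)
  times <- seq(0, duration, by = opts$dt_out)
  out <- deSolve::ode(y = y0, times = times, func = "sinet_dcellgate",
                      parms = parms, dllname = "sinet",
                      initfunc = "sinet_initcellgate",
                      method = opts$method, rtol = opts$rtol,
                      atol = opts$atol, maxsteps = opts$maxsteps)
  check_solver(out, times)
  V <- out[, 2]
  S <- switch(spec$kind,
              ftm = f_inf(V, spec$k, spec$theta_syn),
              alpha = out[, 8],
              cascade = out[, 8 + spec$n_stages],
              dynamic = out[, 12] * out[, 13],
              logistic = out[, 14])
  list(time = out[, 1], V = V, S = S)
}

# lowest frequency at which S_mean first reaches half its maximum,
# linearly interpolated between neighbouring spikes
half_activation_freq <- function(curve) {
  if (!nrow(curve)) return(NA_real_)
  sm <- smooth_curve(curve)
  target <- max(sm$S) / 2
  above <- which(sm$S >= target)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(sm$f[1])
  f0 <- sm$f[i - 1L]; f1 <- sm$f[i]
  s0 <- sm$S[i - 1L]; s1 <- sm$S[i]
  f0 + (target - s0) / (s1 - s0) * (f1 - f0)
}

# inflection = steepest point of the binned curve (the concavity flip of a
# sigmoidal characteristic coincides with its maximal slope)
inflection_freq <- function(curve) {
  sm <- smooth_curve(curve, nbins = 15)
  if (length(sm$f) < 4L) return(NA_real_)
  slope <- diff(sm$S) / diff(sm$f)
  i <- which.max(slope)
  (sm$f[i] + sm$f[i + 1L]) / 2
}

# bin the per-spike cloud onto a regular frequency grid
smooth_curve <- function(curve, nbins = 40) {
  rng <- range(curve$frequency)
  if (diff(rng) <= 0) return(list(f = rng[1], S = mean(curve$S_mean)))
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- cut(curve$frequency, br, include.lowest = TRUE)
  f <- tapply(curve$frequency, bin, mean)
  S <- tapply(curve$S_mean, bin, mean)
  ok <- !is.na(f)
  list(f = as.numeric(f[ok]), S = as.numeric(S[ok]))
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("frequency response (%s synapse): %d spikes, %.2f-%.2f Hz\n",
              attr(x, "kind"), nrow(x), min(x$frequency),
              max(x$frequency)))
  cat(sprintf("  half-activation %.2f Hz, inflection %.2f Hz\n",
              attr(x, "half_activation"), attr(x, "inflection")))
  invisible(x)
}

#' @export
plot.frequency_response <- function(x, ...) {
  graphics::plot(x$frequency, x$S_mean, pch = 16, cex = 0.4,
                 xlab = "presynaptic spike frequency (Hz)",
                 ylab = expression(group("<", S, ">")), ...)
  graphics::abline(v = attr(x, "half_activation"), lty = 2)
  invisible(x)
}
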