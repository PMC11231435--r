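#' Simulate an isolated swim interneuron
#'
#' Integrates the 6-dimensional SiN model with the stiff adaptive solver
#' (deSolve lsoda, compiled right-hand side) and returns the trajectory on a
#' regular output grid.
#'
#' @param params a \code{\link{sin_params}} object.
#' @param init a \code{\link{sin_state}}; default is the standard initial
#'   condition (V = -55 mV, gates at steady state, Ca = 0.8).
#' @param opts a \code{\link{solver_options}} object.
#' @param g_pulse,E_pulse optional constant-conductance synaptic perturbation
#'   \code{g_pulse * (V - E_pulse)} applied for the whole run (used
#'   internally by the pulse protocol and the dissection module).
#' @param freeze_slow integrate the fast subsystem only (x, Ca frozen at
#'   their initial values).
#' @return A \code{sin_trace}: numeric matrix with columns
#'   \code{time, V, h, n, y, x, Ca} and attributes recording parameters and
#'   solver settings.
#' @examples
#' tr <- simulate_cell(sin_params(delta_Ca = -60), opts = solver_options(5000))
#' range(tr[, "V"])
#' @export
simulate_cell <- function(params, init = NULL, opts = solver_options(),
                          g_pulse = 0, E_pulse = -80, freeze_slow = FALSE) {
  validate_sin_params(params)
  if (is.null(init)) init <- sin_state(params = params)
  validate_sin_state(unclass(init))
  if (opts$duration == 0) {
    out <- matrix(c(0, unclass(init)), nrow = 1,
                  dimnames = list(NULL, c("time", names(init))))
    return(new_trace(out, params, opts))
  }
  times <- seq(0, opts$duration, by = opts$dt_out)
  parms <- c(cell_parms_vec(params), g_pulse, E_pulse,
             as.numeric(freeze_slow), 0, 0, 0, 0)
  out <- deSolve::ode(y = unclass(init), times = times,
                      func = "sinet_dcell", parms = parms,
                      dllname = "sinet", initfunc = "sinet_initcell",
                      method = opts$method, rtol = opts$rtol,
                      atol = opts$atol, maxsteps = opts$maxsteps)
  check_solver(out, times)
  colnames(out) <- c("time", "V", "h", "n", "y", "x", "Ca")
  new_trace(unclass(out), params, opts)
}

check_solver <- function(out, times) {
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop("solver failed; last valid time = ",
         max(out[stats::complete.cases(out), 1]), call. = FALSE)
  invisible(out)
}

new_trace <- function(m, params, opts, extra = list()) {
  attr(m, "params") <- params
  attr(m, "solver") <- opts
  for (nm in names(extra)) attr(m, nm) <- extra[[nm]]
  class(m) <- c("sin_trace", class(m))
  m
}

#' @export
print.sin_trace <- function(x, ...) {
  cat(sprintf("SiN trace: %d samples over %g model units, %d variables\n",
              nrow(x), x[nrow(x), "time"] - x[1, "time"], ncol(x) - 1L))
  vc <- grep("^V", colnames(x), value = TRUE)
  for (v in vc)
    cat(sprintf("  %s range: [%.2f, %.2f] mV\n", v, min(x[, v]), max(x[, v])))
  invisible(x)
}

#' @export
plot.sin_trace <- function(x, vars = "V", ...) {
  vars <- intersect(vars, colnames(x))
  opar <- graphics::par(mfrow = c(length(vars), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(opar))
  for (v in vars)
    graphics::plot(x[, "time"] / 1000, x[, v], type = "l",
                   xlab = "time (s)", ylab = v, ...)
  invisible(x)
}

#' Final state of a trace
#'
#' Extracts the last sample of a trace as a state vector (clamping gate
#' round-off into [0, 1]), convenient for restarting simulations.
#'
#' @param trace a \code{sin_trace}.
#' @param cell for network traces, which cell's state to extract.
#' @return A \code{sin_state}.
#' @export
final_state <- function(trace, cell = 1) {
  nm <- c("V", "h", "n", "y", "x", "Ca")
  cols <- if (all(nm %in% colnames(trace))) nm else paste0(nm, cell)
  s <- trace[nrow(trace), cols]
  names(s) <- nm
  s[2:5] <- pmin(pmax(s[2:5], 0), 1)
  s["Ca"] <- max(s[["Ca"]], 0)
  structure(s, class = "sin_state")
}

#' Post-inhibitory rebound (pulse-release) protocol
#'
#' Hyperpolarizes the cell with a constant-conductance inhibitory synaptic
#' current \code{g_syn * (V + 80)} for a fixed window (long enough for the
#' cell to settle on the forced steady state), releases it, and measures the
#' rebound spike train: its peak instantaneous frequency and the duration of
#' the slow spike-frequency adaptation back to the cell's natural attractor.
#'
#' @param params a \code{\link{sin_params}} object.
#' @param g_syn pulse conductance (>= 0).
#' @param pulse_duration pulse length in model units (default 5000, i.e. the
#'   5-s pulse of the source protocol).
#' @param E_rev pulse reversal potential (mV).
#' @param settle pre-pulse settling time so the cell starts from its natural
#'   attractor.
#' @param post observation window after release.
#' @param opts solver options (duration is derived from the protocol).
#' @return List with the full \code{trace}, the release time \code{t_release},
#'   rebound \code{spike_times}, \code{peak_frequency} (Hz, from the minimal
#'   post-release interspike interval), and \code{adaptation_duration}
#'   (model units until the instantaneous rate first falls within 10% of its
#'   final value; NA with fewer than 3 rebound spikes).
#' @export
inhibitory_pulse_protocol <- function(params, g_syn = 1,
                                      pulse_duration = 5000, E_rev = -80,
                                      settle = 40e3, post = 60e3,
                                      opts = solver_options()) {
  if (pulse_duration <= 0) stop("pulse_duration must be > 0", call. = FALSE)
  if (g_syn < 0) stop("g_syn must be >= 0", call. = FALSE)
  o1 <- opts; o1$duration <- settle
  pre <- simulate_cell(params, opts = o1)
  o2 <- opts; o2$duration <- pulse_duration
  during <- simulate_cell(params, init = final_state(pre), opts = o2,
                          g_pulse = g_syn, E_pulse = E_rev)
  o3 <- opts; o3$duration <- post
  after <- simulate_cell(params, init = final_state(during), opts = o3)

  shift <- function(tr, t0) { tr[, "time"] <- tr[, "time"] + t0; tr }
  full <- rbind(pre[-nrow(pre), ],
                shift(during[-nrow(during), ], settle),
                shift(unclass(after), settle + pulse_duration))
  full <- new_trace(full, params, opts)
  t_rel <- settle + pulse_duration

  st <- spike_times(after[, "time"], after[, "V"])
  peak <- NA_real_; adapt <- NA_real_
  if (length(st) >= 2) {
    isi <- diff(st)
    peak <- 1000 / min(isi)
    if (length(isi) >= 3) {
      final_rate <- mean(1000 / utils::tail(isi, 3))
      inst <- 1000 / isi
      ok <- which(abs(inst - final_rate) <= 0.1 * max(final_rate, 0.1))
      if (length(ok)) adapt <- st[ok[1] + 1]
    }
  }
  list(trace = full, t_release = t_rel, spike_times = st + t_rel,
       peak_frequency = peak, adaptation_duration = adapt)
}
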