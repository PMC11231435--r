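#' Swim-interneuron (SiN) model parameters
#'
#' Constructs the full parameter set of the conductance-based swim-interneuron
#' model: an adapted Plant R15 burster in which two shift parameters,
#' \code{delta_x} (half-activation shift of the slow TTX-resistant gate) and
#' \code{delta_Ca} (shift of the nominal +140 mV calcium reversal), control
#' the slow subsystem and can remove endogenous bursting, plus a depolarizing
#' h-current that prevents excessive hyperpolarization.
#'
#' Voltages are in mV, conductances in nS, time in model units (the
#' millisecond-scale Plant clock; rates such as \code{rho} and the synaptic
#' kinetics are per model unit).
#'
#' @param Cm membrane capacitance (must be positive; default 1).
#' @param gI,gK,gT,gKCa,gh,gL maximal conductances of the fast inward
#'   sodium-calcium, potassium, slow TTX-resistant inward, calcium-sensitive
#'   potassium, h-, and leak currents.
#' @param EI,EK,Eh,EL reversal potentials (mV).
#' @param ECa baseline calcium reversal potential (mV, nominally +140).
#' @param rho calcium relaxation rate (dimensionless, much less than 1).
#' @param Kc calcium influx gain.
#' @param tau_x time constant of the slow x-gate (100 or 273 in the source
#'   experiments).
#' @param delta_x,delta_Ca the two slow-subsystem shift parameters (mV).
#' @param Iapp constant applied current.
#' @return An object of class \code{sin_params} (a validated named list).
#' @examples
#' p <- sin_params(delta_Ca = -30, delta_x = -4)
#' p$gI
#' @export
sin_params <- function(Cm = 1, gI = 4, gK = 0.3, gT = 0.00875, gKCa = 0.0303,
                       gh = 0.002, gL = 0.003,
                       EI = 40, EK = -75, Eh = -52, EL = -40, ECa = 140,
                       rho = 1.5e-4, Kc = 0.0085, tau_x = 273,
                       delta_x = 0, delta_Ca = 0, Iapp = 0) {
  p <- list(Cm = Cm, gI = gI, gK = gK, gT = gT, gKCa = gKCa, gh = gh,
            gL = gL, EI = EI, EK = EK, Eh = Eh, EL = EL, ECa = ECa,
            rho = rho, Kc = Kc, tau_x = tau_x, delta_x = delta_x,
            delta_Ca = delta_Ca, Iapp = Iapp)
  validate_sin_params(p)
  structure(p, class = "sin_params")
}

validate_sin_params <- function(p) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  if (p$Cm <= 0) stop("Cm must be > 0", call. = FALSE)
  for (g in c("gI", "gK", "gT", "gKCa", "gh", "gL"))
    if (p[[g]] < 0) stop(g, " must be >= 0", call. = FALSE)
  if (p$rho <= 0 || p$rho > 0.01)
    stop("rho must lie in (0, 0.01]", call. = FALSE)
  if (p$tau_x <= 0) stop("tau_x must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.sin_params <- function(x, ...) {
  cat("Swim-interneuron model parameters\n")
  cat(sprintf("  delta_Ca = %g mV, delta_x = %g mV, tau_x = %g, Iapp = %g\n",
              x$delta_Ca, x$delta_x, x$tau_x, x$Iapp))
  cat(sprintf("  conductances (nS): gI=%g gK=%g gT=%g gKCa=%g gh=%g gL=%g\n",
              x$gI, x$gK, x$gT, x$gKCa, x$gh, x$gL))
  cat(sprintf("  reversals (mV): EI=%g EK=%g Eh=%g EL=%g ECa=%g\n",
              x$EI, x$EK, x$Eh, x$EL, x$ECa))
  cat(sprintf("  slow kinetics: rho=%g Kc=%g\n", x$rho, x$Kc))
  invisible(x)
}

#' Swim-interneuron state vector
#'
#' A full dynamic state of the SiN model: membrane voltage, the four gating
#' probabilities, and the intracellular calcium concentration (model units).
#' By default gates are placed at their voltage steady states, mirroring the
#' relaxation form of their kinetics.
#'
#' @param V membrane voltage (mV).
#' @param h,n,y,x gating probabilities in [0, 1]; \code{NULL} means the
#'   voltage steady state at \code{V} (for \code{x}, using \code{delta_x}
#'   from \code{params}).
#' @param Ca calcium concentration (>= 0).
#' @param params a \code{sin_params} object (needed only for defaulted
#'   \code{x}).
#' @return Named numeric vector of class \code{sin_state} with elements
#'   \code{V, h, n, y, x, Ca}.
#' @examples
#' sin_state()                    # the default initial condition
#' @export
sin_state <- function(V = -55, h = NULL, n = NULL, y = NULL, x = NULL,
                      Ca = 0.8, params = sin_params()) {
  if (!is.finite(V)) stop("V must be finite", call. = FALSE)
  if (is.null(h)) h <- h_inf(V)
  if (is.null(n)) n <- n_inf(V)
  if (is.null(y)) y <- y_inf(V)
  if (is.null(x)) x <- x_inf(V, params$delta_x)
  s <- c(V = V, h = h, n = n, y = y, x = x, Ca = Ca)
  validate_sin_state(s)
  structure(s, class = "sin_state")
}

validate_sin_state <- function(s) {
  if (!is.numeric(s) || length(s) != 6L || any(!is.finite(s)))
    stop("state must be six finite numbers (V, h, n, y, x, Ca)", call. = FALSE)
  g <- s[c("h", "n", "y", "x")]
  if (any(g < -1e-9) || any(g > 1 + 1e-9))
    stop("gating probabilities h, n, y, x must lie in [0, 1]", call. = FALSE)
  if (s[["Ca"]] < 0) stop("Ca must be >= 0", call. = FALSE)
  invisible(s)
}

#' Numerical solver options
#'
#' Settings for the stiff adaptive integrator (deSolve's lsoda) used by all
#' simulation entry points. Dense output is produced on a fixed stride so
#' downstream spike/burst analysis sees a regular time grid.
#'
#' @param duration total integration time (model units).
#' @param dt_out output stride (model units).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param method deSolve method name (default \code{"lsoda"}).
#' @param maxsteps maximal internal steps between output points.
#' @return A list of class \code{solver_options}.
#' @export
solver_options <- function(duration = 100e3, dt_out = 1, rtol = 1e-8,
                           atol = 1e-10, method = "lsoda",
                           maxsteps = 50000) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0", call. = FALSE)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (dt_out <= 0) stop("dt_out must be > 0", call. = FALSE)
  structure(list(duration = duration, dt_out = dt_out, rtol = rtol,
                 atol = atol, method = method, maxsteps = maxsteps),
            class = "solver_options")
}

# flatten cell parameters into the C parameter block (core 18 slots)
cell_parms_vec <- function(p) {
  c(p$Cm, p$gI, p$gK, p$gT, p$gKCa, p$gh, p$gL, p$EI, p$EK, p$Eh, p$EL,
    p$ECa, p$rho, p$Kc, p$tau_x, p$delta_x, p$delta_Ca, p$Iapp)
}
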