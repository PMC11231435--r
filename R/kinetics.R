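#' Gating kinetics of the swim-interneuron model
#'
#' Voltage-dependent steady states and time constants of the model's gating
#' variables. The fast sodium-calcium activation \code{m}, inactivation
#' \code{h} and the potassium activation \code{n} use the voltage-shifted
#' Hodgkin-Huxley forms of the original Plant R15 burster; the slow gate
#' \code{x} has the sigmoidal steady state
#' \deqn{x_\infty(V) = 1 / (1 + e^{-0.15 (V + 50 - \Delta_x)})}
#' so that the slow TTX-resistant current is half-activated at
#' \eqn{V = -50 + \Delta_x} mV.
#'
#' @param V membrane voltage (mV); vectorized.
#' @param delta_x half-activation shift (mV) of the slow gate.
#' @return Activation probabilities in (0, 1) (or time constants, in model
#'   units, for the \code{tau_*} functions).
#' @examples
#' x_inf(-50, 0)        # 0.5: half-activation at V = -50 + delta_x
#' x_inf(-60, 0)        # 1 / (1 + exp(1.5))
#' @name kinetics
NULL

plant_vs <- function(V) (127 * V + 8265) / 105

# scale of the h/n time constants (sets the spike width)
tau_hh_scale <- function() 12.5

exprel <- function(z) ifelse(abs(z) < 1e-7, 1 - z / 2, z / expm1(z))

#' @rdname kinetics
#' @export
x_inf <- function(V, delta_x = 0) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  1 / (1 + exp(-0.15 * (V + 50 - delta_x)))
}

#' @rdname kinetics
#' @export
m_inf <- function(V) {
  Vs <- plant_vs(V)
  am <- exprel((50 - Vs) / 10)
  bm <- 4 * exp((25 - Vs) / 18)
  am / (am + bm)
}

#' @rdname kinetics
#' @export
h_inf <- function(V) {
  Vs <- plant_vs(V)
  ah <- 0.07 * exp((25 - Vs) / 20)
  bh <- 1 / (1 + exp((55 - Vs) / 10))
  ah / (ah + bh)
}

#' @rdname kinetics
#' @export
tau_h <- function(V) {
  Vs <- plant_vs(V)
  ah <- 0.07 * exp((25 - Vs) / 20)
  bh <- 1 / (1 + exp((55 - Vs) / 10))
  tau_hh_scale() / (ah + bh)
}

#' @rdname kinetics
#' @export
n_inf <- function(V) {
  Vs <- plant_vs(V)
  an <- 0.1 * exprel((55 - Vs) / 10)
  bn <- 0.125 * exp((45 - Vs) / 80)
  an / (an + bn)
}

#' @rdname kinetics
#' @export
tau_n <- function(V) {
  Vs <- plant_vs(V)
  an <- 0.1 * exprel((55 - Vs) / 10)
  bn <- 0.125 * exp((45 - Vs) / 80)
  tau_hh_scale() / (an + bn)
}

#' @rdname kinetics
#' @export
y_inf <- function(V) 1 / (1 + exp(10 * (V - 50)))

#' @rdname kinetics
#' @export
tau_y <- function(V) 7.1 + 10.4 / (1 + exp((V + 68) / 2.2))

#' @rdname kinetics
#' @export
sigma_h <- function(V) 1 / (1 + exp((V + 63) / 7.83))

#' Membrane currents of the swim-interneuron model
#'
#' Evaluates the six intrinsic currents at a given state: fast inward
#' sodium-calcium \code{I_I}, delayed-rectifier \code{I_K}, depolarizing
#' h-current \code{I_h}, ohmic leak, slow TTX-resistant inward \code{I_T},
#' and the calcium-sensitive potassium current \code{I_KCa}.
#'
#' @param state a \code{\link{sin_state}} (or named vector with V, h, n, y,
#'   x, Ca).
#' @param params a \code{\link{sin_params}} object.
#' @return Named numeric vector \code{c(I_I, I_K, I_h, I_leak, I_T, I_KCa)}.
#' @examples
#' currents(sin_state(V = -40), sin_params())
#' @export
currents <- function(state, params) {
  validate_sin_state(unclass(state))
  V <- state[["V"]]; Ca <- state[["Ca"]]
  c(I_I    = params$gI * state[["h"]] * m_inf(V)^3 * (V - params$EI),
    I_K    = params$gK * state[["n"]]^4 * (V - params$EK),
    I_h    = params$gh * state[["y"]] * sigma_h(V) * (V - params$Eh),
    I_leak = params$gL * (V - params$EL),
    I_T    = params$gT * state[["x"]] * (V - params$EI),
    I_KCa  = params$gKCa * Ca / (0.5 + Ca) * (V - params$EK))
}

# non-validating internals used for numerical Jacobians, where finite
# differences may step marginally outside the gate box
currents_raw <- function(state, params) {
  V <- state[["V"]]; Ca <- state[["Ca"]]
  Cap <- max(Ca, 0)
  c(I_I    = params$gI * state[["h"]] * m_inf(V)^3 * (V - params$EI),
    I_K    = params$gK * state[["n"]]^4 * (V - params$EK),
    I_h    = params$gh * state[["y"]] * sigma_h(V) * (V - params$Eh),
    I_leak = params$gL * (V - params$EL),
    I_T    = params$gT * state[["x"]] * (V - params$EI),
    I_KCa  = params$gKCa * Cap / (0.5 + Cap) * (V - params$EK))
}

sin_rhs_raw <- function(state, params, I_syn_total = 0,
                        freeze_slow = FALSE) {
  I <- currents_raw(state, params)
  V <- state[["V"]]
  d <- c(V = (-sum(I) - I_syn_total + params$Iapp) / params$Cm,
         h = (h_inf(V) - state[["h"]]) / tau_h(V),
         n = (n_inf(V) - state[["n"]]) / tau_n(V),
         y = (y_inf(V) - state[["y"]]) / tau_y(V),
         x = (x_inf(V, params$delta_x) - state[["x"]]) / params$tau_x,
         Ca = params$rho * (params$Kc * state[["x"]] *
                              (params$ECa - V + params$delta_Ca) -
                              state[["Ca"]]))
  if (freeze_slow) d[c("x", "Ca")] <- 0
  d
}

#' Right-hand side of the swim-interneuron ODE system
#'
#' The time derivative of the full 6-dimensional state. Used directly for
#' equilibrium analysis and testing; time stepping goes through the compiled
#' equivalent inside \code{\link{simulate_cell}}.
#'
#' @inheritParams currents
#' @param I_syn_total total synaptic current entering the voltage equation
#'   (0 for an isolated cell), with the intrinsic currents' sign convention.
#' @param freeze_slow if TRUE the slow subsystem is frozen (x' = Ca' = 0),
#'   exposing the fast spike-generating subsystem.
#' @return Named numeric derivative vector (same layout as the state).
#' @export
sin_rhs <- function(state, params, I_syn_total = 0, freeze_slow = FALSE) {
  if (!is.finite(I_syn_total))
    stop("I_syn_total must be finite", call. = FALSE)
  I <- currents(state, params)
  V <- state[["V"]]
  d <- c(V = (-sum(I) - I_syn_total + params$Iapp) / params$Cm,
         h = (h_inf(V) - state[["h"]]) / tau_h(V),
         n = (n_inf(V) - state[["n"]]) / tau_n(V),
         y = (y_inf(V) - state[["y"]]) / tau_y(V),
         x = (x_inf(V, params$delta_x) - state[["x"]]) / params$tau_x,
         Ca = params$rho * (params$Kc * state[["x"]] *
                              (params$ECa - V + params$delta_Ca) -
                              state[["Ca"]]))
  if (freeze_slow) d[c("x", "Ca")] <- 0
  if (any(!is.finite(d)))
    stop("non-finite derivative encountered in sin_rhs", call. = FALSE)
  d
}
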