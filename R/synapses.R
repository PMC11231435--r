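#' Synapse model specification
#'
#' Describes one chemical synapse by kind and kinetic constants. Five kinds
#' are supported:
#' \describe{
#'   \item{ftm}{fast threshold modulation: the gate is set algebraically to
#'     \code{f_inf(V_pre)}, no temporal dynamics.}
#'   \item{alpha}{first-order kinetics
#'     \code{dS/dt = alpha (1 - S) f_inf - beta S}.}
#'   \item{cascade}{a feed-forward chain of alpha-type stages; each stage is
#'     driven by the previous one, smoothing individual spikes.}
#'   \item{dynamic}{an alpha-form gate times a slow modulation variable
#'     \code{dM/dt = (f_inf - M) / tau_M}; the current uses \code{S * M}.}
#'   \item{logistic}{\code{dS/dt = alpha S (1 - S) f_inf - beta (S - S0)}: the
#'     \code{S (1 - S)} factor yields latency, sigmoidal summation and
#'     high-pass frequency filtering.}
#' }
#'
#' @param kind one of \code{"ftm"}, \code{"alpha"}, \code{"cascade"},
#'   \code{"dynamic"}, \code{"logistic"}.
#' @param g_syn maximal conductance (nS, >= 0).
#' @param E_rev reversal potential (mV): -80 inhibitory (default), +40
#'   excitatory.
#' @param alpha,beta rate constants (per model unit, > 0); for
#'   \code{cascade} they may be vectors with one entry per stage (recycled).
#' @param n_stages cascade depth (1 to 3; default 2, second-order kinetics).
#' @param tau_M modulation time constant of the dynamic kind.
#' @param S0 spontaneous release floor of the logistic kind (0 to 1e-3).
#' @param k slope of the release sigmoid \code{f_inf} (0.5 to 50).
#' @param theta_syn synaptic threshold (mV), the release sigmoid's
#'   inflection voltage, set mid-spike.
#' @param power exponent p of S in the synaptic current \code{g S^p (V -
#'   E_rev)}.
#' @return A validated list of class \code{synapse_spec}.
#' @examples
#' synapse_spec("logistic", g_syn = 0.047, alpha = 0.05, beta = 0.0051)
#' @export
synapse_spec <- function(kind = c("logistic", "ftm", "alpha", "cascade",
                                  "dynamic"),
                         g_syn = 0.05, E_rev = -80,
                         alpha = 0.01, beta = 0.001, n_stages = 2,
                         tau_M = 1200, S0 = 1e-3, k = 1, theta_syn = 20,
                         power = 1) {
  kind <- match.arg(kind)
  if (g_syn < 0) stop("g_syn must be >= 0", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0))
    stop("rate constants alpha, beta must be > 0", call. = FALSE)
  if (S0 < 0 || S0 > 1e-3)
    stop("S0 must lie in [0, 1e-3]", call. = FALSE)
  if (k < 0.5 || k > 50) stop("k must lie in [0.5, 50]", call. = FALSE)
  if (n_stages < 1 || n_stages > 3)
    stop("n_stages must be 1, 2 or 3", call. = FALSE)
  if (tau_M <= 0) stop("tau_M must be > 0", call. = FALSE)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  n_stages <- as.integer(n_stages)
  structure(list(kind = kind, g_syn = g_syn, E_rev = E_rev,
                 alpha = rep_len(alpha, if (kind == "cascade") n_stages else 1L),
                 beta = rep_len(beta, if (kind == "cascade") n_stages else 1L),
                 n_stages = n_stages, tau_M = tau_M, S0 = S0, k = k,
                 theta_syn = theta_syn, power = power),
            class = "synapse_spec")
}

#' @export
print.synapse_spec <- function(x, ...) {
  cat(sprintf("%s synapse: g_syn=%g nS, E_rev=%g mV, alpha=%s, beta=%s\n",
              x$kind, x$g_syn, x$E_rev, paste(x$alpha, collapse = "/"),
              paste(x$beta, collapse = "/")))
  invisible(x)
}

#' Gap junction (electrical synapse) specification
#'
#' @param g_elec electrical coupling conductance (nS, >= 0).
#' @return A list of class \code{gap_junction_spec}.
#' @export
gap_junction_spec <- function(g_elec = 0) {
  if (g_elec < 0) stop("g_elec must be >= 0", call. = FALSE)
  structure(list(g_elec = g_elec), class = "gap_junction_spec")
}

#' Presynaptic release sigmoid
#'
#' \code{f_inf(V) = 1 / (1 + exp(-k (V - theta_syn)))}: the fraction of
#' maximal transmitter release driven by the presynaptic voltage, with
#' inflection at the synaptic threshold.
#'
#' @param V_pre presynaptic voltage (mV); vectorized.
#' @param k sigmoid slope.
#' @param theta_syn threshold voltage (mV).
#' @return Probability in (0, 1).
#' @examples
#' f_inf(20, k = 1, theta_syn = 20)   # 0.5 at threshold
#' @export
f_inf <- function(V_pre, k = 1, theta_syn = 20) {
  if (any(!is.finite(V_pre))) stop("V_pre must be finite", call. = FALSE)
  1 / (1 + exp(-k * (V_pre - theta_syn)))
}

# number of ODE states a synapse kind carries
n_gate_states <- function(spec) {
  switch(spec$kind, ftm = 0L, alpha = 1L, cascade = spec$n_stages,
         dynamic = 2L, logistic = 1L)
}

#' Initial gate state for a synapse
#'
#' @param spec a \code{\link{synapse_spec}}.
#' @param S initial value for the primary gate (recycled over cascade
#'   stages; the dynamic kind's modulation M starts at the same value
#'   unless \code{M} is given).
#' @param M initial modulation value (dynamic kind only).
#' @return Numeric vector of gate states (length 0 for ftm).
#' @export
gate_init <- function(spec, S = 0, M = NULL) {
  n <- n_gate_states(spec)
  if (n == 0L) return(numeric(0))
  g <- rep_len(S, n)
  if (spec$kind == "dynamic") g[2] <- if (is.null(M)) S else M
  if (any(g < 0) || any(g > 1))
    stop("gate states must lie in [0, 1]", call. = FALSE)
  g
}

#' Gate kinetics right-hand side
#'
#' Time derivative of a synapse's gate states given the presynaptic
#' voltage. For the algebraic ftm kind the derivative is empty; use
#' \code{\link{gate_value}} for its instantaneous gate.
#'
#' @param spec a \code{\link{synapse_spec}}.
#' @param state gate state vector (layout of \code{\link{gate_init}}).
#' @param V_pre presynaptic voltage (mV).
#' @return Derivative vector, same length as \code{state}.
#' @examples
#' sp <- synapse_spec("alpha", alpha = 0.01, beta = 0.001)
#' gate_rhs(sp, 0.2, V_pre = 30)
#' @export
gate_rhs <- function(spec, state, V_pre) {
  if (length(state) != n_gate_states(spec))
    stop("gate state has wrong length for kind '", spec$kind, "'",
         call. = FALSE)
  f <- f_inf(V_pre, spec$k, spec$theta_syn)
  switch(spec$kind,
    ftm = numeric(0),
    alpha = spec$alpha * (1 - state) * f - spec$beta * state,
    cascade = {
      drive <- c(f, state[-length(state)])
      spec$alpha * (1 - state) * drive - spec$beta * state
    },
    dynamic = c(spec$alpha[1] * (1 - state[1]) * f - spec$beta[1] * state[1],
                (f - state[2]) / spec$tau_M),
    logistic = spec$alpha * state * (1 - state) * f -
      spec$beta * (state - spec$S0))
}

#' Effective gate value entering the synaptic current
#'
#' @inheritParams gate_rhs
#' @return The scalar gate: \code{f_inf(V_pre)} for ftm, the last stage for
#'   cascade, \code{S * M} for dynamic, otherwise \code{S}.
#' @export
gate_value <- function(spec, state, V_pre = NULL) {
  switch(spec$kind,
    ftm = f_inf(V_pre, spec$k, spec$theta_syn),
    cascade = state[length(state)],
    dynamic = state[1] * state[2],
    state[1])
}

#' Synaptic current onto the postsynaptic cell
#'
#' \code{I_syn = g_syn S^p (V_post - E_rev)} with S the effective gate
#' (\code{S M} for the dynamic kind), using the intrinsic currents' sign
#' convention (positive = outward).
#'
#' @inheritParams gate_rhs
#' @param V_post postsynaptic voltage (mV).
#' @return Current (same units as the cell currents).
#' @export
syn_current <- function(spec, state, V_post, V_pre = NULL) {
  S <- gate_value(spec, state, V_pre)
  spec$g_syn * S^spec$power * (V_post - spec$E_rev)
}

#' Gap-junction current
#'
#' Ohmic electrical coupling \code{g_elec (V_self - V_other)}, entering each
#' cell's voltage equation with the intrinsic currents' sign convention;
#' antisymmetric under exchange of the two voltages.
#'
#' @param g_elec coupling conductance (nS).
#' @param V_self,V_other the two membrane voltages (mV).
#' @return Current into the cell at \code{V_self}.
#' @export
gap_current <- function(g_elec, V_self, V_other) {
  g_elec * (V_self - V_other)
}

#' Integrate synapse gates driven by a voltage waveform
#'
#' Drives a synapse's gate kinetics with a prescribed presynaptic voltage
#' command (a \code{\link{pulse_fixture}} waveform) without simulating a
#' presynaptic cell. Integration proceeds segment by segment over the
#' waveform's constant-voltage pieces.
#'
#' @param spec a \code{\link{synapse_spec}}.
#' @param waveform a \code{drive_waveform}.
#' @param duration total time (model units); defaults to the waveform's
#'   extent.
#' @param init initial gate state.
#' @param dt_out output stride.
#' @param rtol,atol solver tolerances.
#' @return Matrix with \code{time}, \code{V_pre}, one column per gate state,
#'   and \code{S} (the effective gate).
#' @export
simulate_gate <- function(spec, waveform, duration = NULL, init = NULL,
                          dt_out = 1, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(waveform, "drive_waveform"))
  if (is.null(duration)) duration <- waveform_end(waveform)
  if (is.null(init)) init <- gate_init(spec, S = if (spec$kind ==
                                                     "logistic") spec$S0 else 0)
  brk <- sort(unique(c(0, waveform$t[waveform$t > 0 & waveform$t < duration],
                       duration)))
  rows <- list(); y <- init; t0 <- brk[1]
  for (i in seq_len(length(brk) - 1L)) {
    t1 <- brk[i + 1L]
    Vp <- waveform_at(waveform, (t0 + t1) / 2)
    times <- sort(unique(c(seq(t0, t1, by = dt_out), t1)))
    if (length(init) == 0L) {        # ftm: algebraic, nothing to integrate
      seg <- cbind(times, matrix(numeric(0), length(times), 0))
    } else {
      seg <- deSolve::ode(y = y, times = times,
                          func = function(t, y, p) list(gate_rhs(spec, y, Vp)),
                          parms = NULL, method = "lsoda",
                          rtol = rtol, atol = atol)
      y <- pmin(pmax(seg[nrow(seg), -1], 0), 1)
    }
    seg <- cbind(seg, V_pre = Vp)
    rows[[i]] <- if (i < length(brk) - 1L) seg[-nrow(seg), , drop = FALSE]
                 else seg
    t0 <- t1
  }
  out <- do.call(rbind, rows)
  ns <- n_gate_states(spec)
  colnames(out) <- c("time", if (ns) paste0("g", seq_len(ns)), "V_pre")
  S <- apply(out, 1L, function(r)
    gate_value(spec, r[1L + seq_len(ns)], r[["V_pre"]]))
  cbind(out, S = S)
}
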