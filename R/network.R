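#' Two-cell network configuration
#'
#' Assembles a pair of swim interneurons coupled by directed chemical
#' synapses (cell 1 to cell 2 and cell 2 to cell 1) and an optional gap
#' junction. Setting a synapse's \code{g_syn} (or the gap junction's
#' \code{g_elec}) to zero removes that coupling element.
#'
#' @param cell1,cell2 \code{\link{sin_params}} objects.
#' @param syn12 \code{\link{synapse_spec}} for the cell 1 -> cell 2
#'   synapse.
#' @param syn21 \code{\link{synapse_spec}} for the cell 2 -> cell 1
#'   synapse.
#' @param gap a \code{\link{gap_junction_spec}}.
#' @param init named list with optional entries \code{cell1}, \code{cell2}
#'   (\code{\link{sin_state}}s) and \code{S12}, \code{S21} (gate state
#'   vectors); missing entries default to the standard initial condition
#'   and resting gates.
#' @param opts \code{\link{solver_options}}; the default runs 400,000 model
#'   units so the slow network rhythm settles, and analysis conventionally
#'   uses the final half.
#' @return A validated list of class \code{network_config}.
#' @examples
#' cfg <- hco_config(delta_Ca = -30, g_syn = 0.047,
#'                   alpha = 0.05, beta = 0.0051)
#' @export
network_config <- function(cell1, cell2, syn12, syn21,
                           gap = gap_junction_spec(0), init = list(),
                           opts = solver_options(duration = 400e3,
                                                 dt_out = 2, rtol = 1e-7,
                                                 atol = 1e-9)) {
  stopifnot(inherits(cell1, "sin_params"), inherits(cell2, "sin_params"),
            inherits(syn12, "synapse_spec"), inherits(syn21, "synapse_spec"),
            inherits(gap, "gap_junction_spec"))
  if (syn12$g_syn == 0 && syn21$g_syn == 0 && gap$g_elec == 0 &&
      !isTRUE(attr(init, "allow_uncoupled")))
    warning("network has no coupling element; cells evolve independently")
  structure(list(cell1 = cell1, cell2 = cell2, syn12 = syn12,
                 syn21 = syn21, gap = gap, init = init, opts = opts),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("two-cell network\n")
  cat(sprintf("  cell1: delta_Ca=%g delta_x=%g | cell2: delta_Ca=%g delta_x=%g\n",
              x$cell1$delta_Ca, x$cell1$delta_x,
              x$cell2$delta_Ca, x$cell2$delta_x))
  cat(sprintf("  syn12: %s g=%g E=%g | syn21: %s g=%g E=%g | g_elec=%g\n",
              x$syn12$kind, x$syn12$g_syn, x$syn12$E_rev,
              x$syn21$kind, x$syn21$g_syn, x$syn21$E_rev, x$gap$g_elec))
  invisible(x)
}

syn_parms_vec <- function(sp) {
  kind <- match(sp$kind, c("ftm", "alpha", "cascade", "dynamic",
                           "logistic")) - 1L
  a <- rep_len(sp$alpha, 3); b <- rep_len(sp$beta, 3)
  c(kind, sp$g_syn, sp$E_rev, sp$k, sp$theta_syn,
    a[1], b[1], a[2], b[2], a[3], b[3],
    sp$n_stages, sp$tau_M, sp$S0, sp$power)
}

gate_slots <- function(spec, g) {
  out <- numeric(4)
  out[seq_along(g)] <- g
  out
}

#' Simulate a two-cell network
#'
#' Integrates the joint ODE system (two cells plus all synapse gate
#' variables) as a single flow with the stiff adaptive solver and the
#' compiled network right-hand side.
#'
#' @param cfg a \code{\link{network_config}}.
#' @return A \code{sin_trace} matrix with per-cell state columns
#'   (\code{V1 ... Ca1, V2 ... Ca2}), raw gate slots, and the effective
#'   gates \code{S12}, \code{S21} driving the synaptic currents.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  opts <- cfg$opts
  init <- cfg$init
  c1 <- if (!is.null(init$cell1)) init$cell1 else sin_state(params = cfg$cell1)
  c2 <- if (!is.null(init$cell2)) init$cell2 else sin_state(params = cfg$cell2)
  g12 <- if (!is.null(init$S12)) gate_slots(cfg$syn12, init$S12)
         else gate_slots(cfg$syn12, gate_init(cfg$syn12, S = cfg$syn12$S0))
  g21 <- if (!is.null(init$S21)) gate_slots(cfg$syn21, init$S21)
         else gate_slots(cfg$syn21, gate_init(cfg$syn21, S = cfg$syn21$S0))
  y0 <- c(unclass(c1), unclass(c2), g12, g21)
  names(y0) <- c(paste0(c("V", "h", "n", "y", "x", "Ca"), 1),
                 paste0(c("V", "h", "n", "y", "x", "Ca"), 2),
                 paste0("s12_", 1:4), paste0("s21_", 1:4))
  parms <- c(cell_parms_vec(cfg$cell1), cell_parms_vec(cfg$cell2),
             syn_parms_vec(cfg$syn12), syn_parms_vec(cfg$syn21),
             cfg$gap$g_elec)
  times <- seq(0, opts$duration, by = opts$dt_out)
  out <- deSolve::ode(y = y0, times = times, func = "sinet_dnet",
                      parms = parms, dllname = "sinet",
                      initfunc = "sinet_initnet", method = opts$method,
                      rtol = opts$rtol, atol = opts$atol,
                      maxsteps = opts$maxsteps)
  check_solver(out, times)
  out <- unclass(out)
  colnames(out) <- c("time", names(y0))
  S12 <- effective_gate_col(cfg$syn12, out, "s12_", out[, "V1"])
  S21 <- effective_gate_col(cfg$syn21, out, "s21_", out[, "V2"])
  out <- cbind(out, S12 = S12, S21 = S21)
  new_trace(out, cfg$cell1, opts, extra = list(config = cfg))
}

effective_gate_col <- function(spec, out, prefix, Vpre) {
  switch(spec$kind,
    ftm = f_inf(Vpre, spec$k, spec$theta_syn),
    cascade = out[, paste0(prefix, spec$n_stages)],
    dynamic = out[, paste0(prefix, 1)] * out[, paste0(prefix, 2)],
    out[, paste0(prefix, 1)])
}

#' Burst metrics and network phase lag
#'
#' Delimits bursts with the ISI-gap rule shared with the trace classifier
#' and summarizes the network rhythm: per-cell burst onsets/offsets, burst
#' period, duty cycle, interburst interval, within-burst spike frequency,
#' and the normalized phase lag between the two cells (circular mean of the
#' lag from each cell-2 burst onset to the nearest preceding cell-1 onset,
#' divided by the cell-1 period).
#'
#' @param trace a network \code{sin_trace} (columns \code{V1}, \code{V2}).
#' @param window analysis window: the trailing portion of the trace to use
#'   (model units); default the final half.
#' @param gap_factor burst-delimiting ISI gap factor.
#' @return List of class \code{burst_metrics} with per-cell summaries and
#'   \code{phase_lag} in [0, 1).
#' @export
burst_metrics <- function(trace, window = NULL, gap_factor = 3) {
  tm <- trace[, "time"]
  if (is.null(window)) window <- (tm[length(tm)] - tm[1]) / 2
  keep <- tm >= tm[length(tm)] - window
  cell <- function(v) {
    st <- spike_times(tm[keep], trace[keep, v])
    groups <- split_bursts(st, gap_factor)
    groups <- groups[lengths(groups) > 0]
    onsets <- vapply(groups, function(g) g[1], numeric(1))
    offsets <- vapply(groups, function(g) g[length(g)], numeric(1))
    list(spikes = st, onsets = onsets, offsets = offsets,
         n_bursts = length(groups),
         spikes_per_burst = mean(lengths(groups)))
  }
  c1 <- cell("V1"); c2 <- cell("V2")
  if (c1$n_bursts < 3 || c2$n_bursts < 3)
    stop("insufficient data: fewer than 3 bursts per cell in the window",
         call. = FALSE)
  period <- mean(diff(c1$onsets))
  duty1 <- mean((c1$offsets - c1$onsets)) / period
  duty2 <- mean((c2$offsets - c2$onsets)) / period
  inter1 <- mean(c1$onsets[-1] - c1$offsets[-c1$n_bursts])
  inter2 <- mean(c2$onsets[-1] - c2$offsets[-c2$n_bursts])
  lags <- vapply(c2$onsets, function(o2) {
    pre <- c1$onsets[c1$onsets <= o2]
    if (!length(pre)) return(NA_real_)
    (o2 - pre[length(pre)]) / period
  }, numeric(1))
  lags <- lags[is.finite(lags)]
  phase <- if (length(lags)) {
    ang <- 2 * pi * lags
    (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
  } else NA_real_
  structure(list(period = period, phase_lag = phase,
                 cell1 = c(n_bursts = c1$n_bursts, duty = duty1,
                           interburst = inter1,
                           spikes_per_burst = c1$spikes_per_burst),
                 cell2 = c(n_bursts = c2$n_bursts, duty = duty2,
                           interburst = inter2,
                           spikes_per_burst = c2$spikes_per_burst),
                 onsets1 = c1$onsets, onsets2 = c2$onsets),
            class = "burst_metrics")
}

#' @export
print.burst_metrics <- function(x, ...) {
  cat(sprintf("network bursting: period %.0f units (%.1f s), phase lag %.3f\n",
              x$period, x$period / 1000, x$phase_lag))
  cat(sprintf("  cell1: %d bursts, duty %.2f | cell2: %d bursts, duty %.2f\n",
              x$cell1[["n_bursts"]], x$cell1[["duty"]],
              x$cell2[["n_bursts"]], x$cell2[["duty"]]))
  invisible(x)
}

#' Steady-state network label
#'
#' Classifies each cell's steady-state activity over the trailing window
#' and reduces the pair to a network-level outcome: \code{"bursting"} when
#' both cells burst, otherwise the pair of cell labels.
#'
#' @param trace a network \code{sin_trace}.
#' @param copts classifier thresholds (transient taken as everything before
#'   the final \code{window}).
#' @param window trailing analysis window (model units), default final half.
#' @return List with \code{network} (\code{"bursting"} or
#'   \code{"non-bursting"}) and the two per-cell labels.
#' @export
network_label <- function(trace, window = NULL, copts = NULL) {
  tm <- trace[, "time"]
  if (is.null(window)) window <- (tm[length(tm)] - tm[1]) / 2
  if (is.null(copts))
    copts <- classifier_options(transient = tm[length(tm)] - window,
                                window = window * 0.99)
  l1 <- classify_trace(trace, copts, vcol = "V1")$label
  l2 <- classify_trace(trace, copts, vcol = "V2")$label
  list(network = if (l1 == "bursting" && l2 == "bursting") "bursting"
       else "non-bursting", cell1 = l1, cell2 = l2)
}

#' Probe network bistability
#'
#' Runs the same network from two initial-condition families and returns
#' the steady-state label reached from each, exposing the coexistence of a
#' sustained network rhythm with a non-bursting attractor.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param init_A,init_B init lists as in \code{\link{network_config}};
#'   defaults: A = anti-phase (cell 1 on its attractor with an active
#'   outgoing gate, cell 2 released from a standard inhibitory pulse), B =
#'   in-phase (both cells in identical states, equal gates).
#' @return List with the two steady-state labels (\code{A}, \code{B}) and
#'   \code{bistable} (TRUE when they differ).
#' @export
bistability_probe <- function(cfg, init_A = NULL, init_B = NULL) {
  if (is.null(init_A)) init_A <- antiphase_init(cfg)
  if (is.null(init_B)) init_B <- inphase_init(cfg)
  lab <- function(init) {
    cfg$init <- init
    tr <- simulate_network(cfg)
    network_label(tr)
  }
  A <- lab(init_A); B <- lab(init_B)
  list(A = A, B = B, bistable = !identical(A$network, B$network))
}

#' Anti-phase and in-phase initial-condition families
#'
#' The anti-phase family starts cell 1 on its natural attractor with its
#' outgoing gate active, and cell 2 at the deeply hyperpolarized state
#' reached at the end of a long (20,000-unit) inhibitory pulse (the
#' pulse-release protocol), with its outgoing gate at rest: this mirrors
#' the inhibitory race that initiates network bursting, and the long pulse
#' drains the driven cell's calcium so its rebound is fast enough to engage
#' the partner's high-pass synapse. The in-phase family starts both
#' cells in the same state with equal gates, which for a symmetric network
#' is an exchange-invariant (hence non-alternating) initial condition.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param S_active initial value of the active cell's outgoing gate.
#' @param active which cell starts on its attractor (the other is released
#'   from inhibition at t = 0).
#' @return An init list usable in \code{\link{network_config}}.
#' @export
antiphase_init <- function(cfg, S_active = 0.5, active = 1) {
  pa <- if (active == 1) cfg$cell1 else cfg$cell2
  pq <- if (active == 1) cfg$cell2 else cfg$cell1
  settle <- simulate_cell(pa,
                          opts = solver_options(duration = 300e3, dt_out = 5,
                                                rtol = 1e-7, atol = 1e-9))
  sa <- final_state(settle)
  preq <- simulate_cell(pq,
                        opts = solver_options(duration = 100e3, dt_out = 5,
                                              rtol = 1e-7, atol = 1e-9))
  pulse <- simulate_cell(pq, init = final_state(preq),
                         opts = solver_options(duration = 20000, dt_out = 5,
                                               rtol = 1e-7, atol = 1e-9),
                         g_pulse = 1, E_pulse = -80)
  sq <- final_state(pulse)
  sa_gate <- function(spec) gate_init(spec, S = S_active)
  sq_gate <- function(spec) gate_init(spec, S = spec$S0)
  if (active == 1)
    list(cell1 = sa, cell2 = sq, S12 = sa_gate(cfg$syn12),
         S21 = sq_gate(cfg$syn21))
  else
    list(cell1 = sq, cell2 = sa, S12 = sq_gate(cfg$syn12),
         S21 = sa_gate(cfg$syn21))
}

#' @rdname antiphase_init
#' @export
inphase_init <- function(cfg) {
  settle <- simulate_cell(cfg$cell1,
                          opts = solver_options(duration = 300e3, dt_out = 5,
                                                rtol = 1e-7, atol = 1e-9))
  s1 <- final_state(settle)
  list(cell1 = s1, cell2 = s1,
       S12 = gate_init(cfg$syn12, S = cfg$syn12$S0),
       S21 = gate_init(cfg$syn21, S = cfg$syn21$S0))
}

#' @rdname antiphase_init
#' @param release which cell is released from a long inhibitory pulse at
#'   t = 0 while the other starts on its natural attractor; both gates
#'   start at their spontaneous floor. This is the standard ignition for
#'   the excitatory/inhibitory module, whose rhythm is launched by the
#'   excitatory cell's rebound burst.
#' @export
release_init <- function(cfg, release = 1) {
  pr <- if (release == 1) cfg$cell1 else cfg$cell2
  po <- if (release == 1) cfg$cell2 else cfg$cell1
  pre <- simulate_cell(pr, opts = solver_options(duration = 100e3, dt_out = 5,
                                                 rtol = 1e-7, atol = 1e-9))
  pulse <- simulate_cell(pr, init = final_state(pre),
                         opts = solver_options(duration = 20000, dt_out = 5,
                                               rtol = 1e-7, atol = 1e-9),
                         g_pulse = 1, E_pulse = -80)
  sr <- final_state(pulse)
  so <- final_state(simulate_cell(po, opts = solver_options(duration = 200e3,
                                                            dt_out = 5,
                                                            rtol = 1e-7,
                                                            atol = 1e-9)))
  g12 <- gate_init(cfg$syn12, S = cfg$syn12$S0)
  g21 <- gate_init(cfg$syn21, S = cfg$syn21$S0)
  if (release == 1) list(cell1 = sr, cell2 = so, S12 = g12, S21 = g21)
  else list(cell1 = so, cell2 = sr, S12 = g12, S21 = g21)
}

# convenience constructor for a symmetric half-center oscillator
#' @rdname network_config
#' @param delta_Ca shared delta_Ca of the two identical HCO cells (mV).
#' @param g_syn,alpha,beta shared logistic-synapse constants of the two
#'   reciprocal inhibitory synapses.
#' @param delta_x shared delta_x (mV; the no-endogenous-bursting region).
#' @export
hco_config <- function(delta_Ca = -30, g_syn = 0.047, alpha = 0.05,
                       beta = 0.0051, delta_x = -4) {
  cell <- sin_params(delta_Ca = delta_Ca, delta_x = delta_x)
  syn <- synapse_spec("logistic", g_syn = g_syn, E_rev = -80,
                      alpha = alpha, beta = beta)
  network_config(cell, cell, syn, syn)
}

#' Network experiment presets
#'
#' The registry of two-cell experiments studied in the source material:
#' half-center oscillators of quiescent or tonic cells at weak/sufficient
#' inhibition, the winner-takes-all pair, and the excitatory/inhibitory
#' module family. Every numeric field is the corresponding published
#' parameter set; chemical synapses are logistic, inhibitory at -80 mV and
#' excitatory at +40 mV, and cells sit at delta_x = -4 (no endogenous
#' bursting).
#'
#' @param ignite compute the preset's standard ignition initial condition
#'   (a short simulation; see \code{\link{antiphase_init}} and
#'   \code{\link{release_init}}). With \code{FALSE} the configuration is
#'   returned with the default resting initial condition.
#' @param name preset name; one of \code{hco_quiescent_weak},
#'   \code{hco_quiescent}, \code{hco_tonic_weak}, \code{hco_tonic},
#'   \code{winner_strong}, \code{winner_weak}, \code{ei_uncoupled},
#'   \code{ei_exc_only}, \code{ei_weak}, \code{ei_balanced},
#'   \code{ei_diverse}, \code{ei_quiescent_pair_weak},
#'   \code{ei_quiescent_pair}, \code{ei_tonic_pair}.
#' @return A \code{\link{network_config}}.
#' @examples
#' preset("hco_quiescent")$syn12$g_syn    # 0.047
#' @export
preset <- function(name, ignite = TRUE) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  cfg <- reg[[name]]()
  cfg$preset <- name
  if (ignite) {
    cfg$init <- switch(cfg$ignition,
                       antiphase = antiphase_init(cfg),
                       antiphase2 = antiphase_init(cfg, active = 2),
                       release = release_init(cfg),
                       list())
  }
  cfg
}

#' @rdname preset
#' @export
preset_names <- function() names(preset_registry())

preset_registry <- function() {
  cell <- function(dca) sin_params(delta_Ca = dca, delta_x = -4)
  # mid-spike synaptic threshold for the network experiments (see the
  # methods vignette): between the spike threshold and the spike peak
  inh <- function(g, a, b) synapse_spec("logistic", g_syn = g, E_rev = -80,
                                        alpha = a, beta = b,
                                        theta_syn = -20)
  exc <- function(g, a, b) synapse_spec("logistic", g_syn = g, E_rev = 40,
                                        alpha = a, beta = b,
                                        theta_syn = -20)
  ei <- function(dca1, dca2, s12, s21, gel, ign = "release") {
    cfg <- network_config(cell(dca1), cell(dca2), s12, s21,
                          gap_junction_spec(gel))
    cfg$ignition <- ign
    cfg
  }
  hco <- function(dca, g, a, b) {
    cfg <- network_config(cell(dca), cell(dca), inh(g, a, b), inh(g, a, b))
    cfg$ignition <- "antiphase"
    cfg
  }
  list(
    hco_quiescent_weak = function() hco(-30, 0.027, 0.05, 0.0051),
    hco_quiescent      = function() hco(-30, 0.047, 0.05, 0.0051),
    hco_tonic_weak     = function() hco(-40, 0.057, 0.03, 0.003),
    hco_tonic          = function() hco(-40, 0.067, 0.03, 0.003),
    winner_strong = function() {
      cfg <- network_config(cell(-50), cell(-40),
                            inh(0.1, 0.021, 0.0013), inh(0.8, 0.03, 0.0011))
      cfg$ignition <- "antiphase2"
      cfg
    },
    winner_weak = function() {
      cfg <- network_config(cell(-50), cell(-40),
                            inh(0.1, 0.021, 0.0013), inh(0.1, 0.03, 0.0011))
      cfg$ignition <- "antiphase2"
      cfg
    },
    ei_uncoupled = function()
      suppressWarnings(ei(-50, -20, exc(0, 0.016, 0.001),
                          inh(0, 0.01, 0.001), 0, ign = "none")),
    ei_exc_only = function()
      ei(-50, -20, exc(0.2, 0.016, 0.001), inh(0, 0.01, 0.001), 2e-4,
         ign = "none"),
    ei_weak = function()
      ei(-50, -20, exc(0.15, 0.0142, 0.001), inh(0.2, 0.01, 0.001), 0),
    ei_balanced = function()
      ei(-50, -20, exc(0.2, 0.016, 0.001), inh(0.5, 0.011, 0.001), 3e-4),
    ei_diverse = function()
      ei(-60, 60, exc(0.03, 0.02, 0.0011), inh(0.1, 0.012, 0.001), 1e-3,
         ign = "none"),
    ei_quiescent_pair_weak = function()
      ei(20, 60, exc(0.0375, 0.033, 0.001), inh(0.6, 0.021, 0.001), 2.5e-4),
    ei_quiescent_pair = function()
      ei(20, 60, exc(0.045, 0.033, 0.001), inh(0.6, 0.021, 0.001), 2.5e-4),
    ei_tonic_pair = function()
      ei(-60, -40, exc(0.01, 0.025, 0.001), inh(0.15, 0.01, 0.0014), 4e-3,
         ign = "none")
  )
}
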