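#' Constant perturbation context for the frozen fast subsystem
#'
#' The dissection operations can be carried out under a constant applied
#' current and/or a constant-conductance synaptic drive
#' \code{-g_syn (V - E_rev)}, mirroring how external and synaptic currents
#' deform the slow phase plane.
#'
#' @param Iapp constant applied current.
#' @param g_syn constant synaptic conductance (nS).
#' @param E_rev synaptic reversal potential (mV).
#' @return A list of class \code{perturbation}.
#' @export
perturbation <- function(Iapp = 0, g_syn = 0, E_rev = -80) {
  structure(list(Iapp = Iapp, g_syn = g_syn, E_rev = E_rev),
            class = "perturbation")
}

# fast-subsystem right-hand side at frozen slow variables
fast_rhs <- function(v4, params, x, Ca, pert = perturbation()) {
  st <- c(V = v4[[1]], h = v4[[2]], n = v4[[3]], y = v4[[4]], x = x, Ca = Ca)
  Isyn <- pert$g_syn * (v4[[1]] - pert$E_rev) - pert$Iapp
  unname(sin_rhs_raw(st, params, I_syn_total = Isyn,
                     freeze_slow = TRUE)[1:4])
}

# total steady-state current balance of the fast subsystem as a function of
# V alone (gates at their steady states), used to locate equilibria
fast_balance <- function(V, params, x, Ca, pert = perturbation()) {
  st <- c(V = V, h = h_inf(V), n = n_inf(V), y = y_inf(V), x = x, Ca = Ca)
  I <- currents(st, params)
  -sum(I) - pert$g_syn * (V - pert$E_rev) + pert$Iapp + params$Iapp
}

#' Fast-subsystem attractor at frozen slow variables
#'
#' With the slow pair (Ca, x) frozen, locates the fast subsystem's
#' (V, h, n, y) equilibria by scalar root bracketing of the steady-state
#' current balance (with stability from the Jacobian's eigenvalues), and
#' probes for a stable periodic orbit by long-transient integration with
#' spike-based period detection. Orbit averages of V and of
#' \code{x_inf(V)} are computed by trapezoidal quadrature over the detected
#' periods.
#'
#' @param Ca,x frozen slow coordinates.
#' @param params a \code{\link{sin_params}} object.
#' @param pert a \code{\link{perturbation}}.
#' @param V_range voltage window scanned for equilibria.
#' @param t_transient,t_measure integration lengths for the orbit probe.
#' @return A \code{manifold_sample}: list with \code{equilibria} (data
#'   frame of V, stability flag, max real eigenvalue) and \code{orbit}
#'   (NULL, or list with period T, \code{V_mean}, \code{xinf_mean}).
#' @export
fast_attractor <- function(Ca, x, params, pert = perturbation(),
                           V_range = c(-90, 20), t_transient = 20e3,
                           t_measure = 10e3) {
  Vs <- seq(V_range[1], V_range[2], by = 0.25)
  f <- vapply(Vs, fast_balance, numeric(1), params = params, x = x, Ca = Ca,
              pert = pert)
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  eq <- lapply(idx, function(i) {
    r <- uniroot(fast_balance, c(Vs[i], Vs[i + 1]), params = params, x = x,
                 Ca = Ca, pert = pert, tol = 1e-10)
    V <- r$root
    J <- numeric_jacobian(function(v) fast_rhs(v, params, x, Ca, pert),
                          c(V, h_inf(V), n_inf(V), y_inf(V)))
    lam <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(V = V, stable = lam < 0, max_re_eig = lam)
  })
  eq <- if (length(eq)) do.call(rbind, eq) else
    data.frame(V = numeric(0), stable = logical(0), max_re_eig = numeric(0))

  orbit <- fast_orbit(Ca, x, params, pert, t_transient, t_measure)
  structure(list(Ca = Ca, x = x, equilibria = eq, orbit = orbit,
                 pert = pert),
            class = "manifold_sample")
}

numeric_jacobian <- function(f, x0, eps = 1e-6) {
  n <- length(x0)
  f0 <- f(x0)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    dx <- eps * max(1, abs(x0[j]))
    xp <- x0; xp[j] <- xp[j] + dx
    J[, j] <- (f(xp) - f0) / dx
  }
  J
}

# probe the stable spiking orbit of the frozen fast subsystem
fast_orbit <- function(Ca, x, params, pert, t_transient = 20e3,
                       t_measure = 10e3) {
  init <- sin_state(V = -45, x = x, Ca = Ca, params = params)
  opts <- solver_options(duration = t_transient + t_measure, dt_out = 0.25,
                         rtol = 1e-8, atol = 1e-10)
  p2 <- params
  p2$Iapp <- params$Iapp + pert$Iapp   # constant current folded into params
  tr <- tryCatch(simulate_cell(p2, init = init, opts = opts,
                               g_pulse = pert$g_syn, E_pulse = pert$E_rev,
                               freeze_slow = TRUE),
                 error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  keep <- tr[, "time"] >= t_transient
  tm <- tr[keep, "time"]; V <- tr[keep, "V"]
  st <- spike_times(tm, V)
  if (length(st) < 3L) return(NULL)
  isi <- diff(st)
  if (max(isi) > 3 * stats::median(isi)) return(NULL)   # not sustained
  # average over the maximal whole number of periods
  t0 <- st[1]; t1 <- st[length(st)]
  seg <- tm >= t0 & tm <= t1
  structure(list(T = mean(isi), V_mean = trap_mean(tm[seg], V[seg]),
                 xinf_mean = trap_mean(tm[seg],
                                       x_inf(V[seg], params$delta_x)),
                 n_periods = length(st) - 1L),
            class = "fast_orbit")
}

trap_mean <- function(t, y) {
  if (length(t) < 2L) return(mean(y))
  dt <- diff(t)
  sum((y[-1] + y[-length(y)]) / 2 * dt) / sum(dt)
}

#' SNIC boundary of the frozen fast subsystem
#'
#' For each calcium value, bisects in the slow gate x on the indicator
#' "the fast subsystem sustains spiking" to locate the saddle-node-on-
#' invariant-circle boundary separating tonic spiking (above the curve)
#' from hyperpolarized quiescence (below).
#'
#' @param params a \code{\link{sin_params}} object.
#' @param Ca_grid calcium values at which to bisect.
#' @param pert a \code{\link{perturbation}}.
#' @param x_range bracket for the bisection.
#' @param tol bisection tolerance in x.
#' @return Data frame with columns \code{Ca} and \code{x} (NA where the
#'   indicator does not change over the bracket).
#' @export
snic_curve <- function(params, Ca_grid = seq(0.2, 1.6, by = 0.1),
                       pert = perturbation(), x_range = c(0.005, 0.995),
                       tol = 1e-4) {
  spikes_at <- function(Ca, x) {
    orb <- fast_orbit(Ca, x, params, pert, t_transient = 10e3,
                      t_measure = 10e3)
    !is.null(orb)
  }
  xs <- vapply(Ca_grid, function(Ca) {
    lo <- x_range[1]; hi <- x_range[2]
    if (spikes_at(Ca, lo) || !spikes_at(Ca, hi)) return(NA_real_)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (spikes_at(Ca, mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(Ca = Ca_grid, x = xs)
}

#' Slow-plane nullclines of the swim interneuron model
#'
#' Computes the four organizing curves of the slow (Ca, x) phase plane
#' under an optional constant perturbation:
#' \itemize{
#'   \item the x-nullcline traced along the fast equilibrium manifold
#'     (closed form, parameterized by the equilibrium voltage), with
#'     per-point fast-subsystem stability;
#'   \item the averaged x-nullcline on the spiking manifold: points where
#'     the orbit-averaged \code{x_inf(V)} equals x;
#'   \item the calcium nullcline \code{Ca = Kc x (ECa - V + delta_Ca)}
#'     with V taken from the locally relevant manifold (equilibrium branch
#'     below the SNIC boundary, orbit average above);
#'   \item the SNIC curve itself.
#' }
#'
#' @param params a \code{\link{sin_params}} object.
#' @param pert a \code{\link{perturbation}}.
#' @param V_grid voltage parameterization of the equilibrium manifold.
#' @param Ca_grid calcium grid for the averaged nullcline and SNIC curve.
#' @param geometry optional \code{nullcline_set} computed at the same
#'   \code{delta_x}, perturbation and conductances whose fast-subsystem
#'   geometry (x-nullcline, averaged curve, SNIC boundary) is reused: the
#'   frozen fast subsystem does not involve \code{delta_Ca}, so scanning
#'   \code{delta_Ca} only moves the calcium nullcline.
#' @return An object of class \code{nullcline_set}: list with data frames
#'   \code{x_null} (V, Ca, x, stable), \code{x_avg} (Ca, x, V_mean, T),
#'   \code{ca_null} (Ca, x), \code{snic} (Ca, x), plus the perturbation
#'   context and parameters.
#' @export
slow_nullclines <- function(params, pert = perturbation(),
                            V_grid = seq(-85, -25, by = 0.25),
                            Ca_grid = seq(0.2, 1.6, by = 0.1),
                            geometry = NULL) {
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "nullcline_set"),
              geometry$params$delta_x == params$delta_x)
    xn <- geometry$x_null
    sn <- geometry$snic
    xa <- geometry$x_avg
  } else {
    xn <- x_nullcline(params, pert, V_grid)
    if (!nrow(xn)) stop("empty manifold sweep over the voltage grid",
                        call. = FALSE)
    sn <- snic_curve(params, Ca_grid, pert)
    xa <- x_avg_nullcline(params, pert, Ca_grid, sn)
  }
  cn <- ca_nullcline(params, pert, xn, xa, sn)
  structure(list(x_null = xn, x_avg = xa, ca_null = cn, snic = sn,
                 pert = pert, params = params),
            class = "nullcline_set")
}

# x-nullcline in closed form: on the equilibrium manifold with x = x_inf(V)
x_nullcline <- function(params, pert, V_grid) {
  rows <- lapply(V_grid, function(V) {
    x <- x_inf(V, params$delta_x)
    st <- c(V = V, h = h_inf(V), n = n_inf(V), y = y_inf(V), x = x, Ca = 0)
    I <- currents(st, params)
    R <- -(I[["I_I"]] + I[["I_K"]] + I[["I_h"]] + I[["I_leak"]] +
             I[["I_T"]]) -
      pert$g_syn * (V - pert$E_rev) + pert$Iapp + params$Iapp
    ct <- R / (params$gKCa * (V - params$EK))
    if (!is.finite(ct) || ct <= 0 || ct >= 1) return(NULL)
    Ca <- 0.5 * ct / (1 - ct)
    J <- numeric_jacobian(function(v) fast_rhs(v, params, x, Ca, pert),
                          c(V, h_inf(V), n_inf(V), y_inf(V)))
    lam <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(V = V, Ca = Ca, x = x, stable = lam < 0)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# averaged nullcline: x such that the orbit average of x_inf(V) equals x
x_avg_nullcline <- function(params, pert, Ca_grid, snic) {
  rows <- lapply(seq_along(Ca_grid), function(i) {
    Ca <- Ca_grid[i]
    x_lo <- snic$x[i]
    if (is.na(x_lo)) x_lo <- 0.05
    g <- function(x) {
      orb <- fast_orbit(Ca, x, params, pert, t_transient = 10e3,
                        t_measure = 10e3)
      if (is.null(orb)) return(NA_real_)
      orb$xinf_mean - x
    }
    lo <- min(x_lo + 0.02, 0.9); hi <- 0.995
    glo <- g(lo); ghi <- g(hi)
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(NULL)
    for (k in 1:14) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (!is.finite(gm)) break
      if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
    }
    x <- (lo + hi) / 2
    orb <- fast_orbit(Ca, x, params, pert, t_transient = 10e3,
                      t_measure = 10e3)
    if (is.null(orb)) return(NULL)
    data.frame(Ca = Ca, x = x, V_mean = orb$V_mean, T = orb$T)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) data.frame(Ca = numeric(0), x = numeric(0),
                               V_mean = numeric(0), T = numeric(0))
  else out
}

# calcium nullcline with V from the locally relevant manifold
ca_nullcline <- function(params, pert, xn, xa, snic) {
  x_grid <- seq(0.02, 0.98, by = 0.02)
  Vlow <- function(x) {
    # equilibrium-branch voltage: hyperpolarized solution at this x level
    i <- which.min(abs(xn$x - x))
    xn$V[i]
  }
  Vhigh <- function(x) {
    if (!nrow(xa)) return(NA_real_)
    i <- which.min(abs(xa$x - x))
    xa$V_mean[i]
  }
  rows <- lapply(x_grid, function(x) {
    # fixed-point iteration: Ca depends on V, V on which manifold is local
    Ca <- params$Kc * x * (params$ECa + 50 + params$delta_Ca)
    for (k in 1:12) {
      xs <- stats::approx(snic$Ca, snic$x, xout = Ca, rule = 2)$y
      V <- if (!is.na(xs) && x > xs && is.finite(Vhigh(x))) Vhigh(x)
           else Vlow(x)
      Ca_new <- params$Kc * x * (params$ECa - V + params$delta_Ca)
      if (!is.finite(Ca_new) || Ca_new < 0) return(NULL)
      if (abs(Ca_new - Ca) < 1e-6) { Ca <- Ca_new; break }
      Ca <- Ca_new
    }
    data.frame(Ca = Ca, x = x)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' @export
print.nullcline_set <- function(x, ...) {
  cat(sprintf(paste0("slow-plane nullclines (Iapp=%g, g_syn=%g):\n",
                     "  x-nullcline: %d points (%d stable), knees: %d\n",
                     "  averaged <x>: %d points | Ca-nullcline: %d points",
                     " | SNIC: %d points\n"),
              x$pert$Iapp, x$pert$g_syn, nrow(x$x_null),
              sum(x$x_null$stable), knee_count(x),
              nrow(x$x_avg), nrow(x$ca_null), sum(is.finite(x$snic$x))))
  invisible(x)
}

#' @export
plot.nullcline_set <- function(x, ...) {
  rngx <- range(c(x$x_null$x, x$snic$x, x$x_avg$x), na.rm = TRUE)
  rngc <- range(c(x$x_null$Ca, x$ca_null$Ca), na.rm = TRUE)
  graphics::plot(NA, xlim = rngc, ylim = rngx, xlab = "[Ca]", ylab = "x",
                 ...)
  with(x$x_null[x$x_null$stable, ],
       graphics::points(Ca, x, pch = 16, cex = 0.3, col = "navy"))
  with(x$x_null[!x$x_null$stable, ],
       graphics::points(Ca, x, pch = 1, cex = 0.3, col = "navy"))
  graphics::lines(x$x_avg$Ca, x$x_avg$x, col = "dodgerblue", lwd = 2)
  graphics::lines(x$ca_null$Ca, x$ca_null$x, col = "grey40")
  graphics::lines(x$snic$Ca, x$snic$x, col = "firebrick", lty = 2)
  graphics::legend("topleft",
                   legend = c("x' = 0 (stable/unstable)", "<x> average",
                              "[Ca]' = 0", "SNIC"),
                   col = c("navy", "dodgerblue", "grey40", "firebrick"),
                   lty = c(NA, 1, 1, 2), pch = c(16, NA, NA, NA),
                   cex = 0.8, bg = "white")
  invisible(x)
}

#' Knees (folds) of the x-nullcline
#'
#' Counts sign changes of dCa along the x-nullcline traced by voltage: the
#' folds of the Sigma-shaped curve in the (Ca, x) plane. Inhibitory
#' synaptic drive straightens the nullcline and removes its upper knees.
#'
#' @param nullclines a \code{nullcline_set}.
#' @param span running-mean smoothing half-width (points) applied to Ca
#'   before differencing.
#' @return Integer knee count.
#' @export
knee_count <- function(nullclines, span = 5) {
  ca <- nullclines$x_null$Ca
  if (length(ca) < 2 * span + 3) return(0L)
  ks <- stats::filter(ca, rep(1 / (2 * span + 1), 2 * span + 1),
                      sides = 2)
  d <- diff(ks[!is.na(ks)])
  d <- d[abs(d) > 1e-8]
  sum(diff(sign(d)) != 0)
}

#' Predict the activity regime from the slow phase plane
#'
#' Applies the slow-plane reading rules: a stable full-system equilibrium
#' below the SNIC boundary predicts hyperpolarized quiescence; a stable
#' zero of the averaged calcium drift on the spiking manifold (the
#' intersection of the calcium nullcline with the averaged x-nullcline)
#' predicts tonic spiking; otherwise the slow flow has no stable resting
#' point on either manifold and the model is predicted to oscillate
#' (bursting or subthreshold cycling).
#'
#' @param nullclines a \code{nullcline_set} from
#'   \code{\link{slow_nullclines}}.
#' @return Character: \code{"quiescent"}, \code{"tonic"},
#'   \code{"oscillatory"}, or \code{"inconclusive"} when no structure is
#'   found in the window.
#' @export
predict_activity_from_plane <- function(nullclines) {
  params <- nullclines$params
  pert <- nullclines$pert
  eqs <- full_equilibria(params, pert)
  quiesc <- FALSE
  if (nrow(eqs)) {
    for (i in seq_len(nrow(eqs))) {
      if (!eqs$stable[i]) next
      xs <- stats::approx(nullclines$snic$Ca, nullclines$snic$x,
                          xout = eqs$Ca[i], rule = 2)$y
      if (is.na(xs) || eqs$x[i] < xs) quiesc <- TRUE
    }
  }
  if (quiesc) return("quiescent")
  xa <- nullclines$x_avg
  if (nrow(xa) >= 2) {
    xa <- xa[order(xa$Ca), ]
    drift <- params$Kc * xa$x * (params$ECa - xa$V_mean +
                                   params$delta_Ca) - xa$Ca
    s <- sign(drift)
    cross <- which(s[-1] * s[-length(s)] < 0)
    # stable tonic point: averaged Ca-drift decreasing through zero
    if (any(drift[cross] > 0 & drift[cross + 1] < 0)) return("tonic")
    # the averaged curve ends where the orbit family collapses into the
    # equilibrium manifold; a near-balanced drift at that fold means the
    # slow flow funnels into a tight orbit there (tonic), while a strongly
    # positive drift sends it around a hysteretic burst loop
    if (drift[length(drift)] > 0 && drift[length(drift)] < 0.15)
      return("tonic")
  }
  if (!nrow(eqs) && !nrow(xa)) return("inconclusive")
  "oscillatory"
}

# full-system equilibria parameterized by voltage: every gating variable at
# its steady state and Ca at its influx balance
full_equilibria <- function(params, pert, V_range = c(-80, -20)) {
  bal <- function(V) {
    x <- x_inf(V, params$delta_x)
    Ca <- max(params$Kc * x * (params$ECa - V + params$delta_Ca), 0)
    st <- c(V = V, h = h_inf(V), n = n_inf(V), y = y_inf(V), x = x, Ca = Ca)
    I <- currents(st, params)
    -sum(I) - pert$g_syn * (V - pert$E_rev) + pert$Iapp + params$Iapp
  }
  Vs <- seq(V_range[1], V_range[2], by = 0.1)
  f <- vapply(Vs, bal, numeric(1))
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  rows <- lapply(idx, function(i) {
    V <- uniroot(bal, c(Vs[i], Vs[i + 1]), tol = 1e-12)$root
    x <- x_inf(V, params$delta_x)
    Ca <- max(params$Kc * x * (params$ECa - V + params$delta_Ca), 0)
    st <- sin_state(V = V, x = x, Ca = Ca, params = params)
    J <- numeric_jacobian(function(s) {
      ss <- c(V = s[[1]], h = s[[2]], n = s[[3]], y = s[[4]], x = s[[5]],
              Ca = s[[6]])
      Isyn <- pert$g_syn * (s[[1]] - pert$E_rev) - pert$Iapp
      unname(sin_rhs_raw(ss, params, I_syn_total = Isyn))
    }, unclass(st))
    lam <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(V = V, x = x, Ca = Ca, stable = lam < 0, max_re_eig = lam)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(V = numeric(0), x = numeric(0),
                               Ca = numeric(0), stable = logical(0),
                               max_re_eig = numeric(0))
  else out
}
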