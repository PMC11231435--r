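#' Classification thresholds
#'
#' The trace classifier's conventions, centralized so every module (single
#' cell, scans, networks) shares them: the transient discarded before
#' analysis, the minimal analysis window, the subthreshold-oscillation
#' amplitude cutoff (peak-to-peak, mV), the ISI-gap factor that delimits
#' bursts, and the ISI coefficient-of-variation cutoff separating tonic from
#' irregular spiking.
#'
#' @param transient discarded initial transient (model units).
#' @param window minimal analysis window after the transient (model units).
#' @param amp_sub subthreshold amplitude cutoff (mV, peak-to-peak).
#' @param gap_factor burst-delimiting ISI gap factor.
#' @param cv_tonic ISI coefficient-of-variation cutoff for tonic spiking.
#' @return A named list of thresholds.
#' @export
classifier_options <- function(transient = 40e3, window = 60e3, amp_sub = 2,
                               gap_factor = 3, cv_tonic = 0.15) {
  list(transient = transient, window = window, amp_sub = amp_sub,
       gap_factor = gap_factor, cv_tonic = cv_tonic)
}

#' Classify a voltage trace into an activity regime
#'
#' Applies the regime rules to the post-transient window of a trace:
#' \itemize{
#'   \item no spikes, peak-to-peak voltage < \code{amp_sub} mV: quiescent;
#'   \item no spikes, amplitude >= \code{amp_sub} mV with at least three
#'     oscillation cycles: subthreshold;
#'   \item spikes with ISI coefficient of variation < \code{cv_tonic} and no
#'     gap exceeding \code{gap_factor} times the median ISI: tonic;
#'   \item spikes split by the ISI-gap rule into two or more recurring
#'     groups: bursting.
#' }
#' Traces that spike but fit neither the tonic nor the bursting pattern
#' (single spike groups with irregular ISIs, one-off spike trains) fall back
#' to the closest category by the same rules: a single group is tonic-like
#' if its spiking fills the window, otherwise quiescent/subthreshold by the
#' post-spiking voltage amplitude.
#'
#' @param trace a \code{sin_trace} (column \code{V}) or any matrix with
#'   \code{time} and a voltage column.
#' @param copts classifier thresholds from \code{\link{classifier_options}}.
#' @param vcol voltage column name.
#' @return An object of class \code{activity_label}: list with \code{label}
#'   (one of \code{"tonic"}, \code{"bursting"}, \code{"quiescent"},
#'   \code{"subthreshold"}) and supporting metrics.
#' @examples
#' tr <- cbind(time = 0:110000, V = rep(-60, 110001))
#' classify_trace(tr)$label      # "quiescent"
#' @export
classify_trace <- function(trace, copts = classifier_options(), vcol = "V") {
  time <- trace[, "time"]; V <- trace[, vcol]
  t_end <- time[length(time)]
  if (t_end - time[1] < copts$transient + copts$window)
    stop("trace too short: need >= ", copts$transient + copts$window,
         " model units (transient + analysis window)", call. = FALSE)
  keep <- time >= time[1] + copts$transient
  time <- time[keep]; V <- V[keep]

  st <- spike_times(time, V)
  amp <- diff(range(V))
  metrics <- list(n_spikes = length(st), amplitude = amp,
                  cv = NA_real_, median_isi = NA_real_, n_groups = 1L)

  if (length(st) == 0L) {
    label <- if (amp < copts$amp_sub) "quiescent" else
      if (count_cycles(time, V) >= 3L) "subthreshold" else "quiescent"
    return(new_label(label, metrics))
  }
  s <- isi_stats(st)
  metrics$cv <- s$cv; metrics$median_isi <- s$median
  if (length(st) == 1L) {
    # a lone spike in the window: judge by what the voltage does otherwise
    label <- if (amp_excluding_spikes(time, V, st) < copts$amp_sub)
      "quiescent" else "subthreshold"
    return(new_label(label, metrics))
  }
  groups <- split_bursts(st, copts$gap_factor)
  metrics$n_groups <- length(groups)
  no_gap <- length(groups) == 1L
  if (no_gap && s$cv < copts$cv_tonic)
    return(new_label("tonic", metrics))
  multi <- lengths(groups) >= 2
  if (length(groups) >= 2L && sum(multi) >= 2L)
    return(new_label("bursting", metrics))
  if (no_gap)                      # irregular but gap-free spiking
    return(new_label("tonic", metrics))
  # gaps present but groups do not recur: one-off train; judge the tail
  label <- if (amp_excluding_spikes(time, V, st) < copts$amp_sub)
    "quiescent" else "subthreshold"
  new_label(label, metrics)
}

new_label <- function(label, metrics) {
  structure(c(list(label = label), metrics), class = "activity_label")
}

#' @export
print.activity_label <- function(x, ...) {
  cat(sprintf("activity: %s (%d spikes, amplitude %.2f mV",
              x$label, x$n_spikes, x$amplitude))
  if (!is.na(x$cv)) cat(sprintf(", ISI CV %.3f", x$cv))
  cat(")\n")
  invisible(x)
}

# count oscillation cycles as upward mean-crossings of the voltage
count_cycles <- function(time, V) {
  m <- mean(range(V))
  sum(V[-length(V)] < m & V[-1] >= m)
}

# peak-to-peak amplitude outside +-100-unit spike neighbourhoods
amp_excluding_spikes <- function(time, V, st, halo = 100) {
  keep <- rep(TRUE, length(time))
  for (s in st) keep <- keep & (abs(time - s) > halo)
  if (!any(keep)) return(diff(range(V)))
  diff(range(V[keep]))
}

#' Activity regime diagram over the (delta_Ca, delta_x) plane
#'
#' Simulates and classifies the SiN model on a rectangular grid of the two
#' slow-subsystem shift parameters, reproducing the model's two-parameter
#' regime diagram (tonic-spiking / bursting / quiescent, with a
#' subthreshold-oscillation fringe).
#'
#' @param params base \code{\link{sin_params}} (delta values are overridden
#'   per node).
#' @param delta_Ca,delta_x grid vectors (strictly monotone).
#' @param opts solver options per node; the default (400,000 model units at
#'   a tolerance loose enough for a scan but validated for label stability)
#'   gives the slow subsystem several burst periods after its transient.
#' @param copts classifier thresholds; scans discard a long transient
#'   (250,000 units) because slow-plane transients near regime boundaries
#'   take many burst periods to settle.
#' @param cache optional directory for per-node caching (scan is resumable).
#' @return A \code{regime_diagram}: list with the grids and a character
#'   label matrix (delta_Ca in rows, delta_x in columns; solver failures
#'   are recorded as NA).
#' @export
scan_diagram <- function(params = sin_params(),
                         delta_Ca = seq(-80, 150, by = 10),
                         delta_x = seq(-5, 0, by = 0.5),
                         opts = solver_options(duration = 400e3, dt_out = 1,
                                               rtol = 1e-7, atol = 1e-9),
                         copts = classifier_options(transient = 250e3,
                                                    window = 140e3),
                         cache = NULL) {
  stopifnot(all(diff(delta_Ca) > 0), all(diff(delta_x) > 0))
  lab <- matrix(NA_character_, length(delta_Ca), length(delta_x),
                dimnames = list(paste0("dCa=", delta_Ca),
                                paste0("dx=", delta_x)))
  for (j in seq_along(delta_x)) for (i in seq_along(delta_Ca)) {
    key <- NULL
    if (!is.null(cache)) {
      key <- file.path(cache, sprintf("node_%g_%g.txt",
                                      delta_Ca[i], delta_x[j]))
      if (file.exists(key)) {
        lab[i, j] <- readLines(key, n = 1L)
        next
      }
    }
    p <- params; p$delta_Ca <- delta_Ca[i]; p$delta_x <- delta_x[j]
    lab[i, j] <- tryCatch(
      classify_trace(simulate_cell(p, opts = opts), copts)$label,
      error = function(e) NA_character_)
    if (!is.null(key)) {
      dir.create(dirname(key), showWarnings = FALSE, recursive = TRUE)
      writeLines(lab[i, j], key)
    }
  }
  structure(list(delta_Ca = delta_Ca, delta_x = delta_x, labels = lab,
                 transient = copts$transient, window = copts$window),
            class = "regime_diagram")
}

#' @export
print.regime_diagram <- function(x, ...) {
  cat(sprintf("regime diagram: %d x %d nodes\n",
              length(x$delta_Ca), length(x$delta_x)))
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' @export
plot.regime_diagram <- function(x, ...) {
  levs <- c("quiescent", "subthreshold", "bursting", "tonic")
  z <- matrix(match(x$labels, levs), nrow(x$labels), ncol(x$labels))
  graphics::image(x$delta_Ca, x$delta_x, z, zlim = c(1, 4),
                  col = c("grey85", "goldenrod1", "firebrick", "steelblue"),
                  xlab = expression(Delta[Ca] ~ "(mV)"),
                  ylab = expression(Delta[x] ~ "(mV)"), ...)
  graphics::legend("topright", legend = levs, fill =
                     c("grey85", "goldenrod1", "firebrick", "steelblue"),
                   bg = "white", cex = 0.8)
  invisible(x)
}

#' Transition routes along delta_Ca sweeps
#'
#' For each requested \code{delta_x} level, sweeps \code{delta_Ca} upward,
#' classifies every node, and compresses the label sequence by run-length
#' encoding, giving the regime order the model traverses (e.g.
#' tonic -> bursting).
#'
#' @param params base parameters.
#' @param delta_x_levels levels at which to sweep.
#' @param delta_Ca ascending sweep values.
#' @param ... passed to \code{\link{scan_diagram}} (e.g. \code{opts},
#'   \code{cache}).
#' @return Named list (one element per level) of character vectors: the
#'   run-length-encoded regime sequences.
#' @export
transition_routes <- function(params = sin_params(),
                              delta_x_levels = c(0, -2, -4),
                              delta_Ca = seq(-80, 50, by = 10), ...) {
  stopifnot(all(diff(delta_Ca) > 0))
  out <- lapply(delta_x_levels, function(dx) {
    d <- scan_diagram(params, delta_Ca = delta_Ca, delta_x = dx, ...)
    rle(as.vector(d$labels))$values
  })
  names(out) <- paste0("dx=", delta_x_levels)
  out
}
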