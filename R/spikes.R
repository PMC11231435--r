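#' Spike detection on a voltage trace
#'
#' A spike is an upward crossing of the -10 mV threshold with a 5-model-unit
#' refractory lockout. The threshold sits between the spike-generation
#' threshold (about -40 mV) and the spike peak (about +40 mV), so
#' subthreshold oscillations never register as spikes. Crossing times are
#' linearly interpolated between grid samples.
#'
#' @param time,V numeric vectors of equal length (regular or irregular grid).
#' @param threshold crossing threshold (mV).
#' @param refractory minimal spacing between detected spikes (model units).
#' @return Numeric vector of spike times (possibly empty).
#' @examples
#' t <- seq(0, 1000, by = 1)
#' spike_times(t, 30 * sin(t / 20) - 10 + 10 * (sin(t / 20) > 0))
#' @export
spike_times <- function(time, V, threshold = -10, refractory = 5) {
  n <- length(V)
  if (n < 2L) return(numeric(0))
  up <- which(V[-n] < threshold & V[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  frac <- (threshold - V[up]) / (V[up + 1L] - V[up])
  st <- time[up] + frac * (time[up + 1L] - time[up])
  keep <- c(TRUE, diff(st) >= refractory)
  while (!all(keep)) {            # enforce lockout after thinning
    st <- st[keep]
    keep <- c(TRUE, diff(st) >= refractory)
  }
  st
}

# interspike intervals and basic statistics for classification
isi_stats <- function(st) {
  if (length(st) < 2L)
    return(list(n = length(st), isi = numeric(0), cv = NA_real_,
                median = NA_real_))
  isi <- diff(st)
  list(n = length(st), isi = isi, cv = stats::sd(isi) / mean(isi),
       median = stats::median(isi))
}

# split spike times into bursts with the shared ISI-gap rule:
# gaps exceeding gap_factor * median(ISI) delimit bursts
split_bursts <- function(st, gap_factor = 3) {
  if (length(st) < 2L) return(list(st))
  isi <- diff(st)
  gap <- which(isi > gap_factor * stats::median(isi))
  if (!length(gap)) return(list(st))
  idx <- cbind(c(1, gap + 1), c(gap, length(st)))
  lapply(seq_len(nrow(idx)), function(i) st[idx[i, 1]:idx[i, 2]])
}
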