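#' Square-pulse presynaptic drive waveform
#'
#' Builds a piecewise-constant voltage command emulating a presynaptic cell
#' receiving depolarizing square pulses of given amplitudes: the voltage
#' sits at \code{V_base} between pulses and jumps to \code{V_base +
#' amplitude} during each pulse. Used to exercise synapse gate kinetics
#' without a presynaptic cell.
#'
#' @param amplitudes pulse amplitudes (mV above base); may be empty for a
#'   flat subthreshold command.
#' @param widths pulse widths (model units, recycled).
#' @param gaps gaps between pulses (model units, recycled; the first gap
#'   precedes the first pulse).
#' @param V_base baseline voltage (mV).
#' @return A \code{drive_waveform}: step function with jump times \code{t}
#'   and levels \code{V} (level i holds on [t_i, t_{i+1})).
#' @examples
#' w <- pulse_fixture(c(80, 90, 100), widths = 500, gaps = 1000)
#' waveform_at(w, c(0, 1200, 1600))
#' @export
pulse_fixture <- function(amplitudes = numeric(0), widths = 500,
                          gaps = 1000, V_base = -60) {
  n <- length(amplitudes)
  widths <- rep_len(widths, max(n, 1L))
  gaps <- rep_len(gaps, max(n, 1L))
  if (any(widths < 0) || any(gaps < 0))
    stop("widths and gaps must be non-negative", call. = FALSE)
  t <- 0; V <- V_base
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + gaps[i]
    t <- c(t, cur); V <- c(V, V_base + amplitudes[i])
    cur <- cur + widths[i]
    t <- c(t, cur); V <- c(V, V_base)
  }
  structure(list(t = t, V = V,
                 end = cur + if (n) gaps[1] else 1000),
            class = "drive_waveform")
}

#' @rdname pulse_fixture
#' @param waveform a \code{drive_waveform}.
#' @param time query times.
#' @export
waveform_at <- function(waveform, time) {
  idx <- findInterval(time, waveform$t)
  waveform$V[pmax(idx, 1L)]
}

waveform_end <- function(waveform) waveform$end
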