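# Second-order (biquad) IIR notch from center frequency and -3 dB
# bandwidth (RBJ cookbook): zeros exactly on the unit circle at the
# center frequency, unit gain at DC and Nyquist.
design_notch <- function(center_hz, bandwidth_hz, fs_hz) {
  if (center_hz <= 0 || center_hz >= fs_hz / 2)
    stop_ft("notch center must lie in (0, Nyquist); got ", center_hz,
            " Hz at fs = ", fs_hz, " Hz")
  if (bandwidth_hz <= 0) stop_ft("notch bandwidth must be positive")
  w0 <- 2 * pi * center_hz / fs_hz
  alpha <- sin(w0) * bandwidth_hz / (2 * center_hz)  # sin(w0)/(2*Q), Q = f0/bw
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a, center_hz = center_hz, bandwidth_hz = bandwidth_hz,
       fs_hz = fs_hz)
}

# Forward-backward (zero-phase) application of one biquad with odd
# reflection padding of three filter lengths (filter length taken as
# fs / bandwidth samples, the scale of the notch impulse response).
filtfilt_notch <- function(x, flt) {
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * flt$fs_hz / flt$bandwidth_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  # filter around the first sample so the DC component (unit gain) sees no
  # start-up transient from the zero initial filter state
  run <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(flt$b, flt$a, v - v0)) + v0
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

trace_values <- function(trace) {
  if (inherits(trace, c("raw_trace", "dff_trace"))) trace$values else trace
}

replace_values <- function(trace, values) {
  if (inherits(trace, c("raw_trace", "dff_trace"))) {
    trace$values <- values
    trace
  } else values
}

#' Second-order zero-phase notch filter
#'
#' Applies a second-order IIR notch (designed from center frequency and
#' -3 dB bandwidth) forward and backward so the net filter has zero phase
#' and does not shift transient timings. DC gain is exactly 1. Edge
#' effects are handled by odd reflection padding of three filter lengths.
#'
#' @param trace a [raw_trace()], `dff_trace`, or bare numeric vector (in
#'   which case `fs_hz` must be given).
#' @param center_hz notch center frequency (0 < center < Nyquist).
#' @param bandwidth_hz -3 dB bandwidth (> 0).
#' @param fs_hz sampling rate; taken from the trace when omitted.
#' @return The filtered trace, same type as the input.
#' @export
notch_filter <- function(trace, center_hz, bandwidth_hz, fs_hz = NULL) {
  if (is.null(fs_hz)) {
    if (!inherits(trace, c("raw_trace", "dff_trace")))
      stop_ft("fs_hz required for bare numeric traces")
    fs_hz <- trace$frame_rate_hz
  }
  flt <- design_notch(center_hz, bandwidth_hz, fs_hz)
  replace_values(trace, filtfilt_notch(trace_values(trace), flt))
}

#' Remove the slow brain-motion oscillation
#'
#' Roughly half of bath recordings show a slow multiplicative oscillation
#' of the whole brain at about 0.04 Hz. This applies the standard notch for
#' it: second order, centered at 0.04 Hz with a 0.005 Hz bandwidth,
#' zero phase. Filtering is never applied silently by the pipeline; see
#' [motion_oscillation_advisory()].
#'
#' @param trace a trace as for [notch_filter()].
#' @param fs_hz sampling rate for bare numeric input.
#' @return Filtered trace.
#' @export
remove_motion_oscillation <- function(trace, fs_hz = NULL) {
  notch_filter(trace, center_hz = 0.04, bandwidth_hz = 0.005, fs_hz = fs_hz)
}

#' Remove the stimulus-response bands
#'
#' For the basal-calcium readout in visual experiments the responses to
#' the 5-s flash train occupy narrow bands at the stimulus rate
#' (0.19-0.21 Hz) and its first harmonic (0.38-0.42 Hz). These are removed
#' by a cascade of two second-order zero-phase notches centered at 0.20 Hz
#' (bandwidth 0.02 Hz) and 0.40 Hz (bandwidth 0.04 Hz).
#'
#' @param trace a trace as for [notch_filter()].
#' @param fs_hz sampling rate for bare numeric input.
#' @return Filtered trace.
#' @export
remove_stimulus_band <- function(trace, fs_hz = NULL) {
  out <- notch_filter(trace, center_hz = 0.20, bandwidth_hz = 0.02,
                      fs_hz = fs_hz)
  notch_filter(out, center_hz = 0.40, bandwidth_hz = 0.04, fs_hz = fs_hz)
}

#' Advisory detector for the 0.04 Hz motion oscillation
#'
#' Flags a recording when its smoothed periodogram has a peak within
#' 0.04 +/- 0.01 Hz exceeding `ratio` times the median spectral density.
#' The advisory never triggers filtering by itself; the motion notch is
#' applied per recording under explicit control.
#'
#' @param trace a [raw_trace()] or numeric vector.
#' @param fs_hz sampling rate for bare numeric input.
#' @param ratio detection threshold relative to the median spectral
#'   density (default 5).
#' @return A list: `advise` (logical), `peak_hz`, `peak_ratio`.
#' @export
motion_oscillation_advisory <- function(trace, fs_hz = NULL, ratio = 5) {
  if (is.null(fs_hz)) fs_hz <- trace$frame_rate_hz
  v <- trace_values(trace)
  sp <- stats::spec.pgram(stats::ts(v - mean(v), frequency = fs_hz),
                          spans = c(7, 7), plot = FALSE, taper = 0.1,
                          detrend = TRUE)
  band <- sp$freq >= 0.03 & sp$freq <= 0.05
  if (!any(band)) return(list(advise = FALSE, peak_hz = NA_real_,
                              peak_ratio = NA_real_))
  med <- stats::median(sp$spec)
  i <- which(band)[which.max(sp$spec[band])]
  pr <- sp$spec[i] / med
  list(advise = pr > ratio, peak_hz = sp$freq[i], peak_ratio = pr)
}
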