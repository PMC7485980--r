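#' dF/F trace container
#'
#' Fractional fluorescence change (F_t - F0) / F0 per frame, with the
#' baseline F0 and baseline rule recorded.
#'
#' @param values dF/F per frame (dimensionless, finite).
#' @param f0 baseline fluorescence (> 0).
#' @param baseline_rule `"bath"` or `"visual"`.
#' @param frame_rate_hz frames per second.
#' @param t0_s start time (s).
#' @param subject_id,group,roi_id metadata labels.
#' @return An object of class `dff_trace`.
#' @export
dff_trace <- function(values, f0, baseline_rule, frame_rate_hz, t0_s = 0,
                      subject_id = NA_character_, group = NA_character_,
                      roi_id = NA_integer_) {
  if (!all(is.finite(values))) stop_ft("dF/F values must be finite")
  if (!is.finite(f0) || f0 <= 0) stop_ft("baseline F0 must be positive")
  structure(list(values = as.numeric(values), f0 = f0,
                 baseline_rule = baseline_rule,
                 frame_rate_hz = frame_rate_hz, t0_s = t0_s,
                 subject_id = subject_id, group = group, roi_id = roi_id),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames @ %.3g fps, F0 = %.4g (%s baseline)\n",
              length(x$values), x$frame_rate_hz, x$f0, x$baseline_rule))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, ...) {
  t <- frame_times(length(x$values), x$frame_rate_hz, x$t0_s)
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = expression(Delta * F / F), ...)
  invisible(x)
}

#' dF/F with the bath baseline rule
#'
#' F0 is the mean fluorescence during the first `baseline_duration_s`
#' seconds of the recording (baseline activity before the perfusion
#' change); values are (F_t - F0) / F0.
#'
#' @param trace a [raw_trace()].
#' @param baseline_duration_s baseline window length (default 60 s).
#' @return A [dff_trace()].
#' @export
dff_bath <- function(trace, baseline_duration_s = 60) {
  stopifnot(inherits(trace, "raw_trace"))
  nb <- round(baseline_duration_s * trace$frame_rate_hz)
  if (nb < 1 || nb > length(trace$values))
    stop_ft("trace must span at least the ", baseline_duration_s,
            " s baseline window")
  f0 <- mean(trace$values[seq_len(nb)])
  if (f0 <= 0) stop_ft("baseline F0 is not positive (F0 = ", f0, ")")
  dff_trace((trace$values - f0) / f0, f0 = f0, baseline_rule = "bath",
            frame_rate_hz = trace$frame_rate_hz, t0_s = trace$t0_s,
            subject_id = trace$subject_id, group = trace$group,
            roi_id = trace$roi_id)
}

#' Inter-stimulus baseline segments of epoch 1
#'
#' The visual baseline uses 30 s of non-consecutive quiet time between
#' stimulus presentations in epoch 1. From the gap preceding each epoch-1
#' flash this takes the segment ending 0.5 s before the flash onset,
#' sized so the segments total `baseline_total_s` (2.5 s each for the
#' standard 12-flash epoch); late-gap samples avoid the preceding flash's
#' transient.
#'
#' @param protocol a [stimulus_protocol()].
#' @param baseline_total_s total baseline time required (default 30 s).
#' @return Data frame with columns `start_s`, `end_s` (half-open segments).
#' @export
baseline_segments_visual <- function(protocol, baseline_total_s = 30) {
  ep1 <- protocol$flash_onsets_s[flash_epochs(protocol) == 1L]
  if (length(ep1) == 0) stop_ft("epoch 1 contains no flashes")
  seg_len <- baseline_total_s / length(ep1)
  start <- ep1 - 0.5 - seg_len
  end <- ep1 - 0.5
  if (any(start < 0))
    stop_ft("insufficient inter-stimulus time in epoch 1 for a ",
            baseline_total_s, " s baseline")
  # segments must not reach into the previous flash's response window
  prev_end <- c(-Inf, ep1[-length(ep1)] + protocol$flash_duration_s)
  if (any(start < prev_end))
    stop_ft("insufficient inter-stimulus time in epoch 1 for a ",
            baseline_total_s, " s baseline")
  data.frame(start_s = start, end_s = end)
}

#' dF/F with the visual baseline rule
#'
#' F0 is the mean fluorescence over `baseline_total_s` seconds of
#' non-consecutive inter-stimulus segments of epoch 1 (see
#' [baseline_segments_visual()]); values are (F_t - F0) / F0.
#'
#' @param trace a [raw_trace()].
#' @param protocol a [stimulus_protocol()].
#' @param baseline_total_s total baseline time (default 30 s).
#' @return A [dff_trace()].
#' @export
dff_visual <- function(trace, protocol, baseline_total_s = 30) {
  stopifnot(inherits(trace, "raw_trace"),
            inherits(protocol, "stimulus_protocol"))
  segs <- baseline_segments_visual(protocol, baseline_total_s)
  t <- frame_times(length(trace$values), trace$frame_rate_hz, trace$t0_s)
  in_seg <- rep(FALSE, length(t))
  for (i in seq_len(nrow(segs)))
    in_seg <- in_seg | (t >= segs$start_s[i] & t < segs$end_s[i])
  if (!any(in_seg))
    stop_ft("no trace samples fall inside the epoch-1 baseline segments")
  f0 <- mean(trace$values[in_seg])
  if (f0 <= 0) stop_ft("baseline F0 is not positive (F0 = ", f0, ")")
  dff_trace((trace$values - f0) / f0, f0 = f0, baseline_rule = "visual",
            frame_rate_hz = trace$frame_rate_hz, t0_s = trace$t0_s,
            subject_id = trace$subject_id, group = trace$group,
            roi_id = trace$roi_id)
}

#' Average dF/F traces across ROIs
#'
#' Pointwise mean of the terminal traces of one animal.
#'
#' @param traces list of `dff_trace` objects with equal lengths and frame
#'   rates.
#' @return A single `dff_trace` (f0 = mean of the per-ROI baselines).
#' @export
average_across_rois <- function(traces) {
  stopifnot(length(traces) >= 1, all(vapply(traces, inherits, TRUE, "dff_trace")))
  n <- vapply(traces, function(x) length(x$values), integer(1))
  if (length(unique(n)) != 1) stop_ft("traces have mismatched lengths")
  fr <- vapply(traces, `[[`, numeric(1), "frame_rate_hz")
  if (length(unique(fr)) != 1) stop_ft("traces have mismatched frame rates")
  vals <- rowMeans(do.call(cbind, lapply(traces, `[[`, "values")))
  dff_trace(vals, f0 = mean(vapply(traces, `[[`, numeric(1), "f0")),
            baseline_rule = traces[[1]]$baseline_rule,
            frame_rate_hz = fr[1], t0_s = traces[[1]]$t0_s,
            subject_id = traces[[1]]$subject_id, group = traces[[1]]$group)
}

#' Stimulus-locked epoch-average response
#'
#' For every flash of the requested polarity inside the requested epoch, a
#' window from -0.5 s to +4.9 s around the onset is resampled (linear
#' interpolation) onto a common time base at the recording's frame rate,
#' shifted by its own mean over the 0.5 s preceding the onset (so every
#' response starts aligned at 0 dF/F), and the windows are averaged.
#' Flashes whose window extends past the end of the trace are dropped with
#' a warning.
#'
#' @param dff a `dff_trace`.
#' @param protocol a [stimulus_protocol()].
#' @param epoch epoch index (1-based).
#' @param polarity `"light"` or `"dark"`.
#' @param window_s response window relative to onset (default
#'   `c(-0.5, 4.9)`).
#' @return An object of class `epoch_response`: list with `time_s`,
#'   `value` (mean aligned dF/F), `epoch`, `polarity`, `n_flashes`,
#'   `frame_rate_hz`.
#' @export
stimulus_locked_epoch_average <- function(dff, protocol, epoch, polarity,
                                          window_s = c(-0.5, 4.9)) {
  stopifnot(inherits(dff, "dff_trace"),
            inherits(protocol, "stimulus_protocol"),
            polarity %in% c("light", "dark"))
  sel <- flash_epochs(protocol) == epoch & protocol$polarities == polarity
  onsets <- protocol$flash_onsets_s[sel]
  if (length(onsets) == 0)
    stop_ft("no ", polarity, " flashes in epoch ", epoch)
  fs <- dff$frame_rate_hz
  rel_t <- seq(window_s[1], window_s[2], by = 1 / fs)
  t_end <- dff$t0_s + (length(dff$values) - 1) / fs
  acc <- NULL; used <- 0L
  for (on in onsets) {
    if (on + window_s[2] > t_end || on + window_s[1] < dff$t0_s) {
      warning(sprintf("flash at %.2f s extends outside the trace; dropped", on),
              call. = FALSE)
      next
    }
    w <- sample_trace(dff$values, fs, on + rel_t, t0_s = dff$t0_s)
    pre <- rel_t >= -0.5 & rel_t < 0
    w <- w - mean(w[pre])
    acc <- if (is.null(acc)) w else acc + w
    used <- used + 1L
  }
  if (used == 0L) stop_ft("no usable flashes for epoch ", epoch, " (",
                          polarity, ")")
  structure(list(time_s = rel_t, value = acc / used, epoch = epoch,
                 polarity = polarity, n_flashes = used,
                 frame_rate_hz = fs),
            class = "epoch_response")
}

#' Construct an epoch response directly from samples
#'
#' Mainly for kinetic analysis of externally averaged or analytic
#' responses; the pre-stimulus mean is subtracted so the response is
#' aligned at 0 like the output of [stimulus_locked_epoch_average()].
#'
#' @param time_s time axis relative to flash onset (s).
#' @param value dF/F samples.
#' @param polarity `"light"` or `"dark"`.
#' @param epoch epoch index (default 1).
#' @param align subtract the pre-stimulus (t < 0) mean (default `TRUE`
#'   when any t < 0 samples exist).
#' @return An `epoch_response`.
#' @export
epoch_response <- function(time_s, value, polarity, epoch = 1L,
                           align = any(time_s < 0)) {
  stopifnot(length(time_s) == length(value), polarity %in% c("light", "dark"))
  if (align && any(time_s < 0)) value <- value - mean(value[time_s < 0])
  fs <- if (length(time_s) > 1) 1 / stats::median(diff(time_s)) else NA_real_
  structure(list(time_s = time_s, value = value, epoch = epoch,
                 polarity = polarity, n_flashes = 1L, frame_rate_hz = fs),
            class = "epoch_response")
}

#' @export
print.epoch_response <- function(x, ...) {
  cat(sprintf(
    "<epoch_response> epoch %s, %s flash, %d flashes averaged, [%.1f, %.1f] s\n",
    as.character(x$epoch), x$polarity, x$n_flashes, min(x$time_s),
    max(x$time_s)))
  invisible(x)
}

#' @export
plot.epoch_response <- function(x, ...) {
  graphics::plot(x$time_s, x$value, type = "l", xlab = "time from flash (s)",
                 ylab = expression(Delta * F / F), ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}
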