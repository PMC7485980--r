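# Post-stimulus samples of an epoch response within (0, t_max].
post_window <- function(resp, t_max = Inf) {
  sel <- resp$time_s > 0 & resp$time_s <= t_max
  list(t = resp$time_s[sel], v = resp$value[sel])
}

#' Calcium transient peak size (dark flashes)
#'
#' Difference between the pre-stimulus baseline (0 after alignment) and
#' the maximum post-stimulus dF/F, searched over (0, `w_post`] seconds
#' after the onset. Transients return to basal levels within about a
#' second, so 2 s bounds the primary response by default.
#'
#' @param resp a dark-polarity `epoch_response`.
#' @param w_post primary-extremum search window end (default 2 s).
#' @return List: `value` (dF/F) and `valid`.
#' @export
peak_size <- function(resp, w_post = 2) {
  stopifnot(inherits(resp, "epoch_response"))
  w <- post_window(resp, w_post)
  if (length(w$v) == 0) return(list(value = NA_real_, valid = FALSE))
  list(value = max(w$v), valid = TRUE)
}

#' Calcium trough size (light flashes)
#'
#' Magnitude of the initial calcium decrease: pre-stimulus baseline minus
#' the post-stimulus minimum over (0, `w_post`] s, reported as a
#' non-negative magnitude.
#'
#' @inheritParams peak_size
#' @return List: `value` (dF/F magnitude) and `valid`.
#' @export
trough_size <- function(resp, w_post = 2) {
  stopifnot(inherits(resp, "epoch_response"))
  w <- post_window(resp, w_post)
  if (length(w$v) == 0) return(list(value = NA_real_, valid = FALSE))
  list(value = -min(w$v), valid = TRUE)
}

#' Level-crossing times of the post-stimulus transient
#'
#' The reference span is the post-stimulus peak-to-peak difference
#' (post-stimulus max minus post-stimulus min over (0, 4.9] s). Crossing
#' levels are `min + frac * (max - min)`. Starting at the primary
#' extremum (the max for `direction = "down"`, the min for `"up"`) the
#' first forward crossings of the high and low levels are located by
#' linear interpolation between samples.
#'
#' @param resp an `epoch_response`.
#' @param hi_frac,lo_frac level fractions (defaults 0.9 and 0.1).
#' @param direction `"down"` for decays after a peak, `"up"` for rises
#'   after a trough.
#' @param w_primary search window end for the primary extremum (default
#'   2 s).
#' @return List: `t_hi`, `t_lo` (s, relative to onset), `level_hi`,
#'   `level_lo`, `p2p`, `valid`.
#' @export
crossing_times <- function(resp, hi_frac = 0.9, lo_frac = 0.1,
                           direction = c("down", "up"), w_primary = 2) {
  stopifnot(inherits(resp, "epoch_response"))
  direction <- match.arg(direction)
  w <- post_window(resp)
  bad <- list(t_hi = NA_real_, t_lo = NA_real_, level_hi = NA_real_,
              level_lo = NA_real_, p2p = NA_real_, valid = FALSE)
  if (length(w$v) < 2) return(bad)
  vmax <- max(w$v); vmin <- min(w$v)
  p2p <- vmax - vmin
  if (p2p <= 0) return(bad)
  lev_hi <- vmin + hi_frac * p2p
  lev_lo <- vmin + lo_frac * p2p
  prim <- post_window(resp, w_primary)
  if (length(prim$v) == 0) return(bad)
  i0 <- if (direction == "down") which.max(prim$v) else which.min(prim$v)
  t0 <- prim$t[i0]
  after <- which(w$t >= t0)
  tt <- w$t[after]; vv <- w$v[after]
  cross <- function(level, downward) {
    if (downward) hit <- which(vv[-1] <= level & vv[-length(vv)] > level)
    else hit <- which(vv[-1] >= level & vv[-length(vv)] < level)
    if (length(vv) && ((downward && vv[1] <= level) ||
                       (!downward && vv[1] >= level))) return(tt[1])
    if (length(hit) == 0) return(NA_real_)
    i <- hit[1]
    tt[i] + (level - vv[i]) / (vv[i + 1] - vv[i]) * (tt[i + 1] - tt[i])
  }
  if (direction == "down") {
    t_hi <- cross(lev_hi, TRUE); t_lo <- cross(lev_lo, TRUE)
  } else {
    t_lo <- cross(lev_lo, FALSE); t_hi <- cross(lev_hi, FALSE)
  }
  valid <- is.finite(t_hi) && is.finite(t_lo)
  list(t_hi = t_hi, t_lo = t_lo, level_hi = lev_hi, level_lo = lev_lo,
       p2p = p2p, valid = valid)
}

#' 90-to-10 percent decay time (dark flashes)
#'
#' Time from 90% to 10% of the post-stimulus peak-to-peak difference,
#' measured forward from the dark-response peak.
#'
#' @param resp a dark-polarity `epoch_response`.
#' @param ... passed to [crossing_times()].
#' @return List: `value` (s), `valid`, plus the crossing bookkeeping.
#' @export
decay_time_90_10 <- function(resp, ...) {
  ct <- crossing_times(resp, direction = "down", ...)
  c(list(value = if (ct$valid) ct$t_lo - ct$t_hi else NA_real_), ct)
}

#' 10-to-90 percent rise time (light flashes)
#'
#' Time from 10% to 90% of the post-stimulus peak-to-peak difference on
#' the rising limb following the light-induced trough.
#'
#' @param resp a light-polarity `epoch_response`.
#' @param ... passed to [crossing_times()].
#' @return List: `value` (s), `valid`, plus the crossing bookkeeping.
#' @export
rise_time_10_90 <- function(resp, ...) {
  ct <- crossing_times(resp, direction = "up", ...)
  c(list(value = if (ct$valid) ct$t_hi - ct$t_lo else NA_real_), ct)
}

#' Exponential fit of the transient limb, dF/F(t) = c * exp(k t)
#'
#' Least-squares fit of the log-transformed transient over the span
#' between the 10% and 90% crossings of the post-stimulus peak-to-peak
#' difference. For decays the values are offset by the post-stimulus
#' minimum, for rises subtracted from the post-stimulus maximum, with a
#' floor of 1% of the peak-to-peak difference to keep the logarithm
#' defined. By convention k < 0 for decays and k > 0 for rises.
#'
#' @param resp an `epoch_response`.
#' @param window optional numeric `c(t_start, t_end)` span (s); by default
#'   the 90/10 crossing span for the polarity-appropriate direction.
#' @param direction `"down"` (decay) or `"up"` (rise); defaults to
#'   `"down"` for dark and `"up"` for light responses.
#' @return List: `c`, `k` (1/s), `valid`.
#' @export
fit_exponential <- function(resp, window = NULL, direction = NULL) {
  stopifnot(inherits(resp, "epoch_response"))
  if (is.null(direction))
    direction <- if (resp$polarity == "dark") "down" else "up"
  w <- post_window(resp)
  bad <- list(c = NA_real_, k = NA_real_, valid = FALSE)
  if (length(w$v) < 3) return(bad)
  vmax <- max(w$v); vmin <- min(w$v); p2p <- vmax - vmin
  if (p2p <= 0) return(bad)
  if (is.null(window)) {
    ct <- crossing_times(resp, direction = direction)
    if (!ct$valid) return(bad)
    window <- sort(c(ct$t_hi, ct$t_lo))
  }
  sel <- w$t >= window[1] & w$t <= window[2]
  if (sum(sel) < 3) return(bad)
  tt <- w$t[sel]; vv <- w$v[sel]
  off <- if (direction == "down") vv - vmin else vmax - vv
  off <- pmax(off, 0.01 * p2p)
  fit <- stats::lm(log(off) ~ tt)
  slope <- unname(stats::coef(fit)[2])
  intc <- unname(stats::coef(fit)[1])
  if (direction == "down") list(c = exp(intc), k = slope, valid = TRUE)
  else list(c = exp(intc), k = -slope, valid = TRUE)
}

#' Secondary calcium response
#'
#' For dark flashes: the magnitude of the calcium decrease below the
#' pre-stimulus baseline following the initial peak. For light flashes:
#' the magnitude of the calcium increase above baseline following the
#' initial trough. Searched from the primary extremum to the end of the
#' response window; monophasic responses that never cross baseline give 0
#' with a valid flag.
#'
#' @param resp an `epoch_response`.
#' @param w_primary primary-extremum search window (default 2 s).
#' @return List: `value` (dF/F magnitude) and `valid`.
#' @export
secondary_response <- function(resp, w_primary = 2) {
  stopifnot(inherits(resp, "epoch_response"))
  prim <- post_window(resp, w_primary)
  if (length(prim$v) == 0) return(list(value = NA_real_, valid = FALSE))
  i0 <- if (resp$polarity == "dark") which.max(prim$v) else which.min(prim$v)
  t0 <- prim$t[i0]
  w <- post_window(resp)
  sel <- w$t > t0
  if (!any(sel)) return(list(value = NA_real_, valid = FALSE))
  vv <- w$v[sel]
  val <- if (resp$polarity == "dark") max(0, -min(vv)) else max(0, max(vv))
  list(value = val, valid = TRUE)
}

#' All transient metrics for one epoch response
#'
#' Computes the metrics applicable to the response polarity: dark flashes
#' get peak size, 90-10 decay time, the decay exponential constant and the
#' secondary (undershoot) response; light flashes get trough size, 10-90
#' rise time, the rise exponential constant and the secondary (overshoot)
#' response.
#'
#' @param resp an `epoch_response`.
#' @param w_post primary-extremum window (default 2 s).
#' @return A data frame (class `transient_metrics`): epoch, polarity,
#'   metric, value, valid.
#' @export
transient_metrics <- function(resp, w_post = 2) {
  stopifnot(inherits(resp, "epoch_response"))
  if (resp$polarity == "dark") {
    pk <- peak_size(resp, w_post)
    dk <- decay_time_90_10(resp, w_primary = w_post)
    ex <- fit_exponential(resp, direction = "down")
    sec <- secondary_response(resp, w_primary = w_post)
    out <- data.frame(
      metric = c("peak_size", "decay_time_90_10_s", "exp_k_per_s",
                 "secondary_response"),
      value = c(pk$value, dk$value, ex$k, sec$value),
      valid = c(pk$valid, dk$valid, ex$valid, sec$valid))
  } else {
    tr <- trough_size(resp, w_post)
    rs <- rise_time_10_90(resp, w_primary = w_post)
    ex <- fit_exponential(resp, direction = "up")
    sec <- secondary_response(resp, w_primary = w_post)
    out <- data.frame(
      metric = c("trough_size", "rise_time_10_90_s", "exp_k_per_s",
                 "secondary_response"),
      value = c(tr$value, rs$value, ex$k, sec$value),
      valid = c(tr$valid, rs$valid, ex$valid, sec$valid))
  }
  out <- cbind(data.frame(epoch = resp$epoch, polarity = resp$polarity), out)
  class(out) <- c("transient_metrics", "data.frame")
  out
}

#' Epoch-1-normalized metric deltas
#'
#' Subtracts the epoch-1 value of each metric from every epoch's value
#' (epoch_n - epoch_1), so epoch 1 is exactly 0. If the epoch-1 value of
#' a metric is invalid, all deltas for that metric are flagged invalid.
#'
#' @param metrics data frame with columns `epoch`, `metric`, `value`,
#'   `valid` (rows for one subject/polarity; e.g. row-bound
#'   [transient_metrics()] across epochs).
#' @return Data frame: epoch, metric, delta, valid.
#' @export
epoch1_normalize <- function(metrics) {
  stopifnot(all(c("epoch", "metric", "value", "valid") %in% names(metrics)))
  out <- do.call(rbind, lapply(split(metrics, metrics$metric), function(d) {
    base <- d[d$epoch == 1L, , drop = FALSE]
    if (nrow(base) != 1)
      stop_ft("metric '", d$metric[1], "' needs exactly one epoch-1 value")
    ok <- base$valid
    delta <- d$value - base$value
    delta[d$epoch == 1L] <- 0
    data.frame(epoch = d$epoch, metric = d$metric, delta = delta,
               valid = d$valid & ok)
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$epoch), ]
}
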