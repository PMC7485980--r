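alpha_lobe <- function(s) ifelse(s > 0, s * exp(1 - s), 0)

#' Analytic flash-response kernel
#'
#' Closed-form calcium transient kernels emulating lamina monopolar
#' terminal responses. A dark flash gives a fast rise to a positive peak
#' followed by an exactly exponential decay and an optional delayed
#' undershoot lobe; a light flash gives a fast dip to a negative trough,
#' an exactly exponential (saturating) recovery and an optional delayed
#' overshoot lobe. The rise/dip limb is a raised cosine so the kernel is
#' smooth up to the extremum; the decay/recovery limb is pure
#' `exp(-rate * t)` so its 90-to-10 span is exactly `ln(9)/rate` when the
#' secondary lobe is zero. Kernels return to ~0 well before the next
#' flash (+4.9 s).
#'
#' @param polarity `"dark"` or `"light"`.
#' @param amp peak (dark) or trough (light) magnitude in dF/F units.
#' @param rate decay (dark) or recovery (light) rate in 1/s.
#' @param t_peak time to the primary extremum (s, default 0.15).
#' @param secondary_frac magnitude of the secondary lobe as a fraction of
#'   `amp` (undershoot for dark, overshoot for light; default 0).
#' @param secondary_tau time scale of the secondary alpha lobe (s).
#' @param secondary_delay onset of the secondary lobe after the primary
#'   extremum (s); default `log(9)/rate` (the end of the 90-10 span).
#' @return A function `f(t)` (vectorized, 0 for t < 0) with the
#'   parameters attached as attribute `params`.
#' @export
make_kernel <- function(polarity = c("dark", "light"), amp = 0.8,
                        rate = 2.2, t_peak = 0.15, secondary_frac = 0,
                        secondary_tau = 0.6,
                        secondary_delay = log(9) / rate) {
  polarity <- match.arg(polarity)
  stopifnot(rate > 0, t_peak > 0, amp >= 0, secondary_frac >= 0)
  sgn <- if (polarity == "dark") 1 else -1
  t_sec <- t_peak + secondary_delay
  f <- function(t) {
    out <- numeric(length(t))
    ris <- t > 0 & t <= t_peak
    dec <- t > t_peak
    out[ris] <- amp * (1 - cos(pi * t[ris] / t_peak)) / 2
    out[dec] <- amp * exp(-rate * (t[dec] - t_peak))
    out <- sgn * out -
      sgn * secondary_frac * amp * alpha_lobe((t - t_sec) / secondary_tau)
    out
  }
  attr(f, "params") <- list(polarity = polarity, amp = amp, rate = rate,
                            t_peak = t_peak, secondary_frac = secondary_frac,
                            secondary_tau = secondary_tau,
                            secondary_delay = secondary_delay)
  f
}

# Piecewise-linear basal ramp: 0 before arrival, linear to `plateau`
# over `ramp_s`, then flat.
basal_ramp <- function(t, arrival_s, plateau, ramp_s) {
  if (ramp_s <= 0) return(ifelse(t >= arrival_s, plateau, 0))
  pmin(pmax((t - arrival_s) / ramp_s, 0), 1) * plateau
}

#' Ground-truth parameter set for the synthetic generator
#'
#' Collects every parameter of the synthetic movie/trace generator so the
#' realization can be reproduced and used as an exact oracle. Defaults
#' emulate the study conditions: GCaMP6f transients with ~1 s dark-flash
#' decay, a serotonin-driven basal ramp starting at perfusion arrival, a
#' 0.04 Hz multiplicative brain-motion oscillation, in-plane rigid
#' jitter, and intensity-dependent Gaussian noise (photon-noise
#' surrogate; `snr = Inf` disables noise).
#'
#' @param n_terminals number of terminals (default 6).
#' @param centers terminal centers, n x 2 matrix (row, col); default: a
#'   ring placed by [default_centers()].
#' @param sigma_px spatial Gaussian radius of each terminal (default 3.5;
#'   terminals cover roughly half the default 48 x 48 field, as in an
#'   imaging plane packed with terminal columns, which is what makes the
#'   global-median threshold separate background from signal).
#' @param spot_sharpness super-Gaussian exponent of the spot profile
#'   `exp(-(r^2 / 2 sigma^2)^sharpness)`. The default 2 gives terminals a
#'   fairly uniform bright interior with a soft edge (like a filled axon
#'   terminal viewed in cross-section) while keeping a single intensity
#'   maximum per terminal; 1 gives a plain Gaussian.
#' @param f0 baseline fluorescence amplitude at each terminal center.
#' @param dark_amp,dark_rate,light_amp,light_rate kernel parameters
#'   (dF/F peak 0.8 / trough 0.25; rates 2.2 and 1.8 per second).
#' @param dark_undershoot,light_overshoot secondary-lobe fractions.
#' @param drift_plateau_dff basal-ramp plateau in dF/F (1.73 mirrors the
#'   serotonin condition; 0 = saline).
#' @param drift_arrival_s ramp onset (perfusion arrival; 105 s gravity
#'   rig, 45 s valve rig).
#' @param drift_ramp_s time to reach the plateau (default 180 s).
#' @param motion_amp multiplicative oscillation amplitude fraction
#'   (default 0 = off; ~0.05 when present).
#' @param motion_hz oscillation frequency (default 0.04).
#' @param jitter_amp_px rigid-jitter amplitude (default 0 = off).
#' @param background_level additive background intensity.
#' @param background_gradient relative amplitude of a fixed linear
#'   illumination gradient across the field (breaks exact background
#'   ties at the median threshold; default 0.2).
#' @param snr peak transient amplitude over noise sigma at the terminal
#'   center (`Inf` = noiseless).
#' @param seed integer seed for all stochastic components.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(n_terminals = 6, centers = NULL, sigma_px = 3.5,
                         spot_sharpness = 2,
                         f0 = 100, dark_amp = 0.8, dark_rate = 2.2,
                         light_amp = 0.25, light_rate = 1.8,
                         dark_undershoot = 0.2, light_overshoot = 0.6,
                         drift_plateau_dff = 0, drift_arrival_s = 105,
                         drift_ramp_s = 180, motion_amp = 0,
                         motion_hz = 0.04, jitter_amp_px = 0,
                         background_level = 10, background_gradient = 0.2,
                         snr = Inf, seed = 1) {
  gt <- list(n_terminals = n_terminals, centers = centers,
             sigma_px = sigma_px, spot_sharpness = spot_sharpness,
             f0 = f0, dark_amp = dark_amp,
             dark_rate = dark_rate, light_amp = light_amp,
             light_rate = light_rate, dark_undershoot = dark_undershoot,
             light_overshoot = light_overshoot,
             drift_plateau_dff = drift_plateau_dff,
             drift_arrival_s = drift_arrival_s, drift_ramp_s = drift_ramp_s,
             motion_amp = motion_amp, motion_hz = motion_hz,
             jitter_amp_px = jitter_amp_px,
             background_level = background_level,
             background_gradient = background_gradient,
             snr = snr, seed = seed)
  class(gt) <- "ground_truth"
  gt
}

#' Default terminal centers
#'
#' Places `n` terminal centers on a ring of radius 0.3 * min(dims) around
#' the field center (deterministic).
#'
#' @param n number of terminals.
#' @param dims c(height, width) in px.
#' @return n x 2 matrix of (row, col) centers.
#' @export
default_centers <- function(n, dims) {
  r <- 0.3 * min(dims)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(row = dims[1] / 2 + r * sin(ang), col = dims[2] / 2 + r * cos(ang))
}

# True dF/F time course of one terminal under a protocol: triggered
# kernels plus the basal ramp. `epoch_mod` optionally scales kernel
# parameters per epoch: a list with amp_growth (additive dF/F per epoch
# for dark amp / light trough) and rate_growth (multiplicative per epoch).
dff_true_course <- function(t, gt, protocol = NULL, epoch_mod = NULL) {
  out <- basal_ramp(t, gt$drift_arrival_s, gt$drift_plateau_dff,
                    gt$drift_ramp_s)
  if (is.null(protocol)) return(out)
  eps <- flash_epochs(protocol)
  for (i in seq_along(protocol$flash_onsets_s)) {
    e <- eps[i] - 1L
    ag <- if (is.null(epoch_mod)) 0 else epoch_mod$amp_growth * e
    rg <- if (is.null(epoch_mod)) 1 else epoch_mod$rate_growth^e
    pol <- protocol$polarities[i]
    kern <- if (pol == "dark") {
      make_kernel("dark", amp = gt$dark_amp + ag, rate = gt$dark_rate * rg,
                  secondary_frac = gt$dark_undershoot)
    } else {
      make_kernel("light", amp = gt$light_amp + ag,
                  rate = gt$light_rate * rg,
                  secondary_frac = gt$light_overshoot)
    }
    out <- out + kern(t - protocol$flash_onsets_s[i])
  }
  out
}

#' Simulate a bath-application fluorescence trace
#'
#' One pooled-ROI raw trace for a bath experiment: constant baseline
#' fluorescence, then (serotonin condition) a piecewise-linear basal
#' calcium ramp beginning at perfusion arrival and rising to the
#' configured plateau; saline stays flat. Optional 0.04 Hz multiplicative
#' oscillation and Gaussian noise.
#'
#' @param gt a [ground_truth()]; `drift_plateau_dff` is forced to 0 for
#'   `condition = "saline"`.
#' @param duration_s recording length (s); must cover arrival + 60 s.
#' @param fps frame rate (default 15, bath mode).
#' @param condition `"serotonin"` or `"saline"`.
#' @param noise_sd additive Gaussian noise sd in intensity units
#'   (default derived from `gt$snr`).
#' @return A [raw_trace()] with the realized true dF/F attached as
#'   attribute `dff_true`.
#' @export
simulate_bath_trace <- function(gt = ground_truth(), duration_s = 360,
                                fps = 15,
                                condition = c("serotonin", "saline"),
                                noise_sd = NULL) {
  condition <- match.arg(condition)
  if (duration_s < gt$drift_arrival_s + 60 && condition == "serotonin")
    stop_ft("duration must cover perfusion arrival + 60 s")
  plateau <- if (condition == "saline") 0 else gt$drift_plateau_dff
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  dff <- basal_ramp(t, gt$drift_arrival_s, plateau, gt$drift_ramp_s)
  f <- gt$f0 * (1 + dff)
  if (gt$motion_amp > 0)
    f <- f * (1 + gt$motion_amp * sin(2 * pi * gt$motion_hz * t))
  if (is.null(noise_sd))
    noise_sd <- if (is.finite(gt$snr)) gt$dark_amp * gt$f0 / gt$snr else 0
  if (noise_sd > 0)
    f <- with_seed(gt$seed, pmax(0, f + stats::rnorm(length(f), 0, noise_sd)))
  tr <- raw_trace(f, frame_rate_hz = fps, group = condition)
  attr(tr, "dff_true") <- dff
  tr
}

#' Simulate a visual-experiment fluorescence trace
#'
#' One animal-average raw trace for a flash experiment: triggered
#' transient kernels for every flash of the protocol, a basal ramp from
#' perfusion arrival, optional per-epoch modulation of kernel parameters
#' (emulating treatment effects that grow across epochs), optional
#' motion oscillation, and Gaussian noise.
#'
#' @param gt a [ground_truth()].
#' @param protocol a [stimulus_protocol()] (default [make_protocol()]
#'   with the ground truth's seed).
#' @param fps frame rate (default 27, visual mode).
#' @param epoch_mod `NULL`, or list(amp_growth =, rate_growth =): additive
#'   dF/F amplitude growth and multiplicative rate growth per epoch after
#'   the first.
#' @param duration_s recording length; default covers the protocol plus
#'   the final response window.
#' @param noise_sd Gaussian noise sd in intensity units (default from
#'   `gt$snr`).
#' @return A [raw_trace()] with attributes `dff_true` (numeric vector)
#'   and `protocol`.
#' @export
simulate_visual_trace <- function(gt = ground_truth(drift_arrival_s = 105),
                                  protocol = make_protocol(seed = gt$seed),
                                  fps = 27, epoch_mod = NULL,
                                  duration_s = NULL, noise_sd = NULL) {
  if (is.null(duration_s))
    duration_s <- protocol$n_epochs * protocol$epoch_length_s + 5
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  dff <- dff_true_course(t, gt, protocol, epoch_mod)
  f <- gt$f0 * (1 + dff)
  if (gt$motion_amp > 0)
    f <- f * (1 + gt$motion_amp * sin(2 * pi * gt$motion_hz * t))
  if (is.null(noise_sd))
    noise_sd <- if (is.finite(gt$snr)) gt$dark_amp * gt$f0 / gt$snr else 0
  if (noise_sd > 0)
    f <- with_seed(gt$seed, pmax(0, f + stats::rnorm(length(f), 0, noise_sd)))
  tr <- raw_trace(f, frame_rate_hz = fps)
  attr(tr, "dff_true") <- dff
  attr(tr, "protocol") <- protocol
  tr
}

#' Simulate a fluorescence movie with exported ground truth
#'
#' Builds frames as `background(x, y) + sum_i f0 * G_i(x, y) * (1 +
#' dff_i(t))` over Gaussian terminal spots, applies the multiplicative
#' motion oscillation and rigid in-plane jitter when enabled, and adds
#' intensity-dependent Gaussian noise (sd proportional to the square root
#' of intensity, a photon-noise surrogate). The background is a dim fixed
#' linear gradient. Every stochastic realization (jitter series, noise
#' seed, protocol shuffle) is reproducible from `gt$seed` and echoed back
#' so tests can use the generator as an exact oracle.
#'
#' @param gt a [ground_truth()].
#' @param protocol a [stimulus_protocol()] or `NULL` for bath mode
#'   (ramp only).
#' @param fps frame rate.
#' @param dims c(height, width) in px (default c(48, 48)).
#' @param duration_s movie length (s).
#' @param epoch_mod per-epoch kernel modulation, see
#'   [simulate_visual_trace()].
#' @return A list: `movie` ([movie_stack()]), `gt` (input parameters),
#'   `dff_true` (terminals x frames matrix), `jitter` (frame, dy, dx),
#'   `centers`, `spot_masks` (list of logical matrices, spot weight >=
#'   half maximum), `protocol`.
#' @export
simulate_movie <- function(gt = ground_truth(), protocol = NULL, fps = 10,
                           dims = c(48, 48), duration_s = 60,
                           epoch_mod = NULL) {
  centers <- gt$centers
  if (is.null(centers)) centers <- default_centers(gt$n_terminals, dims)
  nt <- nrow(centers)
  if (any(centers[, 1] < 1 | centers[, 1] > dims[1] |
          centers[, 2] < 1 | centers[, 2] > dims[2]))
    stop_ft("terminal centers must fit within dims")
  t <- seq(0, duration_s - 1 / fps, by = 1 / fps)
  nf <- length(t)
  # spatial components
  rowg <- matrix(seq_len(dims[1]), dims[1], dims[2])
  colg <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  bg <- gt$background_level *
    (1 + gt$background_gradient * ((colg - 1) / max(1, dims[2] - 1) - 0.5))
  spots <- lapply(seq_len(nt), function(i) {
    r2 <- ((rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2) /
      (2 * gt$sigma_px^2)
    exp(-r2^gt$spot_sharpness)
  })
  dff <- matrix(0, nt, nf)
  for (i in seq_len(nt))
    dff[i, ] <- dff_true_course(t, gt, protocol, epoch_mod)
  realized <- with_seed(gt$seed, {
    jit <- if (gt$jitter_amp_px > 0) {
      # smooth random walk, clipped to the amplitude
      raw <- apply(matrix(stats::rnorm(2 * nf, 0, gt$jitter_amp_px / 3),
                          nf, 2), 2, cumsum)
      sweep(raw, 2, colMeans(raw))
    } else matrix(0, nf, 2)
    jit <- pmin(pmax(jit, -gt$jitter_amp_px), gt$jitter_amp_px)
    jit <- round(jit)
    noise_gain <- if (is.finite(gt$snr))
      gt$dark_amp * sqrt(gt$f0) / gt$snr else 0
    data_arr <- array(0, dim = c(nf, dims[1], dims[2]))
    for (k in seq_len(nf)) {
      fr <- bg
      for (i in seq_len(nt))
        fr <- fr + gt$f0 * spots[[i]] * (1 + dff[i, k])
      if (gt$motion_amp > 0)
        fr <- fr * (1 + gt$motion_amp * sin(2 * pi * gt$motion_hz * t[k]))
      if (any(jit[k, ] != 0))
        fr <- shift_frame(fr, jit[k, 1], jit[k, 2])
      if (noise_gain > 0)
        fr <- fr + stats::rnorm(length(fr), 0, noise_gain * sqrt(pmax(fr, 0)))
      data_arr[k, , ] <- pmax(fr, 0)
    }
    list(data = data_arr, jitter = jit)
  })
  list(movie = movie_stack(realized$data, frame_rate_hz = fps),
       gt = gt, dff_true = dff,
       jitter = data.frame(frame = seq_len(nf),
                           dy = realized$jitter[, 1],
                           dx = realized$jitter[, 2]),
       centers = centers,
       spot_masks = lapply(spots, function(s) s >= 0.5 * max(s)),
       protocol = protocol)
}
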