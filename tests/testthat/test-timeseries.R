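test_that("notch filter preserves DC and attenuates only its band", {
  fs <- 20
  # constant trace unchanged (DC gain 1)
  const <- notch_filter(rep(5, 2000), 0.04, 0.005, fs_hz = fs)
  expect_equal(const, rep(5, 2000), tolerance = 1e-9)
  # pure sinusoid at the center: RMS <= 5% after discarding 10 s edges
  t <- seq(0, 600, by = 1 / fs)
  x <- sin(2 * pi * 0.04 * t)
  y <- notch_filter(x, 0.04, 0.005, fs_hz = fs)
  interior <- t > 10 & t < 590
  expect_lte(rms(y[interior]), 0.05 * rms(x[interior]))
  # sinusoid at 5x the center passes
  x5 <- sin(2 * pi * 0.20 * t)
  y5 <- notch_filter(x5, 0.04, 0.005, fs_hz = fs)
  expect_gte(rms(y5[interior]), 0.95 * rms(x5[interior]))
  # center above Nyquist rejected
  expect_error(notch_filter(x, 11, 0.1, fs_hz = fs), "Nyquist")
})

test_that("zero-phase filtering introduces no lag on broadband noise", {
  set.seed(10)
  fs <- 20
  x <- as.numeric(stats::filter(rnorm(4000), rep(0.2, 5), sides = 2))
  x[is.na(x)] <- 0
  y <- notch_filter(x, 0.2, 0.02, fs_hz = fs)
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("motion-oscillation removal is powerful and near-idempotent", {
  fs <- 15
  t <- seq(0, 600, by = 1 / fs)
  signal <- 0.5 * sin(2 * pi * 0.005 * t)     # slow trend to keep
  x <- signal + 0.3 * sin(2 * pi * 0.04 * t)
  y <- remove_motion_oscillation(x, fs_hz = fs)
  # >= 20x reduction of 0.04 Hz periodogram power
  expect_lte(band_power(y, fs, 0.04) / band_power(x, fs, 0.04), 1 / 20)
  # flat trace stays flat
  expect_equal(remove_motion_oscillation(rep(2, 500), fs_hz = fs),
               rep(2, 500), tolerance = 1e-9)
  # twice ~ once on the notched band; the filter's own transient decays
  # on the 1/bandwidth scale, so judge on the deep interior of a long trace
  tl <- seq(0, 2400, by = 1 / fs)
  xl <- 0.3 * sin(2 * pi * 0.04 * tl)
  yl <- remove_motion_oscillation(xl, fs_hz = fs)
  yl2 <- remove_motion_oscillation(yl, fs_hz = fs)
  deep <- tl > 700 & tl < 1700
  expect_lt(max(abs(yl2[deep] - yl[deep])), 1e-6)
})

test_that("stimulus-band removal clears flash-rate bands, keeps slow signal", {
  fs <- 27
  t <- seq(0, 360, by = 1 / fs)
  ramp <- 0.002 * t
  stim <- 0.4 * sin(2 * pi * 0.20 * t) + 0.2 * sin(2 * pi * 0.40 * t)
  y <- remove_stimulus_band(ramp + stim, fs_hz = fs)
  interior <- t > 60 & t < 300
  # recovers the ramp within 10% of the stimulus amplitude
  expect_lte(max(abs(y[interior] - ramp[interior])), 0.1 * 0.4)
  # constant unchanged
  expect_equal(remove_stimulus_band(rep(1, 1000), fs_hz = fs),
               rep(1, 1000), tolerance = 1e-9)
  # 0.04 Hz motion band passes unattenuated
  x04 <- sin(2 * pi * 0.04 * t)
  y04 <- remove_stimulus_band(x04, fs_hz = fs)
  expect_gte(rms(y04[interior]), 0.95 * rms(x04[interior]))
})

test_that("stimulus-band removal recovers the basal drift under a kernel train", {
  # full-field flash train every 5 s riding a linear basal ramp; the
  # 0.2 / 0.4 Hz notches remove the dominant stimulus-locked bands
  prot <- make_protocol(seed = 31)
  gt <- ground_truth(snr = Inf, drift_plateau_dff = 0.5, drift_arrival_s = 105,
                     drift_ramp_s = 255, seed = 31)
  tr <- simulate_visual_trace(gt, prot, fps = 27)
  d <- dff_visual(tr, prot)
  y <- remove_stimulus_band(d)
  t <- flytrace:::frame_times(length(y$values), 27)
  drift <- flytrace:::basal_ramp(t, 105, 0.5, 255)
  interior <- t > 60 & t < 330
  resid <- y$values[interior] - drift[interior]
  # the notches remove the 0.2 / 0.4 Hz bands (higher kernel-train
  # harmonics remain by design); the slow drift is recovered without bias
  expect_lte(band_power(y$values, 27, 0.20) /
               band_power(d$values, 27, 0.20), 1 / 20)
  expect_lte(band_power(y$values, 27, 0.40) /
               band_power(d$values, 27, 0.40), 1 / 20)
  expect_lt(rms(resid), 0.25 * gt$dark_amp)
  expect_lt(abs(mean(resid)), 0.05 * gt$dark_amp)
})

test_that("bath dF/F follows the first-60-s baseline definition", {
  tr <- raw_trace(rep(100, 1800), frame_rate_hz = 15)
  expect_equal(dff_bath(tr)$values, rep(0, 1800))
  # 100 for 60 s then 150: 0 then 0.5
  tr2 <- raw_trace(c(rep(100, 900), rep(150, 900)), frame_rate_hz = 15)
  d2 <- dff_bath(tr2)
  expect_equal(d2$f0, 100)
  expect_equal(unique(d2$values), c(0, 0.5))
  # programmed ramp to 1.73 above baseline is recovered at the end
  gt <- ground_truth(drift_plateau_dff = 1.73, drift_arrival_s = 105,
                     drift_ramp_s = 180, snr = 20, seed = 12)
  tr3 <- simulate_bath_trace(gt, duration_s = 360, fps = 15)
  d3 <- dff_bath(tr3)
  expect_equal(d3$values[length(d3$values)], 1.73, tolerance = 0.05)
  expect_error(dff_bath(raw_trace(rep(100, 10), 15)), "baseline window")
})

test_that("visual dF/F uses only inter-stimulus epoch-1 segments", {
  prot <- make_protocol(seed = 1)
  segs <- baseline_segments_visual(prot)
  expect_equal(nrow(segs), 12)
  expect_equal(sum(segs$end_s - segs$start_s), 30)
  expect_true(all(segs$end_s <= 60))
  # segments end 0.5 s before each flash and avoid the previous transient
  ep1 <- prot$flash_onsets_s[flash_epochs(prot) == 1]
  expect_equal(segs$end_s, ep1 - 0.5)
  # trace constant 100 between flashes, 200 during 1-s post-flash
  # transients: F0 must be exactly 100
  fs <- 27
  tt <- flytrace:::frame_times(ceiling(365 * fs), fs)
  vals <- rep(100, length(tt))
  for (on in prot$flash_onsets_s)
    vals[tt >= on & tt < on + 1] <- 200
  tr <- raw_trace(vals, frame_rate_hz = fs)
  d <- dff_visual(tr, prot)
  expect_equal(d$f0, 100)
  # constant trace: all zeros regardless of protocol
  dz <- dff_visual(raw_trace(rep(80, length(tt)), fs), prot)
  expect_equal(dz$values, rep(0, length(tt)))
  # halving baseline_total_s on a constant trace leaves F0 unchanged
  expect_equal(dff_visual(tr, prot, baseline_total_s = 15)$f0, 100)
})

test_that("epoch averaging aligns, resamples and drops incomplete flashes", {
  prot <- make_protocol(seed = 2)
  fs <- 27
  tt <- flytrace:::frame_times(ceiling(365 * fs), fs)
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2)
  vals <- rep(0, length(tt))
  dark1 <- prot$flash_onsets_s[flash_epochs(prot) == 1 &
                                 prot$polarities == "dark"]
  for (on in dark1) vals <- vals + kern(tt - on)
  d <- dff_trace(vals, f0 = 100, baseline_rule = "visual", frame_rate_hz = fs)
  r <- stimulus_locked_epoch_average(d, prot, 1, "dark")
  expect_equal(r$n_flashes, 6)
  expect_lt(abs(mean(r$value[r$time_s < 0])), 1e-12)
  # average of six identical responses reproduces the kernel shape
  expect_equal(r$value[r$time_s > 0],
               kern(r$time_s[r$time_s > 0]), tolerance = 0.02)
  expect_error(stimulus_locked_epoch_average(d, prot, 7, "dark"),
               "no dark flashes")
})

test_that("epoch averaging removes per-flash constants and drops short flashes", {
  # wide-spaced protocol so each flash window carries its own constant
  wide <- stimulus_protocol(flash_onsets_s = 3 + 10 * (0:5),
                            polarities = rep("dark", 6),
                            inter_onset_s = 10, epoch_length_s = 60,
                            n_epochs = 1)
  fs <- 27
  tt <- flytrace:::frame_times(ceiling(62 * fs), fs)
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2)
  vals <- rep(0, length(tt))
  for (on in wide$flash_onsets_s) vals <- vals + kern(tt - on)
  d <- dff_trace(vals, 100, "visual", fs)
  r <- stimulus_locked_epoch_average(d, wide, 1, "dark")
  # add a different constant across each flash's whole window
  set.seed(3)
  offs <- rnorm(6)
  vals2 <- vals
  for (i in 1:6) {
    w <- tt >= wide$flash_onsets_s[i] - 5 & tt < wide$flash_onsets_s[i] + 5
    vals2[w] <- vals2[w] + offs[i]
  }
  r2 <- stimulus_locked_epoch_average(dff_trace(vals2, 100, "visual", fs),
                                      wide, 1, "dark")
  expect_equal(r2$value, r$value, tolerance = 1e-9)
  # flash windows past the trace end are dropped with a warning
  short <- dff_trace(vals[tt < 50], 100, "visual", fs)
  expect_warning(rs <- stimulus_locked_epoch_average(short, wide, 1, "dark"),
                 "dropped")
  expect_equal(rs$n_flashes, 5L)
})

test_that("averaging across ROIs is the pointwise mean", {
  mk <- function(v) dff_trace(v, 100, "visual", 10)
  a <- mk(c(1, 2, 3)); b <- mk(c(3, 2, 1))
  expect_equal(average_across_rois(list(a, a))$values, a$values)
  expect_equal(average_across_rois(list(a, b))$values, c(2, 2, 2))
  expect_error(average_across_rois(list(a, mk(c(1, 2)))), "mismatched")
})

test_that("motion notch and dF/F commute for a fixed baseline", {
  # dF/F is affine in F_t and the notch has unit DC gain, so for a given
  # F0 the filter and the normalization commute exactly
  gt <- ground_truth(snr = Inf, drift_plateau_dff = 0.5, motion_amp = 0.05,
                     seed = 14)
  tr <- simulate_bath_trace(gt, duration_s = 360, fps = 15)
  f0 <- mean(tr$values[seq_len(60 * 15)])
  a <- remove_motion_oscillation(tr$values / f0 - 1, fs_hz = 15)
  b <- (remove_motion_oscillation(tr$values, fs_hz = 15) - f0) / f0
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("motion advisory flags oscillating recordings only", {
  fs <- 15
  t <- seq(0, 360, by = 1 / fs)
  set.seed(15)
  osc <- raw_trace(100 * (1 + 0.05 * sin(2 * pi * 0.04 * t)) + rnorm(length(t), 0, 0.5), fs)
  quiet <- raw_trace(100 + rnorm(length(t), 0, 0.5), fs)
  expect_true(motion_oscillation_advisory(osc)$advise)
  expect_false(motion_oscillation_advisory(quiet)$advise)
})
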