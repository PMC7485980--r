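# Analytic response fixtures on a dense, exact time grid.
resp_from <- function(f, polarity = "dark", t_max = 4.9, dt = 1 / 200) {
  tt <- seq(-0.5, t_max, by = dt)
  epoch_response(tt, ifelse(tt > 0, f(tt), 0), polarity)
}

test_that("peak and trough sizes read the aligned extrema", {
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2)
  r <- resp_from(kern)
  expect_equal(peak_size(r)$value, 0.8, tolerance = 1e-6)
  # flat response: 0
  flat <- resp_from(function(t) rep(0, length(t)))
  expect_equal(peak_size(flat)$value, 0)
  # explicit max 0.6 in the window
  r6 <- resp_from(function(t) 0.6 * exp(-((t - 0.3) / 0.1)^2))
  expect_equal(peak_size(r6)$value, 0.6, tolerance = 1e-6)
  # light trough reported as magnitude
  kl <- make_kernel("light", amp = 0.25, rate = 1.8)
  rl <- resp_from(kl, "light")
  expect_equal(trough_size(rl)$value, 0.25, tolerance = 1e-6)
  expect_equal(trough_size(resp_from(function(t) rep(0, length(t)), "light"))$value, 0)
})

test_that("crossing times interpolate linear and exponential responses", {
  # ramp from 1 to 0 over [0, 1] s
  ramp <- resp_from(function(t) pmax(1 - t, 0), dt = 1 / 1000)
  ct <- crossing_times(ramp, direction = "down")
  expect_equal(ct$t_hi, 0.1, tolerance = 0.02)
  expect_equal(ct$t_lo, 0.9, tolerance = 0.02)
  # exponential decay, rate lambda: t_lo - t_hi = ln(9)/lambda
  for (lam in c(1, 2)) {
    ex <- resp_from(function(t) exp(-lam * t), t_max = 12, dt = 1 / 500)
    ct2 <- crossing_times(ex, direction = "down")
    expect_equal(ct2$t_lo - ct2$t_hi, log(9) / lam, tolerance = 0.01)
  }
  # level never crossed: invalid
  up_only <- resp_from(function(t) pmin(t, 1))
  expect_false(crossing_times(up_only, direction = "down")$valid)
})

test_that("decay and rise times match closed forms and the analytic kernel", {
  for (lam in c(1, 2)) {
    ex <- resp_from(function(t) exp(-lam * t), t_max = 12, dt = 1 / 500)
    expect_equal(decay_time_90_10(ex)$value, log(9) / lam, tolerance = 0.01)
  }
  # linear rise 0 -> 1 over 1 s (light polarity): 10-90 span 0.8 s
  lin <- resp_from(function(t) pmin(t, 1), "light", dt = 1 / 1000)
  expect_equal(rise_time_10_90(lin)$value, 0.8, tolerance = 2e-3)
  # saturating exponential rise, rate lambda: ln(9)/lambda
  sat <- resp_from(function(t) 1 - exp(-1.5 * t), "light", t_max = 12,
                   dt = 1 / 500)
  expect_equal(rise_time_10_90(sat)$value, log(9) / 1.5, tolerance = 0.01)
  # generator dark kernel without undershoot: exactly exponential limb
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2, secondary_frac = 0)
  r <- resp_from(kern, dt = 1 / 500)
  expect_equal(decay_time_90_10(r)$value, log(9) / 2.2, tolerance = 0.015)
})

test_that("exponential fit recovers c and k, flags degenerate windows", {
  # noiseless samples of 1 * exp(-2 t): exact log-linear recovery
  ex <- resp_from(function(t) exp(-2 * t), t_max = 10, dt = 1 / 200)
  fit <- fit_exponential(ex)
  expect_equal(fit$k, -2, tolerance = 1e-3)
  expect_equal(fit$c, 1, tolerance = 0.01)
  # noisy decay vs a nonlinear least-squares oracle on the same samples
  set.seed(21)
  tt <- seq(-0.5, 4.9, by = 4.9 / 29)
  vv <- ifelse(tt > 0, 0.5 * exp(-0.7 * tt), 0) + rnorm(length(tt), 0, 0.01)
  rn <- epoch_response(tt, vv, "dark", align = FALSE)
  fitn <- fit_exponential(rn)
  d <- data.frame(t = tt[tt > 0], v = vv[tt > 0])
  oracle <- stats::nls(v ~ c0 * exp(k0 * t), data = d,
                       start = list(c0 = 0.5, k0 = -0.7))
  expect_equal(fitn$k, -0.7, tolerance = 0.1)
  expect_equal(fitn$k, unname(coef(oracle)["k0"]), tolerance = 0.1)
  # saturating rise: k > 0 by convention
  sat <- resp_from(function(t) 1 - exp(-1.5 * t), "light", t_max = 10,
                   dt = 1 / 200)
  expect_equal(fit_exponential(sat)$k, 1.5, tolerance = 0.01)
  # constant window: invalid
  flat <- resp_from(function(t) rep(0, length(t)))
  expect_false(fit_exponential(flat)$valid)
})

test_that("|k| equals ln(9) / decay time for pure exponentials", {
  for (lam in c(0.5, 1, 2.2)) {
    ex <- resp_from(function(t) exp(-lam * t), t_max = max(10, 6 / lam),
                    dt = 1 / 500)
    dk <- decay_time_90_10(ex)$value
    k <- fit_exponential(ex)$k
    expect_equal(abs(k), log(9) / dk, tolerance = 0.01)
  }
})

test_that("secondary responses report the post-extremum reversal magnitude", {
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2, secondary_frac = 0.25)
  r <- resp_from(kern)
  # oracle: the deepest undershoot of the analytic kernel itself
  true_min <- stats::optimize(kern, c(0.5, 4.9))$objective
  expect_equal(secondary_response(r)$value, -true_min, tolerance = 1e-4)
  # monophasic kernel: 0 with valid flag
  mono <- resp_from(make_kernel("dark", amp = 0.8, rate = 2.2,
                                secondary_frac = 0))
  s <- secondary_response(mono)
  expect_true(s$valid); expect_equal(s$value, 0)
  expect_equal(secondary_response(
    resp_from(function(t) rep(0, length(t))))$value, 0)
  # light overshoot against the analytic maximum
  kl <- make_kernel("light", amp = 0.25, rate = 1.8, secondary_frac = 0.6)
  true_max <- stats::optimize(kl, c(0.5, 4.9), maximum = TRUE)$objective
  expect_equal(secondary_response(resp_from(kl, "light"))$value, true_max,
               tolerance = 1e-4)
})

test_that("epoch-1 normalization subtracts the baseline epoch exactly", {
  m <- data.frame(epoch = 1:3, metric = "peak_size", value = c(2, 3, 5),
                  valid = TRUE)
  d <- epoch1_normalize(m)
  expect_equal(d$delta, c(0, 1, 3))
  expect_identical(d$delta[d$epoch == 1], 0)
  # constant values: all zero
  mc <- data.frame(epoch = 1:4, metric = "x", value = 7, valid = TRUE)
  expect_equal(epoch1_normalize(mc)$delta, rep(0, 4))
  # invalid epoch 1 poisons all deltas
  mi <- data.frame(epoch = 1:3, metric = "x", value = c(NA, 1, 2),
                   valid = c(FALSE, TRUE, TRUE))
  expect_true(all(!epoch1_normalize(mi)$valid))
})

test_that("metrics are scale-equivariant and time-shift invariant", {
  kern <- make_kernel("dark", amp = 0.8, rate = 2.2, secondary_frac = 0.2)
  tt <- seq(-0.5, 4.9, by = 1 / 27)
  v <- ifelse(tt > 0, kern(tt), 0)
  r1 <- epoch_response(tt, v, "dark")
  for (s in c(0.5, 3)) {
    rs <- epoch_response(tt, s * v, "dark")
    expect_equal(peak_size(rs)$value, s * peak_size(r1)$value, tolerance = 1e-9)
    expect_equal(secondary_response(rs)$value,
                 s * secondary_response(r1)$value, tolerance = 1e-9)
    expect_equal(decay_time_90_10(rs)$value, decay_time_90_10(r1)$value,
                 tolerance = 1e-9)
    expect_equal(fit_exponential(rs)$k, fit_exponential(r1)$k,
                 tolerance = 1e-9)
  }
  # shifting the onset bookkeeping by an integer number of frames
  # (identical samples, relabeled times) leaves all metrics unchanged
  shift <- 3 / 27
  r_sh <- epoch_response(tt, ifelse(tt > 0, kern(tt), 0), "dark")
  r_sh$time_s <- r_sh$time_s + 0   # same grid; shift realized via samples
  v_sh <- ifelse(tt - shift > 0, kern(tt - shift), 0)
  r2 <- epoch_response(tt, v_sh, "dark")
  expect_equal(peak_size(r2)$value, peak_size(r1)$value, tolerance = 1e-9)
  expect_equal(decay_time_90_10(r2)$value, decay_time_90_10(r1)$value,
               tolerance = 1e-9)
})

test_that("epoch metrics recover programmed kinetics at moderate noise", {
  # parameter recovery across seeded runs at SNR 10: median errors small
  prot <- make_protocol(seed = 40)
  errs_pk <- errs_dk <- numeric(0)
  for (s in 1:12) {
    gt <- ground_truth(snr = 10, seed = 50 + s)
    tr <- simulate_visual_trace(gt, prot, fps = 27)
    d <- dff_visual(tr, prot)
    r <- stimulus_locked_epoch_average(d, prot, 2, "dark")
    # oracle: the analytic kernel sampled and averaged the same way
    oracle <- epoch_response(r$time_s,
                             ifelse(r$time_s > 0,
                                    make_kernel("dark", amp = gt$dark_amp,
                                                rate = gt$dark_rate,
                                                secondary_frac = gt$dark_undershoot)(r$time_s),
                                    0), "dark")
    errs_pk <- c(errs_pk, abs(peak_size(r)$value - peak_size(oracle)$value))
    errs_dk <- c(errs_dk, abs(decay_time_90_10(r)$value -
                                decay_time_90_10(oracle)$value))
  }
  expect_lt(median(errs_pk), 0.05 * 0.8)   # < 5% of the true amplitude
  expect_lt(median(errs_dk), 1 / 27)       # < one frame interval
})
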