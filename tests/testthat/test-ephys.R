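test_that("K+ current measurement matches closed forms", {
  t <- seq(0, 10, by = 2e-4)
  # pure A exp(-t / 2.5) from the stimulus
  tr <- data.frame(time_s = t,
                   current_pA = ifelse(t >= 0.5, 40 * exp(-(t - 0.5) / 2.5), 0))
  ik <- measure_ik(tr, stim_time = 0.5)
  expect_equal(ik$tau_decay_s, 2.5, tolerance = 1e-6)
  expect_equal(ik$ik_amp, 40 * exp(-0.2 / 2.5), tolerance = 1e-9)
  expect_true(ik$valid)

  # fast 80-ms contaminant does not disturb the 200 ms window
  tr2 <- tr
  tr2$current_pA <- tr2$current_pA +
    ifelse(t >= 0.5 & t < 0.58, 120 * exp(-(t - 0.5) / 0.01), 0)
  ik2 <- measure_ik(tr2, stim_time = 0.5)
  expect_equal(ik2$tau_decay_s, 2.5, tolerance = 0.02)

  # flat trace flagged invalid
  ik0 <- measure_ik(data.frame(time_s = t, current_pA = 0 * t), 0.5)
  expect_false(ik0$valid)

  # DC offsets are the caller's concern (baseline-subtracted input), but
  # tau is offset-free on noiseless data after amplitude re-read
  expect_true(is.na(ik0$tau_decay_s))
})

test_that("5-minus-4 subtraction isolates the planted 5th-stimulus current", {
  ts <- gen_traces(tau_s = 2.5, ik5_ratio = 0.72, tau5_ratio = 1.45, seed = 3)
  # identical responses -> zero trace
  z <- isolate_fifth(ts$resp4, ts$resp4)
  expect_true(all(z$current_pA == 0))
  # linearity: planted exponential recovered exactly
  i5 <- isolate_fifth(ts$resp5, ts$resp4)
  t5 <- ts$stim_times$train[5]
  sel <- i5$time_s > t5 + 0.15
  expect_equal(i5$current_pA[sel],
               ts$truth$amp5_pA * exp(-(i5$time_s[sel] - t5) / ts$truth$tau5_s),
               tolerance = 1e-9)
  # planted amplitude ratio recovered through the measurement chain
  ik1 <- measure_ik(ts$ik1, ts$stim_times$ik)
  ik5 <- measure_ik(i5, t5)
  expect_equal(ik5$ik_amp / ik1$ik_amp, 0.72, tolerance = 0.02 * 0.72)
  expect_equal(ik5$tau_decay_s / ik1$tau_decay_s, 1.45, tolerance = 0.01)

  expect_error(isolate_fifth(ts$resp5[-1, ], ts$resp4), "length")
})

test_that("fEPSP metrics: analytic ramp slope, PPR linearity, volley amplitude", {
  # ramp 0 -> -1 mV over 1 ms starting 5 ms post stimulus:
  # 20-80% slope = 0.6 mV / 0.6 ms = 1 mV/ms
  tt <- seq(0, 0.05, by = 1e-5)
  v <- ifelse(tt < 0.015, 0, ifelse(tt < 0.016, -(tt - 0.015) / 0.001, -1))
  fm <- fepsp_metrics(data.frame(time_s = tt, v_mV = v), 0.01)
  expect_equal(fm$slope_20_80_mV_per_ms[1], 1, tolerance = 1e-6)
  expect_equal(fm$amplitude_mV[1], 1, tolerance = 1e-9)

  ts <- gen_traces(fepsp_amp1_mV = 0.8, ppr = 1.0, prv_amp_mV = 0.3, seed = 2)
  fm1 <- fepsp_metrics(ts$fepsp, ts$stim_times$fepsp)
  expect_equal(fm1$ppr, 1.0, tolerance = 1e-3)
  ts2 <- gen_traces(fepsp_amp1_mV = 0.8, ppr = 1.4, seed = 2)
  fm2 <- fepsp_metrics(ts2$fepsp, ts2$stim_times$fepsp)
  expect_equal(fm2$ppr, 1.4, tolerance = 1e-3)
  expect_equal(fm2$prv_amp_mV[1], 0.3, tolerance = 1e-3)
})

test_that("Gompertz fits recover parameters and the ak/e maximum slope", {
  x <- seq(0, 2, length.out = 15)
  y <- 4 * exp(-exp(-1 * (x - 0.5)))
  gf <- fit_gompertz(data.frame(prv = x, fepsp = y))
  expect_equal(gf$a, 4, tolerance = 1e-6)
  expect_equal(gf$k, 1, tolerance = 1e-6)
  expect_equal(gf$xc, 0.5, tolerance = 1e-6)
  expect_equal(gf$max_slope, 4 / exp(1), tolerance = 1e-6)

  # analytic max slope equals the numeric maximum of dy/dx
  xx <- seq(-2, 4, by = 1e-4)
  yy <- gf$a * exp(-exp(-gf$k * (xx - gf$xc)))
  expect_equal(max(diff(yy) / diff(xx)), gf$max_slope, tolerance = 1e-6)

  # degenerate flat input
  g0 <- fit_gompertz(data.frame(prv = x, fepsp = 0 * x))
  expect_false(g0$valid)

  # noisy points: asymptote within 5%
  set.seed(9)
  yn <- y + rnorm(length(y), 0, 0.02 * 4)
  gn <- fit_gompertz(data.frame(prv = x, fepsp = yn))
  expect_lt(abs(gn$a - 4) / 4, 0.05)
})

test_that("LTP magnitude averages the stated windows", {
  # uniform 1.73-fold potentiation
  ts <- gen_traces(ltp_early = 1.73, seed = 1)
  expect_equal(ltp_magnitude(ts$ltp_series)$magnitude, 1.73,
               tolerance = 1e-9)
  # decaying potentiation: early window beats the late one, both matching
  # the generator's closed form
  td <- gen_traces(ltp_early = 2.0, ltp_late = 1.2, ltp_decay_min = 20,
                   seed = 1)
  lt_late <- ltp_magnitude(td$ltp_series, window_min = c(47, 60))
  lt_early <- ltp_magnitude(td$ltp_series, window_min = c(5, 15))
  expect_gt(lt_early$magnitude, lt_late$magnitude)
  closed_form <- function(w) {
    tt <- seq(w[1], w[2])
    mean(1.2 + (2.0 - 1.2) * exp(-tt / 20))
  }
  expect_equal(lt_early$magnitude, closed_form(c(5, 15)), tolerance = 0.01)
  expect_equal(lt_late$magnitude, closed_form(c(47, 60)), tolerance = 0.01)

  expect_error(ltp_magnitude(data.frame(time_min = 0:10, slope = rep(1, 11))),
               "baseline|window")
})
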