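test_that("dark-noise subtraction removes the per-pixel median offset", {
  sig <- array(rep(1:24, each = 16), c(24, 4, 4))
  # constant offset
  mv <- sig + 10
  dark <- array(10, c(5, 4, 4))
  expect_equal(as.vector(subtract_dark_noise(mv, dark)), as.vector(sig))
  # zero dark frames: identity
  expect_equal(as.vector(subtract_dark_noise(sig, array(0, c(3, 4, 4)))),
               as.vector(sig))
  # per-pixel gradient offset removed to machine precision
  grad <- matrix(seq(0, 15), 4, 4)
  mv2 <- sweep(sig, c(2, 3), grad, `+`)
  dark2 <- array(rep(grad, each = 7), c(7, 4, 4))
  dark2 <- aperm(array(grad, c(4, 4, 7)), c(3, 1, 2))
  expect_equal(as.vector(subtract_dark_noise(mv2, dark2)), as.vector(sig),
               tolerance = 1e-12)
  expect_error(subtract_dark_noise(sig, array(0, c(3, 5, 5))), "shape")
})

test_that("phase-correlation registration recovers planted shifts", {
  set.seed(41)
  frame <- matrix(0, 64, 64)
  frame[20:30, 25:40] <- 5
  frame <- frame + matrix(runif(64 * 64, 0, 0.2), 64, 64)
  # integer shift (2, -3)
  shifted <- frame[c(63:64, 1:62), c(4:64, 1:3)]
  mv <- array(0, c(3, 64, 64))
  mv[1, , ] <- frame; mv[2, , ] <- shifted; mv[3, , ] <- frame
  reg <- register_movie(mv)
  expect_equal(reg$shifts[2, ], c(2, -3), tolerance = 0.05)
  expect_equal(reg$shifts[3, ], c(0, 0))
  expect_lt(max(abs(reg$movie[2, , ] - frame)), 0.25)

  # subpixel shift of 0.5 px along y applied via a Fourier phase ramp
  fy <- c(0:31, -32:-1) / 64
  ph <- exp(-2i * pi * matrix(fy * 0.5, 64, 64))
  sub <- Re(stats::fft(stats::fft(frame) * ph, inverse = TRUE)) / 4096
  mv2 <- array(0, c(2, 64, 64)); mv2[1, , ] <- frame; mv2[2, , ] <- sub
  reg2 <- register_movie(mv2, upsample = 10)
  expect_equal(reg2$shifts[2, 1], 0.5, tolerance = 0.1)
  expect_equal(reg2$shifts[2, 2], 0, tolerance = 0.1)

  # static movie: all zero shifts
  mv3 <- array(rep(frame, each = 1), c(1, 64, 64))
  mv3 <- array(c(frame, frame), c(64, 64, 2))
  mv3 <- aperm(mv3, c(3, 1, 2))
  reg3 <- register_movie(mv3)
  expect_true(all(abs(reg3$shifts) < 0.05))
})

test_that("two-pass baseline yields flat dF/F under drift and shields transients", {
  Tn <- 300
  # constant pixel -> dF/F identically 0
  mv <- array(100, c(Tn, 2, 2))
  dm <- compute_dff(mv)
  expect_lt(max(abs(dm$dff)), 1e-10)

  # slow linear drift only: absorbed into the baseline
  drift <- 100 * (1 + 0.2 * seq_len(Tn) / Tn)
  mv2 <- array(rep(drift, 4), c(Tn, 2, 2))
  dm2 <- compute_dff(mv2)
  expect_lt(max(abs(dm2$dff)), 0.02)

  # planted boxcar transient: the final baseline stays near truth inside it
  tr <- rep(100, Tn); tr[140:160] <- 180
  mv3 <- array(rep(tr, 4), c(Tn, 2, 2))
  mv3 <- mv3 + array(rnorm(length(mv3), 0, 1), dim(mv3))
  dm3 <- compute_dff(mv3)
  expect_lt(max(abs(dm3$F0[140:160, 1, 1] - 100) / 100), 0.02)
  expect_gt(max(dm3$dff[145:155, 1, 1]), 0.5)

  expect_error(compute_dff(array(100, c(60, 2, 2))), "shorter")
})

test_that("x-y-time linking groups voxels like the stated connectivity", {
  # three disjoint planted boxes -> three events with exact metrics
  dff <- array(0, c(40, 32, 32))
  dff[5:8, 4:6, 4:6] <- 1       # 9 px footprint, 4 frames
  dff[20:21, 20:24, 20:24] <- 1 # 25 px, 2 frames
  dff[30, 10, 28] <- 1          # single voxel
  dm <- make_dff_movie(dff)
  ev <- detect_events(dm, threshold_k = 2.5)
  ev <- ev[order(ev$t_start_s), ]
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$duration_s, c(4, 2, 1))
  expect_equal(ev$s_max_um2, c(9, 25, 1) * 0.25)
  expect_equal(ev$integral_um2s, c(36, 50, 1) * 0.25)
  # invariants: s_max >= largest frame; integral <= s_max * duration
  expect_true(all(ev$s_max_um2 >= ev$max_frame_area_um2))
  expect_true(all(ev$integral_um2s <= ev$s_max_um2 * ev$duration_s + 1e-12))

  # same footprint, >= 2 silent frames apart -> two events
  dff2 <- array(0, c(40, 16, 16))
  dff2[5:8, 6:8, 6:8] <- 1
  dff2[11:13, 6:8, 6:8] <- 1
  ev2 <- detect_events(make_dff_movie(dff2))
  expect_equal(nrow(ev2), 2L)
  # with a 2-frame gap tolerance they merge
  ev2g <- detect_events(make_dff_movie(dff2), gap_frames = 2)
  expect_equal(nrow(ev2g), 1L)

  # empty input
  expect_equal(nrow(detect_events(make_dff_movie(array(0, c(30, 8, 8))))), 0L)
})

test_that("exclusion filters implement the strict less-than rule", {
  ev <- data.frame(
    event_id = 1:6,
    t_start_s = 0, cy = 0, cx = 0, n_voxels = 1L, max_frame_area_um2 = 1,
    integral_um2s = c(3.9, 4.0, 100, 100, 100, 100),
    s_max_um2     = c(50, 50, 9.9, 10.0, 50, 50),
    duration_s    = c(5, 5, 5, 5, 1.9, 2.0)
  )
  class(ev) <- c("ca_events", class(ev))
  kept <- filter_events(ev)
  expect_equal(kept$event_id, c(2L, 4L, 6L))
})

test_that("frequency density is count over time and area", {
  expect_equal(frequency_density(60, 0.02, 600), 5)
  expect_equal(frequency_density(60, 0.02, 1200), 2.5)
  expect_equal(frequency_density(data.frame()[0, ], 0.02, 600), 0)
})

test_that("log-binned regression recovers exponents from exact and sampled data", {
  # exact construction: values at geometric bin centres with counts
  # proportional to the true bin mass of a pure alpha = 3 law
  edges <- 10 * 2^(0:10 / 2)
  centres <- sqrt(edges[-1] * edges[-11])
  mass <- edges[-11]^(1 - 3) - edges[-1]^(1 - 3)
  counts <- round(mass / sum(mass) * 1e6)
  vals <- rep(centres, counts)
  f <- fit_power_law(vals, bin_edges = edges)
  expect_equal(f$alpha, 3, tolerance = 0.01)

  # inverse-CDF samples: recovery within 2 standard errors
  set.seed(7)
  for (alpha in c(2.7, 3.5)) {
    v <- sample_power_law(1e4, alpha, 10)
    fv <- fit_power_law(v, x_min = 10)
    expect_lt(abs(fv$alpha - alpha), 2 * fv$fit_stderr + 0.05)
  }
  expect_error(fit_power_law(rexp(10) + 1), "20 samples")
})
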