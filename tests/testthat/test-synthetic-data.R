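test_that("generators are pure functions of (params, seed)", {
  expect_identical(gen_pattern("noise", 64, 7), gen_pattern("noise", 64, 7))
  expect_identical(gen_astrocyte(seed = 3), gen_astrocyte(seed = 3))
  m1 <- gen_ca_movie(n_events = 5, frames = 150, fov_um = 16, seed = 9)
  m2 <- gen_ca_movie(n_events = 5, frames = 150, fov_um = 16, seed = 9)
  expect_identical(m1$movie, m2$movie)
  expect_identical(m1$planted_events, m2$planted_events)
  expect_identical(gen_coupling_set(33, seed = 2)$records,
                   gen_coupling_set(33, seed = 2)$records)
  expect_identical(gen_traces(seed = 4)$ik1, gen_traces(seed = 4)$ik1)
  # the caller's RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_pattern("noise", 64, 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generator preconditions are enforced", {
  expect_error(gen_pattern("blob", 128, 1))
  expect_error(gen_pattern("noise", 32, 1), ">= 64")
  expect_error(gen_astrocyte(n_rays = 0), "n_rays")
  expect_error(gen_astrocyte(leaflet_vf = 0), "leaflet_vf")
  expect_error(gen_astrocyte(ray_length_um = 60, fov_um = 100),
               "field of view")
  expect_error(gen_ca_movie(alpha_area = 0.9))
  expect_error(gen_ca_movie(frames = 60), "frames")
  expect_error(gen_coupling_set(-5), "c_lambda")
  expect_error(gen_coupling_set(33, n = 2), "n must be")
  expect_error(gen_traces(tau_s = -1), "tau_s")
})

test_that("synthetic astrocyte honors its stated invariants", {
  a <- gen_astrocyte(n_rays = 5, ray_length_um = 30, leaflet_vf = 0.05,
                     seed = 6)
  expect_true(all(a$image_stack >= 0))
  expect_equal(a$truth$n_primary_rays, 5L)
  # soma is the brightest region
  zmid <- a$soma_center["z"]
  expect_equal(max(a$image_stack),
               a$image_stack[zmid, a$soma_center["y"], a$soma_center["x"]])
  # haze level equals leaflet_vf times soma intensity inside the domain
  plane <- a$image_stack[zmid, , ]
  npx <- nrow(plane)
  far_corner_r <- sqrt(2) * npx / 2 * a$pixel_size
  expect_gt(far_corner_r, a$truth$domain_radius_um)  # background exists
  vals <- sort(unique(round(as.vector(plane), 10)))
  expect_true(all(c(0, 0.05, 1) %in% vals))
})

test_that("planted power-law samples and movie truths respect their bounds", {
  mv <- gen_ca_movie(n_events = 40, frames = 200, fov_um = 48, seed = 12)
  ev <- mv$planted_events
  expect_equal(nrow(ev), 40L)
  expect_true(all(ev$footprint_area_um2 >= 10))
  expect_true(all(ev$duration_s >= 2))
  expect_true(all(ev$cy >= 1 & ev$cy <= 96 & ev$cx >= 1 & ev$cx <= 96))
  expect_true(all(dim(mv$dark_frames) == c(30, 96, 96)))
  # empty case
  mv0 <- gen_ca_movie(n_events = 0, frames = 150, fov_um = 16, seed = 1)
  expect_equal(nrow(mv0$planted_events), 0L)
})

test_that("inverse-CDF power-law sampling matches its distribution", {
  set.seed(33)
  v <- sample_power_law(2e4, 2.5, 10)
  expect_true(all(v >= 10))
  # closed-form CDF: P(X > x) = (x / xmin)^(1 - alpha)
  for (x in c(20, 50, 100))
    expect_equal(mean(v > x), (x / 10)^(1 - 2.5), tolerance = 0.05)
  vt <- sample_power_law(1e4, 2.5, 10, x_max = 50)
  expect_true(all(vt <= 50))
})

test_that("noiseless coupling sets decode to the exact planted constant", {
  cs <- gen_coupling_set(33, n = 50, noise_sd = 0, seed = 5)
  expect_true(all(cs$records$normalized_intensity > 0 &
                  cs$records$normalized_intensity <= 1))
  expect_equal(fit_coupling(cs)$c_lambda, 33, tolerance = 1e-9)
})

test_that("trace generator closed forms hold", {
  ts <- gen_traces(tau_s = 2.5, ik_amp_pA = 30, seed = 2)
  t0 <- ts$stim_times$ik
  sel <- ts$ik1$time_s > t0 + 0.15  # past the fast contaminant
  expected <- 30 * exp(-(ts$ik1$time_s[sel] - t0) / 2.5)
  expect_equal(ts$ik1$current_pA[sel], expected, tolerance = 1e-12)
  # Gompertz truth: max slope a*k/e
  expect_equal(ts$truth$max_slope, 3.32 * 6 / exp(1))
  # null plasticity
  ts0 <- gen_traces(ltp_early = 1, seed = 2)
  expect_equal(ltp_magnitude(ts0$ltp_series)$magnitude, 1)
})
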