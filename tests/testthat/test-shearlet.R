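test_that("system construction matches the cone-adapted index set and is a tight frame", {
  for (J in 1:3) {
    sys <- build_system(64, J)
    expect_equal(length(sys$windows), oracle_n_features(J))
    expect_equal(n_features(J), oracle_n_features(J))
    tot <- sys$lowpass^2
    for (w in sys$windows) tot <- tot + w^2
    expect_lt(max(abs(tot - 1)), 1e-10)
  }
  expect_error(build_system(255, 3), "square|even")
  expect_error(build_system(c(64, 60), 3), "square")
})

test_that("transform is linear, invertible and translation covariant", {
  sys <- build_system(64, 3)
  set.seed(11)
  img <- matrix(rnorm(64 * 64), 64, 64)

  st <- transform(img, sys)
  expect_equal(length(st$coefficients), length(sys$windows))

  # linearity and the zero image
  z <- transform(matrix(0, 64, 64), sys)
  expect_true(all(vapply(z$coefficients, function(co) max(Mod(co)),
                         numeric(1)) == 0))
  st2 <- transform(3.5 * img, sys)
  expect_lt(max(Mod(st2$coefficients[[7]] - 3.5 * st$coefficients[[7]])),
            1e-10)

  # exact reconstruction, mean preserved
  rec <- inverse_transform(st, sys)
  expect_lt(max(abs(rec - img)), 1e-8)
  expect_lt(abs(mean(rec) - mean(img)), 1e-10)

  # circular shift covariance
  sh <- img[c(9:64, 1:8), c(4:64, 1:3)]
  sts <- transform(sh, sys)
  expect_lt(max(Mod(sts$coefficients[[12]] -
                    st$coefficients[[12]][c(9:64, 1:8), c(4:64, 1:3)])),
            1e-8)

  expect_error(transform(matrix(0, 32, 32), sys), "shape")
})

test_that("stripe power lands in the band predicted by a Fourier-geometry oracle", {
  size <- 128
  sys <- build_system(size, 3)
  fi <- sys$feature_index
  cases <- list(c(theta = 0, cycles = 20), c(theta = pi / 2, cycles = 20),
                c(theta = 0.35, cycles = 10))
  for (cs in cases) {
    img <- oracle_stripe(size, cs["theta"], cs["cycles"])
    st <- transform(img, sys)
    band_power <- vapply(st$coefficients, function(co) sum(Mod(co)^2),
                         numeric(1))
    got <- which.max(band_power)

    # oracle: the stripe's wavevector is (fx, fy) = cycles * (cos, sin) /
    # (N/2 cycles at Nyquist); locate its scale ring and shear index directly
    fx <- cs["cycles"] * cos(cs["theta"]) / (size / 2)
    fy <- cs["cycles"] * sin(cs["theta"]) / (size / 2)
    rho <- sqrt(fx^2 + fy^2)
    J <- 3
    exp_scale <- max(which(2^((0:(J - 1)) - J) < rho))  # band lower edges
    cone <- if (abs(fy) <= abs(fx)) "h" else "v"
    u <- if (cone == "h") fy / fx else fx / fy
    m <- 2^(exp_scale - 1)
    exp_shear <- round(m * u)
    ok_cone <- fi$cone[got] %in% c(cone, "seam")
    expect_equal(fi$scale[got], exp_scale)
    expect_true(ok_cone)
    expect_lte(abs(fi$shear[got] - exp_shear), 1)
  }
})

test_that("feature densities are simplex-valued with a flagged uniform fallback", {
  sys <- build_system(64, 2)
  set.seed(5)
  st <- transform(matrix(runif(64 * 64), 64, 64), sys)
  pd <- local_power_density(st)
  expect_lt(max(abs(rowSums(pd$P) - 1)), 1e-12)
  expect_true(all(pd$P >= 0))
  expect_false(any(pd$uniform_fallback))

  z <- local_power_density(transform(matrix(0, 64, 64), sys))
  expect_true(all(z$uniform_fallback))
  expect_equal(unname(z$P[1, ]), rep(1 / ncol(z$P), ncol(z$P)))

  expect_error(local_power_density(st, smoothing_sigmas = c(1, 2, 3)),
               "sigma")
})

test_that("noise density sits far closer to uniform than an ordered stripe's", {
  size <- 128
  sys <- build_system(size, 3)
  tv <- function(img) {
    pd <- local_power_density(transform(img, sys))
    mean(0.5 * rowSums(abs(pd$P - 1 / ncol(pd$P))))
  }
  tv_noise <- tv(gen_pattern("noise", size, 3))
  tv_stripe <- tv(oracle_stripe(size, 0.4, 16))
  expect_lt(tv_noise, tv_stripe / 2)
})
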