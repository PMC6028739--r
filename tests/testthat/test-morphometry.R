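test_that("branch masks cover the generated skeleton and are deterministic", {
  a <- gen_astrocyte(n_rays = 6, ray_length_um = 40, seed = 3)
  bm <- make_branch_mask(a)
  expect_false(bm$empty)
  # ground-truth skeleton: ray pixels from the generator's angles
  npx <- dim(a$image_stack)[2]
  cy <- a$soma_center["y"]; cx <- a$soma_center["x"]
  px_len <- a$truth$ray_lengths[1] / a$pixel_size
  covered <- 0L; total <- 0L
  for (ang in a$truth$ray_angles) {
    for (s in seq(8, px_len - 2, by = 1)) {  # skip soma, stop short of tips
      r <- round(cy + s * sin(ang)); c <- round(cx + s * cos(ang))
      total <- total + 1L
      # allow 1-px dilation
      hit <- FALSE
      for (dr in -1:1) for (dc in -1:1)
        if (bm$mask[r + dr, c + dc]) hit <- TRUE
      covered <- covered + hit
    }
  }
  expect_gte(covered / total, 0.95)

  bm2 <- make_branch_mask(a)
  expect_identical(bm$mask, bm2$mask)

  # degenerate input
  flat <- array(1, c(2, 64, 64))
  bmf <- make_branch_mask(flat, soma_center = c(32, 32))
  expect_true(bmf$empty)
  expect_false(any(bmf$mask))
})

test_that("Sholl counts equal the analytic ray-circle crossing count", {
  # oracle: n straight rays of length L cross every circle of radius
  # r in (soma, L) exactly n times
  for (n_rays in c(3, 6)) {
    m <- oracle_star_mask(256, n_rays, ray_len_px = 100)
    sp <- sholl_profile(m, step_um = 2, soma_center = c(128, 128),
                        pixel_size = 0.5)
    in_ray <- sp$radii_um > 4 & sp$radii_um < 49
    expect_true(all(sp$intersections[in_ray] == n_rays))
    expect_equal(sp$metrics$n_primary, n_rays)
    expect_true(all(sp$intersections[sp$radii_um > 51] == 0))
  }
  # empty mask
  sp0 <- sholl_profile(matrix(FALSE, 64, 64), step_um = 2,
                       soma_center = c(32, 32), pixel_size = 0.5)
  expect_true(all(sp0$intersections == 0))
  expect_equal(sp0$metrics$enclosing_radius_um, 0)
  # soma off the mask
  m <- oracle_star_mask(128, 3, 40)
  expect_error(sholl_profile(m, step_um = 2, soma_center = c(2, 2),
                             pixel_size = 0.5), "soma")
})

test_that("a bifurcating ray steps the profile from 1 to 2 at the branch point", {
  n <- 256
  m <- matrix(FALSE, n, n)
  cy <- cx <- 128
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  m[(yy - cy)^2 + (xx - cx)^2 <= 36] <- TRUE
  draw_seg <- function(p0, ang, len) {
    for (s in seq(0, len, by = 0.4)) {
      r <- round(p0[1] + s * sin(ang)); c <- round(p0[2] + s * cos(ang))
      m[max(1, r - 1):min(n, r + 1), max(1, c - 1):min(n, c + 1)] <<- TRUE
    }
    p0 + len * c(sin(ang), cos(ang))
  }
  # stem to 20 um (40 px at 0.5 um/px), then two branches to 40 um
  tip <- draw_seg(c(cy, cx), 0.5, 40)
  draw_seg(tip, 0.5 + 0.5, 40)
  draw_seg(tip, 0.5 - 0.5, 40)
  sp <- sholl_profile(m, step_um = 2, soma_center = c(cy, cx),
                      pixel_size = 0.5)
  expect_true(all(sp$intersections[sp$radii_um > 4 & sp$radii_um < 19] == 1))
  expect_true(all(sp$intersections[sp$radii_um > 23 & sp$radii_um < 36] == 2))
})

test_that("Sholl counts are rotation tolerant and pixel-size aware", {
  base <- sholl_profile(oracle_star_mask(256, 6, 100, angle0 = 0.3),
                        step_um = 2, soma_center = c(128, 128),
                        pixel_size = 0.5)
  rot <- sholl_profile(oracle_star_mask(256, 6, 100, angle0 = 0.3 + 0.7),
                       step_um = 2, soma_center = c(128, 128),
                       pixel_size = 0.5)
  in_ray <- base$radii_um > 4 & base$radii_um < 49
  expect_true(all(abs(base$intersections[in_ray] -
                      rot$intersections[in_ray]) <= 1))
  # halving pixel size halves the um enclosing radius for the same mask
  fine <- sholl_profile(oracle_star_mask(256, 6, 100), step_um = 1,
                        soma_center = c(128, 128), pixel_size = 0.25)
  expect_equal(fine$metrics$enclosing_radius_um,
               base$metrics$enclosing_radius_um / 2, tolerance = 0.1)
})

test_that("volume fraction implements the soma/background calibration identity", {
  plane <- matrix(10, 64, 64)          # background level 10
  plane[28:36, 28:36] <- 110           # soma
  plane[40:50, 10:20] <- 10 + 0.05 * 100  # 5% haze patch
  soma <- matrix(FALSE, 64, 64); soma[29:35, 29:35] <- TRUE
  bg <- matrix(FALSE, 64, 64); bg[1:10, 1:10] <- TRUE
  line <- rbind(c(32, 32), c(45, 15))
  vp <- vf_profile(plane, line, soma, bg, pixel_size = 1)
  expect_equal(vp$F_max, 110)
  expect_equal(vp$F_0, 10)
  expect_equal(max(vp$GV), 1)          # F = Fmax -> GV = 1
  expect_equal(vp$GV[length(vp$GV)], 0.05, tolerance = 1e-9)

  # affine intensity invariance: GV unchanged under a*F + b
  vp2 <- vf_profile(3 * plane + 7, line, soma, bg, pixel_size = 1)
  expect_equal(vp2$GV, vp$GV, tolerance = 1e-9)

  # degenerate calibration and saturation
  expect_error(vf_profile(plane, line, bg, soma, pixel_size = 1),
               "exceed")
  expect_error(vf_profile(plane, line, soma, bg, pixel_size = 1,
                          detector_ceiling = 100), "saturated")
})

test_that("planted leaflet volume fractions are recovered on noiseless stacks", {
  for (vf in c(0.01, 0.034, 0.10)) {
    a <- gen_astrocyte(n_rays = 4, ray_length_um = 40, leaflet_vf = vf,
                       seed = 7)
    vp <- vf_from_synthetic(a)
    expect_equal(vp$mean_leaflet_vf, 100 * vf, tolerance = 0.3)
  }
})
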