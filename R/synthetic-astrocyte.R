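# Synthetic astrocyte z-stacks with known morphological ground truth.

#' Generate a synthetic astrocyte z-stack
#'
#' Builds a small fluorescence z-stack emulating a dye-filled astrocyte: a
#' bright soma, `n_rays` straight (optionally gently curved) processes
#' radiating from it, and a uniform sub-resolution "leaflet haze" filling the
#' cell's territory at a fraction `leaflet_vf` of the soma intensity.
#' Background outside the territory is zero (plus noise). The exact ground
#' truth is returned alongside the stack, so Sholl counts and
#' volume-fraction recovery can be tested against it.
#'
#' @param n_rays number of primary processes (>= 1).
#' @param ray_length_um process length in micrometers.
#' @param leaflet_vf leaflet volume fraction in (0, 1); the haze intensity is
#'   `leaflet_vf * soma intensity` (default 0.034, the scale reported for
#'   hippocampal astrocytes).
#' @param pixel_size micrometers per pixel (default 0.5).
#' @param noise_sd additive Gaussian noise sd as a fraction of soma intensity
#'   (default 0 = noiseless).
#' @param fov_um side of the square field of view, micrometers; default
#'   `2 * (ray_length_um + 15)`. Must be at least `2 * ray_length_um`.
#' @param n_planes number of z planes (default 3; soma and rays sit in the
#'   middle plane, haze fills all planes).
#' @param curvature per-step heading jitter (radians) of the rays; 0 =
#'   perfectly straight.
#' @param seed integer seed.
#' @return `synthetic_astrocyte`: list with `image_stack` (z, y, x array),
#'   `soma_center` (z, y, x voxel), `pixel_size`, and `truth`
#'   (`n_primary_rays`, `ray_lengths`, `ray_angles`, `leaflet_vf`,
#'   `soma_radius_um`, `domain_radius_um`).
#' @export
gen_astrocyte <- function(n_rays = 6, ray_length_um = 40, leaflet_vf = 0.034,
                          pixel_size = 0.5, noise_sd = 0, fov_um = NULL,
                          n_planes = 3, curvature = 0, seed = 1) {
  n_rays <- as.integer(n_rays)
  if (n_rays < 1L) stop("n_rays must be >= 1", call. = FALSE)
  if (leaflet_vf <= 0 || leaflet_vf >= 1)
    stop("leaflet_vf must be in (0, 1)", call. = FALSE)
  if (is.null(fov_um)) fov_um <- 2 * (ray_length_um + 15)
  if (fov_um < 2 * ray_length_um)
    stop("field of view smaller than 2 * ray_length_um", call. = FALSE)

  with_seed(seed, {
    npx <- as.integer(round(fov_um / pixel_size))
    if (npx %% 2L == 1L) npx <- npx + 1L
    soma_radius_um <- 5
    domain_radius_um <- min(ray_length_um + 10, fov_um / 2)
    cy <- npx / 2; cx <- npx / 2
    yy <- matrix(seq_len(npx), npx, npx)
    xx <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
    r_um <- sqrt((yy - cy)^2 + (xx - cx)^2) * pixel_size

    soma_peak <- 1
    haze <- ifelse(r_um <= domain_radius_um, leaflet_vf * soma_peak, 0)
    plane_mid <- haze
    # soma disk
    plane_mid[r_um <= soma_radius_um] <- soma_peak
    # rays: evenly spaced headings with a common random offset
    ang0 <- stats::runif(1, 0, 2 * pi)
    angles <- ang0 + 2 * pi * (seq_len(n_rays) - 1) / n_rays
    ray_half_w <- max(1L, round(0.75 / pixel_size))  # ~1.5 um wide
    for (a in angles) {
      pos <- c(cy, cx)
      heading <- a
      step_um <- 1
      n_step <- ceiling(ray_length_um / step_um)
      for (s in seq_len(n_step)) {
        nxt <- pos + (step_um / pixel_size) * c(sin(heading), cos(heading))
        px <- line_pixels(pos, nxt)
        for (dr in -ray_half_w:ray_half_w) for (dc in -ray_half_w:ray_half_w) {
          rr <- px[, 1L] + dr; cc <- px[, 2L] + dc
          ok <- rr >= 1 & rr <= npx & cc >= 1 & cc <= npx
          plane_mid[cbind(rr[ok], cc[ok])] <- soma_peak
        }
        pos <- nxt
        if (curvature > 0) heading <- heading + stats::rnorm(1, 0, curvature)
      }
    }

    stack <- array(0, dim = c(n_planes, npx, npx))
    zmid <- (n_planes + 1L) %/% 2L
    for (z in seq_len(n_planes))
      stack[z, , ] <- if (z == zmid) plane_mid else haze
    if (noise_sd > 0)
      stack <- pmax(stack + array(stats::rnorm(length(stack), 0,
                                               noise_sd * soma_peak),
                                  dim = dim(stack)), 0)

    structure(list(
      image_stack = stack,
      soma_center = c(z = zmid, y = cy, x = cx),
      pixel_size = pixel_size,
      truth = list(n_primary_rays = n_rays,
                   ray_lengths = rep(ray_length_um, n_rays),
                   ray_angles = angles,
                   leaflet_vf = leaflet_vf,
                   soma_radius_um = soma_radius_um,
                   domain_radius_um = domain_radius_um)
    ), class = "synthetic_astrocyte")
  })
}
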