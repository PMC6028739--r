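# Branch-mask preprocessing, Sholl intersection profiling and leaflet
# volume-fraction estimation.

# Perona-Malik edge-preserving diffusion, exponential conductance.
# `kappa_q` sets the conduction scale from the given gradient-magnitude
# quantile of the input.
perona_malik <- function(img, n_iter = 10, kappa_q = 0.9, lambda = 0.15) {
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img
  gy <- img[c(2:nr, nr), ] - img
  kappa <- stats::quantile(abs(c(gx, gy)), kappa_q, names = FALSE)
  if (kappa <= 0) return(img)
  u <- img
  for (i in seq_len(n_iter)) {
    dn <- rbind(u[1, ], u[-nr, ]) - u
    ds <- rbind(u[-1, ], u[nr, ]) - u
    dw <- cbind(u[, 1], u[, -nc]) - u
    de <- cbind(u[, -1], u[, nc]) - u
    u <- u + lambda * (exp(-(dn / kappa)^2) * dn + exp(-(ds / kappa)^2) * ds +
                       exp(-(dw / kappa)^2) * dw + exp(-(de / kappa)^2) * de)
  }
  u
}

#' Binary branch mask from a fluorescence z-stack
#'
#' Each plane is smoothed with edge-preserving (Perona-Malik) anisotropic
#' diffusion; the maximum intensity projection is then adaptively thresholded
#' against a local-mean surface (boxcar window) plus a small offset, and
#' small objects are removed. All parameters are recorded in the result.
#'
#' @param z_stack 3D array (z, y, x) or a `synthetic_astrocyte`, or a single
#'   2D matrix.
#' @param soma_center `(y, x)` pixel position of the soma; taken from a
#'   `synthetic_astrocyte` input automatically, otherwise the brightest pixel
#'   of the projection.
#' @param pixel_size micrometers per pixel (default 0.5; taken from a
#'   `synthetic_astrocyte` input).
#' @param diffusion_iters Perona-Malik iterations (default 10).
#' @param window adaptive-threshold window, odd pixels (default 31).
#' @param offset_frac threshold offset as a fraction of the projection's
#'   intensity range (default 0.02).
#' @param min_size_px small-object removal floor, pixels (default 20).
#' @return `branch_mask`: list with `mask` (logical matrix), `soma_center`,
#'   `pixel_size`, `empty` flag, `provenance` (parameters used).
#' @export
make_branch_mask <- function(z_stack, soma_center = NULL, pixel_size = 0.5,
                             diffusion_iters = 10, window = 31,
                             offset_frac = 0.02, min_size_px = 20) {
  if (inherits(z_stack, "synthetic_astrocyte")) {
    soma_center <- soma_center %||% z_stack$soma_center[c("y", "x")]
    pixel_size <- z_stack$pixel_size
    z_stack <- z_stack$image_stack
  }
  if (is.matrix(z_stack)) z_stack <- array(z_stack, c(1L, dim(z_stack)))
  stopifnot(length(dim(z_stack)) == 3L)
  nz <- dim(z_stack)[1L]
  planes <- lapply(seq_len(nz), function(z)
    perona_malik(z_stack[z, , ], n_iter = diffusion_iters))
  proj <- Reduce(pmax, planes)

  rng <- diff(range(proj))
  if (rng == 0) {
    mask <- matrix(FALSE, nrow(proj), ncol(proj))
    return(structure(list(mask = mask, soma_center = soma_center,
                          pixel_size = pixel_size, empty = TRUE,
                          provenance = list(diffusion_iters = diffusion_iters,
                                            threshold_method = "local_mean",
                                            window = window,
                                            offset_frac = offset_frac)),
                     class = "branch_mask"))
  }
  local_mean <- box_filter(proj, as.integer(window))
  mask <- proj > local_mean + offset_frac * rng
  # remove small objects
  lab <- label_components_2d(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    mask <- lab > 0L & sizes[pmax(lab, 1L)] >= min_size_px
    dim(mask) <- dim(lab)
  }
  if (is.null(soma_center)) {
    i <- which.max(proj)
    soma_center <- c(y = ((i - 1L) %% nrow(proj)) + 1L,
                     x = ((i - 1L) %/% nrow(proj)) + 1L)
  }
  structure(list(mask = mask,
                 soma_center = as.numeric(soma_center[1:2]),
                 pixel_size = pixel_size,
                 empty = !any(mask),
                 provenance = list(diffusion_iters = diffusion_iters,
                                   threshold_method = "local_mean",
                                   window = window,
                                   offset_frac = offset_frac,
                                   min_size_px = min_size_px)),
            class = "branch_mask")
}

# Pixels on the discretized circle of radius r_px about (cy, cx), in angular
# order (step chosen below half a pixel so no circle pixel is skipped).
circle_pixels <- function(cy, cx, r_px) {
  n <- max(8L, ceiling(2 * pi * r_px / 0.4))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rr <- round(cy + r_px * sin(th))
  cc <- round(cx + r_px * cos(th))
  keep <- c(TRUE, diff(rr) != 0 | diff(cc) != 0)
  cbind(row = rr[keep], col = cc[keep])
}

# Count foreground runs around the (cyclic) sequence of circle pixels.
count_crossings <- function(mask, cy, cx, r_px) {
  px <- circle_pixels(cy, cx, r_px)
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- px[, 1L] >= 1 & px[, 1L] <= nr & px[, 2L] >= 1 & px[, 2L] <= nc
  fg <- logical(nrow(px))
  fg[inside] <- mask[px[inside, , drop = FALSE]]
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  runs <- sum(diff(c(fg, fg[1L])) == 1L)  # rising edges, cyclic
  runs
}

#' Sholl intersection profile
#'
#' Counts intersections of the branch mask with circles of increasing radius
#' centred on the soma. An intersection is one contiguous run of foreground
#' pixels along the discretized circle (run-length merging avoids double
#' counting thick branches). Derived metrics: `n_primary` (count at the first
#' radius where the circle leaves the soma's own foreground blob),
#' `peak_count`, `enclosing_radius_um` (largest radius with a non-zero
#' count), and `distal_counts` (counts at radii beyond the profile peak).
#'
#' @param mask a [make_branch_mask()] object (or logical matrix, in which
#'   case `soma_center` and `pixel_size` must be given).
#' @param step_um radius increment, micrometers (default 2).
#' @param max_radius_um largest radius; default reaches the image corner.
#' @param soma_center,pixel_size used when `mask` is a bare matrix.
#' @return `sholl_profile`: list with `radii_um`, `intersections`, `metrics`.
#' @export
sholl_profile <- function(mask, step_um = 2, max_radius_um = NULL,
                          soma_center = NULL, pixel_size = NULL) {
  if (inherits(mask, "branch_mask")) {
    soma_center <- mask$soma_center
    pixel_size <- mask$pixel_size
    m <- mask$mask
  } else {
    m <- mask
    if (is.null(soma_center) || is.null(pixel_size))
      stop("soma_center and pixel_size required for a bare mask",
           call. = FALSE)
  }
  if (step_um <= 0) stop("step_um must be > 0", call. = FALSE)
  cy <- soma_center[1L]; cx <- soma_center[2L]
  if (is.null(max_radius_um))
    max_radius_um <- max(dim(m)) / 2 * pixel_size
  radii <- seq(step_um, max_radius_um, by = step_um)
  empty <- !any(m)
  if (!empty && !m[round(cy), round(cx)])
    stop("soma_center does not lie on the foreground mask", call. = FALSE)
  counts <- vapply(radii, function(r)
    count_crossings(m, cy, cx, r / pixel_size), integer(1L))

  if (empty) {
    metrics <- list(n_primary = 0L, peak_count = 0L, enclosing_radius_um = 0,
                    distal_counts = integer(0), soma_radius_um = 0)
  } else {
    # soma blob: component containing the soma centre
    lab <- label_components_2d(m)
    soma_lab <- lab[round(cy), round(cx)]
    exits <- vapply(radii, function(r) {
      px <- circle_pixels(cy, cx, r / pixel_size)
      inb <- px[, 1L] >= 1 & px[, 1L] <= nrow(m) &
             px[, 2L] >= 1 & px[, 2L] <= ncol(m)
      if (!all(inb)) return(TRUE)
      any(lab[px] != soma_lab)
    }, logical(1L))
    first_out <- which(exits)[1L]
    n_primary <- if (is.na(first_out)) 0L else counts[first_out]
    nz <- which(counts > 0L)
    enclosing <- if (length(nz)) radii[max(nz)] else 0
    peak_i <- which.max(counts)
    metrics <- list(
      n_primary = n_primary,
      peak_count = max(counts),
      enclosing_radius_um = enclosing,
      distal_counts = if (peak_i < length(counts))
        counts[(peak_i + 1L):length(counts)] else integer(0),
      soma_radius_um = if (is.na(first_out)) 0 else radii[first_out]
    )
  }
  structure(list(radii_um = radii, intersections = counts, metrics = metrics,
                 step_um = step_um),
            class = "sholl_profile")
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf(
    "Sholl profile: %d radii (step %.1f um), primary = %d, peak = %d, enclosing = %.1f um\n",
    length(x$radii_um), x$step_um, x$metrics$n_primary, x$metrics$peak_count,
    x$metrics$enclosing_radius_um))
  invisible(x)
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$radii_um, x$intersections, type = "b",
                 xlab = "radius (um)", ylab = "intersections", ...)
  invisible(x)
}

#' Leaflet volume-fraction profile along a line
#'
#' Samples fluorescence along a line drawn from the soma on a single z plane
#' and converts it to an estimated volume fraction
#' `GV = (F - F0) / (Fmax - F0)`, where `Fmax` is the mean soma fluorescence
#' (assumed 100 percent cytosol in the excitation volume) and `F0` the mean
#' background in an area free of stained astrocytes. The summary
#' `mean_leaflet_vf` (percent) averages GV over line positions outside the
#' soma and outside caller-marked branch intervals.
#'
#' @param plane 2D numeric matrix (single z plane).
#' @param line_endpoints 2x2 matrix, rows `(y, x)` in pixels: start (at/near
#'   the soma) and end of the profile line. Conventionally 45 um long.
#' @param soma_roi logical matrix marking soma pixels (for `Fmax`).
#' @param background_roi logical matrix marking background pixels (for `F0`).
#' @param pixel_size micrometers per pixel.
#' @param soma_exclude_um positions closer than this to the line start are
#'   excluded from the leaflet mean (default: first position with GV < 0.5,
#'   i.e. past the soma edge).
#' @param branch_exclude_um list of `c(from, to)` position intervals (um) to
#'   exclude as branches (default none).
#' @param detector_ceiling optional saturation level; an error is raised if
#'   soma pixels reach it (the method requires unsaturated soma).
#' @return `vf_profile`: list with `positions_um`, `GV`, `F_max`, `F_0`,
#'   `mean_leaflet_vf` (percent), `clipped` (count of GV values clipped to
#'   [0, 1]).
#' @export
vf_profile <- function(plane, line_endpoints, soma_roi, background_roi,
                       pixel_size = 0.5, soma_exclude_um = NULL,
                       branch_exclude_um = list(), detector_ceiling = NULL) {
  stopifnot(is.matrix(plane), all(dim(soma_roi) == dim(plane)),
            all(dim(background_roi) == dim(plane)))
  F_max <- mean(plane[soma_roi])
  F_0 <- mean(plane[background_roi])
  if (!is.null(detector_ceiling) && any(plane[soma_roi] >= detector_ceiling))
    stop("soma fluorescence saturated; volume fraction calibration invalid",
         call. = FALSE)
  if (F_max <= F_0)
    stop("soma fluorescence must exceed background (degenerate calibration)",
         call. = FALSE)
  p0 <- as.numeric(line_endpoints[1L, ])
  p1 <- as.numeric(line_endpoints[2L, ])
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len_px * 2))
  tt <- seq(0, 1, length.out = n)
  rr <- pmin(pmax(round(p0[1L] + tt * (p1[1L] - p0[1L])), 1L), nrow(plane))
  cc <- pmin(pmax(round(p0[2L] + tt * (p1[2L] - p0[2L])), 1L), ncol(plane))
  Fline <- plane[cbind(rr, cc)]
  pos <- tt * len_px * pixel_size
  GV <- (Fline - F_0) / (F_max - F_0)
  clipped <- sum(GV < 0 | GV > 1)
  GV <- pmin(pmax(GV, 0), 1)

  if (is.null(soma_exclude_um)) {
    below <- which(GV < 0.5)
    soma_exclude_um <- if (length(below)) pos[below[1L]] else max(pos)
  }
  leaf <- pos > soma_exclude_um
  for (iv in branch_exclude_um)
    leaf <- leaf & !(pos >= iv[1L] & pos <= iv[2L])
  mean_vf <- if (any(leaf)) 100 * mean(GV[leaf]) else NA_real_

  structure(list(positions_um = pos, GV = GV, F_max = F_max, F_0 = F_0,
                 mean_leaflet_vf = mean_vf, clipped = clipped,
                 soma_exclude_um = soma_exclude_um),
            class = "vf_profile")
}
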