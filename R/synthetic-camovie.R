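# Synthetic calcium imaging movies with planted x-y-time events whose
# footprint areas and durations follow power laws.

#' Sample from a continuous power-law distribution
#'
#' Inverse-CDF sampling from `P(x) ~ x^-alpha` for `x >= x_min`
#' (`alpha > 1`), optionally truncated at `x_max` (resampling).
#'
#' @param n number of samples.
#' @param alpha exponent (> 1).
#' @param x_min lower bound (> 0).
#' @param x_max optional upper truncation.
#' @return Numeric vector of length `n`. Uses the current RNG state; seed with
#'   [with_seed()]-style wrappers or `set.seed()` upstream.
#' @export
sample_power_law <- function(n, alpha, x_min, x_max = Inf) {
  stopifnot(alpha > 1, x_min > 0, x_max > x_min)
  u <- stats::runif(n)
  if (is.finite(x_max)) {
    # inverse CDF of the truncated law
    a1 <- 1 - alpha
    u <- u * (x_max^a1 - x_min^a1) + x_min^a1
    u^(1 / a1)
  } else {
    x_min * (1 - u)^(-1 / (alpha - 1))
  }
}

#' Generate a synthetic calcium imaging movie
#'
#' Plants `n_events` elliptical x-y-time events on a drifting baseline with
#' shot-like noise. Event footprint areas (um^2) and durations (s) are drawn
#' from power laws with exponents `alpha_area` and `alpha_duration` above the
#' analysis filter floors (10 um^2, 2 s), so the downstream exclusion filters
#' do not bias exponent recovery. Each event rises linearly over one frame and
#' decays exponentially, truncated at half amplitude so its supra-threshold
#' support equals the planted duration. Dark-noise frames (constant offset +
#' Gaussian noise) are returned with the movie.
#'
#' Events are placed by rejection sampling so that their padded x-y-time
#' bounding boxes are disjoint; if a placement cannot be found, or if the
#' requested event load implies > 50 percent per-pixel duty cycle, a warning
#' is issued (overlapping events confound the ground truth).
#'
#' @param n_events number of planted events (0 allowed).
#' @param alpha_area,alpha_duration power-law exponents (> 1); defaults 2.7
#'   and 2.75, the control-condition scale.
#' @param area_min_um2 minimum footprint area (default 10 um^2).
#' @param dur_min_s minimum duration (default 2 s).
#' @param fov_um field-of-view side (default 32 um).
#' @param frames number of frames (>= 120; default 300).
#' @param frame_interval seconds per frame (default 1).
#' @param pixel_size micrometers per pixel (default 0.5).
#' @param baseline_drift peak fractional amplitude of the slow multiplicative
#'   baseline drift (default 0.05).
#' @param noise_sd shot-noise scale: per-voxel Gaussian sd is
#'   `noise_sd * sqrt(F)` counts (default 0.3).
#' @param amp_range range of event amplitudes in dF/F units (default
#'   `c(0.8, 2)`).
#' @param baseline_f mean baseline fluorescence, counts (default 100).
#' @param dark_offset,dark_sd,n_dark dark-frame model: constant offset +
#'   Gaussian noise, `n_dark` frames (default 10, 2, 30).
#' @param seed integer seed.
#' @return `synthetic_ca_movie`: list with `movie` (t, y, x array, counts),
#'   `dark_frames`, `frame_interval`, `pixel_size`, `planted_events` (data
#'   frame: `t0_s`, `duration_s`, `footprint_area_um2`, `amplitude_dff`,
#'   `cy`, `cx`), `alpha_true_area`, `alpha_true_duration`.
#' @export
gen_ca_movie <- function(n_events = 15, alpha_area = 2.7,
                         alpha_duration = 2.75, area_min_um2 = 10,
                         dur_min_s = 2, fov_um = 32, frames = 300,
                         frame_interval = 1, pixel_size = 0.5,
                         baseline_drift = 0.05, noise_sd = 0.3,
                         amp_range = c(0.8, 2), baseline_f = 100,
                         dark_offset = 10, dark_sd = 2, n_dark = 30,
                         seed = 1) {
  stopifnot(alpha_area > 1, alpha_duration > 1)
  frames <- as.integer(frames)
  if (frames < 120L) stop("frames must be >= 120", call. = FALSE)
  n_events <- as.integer(n_events)

  with_seed(seed, {
    npx <- as.integer(round(fov_um / pixel_size))
    pixel_area <- pixel_size^2
    area_max <- 0.2 * npx^2 * pixel_area          # footprint must fit the field
    dur_max <- frames * frame_interval / 4

    ev <- NULL
    dff_sig <- array(0, dim = c(frames, npx, npx))
    if (n_events > 0L) {
      areas <- sample_power_law(n_events, alpha_area, area_min_um2, area_max)
      durs <- sample_power_law(n_events, alpha_duration, dur_min_s, dur_max)
      duty <- sum(areas * durs) /
        (npx^2 * pixel_area * frames * frame_interval)
      if (duty > 0.5)
        warning("planted event load implies > 50% per-pixel duty cycle; ",
                "overlapping events will confound the ground truth")
      amps <- stats::runif(n_events, amp_range[1L], amp_range[2L])
      placed <- place_events(n_events, areas, durs, npx, pixel_size,
                             frames, frame_interval)
      ev <- data.frame(t0_s = placed$t0 * frame_interval,
                       duration_s = durs,
                       footprint_area_um2 = areas,
                       amplitude_dff = amps,
                       cy = placed$cy, cx = placed$cx)
      for (i in seq_len(n_events)) {
        fp <- ellipse_footprint(placed$cy[i], placed$cx[i], areas[i],
                                placed$ar[i], placed$th[i], pixel_size, npx)
        nfr <- max(1L, round(durs[i] / frame_interval))
        tt <- placed$t0[i] + seq_len(nfr) - 1L
        tt <- tt[tt <= frames]
        prof <- amps[i] * exp(-(seq_along(tt) - 1L) * log(2) / nfr)
        for (q in seq_along(tt))
          dff_sig[tt[q], , ][fp] <- dff_sig[tt[q], , ][fp] + prof[q]
      }
    }

    drift <- 1 + baseline_drift *
      sin(2 * pi * seq_len(frames) / frames + stats::runif(1, 0, 2 * pi))
    F <- baseline_f * drift * (1 + dff_sig)
    F <- F + array(stats::rnorm(length(F), 0, noise_sd) * sqrt(pmax(F, 1)),
                   dim = dim(F))
    movie <- pmax(F, 0) + dark_offset
    dark <- array(dark_offset + stats::rnorm(n_dark * npx * npx, 0, dark_sd),
                  dim = c(n_dark, npx, npx))

    structure(list(
      movie = movie, dark_frames = dark,
      frame_interval = frame_interval, pixel_size = pixel_size,
      planted_events = ev %||%
        data.frame(t0_s = numeric(0), duration_s = numeric(0),
                   footprint_area_um2 = numeric(0), amplitude_dff = numeric(0),
                   cy = numeric(0), cx = numeric(0)),
      alpha_true_area = alpha_area,
      alpha_true_duration = alpha_duration
    ), class = "synthetic_ca_movie")
  })
}

# Rejection-sample disjoint placements (padded x-y-time bounding boxes).
place_events <- function(n, areas, durs, npx, pixel_size, frames,
                         frame_interval) {
  cy <- cx <- t0 <- ar <- th <- numeric(n)
  boxes <- matrix(numeric(0), ncol = 6L)  # y0,y1,x0,x1,t0,t1
  pad_px <- 3; pad_t <- 3
  for (i in seq_len(n)) {
    rad_px <- sqrt(areas[i] / pi) / pixel_size
    nfr <- max(1L, round(durs[i] / frame_interval))
    ok <- FALSE
    for (try in 1:200) {
      ari <- stats::runif(1, 0.5, 1); thi <- stats::runif(1, 0, pi)
      a_px <- rad_px / sqrt(ari)
      yi <- stats::runif(1, 1 + a_px, npx - a_px)
      xi <- stats::runif(1, 1 + a_px, npx - a_px)
      ti <- sample.int(max(1L, frames - nfr - 2L), 1L)
      box <- c(yi - a_px - pad_px, yi + a_px + pad_px,
               xi - a_px - pad_px, xi + a_px + pad_px,
               ti - pad_t, ti + nfr + pad_t)
      clash <- FALSE
      if (nrow(boxes)) {
        clash <- any(boxes[, 1L] <= box[2L] & boxes[, 2L] >= box[1L] &
                     boxes[, 3L] <= box[4L] & boxes[, 4L] >= box[3L] &
                     boxes[, 5L] <= box[6L] & boxes[, 6L] >= box[5L])
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) warning("could not place event ", i,
                     " without overlap; placing anyway")
    cy[i] <- yi; cx[i] <- xi; t0[i] <- ti; ar[i] <- ari; th[i] <- thi
    boxes <- rbind(boxes, box)
  }
  list(cy = cy, cx = cx, t0 = as.integer(t0), ar = ar, th = th)
}

# Logical footprint of an ellipse with the requested area (um^2), axis ratio
# and orientation, clipped to the field.
ellipse_footprint <- function(cy, cx, area_um2, axis_ratio, theta,
                              pixel_size, npx) {
  r_px <- sqrt(area_um2 / pi) / pixel_size
  a <- r_px / sqrt(axis_ratio); b <- r_px * sqrt(axis_ratio)
  yy <- matrix(seq_len(npx), npx, npx) - cy
  xx <- matrix(seq_len(npx), npx, npx, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / a)^2 + (v / b)^2 <= 1
}
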