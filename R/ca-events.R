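# x-y-time calcium event detection and power-law statistics.
#
# Processing chain: dark-noise subtraction -> (optional denoising hook) ->
# motion registration -> per-pixel dF/F with a two-pass Savitzky-Golay
# baseline (transients excluded from the second pass) -> statistical
# thresholding -> grouping of active pixels into 2D events and linking across
# frames into x-y-time 3D events -> size filters -> log-binned power-law fits.

#' Subtract dark noise from a movie
#'
#' The per-pixel median over the dark frames is subtracted from every movie
#' frame; negative results are clipped to zero (count recorded in attribute
#' `"n_clipped"`).
#'
#' @param movie 3D array (t, y, x).
#' @param dark_frames 3D array (t, y, x) with the same spatial shape
#'   (>= 1 frame).
#' @return The corrected movie.
#' @export
subtract_dark_noise <- function(movie, dark_frames) {
  stopifnot(length(dim(movie)) == 3L, length(dim(dark_frames)) == 3L)
  if (any(dim(movie)[2:3] != dim(dark_frames)[2:3]))
    stop("dark frames do not match the movie's spatial shape", call. = FALSE)
  med <- apply(dark_frames, c(2L, 3L), stats::median)
  out <- sweep(movie, c(2L, 3L), med, `-`)
  ncl <- sum(out < 0)
  out[out < 0] <- 0
  attr(out, "n_clipped") <- ncl
  out
}

# Single-frame phase correlation with subpixel refinement by local DFT
# upsampling (matrix-multiply DFT around the coarse peak). Returns the
# displacement of the frame relative to the reference (the cross-correlation
# peak sits at minus the displacement).
phase_corr_shift <- function(ref_f, frm_f, usfac = 10) {
  d <- dim(ref_f)
  R <- ref_f * Conj(frm_f)
  cc <- stats::fft(R, inverse = TRUE)
  pk <- which.max(Mod(cc))
  py <- ((pk - 1L) %% d[1L])
  px <- ((pk - 1L) %/% d[1L])
  if (py > d[1L] / 2) py <- py - d[1L]
  if (px > d[2L] / 2) px <- px - d[2L]
  if (usfac <= 1) return(c(-py, -px))
  # refine on a +/- 0.75 px neighbourhood at 1/usfac resolution; the grid
  # contains the coarse peak exactly
  w <- ceiling(0.75 * usfac)
  pos_y <- py + (-w:w) / usfac
  pos_x <- px + (-w:w) / usfac
  fy <- c(0:(d[1L] %/% 2 - 1L), -(d[1L] - d[1L] %/% 2):-1L)
  fx <- c(0:(d[2L] %/% 2 - 1L), -(d[2L] - d[2L] %/% 2):-1L)
  ky <- exp(2i * pi / d[1L] * outer(pos_y, fy))
  kx <- exp(2i * pi / d[2L] * outer(fx, pos_x))
  cc_up <- ky %*% R %*% kx
  pk2 <- which.max(Mod(cc_up))
  iy <- ((pk2 - 1L) %% nrow(cc_up)) + 1L
  ix <- ((pk2 - 1L) %/% nrow(cc_up)) + 1L
  -c(pos_y[iy], pos_x[ix])
}

#' Register a movie by phase correlation
#'
#' Each frame is aligned to the reference frame (the first, by default) by
#' cross-correlation in the Fourier domain; the peak is refined to subpixel
#' precision by local DFT upsampling and the shift applied as a Fourier phase
#' ramp. Frames carrying no information (zero variance) receive zero shift
#' with a warning.
#'
#' @param movie 3D array (t, y, x), >= 2 frames.
#' @param reference frame index used as the alignment target (default 1).
#' @param upsample subpixel upsampling factor (default 10).
#' @return List with `movie` (registered) and `shifts` (t x 2 matrix of
#'   applied `(dy, dx)` shifts, in pixels).
#' @export
register_movie <- function(movie, reference = 1L, upsample = 10) {
  stopifnot(length(dim(movie)) == 3L)
  d <- dim(movie)
  if (d[1L] < 2L) stop("need at least 2 frames", call. = FALSE)
  ref <- movie[reference, , ]
  ref_f <- stats::fft(ref)
  shifts <- matrix(0, d[1L], 2L)
  fy <- c(0:(d[2L] %/% 2 - 1L), -(d[2L] - d[2L] %/% 2):-1L) / d[2L]
  fx <- c(0:(d[3L] %/% 2 - 1L), -(d[3L] - d[3L] %/% 2):-1L) / d[3L]
  out <- movie
  for (t in seq_len(d[1L])) {
    frm <- movie[t, , ]
    if (stats::sd(frm) == 0) {
      warning("frame ", t, " carries no information; zero shift applied")
      next
    }
    s <- phase_corr_shift(ref_f, stats::fft(frm), usfac = upsample)
    shifts[t, ] <- s
    if (any(s != 0)) {
      # translate the frame by -s to undo its displacement
      ph <- exp(2i * pi * (outer(fy * s[1L], rep(1, d[3L])) +
                           outer(rep(1, d[2L]), fx * s[2L])))
      out[t, , ] <- Re(stats::fft(stats::fft(frm) * ph, inverse = TRUE)) /
        (d[2L] * d[3L])
    }
  }
  list(movie = out, shifts = shifts)
}

# Savitzky-Golay smoothing coefficients (value at the window centre).
sgolay_coef <- function(window, order = 3L) {
  stopifnot(window %% 2L == 1L, window > order)
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:order, `^`)
  H <- A %*% solve(crossprod(A), t(A))
  H[h + 1L, ]
}

# Apply an odd-length FIR smoothing kernel along the rows (time) of a
# T x npix matrix, reflection-padded at the ends.
smooth_columns <- function(X, coefs) {
  h <- (length(coefs) - 1L) %/% 2L
  Tn <- nrow(X)
  pad_top <- X[pmin(h + 1L, Tn):2L, , drop = FALSE]
  pad_bot <- X[(Tn - 1L):max(Tn - h, 1L), , drop = FALSE]
  Xp <- rbind(pad_top, X, pad_bot)
  Y <- stats::filter(Xp, coefs, method = "convolution", sides = 2L)
  Y <- as.matrix(Y)[(nrow(pad_top) + 1L):(nrow(pad_top) + Tn), , drop = FALSE]
  Y
}

#' Per-pixel dF/F with a two-pass Savitzky-Golay baseline
#'
#' Pass 1: each pixel's trace is smoothed with a 60-s, 3rd-order
#' Savitzky-Golay filter to get a provisional baseline; a provisional dF/F
#' flags transient epochs exceeding `threshold_k` robust noise SDs. Pass 2:
#' transient samples (dilated by `dilate_frames`) are removed, the gaps
#' linearly interpolated, and a 100-s filter produces the final uninterrupted
#' baseline `F0`, from which `dF/F = (F - F0) / F0`.
#'
#' @param movie 3D array (t, y, x), dark-subtracted and registered.
#' @param frame_interval seconds per frame.
#' @param pixel_size micrometers per pixel (propagated to event detection).
#' @param window1_s,window2_s filter windows, seconds (defaults 60 and 100).
#' @param sg_order polynomial order (default 3).
#' @param threshold_k transient-exclusion threshold in robust noise SDs
#'   (default 2.5).
#' @param dilate_frames frames added on both sides of each flagged transient
#'   epoch before interpolation (default 2).
#' @param denoise optional function `movie -> movie` applied before baseline
#'   estimation (pluggable denoising hook; identity by default).
#' @return `dff_movie`: list with `dff` (t, y, x array), `F0`, `noise_sd`
#'   (per-pixel robust SD of dF/F), `frame_interval`, `pixel_size`.
#' @export
compute_dff <- function(movie, frame_interval = 1, pixel_size = 0.5,
                        window1_s = 60, window2_s = 100, sg_order = 3L,
                        threshold_k = 2.5, dilate_frames = 2L,
                        denoise = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  d <- dim(movie)
  if (d[1L] * frame_interval < window2_s + 20)
    stop("movie shorter than the baseline filter window", call. = FALSE)
  if (!is.null(denoise)) movie <- denoise(movie)

  w1 <- odd_at_least(window1_s / frame_interval)
  w2 <- odd_at_least(window2_s / frame_interval)
  Tn <- d[1L]; npix <- d[2L] * d[3L]
  X <- matrix(movie, Tn, npix)

  F0t <- smooth_columns(X, sgolay_coef(w1, sg_order))
  F0t <- pmax(F0t, .Machine$double.eps)
  dfft <- (X - F0t) / F0t
  sig <- apply(dfft, 2L, stats::mad)
  sig[sig == 0] <- Inf
  act <- sweep(dfft, 2L, threshold_k * sig, `>`)
  # temporal dilation of flagged epochs
  if (dilate_frames > 0L && any(act)) {
    actd <- act
    for (s in seq_len(dilate_frames)) {
      actd[1:(Tn - s), ] <- actd[1:(Tn - s), ] | act[(s + 1L):Tn, ]
      actd[(s + 1L):Tn, ] <- actd[(s + 1L):Tn, ] | act[1:(Tn - s), ]
    }
    act <- actd
  }
  Xm <- X
  Xm[act] <- NA
  bad <- which(colSums(act) > 0L)
  for (j in bad) Xm[, j] <- fill_na_linear(Xm[, j])
  F0 <- smooth_columns(Xm, sgolay_coef(w2, sg_order))
  F0 <- pmax(F0, .Machine$double.eps)
  dff <- (X - F0) / F0
  nsd <- apply(dff, 2L, stats::mad)

  structure(list(
    dff = array(dff, d),
    F0 = array(F0, d),
    noise_sd = matrix(nsd, d[2L], d[3L]),
    frame_interval = frame_interval,
    pixel_size = pixel_size
  ), class = "dff_movie")
}

#' Detect x-y-time calcium events
#'
#' Voxels with `dF/F > threshold_k` times the per-pixel robust noise SD are
#' binarized; active pixels are grouped within each frame (8-connectivity)
#' and 2D events in consecutive frames sharing at least one pixel are linked
#' into x-y-time 3D events (equivalently: connected components under in-plane
#' 8-connectivity plus same-pixel temporal adjacency, with an optional
#' `gap_frames` tolerance). Per event: `s_max` (area of the union of
#' per-frame footprints, um^2; the largest single-frame area is also
#' reported), `integral` (voxel count x pixel area x frame interval,
#' um^2 s), `duration` (s), `t_start` (s).
#'
#' @param dff a [compute_dff()] result.
#' @param threshold_k detection threshold in robust noise SDs (default 2.5).
#' @param gap_frames temporal linking gap tolerance, frames (default 0).
#' @return Data frame of class `ca_events` with one row per event
#'   (`event_id`, `t_start_s`, `duration_s`, `s_max_um2`,
#'   `max_frame_area_um2`, `integral_um2s`, `n_voxels`, `cy`, `cx`) and the
#'   voxel lists in attribute `"voxels"`.
#' @export
detect_events <- function(dff, threshold_k = 2.5, gap_frames = 0L) {
  stopifnot(inherits(dff, "dff_movie"), threshold_k > 0)
  d <- dim(dff$dff)
  Tn <- d[1L]; ny <- d[2L]; nx <- d[3L]
  thr <- threshold_k * dff$noise_sd
  act <- sweep(matrix(dff$dff, Tn, ny * nx), 2L, as.vector(thr), `>`)
  act <- array(act, d)
  idx <- which(act)
  empty <- event_table(NULL, dff)
  if (length(idx) == 0L) return(empty)

  # voxel coordinates from linear indices of a (t, y, x) array
  tt <- ((idx - 1L) %% Tn) + 1L
  rest <- (idx - 1L) %/% Tn
  yy <- (rest %% ny) + 1L
  xx <- (rest %/% ny) + 1L

  lin <- function(t, y, x) t + Tn * ((y - 1L) + ny * (x - 1L))
  edges <- list(); k <- 1L
  offs <- list(c(0L, 1L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L), c(0L, -1L, 1L))
  for (g in seq_len(max(1L, gap_frames + 1L)))
    offs <- c(offs, list(c(g, 0L, 0L)))
  for (off in offs) {
    t2 <- tt + off[1L]; y2 <- yy + off[2L]; x2 <- xx + off[3L]
    ok <- t2 >= 1L & t2 <= Tn & y2 >= 1L & y2 <= ny & x2 >= 1L & x2 <= nx
    nb <- lin(t2[ok], y2[ok], x2[ok])
    hit <- act[nb]
    if (any(hit)) {
      edges[[k]] <- cbind(idx[ok][hit], nb[hit])
      k <- k + 1L
    }
  }
  memb <- components_from_edges(idx, edges)
  comps <- split(seq_along(idx), memb)
  ev <- lapply(comps, function(ii) {
    ts <- tt[ii]; ys <- yy[ii]; xs <- xx[ii]
    fp <- unique((xs - 1L) * ny + ys)
    per_frame <- tabulate(ts - min(ts) + 1L)
    list(t0 = min(ts), t1 = max(ts), n_fp = length(fp),
         max_frame = max(per_frame), n_vox = length(ii),
         cy = mean(ys), cx = mean(xs))
  })
  event_table(ev, dff)
}

event_table <- function(ev, dff) {
  pa <- dff$pixel_size^2
  dt <- dff$frame_interval
  if (is.null(ev) || length(ev) == 0L) {
    out <- data.frame(event_id = integer(0), t_start_s = numeric(0),
                      duration_s = numeric(0), s_max_um2 = numeric(0),
                      max_frame_area_um2 = numeric(0),
                      integral_um2s = numeric(0), n_voxels = integer(0),
                      cy = numeric(0), cx = numeric(0))
    class(out) <- c("ca_events", class(out))
    return(out)
  }
  out <- data.frame(
    event_id = seq_along(ev),
    t_start_s = vapply(ev, function(e) (e$t0 - 1) * dt, numeric(1L)),
    duration_s = vapply(ev, function(e) (e$t1 - e$t0 + 1) * dt, numeric(1L)),
    s_max_um2 = vapply(ev, function(e) e$n_fp * pa, numeric(1L)),
    max_frame_area_um2 = vapply(ev, function(e) e$max_frame * pa, numeric(1L)),
    integral_um2s = vapply(ev, function(e) e$n_vox * pa * dt, numeric(1L)),
    n_voxels = vapply(ev, function(e) e$n_vox, integer(1L)),
    cy = vapply(ev, function(e) e$cy, numeric(1L)),
    cx = vapply(ev, function(e) e$cx, numeric(1L))
  )
  class(out) <- c("ca_events", class(out))
  out
}

#' Apply the event exclusion filters
#'
#' Keeps events with integral >= 4 um^2 s, maximal projection >= 10 um^2 and
#' duration >= 2 s. The thresholds are exclusive as stated ("less than" is
#' excluded), so events exactly at a threshold are kept; events lasting at
#' least 2 s are the astrocytic class.
#'
#' @param events a `ca_events` data frame from [detect_events()].
#' @param min_integral_um2s,min_s_max_um2,min_duration_s filter floors
#'   (defaults 4, 10, 2).
#' @return The filtered `ca_events` data frame.
#' @export
filter_events <- function(events, min_integral_um2s = 4, min_s_max_um2 = 10,
                          min_duration_s = 2) {
  keep <- events$integral_um2s >= min_integral_um2s &
    events$s_max_um2 >= min_s_max_um2 &
    events$duration_s >= min_duration_s
  out <- events[keep, , drop = FALSE]
  class(out) <- class(events)
  out
}

#' Event frequency density
#'
#' Event count normalized by recording duration and imaged area:
#' `count / (duration_s * area_mm2)`, in events per second per mm^2.
#'
#' @param events a `ca_events` data frame (or an event count).
#' @param fov_area_mm2 imaged area, mm^2.
#' @param movie_duration_s recording duration, seconds.
#' @export
frequency_density <- function(events, fov_area_mm2, movie_duration_s) {
  stopifnot(fov_area_mm2 > 0, movie_duration_s > 0)
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / (movie_duration_s * fov_area_mm2)
}

#' Power-law exponent by log-binned regression
#'
#' The sample is binned in log-spaced bins above `x_min`; per-bin probability
#' density is `count / (bin width * n)`; empty bins are dropped and a
#' straight line is fitted to `(log10 centre, log10 density)`. The exponent
#' is minus the slope; its standard error comes from the regression.
#'
#' @param values positive numeric sample.
#' @param x_min lower bound of the fitted range (default `min(values)`).
#' @param n_bins number of log bins (default 12).
#' @param bin_edges optional explicit bin edges (overrides `x_min`/`n_bins`
#'   for the binning; values below the first edge are dropped).
#' @return `power_law_fit`: list with `alpha`, `fit_stderr`, `x_min`,
#'   `n_samples`, `bin_edges`, `bin_centers`, `density`.
#' @export
fit_power_law <- function(values, x_min = NULL, n_bins = 12,
                          bin_edges = NULL) {
  values <- values[is.finite(values) & values > 0]
  if (is.null(x_min)) x_min <- if (is.null(bin_edges)) min(values)
                               else min(bin_edges)
  v <- values[values >= x_min]
  if (length(v) < 20L)
    stop("need at least 20 samples >= x_min for a reliable fit",
         call. = FALSE)
  if (is.null(bin_edges))
    bin_edges <- exp(seq(log(x_min), log(max(v) * (1 + 1e-9)),
                         length.out = n_bins + 1L))
  cnt <- graphics::hist(v, breaks = bin_edges, plot = FALSE)$counts
  width <- diff(bin_edges)
  centre <- sqrt(bin_edges[-length(bin_edges)] * bin_edges[-1L])
  dens <- cnt / (width * length(v))
  keep <- cnt > 0L
  if (sum(keep) < 3L)
    stop("fewer than 3 non-empty bins; cannot fit", call. = FALSE)
  fit <- stats::lm(log10(dens[keep]) ~ log10(centre[keep]))
  s <- summary(fit)$coefficients
  structure(list(alpha = -unname(coef(fit)[2L]),
                 fit_stderr = unname(s[2L, 2L]),
                 x_min = x_min, n_samples = length(v),
                 bin_edges = bin_edges, bin_centers = centre,
                 density = dens),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f +/- %.3f (n = %d, x_min = %.3g)\n",
              x$alpha, x$fit_stderr, x$n_samples, x$x_min))
  invisible(x)
}
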