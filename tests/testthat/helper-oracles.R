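# Independent oracles and fixture builders used across the test files.

# Brute-force Jensen-Shannon machinery written directly from the defining
# formulas (independent of the package's vectorized implementation).
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
oracle_js_diseq <- function(p) {
  n <- length(p)
  pe <- rep(1 / n, n)
  J <- oracle_entropy((p + pe) / 2) - (oracle_entropy(p) + oracle_entropy(pe)) / 2
  pdeg <- c(1, rep(0, n - 1))
  Jmax <- oracle_entropy((pdeg + pe) / 2) -
    (oracle_entropy(pdeg) + oracle_entropy(pe)) / 2
  J / Jmax
}

# FFST-style feature enumeration, written independently: per scale j
# (1-based), shears -2^(j-1)..2^(j-1) in each of two cones, the two
# boundary shears glued across cones.
oracle_n_features <- function(n_scales) {
  total <- 0L
  for (j in seq_len(n_scales)) {
    m <- 2L^(j - 1L)
    per_cone <- 2L * m + 1L
    total <- total + 2L * per_cone - 2L   # glue the two seam windows
  }
  total
}

# Stripe image with known orientation (radians, 0 = pattern varying along x)
# and spatial frequency (cycles per image side).
oracle_stripe <- function(size, theta, cycles) {
  x <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - 1, size, size)
  0.5 + 0.5 * sin(2 * pi * cycles / size * (cos(theta) * x + sin(theta) * y))
}

# Build a branch mask matrix directly (bypassing image preprocessing):
# straight rays of the given half-width from a centre, on an n x n grid.
oracle_star_mask <- function(n, n_rays, ray_len_px, half_w = 1L,
                             soma_r_px = 6L, angle0 = 0.3) {
  m <- matrix(FALSE, n, n)
  cy <- cx <- n / 2
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  m[(yy - cy)^2 + (xx - cx)^2 <= soma_r_px^2] <- TRUE
  for (i in seq_len(n_rays)) {
    a <- angle0 + 2 * pi * (i - 1) / n_rays
    for (s in seq(0, ray_len_px, by = 0.4)) {
      r <- round(cy + s * sin(a)); c <- round(cx + s * cos(a))
      for (dr in -half_w:half_w) for (dc in -half_w:half_w) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= n) m[r2, c2] <- TRUE
      }
    }
  }
  m
}

# Run the detection chain on a synthetic movie and return filtered events.
run_ca_pipeline <- function(mv, threshold_k = 2.5) {
  m <- subtract_dark_noise(mv$movie, mv$dark_frames)
  dm <- compute_dff(m, mv$frame_interval, mv$pixel_size,
                    threshold_k = threshold_k)
  filter_events(detect_events(dm, threshold_k = threshold_k))
}

# Match planted events to detected ones by time overlap and centroid
# proximity; returns the recall (fraction of planted events matched).
event_recall <- function(planted, detected, pixel_size, frame_interval) {
  if (nrow(planted) == 0L) return(NA_real_)
  if (nrow(detected) == 0L) return(0)
  hit <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    p0 <- planted$t0_s[i]
    p1 <- p0 + planted$duration_s[i]
    d0 <- detected$t_start_s
    d1 <- d0 + detected$duration_s
    t_ok <- d0 <= p1 + 2 * frame_interval & d1 >= p0 - 2 * frame_interval
    r_px <- sqrt(planted$footprint_area_um2[i] / pi) / pixel_size
    c_ok <- sqrt((detected$cy - planted$cy[i])^2 +
                 (detected$cx - planted$cx[i])^2) <= r_px + 3
    hit[i] <- any(t_ok & c_ok)
  }
  mean(hit)
}

# Construct a dff_movie object directly (unit tests of the detector that
# bypass baseline estimation).
make_dff_movie <- function(dff, noise_sd = 0.01, frame_interval = 1,
                           pixel_size = 0.5) {
  structure(list(
    dff = dff,
    F0 = array(1, dim(dff)),
    noise_sd = matrix(noise_sd, dim(dff)[2L], dim(dff)[3L]),
    frame_interval = frame_interval,
    pixel_size = pixel_size
  ), class = "dff_movie")
}
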