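# Cone-adapted Meyer-type discrete shearlet transform.
#
# Frequency-domain construction in the style of the fast finite shearlet
# transform: a radial Meyer partition into scales, an angular Meyer partition
# into shears within horizontal / vertical frequency cones, seam windows glued
# across the cone boundary, and a lowpass residual. The squared windows sum to
# one at every frequency bin, so the system is a Parseval (tight) frame and
# inversion is exact up to round-off.

# Meyer auxiliary polynomial: smooth step, v(0)=0, v(1)=1.
meyer_v <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Angular bump, support (-1, 1), psi2(0) = 1; squared copies at integer
# shifts form a partition of unity.
meyer_psi2 <- function(t) sqrt(meyer_v(1 - abs(t)))

# Radial Meyer lowpass: 1 inside rho <= c/2, cosine taper to 0 at rho = c.
meyer_lowpass <- function(rho, c) {
  out <- numeric(length(rho))
  out[rho <= c / 2] <- 1
  mid <- rho > c / 2 & rho < c
  out[mid] <- cos(pi / 2 * meyer_v(2 * rho[mid] / c - 1))
  dim(out) <- dim(rho)
  out
}

#' Build a shearlet system
#'
#' Constructs the frequency-domain windows of a cone-adapted Meyer shearlet
#' frame for square even-sized images. Scale `j` (1 = coarsest) carries shear
#' indices `k` in `-2^(j-1) .. 2^(j-1)` per cone, with the two diagonal seam
#' windows glued across cones, plus one lowpass band — so orientation
#' resolution doubles with spatial frequency. The window stack is renormalized
#' so the squared windows sum to exactly 1 at every frequency bin.
#'
#' @param image_shape integer of length 1 or 2; side length(s) of the image.
#'   Must be square and even.
#' @param n_scales number of shearlet scales (>= 1); default 3.
#' @return An object of class `shearlet_system` with elements `windows`
#'   (list of real matrices, one per directional feature), `lowpass`,
#'   `feature_index` (data frame with `scale`, `shear`, `cone`), `image_shape`
#'   and `n_scales`.
#' @examples
#' sys <- build_system(64, 2)
#' nrow(sys$feature_index)
#' @export
build_system <- function(image_shape, n_scales = 3) {
  if (length(image_shape) == 1L) image_shape <- c(image_shape, image_shape)
  image_shape <- as.integer(image_shape)
  if (image_shape[1L] != image_shape[2L])
    stop("image must be square; mirror-pad upstream (see pad_to_square())",
         call. = FALSE)
  N <- image_shape[1L]
  if (N %% 2L != 0L) stop("image side must be even", call. = FALSE)
  if (N < 16L) stop("image side must be >= 16", call. = FALSE)
  n_scales <- as.integer(n_scales)
  if (n_scales < 1L) stop("n_scales must be >= 1", call. = FALSE)

  # unshifted FFT frequency grid, normalized so Nyquist radius = 1
  f <- c(0:(N %/% 2L - 1L), -(N %/% 2L):-1L) / (N / 2)
  fx <- matrix(f, N, N, byrow = TRUE)   # along columns (x)
  fy <- matrix(f, N, N)                 # along rows (y)
  rho <- sqrt(fx^2 + fy^2)
  hmask <- abs(fy) <= abs(fx)           # horizontal cone (diagonal included)
  vmask <- !hmask
  u_h <- ifelse(fx != 0, fy / fx, 0)
  u_v <- ifelse(fy != 0, fx / fy, 0)

  # radial partition: lowpass at c0 = 2^-J, band j between c_{j-1} and c_j,
  # finest band extended to the grid corners
  cs <- 2^((0:n_scales) - n_scales)
  low <- meyer_lowpass(rho, cs[1L])
  radial <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    if (j < n_scales) {
      radial[[j]] <- sqrt(pmax(meyer_lowpass(rho, cs[j + 1L])^2 -
                               meyer_lowpass(rho, cs[j])^2, 0))
    } else {
      radial[[j]] <- sqrt(pmax(1 - meyer_lowpass(rho, cs[j])^2, 0))
    }
  }

  windows <- list()
  feat <- list()
  i <- 0L
  for (j in seq_len(n_scales)) {
    m <- 2L^(j - 1L)
    Rj <- radial[[j]]
    for (k in (-(m - 1L)):(m - 1L)) {     # interior shears, each cone
      i <- i + 1L
      windows[[i]] <- Rj * (hmask * meyer_psi2(m * u_h - k))
      feat[[i]] <- data.frame(scale = j, shear = k, cone = "h")
      i <- i + 1L
      windows[[i]] <- Rj * (vmask * meyer_psi2(m * u_v - k))
      feat[[i]] <- data.frame(scale = j, shear = k, cone = "v")
    }
    for (k in c(-m, m)) {                 # seam windows glued across cones
      i <- i + 1L
      windows[[i]] <- Rj * (hmask * meyer_psi2(m * u_h - k) +
                            vmask * meyer_psi2(m * u_v - k))
      feat[[i]] <- data.frame(scale = j, shear = k, cone = "seam")
    }
  }

  # enforce the tight-frame property exactly
  total <- low^2
  for (w in windows) total <- total + w^2
  norm <- sqrt(total)
  low <- low / norm
  windows <- lapply(windows, function(w) w / norm)

  structure(list(
    windows = windows,
    lowpass = low,
    feature_index = do.call(rbind, feat),
    image_shape = image_shape,
    n_scales = n_scales
  ), class = "shearlet_system")
}

#' @export
print.shearlet_system <- function(x, ...) {
  cat(sprintf("shearlet system: %dx%d image, %d scales, %d directional features (+ lowpass)\n",
              x$image_shape[1L], x$image_shape[2L], x$n_scales,
              length(x$windows)))
  invisible(x)
}

#' Number of directional features of a shearlet system
#'
#' @param n_scales number of scales.
#' @param include_lowpass count the lowpass band as a feature?
#' @return Integer feature count: `sum over j of 2^(j+1)` directional windows
#'   (plus one if `include_lowpass`).
#' @export
n_features <- function(n_scales, include_lowpass = FALSE) {
  sum(2L^(seq_len(n_scales) + 1L)) + as.integer(include_lowpass)
}

#' Shearlet decomposition of an image
#'
#' Computes the coefficient images of `image` in the frame defined by
#' `system`, by frequency-domain windowing. One complex coefficient image per
#' directional feature, plus the lowpass band. The transform is linear and
#' covariant to circular translation.
#'
#' @param image numeric matrix matching `system$image_shape`.
#' @param system a [build_system()] object.
#' @return `shearlet_coefficients`: list with `coefficients` (list of complex
#'   matrices), `lowpass_coef`, `feature_index`, `image_shape`, `n_scales`.
#' @export
transform <- function(image, system) {
  stopifnot(inherits(system, "shearlet_system"))
  if (!is.matrix(image) || any(dim(image) != system$image_shape))
    stop("image shape does not match the shearlet system", call. = FALSE)
  FI <- stats::fft(image)
  n <- prod(dim(image))
  coefs <- lapply(system$windows, function(w)
    stats::fft(FI * w, inverse = TRUE) / n)
  lowc <- stats::fft(FI * system$lowpass, inverse = TRUE) / n
  structure(list(
    coefficients = coefs,
    lowpass_coef = lowc,
    feature_index = system$feature_index,
    image_shape = system$image_shape,
    n_scales = system$n_scales
  ), class = "shearlet_coefficients")
}

#' Inverse shearlet transform
#'
#' Reconstructs the image from a coefficient stack produced by [transform()]
#' with the same system. Exact (to round-off) by the tight-frame property.
#'
#' @param stack a `shearlet_coefficients` object.
#' @param system the [build_system()] object that produced it.
#' @return Numeric matrix.
#' @export
inverse_transform <- function(stack, system) {
  stopifnot(inherits(stack, "shearlet_coefficients"),
            inherits(system, "shearlet_system"))
  if (any(stack$image_shape != system$image_shape) ||
      length(stack$coefficients) != length(system$windows))
    stop("coefficient stack does not match the shearlet system", call. = FALSE)
  acc <- stats::fft(stack$lowpass_coef) * system$lowpass
  for (i in seq_along(system$windows))
    acc <- acc + stats::fft(stack$coefficients[[i]]) * system$windows[[i]]
  n <- prod(system$image_shape)
  Re(stats::fft(acc, inverse = TRUE) / n)
}

#' Per-pixel feature density from shearlet power
#'
#' Squared coefficient magnitudes are smoothed with a Gaussian kernel whose
#' width follows the feature's scale (coarser scale, wider kernel), then
#' normalized across all directional features at each pixel, yielding a
#' per-pixel probability distribution over scale/orientation features. Pixels
#' whose total smoothed power falls below a floor (1e-12 of the mean) are
#' assigned the uniform distribution and flagged.
#'
#' @param stack a `shearlet_coefficients` object.
#' @param smoothing_sigmas numeric vector, one sigma (pixels) per scale;
#'   default `8 / 2^(j-1)` for scale `j`.
#' @param include_lowpass include the lowpass band as a feature? Default
#'   `FALSE`: the lowpass encodes local offset, not structure.
#' @return `feature_density`: list with `P` (pixels x features matrix of
#'   per-pixel probabilities), `E` (smoothed powers), `smoothing_sigmas`,
#'   `uniform_fallback` (logical per pixel), `image_shape`, `feature_index`.
#' @export
local_power_density <- function(stack, smoothing_sigmas = NULL,
                                include_lowpass = FALSE) {
  stopifnot(inherits(stack, "shearlet_coefficients"))
  J <- stack$n_scales
  if (is.null(smoothing_sigmas)) smoothing_sigmas <- 8 / 2^(seq_len(J) - 1)
  if (length(smoothing_sigmas) != J || any(smoothing_sigmas <= 0))
    stop("need one positive smoothing sigma per scale", call. = FALSE)
  coefs <- stack$coefficients
  scales <- stack$feature_index$scale
  if (include_lowpass) {
    coefs <- c(coefs, list(stack$lowpass_coef))
    scales <- c(scales, 1L)
  }
  K <- length(coefs)
  npix <- prod(stack$image_shape)
  E <- matrix(0, npix, K)
  for (i in seq_len(K))
    E[, i] <- as.vector(gaussian_blur(Mod(coefs[[i]])^2,
                                      smoothing_sigmas[scales[i]]))
  denom <- rowSums(E)
  floor_p <- 1e-12 * mean(denom)
  fallback <- denom <= floor_p | denom == 0
  P <- E / ifelse(denom > 0, denom, 1)
  P[fallback, ] <- 1 / K
  structure(list(
    P = P, E = E,
    smoothing_sigmas = smoothing_sigmas,
    uniform_fallback = fallback,
    image_shape = stack$image_shape,
    feature_index = stack$feature_index,
    include_lowpass = include_lowpass
  ), class = "feature_density")
}

#' Mirror-pad an image to a square, even-sized frame
#'
#' @param image numeric matrix.
#' @return List with `image` (padded matrix) and `crop` (row/col ranges of the
#'   original data inside the pad).
#' @export
pad_to_square <- function(image) {
  stopifnot(is.matrix(image))
  n <- max(dim(image))
  if (n %% 2L == 1L) n <- n + 1L
  out <- matrix(0, n, n)
  mirror_idx <- function(n_src, n_dst) {
    idx <- seq_len(n_dst)
    # reflect indices > n_src back into range
    over <- idx > n_src
    idx[over] <- 2L * n_src - idx[over]
    idx
  }
  ri <- mirror_idx(nrow(image), n)
  ci <- mirror_idx(ncol(image), n)
  out <- image[ri, ci, drop = FALSE]
  list(image = out,
       crop = list(rows = seq_len(nrow(image)), cols = seq_len(ncol(image))))
}
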