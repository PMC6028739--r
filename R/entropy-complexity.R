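# Spatial entropy and disequilibrium-based statistical complexity.
#
# A probability distribution P over N scale/orientation features is scored by
# its normalized Shannon entropy H_s = S[P]/log2(N) and by the statistical
# complexity C = Q_JS * H_s, where Q_JS is the Jensen-Shannon divergence from
# the equiprobable distribution, normalized by its maximum (attained at a
# degenerate P). C vanishes both for perfectly ordered (degenerate) and fully
# random (uniform) distributions and peaks in between.

check_pvec <- function(P) {
  if (!is.numeric(P) || length(P) < 1L)
    stop("P must be a numeric probability vector", call. = FALSE)
  if (any(P < 0)) stop("P must be non-negative", call. = FALSE)
  if (abs(sum(P) - 1) > 1e-9)
    stop("P must sum to 1 (tolerance 1e-9)", call. = FALSE)
  invisible(P)
}

#' Shannon entropy (bits)
#'
#' `S[P] = -sum P_i log2 P_i`, with `0 log 0 = 0`.
#'
#' @param P probability vector (non-negative, sums to 1 within 1e-9).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
#' @export
shannon_entropy <- function(P) {
  check_pvec(P)
  nz <- P > 0
  -sum(P[nz] * log2(P[nz]))
}

#' Normalized Shannon entropy
#'
#' `H_s = S[P] / log2(N)`, in `[0, 1]`; 1 for the uniform distribution,
#' 0 for a degenerate one.
#'
#' @inheritParams shannon_entropy
#' @export
normalized_entropy <- function(P) {
  check_pvec(P)
  N <- length(P)
  if (N < 2L) stop("normalized entropy undefined for N = 1", call. = FALSE)
  shannon_entropy(P) / log2(N)
}

# Closed form for the maximal Jensen-Shannon divergence to the uniform
# distribution over N features, attained at a degenerate P: the mixture
# (P + Pe)/2 then has one mass (N+1)/(2N) and N-1 masses 1/(2N).
js_divergence_max <- function(N) {
  stopifnot(N >= 2)
  a <- (N + 1) / (2 * N)
  -a * log2(a) + (N - 1) / (2 * N) * log2(2 * N) - log2(N) / 2
}

#' Jensen-Shannon divergence from the uniform distribution (bits)
#'
#' `J[P, Pe] = S[(P + Pe)/2] - (S[P] + S[Pe]) / 2` with `Pe` equiprobable.
#'
#' @inheritParams shannon_entropy
#' @export
js_divergence <- function(P) {
  check_pvec(P)
  N <- length(P)
  if (N < 2L) stop("need at least 2 features", call. = FALSE)
  Pe <- rep(1 / N, N)
  shannon_entropy((P + Pe) / 2) -
    (shannon_entropy(P) + shannon_entropy(Pe)) / 2
}

#' Normalized Jensen-Shannon disequilibrium
#'
#' `Q_JS = J[P, Pe] / J_max`, where `J_max` (closed form in N) is the
#' divergence of a degenerate distribution. 0 for uniform P, 1 for
#' degenerate P.
#'
#' @inheritParams shannon_entropy
#' @export
js_disequilibrium <- function(P) {
  js_divergence(P) / js_divergence_max(length(P))
}

#' Statistical complexity
#'
#' `C = Q_JS[P, Pe] * H_s[P]`: the product of the normalized disequilibrium
#' and the normalized entropy. Zero for both the uniform and any degenerate
#' distribution.
#'
#' @inheritParams shannon_entropy
#' @export
complexity <- function(P) {
  js_disequilibrium(P) * normalized_entropy(P)
}

# Vectorized versions over the rows of a pixels-by-features matrix.
entropy_rows <- function(P) {
  PL <- P
  PL[PL <= 0] <- 1   # 0 log 0 = 0
  -rowSums(P * log2(PL))
}

ec_from_density_matrix <- function(P) {
  K <- ncol(P)
  S <- entropy_rows(P)
  Hs <- S / log2(K)
  M <- (P + 1 / K) / 2
  J <- entropy_rows(M) - (S + log2(K)) / 2
  Q <- pmin(pmax(J / js_divergence_max(K), 0), 1)
  Hs <- pmin(pmax(Hs, 0), 1)
  list(Hs = Hs, C = Q * Hs, Q = Q, S = S)
}

#' Map spatial entropy and complexity across an image
#'
#' Runs the shearlet decomposition, forms the per-pixel feature density
#' ([local_power_density()]), and evaluates normalized entropy and statistical
#' complexity at every pixel. Non-square or odd-sized images are mirror-padded
#' for the transform and the maps cropped back. The summary is the mean (or
#' median) over `cell_mask`.
#'
#' @param image numeric matrix.
#' @param system optional pre-built [build_system()] (must match the padded
#'   image size); built on the fly if `NULL`.
#' @param n_scales scales used when building the system; default 3.
#' @param smoothing_sigmas per-scale Gaussian sigmas for
#'   [local_power_density()]; default `8 / 2^(j-1)`.
#' @param cell_mask logical matrix, same shape as `image`, selecting the cell
#'   region for the summary; default: all pixels.
#' @param summary_fun `"mean"` (default) or `"median"` reduction over the mask.
#' @return `ec_map`: list with `entropy_map`, `complexity_map` (matrices),
#'   `cell_mask`, `summary` (named vector `mean_Hs`, `mean_C`), `n_features`.
#' @export
map_entropy_complexity <- function(image, system = NULL, n_scales = 3,
                                   smoothing_sigmas = NULL, cell_mask = NULL,
                                   summary_fun = c("mean", "median")) {
  stopifnot(is.matrix(image))
  summary_fun <- match.arg(summary_fun)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!is.logical(cell_mask) || any(dim(cell_mask) != dim(image)))
    stop("cell_mask must be a logical matrix with the shape of image",
         call. = FALSE)
  if (!any(cell_mask)) stop("cell_mask is empty", call. = FALSE)

  orig_dim <- dim(image)
  work <- image
  if (orig_dim[1L] != orig_dim[2L] || orig_dim[1L] %% 2L == 1L)
    work <- pad_to_square(image)$image
  if (is.null(system)) system <- build_system(nrow(work), n_scales)
  st <- transform(work, system)
  pd <- local_power_density(st, smoothing_sigmas)
  ec <- ec_from_density_matrix(pd$P)
  Hmap <- matrix(ec$Hs, nrow(work), ncol(work))[seq_len(orig_dim[1L]),
                                                seq_len(orig_dim[2L]),
                                                drop = FALSE]
  Cmap <- matrix(ec$C, nrow(work), ncol(work))[seq_len(orig_dim[1L]),
                                               seq_len(orig_dim[2L]),
                                               drop = FALSE]
  red <- if (summary_fun == "mean") mean else stats::median
  structure(list(
    entropy_map = Hmap,
    complexity_map = Cmap,
    cell_mask = cell_mask,
    summary = c(mean_Hs = red(Hmap[cell_mask]), mean_C = red(Cmap[cell_mask])),
    n_features = ncol(pd$P),
    n_scales = system$n_scales
  ), class = "ec_map")
}

#' @export
print.ec_map <- function(x, ...) {
  cat(sprintf("entropy-complexity map %dx%d: mean H_s = %.3f, mean C = %.3f (%d features)\n",
              nrow(x$entropy_map), ncol(x$entropy_map),
              x$summary["mean_Hs"], x$summary["mean_C"], x$n_features))
  invisible(x)
}
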