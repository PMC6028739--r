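# Internal helpers shared across modules.

# Run `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so every generator is a pure function of
# (params, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Smallest odd integer >= n (Savitzky-Golay windows must be odd).
odd_at_least <- function(n) {
  n <- max(3L, as.integer(ceiling(n)))
  if (n %% 2L == 0L) n + 1L else n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FFT-based circular convolution of a 2D matrix with an isotropic Gaussian
# kernel (unit mass). Periodic boundary; adequate for the smoothing scales
# used here (sigma << image size).
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma > 0)
  n1 <- nrow(x); n2 <- ncol(x)
  g1 <- gauss_kernel_1d(n1, sigma)
  g2 <- gauss_kernel_1d(n2, sigma)
  K <- outer(g1, g2)
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
}

gauss_kernel_1d <- function(n, sigma) {
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  g <- exp(-d^2 / (2 * sigma^2))
  g / sum(g)
}

# Box (moving-average) filter with replicate padding, separable; used by the
# adaptive threshold. `w` must be odd.
box_filter <- function(x, w) {
  stopifnot(is.matrix(x), w %% 2L == 1L)
  h <- (w - 1L) %/% 2L
  pad_run <- function(m) {
    # cumulative-sum running mean along rows of m with replicate padding
    n <- nrow(m)
    mp <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(n, h), , drop = FALSE])
    cs <- apply(mp, 2L, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1L):(n + w), , drop = FALSE] - cs[1L:n, , drop = FALSE]) / w
  }
  t(pad_run(t(pad_run(x))))
}

# Label connected components of a logical matrix (8-connectivity).
# Returns an integer matrix, 0 = background. Built on igraph.
label_components_2d <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  k <- 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges[[k]] <- cbind(src[hit], nb[hit])
      k <- k + 1L
    }
  }
  comp <- components_from_edges(idx, edges)
  lab[idx] <- comp
  lab
}

# Shared union-find via igraph: `nodes` are linear indices, `edges` a list of
# 2-col matrices of linear indices (subset of nodes). Returns membership 1..k
# aligned with `nodes`.
components_from_edges <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    if (nrow(em)) {
      a <- match(em[, 1L], nodes)
      b <- match(em[, 2L], nodes)
      g <- igraph::add_edges(g, rbind(a, b))
    }
  }
  igraph::components(g)$membership
}

# Linear interpolation over NA runs of a vector; ends extended by the nearest
# finite value.
fill_na_linear <- function(y) {
  na <- is.na(y)
  if (!any(na)) return(y)
  if (all(na)) return(rep(0, length(y)))
  idx <- which(!na)
  stats::approx(idx, y[idx], xout = seq_along(y), rule = 2)$y
}

# Sample points along the segment p0 -> p1 (row, col in pixels) at roughly
# half-pixel spacing; returns unique integer pixel coordinates in order.
line_pixels <- function(p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = n)
  rr <- round(p0[1L] + t * (p1[1L] - p0[1L]))
  cc <- round(p0[2L] + t * (p1[2L] - p0[2L]))
  keep <- c(TRUE, diff(rr) != 0 | diff(cc) != 0)
  cbind(row = rr[keep], col = cc[keep])
}
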