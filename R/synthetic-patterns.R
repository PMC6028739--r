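# Calibration textures for the entropy-complexity plane.

#' Generate a calibration texture
#'
#' Three texture families spanning the entropy-complexity plane: `periodic`
#' (oriented stripes of a single spatial frequency — ordered, low entropy and
#' low complexity), `noise` (i.i.d. pixels — maximal entropy, low complexity),
#' and `branching` (a recursive random tree silhouette blurred by a Gaussian
#' point-spread kernel — structured randomness, high complexity).
#'
#' @param kind one of `"periodic"`, `"branching"`, `"noise"`.
#' @param size image side in pixels (>= 64).
#' @param seed integer seed; the generator is a pure function of
#'   `(kind, size, seed)`.
#' @return A `size` x `size` numeric matrix with non-negative intensities.
#' @examples
#' img <- gen_pattern("branching", 128, 1)
#' @export
gen_pattern <- function(kind = c("periodic", "branching", "noise"),
                        size = 256, seed = 1) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  with_seed(seed, switch(kind,
    periodic = pattern_periodic(size),
    noise = matrix(stats::runif(size * size), size, size),
    branching = pattern_branching(size)
  ))
}

pattern_periodic <- function(size) {
  theta <- stats::runif(1, 0, pi)
  cycles <- 8                       # one spatial frequency
  x <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - 1, size, size)
  ph <- 2 * pi * cycles / size * (cos(theta) * x + sin(theta) * y)
  0.5 + 0.5 * sin(ph + stats::runif(1, 0, 2 * pi))
}

# Recursive random tree: branches split with shrinking length and random
# heading changes, rasterized onto the grid and blurred by a Gaussian PSF.
pattern_branching <- function(size) {
  img <- matrix(0, size, size)
  draw <- function(p0, p1) {
    px <- line_pixels(p0, p1)
    ok <- px[, 1L] >= 1 & px[, 1L] <= size & px[, 2L] >= 1 & px[, 2L] <= size
    img[px[ok, , drop = FALSE]] <<- 1
  }
  grow <- function(pos, heading, len, depth) {
    if (depth <= 0L || len < 2) return(invisible())
    end <- pos + len * c(sin(heading), cos(heading))
    draw(pos, end)
    n_child <- 1L + stats::rbinom(1L, 1L, 0.75)
    for (i in seq_len(n_child)) {
      dh <- stats::rnorm(1, 0, 0.55)
      grow(end, heading + dh, len * stats::runif(1, 0.6, 0.85), depth - 1L)
    }
  }
  centre <- c(size / 2, size / 2)
  n_trunks <- 5L
  offs <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n_trunks))
    grow(centre, offs + 2 * pi * i / n_trunks + stats::rnorm(1, 0, 0.2),
         size / 5, 6L)
  gaussian_blur(img, 1.5)
}
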