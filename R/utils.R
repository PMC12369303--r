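#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' Derive a child seed from a top-level seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single top-level integer seed. Independent streams (one per unit, per
#' trial, per frame stack, ...) are derived deterministically with a
#' multiplicative congruential step so that changing the stream index never
#' re-uses another stream's state. Results always stay below 2^31 - 1.
#'
#' @param seed Top-level integer seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stream = 0L) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  k <- (as.double(stream) %% m)
  as.integer((s * 48271 + k * 30269 + 11) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' One-dimensional Gaussian kernel
#'
#' @param sigma Standard deviation in samples.
#' @param radius Kernel radius; defaults to `ceiling(4 * sigma)`.
#' @return Numeric vector of weights summing to one.
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smoothing of a series with reflective end handling.
smooth_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  pad <- c(x[pmin(n, (r + 1):2)], x, x[pmax(1, (n - 1):(n - r))])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1):(r + n)]
}

# Separable 2-D correlation (no kernel flip) with replicate borders.
# out[i, j] = sum_u sum_v ky[u] * kx[v] * m[i + u - cy, j + v - cx]
sep_cor <- function(m, ky, kx) {
  nr <- nrow(m); nc <- ncol(m)
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  # pad with replicated borders
  ri <- c(rep(1L, ry), seq_len(nr), rep(nr, ry))
  ci <- c(rep(1L, rx), seq_len(nc), rep(nc, rx))
  p <- m[ri, ci, drop = FALSE]
  # correlate along rows (vertical)
  tmp <- matrix(0, nr, ncol(p))
  for (u in seq_along(ky)) {
    tmp <- tmp + ky[u] * p[(u - 1L) + seq_len(nr), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (v in seq_along(kx)) {
    out <- out + kx[v] * tmp[, (v - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# Bilinear sampling of matrix m at (row = y, col = x) positions, replicate
# border. x, y are numeric vectors of equal length, 1-based coordinates.
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1L); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x1)] * fx * (1 - fy) +
    m[cbind(y1, x0)] * (1 - fx) * fy +
    m[cbind(y1, x1)] * fx * fy
}

# Bilinear resize of a matrix to nr2 x nc2 (used by the flow pyramid).
resize_bilinear <- function(m, nr2, nc2) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr2 == nr && nc2 == nc) return(m)
  ys <- (seq_len(nr2) - 0.5) * nr / nr2 + 0.5
  xs <- (seq_len(nc2) - 0.5) * nc / nc2 + 0.5
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinear_sample(m, g$x, g$y), nr2, nc2)
}

# Draw from a normal distribution, resampling non-positive values.
rnorm_positive <- function(n, mean, sd, floor = 0) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= floor)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= floor)
    guard <- guard + 1L
  }
  if (length(bad) > 0) out[bad] <- mean
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
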