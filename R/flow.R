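#' Parameters for polynomial-expansion dense optical flow
#'
#' Defaults follow the video-analysis settings used throughout the
#' package: pyramid scale 0.6 over four levels, a 7 px averaging window,
#' up to eight iterations per level, and a quadratic polynomial expansion
#' over a 5 px neighbourhood with Gaussian applicability sigma 1.5.
#'
#' @param pyr_scale Pyramid downscale factor in (0, 1).
#' @param levels Number of pyramid levels (>= 1).
#' @param winsize Averaging window in px (odd).
#' @param iterations Iterations per level.
#' @param poly_n Polynomial expansion neighbourhood in px (odd).
#' @param poly_sigma Gaussian applicability SD in px.
#' @return A `farneback_params` object.
#' @export
farneback_params <- function(pyr_scale = 0.6, levels = 4, winsize = 7,
                             iterations = 8, poly_n = 5, poly_sigma = 1.5) {
  if (pyr_scale <= 0 || pyr_scale >= 1) abort("pyr_scale must be in (0, 1)")
  if (levels < 1) abort("levels must be >= 1")
  if (winsize %% 2 != 1) abort("winsize must be odd")
  if (poly_n %% 2 != 1) abort("poly_n must be odd")
  structure(
    list(pyr_scale = pyr_scale, levels = as.integer(levels),
         winsize = as.integer(winsize), iterations = as.integer(iterations),
         poly_n = as.integer(poly_n), poly_sigma = poly_sigma),
    class = "farneback_params"
  )
}

#' Local quadratic polynomial expansion of an image
#'
#' Approximates the image locally as
#' `f(x) ~ x' A x + b' x + c` by weighted least squares over a
#' `poly_n` x `poly_n` neighbourhood with a Gaussian applicability of
#' scale `poly_sigma`, computed with separable correlations (coordinates:
#' x along columns, y along rows, both relative to the centre pixel).
#'
#' @param frame Grayscale numeric matrix.
#' @param poly_n Neighbourhood size (odd).
#' @param poly_sigma Applicability SD in px.
#' @return A list of coefficient matrices `A11`, `A12`, `A22`, `b1`
#'   (x), `b2` (y), `c`, each the size of `frame`.
#' @export
polynomial_expansion <- function(frame, poly_n = 5, poly_sigma = 1.5) {
  if (poly_n %% 2 != 1) abort("poly_n must be odd")
  if (nrow(frame) < poly_n || ncol(frame) < poly_n) {
    abort("frame smaller than the expansion neighbourhood")
  }
  n <- (poly_n - 1L) / 2L
  x <- seq(-n, n)
  a <- exp(-x^2 / (2 * poly_sigma^2))

  # separable applicability moments
  s0 <- sum(a); s2 <- sum(a * x^2); s4 <- sum(a * x^4)
  # normal-equation matrix over basis (1, x, y, x^2, y^2, xy)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[2, 2] <- s2 * s0
  G[3, 3] <- s0 * s2
  G[4, 4] <- s4 * s0
  G[5, 5] <- s0 * s4
  G[6, 6] <- s2 * s2
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[4, 5] <- G[5, 4] <- s2 * s2
  Ginv <- solve(G)

  k0 <- a; k1 <- a * x; k2 <- a * x^2
  # m[i] = correlation of f with a(y) y^p * a(x) x^q for basis element i
  m <- list(
    sep_cor(frame, k0, k0),  # 1
    sep_cor(frame, k0, k1),  # x
    sep_cor(frame, k1, k0),  # y
    sep_cor(frame, k0, k2),  # x^2
    sep_cor(frame, k2, k0),  # y^2
    sep_cor(frame, k1, k1)   # xy
  )
  r <- vector("list", 6)
  for (i in 1:6) {
    acc <- 0
    for (j in 1:6) if (Ginv[i, j] != 0) acc <- acc + Ginv[i, j] * m[[j]]
    r[[i]] <- acc
  }
  list(c = r[[1]], b1 = r[[2]], b2 = r[[3]],
       A11 = r[[4]], A22 = r[[5]], A12 = r[[6]] / 2)
}

# one flow update at a fixed pyramid level; d1, d2 are the current total
# displacement fields (x, y)
flow_update <- function(ea, frame_b, d1, d2, params) {
  nr <- nrow(frame_b); nc <- ncol(frame_b)
  xg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  yg <- matrix(seq_len(nr), nr, nc)
  warped <- matrix(bilinear_sample(frame_b, as.numeric(xg + d1),
                                   as.numeric(yg + d2)), nr, nc)
  eb <- polynomial_expansion(warped, params$poly_n, params$poly_sigma)

  A11 <- (ea$A11 + eb$A11) / 2
  A12 <- (ea$A12 + eb$A12) / 2
  A22 <- (ea$A22 + eb$A22) / 2
  db1 <- -0.5 * (eb$b1 - ea$b1) + A11 * d1 + A12 * d2
  db2 <- -0.5 * (eb$b2 - ea$b2) + A12 * d1 + A22 * d2

  w <- rep(1, params$winsize) / params$winsize
  g11 <- sep_cor(A11 * A11 + A12 * A12, w, w)
  g12 <- sep_cor(A11 * A12 + A12 * A22, w, w)
  g22 <- sep_cor(A12 * A12 + A22 * A22, w, w)
  h1 <- sep_cor(A11 * db1 + A12 * db2, w, w)
  h2 <- sep_cor(A12 * db1 + A22 * db2, w, w)

  det <- g11 * g22 - g12 * g12
  eps <- 1e-9 * stats::median(abs(det)) + 1e-30
  ok <- abs(det) > eps
  nd1 <- d1; nd2 <- d2
  nd1[ok] <- (g22[ok] * h1[ok] - g12[ok] * h2[ok]) / det[ok]
  nd2[ok] <- (g11[ok] * h2[ok] - g12[ok] * h1[ok]) / det[ok]
  list(d1 = nd1, d2 = nd2)
}

#' Dense two-frame optical flow by polynomial expansion
#'
#' Coarse-to-fine estimation: both frames are expanded into local
#' quadratic polynomials at each pyramid level and the displacement that
#' maps one expansion onto the other is solved per pixel after averaging
#' the normal equations over `winsize`, iterating with bilinear warping of
#' the second frame. The returned flow `d` satisfies
#' `frame_b(x + dx, y + dy) ~ frame_a(x, y)`: it is the motion of image
#' content from the first to the second frame, in px/frame.
#'
#' @param frame_a,frame_b Equal-size grayscale matrices.
#' @param params A [farneback_params()].
#' @return A `flow_field`: matrices `dx`, `dy` and the parameters used.
#'   Pixels within `poly_n` of the border are flagged low-confidence in
#'   the `border_margin` attribute.
#' @export
farneback_flow <- function(frame_a, frame_b, params = farneback_params()) {
  if (!all(dim(frame_a) == dim(frame_b))) abort("frame size mismatch")
  nr <- nrow(frame_a); nc <- ncol(frame_a)

  # pyramid sizes, coarse last
  sizes <- list()
  for (l in seq_len(params$levels)) {
    f <- params$pyr_scale^(l - 1)
    r2 <- max(round(nr * f), params$poly_n + 2L)
    c2 <- max(round(nc * f), params$poly_n + 2L)
    sizes[[l]] <- c(r2, c2)
  }
  smooth_sigma <- 0.5 * sqrt(1 / params$pyr_scale^2 - 1)
  gk <- gaussian_kernel(smooth_sigma)
  pyr_a <- list(frame_a); pyr_b <- list(frame_b)
  for (l in 2:max(2, params$levels)) {
    if (l > params$levels) break
    sa <- sep_cor(pyr_a[[l - 1]], gk, gk)
    sb <- sep_cor(pyr_b[[l - 1]], gk, gk)
    pyr_a[[l]] <- resize_bilinear(sa, sizes[[l]][1], sizes[[l]][2])
    pyr_b[[l]] <- resize_bilinear(sb, sizes[[l]][1], sizes[[l]][2])
  }

  d1 <- matrix(0, sizes[[params$levels]][1], sizes[[params$levels]][2])
  d2 <- d1
  for (l in rev(seq_len(params$levels))) {
    if (!all(dim(d1) == dim(pyr_a[[l]]))) {
      ry <- nrow(pyr_a[[l]]) / nrow(d1)
      rx <- ncol(pyr_a[[l]]) / ncol(d1)
      d1 <- resize_bilinear(d1, nrow(pyr_a[[l]]), ncol(pyr_a[[l]])) * rx
      d2 <- resize_bilinear(d2, nrow(pyr_a[[l]]), ncol(pyr_a[[l]])) * ry
    }
    ea <- polynomial_expansion(pyr_a[[l]], params$poly_n, params$poly_sigma)
    for (it in seq_len(params$iterations)) {
      upd <- flow_update(ea, pyr_b[[l]], d1, d2, params)
      if (max(abs(upd$d1 - d1), abs(upd$d2 - d2)) < 1e-4) {
        d1 <- upd$d1; d2 <- upd$d2
        break
      }
      d1 <- upd$d1; d2 <- upd$d2
    }
  }

  structure(
    list(dx = d1, dy = d2, params = params,
         border_margin = params$poly_n),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<flow_field> %d x %d px, median |d| = %.3f px, max = %.2f px\n",
              nrow(x$dx), ncol(x$dx), stats::median(mag), max(mag)))
  invisible(x)
}

#' Accumulate incremental flow fields
#'
#' Sums incremental per-pixel flow vectors (computed between consecutive
#' frames) elementwise at fixed pixel locations, so the result represents
#' the total displacement from the start of the sequence at each pixel.
#' The summation is Eulerian: it does not follow material points, matching
#' the cumulative-field definition used for displacement visualisation.
#'
#' @param flows A list of `flow_field` objects with identical dimensions.
#' @return A `cumulative_flow`: `cum_flow_x`, `cum_flow_y`, `n_increments`.
#' @export
accumulate_flow <- function(flows) {
  if (length(flows) == 0) abort("empty flow sequence")
  dims <- lapply(flows, function(f) dim(f$dx))
  if (!all(vapply(dims, identical, logical(1), y = dims[[1]]))) {
    abort("flow fields must have identical dimensions")
  }
  cx <- Reduce(`+`, lapply(flows, function(f) f$dx))
  cy <- Reduce(`+`, lapply(flows, function(f) f$dy))
  structure(
    list(cum_flow_x = cx, cum_flow_y = cy, n_increments = length(flows)),
    class = "cumulative_flow"
  )
}

#' Summarise a cumulative displacement field
#'
#' @param cum A `cumulative_flow`.
#' @param calibration Pixels per cm (465 with the study's video setup).
#' @param stride Sampling stride in px for the quiver-style vector export.
#' @param background_mask Optional logical matrix marking background
#'   pixels; by default the background median is the global median
#'   magnitude, which coincides with the background when moving structures
#'   cover less than half the frame.
#' @return A `flow_summary`: maximum cumulative magnitude in px and cm,
#'   background median magnitude (px), and a tibble of strided vectors
#'   (`x`, `y`, `dx`, `dy`, `magnitude`).
#' @export
summarize_flow <- function(cum, calibration = 465, stride = 16,
                           background_mask = NULL) {
  if (calibration <= 0) abort("calibration must be > 0")
  mag <- sqrt(cum$cum_flow_x^2 + cum$cum_flow_y^2)
  bg_med <- if (is.null(background_mask)) {
    stats::median(mag)
  } else {
    stats::median(mag[background_mask])
  }
  ys <- seq(1, nrow(mag), by = stride)
  xs <- seq(1, ncol(mag), by = stride)
  g <- expand.grid(y = ys, x = xs)
  vectors <- tibble(
    x = g$x, y = g$y,
    dx = cum$cum_flow_x[cbind(g$y, g$x)],
    dy = cum$cum_flow_y[cbind(g$y, g$x)],
    magnitude = mag[cbind(g$y, g$x)]
  )
  structure(
    list(max_magnitude_px = max(mag),
         max_magnitude_cm = max(mag) / calibration,
         background_median_px = bg_med,
         calibration = calibration,
         vectors = vectors),
    class = "flow_summary"
  )
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf(
    "<flow_summary> max |d| = %.2f px (%.4f cm), background median %.3f px\n",
    x$max_magnitude_px, x$max_magnitude_cm, x$background_median_px))
  invisible(x)
}

#' @export
tidy.flow_summary <- function(x, ...) {
  x$vectors
}
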