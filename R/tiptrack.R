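#' Parameters for instrument tip tracking
#'
#' @param open_radius,close_radius Morphological opening/closing radii px.
#'   Opening is off by default: largest-component selection already
#'   removes speckle, and opening erodes a sharp apex by several px.
#' @param tolerance Contour simplification tolerance px.
#' @param search_radius Temporal-consistency radius px: the tip must lie
#'   within this distance of the previous frame's tip (about 0.65 mm at
#'   465 px/cm with the default 30 px).
#' @param curvature_span Vertex span for the turning-angle curvature
#'   estimate.
#' @param gaussian_sigma Speed smoothing SD in frames.
#' @param calibration px/cm.
#' @param fps Frames per second.
#' @return A `tip_track_params` object.
#' @export
tip_track_params <- function(open_radius = 0, close_radius = 1,
                             tolerance = 1, search_radius = 30,
                             curvature_span = 3, gaussian_sigma = 5,
                             calibration = 465, fps = 60) {
  if (search_radius <= 0) abort("search_radius must be > 0")
  if (gaussian_sigma <= 0) abort("gaussian_sigma must be > 0")
  structure(
    list(open_radius = open_radius, close_radius = close_radius,
         tolerance = tolerance, search_radius = search_radius,
         curvature_span = as.integer(curvature_span),
         gaussian_sigma = gaussian_sigma, calibration = calibration,
         fps = fps),
    class = "tip_track_params"
  )
}

# between-class variance maximisation (Otsu) threshold on [0, 1] values
otsu_threshold <- function(v, breaks = 256) {
  v <- v[is.finite(v)]
  h <- graphics::hist(v, breaks = seq(min(v), max(v), length.out = breaks + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) == 0) return(mask * 0 > 1)
  lab == which.max(tab)
}

#' Segment the dark instrument in a frame
#'
#' Thresholds the frame automatically by between-class variance
#' maximisation, keeps the below-threshold (dark) pixels and retains the
#' largest connected component. Assumes the study's imaging contrast: a
#' dark instrument over a lighter skin background. An externally supplied
#' mask (e.g. from a learned segmentation front end) can be passed to
#' downstream steps instead.
#'
#' @param frame Grayscale matrix with values in \[0, 1\].
#' @param params A [tip_track_params()] (unused fields ignored).
#' @return A logical mask matrix.
#' @export
segment_instrument <- function(frame, params = tip_track_params()) {
  thr <- otsu_threshold(as.numeric(frame))
  mask <- frame < thr
  if (!any(mask) || stats::sd(as.numeric(frame)) < 1e-6) {
    abort("no instrument found in frame", class = "cthair_no_instrument")
  }
  out <- largest_component(mask)
  if (!any(out)) {
    abort("no instrument found in frame", class = "cthair_no_instrument")
  }
  out
}

#' Refine a segmentation mask morphologically
#'
#' Opening (removes salt noise) followed by closing (fills small holes),
#' then retains the largest connected component. The open-close filter is
#' idempotent: refining twice equals refining once.
#'
#' @param mask Logical matrix.
#' @param open_radius,close_radius Structuring disc radii in px.
#' @return Refined logical mask.
#' @export
refine_mask <- function(mask, open_radius = 2, close_radius = 2) {
  m <- EBImage::Image(mask * 1)
  if (open_radius > 0) {
    m <- EBImage::opening(m, EBImage::makeBrush(2 * open_radius + 1, "disc"))
  }
  if (close_radius > 0) {
    m <- EBImage::closing(m, EBImage::makeBrush(2 * close_radius + 1, "disc"))
  }
  out <- matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask))
  if (!any(out)) return(out)
  largest_component(out)
}

# Douglas-Peucker simplification of an open polyline (n x 2 matrix)
dp_open <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) {
    sqrt(rowSums(sweep(pts, 2, a)^2))
  } else {
    abs((pts[, 1] - a[1]) * ab[2] - (pts[, 2] - a[2]) * ab[1]) / len
  }
  i <- which.max(d)
  if (d[i] <= tol) return(c(1L, n))
  left <- dp_open(pts[1:i, , drop = FALSE], tol)
  right <- dp_open(pts[i:n, , drop = FALSE], tol)
  c(left, (right[-1] + i - 1L))
}

#' Extract and simplify the outer contour of a mask
#'
#' Traces the outer boundary of the (single-component) mask as a closed
#' ordered polyline and simplifies it by maximum-deviation (Douglas-
#' Peucker) reduction; the split anchors are the two most distant boundary
#' points so that sharp features such as an instrument apex survive
#' simplification. A tolerance of zero keeps every boundary pixel.
#'
#' @param mask Logical matrix.
#' @param tolerance Maximum allowed deviation in px.
#' @return An n x 2 matrix of (x, y) vertices (closed implicitly).
#' @export
extract_contour <- function(mask, tolerance = 1) {
  if (!any(mask)) abort("empty mask")
  oc <- EBImage::ocontour(EBImage::Image(largest_component(mask) * 1))
  raw <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # ocontour is 0-based with the first coordinate along the matrix's first
  # dimension (rows = y); reorder to (x, y) = (col, row), 1-based
  pts <- cbind(x = raw[, 2] + 1, y = raw[, 1] + 1)
  if (tolerance <= 0 || nrow(pts) <= 4) return(pts)
  # split the closed contour at its two mutually most distant vertices
  c1 <- which.max(rowSums(sweep(pts, 2, colMeans(pts))^2))
  d1 <- rowSums(sweep(pts, 2, pts[c1, ])^2)
  c2 <- which.max(d1)
  i <- sort(c(c1, c2))
  seg1 <- pts[i[1]:i[2], , drop = FALSE]
  seg2 <- pts[c(i[2]:nrow(pts), 1:i[1]), , drop = FALSE]
  k1 <- dp_open(seg1, tolerance)
  k2 <- dp_open(seg2, tolerance)
  keep <- unique(c(i[1]:i[2])[k1])
  wrap <- c(i[2]:nrow(pts), 1:i[1])
  keep <- sort(unique(c(keep, wrap[k2])))
  pts[keep, , drop = FALSE]
}

# turning-angle curvature per vertex of a closed polyline
contour_curvature <- function(pts, span = 3) {
  n <- nrow(pts)
  idx <- seq_len(n)
  prev <- ((idx - 1 - span) %% n) + 1
  nxt <- ((idx - 1 + span) %% n) + 1
  v1x <- pts[idx, 1] - pts[prev, 1]; v1y <- pts[idx, 2] - pts[prev, 2]
  v2x <- pts[nxt, 1] - pts[idx, 1]; v2y <- pts[nxt, 2] - pts[idx, 2]
  dot <- v1x * v2x + v1y * v2y
  crs <- v1x * v2y - v1y * v2x
  ang <- abs(atan2(crs, dot))
  # normalise by the longer arm: with unevenly spaced vertices this keeps a
  # vertex whose span straddles a corner from outranking the corner itself
  arc <- pmax(sqrt(v1x^2 + v1y^2), sqrt(v2x^2 + v2y^2))
  ang / pmax(arc, 1e-9)
}

#' Locate the instrument tip on a contour
#'
#' The tip is the contour vertex of highest discrete curvature (turning
#' angle over arc length across a fixed vertex span). When a previous tip
#' position is supplied, candidates are restricted to vertices within
#' `search_radius` of it for temporal consistency; ties are broken by
#' proximity to the previous tip, then by lowest vertex index.
#'
#' @param contour n x 2 (x, y) vertex matrix with n >= 5.
#' @param prev_tip Optional length-2 (x, y) previous tip position.
#' @param search_radius px.
#' @param span Curvature vertex span.
#' @return Length-2 numeric (x, y).
#' @export
locate_tip <- function(contour, prev_tip = NULL, search_radius = 30,
                       span = 3) {
  if (nrow(contour) < 5) abort("contour needs at least 5 vertices")
  curv <- contour_curvature(contour, span)
  cand <- seq_len(nrow(contour))
  if (!is.null(prev_tip)) {
    d2 <- (contour[, 1] - prev_tip[1])^2 + (contour[, 2] - prev_tip[2])^2
    cand <- cand[d2[cand] <= search_radius^2]
    if (length(cand) == 0) {
      abort("no contour vertex within search_radius of the previous tip",
            class = "cthair_tracking_lost")
    }
  }
  cmax <- max(curv[cand])
  ties <- cand[curv[cand] >= cmax * (1 - 1e-6)]
  if (length(ties) > 1 && !is.null(prev_tip)) {
    d2 <- (contour[ties, 1] - prev_tip[1])^2 +
      (contour[ties, 2] - prev_tip[2])^2
    ties <- ties[order(d2, ties)]
  }
  as.numeric(contour[ties[1], ])
}

# Sub-pixel apex refinement: fit straight lines (principal axes) to the
# two contour flanks adjacent to the tip vertex and return their
# intersection. Falls back to the vertex for near-parallel flanks or when
# the intersection strays implausibly far (the flanks were not straight).
refine_apex <- function(contour, tip, skip = 4, span = 12, max_shift = 8) {
  n <- nrow(contour)
  if (n < 2 * (skip + span) + 1) return(tip)
  d2 <- (contour[, 1] - tip[1])^2 + (contour[, 2] - tip[2])^2
  idx <- which.min(d2)
  side <- function(offsets) {
    ii <- ((idx - 1 + offsets) %% n) + 1
    pts <- contour[ii, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    list(p = ctr, v = sv$v[, 1])
  }
  l1 <- side(seq(skip, skip + span))
  l2 <- side(-seq(skip, skip + span))
  # boundary pixel centres lie ~0.5 px inside the half-coverage outline:
  # shift each flank line half a pixel along its outward normal (away
  # from the contour centroid) before intersecting
  ctr_all <- colMeans(contour)
  shift_out <- function(l) {
    nrm <- c(-l$v[2], l$v[1])
    if (sum(nrm * (l$p - ctr_all)) < 0) nrm <- -nrm
    l$p <- l$p + 0.5 * nrm
    l
  }
  l1 <- shift_out(l1)
  l2 <- shift_out(l2)
  A <- cbind(l1$v, -l2$v)
  if (abs(det(A)) < 0.05) return(tip)
  ts <- solve(A, l2$p - l1$p)
  apex <- l1$p + ts[1] * l1$v
  if (sqrt(sum((apex - tip)^2)) > max_shift) return(tip)
  apex
}

#' Track the instrument tip across a frame stack
#'
#' Runs segmentation, morphological refinement, contour extraction and
#' curvature-based tip localisation on every frame, carrying the previous
#' tip as a temporal-consistency constraint; if tracking is lost the frame
#' is re-seeded without the constraint and flagged.
#'
#' @param frames A `frame_stack` (see [gen_tip_video()]) or list of
#'   grayscale matrices.
#' @param params A [tip_track_params()].
#' @return A tibble: `frame`, `x`, `y`, `reseeded`.
#' @export
track_tip <- function(frames, params = tip_track_params()) {
  flist <- if (inherits(frames, "frame_stack")) frames$frames else frames
  prev <- NULL
  out <- purrr::imap(flist, function(fr, i) {
    mask <- refine_mask(segment_instrument(fr, params),
                        params$open_radius, params$close_radius)
    ctr <- extract_contour(mask, params$tolerance)
    if (nrow(ctr) < max(5L, 2L * params$curvature_span + 3L)) {
      # near-polygonal shapes simplify to a handful of vertices; curvature
      # needs the dense boundary there
      ctr <- extract_contour(mask, 0)
    }
    reseeded <- FALSE
    tip <- tryCatch(
      locate_tip(ctr, prev, params$search_radius, params$curvature_span),
      cthair_tracking_lost = function(e) {
        reseeded <<- TRUE
        locate_tip(ctr, NULL, params$search_radius, params$curvature_span)
      }
    )
    tip <- refine_apex(ctr, tip)
    prev <<- tip
    tibble(frame = i, x = tip[1], y = tip[2], reseeded = reseeded)
  })
  bind_rows(out)
}

#' Tip speed from tracked positions
#'
#' Raw speed per frame is the Euclidean step between consecutive tip
#' positions scaled by `fps / calibration` (cm/s); the smoothed speed is a
#' Gaussian convolution with SD `gaussian_sigma` frames (reflective ends,
#' which preserves the series mean up to small boundary effects).
#'
#' @param positions Tibble with columns `x`, `y` (px), one row per frame,
#'   or an n x 2 matrix.
#' @param fps Frames per second.
#' @param calibration px/cm.
#' @param gaussian_sigma Smoothing SD in frames.
#' @return A `tip_trajectory`: `data` tibble (`frame`, `x`, `y`,
#'   `raw_speed`, `smoothed_speed`, cm/s) and `mean_speed` (cm/s, mean of
#'   the smoothed series).
#' @export
tip_speed <- function(positions, fps = 60, calibration = 465,
                      gaussian_sigma = 5) {
  if (is.matrix(positions)) {
    positions <- tibble(x = positions[, 1], y = positions[, 2])
  }
  n <- nrow(positions)
  if (n < 2) abort("need at least 2 tip positions")
  step <- sqrt(diff(positions$x)^2 + diff(positions$y)^2)
  raw <- step * fps / calibration
  sm <- smooth_gaussian(raw, gaussian_sigma)
  data <- tibble(
    frame = seq_len(n),
    x = positions$x, y = positions$y,
    raw_speed = c(NA_real_, raw),
    smoothed_speed = c(NA_real_, sm)
  )
  structure(
    list(data = data, mean_speed = mean(sm), fps = fps,
         calibration = calibration, gaussian_sigma = gaussian_sigma),
    class = "tip_trajectory"
  )
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat(sprintf("<tip_trajectory> %d frames, mean smoothed speed %.3f cm/s\n",
              nrow(x$data), x$mean_speed))
  invisible(x)
}

#' @export
tidy.tip_trajectory <- function(x, ...) {
  x$data
}

#' @export
glance.tip_trajectory <- function(x, ...) {
  tibble(n_frames = nrow(x$data), mean_speed = x$mean_speed,
         fps = x$fps, calibration = x$calibration,
         gaussian_sigma = x$gaussian_sigma)
}
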