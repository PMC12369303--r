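# Shared fixtures and independent oracles, all built in code.

# smooth random texture sampled from a continuous (bilinear) surface so
# that subpixel-shifted copies are exact resamplings of the same signal
textured_sampler <- function(seed, n_coarse = 26, big = 156) {
  co <- withr::with_seed(seed, matrix(stats::rnorm(n_coarse^2), n_coarse))
  field <- cthair:::resize_bilinear(co, big, big)
  function(n, off_x = 0, off_y = 0, origin = 30) {
    g <- expand.grid(y = seq_len(n), x = seq_len(n))
    matrix(cthair:::bilinear_sample(field, g$x + origin + off_x,
                                    g$y + origin + off_y), n, n)
  }
}

# a reduced OCT protocol for protocol-scale tests (smaller A-line rate and
# grid; window/event geometry unchanged)
small_oct_protocol <- function(...) {
  oct_protocol(aline_rate = 2000, n_depth = 100, grid_dim = c(2, 2),
               trials_per_location = 2, ...)
}

# build a surface_track directly from a depth series (for closed-form
# window tests that do not need image segmentation)
make_track <- function(depth, aline_rate = 2000) {
  structure(
    list(depth = depth, raw_depth = depth,
         valid = rep(TRUE, length(depth)),
         aline_rate = aline_rate, depth_resolution = 5.5,
         threshold = NA, threshold_k = NA, smooth_ms = 0,
         condition = "synthetic", location = c(1L, 1L), replicate = 1L,
         truth = NULL),
    class = "surface_track"
  )
}

# exhaustive-enumeration oracle for the two-sided Mann-Whitney p-value
# (no ties): enumerate all assignments of ranks to group A
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# permutation analogue of the Tukey adjusted p for one pair: probability
# that the maximum pairwise |t| under label permutation exceeds the
# observed |t| of that pair
tukey_perm_oracle <- function(values, groups, n_perm = 3000, seed = 1) {
  pair_ts <- function(v, g) {
    lev <- unique(g)
    s2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) /
      (length(v) - length(lev))
    out <- c()
    for (i in seq_along(lev)) for (j in seq_len(i - 1)) {
      ni <- sum(g == lev[i]); nj <- sum(g == lev[j])
      t <- abs(mean(v[g == lev[i]]) - mean(v[g == lev[j]])) /
        sqrt(s2 * (1 / ni + 1 / nj))
      out <- c(out, stats::setNames(t, paste(lev[i], lev[j], sep = "-")))
    }
    out
  }
  obs <- pair_ts(values, groups)
  withr::with_seed(seed, {
    maxes <- replicate(n_perm, max(pair_ts(values, sample(groups))))
  })
  vapply(obs, function(t) mean(maxes >= t - 1e-12), numeric(1))
}

# run the scikit-image iterative Lucas-Kanade dense flow (independent
# implementation) on a frame pair, returning median (dx, dy) over the
# interior; used as the cross-implementation oracle on translations
ilk_median_flow <- function(frame_a, frame_b, margin = 15) {
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fa, fb)), add = TRUE)
  utils::write.table(frame_a, fa, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  utils::write.table(frame_b, fb, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  script <- sprintf("
import sys, numpy as np
from skimage.registration import optical_flow_ilk
a = np.loadtxt('%s', delimiter=',')
b = np.loadtxt('%s', delimiter=',')
v, u = optical_flow_ilk(a, b, radius=7)
m = %d
print(np.median(u[m:-m, m:-m]), np.median(v[m:-m, m:-m]))
", fa, fb, margin)
  pf <- tempfile(fileext = ".py")
  on.exit(unlink(pf), add = TRUE)
  writeLines(script, pf)
  out <- system2("python", pf, stdout = TRUE, stderr = TRUE)
  as.numeric(strsplit(tail(out, 1), "\\s+")[[1]])
}
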