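# Fixture builders shared across the suite. All randomness is seeded by
# the caller.

# Regular polygon approximating a circle.
circle_contour <- function(z = 0, r = 10, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour_slice(z, cbind(center[1L] + r * cos(th),
                         center[2L] + r * sin(th)))
}

# Random star-shaped polygon about the origin: a polar radius function
# sampled at jittered angles.
star_polygon <- function(n = 40, rmin = 5, rmax = 15) {
  th <- sort(runif(n, 0, 2 * pi))
  # enforce minimal angular separation so edges are well conditioned
  while (min(diff(c(th, th[1L] + 2 * pi))) < 1e-3)
    th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}

# Independent boundary-distance oracle: bisection on a point-in-polygon
# test (mgcv::in.out) along the ray, avoiding the edge-intersection
# algebra used by cast_beam. Valid for star-shaped polygons about the
# origin, where the ray crosses the boundary exactly once.
oracle_beam_length <- function(origin, angle_deg, vertices, tmax = 1e3) {
  a <- angle_deg * pi / 180
  d <- c(-cos(a), sin(a))
  ring <- rbind(vertices, vertices[1L, , drop = FALSE])
  inside <- function(t) {
    p <- origin + t * d
    as.logical(mgcv::in.out(ring, matrix(p, 1L)))
  }
  lo <- 0; hi <- tmax
  if (inside(hi)) stop("oracle bracket too small")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (inside(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A small phantom configuration used across tests (10 slices, defaults
# otherwise).
small_config <- function(...) {
  phantom_config(slice_zs = seq(0, 18, by = 2), ...)
}

# Beam-length field built directly from a per-slice phase x angle matrix
# (list of matrices, one per slice), bypassing the geometry stage.
make_field <- function(per_slice, z = seq_along(per_slice)) {
  P <- nrow(per_slice[[1L]]); K <- ncol(per_slice[[1L]])
  lengths <- array(NA_real_, c(P, length(per_slice), K))
  for (s in seq_along(per_slice)) lengths[, s, ] <- per_slice[[s]]
  structure(list(lengths = lengths, valid = !is.na(lengths), z = z,
                 angles = seq_len(K) - 1L, n_invalid = sum(is.na(lengths))),
            class = "beam_length_field")
}

# Brute-force within-row mid-ranks by counting, written independently of
# base rank(): r_ij = #(x_il < x_ij) + (#(x_il == x_ij) + 1) / 2.
counting_ranks <- function(x) {
  t(apply(x, 1L, function(row)
    vapply(row, function(v)
      sum(row < v) + (sum(row == v) + 1) / 2, numeric(1L))))
}

# Brute-force Friedman chi-square from counting ranks and the textbook
# tie-corrected formula, assembled independently of friedman_rm().
oracle_friedman <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- counting_ranks(x)
  Rj <- colSums(r)
  ties <- 0
  for (i in seq_len(n)) {
    for (v in unique(x[i, ])) {
      t <- sum(x[i, ] == v)
      ties <- ties + t^3 - t
    }
  }
  denom <- n * k * (k + 1) - ties / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((Rj - n * (k + 1) / 2)^2) / denom
}
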