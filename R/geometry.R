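#' Axial skin contour for one CT slice
#'
#' Stores a closed simple polygon (in mm) delineating the skin on one axial
#' slice. Vertices are given as an n x 2 matrix of (x, y) coordinates; the
#' closing edge from the last vertex back to the first is implicit. On
#' construction the orientation is normalised to counter-clockwise, so
#' downstream code can rely on a positive signed area.
#'
#' Coordinate convention (fixed throughout the package): x increases toward
#' the patient's left, y toward anterior, z toward the head. Beam angles are
#' measured so that 0 deg points to the patient's right, 90 deg anterior,
#' 180 deg to the patient's left.
#'
#' @param z axial height of the slice, mm.
#' @param vertices n x 2 numeric matrix (or data.frame) of (x, y) vertices,
#'   mm, at least 3 rows, not self-intersecting. A duplicated closing vertex
#'   is dropped.
#' @return An object of class \code{contour_slice}.
#' @export
contour_slice <- function(z, vertices) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("'z' must be a single finite number (mm)")
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("'vertices' must be an n x 2 numeric matrix")
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ]))
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L)
    stop("contour at z = ", z, " needs at least 3 distinct vertices")
  if (any(!is.finite(v)))
    stop("contour at z = ", z, " has non-finite vertices")
  a <- signed_area(v)
  if (abs(a) < .Machine$double.eps * max(abs(v), 1))
    stop("degenerate (zero-area) contour at z = ", z)
  if (a < 0)  # normalise to counter-clockwise
    v <- v[nrow(v):1L, , drop = FALSE]
  dimnames(v) <- NULL
  structure(list(z = z, vertices = v), class = "contour_slice")
}

# Shoelace signed area of an open-ring polygon (positive = counter-clockwise).
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' @export
print.contour_slice <- function(x, ...) {
  cat(sprintf("<contour_slice> z = %g mm, %d vertices, area = %.1f mm^2\n",
              x$z, nrow(x$vertices), abs(signed_area(x$vertices))))
  invisible(x)
}

#' Skin contour stack for one respiratory phase
#'
#' @param phase respiratory phase index, 0-based (0..n_phases-1).
#' @param slices list of \code{\link{contour_slice}} objects; they are sorted
#'   by ascending z and must have distinct z values.
#' @return An object of class \code{phase_contour_set}.
#' @export
phase_contour_set <- function(phase, slices) {
  if (!is.numeric(phase) || length(phase) != 1L || phase < 0 ||
      phase != round(phase))
    stop("'phase' must be a non-negative integer index")
  if (!length(slices) || !all(vapply(slices, inherits, TRUE, "contour_slice")))
    stop("'slices' must be a non-empty list of contour_slice objects")
  zs <- vapply(slices, `[[`, numeric(1L), "z")
  if (anyDuplicated(zs))
    stop("duplicated slice z in phase ", phase)
  slices <- slices[order(zs)]
  structure(list(phase = as.integer(phase), slices = slices,
                 z = sort(zs)), class = "phase_contour_set")
}

#' @export
print.phase_contour_set <- function(x, ...) {
  cat(sprintf("<phase_contour_set> phase %d, %d slices, z in [%g, %g] mm\n",
              x$phase, length(x$slices), min(x$z), max(x$z)))
  invisible(x)
}

# Check that a list of phase_contour_set objects share one z grid; returns it.
shared_z_grid <- function(phase_sets) {
  if (!length(phase_sets) ||
      !all(vapply(phase_sets, inherits, TRUE, "phase_contour_set")))
    stop("expected a list of phase_contour_set objects")
  z0 <- phase_sets[[1L]]$z
  for (i in seq_along(phase_sets)) {
    if (!isTRUE(all.equal(phase_sets[[i]]$z, z0, tolerance = 0)))
      stop("phase ", phase_sets[[i]]$phase,
           " does not share the z grid of phase ", phase_sets[[1L]]$phase)
  }
  z0
}

#' Area-weighted centroid of a closed polygon
#'
#' Computes the centroid of the polygon interior via the shoelace
#' construction. The result is independent of vertex ordering direction and
#' of the starting vertex, and (unlike the vertex mean) is robust to uneven
#' vertex density along the boundary.
#'
#' @param contour a \code{\link{contour_slice}}, or an n x 2 vertex matrix.
#' @return Numeric vector \code{c(x, y)} in mm.
#' @export
polygon_centroid <- function(contour) {
  v <- if (inherits(contour, "contour_slice")) contour$vertices
       else as.matrix(contour)
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ]))
    v <- v[-nrow(v), , drop = FALSE]
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(abs(v), 1))
    stop("degenerate (zero-area) polygon")
  # work about the vertex mean for numerical stability far from the origin
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  c(x = cx, y = cy)
}

#' Least-squares central craniocaudal axis
#'
#' Fits two independent ordinary least-squares lines, x on z and y on z,
#' through per-slice contour centroids, giving the central body axis point
#' (x(z), y(z)) for any slice height. Collinear centroids are recovered
#' exactly (zero-residual fit).
#'
#' @param centroids n x 2 matrix of per-slice centroid (x, y), mm.
#' @param z numeric vector of the matching slice heights, mm; at least two
#'   distinct values.
#' @return Object of class \code{body_axis} with fields \code{x_intercept},
#'   \code{x_slope}, \code{y_intercept}, \code{y_slope}.
#' @seealso \code{\link{axis_point}}
#' @export
fit_axis <- function(centroids, z) {
  m <- as.matrix(centroids)
  if (ncol(m) != 2L || nrow(m) != length(z))
    stop("'centroids' must be n x 2 with n = length(z)")
  if (length(unique(z)) < 2L)
    stop("axis fit needs at least two distinct slice heights")
  fx <- stats::lm.fit(cbind(1, z), m[, 1L])$coefficients
  fy <- stats::lm.fit(cbind(1, z), m[, 2L])$coefficients
  ax <- structure(list(x_intercept = unname(fx[1L]), x_slope = unname(fx[2L]),
                       y_intercept = unname(fy[1L]), y_slope = unname(fy[2L])),
                  class = "body_axis")
  if (!all(vapply(ax, is.finite, TRUE)))
    stop("axis fit produced non-finite coefficients")
  ax
}

#' Axis point at a slice height
#'
#' @param axis a \code{body_axis} from \code{\link{fit_axis}}.
#' @param z slice height(s), mm.
#' @return n x 2 matrix of (x, y) axis points.
#' @export
axis_point <- function(axis, z) {
  stopifnot(inherits(axis, "body_axis"))
  cbind(x = axis$x_intercept + axis$x_slope * z,
        y = axis$y_intercept + axis$y_slope * z)
}

#' @export
print.body_axis <- function(x, ...) {
  cat(sprintf("<body_axis> x(z) = %.3f %+.5f z ; y(z) = %.3f %+.5f z (mm)\n",
              x$x_intercept, x$x_slope, x$y_intercept, x$y_slope))
  invisible(x)
}

#' Beam-fan angles
#'
#' The fan of 180 radial beam angles, in degrees: 0, 1, ..., 179 (half-open
#' \code{[0, 180)}). 0 deg points to the patient's right, 90 deg anterior,
#' 179 deg just short of the patient's left lateral direction. The in-plane
#' direction vector of a beam at angle theta is \code{(-cos(theta),
#' sin(theta))}.
#'
#' @return Integer vector of the 180 beam angles in degrees.
#' @export
beam_angles <- function() 0:179

# In-plane unit direction(s) for beam angle(s) in degrees.
beam_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  cbind(-cos(a), sin(a))
}

#' Cast a radial beam from an interior origin to the skin contour
#'
#' Intersects the parametric ray \code{origin + t * d(theta)}, \code{t > 0},
#' with every polygon edge and returns the distance to the outermost
#' crossing. When a ray crosses the contour more than twice (skin folds),
#' the largest t is the skin surface an optical camera would see, so that is
#' what is returned.
#'
#' @param origin numeric \code{c(x, y)}, mm; must lie strictly inside the
#'   contour.
#' @param angle beam angle in degrees (see \code{\link{beam_angles}}).
#' @param contour a \code{\link{contour_slice}}.
#' @return Beam length in mm, or \code{NA} with attribute \code{reason} if
#'   the beam is invalid (origin outside the contour, or no crossing found).
#' @export
cast_beam <- function(origin, angle, contour) {
  stopifnot(inherits(contour, "contour_slice"))
  if (!point_in_polygon(origin[1L], origin[2L], contour$vertices)) {
    out <- NA_real_
    attr(out, "reason") <- "origin outside contour"
    return(out)
  }
  len <- cast_beam_fan(origin, angle, contour$vertices)
  if (is.na(len)) {
    out <- NA_real_
    attr(out, "reason") <- "no ray-boundary intersection"
    return(out)
  }
  len
}

# Vectorised ray casting: lengths of rays at `angles` (degrees) from `origin`
# to the outermost crossing of the polygon ring `v` (n x 2, open ring).
# Returns NA where a ray finds no forward crossing. No inside check here.
cast_beam_fan <- function(origin, angles, v) {
  d <- beam_direction(angles)                       # k x 2
  a <- v                                            # n x 2 edge starts
  e <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v  # edges
  wx <- a[, 1L] - origin[1L]
  wy <- a[, 2L] - origin[2L]
  # cross(d, e), cross(w, e), cross(w, d) for all (ray, edge) pairs
  D  <- outer(d[, 1L], e[, 2L]) - outer(d[, 2L], e[, 1L])   # k x n
  tN <- matrix(wx * e[, 2L] - wy * e[, 1L], nrow = nrow(d),
               ncol = nrow(v), byrow = TRUE)                 # cross(w, e)
  sN <- outer(d[, 2L], wx) - outer(d[, 1L], wy)              # cross(w, d)
  # o + t d = a + s e  =>  t = cross(w,e)/cross(d,e), s = cross(w,d)/cross(d,e)
  tt <- tN / D
  ss <- sN / D
  tol <- 1e-9
  ok <- is.finite(tt) & is.finite(ss) & tt > tol & ss >= -tol & ss <= 1 + tol
  tt[!ok] <- -Inf
  len <- tt[cbind(seq_len(nrow(tt)), max.col(tt, ties.method = "first"))]
  len[!is.finite(len)] <- NA_real_
  len
}

# Even-odd point-in-polygon via mgcv::in.out (boundary ring closed here).
point_in_polygon <- function(px, py, v) {
  bnd <- rbind(v, v[1L, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, cbind(px, py)))
}

#' Beam-length field across phases, slices and angles
#'
#' Casts the 180-beam fan on every slice of every respiratory phase. Beam
#' origins are the axis points of the supplied (fixed) central axis, held
#' identical across phases so that length variation reflects skin motion
#' rather than centroid drift.
#'
#' @param phase_sets list of \code{\link{phase_contour_set}} objects sharing
#'   one z grid.
#' @param axis a \code{body_axis}; conventionally fitted on the first-phase
#'   centroids (see \code{\link{surrocor}}).
#' @return Object of class \code{beam_length_field}: \code{lengths} and
#'   \code{valid} arrays of dimension (phase, slice, angle), plus \code{z}
#'   and \code{angles}. Invalid beams are \code{NA} with
#'   \code{valid = FALSE}, never silently zero. A warning reports any slice
#'   with more than 5\% invalid beams; a slice with no valid beam at all in
#'   some phase is an error.
#' @export
build_beam_length_field <- function(phase_sets, axis) {
  z <- shared_z_grid(phase_sets)
  stopifnot(inherits(axis, "body_axis"))
  angles <- beam_angles()
  P <- length(phase_sets); S <- length(z); K <- length(angles)
  lengths <- array(NA_real_, dim = c(P, S, K))
  origins <- axis_point(axis, z)
  for (p in seq_len(P)) {
    for (s in seq_len(S)) {
      cs <- phase_sets[[p]]$slices[[s]]
      o <- origins[s, ]
      if (!point_in_polygon(o[1L], o[2L], cs$vertices)) {
        # whole fan invalid for this slice/phase
        next
      }
      lengths[p, s, ] <- cast_beam_fan(o, angles, cs$vertices)
    }
  }
  valid <- !is.na(lengths)
  n_invalid_slice <- apply(!valid, 2L, sum)
  for (s in seq_len(S)) {
    if (all(!valid[, s, ]))
      stop("slice at z = ", z[s], " mm has no valid beam in any phase")
    if (n_invalid_slice[s] > 0.05 * P * K)
      warning(sprintf("slice z = %g mm: %d of %d beams invalid (>5%%)",
                      z[s], n_invalid_slice[s], P * K))
  }
  structure(list(lengths = lengths, valid = valid, z = z, angles = angles,
                 n_invalid = sum(!valid)),
            class = "beam_length_field")
}

#' @export
print.beam_length_field <- function(x, ...) {
  d <- dim(x$lengths)
  cat(sprintf(paste0("<beam_length_field> %d phases x %d slices x %d beams",
                     " (%d invalid entries)\n"), d[1L], d[2L], d[3L],
              x$n_invalid))
  invisible(x)
}

#' Tracking-structure craniocaudal trajectory
#'
#' The per-phase craniocaudal (z) coordinate of the tracking structure's
#' centroid, in mm, on an axis oriented so that inhalation displacement is
#' positive.
#'
#' @param z_per_phase numeric vector, one z per respiratory phase.
#' @return Object of class \code{ts_trajectory}.
#' @export
ts_trajectory <- function(z_per_phase) {
  z <- as.numeric(z_per_phase)
  if (length(z) < 2L || any(!is.finite(z)))
    stop("a TS trajectory needs at least 2 finite per-phase coordinates")
  structure(list(z_per_phase = z), class = "ts_trajectory")
}

#' @export
print.ts_trajectory <- function(x, ...) {
  cat(sprintf("<ts_trajectory> %d phases, excursion %.2f mm\n",
              length(x$z_per_phase),
              max(x$z_per_phase) - min(x$z_per_phase)))
  invisible(x)
}

#' Craniocaudal centroid trajectory of a delineated tracking structure
#'
#' Per respiratory phase, the volume-weighted centroid z of a stack of
#' tracking-structure contours (slice area times slice z, summed over the
#' stack). Only the craniocaudal coordinate is returned; in-plane TS motion
#' is not considered.
#'
#' @param ts_contours_per_phase list (one element per phase) of lists of
#'   \code{\link{contour_slice}} objects delineating the TS in that phase.
#' @return A \code{\link{ts_trajectory}}.
#' @export
ts_centroid_z <- function(ts_contours_per_phase) {
  if (!length(ts_contours_per_phase))
    stop("no phases supplied")
  z <- vapply(seq_along(ts_contours_per_phase), function(p) {
    slices <- ts_contours_per_phase[[p]]
    if (!length(slices))
      stop("tracking structure is empty in phase ", p - 1L)
    areas <- vapply(slices, function(s) abs(signed_area(s$vertices)),
                    numeric(1L))
    zs <- vapply(slices, `[[`, numeric(1L), "z")
    sum(areas * zs) / sum(areas)
  }, numeric(1L))
  ts_trajectory(z)
}
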