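#' Axial Hounsfield-unit slice
#'
#' A single axial CT slice as a 2-D grid of Hounsfield values, with its
#' pixel spacing and a body mask (pixels inside the skin). Pixel
#' \code{[i, j]} has centre coordinates \code{origin + ((j-1)*dx,
#' (i-1)*dy)} mm.
#'
#' @param hu numeric matrix of Hounsfield values.
#' @param pixel_spacing pixel size \code{c(dx, dy)}, mm, both positive.
#' @param body_mask logical matrix of the same shape, TRUE inside the skin.
#' @param origin centre coordinates of pixel [1, 1], mm.
#' @return Object of class \code{hu_slice}.
#' @export
hu_slice <- function(hu, pixel_spacing = c(1, 1), body_mask = NULL,
                     origin = c(0, 0)) {
  hu <- as.matrix(hu)
  if (!is.numeric(hu)) stop("'hu' must be numeric")
  if (any(pixel_spacing <= 0)) stop("'pixel_spacing' must be positive")
  if (is.null(body_mask)) body_mask <- matrix(TRUE, nrow(hu), ncol(hu))
  body_mask <- as.matrix(body_mask)
  if (!all(dim(body_mask) == dim(hu)))
    stop("'body_mask' and 'hu' must have the same shape")
  structure(list(hu = hu, pixel_spacing = as.numeric(pixel_spacing),
                 body_mask = body_mask, origin = as.numeric(origin)),
            class = "hu_slice")
}

#' @export
print.hu_slice <- function(x, ...) {
  cat(sprintf("<hu_slice> %d x %d px @ %g x %g mm, body area %.0f mm^2\n",
              nrow(x$hu), ncol(x$hu), x$pixel_spacing[1L],
              x$pixel_spacing[2L],
              sum(x$body_mask) * prod(x$pixel_spacing)))
  invisible(x)
}

# Pixel-centre coordinates of the TRUE entries of a mask on a slice grid.
mask_pixel_centers <- function(slice, mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(slice$origin[1L] + (idx[, 2L] - 1L) * slice$pixel_spacing[1L],
        slice$origin[2L] + (idx[, 1L] - 1L) * slice$pixel_spacing[2L])
}

#' Threshold adipose tissue on a HU slice
#'
#' Delineates adipose tissue as the body pixels in the -150 to -20 HU
#' range (bounds inclusive).
#'
#' @param slice an \code{\link{hu_slice}}.
#' @param hu_range adipose HU window, default \code{c(-150, -20)}.
#' @return Logical matrix: the total adipose tissue (TAT) mask.
#' @export
adipose_mask <- function(slice, hu_range = c(-150, -20)) {
  stopifnot(inherits(slice, "hu_slice"))
  slice$body_mask & slice$hu >= hu_range[1L] & slice$hu <= hu_range[2L]
}

#' Split adipose tissue into visceral and subcutaneous compartments
#'
#' Visceral adipose tissue (VAT) is the set of adipose pixels whose
#' centres fall inside the inner abdominal wall polygon; the remaining
#' adipose pixels are subcutaneous (SAT). The two masks are disjoint and
#' their union is exactly the input adipose mask. The wall polygon is a
#' supplied delineation (drawn on the CT), not detected automatically.
#'
#' @param adipose logical adipose (TAT) mask, from
#'   \code{\link{adipose_mask}}.
#' @param inner_wall simple closed polygon (n x 2 matrix, mm) of the inner
#'   abdominal wall; must lie inside the body.
#' @param slice the \code{\link{hu_slice}} the mask came from.
#' @return List with logical matrices \code{sat} and \code{vat}.
#' @export
split_sat_vat <- function(adipose, inner_wall, slice) {
  stopifnot(inherits(slice, "hu_slice"))
  adipose <- as.matrix(adipose)
  if (!all(dim(adipose) == dim(slice$hu)))
    stop("'adipose' mask shape does not match the slice")
  wall <- as.matrix(inner_wall)
  if (nrow(wall) < 3L || ncol(wall) != 2L)
    stop("'inner_wall' must be an n x 2 polygon with n >= 3")
  # the wall must sit inside the body: every vertex on a body pixel
  vi <- round((wall[, 2L] - slice$origin[2L]) / slice$pixel_spacing[2L]) + 1L
  vj <- round((wall[, 1L] - slice$origin[1L]) / slice$pixel_spacing[1L]) + 1L
  inside_grid <- vi >= 1L & vi <= nrow(slice$hu) &
                 vj >= 1L & vj <= ncol(slice$hu)
  if (!all(inside_grid) ||
      !all(slice$body_mask[cbind(vi, vj)]))
    stop("'inner_wall' polygon is not inside the body mask")
  vat <- matrix(FALSE, nrow(adipose), ncol(adipose))
  if (any(adipose)) {
    pts <- mask_pixel_centers(slice, adipose)
    ring <- rbind(wall, wall[1L, , drop = FALSE])
    inside <- as.logical(mgcv::in.out(ring, pts))
    vat[which(adipose)] <- inside
  }
  sat <- adipose & !vat
  list(sat = sat, vat = vat)
}

#' Adipose areas and percentages of the slice surface
#'
#' Converts the SAT and VAT masks to areas (pixel count times pixel area)
#' and to percentages of a reference slice surface: by default the body
#' cross-section area (the meaningful denominator for between-patient
#' comparison), optionally the full image frame.
#'
#' @param sat,vat logical masks from \code{\link{split_sat_vat}}.
#' @param slice the \code{\link{hu_slice}}.
#' @param reference_kind \code{"body"} (default) or \code{"frame"}.
#' @return Object of class \code{adipose_result}: sat/vat/tat areas (mm^2),
#'   sat/vat/tat percentages of the reference area, the reference area and
#'   its kind. \code{tat_area = sat_area + vat_area} exactly.
#' @export
adipose_percentages <- function(sat, vat, slice,
                                reference_kind = c("body", "frame")) {
  reference_kind <- match.arg(reference_kind)
  stopifnot(inherits(slice, "hu_slice"))
  if (any(sat & vat)) stop("SAT and VAT masks overlap")
  px <- prod(slice$pixel_spacing)
  ref <- switch(reference_kind,
                body = sum(slice$body_mask) * px,
                frame = length(slice$hu) * px)
  if (ref <= 0) stop("zero reference area")
  sat_area <- sum(sat) * px
  vat_area <- sum(vat) * px
  structure(list(sat_area = sat_area, vat_area = vat_area,
                 tat_area = sat_area + vat_area,
                 sat_pct = 100 * sat_area / ref,
                 vat_pct = 100 * vat_area / ref,
                 tat_pct = 100 * (sat_area + vat_area) / ref,
                 reference_area = ref, reference_kind = reference_kind),
            class = "adipose_result")
}

#' @export
print.adipose_result <- function(x, ...) {
  cat(sprintf(paste0("<adipose_result> SAT %.0f mm^2 (%.1f%%), VAT %.0f",
                     " mm^2 (%.1f%%), TAT %.1f%% of %s area\n"),
              x$sat_area, x$sat_pct, x$vat_area, x$vat_pct, x$tat_pct,
              x$reference_kind))
  invisible(x)
}

#' Quantify adipose tissue on an L4 slice in one call
#'
#' Convenience wrapper: threshold, split at the inner abdominal wall, and
#' convert to percentages.
#'
#' @inheritParams split_sat_vat
#' @inheritParams adipose_percentages
#' @param hu_range adipose HU window, default \code{c(-150, -20)}.
#' @return An \code{adipose_result}.
#' @export
quantify_adipose <- function(slice, inner_wall,
                             reference_kind = c("body", "frame"),
                             hu_range = c(-150, -20)) {
  tat <- adipose_mask(slice, hu_range)
  sv <- split_sat_vat(tat, inner_wall, slice)
  adipose_percentages(sv$sat, sv$vat, slice, reference_kind)
}
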