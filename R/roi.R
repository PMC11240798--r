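#' Nine-region torso partition
#'
#' Defines the nine anatomical skin regions used to summarise the maps.
#' Columns come from the beam angle: a right parasternal band [30, 75) deg
#' (suffix \code{_R}), a central band [75, 105) deg (no suffix) and a left
#' band [105, 150) deg (suffix \code{_L}); beams lateral of 30 or 150 deg
#' belong to no region. Rows come from the slice height: row A between the
#' xipho-sternal line and the superior limit, row B between the subcostal
#' plane and the xipho-sternal line, row C between the inferior limit
#' (around the umbilicus/L4) and the subcostal plane. All intervals are
#' half-open \code{[lower, upper)}: the 75 and 105 deg boundary beams and
#' the landmark slices belong to exactly one region.
#'
#' Landmark heights are per-patient inputs located anatomically on the CT;
#' no automatic landmark detection is attempted.
#'
#' @param z_xiphosternal height of the xipho-sternal line, mm.
#' @param z_subcostal height of the subcostal plane, mm.
#' @param z_inferior_limit caudal cutoff, mm.
#' @param z_superior_limit cranial cutoff, mm.
#' @return Object of class \code{roi_partition}.
#' @export
roi_partition <- function(z_xiphosternal, z_subcostal,
                          z_inferior_limit, z_superior_limit) {
  if (!(z_inferior_limit < z_subcostal && z_subcostal < z_xiphosternal &&
        z_xiphosternal < z_superior_limit))
    stop("landmarks must satisfy z_inferior_limit < z_subcostal < ",
         "z_xiphosternal < z_superior_limit")
  structure(list(z_xiphosternal = z_xiphosternal,
                 z_subcostal = z_subcostal,
                 z_inferior_limit = z_inferior_limit,
                 z_superior_limit = z_superior_limit,
                 bands = list(right = c(30, 75), central = c(75, 105),
                              left = c(105, 150))),
            class = "roi_partition")
}

#' The nine ROI labels
#' @return Character vector A, A_R, A_L, B, B_R, B_L, C, C_R, C_L.
#' @export
roi_labels <- function()
  c("A", "A_R", "A_L", "B", "B_R", "B_L", "C", "C_R", "C_L")

#' Label every beam with its ROI
#'
#' Assigns each (slice, angle) beam to one of the nine regions of a
#' \code{\link{roi_partition}}, or to none (NA) for beams outside the
#' 30-150 deg angular range or the craniocaudal limits. Each beam maps to
#' at most one region (the bands and rows are disjoint half-open
#' intervals).
#'
#' @param partition a \code{\link{roi_partition}}.
#' @param slice_zs slice heights, mm.
#' @param angles beam angles, degrees (default \code{\link{beam_angles}}).
#' @return n_slices x n_angles character matrix of labels (NA = unassigned)
#'   with attribute \code{counts}, the per-ROI beam counts. It is an error
#'   for any of the nine regions to receive no beams.
#' @export
label_beams <- function(partition, slice_zs, angles = beam_angles()) {
  stopifnot(inherits(partition, "roi_partition"))
  row_of <- function(z) {
    ifelse(z >= partition$z_xiphosternal & z < partition$z_superior_limit,
           "A",
    ifelse(z >= partition$z_subcostal & z < partition$z_xiphosternal, "B",
    ifelse(z >= partition$z_inferior_limit & z < partition$z_subcostal, "C",
           NA_character_)))
  }
  b <- partition$bands
  col_of <- function(a) {
    ifelse(a >= b$right[1L] & a < b$right[2L], "_R",
    ifelse(a >= b$central[1L] & a < b$central[2L], "",
    ifelse(a >= b$left[1L] & a < b$left[2L], "_L", NA_character_)))
  }
  rows <- row_of(slice_zs)
  cols <- col_of(angles)
  lab <- outer(rows, cols, function(r, c)
    ifelse(is.na(r) | is.na(c), NA_character_, paste0(r, c)))
  counts <- table(factor(lab, levels = roi_labels()))
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop("ROI(s) with zero beams: ", paste(empty, collapse = ", "))
  dimnames(lab) <- NULL
  attr(lab, "counts") <- counts
  attr(lab, "z") <- slice_zs
  attr(lab, "angles") <- angles
  lab
}

#' Aggregate the maps over the nine ROIs
#'
#' Per region, aggregates the defined per-beam values of the correlation
#' and magnitude maps with the chosen aggregator. Undefined beams are
#' excluded and counted. The mean is the default aggregator; the median is
#' available for robust reporting, and reports state which was used.
#'
#' @param cmap a \code{correlation_map}.
#' @param mmap the matching \code{magnitude_map}.
#' @param labels beam labels from \code{\link{label_beams}} (same shape as
#'   the maps).
#' @param aggregator \code{"mean"} (default) or \code{"median"}.
#' @return data.frame of class \code{roi_summary} with one row per region:
#'   roi, magnitude_mm, pearson_r, n_beams (labelled beams),
#'   n_used_magnitude, n_used_r, aggregator. It is an error for any region
#'   to have only undefined beams.
#' @export
summarize_roi <- function(cmap, mmap, labels,
                          aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(cmap, "correlation_map"),
            inherits(mmap, "magnitude_map"))
  if (!all(dim(labels) == dim(cmap$r)) || !all(dim(labels) == dim(mmap$m)))
    stop("'labels' shape does not match the maps")
  agg <- if (aggregator == "mean") mean else stats::median
  out <- lapply(roi_labels(), function(lb) {
    sel <- !is.na(labels) & labels == lb
    rv <- cmap$r[sel]; mv <- mmap$m[sel]
    if (all(is.na(mv)) || all(is.na(rv)))
      stop("ROI ", lb, " has only undefined beams")
    data.frame(roi = lb,
               magnitude_mm = agg(mv[!is.na(mv)]),
               pearson_r = agg(rv[!is.na(rv)]),
               n_beams = sum(sel),
               n_used_magnitude = sum(!is.na(mv)),
               n_used_r = sum(!is.na(rv)),
               aggregator = aggregator)
  })
  out <- do.call(rbind, out)
  class(out) <- c("roi_summary", "data.frame")
  out
}
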