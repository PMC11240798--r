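#' Skin-surface surrogate analysis of one patient's 4DCT contours
#'
#' The core analysis: from a multi-phase stack of axial skin contours and
#' the craniocaudal trajectory of an internal tracking structure (TS), fit
#' the central craniocaudal body axis by least squares on the per-slice
#' contour centroids, cast the 180-beam radial fan on every slice of every
#' phase from the fixed axis, and derive the per-beam respiratory
#' magnitude map (max - min beam length over phases, mm) and skin-to-TS
#' Pearson correlation map. If a nine-region partition is supplied, the
#' maps are aggregated into per-region summaries.
#'
#' The axis is fitted on the centroids of a single anchor phase (the first
#' by default) and held fixed across phases, so that beam-length variation
#' reflects skin motion rather than centroid drift.
#'
#' @param phases list of \code{\link{phase_contour_set}} objects sharing
#'   one slice z grid (one per respiratory phase, typically 10).
#' @param ts a \code{\link{ts_trajectory}} with one craniocaudal
#'   coordinate per phase.
#' @param partition optional \code{\link{roi_partition}}; when given, the
#'   nine-region summary is computed.
#' @param aggregator per-region aggregator, \code{"mean"} (default) or
#'   \code{"median"}.
#' @param axis_phase 1-based index of the phase whose centroids anchor the
#'   axis fit (default 1).
#' @return Object of class \code{surrocor} with components \code{axis},
#'   \code{field}, \code{correlation} (a \code{correlation_map}),
#'   \code{magnitude} (a \code{magnitude_map}), \code{ts},
#'   \code{ts_magnitude} (mm), and \code{roi} (a \code{roi_summary} or
#'   NULL).
#' @examples
#' cfg <- phantom_config(slice_zs = seq(0, 45, by = 5))
#' torso <- generate_torso(cfg)
#' fit <- surrocor(torso$phases, generate_ts(cfg))
#' fit
#' @export
surrocor <- function(phases, ts, partition = NULL,
                     aggregator = c("mean", "median"), axis_phase = 1L) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(ts, "ts_trajectory"))
  z <- shared_z_grid(phases)
  if (length(ts$z_per_phase) != length(phases))
    stop("trajectory and contour set disagree on the number of phases")
  anchor <- phases[[axis_phase]]
  cents <- t(vapply(anchor$slices, polygon_centroid, numeric(2L)))
  axis <- fit_axis(cents, z)
  field <- build_beam_length_field(phases, axis)
  cmap <- pearson_map(field, ts)
  mmap <- magnitude_map(field)
  roi <- NULL
  if (!is.null(partition)) {
    labels <- label_beams(partition, z)
    roi <- summarize_roi(cmap, mmap, labels, aggregator)
  }
  structure(list(axis = axis, field = field, correlation = cmap,
                 magnitude = mmap, ts = ts,
                 ts_magnitude = ts_magnitude(ts), roi = roi,
                 aggregator = aggregator, call = match.call()),
            class = "surrocor")
}

#' @export
print.surrocor <- function(x, ...) {
  d <- dim(x$field$lengths)
  cat("Skin-surface surrogate analysis\n")
  cat(sprintf("  %d phases, %d slices, %d beams/slice (%d invalid beams)\n",
              d[1L], d[2L], d[3L], x$field$n_invalid))
  cat(sprintf("  TS craniocaudal magnitude: %.2f mm\n", x$ts_magnitude))
  cat(sprintf("  median beam magnitude: %.2f mm; median skin-to-TS R: %.3f\n",
              stats::median(x$magnitude$m, na.rm = TRUE),
              stats::median(x$correlation$r, na.rm = TRUE)))
  if (!is.null(x$roi))
    cat(sprintf("  nine-region summary available (aggregator: %s)\n",
                x$aggregator))
  invisible(x)
}

#' @export
summary.surrocor <- function(object, ...) {
  structure(list(n_phases = dim(object$field$lengths)[1L],
                 n_slices = dim(object$field$lengths)[2L],
                 n_invalid = object$field$n_invalid,
                 ts_magnitude = object$ts_magnitude,
                 magnitude_quartiles =
                   stats::quantile(object$magnitude$m,
                                   c(0.25, 0.5, 0.75), na.rm = TRUE),
                 r_quartiles =
                   stats::quantile(object$correlation$r,
                                   c(0.25, 0.5, 0.75), na.rm = TRUE),
                 roi = object$roi, aggregator = object$aggregator),
            class = "summary.surrocor")
}

#' @export
print.summary.surrocor <- function(x, ...) {
  cat(sprintf(
    "Skin-surface surrogate analysis: %d phases x %d slices x 180 beams\n",
    x$n_phases, x$n_slices))
  cat(sprintf("  TS magnitude %.2f mm; invalid beams: %d\n",
              x$ts_magnitude, x$n_invalid))
  q <- x$magnitude_quartiles
  cat(sprintf("  beam magnitude quartiles: %.2f / %.2f / %.2f mm\n",
              q[1L], q[2L], q[3L]))
  q <- x$r_quartiles
  cat(sprintf("  skin-to-TS R quartiles: %.3f / %.3f / %.3f\n",
              q[1L], q[2L], q[3L]))
  if (!is.null(x$roi)) {
    cat(sprintf("  nine-region summary (%s):\n", x$aggregator))
    print(as.data.frame(x$roi)[c("roi", "magnitude_mm", "pearson_r",
                                 "n_beams")], row.names = FALSE)
  }
  invisible(x)
}

#' Heat-map display of a fitted surrogate analysis
#'
#' Draws the correlation map (bins anchored at R < 0.5, black, and
#' R > 0.95, deep blue) or the magnitude map (green-to-red) over the
#' (angle, slice) grid on the active graphics device.
#'
#' @param x a \code{surrocor} fit.
#' @param which \code{"correlation"} or \code{"magnitude"}.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.surrocor <- function(x, which = c("correlation", "magnitude"), ...) {
  which <- match.arg(which)
  if (which == "correlation") {
    bins <- correlation_bins()
    graphics::image(x = x$correlation$angles, y = x$correlation$z,
                    z = t(x$correlation$r),
                    breaks = c(-1, bins$breaks[-c(1L, 8L)], 1),
                    col = bins$colors,
                    xlab = "beam angle (deg)", ylab = "slice z (mm)",
                    main = "Skin-to-TS Pearson R", ...)
  } else {
    ramp <- grDevices::colorRampPalette(c("#00A000", "#FFFF00",
                                          "#FF0000"))(64)
    graphics::image(x = x$magnitude$angles, y = x$magnitude$z,
                    z = t(x$magnitude$m), col = ramp,
                    xlab = "beam angle (deg)", ylab = "slice z (mm)",
                    main = "Respiratory magnitude (mm)", ...)
  }
  invisible(x)
}

#' @export
as.data.frame.surrocor <- function(x, ...)
  maps_to_table(x$correlation, x$magnitude)
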