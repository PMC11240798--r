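#' Per-beam Pearson correlation map against the tracking structure
#'
#' For every beam (slice, angle), the sample Pearson correlation between
#' its lengths over the respiratory phases and the tracking structure's
#' craniocaudal coordinates over the same phases. A beam whose length
#' series has zero variance is not "uncorrelated" but motionless, so it is
#' flagged undefined (NA with a reason) rather than set to 0; beams with an
#' invalid length in any phase are likewise flagged and excluded.
#'
#' @param field a \code{\link{build_beam_length_field}} result.
#' @param ts a \code{\link{ts_trajectory}} with as many phases as the
#'   field; at least 3 phases.
#' @return Object of class \code{correlation_map}: \code{r} (n_slices x 180
#'   matrix in [-1, 1] or NA), \code{reason} (character matrix for flagged
#'   beams), \code{z}, \code{angles}.
#' @export
pearson_map <- function(field, ts) {
  stopifnot(inherits(field, "beam_length_field"),
            inherits(ts, "ts_trajectory"))
  P <- dim(field$lengths)[1L]
  if (length(ts$z_per_phase) != P)
    stop("trajectory has ", length(ts$z_per_phase),
         " phases but the field has ", P)
  if (P < 3L) stop("Pearson map needs at least 3 phases")
  S <- dim(field$lengths)[2L]; K <- dim(field$lengths)[3L]
  r <- matrix(NA_real_, S, K)
  reason <- matrix(NA_character_, S, K)
  tsz <- ts$z_per_phase
  ts_const <- stats::sd(tsz) == 0
  for (s in seq_len(S)) {
    L <- matrix(field$lengths[, s, ], nrow = P)   # P x K
    ok <- colSums(matrix(field$valid[, s, ], nrow = P)) == P
    reason[s, !ok] <- "invalid beam in some phase"
    if (ts_const) {
      reason[s, ok] <- "zero variance in TS trajectory"
      next
    }
    sds <- apply(L[, ok, drop = FALSE], 2L, stats::sd)
    still <- which(ok)[sds == 0]
    reason[s, still] <- "zero variance in beam lengths"
    use <- which(ok)[sds > 0]
    if (length(use))
      r[s, use] <- as.vector(stats::cor(L[, use, drop = FALSE], tsz))
  }
  if (all(is.na(r)))
    stop("all beams have undefined correlation")
  structure(list(r = r, reason = reason, z = field$z, angles = field$angles),
            class = "correlation_map")
}

#' Per-beam respiratory magnitude map
#'
#' Maximum skin excursion per beam: the maximum minus the minimum beam
#' length across the respiratory phases, in mm. Beams invalid in any phase
#' are flagged undefined.
#'
#' @param field a \code{\link{build_beam_length_field}} result with at
#'   least 2 phases.
#' @return Object of class \code{magnitude_map}: \code{m} (n_slices x 180
#'   matrix, mm, >= 0 or NA), \code{z}, \code{angles}.
#' @export
magnitude_map <- function(field) {
  stopifnot(inherits(field, "beam_length_field"))
  if (dim(field$lengths)[1L] < 2L)
    stop("magnitude map needs at least 2 phases")
  mx <- apply(field$lengths, c(2L, 3L), max)
  mn <- apply(field$lengths, c(2L, 3L), min)
  m <- mx - mn                                   # NA wherever any phase NA
  structure(list(m = m, z = field$z, angles = field$angles),
            class = "magnitude_map")
}

#' Respiratory magnitude of the tracking structure
#'
#' @param ts a \code{\link{ts_trajectory}}.
#' @return Craniocaudal excursion max - min, mm.
#' @export
ts_magnitude <- function(ts) {
  stopifnot(inherits(ts, "ts_trajectory"))
  max(ts$z_per_phase) - min(ts$z_per_phase)
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "<correlation_map> %d slices x %d beams; defined %d, median R = %.3f\n",
    nrow(x$r), ncol(x$r), sum(!is.na(x$r)),
    stats::median(x$r, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.magnitude_map <- function(x, ...) {
  cat(sprintf(
    "<magnitude_map> %d slices x %d beams; median %.2f mm, max %.2f mm\n",
    nrow(x$m), ncol(x$m), stats::median(x$m, na.rm = TRUE),
    max(x$m, na.rm = TRUE)))
  invisible(x)
}

#' Long-format table of a correlation and magnitude map pair
#'
#' @param cmap a \code{correlation_map}.
#' @param mmap the matching \code{magnitude_map}.
#' @return data.frame with columns slice_index, z_mm, angle_deg, pearson_r,
#'   magnitude_mm, valid_flag.
#' @export
maps_to_table <- function(cmap, mmap) {
  stopifnot(inherits(cmap, "correlation_map"),
            inherits(mmap, "magnitude_map"),
            all(dim(cmap$r) == dim(mmap$m)))
  S <- nrow(cmap$r); K <- ncol(cmap$r)
  data.frame(
    slice_index = rep(seq_len(S), times = K),
    z_mm = rep(cmap$z, times = K),
    angle_deg = rep(cmap$angles, each = S),
    pearson_r = as.vector(cmap$r),
    magnitude_mm = as.vector(mmap$m),
    valid_flag = !(is.na(as.vector(cmap$r)) | is.na(as.vector(mmap$m))))
}

# Correlation colour bins anchored at R < 0.5 (black) and R > 0.95 (deep
# blue); intermediate bins step through progressively deeper blues.
correlation_bins <- function() {
  list(breaks = c(-Inf, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, Inf),
       colors = c("#000000", "#D6E6F4", "#AFCDE8", "#7FB0DA",
                  "#4A90CB", "#2166AC", "#08306B"))
}

#' Render correlation and magnitude maps as heat images
#'
#' Writes two PNG heat images over the (angle, slice) grid: the correlation
#' map with bins anchored at R < 0.5 (black) and R > 0.95 (deep blue), and
#' the magnitude map on a green-to-red ramp (largest excursions red). One
#' image pixel per beam: width 180, height n_slices, cranial slices at the
#' top. Undefined beams are grey. Rendering is best effort; failures are
#' reported as warnings, never errors.
#'
#' @param cmap a \code{correlation_map}.
#' @param mmap the matching \code{magnitude_map}.
#' @param out_dir output directory (created if needed).
#' @param basename file name stem (default "map").
#' @return Invisibly, the paths of the written files.
#' @export
render_maps <- function(cmap, mmap, out_dir, basename = "map") {
  stopifnot(inherits(cmap, "correlation_map"),
            inherits(mmap, "magnitude_map"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(correlation = file.path(out_dir,
                                     paste0(basename, "_correlation.png")),
             magnitude = file.path(out_dir,
                                   paste0(basename, "_magnitude.png")))
  ok <- requireNamespace("png", quietly = TRUE)
  if (!ok) {
    warning("package 'png' unavailable; maps not rendered")
    return(invisible(character(0)))
  }
  bins <- correlation_bins()
  idx <- matrix(findInterval(cmap$r, bins$breaks[-1L],
                             left.open = TRUE) + 1L,
                nrow(cmap$r), ncol(cmap$r))
  ccol <- matrix("#BDBDBD", nrow(cmap$r), ncol(cmap$r))
  ccol[!is.na(cmap$r)] <- bins$colors[idx[!is.na(cmap$r)]]
  write_color_png(ccol, paths[["correlation"]])
  ramp <- grDevices::colorRampPalette(c("#00A000", "#FFFF00", "#FF0000"))(256)
  mmax <- max(mmap$m, na.rm = TRUE)
  rel <- if (mmax > 0) mmap$m / mmax else mmap$m * 0
  mcol <- matrix("#BDBDBD", nrow(mmap$m), ncol(mmap$m))
  ok_m <- !is.na(rel)
  mcol[ok_m] <- ramp[pmin(255L, floor(rel[ok_m] * 255)) + 1L]
  write_color_png(mcol, paths[["magnitude"]])
  invisible(paths)
}

# col: slice x angle matrix of hex colours; writes slice rows top = cranial.
write_color_png <- function(col, path) {
  rgb <- grDevices::col2rgb(col) / 255
  S <- nrow(col); K <- ncol(col)
  arr <- array(0, dim = c(S, K, 3L))
  flip <- S:1  # last (most cranial) slice on top
  arr[, , 1L] <- matrix(rgb[1L, ], S, K)[flip, ]
  arr[, , 2L] <- matrix(rgb[2L, ], S, K)[flip, ]
  arr[, , 3L] <- matrix(rgb[3L, ], S, K)[flip, ]
  tryCatch(png::writePNG(arr, target = path),
           error = function(e) warning("map rendering failed: ",
                                       conditionMessage(e)))
}
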