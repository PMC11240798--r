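# File formats. Contour sets travel as JSON (human-diffable, written by
# the phantom, readable without binary medical-imaging dependencies):
#   { "units": "mm", "n_phases": P,
#     "phases": [ { "phase": 0,
#                   "slices": [ { "z": 0, "x": [...], "y": [...] }, ... ]
#                 }, ... ] }
# All tabular outputs are CSV. A DICOM-RT STRUCT import adapter is an
# extension point, not needed by any core functionality.

#' Write a multi-phase contour set to JSON
#'
#' @param phases list of \code{\link{phase_contour_set}} objects.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_contour_set <- function(phases, path) {
  shared_z_grid(phases)
  obj <- list(units = "mm", n_phases = length(phases),
              phases = lapply(phases, function(ph) {
                list(phase = ph$phase,
                     slices = lapply(ph$slices, function(s)
                       list(z = s$z, x = s$vertices[, 1L],
                            y = s$vertices[, 2L])))
              }))
  # 17 significant digits: IEEE doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a multi-phase contour set from JSON
#'
#' Validates the documented schema (units mm; per phase, per slice: z and
#' equal-length x/y vertex arrays with at least 3 vertices), normalises
#' polygon orientation to counter-clockwise, and checks that all phases
#' share an identical slice z grid. Violations are errors naming the
#' offending phase and slice.
#'
#' @param path JSON file path.
#' @param n_phases optional declared phase count; a mismatch is an error.
#' @return List of \code{\link{phase_contour_set}} objects.
#' @export
read_contour_set <- function(path, n_phases = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$phases) || !length(obj$phases))
    stop("contour file has no 'phases'")
  if (!identical(obj$units, "mm"))
    stop("contour file units must be 'mm'")
  declared <- if (!is.null(n_phases)) n_phases else obj$n_phases
  if (!is.null(declared) && length(obj$phases) != declared)
    stop("contour file has ", length(obj$phases), " phases but ",
         declared, " were declared")
  phases <- lapply(seq_along(obj$phases), function(i) {
    ph <- obj$phases[[i]]
    if (is.null(ph$phase) || is.null(ph$slices) || !length(ph$slices))
      stop("phase entry ", i, " is missing 'phase' or 'slices'")
    slices <- lapply(seq_along(ph$slices), function(j) {
      s <- ph$slices[[j]]
      if (is.null(s$z) || is.null(s$x) || is.null(s$y))
        stop("phase ", ph$phase, ", slice ", j,
             ": missing 'z', 'x' or 'y'")
      x <- as.numeric(s$x); y <- as.numeric(s$y)
      if (length(x) != length(y))
        stop("phase ", ph$phase, ", slice ", j,
             ": 'x' and 'y' lengths differ")
      if (length(x) < 3L)
        stop("phase ", ph$phase, ", slice ", j,
             ": open or degenerate polygon (fewer than 3 vertices)")
      tryCatch(contour_slice(as.numeric(s$z), cbind(x, y)),
               error = function(e)
                 stop("phase ", ph$phase, ", slice ", j, ": ",
                      conditionMessage(e), call. = FALSE))
    })
    phase_contour_set(ph$phase, slices)
  })
  shared_z_grid(phases)
  phases
}

#' Write / read a TS trajectory as CSV
#'
#' One row per phase, columns \code{phase} (0-based) and \code{z_mm}.
#'
#' @param ts a \code{\link{ts_trajectory}}.
#' @param path CSV file path.
#' @return \code{write_ts_csv}: the path, invisibly; \code{read_ts_csv}:
#'   a \code{ts_trajectory}.
#' @export
write_ts_csv <- function(ts, path) {
  stopifnot(inherits(ts, "ts_trajectory"))
  utils::write.csv(data.frame(phase = seq_along(ts$z_per_phase) - 1L,
                              z_mm = ts$z_per_phase),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ts_csv
#' @export
read_ts_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("phase", "z_mm") %in% names(d)))
    stop("TS CSV needs columns 'phase' and 'z_mm'")
  ts_trajectory(d$z_mm[order(d$phase)])
}

#' Write / read a HU grid as CSV
#'
#' Plain rectangular CSV of Hounsfield values (no header); pixel spacing
#' and origin travel in a sidecar JSON with the same stem.
#'
#' @param slice an \code{\link{hu_slice}}.
#' @param path CSV file path.
#' @return \code{write_hu_csv}: the path, invisibly; \code{read_hu_csv}:
#'   an \code{hu_slice}.
#' @export
write_hu_csv <- function(slice, path) {
  stopifnot(inherits(slice, "hu_slice"))
  utils::write.table(slice$hu, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(pixel_spacing = slice$pixel_spacing, origin = slice$origin,
               body_hu_threshold = NULL)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(1L * slice$body_mask, paste0(path, ".body.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hu_csv
#' @export
read_hu_csv <- function(path) {
  hu <- as.matrix(utils::read.csv(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  body_path <- paste0(path, ".body.csv")
  body <- if (file.exists(body_path))
    as.matrix(utils::read.csv(body_path, header = FALSE)) > 0 else NULL
  hu_slice(hu, pixel_spacing = meta$pixel_spacing, body_mask = body,
           origin = meta$origin)
}

#' Read per-patient ROI landmarks from JSON
#'
#' Expects fields z_xiphosternal, z_subcostal, z_inferior_limit,
#' z_superior_limit (mm).
#'
#' @param path JSON file path.
#' @return A \code{\link{roi_partition}}.
#' @export
read_landmarks_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("z_xiphosternal", "z_subcostal", "z_inferior_limit",
           "z_superior_limit")
  missing <- setdiff(req, names(d))
  if (length(missing))
    stop("landmark file is missing: ", paste(missing, collapse = ", "))
  roi_partition(d$z_xiphosternal, d$z_subcostal, d$z_inferior_limit,
                d$z_superior_limit)
}

#' Run the end-to-end cohort pipeline
#'
#' For each patient: load (or take in-memory) contours, TS trajectory,
#' landmarks and optionally an L4 HU slice; run \code{\link{surrocor}};
#' write the per-patient maps CSV, ROI summary CSV and adipose CSV. A
#' patient whose processing fails is recorded in the run manifest and
#' skipped; the cohort table is then assembled from the successes (at
#' least 2 required) and the cohort reports are built.
#'
#' Each element of \code{patients} is a list with fields:
#' \describe{
#'   \item{id}{patient identifier (used as output subdirectory).}
#'   \item{contours}{list of phase_contour_sets, or a contour-set JSON
#'     path.}
#'   \item{ts}{a ts_trajectory, or a TS CSV path.}
#'   \item{landmarks}{a roi_partition, or a landmarks JSON path.}
#'   \item{l4}{optional: list(slice = hu_slice or HU CSV path,
#'     inner_wall = n x 2 polygon matrix or polygon JSON path).}
#'   \item{sex, height_cm, bmi}{covariates for the cohort table.}
#' }
#'
#' @param patients list of per-patient specifications (above).
#' @param out_dir output directory.
#' @param aggregator per-ROI aggregator, "mean" or "median".
#' @param reference_kind adipose percentage denominator, "body" or
#'   "frame".
#' @return Object of class \code{surrocor_run}: \code{manifest} (one row
#'   per patient: id, status, message), \code{cohort} (the assembled
#'   table) and \code{reports} (a \code{cohort_reports}).
#' @export
run_pipeline <- function(patients, out_dir,
                         aggregator = c("mean", "median"),
                         reference_kind = c("body", "frame")) {
  aggregator <- match.arg(aggregator)
  reference_kind <- match.arg(reference_kind)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame(id = character(0), status = character(0),
                         message = character(0))
  rows <- list()
  for (pt in patients) {
    id <- pt$id
    res <- tryCatch({
      contours <- if (is.character(pt$contours))
        read_contour_set(pt$contours) else pt$contours
      ts <- if (is.character(pt$ts)) read_ts_csv(pt$ts) else pt$ts
      landmarks <- if (is.character(pt$landmarks))
        read_landmarks_json(pt$landmarks) else pt$landmarks
      fit <- surrocor(contours, ts, partition = landmarks,
                      aggregator = aggregator)
      pdir <- file.path(out_dir, id)
      if (!dir.exists(pdir)) dir.create(pdir)
      utils::write.csv(as.data.frame(fit),
                       file.path(pdir, "maps.csv"), row.names = FALSE)
      roi <- as.data.frame(fit$roi)
      roi$patient_id <- id
      utils::write.csv(roi, file.path(pdir, "roi_summary.csv"),
                       row.names = FALSE)
      ad <- NULL
      if (!is.null(pt$l4)) {
        slice <- if (is.character(pt$l4$slice))
          read_hu_csv(pt$l4$slice) else pt$l4$slice
        wall <- if (is.character(pt$l4$inner_wall))
          do.call(cbind, jsonlite::read_json(pt$l4$inner_wall,
                                             simplifyVector = TRUE))
          else pt$l4$inner_wall
        ad <- quantify_adipose(slice, wall, reference_kind)
        utils::write.csv(
          data.frame(patient_id = id, sat_pct = ad$sat_pct,
                     vat_pct = ad$vat_pct, tat_pct = ad$tat_pct,
                     reference_kind = ad$reference_kind),
          file.path(pdir, "adipose.csv"), row.names = FALSE)
      }
      row <- data.frame(patient_id = id, sex = pt$sex,
                        height_cm = pt$height_cm, bmi = pt$bmi,
                        sat_pct = if (is.null(ad)) NA_real_ else ad$sat_pct,
                        vat_pct = if (is.null(ad)) NA_real_ else ad$vat_pct,
                        tat_pct = if (is.null(ad)) NA_real_ else ad$tat_pct,
                        ts_magnitude_mm = fit$ts_magnitude)
      for (lb in roi_labels()) {
        row[[paste0("mag_", lb)]] <-
          fit$roi$magnitude_mm[fit$roi$roi == lb]
        row[[paste0("r_", lb)]] <- fit$roi$pearson_r[fit$roi$roi == lb]
      }
      rows[[length(rows) + 1L]] <- row
      "ok"
    }, error = function(e) conditionMessage(e))
    manifest <- rbind(manifest,
                      data.frame(id = id,
                                 status = if (res == "ok") "success"
                                          else "failure",
                                 message = if (res == "ok") "" else res))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cohort <- NULL; reports <- NULL
  if (length(rows) >= 2L) {
    cohort <- do.call(rbind, rows)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    complete <- stats::complete.cases(
      cohort[c("sat_pct", "vat_pct", "tat_pct")])
    reports <- if (all(complete))
      build_reports(cohort, file.path(out_dir, "reports"),
                    aggregator = aggregator) else NULL
  } else if (length(patients) >= 2L) {
    warning("fewer than 2 patients succeeded; cohort stage skipped")
  }
  structure(list(manifest = manifest, cohort = cohort, reports = reports,
                 out_dir = out_dir),
            class = "surrocor_run")
}

#' @export
print.surrocor_run <- function(x, ...) {
  cat(sprintf("<surrocor_run> %d patients: %d success, %d failure\n",
              nrow(x$manifest), sum(x$manifest$status == "success"),
              sum(x$manifest$status == "failure")))
  if (!is.null(x$reports)) cat("  cohort reports written under ",
                               file.path(x$out_dir, "reports"), "\n")
  invisible(x)
}
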