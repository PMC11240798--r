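# Cohort table layout: one row per patient with sex, anthropometrics,
# adipose percentages, TS magnitude and the nine per-ROI magnitude and
# Pearson-R summaries.

cohort_required_columns <- function() {
  c("patient_id", "sex", "height_cm", "bmi",
    "sat_pct", "vat_pct", "tat_pct", "ts_magnitude_mm",
    paste0("mag_", roi_labels()), paste0("r_", roi_labels()))
}

#' Validate a cohort table
#'
#' Checks the per-patient cohort table layout: all required columns
#' present (patient_id, sex in \{M, F\}, height_cm, bmi, sat/vat/tat_pct,
#' ts_magnitude_mm and the nine mag_* / r_* ROI columns), no duplicated
#' patient ids, no empty sex.
#'
#' @param cohort data.frame.
#' @return The cohort, invisibly, after validation.
#' @export
validate_cohort <- function(cohort) {
  req <- cohort_required_columns()
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicated patient_id in cohort table")
  if (any(is.na(cohort$sex)) || !all(cohort$sex %in% c("M", "F")))
    stop("'sex' must be 'M' or 'F' for every patient")
  invisible(cohort)
}

#' Simulate a synthetic patient cohort table
#'
#' Draws a cohort of per-patient ROI summaries and covariates with
#' controllable couplings, for validating the statistical battery. Row
#' medians and spreads emulate a torso cohort: small upper-thoracic (row A)
#' magnitudes around 1 mm, larger abdominal magnitudes of 2-6 mm, high
#' skin-to-TS correlations in rows B and C and weaker ones in row A, an
#' 8 mm-scale TS excursion, plausible height/BMI/adiposity distributions,
#' male magnitudes slightly larger in the abdominal rows.
#'
#' \code{bmi_coupling} injects a linear dependence of the ROI magnitudes on
#' BMI (mm per kg/m^2) per row; strongly negative values with small
#' \code{magnitude_noise_sd} construct an (anti-)monotone BMI-magnitude
#' relationship for effect-recovery checks.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param p_male probability a patient is male (default 26/57).
#' @param bmi_coupling named numeric \code{c(A = , B = , C = )}: magnitude
#'   change per BMI unit for each row.
#' @param magnitude_noise_sd residual SD of the ROI magnitudes, mm.
#' @param sex_effect additive male magnitude offset in rows B and C, mm.
#' @return Validated cohort data.frame.
#' @export
generate_cohort <- function(n = 57L, seed = 1L, p_male = 26 / 57,
                            bmi_coupling = c(A = -0.02, B = -0.06,
                                             C = -0.04),
                            magnitude_noise_sd = 0.8,
                            sex_effect = 1.0) {
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < p_male, "M", "F")
  height <- ifelse(sex == "M", stats::rnorm(n, 178, 7),
                   stats::rnorm(n, 165, 6.5))
  bmi <- pmin(45, pmax(17, stats::rnorm(n, 27, 4.5)))
  # adiposity tracks BMI, visceral fraction larger in men
  sat_pct <- pmax(2, 1.1 * (bmi - 15) + stats::rnorm(n, 0, 2.5))
  vat_pct <- pmax(1, 0.6 * (bmi - 15) + 3 * (sex == "M") +
                     stats::rnorm(n, 0, 2))
  tat_pct <- sat_pct + vat_pct
  ts_magnitude_mm <- pmax(1, stats::rnorm(n, 8, 2.5) + 0.8 * (sex == "M"))
  base_mag <- c(A = 1.0, A_R = 1.0, A_L = 1.0,
                B = 4.5, B_R = 2.6, B_L = 2.4,
                C = 6.0, C_R = 5.0, C_L = 5.0)
  base_r <- c(A = 0.68, A_R = 0.78, A_L = 0.72,
              B = 0.93, B_R = 0.92, B_L = 0.90,
              C = 0.92, C_R = 0.94, C_L = 0.94)
  mags <- sapply(roi_labels(), function(lb) {
    row <- substr(lb, 1L, 1L)
    m <- base_mag[[lb]] +
      bmi_coupling[[row]] * (bmi - mean(bmi)) +
      (if (row %in% c("B", "C")) sex_effect * (sex == "M") else
         -0.15 * (sex == "M")) +
      stats::rnorm(n, 0, magnitude_noise_sd)
    pmax(0.05, m)
  })
  rs <- sapply(roi_labels(), function(lb) {
    pmin(0.999, pmax(-0.999,
                     base_r[[lb]] - stats::rgamma(n, shape = 1.2,
                                                  scale = 0.05)))
  })
  colnames(mags) <- paste0("mag_", roi_labels())
  colnames(rs) <- paste0("r_", roi_labels())
  cohort <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                       sex = sex, height_cm = height, bmi = bmi,
                       sat_pct = sat_pct, vat_pct = vat_pct,
                       tat_pct = tat_pct,
                       ts_magnitude_mm = ts_magnitude_mm,
                       mags, rs, check.names = FALSE)
  validate_cohort(cohort)
  cohort
}

cohort_covariates <- function()
  c("sat_pct", "vat_pct", "tat_pct", "bmi", "height_cm")

#' Cohort reports: region comparisons, sex comparisons, covariate matrix
#'
#' Runs the full statistical battery over a cohort table and assembles
#' three report blocks:
#' \itemize{
#'   \item \code{region_tests}: Friedman test across the nine ROIs
#'     (separately for magnitudes and for skin-to-TS R) with the full
#'     Dunn-Bonferroni pairwise post hoc matrix;
#'   \item \code{sex_comparison}: per ROI and measure, median (IQR) by
#'     sex with the Mann-Whitney U, z, two-sided p and effect size r;
#'   \item \code{covariate_matrix}: Spearman Rho of each covariate
#'     (SAT\%, VAT\%, TAT\%, BMI, height) against each ROI, in two blocks
#'     (magnitude, R), with significance flagged at p < 0.05.
#' }
#'
#' @param cohort validated cohort data.frame (see
#'   \code{\link{validate_cohort}}).
#' @param out_dir optional directory; when given, the blocks are written
#'   as CSV plus a Markdown summary.
#' @param aggregator label recorded in the report stating how the per-ROI
#'   values were aggregated upstream ("mean" or "median").
#' @return Object of class \code{cohort_reports}.
#' @export
build_reports <- function(cohort, out_dir = NULL, aggregator = "mean") {
  validate_cohort(cohort)
  if (nrow(cohort) < 2L) stop("cohort stage requires at least 2 patients")
  mag <- as.matrix(cohort[paste0("mag_", roi_labels())])
  rr <- as.matrix(cohort[paste0("r_", roi_labels())])
  colnames(mag) <- colnames(rr) <- roi_labels()

  region_tests <- list(
    magnitude = list(friedman = friedman_rm(mag),
                     posthoc = dunn_bonferroni(mag)),
    pearson_r = list(friedman = friedman_rm(rr),
                     posthoc = dunn_bonferroni(rr)))

  men <- cohort$sex == "M"
  sex_rows <- lapply(c(magnitude = "mag_", pearson_r = "r_"),
                     function(prefix) {
    do.call(rbind, lapply(roi_labels(), function(lb) {
      v <- cohort[[paste0(prefix, lb)]]
      mw <- mann_whitney_u(v[men], v[!men])
      data.frame(measure = if (prefix == "mag_") "magnitude" else
                   "pearson_r",
                 roi = lb,
                 median_men = stats::median(v[men]),
                 iqr_men = stats::IQR(v[men]),
                 median_women = stats::median(v[!men]),
                 iqr_women = stats::IQR(v[!men]),
                 U = mw$statistic, z = mw$z, p.value = mw$p.value,
                 effect_r = mw$effect_r)
    }))
  })
  sex_comparison <- do.call(rbind, sex_rows)
  rownames(sex_comparison) <- NULL

  cov_rows <- list()
  for (block in c("magnitude", "pearson_r")) {
    prefix <- if (block == "magnitude") "mag_" else "r_"
    for (cv in cohort_covariates()) {
      for (lb in roi_labels()) {
        sp <- tryCatch(spearman_rho(cohort[[cv]],
                                    cohort[[paste0(prefix, lb)]]),
                       error = function(e)
                         list(statistic = NA_real_, p.value = NA_real_))
        cov_rows[[length(cov_rows) + 1L]] <- data.frame(
          block = block, covariate = cv, roi = lb,
          rho = sp$statistic, p.value = sp$p.value,
          significant = !is.na(sp$p.value) && sp$p.value < 0.05)
      }
    }
  }
  covariate_matrix <- do.call(rbind, cov_rows)

  ts_sex <- if (sum(men) >= 2L && sum(!men) >= 2L)
    ttest_ind(cohort$ts_magnitude_mm[men],
              cohort$ts_magnitude_mm[!men]) else NULL

  reports <- structure(list(region_tests = region_tests,
                            sex_comparison = sex_comparison,
                            covariate_matrix = covariate_matrix,
                            ts_sex_ttest = ts_sex,
                            n = nrow(cohort), aggregator = aggregator),
                       class = "cohort_reports")
  if (!is.null(out_dir)) write_reports(reports, out_dir)
  reports
}

#' @export
print.cohort_reports <- function(x, ...) {
  cat(sprintf("<cohort_reports> n = %d patients (per-ROI %s)\n", x$n,
              x$aggregator))
  for (b in names(x$region_tests)) {
    f <- x$region_tests[[b]]$friedman
    cat(sprintf("  Friedman (%s): Chi^2(%d) = %.1f, p = %.3g\n",
                b, f$df, f$statistic, f$p.value))
  }
  sig <- x$covariate_matrix[x$covariate_matrix$significant, ]
  cat(sprintf("  %d of %d covariate-ROI Spearman cells significant",
              nrow(sig), nrow(x$covariate_matrix)), "at p < 0.05\n")
  invisible(x)
}

write_reports <- function(reports, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(reports$sex_comparison,
                   file.path(out_dir, "sex_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(reports$covariate_matrix,
                   file.path(out_dir, "covariate_matrix.csv"),
                   row.names = FALSE)
  for (b in names(reports$region_tests))
    utils::write.csv(reports$region_tests[[b]]$posthoc,
                     file.path(out_dir, paste0("posthoc_", b, ".csv")),
                     row.names = FALSE)
  md <- c("# Cohort reports", "",
          sprintf("Patients: %d; per-ROI aggregator: %s.", reports$n,
                  reports$aggregator), "")
  for (b in names(reports$region_tests)) {
    f <- reports$region_tests[[b]]$friedman
    md <- c(md, sprintf("- Friedman (%s): Chi^2(%d) = %.2f, p = %.3g",
                        b, f$df, f$statistic, f$p.value))
  }
  tt <- reports$ts_sex_ttest
  if (!is.null(tt))
    md <- c(md, sprintf(paste0("- TS magnitude, men vs women: t(%d) = ",
                               "%.2f, p = %.2f, d = %.2f"),
                        tt$df, tt$statistic, tt$p.value, tt$cohens_d))
  writeLines(md, file.path(out_dir, "reports.md"))
  invisible(out_dir)
}
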