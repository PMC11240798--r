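make_partition <- function()
  roi_partition(z_xiphosternal = 60, z_subcostal = 30,
                z_inferior_limit = 0, z_superior_limit = 100)

test_that("partition invariants are enforced", {
  expect_error(roi_partition(30, 60, 0, 100), "must satisfy")
  expect_error(roi_partition(60, 30, 40, 100), "must satisfy")
})

test_that("beams are labelled by angular band and craniocaudal row", {
  part <- make_partition()
  zs <- seq(0, 99)
  lab <- label_beams(part, zs)
  # theta = 90, z between subcostal and xipho-sternal -> central row B
  expect_identical(lab[zs == 45, 91], "B")
  expect_identical(lab[zs == 75, 91], "A")
  expect_identical(lab[zs == 10, 40], "C_R")
  expect_identical(lab[zs == 10, 121], "C_L")
  # lateral beams are unassigned
  expect_true(all(is.na(lab[, 21])))   # theta = 20
  expect_true(all(is.na(lab[, 156]))) # theta = 155
  # band boundary ownership: 75 central, 105 left (half-open bins)
  expect_identical(lab[zs == 45, 76], "B")
  expect_identical(lab[zs == 45, 106], "B_L")
  # per slice, band beam counts are 45 right / 30 central / 45 left
  row_b <- lab[zs == 45, ]
  expect_identical(sum(row_b == "B_R", na.rm = TRUE), 45L)
  expect_identical(sum(row_b == "B", na.rm = TRUE), 30L)
  expect_identical(sum(row_b == "B_L", na.rm = TRUE), 45L)
})

test_that("every beam belongs to at most one ROI and empty ROIs are an error", {
  part <- make_partition()
  lab <- label_beams(part, seq(0, 99))
  counts <- attr(lab, "counts")
  expect_identical(sum(counts), sum(!is.na(lab)))
  expect_setequal(names(counts), roi_labels())
  # z grid that never reaches row A
  expect_error(label_beams(part, seq(0, 50)), "zero beams.*A")
})

test_that("ROI summaries aggregate defined beams and match brute force", {
  part <- make_partition()
  zs <- seq(0, 99)
  lab <- label_beams(part, zs)
  S <- length(zs); K <- 180
  cmap <- structure(list(r = matrix(0.9, S, K),
                         reason = matrix(NA_character_, S, K),
                         z = zs, angles = 0:179), class = "correlation_map")
  mmap <- structure(list(m = matrix(3, S, K), z = zs, angles = 0:179),
                    class = "magnitude_map")
  s <- summarize_roi(cmap, mmap, lab)
  expect_identical(nrow(s), 9L)
  expect_equal(s$pearson_r, rep(0.9, 9))
  expect_equal(s$magnitude_mm, rep(3, 9))

  # non-uniform maps: aggregator equals brute-force sum/count per ROI
  set.seed(5)
  cmap$r <- matrix(runif(S * K, -1, 1), S, K)
  mmap$m <- matrix(rexp(S * K), S, K)
  mmap$m[sample(S * K, 50)] <- NA
  s2 <- summarize_roi(cmap, mmap, lab, aggregator = "mean")
  for (i in seq_len(9)) {
    sel <- !is.na(lab) & lab == s2$roi[i]
    expect_equal(s2$pearson_r[i], sum(cmap$r[sel]) / sum(sel))
    mv <- mmap$m[sel]
    expect_equal(s2$magnitude_mm[i], sum(mv, na.rm = TRUE) / sum(!is.na(mv)))
    expect_identical(s2$n_used_magnitude[i], sum(!is.na(mv)))
  }

  # aggregation is permutation invariant: median path
  s3 <- summarize_roi(cmap, mmap, lab, aggregator = "median")
  perm <- sample(S)
  cmap_p <- cmap; mmap_p <- mmap; lab_p <- lab
  cmap_p$r <- cmap$r[perm, ]; mmap_p$m <- mmap$m[perm, ]
  lab_p <- lab[perm, ]; attributes(lab_p) <- attributes(lab)
  lab_p[] <- lab[perm, ]
  s3p <- summarize_roi(cmap_p, mmap_p, lab_p, aggregator = "median")
  expect_equal(s3$magnitude_mm, s3p$magnitude_mm)
  expect_equal(s3$pearson_r, s3p$pearson_r)
})

test_that("an anterior central amplitude lobe shows up in the central ROI column", {
  # amplitude confined to the central band [75, 105) and scaled by row
  amp <- function(theta, z) {
    a <- ifelse(theta >= 75 & theta < 105, 4, 0.2)
    a * ifelse(z < 30, 1.5, ifelse(z < 60, 1.0, 0.5))
  }
  cfg <- phantom_config(slice_zs = seq(0, 95, by = 5),
                        amplitude_field = amp)
  torso <- generate_torso(cfg)
  part <- make_partition()
  fit <- surrocor(torso$phases, generate_ts(cfg), partition = part)
  s <- fit$roi
  get <- function(lb) s$magnitude_mm[s$roi == lb]
  expect_gt(get("A"), 3 * get("A_R"))
  expect_gt(get("B"), 3 * get("B_L"))
  expect_gt(get("C"), 3 * get("C_R"))
  # central magnitudes match ground-truth aggregation within 2%
  lab <- label_beams(part, cfg$slice_zs)
  for (lb in c("A", "B", "C")) {
    sel <- !is.na(lab) & lab == lb
    expect_equal(get(lb), mean(torso$truth$magnitude_truth[sel]),
                 tolerance = 0.02)
  }
})

test_that("an ROI with only undefined beams is an error", {
  part <- make_partition()
  zs <- seq(0, 99)
  lab <- label_beams(part, zs)
  S <- length(zs); K <- 180
  cmap <- structure(list(r = matrix(0.9, S, K),
                         reason = matrix(NA_character_, S, K),
                         z = zs, angles = 0:179), class = "correlation_map")
  mmap <- structure(list(m = matrix(3, S, K), z = zs, angles = 0:179),
                    class = "magnitude_map")
  cmap$r[!is.na(lab) & lab == "B_R"] <- NA
  expect_error(summarize_roi(cmap, mmap, lab), "B_R")
})
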