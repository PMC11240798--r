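# Cohort statistical battery: Friedman with Dunn-Bonferroni post hoc,
# Mann-Whitney U with effect size r, Spearman, independent t-test with
# Cohen's d. Conventions follow common clinical-statistics software output
# (U = min of the two U's, z with tie and continuity correction,
# r = |z| / sqrt(N)); each routine is cross-checked in the test suite
# against the corresponding base-R test and against brute-force oracles.

new_test_result <- function(method, statistic, ...) {
  structure(c(list(method = method, statistic = statistic), list(...)),
            class = "surrocor_test")
}

#' @export
print.surrocor_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  flds <- setdiff(names(x), "method")
  for (f in flds) {
    v <- x[[f]]
    if (is.numeric(v) && length(v) <= 4L)
      cat(sprintf("  %s: %s\n", f,
                  paste(formatC(v, digits = 4, format = "g"),
                        collapse = ", ")))
  }
  invisible(x)
}

# Mid-ranks within each row of a matrix.
row_ranks <- function(x) t(apply(x, 1L, rank))

#' Friedman test for repeated measurements
#'
#' Nonparametric comparison of k within-patient conditions over n
#' patients: values are mid-ranked within each patient and the
#' tie-corrected chi-square statistic on k - 1 degrees of freedom is
#' computed, with the p-value from the chi-square upper tail. Missing
#' cells are an error; no imputation is performed.
#'
#' @param values n x k numeric matrix: rows = patients, columns =
#'   conditions (e.g. the nine ROIs); n >= 2, k >= 3.
#' @return \code{surrocor_test} with fields statistic (chi-square), df,
#'   p.value, n, k and the per-condition mean ranks.
#' @export
friedman_rm <- function(values) {
  x <- as.matrix(values)
  if (anyNA(x)) stop("missing cells are not allowed in the Friedman test")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 3L) stop("need n >= 2 patients and k >= 3 conditions")
  r <- row_ranks(x)
  Rj <- colSums(r)
  # tie correction: sum over rows of (t^3 - t) over tie groups
  tie_sum <- sum(apply(x, 1L, function(row) {
    t <- tabulate(match(row, unique(row)))
    sum(t^3 - t)
  }))
  denom <- n * k * (k + 1) - tie_sum / (k - 1)
  if (denom <= 0) {  # all rows fully tied
    stat <- 0
  } else {
    stat <- 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  new_test_result("Friedman chi-square", statistic = stat, df = k - 1L,
                  p.value = stats::pchisq(stat, df = k - 1L,
                                          lower.tail = FALSE),
                  n = n, k = k, mean_ranks = Rj / n)
}

#' Dunn-Bonferroni post hoc test after Friedman
#'
#' All k(k-1)/2 pairwise comparisons of mean within-patient ranks:
#' \code{z = (meanrank_i - meanrank_j) / sqrt(k(k+1)/(6n))}, two-sided p
#' from the normal tail, Bonferroni-adjusted by the number of pairs
#' (capped at 1).
#'
#' @inheritParams friedman_rm
#' @return data.frame with one row per pair: group_i, group_j, z, p.value,
#'   p.adjusted.
#' @export
dunn_bonferroni <- function(values) {
  x <- as.matrix(values)
  if (anyNA(x)) stop("missing cells are not allowed")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 3L) stop("need n >= 2 patients and k >= 3 conditions")
  labs <- colnames(x)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  mr <- colSums(row_ranks(x)) / n
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  z <- (mr[pairs[1L, ]] - mr[pairs[2L, ]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_i = labs[pairs[1L, ]], group_j = labs[pairs[2L, ]],
             z = unname(z), p.value = p, p.adjusted = pmin(1, p * m))
}

#' Mann-Whitney U test with effect size r
#'
#' Rank-sum comparison of two independent groups. U is reported as the
#' smaller of the two group U statistics; z uses the normal approximation
#' with tie correction and a 0.5 continuity correction; the two-sided p
#' comes from the normal tail; the effect size is
#' \code{r = |z| / sqrt(n_a + n_b)}.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return \code{surrocor_test} with fields statistic (U), z, p.value,
#'   effect_r, n.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (!na || !nb) stop("both groups must be non-empty")
  N <- na + nb
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(na)])
  Ua <- na * nb + na * (na + 1) / 2 - Ra
  Ub <- na * nb - Ua
  U <- min(Ua, Ub)
  mu <- na * nb / 2
  pooled <- c(a, b)
  ties <- tabulate(match(pooled, unique(pooled)))
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {  # all observations tied
    z <- 0
  } else {
    cc <- if (U != mu) 0.5 else 0  # continuity correction toward the mean
    z <- (U - mu + sign(mu - U) * cc) / sqrt(sigma2)
  }
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result("Mann-Whitney U", statistic = U, z = z, p.value = p,
                  effect_r = effect_size_r(z, N), n = c(na, nb))
}

#' Effect size r for a rank test
#'
#' \code{r = |z| / sqrt(N)} with N the total number of observations, the
#' standard conversion of a normal-approximation z statistic to an effect
#' size for rank tests.
#'
#' @param z the test's z statistic.
#' @param n_total total number of observations across both groups, >= 2.
#' @return The effect size r.
#' @export
effect_size_r <- function(z, n_total) {
  if (n_total < 2L) stop("'n_total' must be at least 2")
  abs(z) / sqrt(n_total)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' \code{t = Rho * sqrt((n-2)/(1-Rho^2))} on n - 2 degrees of freedom.
#' Zero rank variance in either vector gives a flagged-undefined result
#' (NA rho with a reason) rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return \code{surrocor_test} with fields statistic (rho), p.value, n,
#'   and \code{reason} when undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    return(new_test_result("Spearman rho", statistic = NA_real_,
                           p.value = NA_real_, n = n,
                           reason = "zero rank variance"))
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test_result("Spearman rho", statistic = rho, p.value = p, n = n)
}

#' Independent-samples t-test with Cohen's d
#'
#' Pooled-variance two-sample t-test (df = n_a + n_b - 2) with the 95\%
#' confidence interval of the mean difference and Cohen's d =
#' |mean_a - mean_b| / pooled SD.
#'
#' @param a,b numeric vectors, each with >= 2 observations.
#' @return \code{surrocor_test} with fields statistic (t), df, p.value,
#'   conf.int, cohens_d, n.
#' @export
ttest_ind <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 observations")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
         (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  new_test_result("Independent t", statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p.value = tt$p.value,
                  conf.int = as.numeric(tt$conf.int),
                  cohens_d = abs(mean(a) - mean(b)) / sqrt(sp2),
                  n = c(na, nb))
}

#' Cohen's d recovered from a pooled t statistic
#'
#' \code{d = |t| * sqrt(1/n_a + 1/n_b)}; algebraically identical to the
#' pooled-SD Cohen's d of the underlying samples.
#'
#' @param t the pooled-variance t statistic.
#' @param n_a,n_b the two group sizes, each >= 2.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n_a, n_b) {
  if (n_a < 2L || n_b < 2L) stop("group sizes must be at least 2")
  abs(t) * sqrt(1 / n_a + 1 / n_b)
}
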