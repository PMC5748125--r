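# round half away from zero to `digits` decimals, matching how printed
# clinical tables are rounded (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # epsilon guards against binary representation of decimals like 13.95
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Pearson and Spearman correlation with t-based p-values
#'
#' Product-moment and rank correlation of two paired samples. p-values
#' for both coefficients use the two-sided t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (for Pearson this is the exact test); Spearman uses average ranks for
#' ties.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return one-row `data.frame`: `n`, `r_p`, `p_p`, `r_s`, `p_s`.
#' @export
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  p_from_r <- function(r) {
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  r_p <- stats::cor(x, y, method = "pearson")
  r_s <- stats::cor(x, y, method = "spearman")
  data.frame(n = n, r_p = r_p, p_p = p_from_r(r_p),
             r_s = r_s, p_s = p_from_r(r_s))
}

# the six strata used throughout the analysis
stratum_filter <- function(records, stratum, diameter_cutoff_mm) {
  m <- records$match == "match"
  big <- records$diameter_mm > diameter_cutoff_mm
  keep <- switch(stratum,
    all = rep(TRUE, nrow(records)),
    match = m,
    mismatch = !m,
    small = !big,
    large_match = big & m,
    large_mismatch = big & !m,
    stop("unknown stratum: ", stratum))
  records[keep, , drop = FALSE]
}

#' Stratified correlation table
#'
#' Correlations of chosen parameter pairs within the strata of the
#' concordance analysis: all lesions, spatial match, spatial mismatch,
#' small lesions (diameter <= cutoff), and large lesions split by match
#' status. Strata with fewer than 3 lesions yield NA coefficients rather
#' than an error, so cohort runs never abort.
#'
#' @param records `data.frame` of per-lesion records (one reader), as
#'   produced by [lesion_report]; needs the columns named in `pairs`
#'   plus `match` and `diameter_mm`.
#' @param pairs list of character pairs `c(x_column, y_column)`; default
#'   covers SUVmax/ADCmin, SUVmean/ADCmean, SUVmax/ADCmean@SUVmax and
#'   ADCmin/SUVmean@ADCmin.
#' @param strata character vector of stratum names among `"all"`,
#'   `"match"`, `"mismatch"`, `"small"`, `"large_match"`,
#'   `"large_mismatch"`.
#' @param diameter_cutoff_mm size cutoff (mm) separating small from
#'   large lesions; default 30 (the T1 boundary of 3 cm).
#' @return `data.frame`: `stratum`, `pair`, `n`, `r_p`, `p_p`, `r_s`,
#'   `p_s`.
#' @export
stratified_correlations <- function(records,
    pairs = list(c("suv_max", "adc_min"),
                 c("suv_mean", "adc_mean"),
                 c("suv_max", "adc_mean_at_suvmax"),
                 c("adc_min", "suv_mean_at_adcmin")),
    strata = c("all", "match", "mismatch", "small",
               "large_match", "large_mismatch"),
    diameter_cutoff_mm = 30) {
  out <- list()
  for (s in strata) {
    sub <- stratum_filter(records, s, diameter_cutoff_mm)
    for (pr in pairs) {
      name <- paste(pr, collapse = "/")
      row <- if (nrow(sub) >= 3 &&
                 stats::sd(sub[[pr[1]]]) > 0 &&
                 stats::sd(sub[[pr[2]]]) > 0) {
        correlate(sub[[pr[1]]], sub[[pr[2]]])
      } else {
        data.frame(n = nrow(sub), r_p = NA_real_, p_p = NA_real_,
                   r_s = NA_real_, p_s = NA_real_)
      }
      out[[length(out) + 1L]] <- cbind(
        data.frame(stratum = s, pair = name), row)
    }
  }
  do.call(rbind, out)
}

#' Unpaired two-group comparison (t-test)
#'
#' Student's pooled-variance t-test by default, Welch behind a flag.
#' When the pooled variance is (numerically) zero the statistic is
#' guarded: t = 0, p = 1 for identical means, otherwise a large finite t
#' with p ~ 0, and `degenerate = TRUE` in the result.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`, `degenerate`.
#' @export
group_compare <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need n >= 2")
  pooled_var <- (stats::var(a) * (length(a) - 1) +
                 stats::var(b) * (length(b) - 1)) /
                (length(a) + length(b) - 2)
  if (pooled_var < .Machine$double.eps * max(1, mean(a)^2, mean(b)^2)) {
    df <- length(a) + length(b) - 2
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1, df = df, mean_a = mean(a),
                  mean_b = mean(b), degenerate = TRUE))
    }
    tt <- sign(mean(a) - mean(b)) * 1e6
    return(list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Bland-Altman agreement between two readers
#'
#' Differences `a - b` against their limits of agreement
#' `bias +/- 1.96 * sd(differences)`.
#'
#' @param a,b paired numeric vectors (same cases), length >= 3.
#' @return object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `lower`, `upper`, `n`, `n_outside` (pairs strictly outside the
#'   limits), `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("readers must be paired")
  if (length(a) < 3) stop("need n >= 3 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  lower <- bias - 1.96 * s; upper <- bias + 1.96 * s
  structure(list(bias = bias, sd_diff = s, lower = lower, upper = upper,
                 n = length(d), n_outside = sum(d < lower | d > upper),
                 differences = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.2f, limits [%.2f, %.2f], %d/%d outside\n",
    x$bias, x$lower, x$upper, x$n_outside, x$n))
  invisible(x)
}

#' Per-patient measurements of the bundled simultaneous PET/MRI cohort
#'
#' Ten patients examined with simultaneous PET/MRI: SUVmax, SUVmean,
#' per-reader ADCmin, ADCmean and SUVmax-ADCmin distance, and the PET
#' tumor diameter. Bundled as a plain-text fixture.
#'
#' @return `data.frame` with columns `patient`, `suv_max`, `suv_mean`,
#'   `adc_min_r1`, `adc_min_r3`, `adc_mean_r1`, `adc_mean_r3`,
#'   `dist_r1`, `dist_r3`, `diameter_mm`.
#' @export
load_simultaneous_cohort <- function() {
  path <- system.file("extdata", "simultaneous_cohort.csv",
                      package = "petmatch", mustWork = TRUE)
  utils::read.csv(path)
}

#' Summary statistics of the simultaneous PET/MRI cohort
#'
#' Column means rounded to the printed precision, the sample sd of the
#' reader-1 distance column, and the derived counts: lesions with
#' inter-extremum distance below 10 mm, above 20 mm, and spatially
#' matched (distance <= `threshold_mm`) lesions larger than 3 cm.
#'
#' @param tab cohort table as returned by [load_simultaneous_cohort]
#'   (or any table with the same columns).
#' @param threshold_mm spatial-match threshold, default 12.
#' @return list with `means` (named vector, rounded as printed),
#'   `sd_dist_r1`, `n_dist_lt10`, `n_dist_gt20`, `n_match_gt3cm`, `n`.
#' @export
cohort_summary <- function(tab = load_simultaneous_cohort(),
                           threshold_mm = 12) {
  if (nrow(tab) == 0) stop("empty cohort table")
  need <- c("suv_max", "suv_mean", "adc_min_r1", "adc_min_r3",
            "adc_mean_r1", "adc_mean_r3", "dist_r1", "dist_r3",
            "diameter_mm")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)),
                                    collapse = ", "))
  means <- c(
    suv_max = round_half_up(mean(tab$suv_max), 1),
    suv_mean = round_half_up(mean(tab$suv_mean), 1),
    adc_min_r1 = round_half_up(mean(tab$adc_min_r1), 0),
    adc_min_r3 = round_half_up(mean(tab$adc_min_r3), 0),
    adc_mean_r1 = round_half_up(mean(tab$adc_mean_r1), 0),
    adc_mean_r3 = round_half_up(mean(tab$adc_mean_r3), 0),
    dist_r1 = round_half_up(mean(tab$dist_r1), 1),
    dist_r3 = round_half_up(mean(tab$dist_r3), 1),
    diameter_mm = round_half_up(mean(tab$diameter_mm), 1))
  list(means = means,
       sd_dist_r1 = round_half_up(stats::sd(tab$dist_r1), 1),
       n_dist_lt10 = sum(tab$dist_r1 < 10),
       n_dist_gt20 = sum(tab$dist_r1 > 20),
       n_match_gt3cm = sum(tab$dist_r1 <= threshold_mm &
                           tab$diameter_mm > 30),
       n = nrow(tab))
}
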