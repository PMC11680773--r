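#' @title Platform-concordance statistics
#' @name concordance_stats
#' @description
#' The comparison suite applied between score sets computed from different
#' genotyping platforms on the same samples: Spearman correlation with
#' bootstrap intervals, the Meng-Rosenthal-Rubin z-test for two dependent
#' correlations sharing a common variable, paired mean differences,
#' per-variant exact allele-frequency tests with Bonferroni correction,
#' Bland-Altman agreement, centile-threshold re-categorisation tables and
#' ROC AUC.
NULL

#' Spearman correlation with confidence interval
#'
#' Mid-rank Spearman rho. The default CI is a seeded percentile bootstrap
#' (the Fisher-z normal approximation degrades for rho near 1, which is
#' the regime of interest here, but is available as `"fisher_z"`).
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @param ci_method `"bootstrap"` or `"fisher_z"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list: `rho`, `ci_low`, `ci_high`, `n`, `ci_method`.
#' @export
spearman_with_ci <- function(x, y, ci_method = c("bootstrap", "fisher_z"),
                             n_boot = 1000, conf = 0.95, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  a <- (1 - conf) / 2
  if (ci_method == "bootstrap") {
    local_rng(seed)
    rx <- rank(x); ry <- rank(y)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      stats::cor(rx[i], ry[i], method = "spearman")
    }, 1.0)
    ci <- unname(stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, type = 7))
  } else {
    z <- atanh(rho); se <- 1 / sqrt(n - 3)
    ci <- tanh(z + stats::qnorm(c(a, 1 - a)) * se)
  }
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
       ci_method = ci_method)
}

#' Meng-Rosenthal-Rubin z-test for two dependent correlations
#'
#' Tests whether `r1 = cor(x1, y)` differs from `r2 = cor(x2, y)` when
#' both are measured on the same `n` samples, given `r12 = cor(x1, x2)`:
#' \deqn{z = (\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2))
#'       \sqrt{(n-3) / (2 (1 - r_{12}) h)}}
#' with \eqn{\bar{r}^2 = (r_1^2 + r_2^2)/2},
#' \eqn{f = \min(1, (1 - r_{12}) / (2 (1 - \bar{r}^2)))} and
#' \eqn{h = (1 - f \bar{r}^2) / (1 - \bar{r}^2)}; two-sided normal p.
#'
#' @param r1,r2 correlations of each score set with the common reference.
#' @param r12 correlation between the two score sets.
#' @param n sample size (> 3).
#' @return list: `r1`, `r2`, `r12`, `n`, `z`, `p`.
#' @export
meng_z_test <- function(r1, r2, r12, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("correlations must lie strictly inside (-1, 1)")
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  p <- 2 * stats::pnorm(-abs(z))
  list(r1 = r1, r2 = r2, r12 = r12, n = n, z = z, p = max(p, .Machine$double.xmin))
}

#' Paired mean-difference test (two-sided paired t)
#'
#' @param x,y paired numeric vectors (length >= 2).
#' @return list: `mean_diff` (mean of x - y), `ci_low`, `ci_high`, `t`,
#'   `p`, `n`, `degenerate` (TRUE when the differences have zero
#'   variance; then `p` is 1 for a zero mean difference and NA otherwise,
#'   with a zero-width CI).
#' @export
paired_mean_difference_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  if (length(d) < 2) stop("need at least 2 pairs")
  # a floating-point-constant difference (e.g. y = x - c) counts as degenerate
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    m <- mean(d)
    return(list(mean_diff = m, ci_low = m, ci_high = m, t = NA_real_,
                p = if (m == 0) 1 else NA_real_, n = length(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
  list(mean_diff = unname(tt$estimate), ci_low = tt$conf.int[1],
       ci_high = tt$conf.int[2], t = unname(tt$statistic),
       p = tt$p.value, n = length(d), degenerate = FALSE)
}

#' Two-sided Fisher exact test for one variant's allele counts
#'
#' Compares the effect-allele frequency between two platforms: a 2x2
#' table of (effect, other) allele counts. The two-sided p is the exact
#' "probability at most that of the observed table" rule: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed the observed one (within a 1e-7 relative
#' tolerance, the usual guard against floating-point ties).
#'
#' @param k1,m1 effect-allele count and total allele count on platform 1
#'   (`m1 = 2 * called samples`).
#' @param k2,m2 likewise on platform 2.
#' @param n_tests number of variants tested, for the Bonferroni flag.
#' @param alpha family-wise level (default 0.05).
#' @return list: counts, `odds_ratio` (sample OR), `p`,
#'   `bonferroni_threshold`, `significant`.
#' @export
allele_frequency_test <- function(k1, m1, k2, m2, n_tests = 1, alpha = 0.05) {
  if (m1 <= 0 || m2 <= 0) stop("total allele counts must be positive")
  if (k1 > m1 || k2 > m2 || k1 < 0 || k2 < 0)
    stop("allele counts must satisfy 0 <= k <= m")
  kk <- k1 + k2; nn <- m1 + m2
  support <- max(0, kk - m2):min(kk, m1)
  probs <- stats::dhyper(support, kk, nn - kk, m1)
  p_obs <- stats::dhyper(k1, kk, nn - kk, m1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  or <- (k1 / max(m1 - k1, 0.5)) / (k2 / max(m2 - k2, 0.5))
  thr <- alpha / n_tests
  list(k1 = k1, m1 = m1, k2 = k2, m2 = m2, odds_ratio = or, p = p,
       bonferroni_threshold = thr, significant = p < thr)
}

#' Per-variant allele-frequency comparison between two platforms
#'
#' Effect-allele counts are obtained from each platform's harmonized
#' dosages (rounded totals over called samples); each variant gets an
#' exact test, flagged at the Bonferroni level `alpha / n_variants`.
#'
#' @param cohort1,cohort2 harmonized [cohort_genotypes()].
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `variant_id`, counts, frequencies, `odds_ratio`,
#'   `p`, `significant`.
#' @export
variant_frequency_tests <- function(cohort1, cohort2, alpha = 0.05) {
  vids <- intersect(cohort1$variant_ids, cohort2$variant_ids)
  m_tests <- length(vids)
  res <- lapply(vids, function(vid) {
    d1 <- cohort1$dosage[, vid]; d2 <- cohort2$dosage[, vid]
    m1 <- 2L * sum(!is.na(d1)); m2 <- 2L * sum(!is.na(d2))
    k1 <- as.integer(round(sum(d1, na.rm = TRUE)))
    k2 <- as.integer(round(sum(d2, na.rm = TRUE)))
    ft <- allele_frequency_test(k1, m1, k2, m2, n_tests = m_tests,
                                alpha = alpha)
    data.frame(variant_id = vid, k1 = k1, m1 = m1, k2 = k2, m2 = m2,
               freq1 = k1 / m1, freq2 = k2 / m2,
               odds_ratio = ft$odds_ratio, p = ft$p,
               significant = ft$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "bonferroni_threshold") <- alpha / m_tests
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y` against pairwise means `(x + y)/2`: mean
#' difference, 95\% limits of agreement (mean +/- 1.96 SD), and the
#' proportional-bias slope (least-squares regression of `d` on the mean)
#' with its two-sided p.
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @return list: `mean_difference`, `loa_low`, `loa_high`, `sd_diff`,
#'   `slope`, `slope_p`, `n`, `degenerate`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y; m <- (x + y) / 2
  md <- mean(d); sdd <- stats::sd(d)
  degenerate <- sdd <= 1e-10 * max(1, abs(md)) || stats::sd(m) == 0
  slope <- 0; slope_p <- NA_real_
  if (!degenerate) {
    fit <- stats::lm(d ~ m)
    cf <- summary(fit)$coefficients
    slope <- cf["m", "Estimate"]; slope_p <- cf["m", "Pr(>|t|)"]
  }
  list(mean_difference = md, loa_low = md - 1.96 * sdd,
       loa_high = md + 1.96 * sdd, sd_diff = sdd,
       slope = slope, slope_p = slope_p, n = length(d),
       degenerate = degenerate)
}

#' Centile-threshold concordance between two score sets
#'
#' Each sample is classified below vs at/above the qth centile under both
#' score sets. By default each method is classified against its own score
#' distribution (the re-categorisation question is about centile
#' categories, not raw thresholds); pass explicit frames to use a shared
#' reference instead. Returns the 2x2 table with the reference method in
#' rows.
#'
#' @param ref_scores,alt_scores paired score vectors (reference platform
#'   first).
#' @param centile_q threshold centile (e.g. 50 or 90).
#' @param ref_frame,alt_frame optional [centile_frame()]s; default: each
#'   method's own scores.
#' @return a `threshold_concordance` object; see
#'   [threshold_concordance_from_counts()] for fields.
#' @export
threshold_concordance <- function(ref_scores, alt_scores, centile_q,
                                  ref_frame = NULL, alt_frame = NULL) {
  if (length(ref_scores) == 0) stop("empty input")
  if (length(ref_scores) != length(alt_scores))
    stop("score vectors must be paired")
  if (is.null(ref_frame)) ref_frame <- centile_frame(ref_scores, "ref")
  if (is.null(alt_frame)) alt_frame <- centile_frame(alt_scores, "alt")
  ref_hi <- ref_scores >= centile_threshold(ref_frame, centile_q)
  alt_hi <- alt_scores >= centile_threshold(alt_frame, centile_q)
  threshold_concordance_from_counts(
    c11 = sum(!ref_hi & !alt_hi), c12 = sum(!ref_hi & alt_hi),
    c21 = sum(ref_hi & !alt_hi), c22 = sum(ref_hi & alt_hi),
    centile_q = centile_q)
}

#' Threshold-concordance summary from 2x2 counts
#'
#' Builds the summary directly from the four cell counts (reference
#' method in rows: row 1 below the threshold centile, row 2 at/above;
#' columns likewise for the comparison method).
#'
#' @param c11,c12,c21,c22 cell counts.
#' @param centile_q the threshold centile the counts refer to.
#' @return a `threshold_concordance` object: `counts` (2x2 matrix),
#'   `row_pct` (row percentages, raw), `accuracy` (concordant fraction),
#'   `accuracy_pct`, `n`, `recat_low` / `recat_high` (the off-diagonal
#'   row percentages: re-categorised among reference-low and
#'   reference-high samples).
#' @export
threshold_concordance_from_counts <- function(c11, c12, c21, c22, centile_q) {
  counts <- matrix(c(c11, c12, c21, c22), 2, 2, byrow = TRUE,
                   dimnames = list(ref = c("below", "at_or_above"),
                                   alt = c("below", "at_or_above")))
  n <- sum(counts)
  if (n == 0) stop("empty table")
  row_tot <- rowSums(counts)
  row_pct <- 100 * counts / ifelse(row_tot == 0, NA, row_tot)[row(counts)]
  acc <- (c11 + c22) / n
  structure(list(centile_q = centile_q, counts = counts, row_pct = row_pct,
                 accuracy = acc, accuracy_pct = 100 * acc, n = n,
                 recat_low = row_pct[1, 2], recat_high = row_pct[2, 1]),
            class = "threshold_concordance")
}

#' @export
print.threshold_concordance <- function(x, ...) {
  cat(sprintf("threshold concordance at the %gth centile (n = %d)\n",
              x$centile_q, x$n))
  print(x$counts)
  cat(sprintf("accuracy %.2f%%; re-categorised: %.2f%% of reference-low, %.2f%% of reference-high\n",
              x$accuracy_pct, x$recat_low, x$recat_high))
  invisible(x)
}

#' ROC AUC with bootstrap confidence interval
#'
#' Mann-Whitney formulation: `AUC = U / (n1 * n0)` from midranks, ties
#' counted half.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical) case labels; both classes required.
#' @param ci `"bootstrap"` (seeded percentile, default) or `"none"`.
#' @param n_boot bootstrap replicates (default 2000).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return list: `auc`, `ci_low`, `ci_high`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels, ci = c("bootstrap", "none"),
                    n_boot = 2000, conf = 0.95, seed = 1L) {
  ci <- match.arg(ci)
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  auc_of <- function(s, l) {
    r <- rank(s)
    n1 <- sum(l == 1L)
    (sum(r[l == 1L]) - n1 * (n1 + 1) / 2) / (n1 * sum(l == 0L))
  }
  auc <- auc_of(scores, labels)
  lo <- hi <- NA_real_
  if (ci == "bootstrap") {
    local_rng(seed)
    a <- (1 - conf) / 2
    n <- length(scores)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sum(labels[i] == 1L) == 0 || sum(labels[i] == 0L) == 0) return(NA_real_)
      auc_of(scores[i], labels[i])
    }, 1.0)
    qs <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, type = 7)
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  list(auc = auc, ci_low = lo, ci_high = hi, n_case = n1, n_control = n0)
}
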