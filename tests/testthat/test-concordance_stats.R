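test_that("Spearman correlation is rank-invariant with sane bootstrap CIs", {
  set.seed(61)
  x <- rnorm(200)
  r <- spearman_with_ci(x, exp(x), n_boot = 100, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(spearman_with_ci(x, -x, n_boot = 100, seed = 1)$rho, -1)

  # closed-form Spearman for a bivariate normal with Pearson 0.9
  n <- 5000
  set.seed(62)
  z1 <- rnorm(n); z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  r2 <- spearman_with_ci(z1, z2, n_boot = 200, seed = 2)
  expect_equal(r2$rho, (6 / pi) * asin(0.9 / 2), tolerance = 0.01)
  expect_true(r2$ci_low <= r2$rho && r2$rho <= r2$ci_high)
  expect_lt(r2$ci_high - r2$ci_low, 0.05)

  expect_error(spearman_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_with_ci(1:3, 1:3), "4")
})

test_that("Meng z-test matches its closed form and is antisymmetric", {
  # identical correlations give z = 0, p = 1
  m <- meng_z_test(0.9, 0.9, 0.8, 1000)
  expect_equal(m$z, 0)
  expect_equal(m$p, 1)

  # antisymmetry
  a <- meng_z_test(0.98, 0.95, 0.9, 500)
  b <- meng_z_test(0.95, 0.98, 0.9, 500)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  # hand-computed reference value for one parameter set
  r1 <- 0.9; r2 <- 0.85; r12 <- 0.8; n <- 200
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z_ref <- (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  expect_equal(meng_z_test(r1, r2, r12, n)$z, z_ref)

  # behaves like the independent-correlation z as r12 -> 0 (|z| decreases
  # as the shared dependence grows)
  zs <- sapply(c(0, 0.3, 0.6, 0.9), function(r12)
    abs(meng_z_test(0.8, 0.7, r12, 300)$z))
  expect_true(all(diff(zs) > 0))

  expect_error(meng_z_test(0.9, 0.8, 0.5, 3), "n")
  expect_error(meng_z_test(1, 0.8, 0.5, 100), "strictly inside")
})

test_that("paired mean-difference test recovers simulated effects and degenerate cases", {
  x <- rnorm(50)
  same <- paired_mean_difference_test(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shifted <- paired_mean_difference_test(x, x - 0.7)
  expect_equal(shifted$mean_diff, 0.7)
  expect_true(shifted$degenerate)

  set.seed(63)
  n <- 10000
  d <- rnorm(n, 0.043, 0.2)
  res <- paired_mean_difference_test(d, rep(0, n))
  expect_lt(abs(res$mean_diff - 0.043), 0.006)
  expect_lt(res$p, 1e-10)
  expect_true(res$ci_low < 0.043 && 0.043 < res$ci_high)
})

test_that("exact allele-frequency test matches enumeration, fisher.test and tail bounds", {
  # identical tables are null
  expect_equal(allele_frequency_test(100, 2000, 100, 2000)$p, 1)

  # extreme separation has an astronomically small p
  expect_lt(allele_frequency_test(0, 2000, 200, 2000)$p, 1e-50)

  # hand-enumerated table (3,7 / 7,3): two-sided exact p = 0.17887
  p <- allele_frequency_test(3, 10, 7, 10)$p
  expect_equal(p, fisher.test(matrix(c(3, 7, 7, 3), 2))$p.value, tolerance = 1e-9)
  expect_equal(round(p, 4), 0.1789)

  # brute-force oracle over all tables with fixed margins, via choose()
  brute_p <- function(k1, m1, k2, m2) {
    kk <- k1 + k2
    xs <- max(0, kk - m2):min(kk, m1)
    pr <- choose(m1, xs) * choose(m2, kk - xs) / choose(m1 + m2, kk)
    obs <- pr[match(k1, xs)]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(64)
  for (i in 1:200) {
    m1 <- sample(1:30, 1); m2 <- sample(1:30, 1)
    k1 <- sample(0:m1, 1); k2 <- sample(0:m2, 1)
    expect_equal(allele_frequency_test(k1, m1, k2, m2)$p,
                 brute_p(k1, m1, k2, m2), tolerance = 1e-12)
  }

  # Bonferroni flag uses alpha / n_tests
  ft <- allele_frequency_test(10, 1000, 60, 1000, n_tests = 67)
  expect_equal(ft$bonferroni_threshold, 0.05 / 67)
  expect_true(ft$significant)
  expect_error(allele_frequency_test(1, 0, 1, 10), "positive")
})

test_that("per-variant frequency table counts alleles from called dosages", {
  cfg <- hand_config()
  vids <- cfg$variants$variant_id
  n <- 40
  set.seed(65)
  d1 <- matrix(rbinom(n * 5, 2, 0.4) + 0.0, n, dimnames = list(NULL, vids))
  d2 <- d1
  d2[, 1] <- pmin(d1[, 1] + 1, 2)  # inflate one variant's frequency
  d1[1:4, 2] <- NA                 # some missing calls
  c1 <- effect_cohort(d1, cfg); c2 <- effect_cohort(d2, cfg)
  tab <- variant_frequency_tests(c1, c2)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$m1[tab$variant_id == "v2"], 2L * (n - 4L))
  expect_equal(tab$k1, as.integer(round(colSums(d1, na.rm = TRUE))))
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / 5)
  expect_gt(tab$freq2[1], tab$freq1[1])
})

test_that("Bland-Altman detects constructed proportional bias and not its absence", {
  x <- rnorm(100)
  off <- bland_altman(x, x + 0.5)
  expect_equal(off$mean_difference, -0.5)
  expect_true(off$degenerate)
  expect_equal(off$slope, 0)

  set.seed(66)
  n <- 5000
  x <- rnorm(n, 10, 2)
  y <- 1.1 * x + rnorm(n, 0, 0.3)
  ba <- bland_altman(x, y)
  expect_lt(ba$slope, 0)          # y grows faster than x -> negative d-vs-mean slope
  expect_lt(ba$slope_p, 1e-6)
  expect_equal(ba$loa_high - ba$mean_difference, 1.96 * ba$sd_diff)
  expect_equal(ba$mean_difference - ba$loa_low, 1.96 * ba$sd_diff)

  # exchangeable noise: no proportional bias detected at alpha 0.001
  x0 <- rnorm(2000); y0 <- rnorm(2000)
  expect_gt(bland_altman(x0, y0)$slope_p, 0.001)
  expect_error(bland_altman(1:2, 1:2), "3")
})

test_that("threshold concordance matches hand enumeration and identity inputs", {
  set.seed(67)
  s <- rnorm(1000)
  tc <- threshold_concordance(s, s, 50)
  expect_equal(tc$counts[1, 2] + tc$counts[2, 1], 0)
  expect_equal(tc$accuracy, 1)

  # n = 4 toy: ref {1,2,3,4}, alt {1,2,4,3} at the 50th centile
  tc4 <- threshold_concordance(c(1, 2, 3, 4), c(1, 2, 4, 3), 50)
  expect_equal(sum(tc4$counts[1, 2], tc4$counts[2, 1]), 0)
  # both methods rank the same two samples at/above their own medians here;
  # a genuinely discordant toy needs unequal rankings:
  tc4b <- threshold_concordance(c(1, 2, 3, 4), c(4, 3, 2, 1), 50)
  expect_equal(unname(tc4b$counts[1, 2]), 2)
  expect_equal(unname(tc4b$counts[2, 1]), 2)
  expect_equal(tc4b$accuracy, 0)

  # accuracy identity against an independent recount
  a <- rnorm(500); b <- a + rnorm(500, 0, 0.5)
  tcq <- threshold_concordance(a, b, 90)
  fa <- centile_frame(a); fb <- centile_frame(b)
  hi_a <- a >= centile_threshold(fa, 90); hi_b <- b >= centile_threshold(fb, 90)
  expect_equal(tcq$accuracy, mean(hi_a == hi_b))
  expect_equal(sum(tcq$counts), 500)
  expect_error(threshold_concordance(numeric(0), numeric(0), 50), "empty")
})

test_that("ROC AUC equals the brute-force all-pairs count and handles the null", {
  set.seed(68)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  if (sum(y) == 0 || sum(y) == 200) y[1:2] <- c(0L, 1L)
  auc <- roc_auc(s, y, ci = "none")$auc
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc, mean(cmp))

  # perfect separation and label-independence
  expect_equal(roc_auc(c(neg, pos + max(neg) - min(pos) + 1),
                       rep(c(0, 1), c(length(neg), length(pos))),
                       ci = "none")$auc, 1)
  y0 <- rbinom(10000, 1, 0.2)
  expect_equal(roc_auc(rnorm(10000), y0, ci = "none")$auc, 0.5, tolerance = 0.02)

  # bootstrap CI brackets the estimate
  r <- roc_auc(s, y, n_boot = 200, seed = 3)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_error(roc_auc(s, rep(1, 200)), "both classes")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(69)
  s <- rnorm(300); y <- rbinom(300, 1, plogis(2 * s))
  expect_equal(roc_auc(s, y, ci = "none")$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})
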