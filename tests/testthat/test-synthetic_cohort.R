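test_that("Balding-Nichols frequency draws have the right limits and variance", {
  pops <- data.frame(label = c("A", "B"), proportion = c(0.5, 0.5),
                     fst = c(1e-6, 0.1))
  anc <- setNames(rep(0.5, 1000), sprintf("v%04d", 1:1000))
  m <- population_model(pops, anc)
  f <- draw_population_frequencies(m, seed = 3)

  # fst -> 0 limit: per-population freqs collapse onto the ancestral value
  expect_lt(max(abs(f["A", ] - 0.5)), 0.01)

  # closed-form Beta variance F p (1-p) = 0.025 at p = 0.5, F = 0.1
  pops10k <- data.frame(label = "B", proportion = 1, fst = 0.1)
  anc10k <- setNames(rep(0.5, 10000), sprintf("w%05d", 1:10000))
  fB <- draw_population_frequencies(population_model(pops10k, anc10k), seed = 4)
  expect_equal(var(as.numeric(fB)), 0.025, tolerance = 0.05)

  # determinism and validation
  expect_identical(f, draw_population_frequencies(m, seed = 3))
  expect_error(population_model(data.frame(label = "A", proportion = 1, fst = 0),
                                anc), "fst")
  expect_error(population_model(data.frame(label = "A", proportion = 0.9, fst = 0.1),
                                anc), "sum to 1")
})

test_that("true genotypes follow binomial/HWE expectations", {
  freqs <- matrix(c(1e-6, 0.3), 1, 2, dimnames = list("A", c("v1", "v2")))
  g <- simulate_true_genotypes(freqs, rep("A", 10000), seed = 5)
  expect_true(all(g[, "v1"] == 0))          # epsilon-clamped p ~ 0
  expect_equal(mean(g[, "v2"]), 0.6, tolerance = 0.02)
  obs <- tabulate(g[, "v2"] + 1, 3)
  exp_p <- c(0.49, 0.42, 0.09)
  expect_gt(chisq.test(obs, p = exp_p)$p.value, 0.001)
  expect_identical(g, simulate_true_genotypes(freqs, rep("A", 10000), seed = 5))
  expect_error(simulate_true_genotypes(freqs, c("A", "Z"), seed = 1), "Z")
})

test_that("WGS observation model reproduces depth, VAF and missingness behaviour", {
  g <- matrix(rep(0:2, c(300, 400, 300)), ncol = 1,
              dimnames = list(NULL, "v1"))
  hi <- platform_error_model("WGS", mean_depth = 1000, genotype_error_rate = 0)
  obs <- simulate_wgs_observations(g, hi, seed = 6)
  expect_equal(obs$gt, as.integer(g))       # error-free calls equal truth
  het_vaf <- obs$vaf[obs$gt == 1L]
  expect_gt(mean(het_vaf >= 0.45 & het_vaf <= 0.55), 0.95)

  # depth-undershoot rate matches the Poisson CDF at mean depth 5
  g2 <- matrix(rbinom(20000, 2, 0.5), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  lo <- platform_error_model("WGS", mean_depth = 5)
  obs2 <- simulate_wgs_observations(g2, lo, seed = 7)
  expect_equal(mean(obs2$dp < 10), ppois(9, 5), tolerance = 0.01)
  # DP = 0 events are emitted as missing, with undefined VAF
  zero <- obs2$dp == 0
  expect_true(any(zero))
  expect_true(all(is.na(obs2$gt[zero])))
  expect_true(all(is.na(obs2$vaf[zero])))

  expect_error(simulate_wgs_observations(g, platform_error_model("WGS")), "mean_depth")
})

test_that("imputed dosages hit their accuracy target and degrade as documented", {
  n <- 20000
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  freqs <- matrix(0.3, 1, 1, dimnames = list("A", "v1"))

  perfect <- simulate_imputed_observations(
    g, platform_error_model("imp", r2 = 1), freqs, rep("A", n), seed = 8)
  expect_identical(perfect$dosage[, 1], as.numeric(g[, 1]))

  noisy <- simulate_imputed_observations(
    g, platform_error_model("imp", r2 = 0.9), freqs, rep("A", n), seed = 8)
  expect_equal(cor(noisy$dosage[, 1], g[, 1])^2, 0.9, tolerance = 0.02)
  expect_true(all(noisy$dosage >= 0 & noisy$dosage <= 2))

  # ancestry bias: same r2 target, lower realised accuracy in population B
  freqs2 <- rbind(A = 0.3, B = 0.3)
  colnames(freqs2) <- "v1"
  lab <- rep(c("A", "B"), each = n / 2)
  g3 <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  biased <- simulate_imputed_observations(
    g3, platform_error_model("imp", r2 = 0.9,
                             ancestry_bias = c(A = 1, B = 2)),
    freqs2, lab, seed = 9)
  r2A <- cor(biased$dosage[lab == "A", 1], g3[lab == "A", 1])^2
  r2B <- cor(biased$dosage[lab == "B", 1], g3[lab == "B", 1])^2
  expect_gt(r2A - r2B, 0.02)

  expect_error(platform_error_model("imp", r2 = 0), "r2")
})

test_that("liability case simulator calibrates AUC and respects the null", {
  set.seed(70)
  scores <- rnorm(10000)
  y_null <- simulate_case_status(scores, 0.3, 0.5, seed = 10)
  expect_lt(abs(roc_auc(scores, y_null, ci = "none")$auc - 0.5), 0.02)
  expect_lt(abs(mean(y_null) - 0.3), 0.03)
  y <- simulate_case_status(scores, 0.1, 0.8, seed = 11)
  expect_lt(abs(roc_auc(scores, y, ci = "none")$auc - 0.8), 0.02)
  expect_identical(y, simulate_case_status(scores, 0.1, 0.8, seed = 11))
  expect_error(simulate_case_status(rep(1, 100), 0.1, 0.8), "variance")
})

test_that("simulated cohorts are internally consistent and reproducible", {
  cfg <- make_toy_config(6, 3, 3, seed = 2)
  co <- simulate_cohort(cfg, 400, seed = 12)
  expect_setequal(names(co$observations), c("WGS", "panelA", "panelB"))
  expect_equal(dim(co$true_genotypes), c(400, nrow(cfg$variants)))
  expect_true(all(co$true_genotypes %in% 0:2))

  # tag genotypes are consistent with the drawn haplotype pairs
  for (h in cfg$interactions$haplotypes) {
    vid <- cfg$interactions$tag_map[[h]]
    row <- cfg$variants[cfg$variants$variant_id == vid, ]
    copies <- (co$hap1 == h) + (co$hap2 == h)
    eff <- if (row$effect_allele == row$alt) co$true_genotypes[, vid]
           else 2L - co$true_genotypes[, vid]
    expect_equal(unname(eff), copies)
  }

  # allele frequencies recover the drawn per-population values
  big <- simulate_cohort(cfg, 8000,
                         mix = data.frame(label = "EUR", proportion = 1, fst = 0.05),
                         platforms = list(WGS = platform_preset("WGS")),
                         seed = 13)
  add <- cfg$variants$variant_id[cfg$variants$category != "HLA_INTERACTION_TAG"]
  emp <- colMeans(big$true_genotypes[, add]) / 2
  expect_lt(max(abs(emp - big$freqs["EUR", add])), 0.02)

  expect_equal(simulate_cohort(cfg, 400, seed = 12)$true_genotypes,
               co$true_genotypes)
})

test_that("analytic score moments match brute-force simulation", {
  cfg <- make_toy_config(8, 4, 3, seed = 21)
  co <- simulate_cohort(cfg, 20000,
                        mix = data.frame(label = "EUR", proportion = 1, fst = 0.02),
                        platforms = list(WGS = platform_preset("WGS")),
                        seed = 22)
  truth <- effect_cohort_from_truth(co)
  res <- compute_t1dgrs(truth, cfg)
  mom <- expected_score_moments(cfg, co$freqs["EUR", ], co$hap_freqs["EUR", ])
  expect_lt(abs(mean(res$total) - mom$mean), 0.03)
  expect_lt(abs(sd(res$total) - mom$sd), 0.03)
})

test_that("frequency shifting moves the expected score by the requested amount", {
  cfg <- make_toy_config(12, 4, 3, seed = 31)
  pops <- data.frame(label = "A", proportion = 1, fst = 0.01)
  add_ids <- cfg$variants$variant_id[cfg$variants$category != "HLA_INTERACTION_TAG"]
  anc <- setNames(runif(length(add_ids), 0.2, 0.8), add_ids)
  m <- population_model(pops, anc, setNames(c(0.2, 0.15, 0.1),
                                            cfg$interactions$haplotypes))
  f <- draw_population_frequencies(m, seed = 32)
  hf <- draw_haplotype_frequencies(m, seed = 33)
  mom0 <- expected_score_moments(cfg, f["A", ], hf["A", ])
  shifted <- shift_population_frequencies(f["A", ], cfg, -0.9, mom0$sd)
  mom1 <- expected_score_moments(cfg, shifted, hf["A", ])
  expect_equal(mom1$mean - mom0$mean, -0.9 * mom0$sd, tolerance = 1e-8)
  expect_true(all(shifted > 0 & shifted < 1))
})
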