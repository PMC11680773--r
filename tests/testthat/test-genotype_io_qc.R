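test_that("WGS hard filters apply the documented boundary rules", {
  calls <- rbind(
    one_call(1L, 10L, 20L, 0.50),   # boundary DP and GQ pass
    one_call(1L, 9L, 50L, 0.50),    # DP below threshold
    one_call(1L, 30L, 19L, 0.50),   # GQ below threshold
    one_call(1L, 30L, 50L, 0.20),   # het VAF boundary passes
    one_call(1L, 30L, 50L, 0.80),   # het VAF boundary passes
    one_call(1L, 30L, 50L, 0.15),   # het VAF out of range
    one_call(2L, 30L, 50L, 0.97),   # hom call: VAF rule does not apply
    one_call(NA_integer_, 30L, 50L, NA_real_),  # no genotype
    one_call(0L, 0L, 0L, NA_real_)) # zero depth
  out <- apply_wgs_call_filters(calls)
  expect_equal(out$reason,
               c("pass", "dp", "gq", "pass", "pass", "vaf", "pass",
                 "missing", "missing"))
  expect_equal(out$pass, out$reason == "pass")

  # filtering is idempotent
  expect_equal(apply_wgs_call_filters(out)$reason, out$reason)

  rep <- qc_report(out)
  expect_equal(rep$n_pass, 4L)
  expect_equal(rep$n_fail_dp + rep$n_fail_gq + rep$n_fail_vaf + rep$n_missing, 5L)
})

test_that("WGS VCF writing and reading round-trip calls exactly", {
  cfg <- make_toy_config(4, 2, 2, seed = 3)
  co <- simulate_cohort(cfg, 25, seed = 14,
                        platforms = list(WGS = platform_preset("WGS")))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_wgs_vcf(co$observations$WGS, cfg, path)
  back <- read_wgs_vcf(path, cfg)
  key <- function(d) {
    d <- as.data.frame(d)[order(d$sample_id, d$variant_id),
                          c("sample_id", "variant_id", "gt", "dp", "gq", "vaf")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(back), key(as.data.frame(co$observations$WGS)),
               tolerance = 1e-12)
  # AD arithmetic: vaf = alt / (ref + alt)
  with_ad <- back[!is.na(back$vaf) & back$dp > 0, ][1, ]
  expect_equal(with_ad$vaf, with_ad$ad_alt / (with_ad$ad_ref + with_ad$ad_alt))
})

test_that("multiallelic records are decomposed onto the configured alt", {
  cfg <- grs_config(
    data.frame(variant_id = "m1", chrom = "1", pos = 500L, ref = "A",
               alt = "T", effect_allele = "T", weight = 1,
               category = "NON_HLA_ADDITIVE", stringsAsFactors = FALSE),
    NULL)
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
           # ALT list is C,T -> configured alt T is allele index 2
           paste(c("1", "500", "m1", "A", "C,T", ".", "PASS", ".",
                   "GT:DP:GQ:AD", "1/2:30:60:10,10,10", "2/2:30:60:0,0,30"),
                 collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  calls <- read_wgs_vcf(path, cfg)
  calls <- calls[order(calls$sample_id), ]
  # s1 is C/T: one T allele; s2 is T/T: two
  expect_equal(calls$gt, c(1L, 2L))
  # VAF counts the configured alt over ref + alt reads
  expect_equal(calls$vaf, c(10 / 20, 30 / 30))
})

test_that("dosage ingestion keeps fractional values and honours the R2 floor", {
  cfg <- make_toy_config(3, 2, 2, seed = 5)
  vids <- cfg$variants$variant_id
  n <- 8
  dos <- matrix(round(runif(n * length(vids), 0, 2), 3), n,
                dimnames = list(NULL, vids))
  dos[1, 1] <- 1.37
  cg <- cohort_genotypes("arr", sprintf("S%02d", 1:n), vids, dos,
                         rep("alt", length(vids)))
  path <- withr::local_tempfile(fileext = ".vcf")
  r2 <- setNames(rep(0.95, length(vids)), vids)
  r2[vids[2]] <- 0.08  # below the 0.1 retention floor
  write_dosage_vcf(cg, cfg, path, r2 = r2)
  back <- read_dosages(path, cfg, format = "vcf")
  expect_equal(unname(back$dosage[1, 1]), 1.37, tolerance = 1e-6)
  expect_true(back$qc$excluded[2])
  expect_true(all(is.na(back$dosage[, 2])))
  expect_false(any(back$qc$excluded[-2]))

  # hard-called VCF without DS falls back to GT allele counts
  co <- simulate_cohort(cfg, 10, seed = 15,
                        platforms = list(WGS = platform_preset("WGS")))
  wpath <- withr::local_tempfile(fileext = ".vcf")
  write_wgs_vcf(co$observations$WGS, cfg, wpath)
  hard <- read_dosages(wpath, cfg, format = "vcf")
  wgs <- wgs_calls_to_cohort(co$observations$WGS, cfg, thresholds = NULL)
  expect_equal(hard$dosage, wgs$dosage)

  # TSV dosage matrix route
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample_id = cg$sample_ids, dos, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_dosages(tsv, cfg, format = "tsv")
  expect_equal(back2$dosage, dos, tolerance = 1e-9)

  # out-of-range dosage is an error naming the variant
  dos[2, 1] <- 2.5
  write.table(data.frame(sample_id = cg$sample_ids, dos, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dosages(tsv, cfg, format = "tsv"), "outside \\[0,2\\]")
})

test_that("harmonization reflects dosages onto the effect allele and is involutive", {
  cfg <- hand_config()
  vids <- cfg$variants$variant_id
  dos <- matrix(c(1.2, 0.4, 2, 1, NA), 1, dimnames = list(NULL, vids))
  cg <- cohort_genotypes("arr", "S1", vids, dos, rep("alt", 5))
  h <- harmonize_to_effect_allele(cg, cfg)
  # v1 effect = alt: unchanged; v2 effect = ref: reflected; missing stays missing
  expect_equal(unname(h$dosage[1, "v1"]), 1.2)
  expect_equal(unname(h$dosage[1, "v2"]), 1.6)
  expect_true(is.na(h$dosage[1, "t_dr4"]))
  # idempotent once counted_allele is updated
  expect_equal(harmonize_to_effect_allele(h, cfg)$dosage, h$dosage)
  # effect-allele frequency satisfies f_effect = 1 - f_other
  n <- 50
  dmat <- matrix(rbinom(n * 5, 2, 0.4) + 0.0, n, dimnames = list(NULL, vids))
  cg2 <- cohort_genotypes("arr", sprintf("S%02d", 1:n), vids, dmat, rep("alt", 5))
  h2 <- harmonize_to_effect_allele(cg2, cfg)
  f_alt <- colMeans(dmat) / 2
  f_eff <- colMeans(h2$dosage) / 2
  flip <- cfg$variants$effect_allele == cfg$variants$ref
  expect_equal(unname(f_eff[flip]), unname(1 - f_alt[flip]))
  expect_equal(unname(f_eff[!flip]), unname(f_alt[!flip]))

  bad <- cg
  bad$counted_allele[1] <- "Z"
  expect_error(harmonize_to_effect_allele(bad, cfg), "v1")
})

test_that("post-QC WGS dosages equal truth on a high-depth error-free cohort", {
  cfg <- make_toy_config(5, 3, 2, seed = 6)
  co <- simulate_cohort(
    cfg, 300, seed = 16,
    platforms = list(WGS = platform_error_model("WGS", mean_depth = 80,
                                                genotype_error_rate = 0)))
  cg <- wgs_calls_to_cohort(co$observations$WGS, cfg)
  called <- !is.na(cg$dosage)
  expect_gt(mean(called), 0.999)
  expect_equal(cg$dosage[called], co$true_genotypes[called] + 0.0)
})
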