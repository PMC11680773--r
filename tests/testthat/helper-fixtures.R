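# Shared fixtures, all built in code.

# Hand-specified 5-variant config: 2 non-HLA, 1 HLA-additive, 2 DR-DQ tags.
# Weights and pair table are round numbers so score totals can be worked by
# hand in the engine tests.
hand_config <- function() {
  variants <- data.frame(
    variant_id = c("v1", "v2", "v3", "t_dr3", "t_dr4"),
    chrom = c("1", "2", "6", "6", "6"),
    pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G"),
    effect_allele = c("G", "C", "A", "C", "G"),  # v2's effect is the REF allele
    weight = c(0.5, -0.2, 1.1, 0, 0),
    category = c("NON_HLA_ADDITIVE", "NON_HLA_ADDITIVE", "HLA_ADDITIVE",
                 "HLA_INTERACTION_TAG", "HLA_INTERACTION_TAG"),
    stringsAsFactors = FALSE)
  interactions <- list(
    haplotypes = c("DR3", "DR4"),
    tag_map = c(DR3 = "t_dr3", DR4 = "t_dr4"),
    pair_weights = data.frame(
      hap1 = c("DR3", "DR3", "DR4", "DR3", "DR4", "other"),
      hap2 = c("DR3", "DR4", "DR4", "other", "other", "other"),
      weight = c(2.0, 3.1, 2.5, 1.0, 1.2, 0),
      stringsAsFactors = FALSE),
    baseline_weight = 0)
  grs_config(variants, interactions, name = "hand", version = "1")
}

# cohort_genotypes already harmonized to effect alleles
effect_cohort <- function(dosage, config, platform = "test") {
  cohort_genotypes(platform,
                   sample_ids = sprintf("S%02d", seq_len(nrow(dosage))),
                   variant_ids = config$variants$variant_id,
                   dosage = dosage,
                   counted_allele = rep("effect", ncol(dosage)))
}

# harmonized cohort built from a simulated cohort's true genotypes
effect_cohort_from_truth <- function(co) {
  cg <- cohort_genotypes("truth", co$sample_ids, colnames(co$true_genotypes),
                         co$true_genotypes + 0.0,
                         rep("alt", ncol(co$true_genotypes)))
  harmonize_to_effect_allele(cg, co$config)
}

# a single WGS-style call row for the filter truth-table tests
one_call <- function(gt, dp, gq, vaf) {
  ad_alt <- if (is.na(vaf)) NA_integer_ else as.integer(round(vaf * dp))
  data.frame(sample_id = "S1", variant_id = "v", gt = gt, dp = dp, gq = gq,
             ad_ref = dp - ad_alt, ad_alt = ad_alt, vaf = vaf,
             platform = "WGS", stringsAsFactors = FALSE)
}
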