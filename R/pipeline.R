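#' @title End-to-end concordance and ancestry-threshold analyses
#' @name pipeline
#' @description
#' Orchestrates simulate -> QC -> score -> compare runs with explicit
#' seeds and machine-readable reports. Every number in a report is
#' re-derivable from the emitted per-sample score tables.
NULL

# scores for every platform of a simulated cohort, via the QC/harmonize path
.score_all_platforms <- function(cohort, missing_policy = "freq") {
  config <- cohort$config
  out <- list()
  for (nm in names(cohort$observations)) {
    obs <- cohort$observations[[nm]]
    cg <- if (inherits(obs, "wgs_calls")) wgs_calls_to_cohort(obs, config)
          else obs
    cg <- harmonize_to_effect_allele(cg, config)
    out[[nm]] <- list(cohort = cg,
                      scores = compute_t1dgrs(cg, config,
                                              missing_policy = missing_policy))
  }
  out
}

#' Run the full platform-concordance analysis
#'
#' Simulates a multi-platform cohort, scores every platform through the
#' QC/harmonization path, and compares each imputed platform against the
#' WGS reference: Spearman correlation with bootstrap CI, the dependent-
#' correlation z-test between the two imputed platforms, paired mean
#' differences in WGS-frame SD units, Bland-Altman agreement, per-variant
#' exact allele-frequency tests, and centile-threshold re-categorisation
#' tables at each requested centile. Optionally simulates liability-model
#' case labels and reports per-platform ROC AUC.
#'
#' @param config a [grs_config()].
#' @param n cohort size.
#' @param mix population mix (default [default_population_mix()]).
#' @param platforms named list of [platform_error_model()]s; must contain
#'   exactly one WGS-type model (the reference) first.
#' @param thresholds centiles for the re-categorisation tables.
#' @param missing_policy passed to [compute_t1dgrs()].
#' @param seed master seed.
#' @param n_boot bootstrap replicates for interval estimates.
#' @param simulate_cases simulate case labels and report ROC AUC?
#' @param prevalence,auc_target liability-simulator settings.
#' @param out_dir optional directory: writes `scores_<platform>.tsv`,
#'   `qc_report.tsv`, `variant_tests_<platform>.tsv`,
#'   `concordance_report.json` and `run_manifest.json`.
#' @return the report list (platform blocks, `meng`, `tables`, `roc`, ...).
#' @export
run_concordance_analysis <- function(config, n,
                                     mix = default_population_mix(),
                                     platforms = list(
                                       WGS = platform_preset("WGS"),
                                       panelA = platform_preset("panelA-1000G"),
                                       panelB = platform_preset("panelB-TOPMed")),
                                     thresholds = c(50, 90),
                                     missing_policy = "freq",
                                     seed = 1L, n_boot = 200,
                                     simulate_cases = FALSE,
                                     prevalence = 0.005, auc_target = 0.92,
                                     out_dir = NULL) {
  if (any(thresholds <= 0 | thresholds >= 100))
    stop("threshold centiles must lie in (0, 100)")
  is_wgs <- vapply(platforms, function(p) is.finite(p$mean_depth), TRUE)
  if (sum(is_wgs) != 1) stop("platforms must contain exactly one WGS-type model")
  wgs_name <- names(platforms)[is_wgs]
  imp_names <- names(platforms)[!is_wgs]

  cohort <- simulate_cohort(config, n, mix = mix, platforms = platforms,
                            seed = seed)
  scored <- .score_all_platforms(cohort, missing_policy = missing_policy)
  wgs <- scored[[wgs_name]]
  frame_wgs <- centile_frame(wgs$scores$total, "whole-cohort-WGS")

  report <- list(seed = seed, n = n, reference_platform = wgs_name,
                 platforms = list(), tables = list())
  rho <- list()
  for (nm in imp_names) {
    sc <- scored[[nm]]
    sp <- spearman_with_ci(wgs$scores$total, sc$scores$total,
                           n_boot = n_boot, seed = seed + 17L)
    rho[[nm]] <- sp$rho
    zw <- standardize_scores(wgs$scores$total, frame_wgs)
    za <- standardize_scores(sc$scores$total, frame_wgs)
    pt <- paired_mean_difference_test(zw, za)
    ba <- bland_altman(wgs$scores$total, sc$scores$total)
    vt <- variant_frequency_tests(wgs$cohort, sc$cohort)
    report$platforms[[nm]] <- list(
      spearman = sp, paired_sd_units = pt, bland_altman = ba,
      n_significant_variants = sum(vt$significant),
      variant_tests = vt)
    for (q in thresholds) {
      tc <- threshold_concordance(wgs$scores$total, sc$scores$total, q)
      report$tables[[paste0(nm, "_q", q)]] <- tc
    }
  }
  if (length(imp_names) >= 2) {
    r12 <- stats::cor(scored[[imp_names[1]]]$scores$total,
                      scored[[imp_names[2]]]$scores$total,
                      method = "spearman")
    report$meng <- meng_z_test(rho[[imp_names[1]]], rho[[imp_names[2]]],
                               r12, n = n)
  }
  if (simulate_cases) {
    labels <- simulate_case_status(wgs$scores$total, prevalence, auc_target,
                                   seed = seed + 23L)
    report$roc <- lapply(scored, function(sc)
      roc_auc(sc$scores$total, labels, n_boot = n_boot, seed = seed + 29L))
    report$case_prevalence <- mean(labels)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(scored)) {
      sc <- scored[[nm]]$scores
      sc$standardized <- standardize_scores(sc$total, frame_wgs)
      sc$centile_wholecohort <- score_centile(sc$total, frame_wgs)
      utils::write.table(sc, file.path(out_dir, paste0("scores_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(wgs$cohort$qc))
      utils::write.table(wgs$cohort$qc, file.path(out_dir, "qc_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in imp_names)
      utils::write.table(report$platforms[[nm]]$variant_tests,
                         file.path(out_dir, paste0("variant_tests_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    slim <- report
    for (nm in imp_names) slim$platforms[[nm]]$variant_tests <- NULL
    jsonlite::write_json(.unclass_report(slim),
                         file.path(out_dir, "concordance_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(list(seed = seed, n = n,
                              config_name = config$name,
                              config_version = config$version,
                              package_version = as.character(utils::packageVersion("grsconcord"))),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE)
  }
  report
}

.unclass_report <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .unclass_report)
    attributes(x) <- list(names = names(x))
  } else if (is.matrix(x)) {
    x <- as.data.frame(x)
  }
  x
}

#' Run the cross-ancestry threshold analysis
#'
#' Simulates a multi-population cohort (optionally with a configured mean
#' score shift in one population), computes WGS-based scores, builds the
#' reference-population centile frame, and reports per-ancestry
#' standardised score means and the fractions below the reference 50th
#' and at/above the reference 90th centile thresholds, for the total
#' score and for its HLA (additive + interaction) and non-HLA components.
#'
#' @param config a [grs_config()].
#' @param n cohort size.
#' @param mix population mix (needs >= 2 populations).
#' @param ref_pop frame population (default `"EUR"`).
#' @param thresholds centiles (default c(50, 90)).
#' @param shift_spec optional shift passed to [simulate_cohort()].
#' @param seed master seed.
#' @param wgs_model WGS observation model.
#' @param out_dir optional output directory (`ancestry_report.json`,
#'   `scores_by_ancestry.tsv`).
#' @return report list: per-ancestry block with `n`, `mean_sd_units`,
#'   `frac_below_50`, `frac_at_or_above_90` (and per-component means).
#' @export
run_ancestry_threshold_analysis <- function(config, n,
                                            mix = default_population_mix(),
                                            ref_pop = "EUR",
                                            thresholds = c(50, 90),
                                            shift_spec = NULL,
                                            seed = 1L,
                                            wgs_model = platform_preset("WGS"),
                                            out_dir = NULL) {
  if (nrow(mix) < 2) stop("ancestry analysis needs at least two populations")
  if (!ref_pop %in% mix$label) stop("ref_pop not in the population mix")
  cohort <- simulate_cohort(config, n, mix = mix,
                            platforms = list(WGS = wgs_model),
                            seed = seed, shift_spec = shift_spec)
  scored <- .score_all_platforms(cohort)$WGS$scores
  scored$hla <- scored$hla_additive + scored$interaction
  anc <- cohort$ancestry
  in_ref <- anc == ref_pop
  if (!any(in_ref)) stop("no samples from the reference population")
  frames <- list(total = centile_frame(scored$total[in_ref], ref_pop),
                 hla = centile_frame(scored$hla[in_ref], ref_pop),
                 non_hla = centile_frame(scored$non_hla[in_ref], ref_pop))
  thr_lo <- centile_threshold(frames$total, thresholds[1])
  thr_hi <- centile_threshold(frames$total, thresholds[2])
  per_pop <- lapply(unique(mix$label), function(pop) {
    i <- anc == pop
    list(population = pop, n = sum(i),
         mean_sd_units = mean(standardize_scores(scored$total[i], frames$total)),
         mean_hla_sd_units = mean(standardize_scores(scored$hla[i], frames$hla)),
         mean_non_hla_sd_units = mean(standardize_scores(scored$non_hla[i], frames$non_hla)),
         frac_below_50 = mean(scored$total[i] < thr_lo),
         frac_at_or_above_90 = mean(scored$total[i] >= thr_hi))
  })
  names(per_pop) <- unique(mix$label)
  report <- list(seed = seed, n = n, ref_pop = ref_pop,
                 thresholds = thresholds,
                 threshold_values = c(thr_lo, thr_hi),
                 shift_spec = shift_spec, populations = per_pop)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- scored
    tab$ancestry <- anc
    tab$standardized <- standardize_scores(scored$total, frames$total)
    utils::write.table(tab, file.path(out_dir, "scores_by_ancestry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(.unclass_report(report),
                         file.path(out_dir, "ancestry_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}
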