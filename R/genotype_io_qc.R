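#' @title Genotype ingestion, QC filtering and allele harmonization
#' @name genotype_io_qc
#' @description
#' Reads WGS-style VCF calls and imputed dosages, applies the hard call
#' filters (depth >= 10, genotype quality >= 20, heterozygous allelic
#' balance within [0.2, 0.8]) and re-expresses every platform as
#' effect-allele dosage matrices keyed by the score configuration.
NULL

#' Container for a platform's dosage matrix
#'
#' @param platform platform label.
#' @param sample_ids,variant_ids row/column identities.
#' @param dosage numeric samples x variants matrix in [0,2], NA = missing.
#' @param counted_allele per-variant: which allele the dosage counts
#'   (`"alt"`, `"ref"` or `"effect"` after harmonization).
#' @param qc optional per-variant QC data.frame.
#' @param r2_target,r2_info optional per-variant imputation quality.
#' @return a `cohort_genotypes` object.
#' @export
cohort_genotypes <- function(platform, sample_ids, variant_ids, dosage,
                             counted_allele, qc = NULL,
                             r2_target = NULL, r2_info = NULL) {
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == length(variant_ids),
            length(counted_allele) == length(variant_ids))
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-6 || rng[2] > 2 + 1e-6))
    stop("dosages outside [0, 2]")
  structure(list(platform = platform, sample_ids = sample_ids,
                 variant_ids = variant_ids, dosage = dosage,
                 counted_allele = counted_allele, qc = qc,
                 r2_target = r2_target, r2_info = r2_info),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("cohort_genotypes [%s]: %d samples x %d variants, %.2f%% missing\n",
              x$platform, length(x$sample_ids), length(x$variant_ids),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Default WGS call-filter thresholds
#'
#' Depth >= 10, genotype quality >= 20 (both inclusive) and, for
#' heterozygous calls only, allelic balance within the closed interval
#' [0.2, 0.8].
#' @return named list of thresholds.
#' @export
default_wgs_filters <- function() {
  list(min_dp = 10, min_gq = 20, vaf_lo = 0.2, vaf_hi = 0.8)
}

#' Apply WGS hard filters to calls
#'
#' The allelic-balance rule applies to heterozygous calls only; boundary
#' values pass (DP = 10, GQ = 20, VAF exactly 0.2 or 0.8). Calls with no
#' genotype or zero depth are `missing`. The first failed rule, in order
#' missing > dp > gq > vaf, is recorded as the reason.
#'
#' @param calls a `wgs_calls` data.frame (see
#'   [simulate_wgs_observations()] / [read_wgs_vcf()]).
#' @param thresholds list as [default_wgs_filters()].
#' @return `calls` with logical `pass` and character `reason`
#'   (`"pass"`, `"missing"`, `"dp"`, `"gq"`, `"vaf"`) columns.
#' @export
apply_wgs_call_filters <- function(calls, thresholds = default_wgs_filters()) {
  stopifnot(thresholds$vaf_lo >= 0, thresholds$vaf_hi <= 1,
            thresholds$min_dp > 0, thresholds$min_gq > 0)
  reason <- rep("pass", nrow(calls))
  is_het <- !is.na(calls$gt) & calls$gt == 1L
  fail_vaf <- is_het & !is.na(calls$vaf) &
    (calls$vaf < thresholds$vaf_lo | calls$vaf > thresholds$vaf_hi)
  reason[fail_vaf] <- "vaf"
  reason[calls$gq < thresholds$min_gq] <- "gq"
  reason[calls$dp < thresholds$min_dp] <- "dp"
  reason[is.na(calls$gt) | calls$dp == 0L] <- "missing"
  calls$pass <- reason == "pass"
  calls$reason <- reason
  calls
}

#' Per-variant QC summary
#'
#' @param filtered output of [apply_wgs_call_filters()].
#' @return data.frame: `variant_id`, `n_pass`, `n_fail_dp`, `n_fail_gq`,
#'   `n_fail_vaf`, `n_missing`.
#' @export
qc_report <- function(filtered) {
  tab <- table(filtered$variant_id, factor(filtered$reason,
               levels = c("pass", "dp", "gq", "vaf", "missing")))
  data.frame(variant_id = rownames(tab),
             n_pass = as.integer(tab[, "pass"]),
             n_fail_dp = as.integer(tab[, "dp"]),
             n_fail_gq = as.integer(tab[, "gq"]),
             n_fail_vaf = as.integer(tab[, "vaf"]),
             n_missing = as.integer(tab[, "missing"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert filtered WGS calls to a dosage matrix
#'
#' Failed or missing calls become missing dosages (samples are kept; the
#' score engine owns missing-data policy).
#'
#' @param calls a `wgs_calls` data.frame.
#' @param config a [grs_config()]; fixes the variant order.
#' @param thresholds filter thresholds, or NULL to skip filtering.
#' @return a [cohort_genotypes()] with ALT-allele counts.
#' @export
wgs_calls_to_cohort <- function(calls, config,
                                thresholds = default_wgs_filters()) {
  if (!is.null(thresholds)) calls <- apply_wgs_call_filters(calls, thresholds)
  else { calls$pass <- !is.na(calls$gt); calls$reason <- NA_character_ }
  sample_ids <- unique(calls$sample_id)
  vids <- config$variants$variant_id
  dos <- matrix(NA_real_, length(sample_ids), length(vids),
                dimnames = list(NULL, vids))
  ok <- calls$pass & calls$variant_id %in% vids
  i <- match(calls$sample_id[ok], sample_ids)
  j <- match(calls$variant_id[ok], vids)
  dos[cbind(i, j)] <- calls$gt[ok]
  cohort_genotypes(platform = calls$platform[1] %||% "WGS",
                   sample_ids = sample_ids, variant_ids = vids,
                   dosage = dos, counted_allele = rep("alt", length(vids)),
                   qc = if (!is.null(thresholds)) qc_report(calls) else NULL)
}

.gt_string <- function(count, ploidy_sep = "/") {
  ifelse(is.na(count), "./.",
         c("0/0", "0/1", "1/1")[count + 1L])
}

#' Write WGS calls to a VCF 4.2 file
#'
#' FORMAT `GT:DP:GQ:AD`; site coordinates, alleles and IDs come from the
#' score configuration.
#'
#' @param calls a `wgs_calls` data.frame.
#' @param config a [grs_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wgs_vcf <- function(calls, config, path) {
  v <- config$variants
  sample_ids <- unique(calls$sample_id)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  rows <- character(nrow(v))
  for (k in seq_len(nrow(v))) {
    sub <- calls[calls$variant_id == v$variant_id[k], ]
    sub <- sub[match(sample_ids, sub$sample_id), ]
    cell <- sprintf("%s:%s:%s:%s,%s", .gt_string(sub$gt),
                    sub$dp, sub$gq, sub$ad_ref, sub$ad_alt)
    cell[is.na(sub$sample_id)] <- "./.:.:.:.,."
    rows[k] <- paste(c(v$chrom[k], v$pos[k], v$variant_id[k], v$ref[k],
                       v$alt[k], ".", "PASS", ".", "GT:DP:GQ:AD", cell),
                     collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an imputed-dosage VCF (FORMAT DS)
#'
#' @param cohort a [cohort_genotypes()] with ALT-counted dosages.
#' @param config a [grs_config()].
#' @param path output file.
#' @param r2 optional named per-variant imputation quality written as
#'   `INFO R2=`.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(cohort, config, path, r2 = NULL) {
  v <- config$variants[match(cohort$variant_ids, config$variants$variant_id), ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_ids), collapse = "\t"))
  rows <- character(nrow(v))
  for (k in seq_len(nrow(v))) {
    d <- cohort$dosage[, k]
    cell <- ifelse(is.na(d), ".", sprintf("%.8g", d))
    info <- if (!is.null(r2)) sprintf("R2=%.6g", r2[[v$variant_id[k]]]) else "."
    rows[k] <- paste(c(v$chrom[k], v$pos[k], v$variant_id[k], v$ref[k],
                       v$alt[k], ".", "PASS", info, "DS", cell),
                     collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# Match VCF records to configured variants: chrom+pos+ref+alt first,
# rsID fallback (with warning). For multiallelic records, returns the
# 1-based index of the configured alt within the ALT list.
.match_config_variants <- function(fix, config) {
  v <- config$variants
  out <- data.frame(cfg_row = integer(), vcf_row = integer(),
                    alt_index = integer())
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  used_rsid <- FALSE
  for (k in seq_len(nrow(v))) {
    hit <- which(fix[, "CHROM"] == v$chrom[k] &
                 as.integer(fix[, "POS"]) == v$pos[k] &
                 fix[, "REF"] == v$ref[k])
    ai <- NA_integer_
    if (length(hit) > 0) {
      for (h in hit) {
        m <- match(v$alt[k], alt_list[[h]])
        if (!is.na(m)) { hit <- h; ai <- m; break }
      }
    }
    if (is.na(ai)) {
      hit <- which(fix[, "ID"] == v$variant_id[k])
      if (length(hit) == 1) {
        m <- match(v$alt[k], alt_list[[hit]])
        if (!is.na(m)) { ai <- m; used_rsid <- TRUE }
      }
    }
    if (!is.na(ai))
      out <- rbind(out, data.frame(cfg_row = k, vcf_row = hit[1],
                                   alt_index = ai))
  }
  if (used_rsid)
    warning("some variants matched by rsID only, not by chrom/pos/ref/alt")
  missing <- setdiff(v$variant_id, v$variant_id[out$cfg_row])
  if (length(missing) > 0)
    warning("config variants absent from VCF (treated as missing): ",
            paste(missing, collapse = ", "))
  out
}

#' Read WGS calls from a VCF
#'
#' Variants are matched to the configuration by chrom/pos/ref/alt
#' (rsID fallback with a warning); multiallelic records are decomposed and
#' the configured ALT allele counted. VAF is computed from AD as
#' alt / (ref + alt). DP/GQ/AD absent from FORMAT are treated as missing
#' QC information (DP/GQ set to 0 -- such calls fail the hard filters).
#'
#' @param path VCF file (may be bgzipped).
#' @param config a [grs_config()].
#' @return a `wgs_calls` data.frame (one row per sample x matched variant).
#' @export
read_wgs_vcf <- function(path, config) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  map <- .match_config_variants(fix, config)
  gt_raw <- vcfR::extract.gt(vcf, "GT")
  has <- function(f)
    any(grepl(paste0("(^|:)", f, "(:|$)"), vcf@gt[, "FORMAT"]))
  dp_raw <- if (has("DP")) suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)) else NULL
  gq_raw <- if (has("GQ")) suppressWarnings(vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE)) else NULL
  ad_raw <- if (has("AD")) vcfR::extract.gt(vcf, "AD") else NULL
  samples <- colnames(gt_raw)
  v <- config$variants
  res <- vector("list", nrow(map))
  for (r in seq_len(nrow(map))) {
    k <- map$cfg_row[r]; h <- map$vcf_row[r]; ai <- map$alt_index[r]
    gts <- gt_raw[h, ]
    alleles <- strsplit(gts, "[/|]")
    count <- vapply(alleles, function(a) {
      if (length(a) == 0 || any(a == ".") || any(is.na(a))) NA_integer_
      else sum(a == as.character(ai))
    }, 1L)
    dp <- if (!is.null(dp_raw)) dp_raw[h, ] else rep(0, length(samples))
    gq <- if (!is.null(gq_raw)) gq_raw[h, ] else rep(0, length(samples))
    dp[is.na(dp)] <- 0; gq[is.na(gq)] <- 0
    ad_ref <- ad_alt <- rep(NA_integer_, length(samples))
    if (!is.null(ad_raw)) {
      parts <- strsplit(ad_raw[h, ], ",", fixed = TRUE)
      ad_ref <- vapply(parts, function(x)
        suppressWarnings(as.integer(x[1])), 1L)
      ad_alt <- vapply(parts, function(x)
        suppressWarnings(as.integer(x[ai + 1L])), 1L)
    }
    vaf <- ifelse(!is.na(ad_ref) & !is.na(ad_alt) & (ad_ref + ad_alt) > 0,
                  ad_alt / (ad_ref + ad_alt), NA_real_)
    res[[r]] <- data.frame(sample_id = samples, variant_id = v$variant_id[k],
                           gt = count, dp = as.integer(round(dp)),
                           gq = as.integer(round(gq)),
                           ad_ref = ad_ref, ad_alt = ad_alt, vaf = vaf,
                           platform = "WGS", stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  class(out) <- c("wgs_calls", "data.frame")
  out
}

#' Read imputed dosages
#'
#' Accepts a VCF with FORMAT `DS` (falling back to GT allele counts for
#' hard-called files) or a TSV dosage matrix (first column `sample_id`,
#' remaining columns named by variant). INFO `R2`, when present, is
#' attached per variant; variants with `R2` below `r2_floor` are flagged
#' excluded and their dosages set missing.
#'
#' @param path input file.
#' @param config a [grs_config()].
#' @param format `"vcf"` or `"tsv"`.
#' @param platform label for the returned object.
#' @param r2_floor imputation-quality retention floor (panels drop poorly
#'   imputed markers; default 0.1).
#' @return a [cohort_genotypes()] (ALT-counted dosages; `qc` records
#'   per-variant `r2` and `excluded`).
#' @export
read_dosages <- function(path, config, format = c("vcf", "tsv"),
                         platform = "array", r2_floor = 0.1) {
  format <- match.arg(format)
  v <- config$variants
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    sample_ids <- tab[[1]]
    vids <- intersect(v$variant_id, names(tab))
    dos <- matrix(NA_real_, length(sample_ids), nrow(v),
                  dimnames = list(NULL, v$variant_id))
    for (vid in vids) dos[, vid] <- as.numeric(tab[[vid]])
    bad <- which(dos < -1e-6 | dos > 2 + 1e-6, arr.ind = TRUE)
    if (length(bad) > 0)
      stop("dosage outside [0,2] for variant ",
           colnames(dos)[bad[1, 2]], ", sample ", sample_ids[bad[1, 1]])
    return(cohort_genotypes(platform, sample_ids, v$variant_id, dos,
                            counted_allele = rep("alt", nrow(v))))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  map <- .match_config_variants(fix, config)
  has_ds <- any(grepl("(^|:)DS(:|$)", vcf@gt[, "FORMAT"]))
  ds_raw <- if (has_ds) suppressWarnings(vcfR::extract.gt(vcf, "DS", as.numeric = TRUE)) else NULL
  gt_raw <- vcfR::extract.gt(vcf, "GT")
  samples <- colnames(gt_raw)
  info <- vcf@fix[, "INFO"]
  r2_vals <- suppressWarnings(as.numeric(sub(".*R2= *([0-9.eE+-]+).*", "\\1", info)))
  r2_vals[!grepl("R2=", info)] <- NA_real_
  dos <- matrix(NA_real_, length(samples), nrow(v),
                dimnames = list(NULL, v$variant_id))
  r2_out <- stats::setNames(rep(NA_real_, nrow(v)), v$variant_id)
  for (r in seq_len(nrow(map))) {
    k <- map$cfg_row[r]; h <- map$vcf_row[r]; ai <- map$alt_index[r]
    if (has_ds) {
      d <- ds_raw[h, ]
    } else {
      alleles <- strsplit(gt_raw[h, ], "[/|]")
      d <- vapply(alleles, function(a) {
        if (length(a) == 0 || any(a == ".") || any(is.na(a))) NA_real_
        else sum(a == as.character(ai))
      }, 1)
    }
    if (any(d < -1e-6 | d > 2 + 1e-6, na.rm = TRUE))
      stop("dosage outside [0,2] at variant ", v$variant_id[k])
    dos[, v$variant_id[k]] <- d
    r2_out[k] <- r2_vals[h]
  }
  excluded <- !is.na(r2_out) & r2_out < r2_floor
  dos[, excluded] <- NA_real_
  cohort_genotypes(platform, samples, v$variant_id, dos,
                   counted_allele = rep("alt", nrow(v)),
                   qc = data.frame(variant_id = v$variant_id,
                                   r2 = unname(r2_out),
                                   excluded = unname(excluded),
                                   stringsAsFactors = FALSE),
                   r2_info = r2_out)
}

#' Re-express dosages as effect-allele counts
#'
#' Dosages counted on the effect allele are unchanged; dosages counted on
#' the other allele are reflected (`2 - d`). Missing stays missing. A
#' counted allele matching neither configured allele is a
#' (strand-ambiguity) error.
#'
#' @param cohort a [cohort_genotypes()].
#' @param config a [grs_config()].
#' @return the harmonized [cohort_genotypes()] (`counted_allele` all
#'   `"effect"`).
#' @export
harmonize_to_effect_allele <- function(cohort, config) {
  v <- config$variants
  i <- match(cohort$variant_ids, v$variant_id)
  if (any(is.na(i)))
    stop("cohort contains variants not in the config: ",
         paste(cohort$variant_ids[is.na(i)], collapse = ", "))
  counted <- cohort$counted_allele
  counted_base <- ifelse(counted == "alt", v$alt[i],
                  ifelse(counted == "ref", v$ref[i],
                  ifelse(counted == "effect", v$effect_allele[i], counted)))
  ok_eff <- counted_base == v$effect_allele[i]
  ok_other <- counted_base == ifelse(v$effect_allele[i] == v$alt[i],
                                     v$ref[i], v$alt[i])
  if (any(!ok_eff & !ok_other))
    stop("counted allele matches neither configured allele for: ",
         paste(cohort$variant_ids[!ok_eff & !ok_other], collapse = ", "))
  dos <- cohort$dosage
  flip <- which(!ok_eff)
  if (length(flip) > 0) dos[, flip] <- 2 - dos[, flip]
  cohort$dosage <- dos
  cohort$counted_allele <- rep("effect", length(counted))
  cohort
}
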