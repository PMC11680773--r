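#' @title Risk-score engine: additive weights plus DR-DQ diplotype interactions
#' @name grs_engine
#' @description
#' Computes the type 1 diabetes genetic risk score as the sum of three
#' components: a non-HLA additive part, an HLA additive part (each
#' `sum(weight * effect-allele dosage)`), and an interaction term looked
#' up from the diplotype called from the 14-style DR-DQ tag variants.
#' Scores can then be standardised and converted to centiles against a
#' reference frame.
NULL

#' Call a DR-DQ diplotype from tag-variant dosages
#'
#' Tag dosages are hard-called by rounding to the nearest integer (ties at
#' .5 round down: imputed tags near half-copies are genuinely ambiguous).
#' The two carried haplotypes are the multiset top-2 by copy count; with
#' fewer than two tagged copies the remaining slot(s) are `"other"`. More
#' than two total tagged copies is inconsistent (tags are meant to be
#' mutually exclusive haplotype markers): the call is resolved
#' deterministically by taking copies in configuration order and flagged.
#' Missing tag dosages count as zero copies and also flag the call.
#'
#' @param tag_dosages named numeric vector of effect-allele dosages, one
#'   per tag variant.
#' @param interactions the interaction table of a [grs_config()].
#' @return list with `hap1`, `hap2` (sorted lexicographically, `"other"`
#'   last), `flagged`, and `counts` (the hard tag copies used).
#' @export
call_hla_diplotype <- function(tag_dosages, interactions) {
  haps <- interactions$haplotypes
  d <- tag_dosages[unname(interactions$tag_map)]
  miss <- is.na(d)
  counts <- ifelse(miss, 0L, pmin(pmax(ceiling(d - 0.5), 0), 2))
  names(counts) <- haps
  total <- sum(counts)
  flagged <- any(miss) || total > 2
  slots <- character(0)
  for (h in haps) {
    take <- min(counts[[h]], 2 - length(slots))
    if (take > 0) slots <- c(slots, rep(h, take))
    if (length(slots) == 2) break
  }
  while (length(slots) < 2) slots <- c(slots, "other")
  slots <- .sort_diplotype(slots)
  list(hap1 = slots[1], hap2 = slots[2], flagged = flagged, counts = counts)
}

# lexicographic order with "other" always last
.sort_diplotype <- function(slots) {
  is_other <- slots == "other"
  c(sort(slots[!is_other]), slots[is_other])
}

#' Interaction weight for a called diplotype
#'
#' @param diplotype result of [call_hla_diplotype()].
#' @param interactions the interaction table.
#' @return scalar weight (pair-table lookup; unordered, baseline fallback).
#' @export
interaction_score <- function(diplotype, interactions) {
  interaction_weight(interactions, diplotype$hap1, diplotype$hap2)
}

#' Compute per-sample risk scores
#'
#' `total = non_hla + hla_additive + interaction` exactly. Missing
#' additive dosages are handled by `missing_policy`:
#' \describe{
#'   \item{`"freq"` (default)}{substitute twice the effect-allele
#'     frequency (mean-preserving); frequencies from `ref_freqs` or, when
#'     NULL, from the cohort's own non-missing dosages.}
#'   \item{`"zero"`}{substitute 0.}
#'   \item{`"rescale"`}{drop missing terms and rescale each additive
#'     component by (sum of all weights)/(sum of weights present).}
#' }
#' Samples missing more than `unreliable_frac` of configured variants are
#' flagged unreliable.
#'
#' @param cohort a [cohort_genotypes()] harmonized to effect alleles
#'   (see [harmonize_to_effect_allele()]).
#' @param config a [grs_config()].
#' @param missing_policy one of `"freq"`, `"zero"`, `"rescale"`.
#' @param ref_freqs optional named effect-allele frequencies for the
#'   `"freq"` policy.
#' @param unreliable_frac missingness fraction above which a sample is
#'   flagged (default 0.5).
#' @return data.frame: `sample_id`, `total`, `interaction`,
#'   `hla_additive`, `non_hla`, `n_missing`, `diplotype`,
#'   `flagged_diplotype`, `unreliable`, `missing_policy`.
#' @export
compute_t1dgrs <- function(cohort, config,
                           missing_policy = c("freq", "zero", "rescale"),
                           ref_freqs = NULL, unreliable_frac = 0.5) {
  missing_policy <- match.arg(missing_policy)
  if (!all(cohort$counted_allele == "effect"))
    stop("cohort must be harmonized to effect alleles first")
  v <- config$variants
  dos <- cohort$dosage[, v$variant_id, drop = FALSE]
  n <- nrow(dos)
  n_missing <- rowSums(is.na(dos))

  additive_component <- function(category) {
    idx <- which(v$category == category)
    if (length(idx) == 0) return(numeric(n))
    d <- dos[, idx, drop = FALSE]
    w <- v$weight[idx]
    if (missing_policy == "freq") {
      f <- if (!is.null(ref_freqs)) ref_freqs[v$variant_id[idx]]
           else colMeans(d, na.rm = TRUE) / 2
      f[is.na(f)] <- 0.5  # variant missing everywhere: neutral substitution
      for (j in seq_along(idx)) d[is.na(d[, j]), j] <- 2 * f[j]
      as.numeric(d %*% w)
    } else if (missing_policy == "zero") {
      d[is.na(d)] <- 0
      as.numeric(d %*% w)
    } else {
      present <- !is.na(d)
      d[!present] <- 0
      raw <- as.numeric(d %*% w)
      wsum_present <- as.numeric(present %*% w)
      scale <- ifelse(abs(wsum_present) > 1e-12, sum(w) / wsum_present, 1)
      raw * scale
    }
  }
  non_hla <- additive_component("NON_HLA_ADDITIVE")
  hla_add <- additive_component("HLA_ADDITIVE")

  interaction <- numeric(n)
  diplotype <- rep("other/other", n)
  flagged <- rep(FALSE, n)
  it <- config$interactions
  if (!is.null(it) && length(it$haplotypes) > 0) {
    tag_ids <- unname(it$tag_map)
    tagd <- dos[, tag_ids, drop = FALSE]
    pw <- it$pair_weights
    keys <- .pair_key(pw$hap1, pw$hap2)
    for (s in seq_len(n)) {
      dip <- call_hla_diplotype(stats::setNames(tagd[s, ], tag_ids), it)
      i <- match(.pair_key(dip$hap1, dip$hap2), keys)
      interaction[s] <- if (is.na(i)) it$baseline_weight else pw$weight[i]
      diplotype[s] <- paste(dip$hap1, dip$hap2, sep = "/")
      flagged[s] <- dip$flagged
    }
  }
  data.frame(sample_id = cohort$sample_ids,
             total = non_hla + hla_add + interaction,
             interaction = interaction,
             hla_additive = hla_add, non_hla = non_hla,
             n_missing = n_missing,
             diplotype = diplotype, flagged_diplotype = flagged,
             unreliable = n_missing > unreliable_frac * nrow(v),
             missing_policy = missing_policy,
             stringsAsFactors = FALSE)
}

#' Build a centile reference frame
#'
#' @param ref_scores reference score distribution (e.g. whole-cohort WGS
#'   scores, or European-ancestry WGS scores for cross-ancestry
#'   comparisons).
#' @param label frame label.
#' @return a `centile_frame`: sorted reference scores, mean, SD.
#' @export
centile_frame <- function(ref_scores, label = "reference") {
  ref_scores <- ref_scores[!is.na(ref_scores)]
  if (length(ref_scores) == 0) stop("empty reference")
  s <- stats::sd(ref_scores)
  if (!is.finite(s) || s == 0) stop("reference SD must be > 0")
  structure(list(label = label, sorted = sort(ref_scores),
                 mean = mean(ref_scores), sd = s),
            class = "centile_frame")
}

#' Standardise scores against a reference frame
#'
#' @param scores numeric vector.
#' @param frame a [centile_frame()].
#' @return `(scores - frame$mean) / frame$sd`.
#' @export
standardize_scores <- function(scores, frame) {
  (scores - frame$mean) / frame$sd
}

#' Centile of scores within a reference frame
#'
#' Mid-rank convention: `100 * (n_below + n_ties / 2) / n_ref`.
#'
#' @param scores numeric vector.
#' @param frame a [centile_frame()].
#' @return centiles in [0, 100].
#' @export
score_centile <- function(scores, frame) {
  sv <- frame$sorted
  below <- findInterval(scores, sv, left.open = TRUE)
  leq <- findInterval(scores, sv)
  100 * (below + 0.5 * (leq - below)) / length(sv)
}

#' Reference-quantile threshold for "at or above the qth centile"
#'
#' Type-7 linear-interpolation quantile of the reference distribution: a
#' score is at/above the qth centile iff it is `>=` this value.
#'
#' @param frame a [centile_frame()].
#' @param q centile in (0, 100).
#' @return scalar threshold.
#' @export
centile_threshold <- function(frame, q) {
  unname(stats::quantile(frame$sorted, q / 100, type = 7))
}
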