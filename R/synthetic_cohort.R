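#' @title Synthetic multi-ancestry cohort generator
#' @name synthetic_cohort
#' @description
#' Generates cohorts with known truth for end-to-end validation of the
#' scoring and concordance machinery: per-population allele frequencies
#' under a Balding-Nichols divergence model, true genotypes in
#' Hardy-Weinberg proportions, internally consistent DR-DQ haplotype pairs
#' driving the interaction tag variants, a WGS observation model with
#' per-call depth/quality/allelic-balance, imputed-dosage observation
#' models with calibrated accuracy, and liability-model case labels.
NULL

#' Define a population structure model
#'
#' @param populations data.frame with columns `label`, `proportion`
#'   (summing to 1) and `fst` (per-population divergence from the shared
#'   ancestral pool, in (0,1)).
#' @param ancestral_freqs named numeric vector of ancestral ALT-allele
#'   frequencies per variant, all in (0,1).
#' @param ancestral_hap_freqs named numeric vector of ancestral DR-DQ
#'   haplotype frequencies (names are haplotype labels; the remainder to 1
#'   is the untagged `"other"` pool). May be `NULL` when the score has no
#'   interaction component.
#' @return a `population_model` object.
#' @export
population_model <- function(populations, ancestral_freqs,
                             ancestral_hap_freqs = NULL) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "proportion", "fst") %in% names(populations)))
  if (abs(sum(populations$proportion) - 1) > 1e-8)
    stop("population proportions must sum to 1")
  if (any(populations$fst <= 0 | populations$fst >= 1))
    stop("fst must lie strictly inside (0,1)")
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral allele frequencies must lie strictly inside (0,1)")
  if (!is.null(ancestral_hap_freqs)) {
    if (any(ancestral_hap_freqs <= 0) || sum(ancestral_hap_freqs) >= 1)
      stop("ancestral haplotype frequencies must be positive and sum to < 1 (remainder is 'other')")
  }
  structure(list(populations = populations,
                 ancestral_freqs = ancestral_freqs,
                 ancestral_hap_freqs = ancestral_hap_freqs),
            class = "population_model")
}

#' The study's default population mix
#'
#' Four super-populations at the proportions of the cohort the analysis
#' emulates: EUR 92.4\%, AFR 1.6\%, SAS 2.2\%, OTH 3.8\%. Divergence from
#' the shared ancestral pool is smallest for EUR (the reference panels and
#' the score's discovery data are European-centric) and largest for AFR.
#'
#' @return data.frame of labels, proportions and fst values.
#' @export
default_population_mix <- function() {
  data.frame(label = c("EUR", "AFR", "SAS", "OTH"),
             proportion = c(0.924, 0.016, 0.022, 0.038),
             fst = c(0.005, 0.12, 0.06, 0.08),
             stringsAsFactors = FALSE)
}

# floor keeping drawn frequencies away from fixation
.FREQ_EPS <- 1e-4

#' Draw per-population allele frequencies (Balding-Nichols)
#'
#' Each population's frequency for a variant with ancestral frequency `p`
#' and divergence `F` is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), whose
#' mean is `p` and variance `F p (1-p)`. Draws are clamped to
#' `[1e-4, 1 - 1e-4]` so no variant fixes.
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @return matrix populations x variants of ALT-allele frequencies, with
#'   dimnames from the model.
#' @export
draw_population_frequencies <- function(model, seed = 1L) {
  local_rng(seed)
  pops <- model$populations
  p <- model$ancestral_freqs
  out <- matrix(NA_real_, nrow(pops), length(p),
                dimnames = list(pops$label, names(p)))
  for (i in seq_len(nrow(pops))) {
    f <- pops$fst[i]
    scale <- (1 - f) / f
    out[i, ] <- stats::rbeta(length(p), p * scale, (1 - p) * scale)
  }
  pmin(pmax(out, .FREQ_EPS), 1 - .FREQ_EPS)
}

#' Draw per-population DR-DQ haplotype frequencies
#'
#' Dirichlet generalisation of the Balding-Nichols draw: population
#' haplotype frequencies ~ Dirichlet(h (1-F)/F) with `h` the ancestral
#' haplotype frequency vector (tagged haplotypes plus the `"other"` pool).
#'
#' @param model a [population_model()] with `ancestral_hap_freqs`.
#' @param seed integer seed.
#' @return matrix populations x (haplotypes + "other"), rows summing to 1.
#' @export
draw_haplotype_frequencies <- function(model, seed = 1L) {
  if (is.null(model$ancestral_hap_freqs))
    stop("population model has no ancestral haplotype frequencies")
  local_rng(seed)
  h <- c(model$ancestral_hap_freqs,
         other = 1 - sum(model$ancestral_hap_freqs))
  pops <- model$populations
  out <- matrix(NA_real_, nrow(pops), length(h),
                dimnames = list(pops$label, names(h)))
  for (i in seq_len(nrow(pops))) {
    alpha <- h * (1 - pops$fst[i]) / pops$fst[i]
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g <- pmax(g, 1e-12)
    out[i, ] <- g / sum(g)
  }
  out
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' Each sample's ALT-allele count at each variant is Binomial(2, p) with
#' `p` its population's frequency; variants are independent (linkage
#' equilibrium -- DR-DQ tag variants are instead generated from haplotype
#' pairs, see [simulate_cohort()]).
#'
#' @param freqs populations x variants frequency matrix
#'   (from [draw_population_frequencies()]).
#' @param ancestry_labels character vector, one population label per sample.
#' @param seed integer seed.
#' @return integer matrix samples x variants of ALT-allele counts in 0..2.
#' @export
simulate_true_genotypes <- function(freqs, ancestry_labels, seed = 1L) {
  local_rng(seed)
  unknown <- setdiff(unique(ancestry_labels), rownames(freqs))
  if (length(unknown) > 0)
    stop("no frequencies for population(s): ", paste(unknown, collapse = ", "))
  pmat <- freqs[ancestry_labels, , drop = FALSE]
  g <- matrix(stats::rbinom(length(pmat), 2L, pmat), nrow(pmat), ncol(pmat))
  dimnames(g) <- list(NULL, colnames(freqs))
  g
}

#' Define a platform observation-error model
#'
#' @param platform_label e.g. `"WGS"`, `"panelA"`, `"panelB"`.
#' @param r2 target squared correlation between imputed dosage and truth,
#'   either a single value recycled over variants or a named per-variant
#'   vector; values in (0,1]. Ignored for WGS models.
#' @param maf_dependence >= 0; noise inflation factor
#'   `1 + maf_dependence * (0.05 / maf - 1)` applied below MAF 5\%
#'   (rare variants impute worse).
#' @param ancestry_bias named numeric >= 1 per population; multiplies the
#'   noise-variance ratio for under-represented ancestries.
#' @param mean_depth WGS only: mean sequencing depth (Poisson).
#' @param genotype_error_rate WGS only: probability a call differs from
#'   truth.
#' @return a `platform_error_model` object.
#' @export
platform_error_model <- function(platform_label, r2 = 1,
                                 maf_dependence = 0,
                                 ancestry_bias = NULL,
                                 mean_depth = NA_real_,
                                 genotype_error_rate = 0) {
  if (any(r2 <= 0 | r2 > 1)) stop("r2 must lie in (0, 1]")
  if (maf_dependence < 0) stop("maf_dependence must be >= 0")
  if (!is.null(ancestry_bias) && any(ancestry_bias < 1))
    stop("ancestry_bias multipliers must be >= 1")
  structure(list(platform_label = platform_label, r2 = r2,
                 maf_dependence = maf_dependence,
                 ancestry_bias = ancestry_bias,
                 mean_depth = mean_depth,
                 genotype_error_rate = genotype_error_rate),
            class = "platform_error_model")
}

#' Built-in platform presets
#'
#' `"WGS"`: 30x mean depth, 2e-4 genotype error. `"panelA-1000G"`: the
#' older, European-heavy imputation panel -- r2 0.95, strong MAF
#' dependence, noise inflated 3x for AFR and 2x for SAS/OTH.
#' `"panelB-TOPMed"`: the larger, more diverse panel -- r2 0.99, milder
#' MAF dependence, 1.5x/1.2x ancestry inflation. The presets are chosen to
#' reproduce the qualitative ordering of platform concordance (panel B
#' closer to WGS everywhere, with the largest gap for non-European
#' ancestries), not any particular cohort's numbers.
#'
#' @param name preset name.
#' @return a [platform_error_model()].
#' @export
platform_preset <- function(name = c("WGS", "panelA-1000G", "panelB-TOPMed")) {
  name <- match.arg(name)
  switch(name,
    "WGS" = platform_error_model("WGS", mean_depth = 30,
                                 genotype_error_rate = 2e-4),
    "panelA-1000G" = platform_error_model(
      "panelA", r2 = 0.95, maf_dependence = 0.5,
      ancestry_bias = c(EUR = 1, AFR = 3, SAS = 2, OTH = 2)),
    "panelB-TOPMed" = platform_error_model(
      "panelB", r2 = 0.99, maf_dependence = 0.2,
      ancestry_bias = c(EUR = 1, AFR = 1.5, SAS = 1.2, OTH = 1.2)))
}

#' Simulate WGS-style genotype calls
#'
#' Per call: depth `DP ~ Poisson(mean_depth)`; ALT-read count
#' `~ Binomial(DP, a)` with `a = 0.5` for true heterozygotes and a 0.5\%
#' sequencing-error rate for homozygotes; the emitted genotype equals the
#' truth except with probability `genotype_error_rate`, when it flips to
#' one of the other two genotypes; `GQ` is a saturating function of depth,
#' `round(99 (1 - exp(-DP/8)))` plus Normal(0,3) jitter, clamped to 0..99.
#' Calls with `DP = 0` are emitted as missing with undefined VAF.
#'
#' @param true_genotypes samples x variants ALT-count matrix.
#' @param model a WGS-type [platform_error_model()] (`mean_depth` set).
#' @param seed integer seed.
#' @param sample_ids optional sample identifiers.
#' @return a `wgs_calls` data.frame: `sample_id`, `variant_id`, `gt`
#'   (ALT-allele count, NA when missing), `dp`, `gq`, `ad_ref`, `ad_alt`,
#'   `vaf`, `platform`.
#' @export
simulate_wgs_observations <- function(true_genotypes, model, seed = 1L,
                                      sample_ids = NULL) {
  if (!is.finite(model$mean_depth) || model$mean_depth <= 0)
    stop("WGS observation model needs mean_depth > 0")
  local_rng(seed)
  n <- nrow(true_genotypes); m <- ncol(true_genotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  g <- as.integer(true_genotypes)
  nc <- length(g)
  dp <- stats::rpois(nc, model$mean_depth)
  err <- 0.005  # per-read sequencing error
  palt <- ifelse(g == 1L, 0.5, ifelse(g == 0L, err, 1 - err))
  ad_alt <- stats::rbinom(nc, dp, palt)
  flip <- stats::runif(nc) < model$genotype_error_rate
  called <- g
  if (any(flip)) {
    shift <- 1L + (stats::runif(sum(flip)) < 0.5)  # one of the two other genotypes
    called[flip] <- (g[flip] + shift) %% 3L
  }
  gq <- round(99 * (1 - exp(-dp / 8)) + stats::rnorm(nc, 0, 3))
  gq <- pmin(pmax(gq, 0L), 99L)
  missing <- dp == 0L
  called[missing] <- NA_integer_
  vaf <- ifelse(dp > 0, ad_alt / dp, NA_real_)
  out <- data.frame(
    sample_id = rep(sample_ids, times = m),
    variant_id = rep(colnames(true_genotypes), each = n),
    gt = called, dp = dp, gq = as.integer(gq),
    ad_ref = dp - ad_alt, ad_alt = ad_alt, vaf = vaf,
    platform = model$platform_label,
    stringsAsFactors = FALSE)
  class(out) <- c("wgs_calls", "data.frame")
  out
}

# Moments of a Normal(mu, sd) clipped (Winsorised) to [lo, hi].
.clipped_norm_moments <- function(mu, sd, lo = 0, hi = 2) {
  if (sd <= 0) return(c(mean = min(max(mu, lo), hi), m2 = min(max(mu, lo), hi)^2))
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  pin <- Fb - Fa
  m_in <- if (pin > 0) mu - sd * (fb - fa) / pin else 0
  m2_in <- if (pin > 0) mu^2 + sd^2 - sd * ((hi + mu) * fb - (lo + mu) * fa) / pin else 0
  mean_ <- lo * Fa + hi * (1 - Fb) + pin * m_in
  m2 <- lo^2 * Fa + hi^2 * (1 - Fb) + pin * m2_in
  c(mean = mean_, m2 = m2)
}

# Squared correlation between truth g ~ Binom(2, p) and clip(g + N(0, sd), 0, 2).
.clipped_corr2 <- function(sd, p) {
  pg <- stats::dbinom(0:2, 2, p)
  mm <- vapply(0:2, function(g) .clipped_norm_moments(g, sd), numeric(2))
  ed <- sum(pg * mm["mean", ]); ed2 <- sum(pg * mm["m2", ])
  eg <- 2 * p; vg <- 2 * p * (1 - p)
  cov <- sum(pg * (0:2) * mm["mean", ]) - eg * ed
  vd <- ed2 - ed^2
  if (vd <= 0 || vg <= 0) return(0)
  cov^2 / (vd * vg)
}

# Noise SD whose clipped-dosage corr^2 with truth equals target (bisection).
.solve_noise_sd <- function(target_r2, p) {
  if (target_r2 >= 1) return(0)
  lo <- 0; hi <- 4
  while (.clipped_corr2(hi, p) > target_r2 && hi < 64) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.clipped_corr2(mid, p) > target_r2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate imputed-array dosages
#'
#' Dosage = truth + Gaussian noise, clipped to [0, 2]. The noise SD is
#' solved per variant and population (closed-form clipped-normal moments,
#' bisection) so that the squared correlation between dosage and truth
#' equals the model's effective accuracy target
#' `r2_eff = r2 / (r2 + lambda (1 - r2))`, where the noise inflation
#' `lambda = ancestry_bias[pop] * (1 + maf_dependence * max(0, 0.05/maf - 1))`
#' is 1 for a well-represented population at common MAF (so the configured
#' `r2` is hit exactly) and grows for under-represented ancestries and
#' rare variants.
#'
#' @param true_genotypes samples x variants ALT-count matrix.
#' @param model an imputed-type [platform_error_model()].
#' @param freqs populations x variants ALT-frequency matrix used to
#'   calibrate the noise.
#' @param ancestry_labels population label per sample.
#' @param seed integer seed.
#' @param sample_ids optional sample identifiers.
#' @return a [cohort_genotypes()] object with fractional dosages counting
#'   the ALT allele.
#' @export
simulate_imputed_observations <- function(true_genotypes, model, freqs,
                                          ancestry_labels, seed = 1L,
                                          sample_ids = NULL) {
  local_rng(seed)
  n <- nrow(true_genotypes); m <- ncol(true_genotypes)
  vids <- colnames(true_genotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  r2 <- model$r2
  if (length(r2) == 1L) r2 <- stats::setNames(rep(r2, m), vids)
  if (!all(vids %in% names(r2)))
    stop("per-variant r2 missing for some variants")
  pops <- rownames(freqs)
  dos <- matrix(NA_real_, n, m, dimnames = list(NULL, vids))
  for (pop in intersect(pops, unique(ancestry_labels))) {
    rows <- which(ancestry_labels == pop)
    bias <- 1
    if (!is.null(model$ancestry_bias) && pop %in% names(model$ancestry_bias))
      bias <- model$ancestry_bias[[pop]]
    for (j in seq_len(m)) {
      p <- freqs[pop, vids[j]]
      maf <- min(p, 1 - p)
      lambda <- bias * (1 + model$maf_dependence * max(0, 0.05 / max(maf, 1e-6) - 1))
      r2_eff <- r2[[vids[j]]] / (r2[[vids[j]]] + lambda * (1 - r2[[vids[j]]]))
      sd_j <- .solve_noise_sd(r2_eff, p)
      g <- true_genotypes[rows, j]
      dos[rows, j] <- if (sd_j == 0) as.numeric(g) else
        pmin(pmax(g + stats::rnorm(length(g), 0, sd_j), 0), 2)
    }
  }
  cohort_genotypes(platform = model$platform_label,
                   sample_ids = sample_ids, variant_ids = vids,
                   dosage = dos, counted_allele = rep("alt", m),
                   r2_target = unname(r2[vids]))
}

#' Simulate case labels from scores (calibrated liability model)
#'
#' Each sample's case probability is `plogis(a + b z)` with `z` its
#' standardised score. The slope `b` is found by bisection so that the
#' expected ROC AUC over the supplied score vector equals
#' `liability_auc_target`; for each candidate slope the intercept `a` is
#' solved (monotone root) so the expected prevalence matches `prevalence`.
#' The expected AUC is computed exactly from the per-sample probabilities
#' (all-pairs comparison via cumulative sums, ties counted half).
#'
#' @param scores numeric vector of risk scores.
#' @param prevalence target case fraction in (0,1).
#' @param liability_auc_target target AUC in (0.5, 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return integer 0/1 vector of case labels.
#' @export
simulate_case_status <- function(scores, prevalence, liability_auc_target,
                                 seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (liability_auc_target < 0.5 || liability_auc_target >= 1)
    stop("liability_auc_target must be in [0.5, 1)")
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("scores have zero variance; AUC target unattainable")
  z <- (scores - mean(scores)) / s

  probs_for <- function(b) {
    f <- function(a) mean(stats::plogis(a + b * z)) - prevalence
    a <- stats::uniroot(f, c(-50, 50))$root
    stats::plogis(a + b * z)
  }
  expected_auc <- function(p) {
    o <- order(z)
    zs <- z[o]; ps <- p[o]
    # sum over pairs i>j (z_i > z_j) of p_i (1 - p_j), ties half
    grp <- cumsum(!duplicated(zs))
    sp <- tapply(ps, grp, sum); sq <- tapply(1 - ps, grp, sum)
    cum_q <- cumsum(sq) - sq       # strictly-below mass of (1-p)
    num <- sum(sp * cum_q) + 0.5 * sum(sp * sq - tapply(ps * (1 - ps), grp, sum))
    den <- sum(p) * sum(1 - p) - sum(p * (1 - p))
    num / den
  }
  if (liability_auc_target == 0.5) {
    probs <- rep(prevalence, length(z))
  } else {
    lo <- 0; hi <- 1
    while (expected_auc(probs_for(hi)) < liability_auc_target && hi < 64) hi <- hi * 2
    if (expected_auc(probs_for(hi)) < liability_auc_target)
      stop("AUC target unattainable for this score distribution")
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (expected_auc(probs_for(mid)) < liability_auc_target) lo <- mid else hi <- mid
    }
    probs <- probs_for((lo + hi) / 2)
  }
  local_rng(seed)
  as.integer(stats::runif(length(z)) < probs)
}

#' Simulate a complete multi-platform cohort
#'
#' Draws population frequencies (Balding-Nichols), true genotypes (HWE,
#' linkage equilibrium), per-sample DR-DQ haplotype pairs that determine
#' the interaction tag genotypes consistently, then observes the truth
#' through a WGS model and any number of imputed-platform models.
#'
#' @param config a [grs_config()].
#' @param n cohort size.
#' @param mix population mix data.frame (`label`, `proportion`, `fst`);
#'   default [default_population_mix()].
#' @param platforms named list of [platform_error_model()] objects;
#'   default: the three built-in presets.
#' @param seed integer master seed (stage seeds derive from it).
#' @param freq_range range for ancestral ALT frequencies, drawn uniformly.
#' @param shift_spec optional list `(pop, delta_sd, ref_pop)`: after the
#'   frequency draw, shift population `pop`'s non-HLA effect-allele
#'   frequencies so its expected score moves by `delta_sd` standard
#'   deviations of the `ref_pop` (default first label) score distribution
#'   (see [shift_population_frequencies()]).
#' @return a `simulated_cohort` list: `sample_ids`, `ancestry` (truth
#'   labels), `freqs`, `hap_freqs`, `true_genotypes` (ALT counts, tags
#'   included), `hap1`/`hap2` (true diplotypes), `observations` (named
#'   list: `wgs_calls` for WGS models, [cohort_genotypes()] for imputed),
#'   `config`, `model`.
#' @export
simulate_cohort <- function(config, n, mix = default_population_mix(),
                            platforms = list(
                              WGS = platform_preset("WGS"),
                              panelA = platform_preset("panelA-1000G"),
                              panelB = platform_preset("panelB-TOPMed")),
                            seed = 1L, freq_range = c(0.05, 0.95),
                            shift_spec = NULL) {
  local_rng(seed)
  v <- config$variants
  it <- config$interactions
  is_tag <- v$category == "HLA_INTERACTION_TAG"
  add_ids <- v$variant_id[!is_tag]

  anc <- stats::runif(length(add_ids), freq_range[1], freq_range[2])
  names(anc) <- add_ids
  hap_anc <- NULL
  if (!is.null(it) && length(it$haplotypes) > 0) {
    k <- length(it$haplotypes)
    raw <- stats::rgamma(k + 1, shape = c(rep(2, k), 3))
    hap_anc <- stats::setNames((raw / sum(raw))[seq_len(k)], it$haplotypes)
  }
  model <- population_model(mix, anc, hap_anc)

  sub_seed <- function(k) (as.integer(seed) * 131L + k) %% .Machine$integer.max
  ancestry <- sample(mix$label, n, replace = TRUE, prob = mix$proportion)
  freqs <- draw_population_frequencies(model, seed = sub_seed(1L))
  hap_freqs <- if (!is.null(hap_anc))
    draw_haplotype_frequencies(model, seed = sub_seed(3L)) else NULL

  if (!is.null(shift_spec)) {
    ref_pop <- shift_spec$ref_pop %||% mix$label[1]
    sd_ref <- expected_score_moments(
      config, freqs[ref_pop, ],
      if (!is.null(hap_freqs)) hap_freqs[ref_pop, ] else NULL)$sd
    freqs[shift_spec$pop, ] <- shift_population_frequencies(
      freqs[shift_spec$pop, ], config, shift_spec$delta_sd, sd_ref)
  }
  g_add <- simulate_true_genotypes(freqs, ancestry, seed = sub_seed(2L))

  hap1 <- hap2 <- NULL
  g_all <- matrix(0L, n, nrow(v), dimnames = list(NULL, v$variant_id))
  g_all[, add_ids] <- g_add
  if (!is.null(hap_anc)) {
    local_rng(sub_seed(4L))
    labels <- colnames(hap_freqs)
    draw_pair <- function(pop_rows, fr) {
      cbind(sample(labels, length(pop_rows), replace = TRUE, prob = fr),
            sample(labels, length(pop_rows), replace = TRUE, prob = fr))
    }
    hap1 <- hap2 <- character(n)
    for (pop in unique(ancestry)) {
      rows <- which(ancestry == pop)
      hp <- draw_pair(rows, hap_freqs[pop, ])
      hap1[rows] <- hp[, 1]; hap2[rows] <- hp[, 2]
    }
    # tag effect-allele count = haplotype copies; convert to ALT count
    for (h in it$haplotypes) {
      vid <- it$tag_map[[h]]
      copies <- (hap1 == h) + (hap2 == h)
      row <- v[v$variant_id == vid, ]
      g_all[, vid] <- if (row$effect_allele == row$alt) copies else 2L - copies
    }
    # extend the frequency matrix with implied tag ALT frequencies
    tag_f <- matrix(NA_real_, nrow(freqs), sum(is_tag),
                    dimnames = list(rownames(freqs), v$variant_id[is_tag]))
    for (h in it$haplotypes) {
      vid <- it$tag_map[[h]]
      row <- v[v$variant_id == vid, ]
      ef <- hap_freqs[, h]
      tag_f[, vid] <- if (row$effect_allele == row$alt) ef else 1 - ef
    }
    freqs <- cbind(freqs, pmin(pmax(tag_f, .FREQ_EPS), 1 - .FREQ_EPS))
  }
  freqs <- freqs[, v$variant_id, drop = FALSE]

  sample_ids <- sprintf("S%05d", seq_len(n))
  observations <- list()
  pk <- 10L
  for (nm in names(platforms)) {
    pm <- platforms[[nm]]
    pk <- pk + 1L
    observations[[nm]] <- if (is.finite(pm$mean_depth)) {
      simulate_wgs_observations(g_all, pm, seed = sub_seed(pk),
                                sample_ids = sample_ids)
    } else {
      simulate_imputed_observations(g_all, pm, freqs, ancestry,
                                    seed = sub_seed(pk),
                                    sample_ids = sample_ids)
    }
  }
  structure(list(sample_ids = sample_ids, ancestry = ancestry,
                 freqs = freqs, hap_freqs = hap_freqs,
                 true_genotypes = g_all, hap1 = hap1, hap2 = hap2,
                 observations = observations, config = config,
                 model = model, seed = seed),
            class = "simulated_cohort")
}

#' Analytic score moments under a population's frequencies
#'
#' Expected value and variance of the total score for a sample drawn from
#' one population: additive variants contribute `2 w q` to the mean and
#' `2 w^2 q (1-q)` to the variance (`q` = effect-allele frequency, HWE,
#' linkage equilibrium); the interaction component's moments are computed
#' exactly from the diplotype distribution implied by the haplotype
#' frequency vector.
#'
#' @param config a [grs_config()].
#' @param pop_freqs named ALT-frequency vector for the additive variants.
#' @param hap_freqs named haplotype frequency vector including `"other"`,
#'   or NULL for a score without interactions.
#' @return list with `mean` and `sd`.
#' @export
expected_score_moments <- function(config, pop_freqs, hap_freqs = NULL) {
  v <- config$variants
  add <- v[v$category != "HLA_INTERACTION_TAG", , drop = FALSE]
  q <- ifelse(add$effect_allele == add$alt,
              pop_freqs[add$variant_id], 1 - pop_freqs[add$variant_id])
  mu <- sum(2 * add$weight * q)
  va <- sum(2 * add$weight^2 * q * (1 - q))
  if (!is.null(config$interactions) && !is.null(hap_freqs)) {
    labs <- names(hap_freqs)
    wmat <- outer(labs, labs,
                  Vectorize(function(a, b) interaction_weight(config$interactions, a, b)))
    pmat <- outer(hap_freqs, hap_freqs)
    mu_i <- sum(pmat * wmat)
    va_i <- sum(pmat * wmat^2) - mu_i^2
    mu <- mu + mu_i; va <- va + va_i
  }
  list(mean = mu, sd = sqrt(va))
}

#' Shift a population's frequencies to move its mean score
#'
#' Perturbs the effect-allele frequencies of the NON-HLA additive variants
#' so the population's expected total score moves by `delta_sd` reference
#' standard deviations: per-variant shifts are proportional to the variant
#' weights (`dq_i = c w_i`, with `c` solved from
#' `sum(2 w_i dq_i) = delta_sd * sd_ref`) and clamped to keep frequencies
#' inside (eps, 1-eps), re-solving over the unclamped variants until the
#' target is met.
#'
#' @param pop_freqs named ALT-frequency vector (one population's row).
#' @param config a [grs_config()].
#' @param delta_sd target mean shift in units of `sd_ref`.
#' @param sd_ref the reference-frame score SD (e.g. from
#'   [expected_score_moments()] of the reference population).
#' @param eps frequency clamp.
#' @return the shifted ALT-frequency vector.
#' @export
shift_population_frequencies <- function(pop_freqs, config, delta_sd, sd_ref,
                                         eps = 0.01) {
  v <- config$variants
  idx <- which(v$category == "NON_HLA_ADDITIVE")
  if (length(idx) == 0) stop("no NON_HLA_ADDITIVE variants to shift")
  w <- v$weight[idx]
  ids <- v$variant_id[idx]
  sign_eff <- ifelse(v$effect_allele[idx] == v$alt[idx], 1, -1)
  q <- ifelse(sign_eff == 1, pop_freqs[ids], 1 - pop_freqs[ids])
  target <- delta_sd * sd_ref
  free <- rep(TRUE, length(idx))
  dq <- numeric(length(idx))
  for (iter in 1:50) {
    resid <- target - sum(2 * w * dq)
    if (abs(resid) < 1e-12 || !any(free)) break
    cc <- resid / (2 * sum(w[free]^2))
    prop <- dq
    prop[free] <- dq[free] + cc * w[free]
    newq <- pmin(pmax(q + prop, eps), 1 - eps)
    clamped <- free & (newq != q + prop)
    dq <- newq - q
    free <- free & !clamped
  }
  if (abs(target - sum(2 * w * dq)) > 1e-6 * max(1, abs(target)))
    warning("frequency clamping prevented reaching the full target shift")
  q_new <- q + dq
  out <- pop_freqs
  out[ids] <- ifelse(sign_eff == 1, q_new, 1 - q_new)
  out
}
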