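#' @title Ancestry assignment by reference-projected PCA and elastic-net classification
#' @name ancestry
#' @description
#' Mirrors the standard reference-projection workflow: principal
#' components are derived from a labelled reference panel (genotypes
#' centred by twice the allele frequency and scaled by the binomial SD),
#' target samples are projected onto those loadings, and a multinomial
#' elastic-net classifier over the first six PCs predicts super-population
#' membership. A sample is assigned only when its top predicted
#' probability strictly exceeds the threshold (default 0.95); otherwise it
#' is labelled `"OTH"`.
NULL

#' Fit a reference PCA
#'
#' SNP-wise standardisation: centre by `2p`, scale by `sqrt(2 p (1-p))`
#' with `p` the reference ALT-allele frequency. Constant SNPs are dropped
#' with a warning. Loadings are orthonormal; the sign of each component is
#' fixed by making its largest-magnitude loading positive.
#'
#' @param genotypes reference samples x SNPs ALT-count matrix.
#' @param k number of components (default 6).
#' @return list: `snp_ids`, `freqs`, `loadings` (SNP x k), `scores`
#'   (reference sample x k), `k`.
#' @export
fit_reference_pca <- function(genotypes, k = 6) {
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  v <- colMeans(genotypes^2, na.rm = TRUE) - (2 * p)^2
  keep <- p > 0 & p < 1 & v > 1e-12
  if (any(!keep)) {
    warning(sum(!keep), " constant SNP(s) dropped from reference PCA")
    genotypes <- genotypes[, keep, drop = FALSE]
    p <- p[keep]
  }
  if (nrow(genotypes) < k) stop("reference has fewer samples than components")
  x <- sweep(genotypes, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x, nu = 0, nv = min(dim(x)))
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) stop("k exceeds the rank of the standardized reference matrix")
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(l) sign(l[which.max(abs(l))]))
  loadings <- sweep(loadings, 2, flip, "*")
  rownames(loadings) <- colnames(genotypes)
  scores <- x %*% loadings
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(snp_ids = colnames(genotypes), freqs = p,
       loadings = loadings, scores = scores, k = k)
}

#' Project samples onto reference principal components
#'
#' Target genotypes are standardised with the *reference* frequencies and
#' multiplied by the reference loadings. Missing genotypes are
#' mean-substituted (standardised value 0), so an all-missing sample sits
#' at the origin.
#'
#' @param genotypes target samples x SNPs ALT-count matrix (columns named).
#' @param pca output of [fit_reference_pca()] (or an `ancestry_model`).
#' @return samples x k coordinate matrix.
#' @export
project_samples <- function(genotypes, pca) {
  avail <- intersect(pca$snp_ids, colnames(genotypes))
  if (length(avail) < 0.5 * length(pca$snp_ids))
    stop("fewer than 50% of model SNPs available in target data")
  g <- matrix(NA_real_, nrow(genotypes), length(pca$snp_ids),
              dimnames = list(NULL, pca$snp_ids))
  g[, avail] <- as.matrix(genotypes[, avail, drop = FALSE])
  p <- pca$freqs
  x <- sweep(g, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  x %*% pca$loadings
}

#' Fit the multinomial elastic-net ancestry classifier
#'
#' Cross-validated `glmnet` multinomial fit over the reference PC
#' coordinates; the penalty is chosen by `nfolds`-fold CV with a seeded,
#' stored fold assignment so the fit is reproducible. Coefficients are
#' extracted at `lambda.min` into a dense matrix so prediction needs only
#' this object.
#'
#' @param pcs reference samples x k PC coordinates.
#' @param labels reference population labels.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nfolds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return list: `classes`, `coef` ((k+1) x classes, intercept first),
#'   `alpha`, `lambda`, `foldid`.
#' @export
fit_ancestry_classifier <- function(pcs, labels, alpha = 0.5, nfolds = 5,
                                    seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least two reference classes")
  if (any(!is.finite(pcs))) stop("non-finite PC coordinates")
  local_rng(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = length(labels)))
  fit <- glmnet::cv.glmnet(as.matrix(pcs), factor(labels),
                           family = "multinomial", alpha = alpha,
                           foldid = foldid)
  cf <- stats::coef(fit, s = "lambda.min")
  classes <- names(cf)
  coef_mat <- vapply(cf, function(m) as.numeric(m), numeric(ncol(pcs) + 1))
  rownames(coef_mat) <- c("(Intercept)", colnames(pcs))
  list(classes = classes, coef = coef_mat, alpha = alpha,
       lambda = fit$lambda.min, foldid = foldid)
}

#' Class probabilities from the fitted classifier
#'
#' Softmax over the per-class linear predictors.
#'
#' @param classifier output of [fit_ancestry_classifier()].
#' @param pcs samples x k coordinates.
#' @return samples x classes probability matrix (rows sum to 1).
#' @export
predict_ancestry_prob <- function(classifier, pcs) {
  eta <- cbind(1, as.matrix(pcs)) %*% classifier$coef
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  probs <- ex / rowSums(ex)
  colnames(probs) <- classifier$classes
  probs
}

#' Assign labels from class probabilities
#'
#' Strict rule: the argmax class only when its probability *exceeds* the
#' threshold; otherwise `"OTH"` (unassigned/other).
#'
#' @param probs samples x classes probability matrix (rows sum to 1
#'   within 1e-6).
#' @param threshold assignment threshold (default 0.95).
#' @param other_label label for unassigned samples.
#' @return character vector of assigned labels.
#' @export
assign_ancestry <- function(probs, threshold = 0.95, other_label = "OTH") {
  probs <- rbind(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < -1e-9))
    stop("malformed probability matrix: rows must be probabilities summing to 1")
  top <- max.col(probs, ties.method = "first")
  p_top <- probs[cbind(seq_len(nrow(probs)), top)]
  ifelse(p_top > threshold, colnames(probs)[top], other_label)
}

#' Fit a complete ancestry model from a labelled reference panel
#'
#' @param ref_genotypes reference samples x SNPs ALT-count matrix.
#' @param ref_labels reference population labels.
#' @param k PCs to use (default 6).
#' @param threshold assignment threshold (default 0.95).
#' @param alpha,nfolds,seed passed to [fit_ancestry_classifier()].
#' @return an `ancestry_model`: the PCA, the classifier and the threshold.
#' @export
fit_ancestry_model <- function(ref_genotypes, ref_labels, k = 6,
                               threshold = 0.95, alpha = 0.5, nfolds = 5,
                               seed = 1L) {
  pca <- fit_reference_pca(ref_genotypes, k = k)
  clf <- fit_ancestry_classifier(pca$scores, ref_labels, alpha = alpha,
                                 nfolds = nfolds, seed = seed)
  structure(list(snp_ids = pca$snp_ids, freqs = pca$freqs,
                 loadings = pca$loadings, k = k,
                 classifier = clf, threshold = threshold),
            class = "ancestry_model")
}

#' Project, classify and assign ancestry for target samples
#'
#' @param model an `ancestry_model` from [fit_ancestry_model()].
#' @param genotypes target samples x SNPs ALT-count matrix.
#' @param sample_ids optional identifiers.
#' @return data.frame: `sample_id`, one probability column per class,
#'   `assigned`, plus the PC coordinates.
#' @export
assign_cohort_ancestry <- function(model, genotypes, sample_ids = NULL) {
  pcs <- project_samples(genotypes, model)
  probs <- predict_ancestry_prob(model$classifier, pcs)
  assigned <- assign_ancestry(probs, threshold = model$threshold)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(pcs)))
  out <- data.frame(sample_id = sample_ids, probs, assigned = assigned,
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(pcs))
}

#' Save / load an ancestry model as JSON
#'
#' @param model an `ancestry_model`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `ancestry_model` (load).
#' @export
save_ancestry_model <- function(model, path) {
  doc <- list(snp_ids = model$snp_ids, freqs = unname(model$freqs),
              loadings = model$loadings, k = model$k,
              classifier = list(classes = model$classifier$classes,
                                coef = model$classifier$coef,
                                alpha = model$classifier$alpha,
                                lambda = model$classifier$lambda),
              threshold = model$threshold)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ancestry_model
#' @export
read_ancestry_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  loadings <- matrix(unlist(doc$loadings), ncol = doc$k,
                     dimnames = list(doc$snp_ids, paste0("PC", seq_len(doc$k))))
  coef <- matrix(unlist(doc$classifier$coef),
                 ncol = length(doc$classifier$classes),
                 dimnames = list(c("(Intercept)", paste0("PC", seq_len(doc$k))),
                                 doc$classifier$classes))
  structure(list(snp_ids = doc$snp_ids,
                 freqs = stats::setNames(doc$freqs, doc$snp_ids),
                 loadings = loadings, k = doc$k,
                 classifier = list(classes = doc$classifier$classes,
                                   coef = coef, alpha = doc$classifier$alpha,
                                   lambda = doc$classifier$lambda),
                 threshold = doc$threshold),
            class = "ancestry_model")
}

#' Simulate an ancestry-informative SNP panel
#'
#' Convenience generator for ancestry tests: draws per-population
#' frequencies for `n_snps` unlinked SNPs under the Balding-Nichols model
#' and genotypes for `n_per_pop` samples per population.
#'
#' @param mix population mix data.frame (`label`, `proportion`, `fst`).
#' @param n_snps number of SNPs (default 500).
#' @param n_per_pop reference samples per population.
#' @param seed integer seed.
#' @return list: `genotypes`, `labels`, `freqs`, `model`.
#' @export
simulate_ancestry_panel <- function(mix, n_snps = 500, n_per_pop = 100,
                                    seed = 1L) {
  local_rng(seed)
  anc <- stats::runif(n_snps, 0.1, 0.9)
  names(anc) <- sprintf("snp%04d", seq_len(n_snps))
  model <- population_model(mix, anc)
  freqs <- draw_population_frequencies(model, seed = seed + 1L)
  labels <- rep(mix$label, each = n_per_pop)
  g <- simulate_true_genotypes(freqs, labels, seed = seed + 2L)
  list(genotypes = g, labels = labels, freqs = freqs, model = model)
}
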