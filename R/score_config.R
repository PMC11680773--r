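#' @title Score configuration: variants, weights and the HLA DR-DQ interaction table
#' @name score_config
#' @description
#' A `grs_config` object is the single in-memory definition of the risk
#' score: the additive variants with their effect alleles and log-odds
#' weights, and the DR-DQ interaction machinery (tag variants, one per
#' haplotype, plus a symmetric table of diplotype weights). Every
#' downstream stage -- simulation, QC, scoring -- is keyed on it.
NULL

.VARIANT_CATEGORIES <- c("NON_HLA_ADDITIVE", "HLA_ADDITIVE", "HLA_INTERACTION_TAG")

#' Construct a score configuration
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `effect_allele`, `weight` (log-odds), `category`
#'   (one of `NON_HLA_ADDITIVE`, `HLA_ADDITIVE`, `HLA_INTERACTION_TAG`).
#' @param interactions list with elements `haplotypes` (character),
#'   `tag_map` (named character: haplotype -> variant_id),
#'   `pair_weights` (data.frame `hap1`, `hap2`, `weight`; unordered pairs,
#'   self-pairs allowed, pairs involving `"other"` allowed) and
#'   `baseline_weight` (scalar; used when a diplotype pair is absent from
#'   the table).
#' @param name,version config identity strings.
#' @return A validated `grs_config` object.
#' @export
grs_config <- function(variants, interactions, name = "unnamed", version = "0") {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  cfg <- structure(
    list(variants = variants, interactions = interactions,
         name = name, version = version),
    class = "grs_config")
  validate_grs_config(cfg)
  cfg
}

#' Validate a score configuration
#'
#' Checks the structural invariants: unique variant ids, effect allele one of
#' ref/alt, finite weights, known categories, and a consistent interaction
#' table (one tag variant per haplotype, tags carry the
#' `HLA_INTERACTION_TAG` category, pair weights keyed on known haplotypes or
#' `"other"`).
#'
#' @param cfg a `grs_config`.
#' @return `cfg`, invisibly. Errors describe the offending entry.
#' @export
validate_grs_config <- function(cfg) {
  v <- cfg$variants
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "effect_allele",
           "weight", "category")
  miss <- setdiff(req, names(v))
  if (length(miss) > 0)
    stop("score config missing variant columns: ", paste(miss, collapse = ", "))
  dup <- v$variant_id[duplicated(v$variant_id)]
  if (length(dup) > 0)
    stop("duplicate variant_id in score config: ", paste(unique(dup), collapse = ", "))
  bad_cat <- setdiff(unique(v$category), .VARIANT_CATEGORIES)
  if (length(bad_cat) > 0)
    stop("unknown variant category: ", paste(bad_cat, collapse = ", "))
  ok_ea <- v$effect_allele == v$ref | v$effect_allele == v$alt
  if (!all(ok_ea))
    stop("effect allele not among ref/alt for: ",
         paste(v$variant_id[!ok_ea], collapse = ", "))
  if (!all(is.finite(v$weight)))
    stop("non-finite weight for: ",
         paste(v$variant_id[!is.finite(v$weight)], collapse = ", "))

  it <- cfg$interactions
  if (!is.null(it)) {
    haps <- it$haplotypes
    if (length(it$tag_map) != length(haps) ||
        !setequal(names(it$tag_map), haps))
      stop("interaction tag_map must name exactly one tag variant per haplotype")
    unknown <- setdiff(unname(it$tag_map), v$variant_id)
    if (length(unknown) > 0)
      stop("interaction tag variant not in config: ",
           paste(unknown, collapse = ", "))
    tag_cat <- v$category[match(unname(it$tag_map), v$variant_id)]
    if (!all(tag_cat == "HLA_INTERACTION_TAG"))
      stop("interaction tag variant without HLA_INTERACTION_TAG category: ",
           paste(unname(it$tag_map)[tag_cat != "HLA_INTERACTION_TAG"], collapse = ", "))
    extra_tags <- setdiff(v$variant_id[v$category == "HLA_INTERACTION_TAG"],
                          unname(it$tag_map))
    if (length(extra_tags) > 0)
      stop("HLA_INTERACTION_TAG variant not mapped to any haplotype: ",
           paste(extra_tags, collapse = ", "))
    pw <- it$pair_weights
    if (!all(c("hap1", "hap2", "weight") %in% names(pw)))
      stop("pair_weights needs columns hap1, hap2, weight")
    known <- c(haps, "other")
    bad <- !(pw$hap1 %in% known) | !(pw$hap2 %in% known)
    if (any(bad))
      stop("pair_weights references unknown haplotype: ",
           paste(unique(c(pw$hap1[bad], pw$hap2[bad])), collapse = ", "))
    if (!is.numeric(it$baseline_weight) || length(it$baseline_weight) != 1L)
      stop("baseline_weight must be a single number")
  }
  invisible(cfg)
}

#' @export
print.grs_config <- function(x, ...) {
  v <- x$variants
  cat(sprintf("grs_config '%s' (version %s)\n", x$name, x$version))
  cat(sprintf("  %d variants: %d non-HLA additive, %d HLA additive, %d HLA interaction tags\n",
              nrow(v),
              sum(v$category == "NON_HLA_ADDITIVE"),
              sum(v$category == "HLA_ADDITIVE"),
              sum(v$category == "HLA_INTERACTION_TAG")))
  if (!is.null(x$interactions))
    cat(sprintf("  %d tagged haplotypes, %d diplotype pair weights\n",
                length(x$interactions$haplotypes),
                nrow(x$interactions$pair_weights)))
  invisible(x)
}

.pair_key <- function(h1, h2) {
  paste(pmin(h1, h2), pmax(h1, h2), sep = "\r")
}

#' Look up the interaction weight for a diplotype
#'
#' The pair table is keyed on unordered pairs, so the order of `h1`/`h2`
#' never matters. Pairs absent from the table (including pairs involving
#' `"other"` when not listed) fall back to `baseline_weight`.
#'
#' @param interactions the `interactions` element of a `grs_config`.
#' @param h1,h2 haplotype labels (or `"other"`).
#' @return scalar weight.
#' @export
interaction_weight <- function(interactions, h1, h2) {
  pw <- interactions$pair_weights
  i <- match(.pair_key(h1, h2), .pair_key(pw$hap1, pw$hap2))
  if (is.na(i)) interactions$baseline_weight else pw$weight[i]
}

#' Read a score configuration from disk
#'
#' Two on-disk dialects load to identical `grs_config` objects:
#' \describe{
#'   \item{`"json"`}{a single JSON document with `name`, `version`,
#'     `variants` (array of records) and `interactions`.}
#'   \item{`"tsv"`}{a pair of tab-separated files: `path` is the variants
#'     table (columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'     `effect_allele`, `weight`, `category`, and for tag variants a
#'     `haplotype` column) and `interactions_path` the pair table
#'     (columns `hap1`, `hap2`, `weight`; a row with both haplotypes
#'     `"baseline"` carries the baseline weight).}
#' }
#'
#' @param path config file (JSON) or variants TSV.
#' @param format `"json"` or `"tsv"`.
#' @param interactions_path pair-weight TSV (TSV dialect only).
#' @return a validated `grs_config`.
#' @export
read_score_config <- function(path, format = c("json", "tsv"),
                              interactions_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("score config not found: ", path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    variants <- as.data.frame(doc$variants, stringsAsFactors = FALSE)
    it <- doc$interactions
    interactions <- if (is.null(it)) NULL else list(
      haplotypes = as.character(it$haplotypes),
      tag_map = unlist(it$tag_map),
      pair_weights = as.data.frame(it$pair_weights, stringsAsFactors = FALSE),
      baseline_weight = as.numeric(it$baseline_weight))
    grs_config(variants, interactions,
               name = doc$name %||% "unnamed",
               version = as.character(doc$version %||% "0"))
  } else {
    if (is.null(interactions_path))
      stop("TSV dialect needs interactions_path")
    v <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pos = "integer", chrom = "character"))
    pw <- utils::read.delim(interactions_path, stringsAsFactors = FALSE)
    base_row <- pw$hap1 == "baseline" & pw$hap2 == "baseline"
    baseline <- if (any(base_row)) pw$weight[base_row][1] else 0
    pw <- pw[!base_row, , drop = FALSE]
    tags <- v[v$category == "HLA_INTERACTION_TAG", , drop = FALSE]
    if (nrow(tags) > 0 && !"haplotype" %in% names(v))
      stop("variants TSV with tag variants needs a 'haplotype' column")
    interactions <- if (nrow(tags) == 0 && nrow(pw) == 0) NULL else list(
      haplotypes = tags$haplotype,
      tag_map = stats::setNames(tags$variant_id, tags$haplotype),
      pair_weights = pw[, c("hap1", "hap2", "weight")],
      baseline_weight = baseline)
    v$haplotype <- NULL
    grs_config(v, interactions,
               name = sub("\\.tsv$", "", basename(path)))
  }
}

#' Write a score configuration to disk
#'
#' Inverse of [read_score_config()]; both dialects round-trip.
#'
#' @param cfg a `grs_config`.
#' @param path output path (JSON file, or variants TSV for `"tsv"`).
#' @param format `"json"` or `"tsv"`.
#' @param interactions_path pair-weight TSV path (TSV dialect only).
#' @return `path`, invisibly.
#' @export
write_score_config <- function(cfg, path, format = c("json", "tsv"),
                               interactions_path = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(name = cfg$name, version = cfg$version,
                variants = cfg$variants,
                interactions = if (is.null(cfg$interactions)) NULL else list(
                  haplotypes = cfg$interactions$haplotypes,
                  tag_map = as.list(cfg$interactions$tag_map),
                  pair_weights = cfg$interactions$pair_weights,
                  baseline_weight = cfg$interactions$baseline_weight))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    if (is.null(interactions_path))
      stop("TSV dialect needs interactions_path")
    v <- cfg$variants
    it <- cfg$interactions
    v$haplotype <- NA_character_
    if (!is.null(it)) {
      i <- match(unname(it$tag_map), v$variant_id)
      v$haplotype[i] <- names(it$tag_map)
    }
    utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
    pw <- if (is.null(it)) data.frame(hap1 = character(), hap2 = character(),
                                      weight = numeric()) else
      rbind(it$pair_weights,
            data.frame(hap1 = "baseline", hap2 = "baseline",
                       weight = it$baseline_weight))
    utils::write.table(pw, interactions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Generate a toy score configuration
#'
#' Deterministic fixture generator for tests and simulations. Additive
#' weights are drawn Normal(0, 0.3) on the log-odds scale; diplotype pair
#' weights Normal(1, 0.8) for tagged pairs (DR-DQ diplotypes dominate
#' score variance in the real score), with all unordered pairs -- including
#' self-pairs and pairs with `"other"` -- populated. Variants are laid out
#' on alternating chromosomes with unique positions; tags sit on
#' chromosome 6 as the DR-DQ tags do.
#'
#' @param n_nonhla,n_hla_additive numbers of additive variants.
#' @param n_haplotypes number of tagged DR-DQ haplotypes (>= 2; each gets
#'   one tag variant).
#' @param seed integer seed; identical seeds give identical configs.
#' @return a validated `grs_config` with
#'   `n_nonhla + n_hla_additive + n_haplotypes` variants.
#' @export
make_toy_config <- function(n_nonhla, n_hla_additive, n_haplotypes, seed = 1L) {
  if (n_haplotypes < 2)
    stop("n_haplotypes must be >= 2: the diplotype interaction model is undefined otherwise")
  rng <- local_rng(seed)
  n_tag <- n_haplotypes
  n <- n_nonhla + n_hla_additive + n_tag
  cat_vec <- c(rep("NON_HLA_ADDITIVE", n_nonhla),
               rep("HLA_ADDITIVE", n_hla_additive),
               rep("HLA_INTERACTION_TAG", n_tag))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  effect <- ifelse(stats::runif(n) < 0.5, ref, alt)
  weight <- stats::rnorm(n, 0, 0.3)
  weight[cat_vec == "HLA_INTERACTION_TAG"] <- 0  # tags score via the pair table
  chrom <- ifelse(cat_vec == "NON_HLA_ADDITIVE",
                  as.character(1L + (seq_len(n) %% 22L)), "6")
  variants <- data.frame(
    variant_id = sprintf("rs%05d", seq_len(n) * 7L + seed %% 1000L),
    chrom = chrom,
    pos = 10000L + seq_len(n) * 150L,
    ref = ref, alt = alt, effect_allele = effect,
    weight = weight, category = cat_vec,
    stringsAsFactors = FALSE)
  haps <- sprintf("DRDQ%02d", seq_len(n_haplotypes))
  tag_ids <- variants$variant_id[cat_vec == "HLA_INTERACTION_TAG"]
  all_haps <- c(haps, "other")
  pairs <- which(upper.tri(matrix(0, length(all_haps), length(all_haps)),
                           diag = TRUE), arr.ind = TRUE)
  pw <- data.frame(hap1 = all_haps[pairs[, 1]], hap2 = all_haps[pairs[, 2]],
                   weight = stats::rnorm(nrow(pairs), 1, 0.8),
                   stringsAsFactors = FALSE)
  pw$weight[pw$hap1 == "other" & pw$hap2 == "other"] <- 0
  interactions <- list(haplotypes = haps,
                       tag_map = stats::setNames(tag_ids, haps),
                       pair_weights = pw, baseline_weight = 0)
  grs_config(variants, interactions,
             name = sprintf("toy-%d-%d-%d", n_nonhla, n_hla_additive, n_haplotypes),
             version = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded RNG scoped to one generator call: restores the caller's RNG state
# when the calling function exits, so library code never perturbs the
# session stream.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed))
    withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
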