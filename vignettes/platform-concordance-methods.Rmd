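---
title: "Methods: scoring, simulation and concordance models in grsconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, simulation and concordance models in grsconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Clinical use of the type 1 diabetes genetic risk score (T1DGRS) relies on
centile thresholds of a reference population: scores below the 50th
centile argue against T1D (and support monogenic-diabetes testing), and
scores at or above the 90th centile flag candidates for population
screening. The score can be computed from whole-genome sequencing (WGS)
calls or, far more cheaply, from array genotypes imputed against a
haplotype reference panel. Imputation error is not uniform: it grows for
rare variants and for ancestries under-represented in the panel, so the
same person can land on different sides of a clinical threshold depending
on the genotyping route. `grsconcord` implements the full analysis needed
to quantify this: score computation with the HLA DR-DQ interaction model,
WGS call-level quality control, reference-projected ancestry assignment,
and a statistics suite for cross-platform agreement — all driven by a
synthetic multi-ancestry cohort generator, because the population biobank
data such analyses are run on is access-restricted.

# The score model

The score is a config-driven weighted sum over three disjoint variant
sets:

$$\mathrm{GRS}_i \;=\; \underbrace{\sum_{v \in \text{non-HLA}} w_v d_{iv}}_{\text{non-HLA}}
\;+\; \underbrace{\sum_{v \in \text{HLA-additive}} w_v d_{iv}}_{\text{HLA additive}}
\;+\; \underbrace{W\!\big(h_{i1}, h_{i2}\big)}_{\text{DR-DQ interaction}}$$

where $d_{iv} \in [0,2]$ is sample $i$'s effect-allele dosage, $w_v$ the
per-variant weight in log-odds units (natural log of published odds
ratios; the log scale is what makes the accumulation additive), and
$W(\cdot,\cdot)$ a symmetric lookup over the *diplotype* — the unordered
pair of DR-DQ haplotypes — called from a set of tag variants, one per
haplotype. HLA DR-DQ risk is strongly non-additive in haplotype copies
(DR3/DR4 heterozygotes carry more risk than either homozygote), which is
why a pair table rather than per-haplotype weights is required, and why
self-pairs are ordinary keys of that table.

A full-scale configuration mirrors the published score's structure: 67
variants, of which 32 are non-HLA, 35 HLA, and 14 of the HLA variants are
interaction tags. The package does not ship the published weights — the
engine is config-driven and tests use structurally identical synthetic
configs (the shipped `synthetic_full_structure_config.json` fixture is
synthetic, as its name says). Configs load from a single JSON document or
a two-file TSV dialect (variants table + pair-weight table); both parse
to the same in-memory object, so there is exactly one source of truth.

## Diplotype calling

Published descriptions leave the tag-to-diplotype procedure
under-specified, so the package fixes an explicit deterministic rule:

* tag dosages are hard-called by rounding to the nearest integer, with
  ties at .5 rounded *down* — haplotype carriage is discrete, and an
  imputed tag near half a copy is genuinely ambiguous (such samples are
  flagged);
* the two carried haplotypes are the multiset top-2 by copy count; with
  fewer than two tagged copies the remaining slots are `"other"`;
* more than two total tagged copies is biologically inconsistent (the
  tags mark mutually exclusive haplotypes); the call is resolved by
  taking copies in configuration order and the sample is flagged rather
  than dropped.

## Missing data

WGS calls that fail QC become *missing dosages*, never sample
exclusions, so missing-data policy is defined in exactly one place: the
score engine. The default substitutes twice the effect-allele frequency
(mean-preserving); `zero` and `rescale` (drop-and-reweight) policies are
available as config switches and the applied policy is recorded in every
result row. Samples missing more than half the configured variants are
flagged unreliable.

# WGS call filters

Calls are retained when depth DP ≥ 10 and genotype quality GQ ≥ 20, and —
for heterozygous calls only — when the allelic balance (VAF, the fraction
of reads supporting the alternate allele) lies in the closed interval
[0.2, 0.8]. Thresholds are inclusive: the depth and quality rules are
written as "≥", and the VAF interval is resolved as closed for symmetry
with them. Calls with zero depth or no genotype are missing regardless of
thresholds. Variant matching against the config is by
chromosome/position/ref/alt (1-based, as in VCF), with rsID as a
warned-about fallback; multiallelic records are decomposed and only the
configured alternate allele is counted.

# Centiles and standardisation

Two reference frames are first-class: the *whole-cohort* WGS frame (used
for the re-categorisation tables) and the *European-ancestry* frame (used
for cross-ancestry comparisons, since the clinical thresholds in use were
derived in European populations). Standardised scores are
$(s - \bar{s}_\mathrm{ref})/\mathrm{SD}_\mathrm{ref}$. Centiles use the
mid-rank convention, and "at or above the $q$th centile" means at or
above the type-7 (linearly interpolated) $q$-quantile of the reference.
At reference sizes in the tens of thousands the quantile convention is
immaterial, but reproducibility requires fixing one. In the
re-categorisation tables each platform is classified against *its own*
score distribution — the clinical question is about centile categories,
not raw thresholds — though shared-frame classification is available by
passing explicit frames.

# The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed once
and are not tuning knobs.

**Population structure.** The default mix mirrors a large UK population
biobank: EUR 92.4%, AFR 1.6%, SAS 2.2%, OTH 3.8%. Per-population allele
frequencies diverge from a shared ancestral pool under the
Balding–Nichols model, $p_k \sim
\mathrm{Beta}\!\big(p\tfrac{1-F_k}{F_k}, (1-p)\tfrac{1-F_k}{F_k}\big)$,
which has mean $p$ and variance $F_k\,p(1-p)$; draws are clamped to
$[10^{-4}, 1-10^{-4}]$ so nothing fixes. Default divergences
($F$ = 0.005 EUR, 0.12 AFR, 0.06 SAS, 0.08 OTH) reflect that both the
score's discovery data and imputation panels are European-centric.
Haplotype frequency vectors use the Dirichlet generalisation of the same
model.

**Genotypes.** Additive variants are drawn independently in
Hardy–Weinberg proportions (linkage equilibrium). The DR-DQ tags are the
exception: each sample first draws two haplotype labels from its
population's haplotype frequencies, and tag genotypes are set from the
copies carried — so the interaction component always has an internally
consistent truth. Full LD simulation is deliberately out of scope.

**WGS observation model.** Depth is Poisson at the platform's mean
(default 30×); alternate-read counts are Binomial(DP, 0.5) for true
heterozygotes and Binomial(DP, 0.005) / (0.995) for homozygotes; calls
flip away from truth with a small genotype error rate (default
2 × 10⁻⁴); GQ is a saturating function of depth,
$\mathrm{round}(99(1-e^{-\mathrm{DP}/8}))$ with Normal(0, 3) jitter
clamped to 0–99 — real callers' GQ models are platform-specific and
undocumented here; only the filter's behaviour matters. Zero-depth events
emit missing calls with undefined VAF.

**Imputed observation model.** Dosage = truth + Gaussian noise clipped to
[0, 2]. Clipping shrinks and biases naive noise, so the noise SD is not
taken from the usual $\sigma^2 = \mathrm{Var}(g)(1-r^2)/r^2$ formula;
instead it is solved per variant and population by bisection against the
*closed-form* squared correlation between a Binomial(2, p) truth and its
clipped-normal observation (clipped-normal moments via Mills-ratio
algebra). This makes the realised corr²(dosage, truth) equal the
effective target
$r^2_\mathrm{eff} = r^2 / (r^2 + \lambda(1-r^2))$ with noise inflation
$\lambda = \mathrm{bias}_{\mathrm{pop}}\,(1 + m \cdot \max(0, 0.05/\mathrm{MAF} - 1))$,
so a well-represented population at common MAF realises the configured
$r^2$ exactly, and accuracy degrades monotonically for rare variants
(coefficient $m$) and under-represented ancestries (bias ≥ 1). The two
panel presets — `panelA-1000G` ($r^2$ 0.95, strong MAF dependence, 3×/2×
ancestry inflation) and `panelB-TOPMed` ($r^2$ 0.99, milder dependence,
1.5×/1.2×) — are chosen to reproduce the qualitative ordering of
published concordance results (the newer, more diverse panel closer to
WGS everywhere, largest gap in non-European ancestries), not any
cohort's exact numbers: no quantitative error model for either panel is
published. This is Gaussian-on-dosage phenomenology, not a
haplotype-mosaic imputation model; it reproduces attenuation and
frequency bias at desk scale but not LD-structured error.

**Case labels.** Case probability is logistic in the standardised score.
The slope is found by bisection so the *expected* ROC AUC over the
supplied scores (computed exactly from per-sample probabilities by an
all-pairs cumulative-sum identity, ties half) equals the target — 0.92 by
default, the published discrimination regime of the score; for each
candidate slope the intercept is solved so expected prevalence matches.
Unattainable targets error rather than silently saturating.

**What passing tests do not show.** The generator has no LD beyond the
tag-consistency device, no batch effects, no probe-level array artefacts,
no genuinely admixed individuals (except where tests construct them), and
Gaussian rather than mosaic imputation error. Agreement statistics on
synthetic cohorts validate the *machinery*; they are not estimates of any
real cohort's concordance.

# Ancestry assignment

Following the standard reference-projection recipe: reference genotypes
are standardised SNP-wise by $2p$ and $\sqrt{2p(1-p)}$, the top $k = 6$
principal components are extracted (loadings orthonormal; each
component's sign fixed by making its largest-magnitude loading positive),
target samples are projected with *reference* frequencies
(missing SNPs mean-substituted), and a multinomial elastic-net
classifier over the six PCs predicts super-population membership. A
sample is assigned only when its top probability *strictly* exceeds 0.95
("exceeded" is read as strict), else it is labelled `OTH`. The published
description does not state the elastic-net mixing parameter or penalty
grid; the defaults here (α = 0.5, 5-fold cross-validation with a seeded,
stored fold assignment) are documented choices, not claimed matches.
Simulated scenarios use 500–2,000 ancestry-informative SNPs distinct
from the score variants — a desk-scale stand-in for genome-wide data.

# Concordance statistics

* **Spearman correlation** with a seeded 1,000-rep percentile bootstrap
  CI by default; the Fisher-z approximation is offered but is inaccurate
  for ρ near 1, which is exactly this problem's regime.
* **Meng–Rosenthal–Rubin z-test** for two dependent correlations sharing
  a common variable:
  $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)\sqrt{(n-3)/(2(1-r_{12})h)}$
  with $\bar{r}^2 = (r_1^2+r_2^2)/2$,
  $f = \min\{1, (1-r_{12})/(2(1-\bar{r}^2))\}$,
  $h = (1-f\bar{r}^2)/(1-\bar{r}^2)$; two-sided normal p. Antisymmetric
  in $(r_1, r_2)$ by construction.
* **Paired differences** via the two-sided paired t-test, reported in
  reference-frame SD units; differences that are floating-point constant
  are handled as the degenerate-variance case (p = 1 for a zero mean
  difference, NA otherwise, zero-width CI) rather than passed to a
  t-statistic.
* **Exact allele-frequency tests** per variant: two-sided Fisher exact p
  under the "probability at most that of the observed table" convention
  (computed from the hypergeometric mass with the standard 1 + 10⁻⁷
  relative guard against floating-point ties — the doubling convention
  exists but is not used), flagged at the Bonferroni level α/m with m the
  number of variants tested (0.05/67 = 7.46 × 10⁻⁴ at full scale; the
  exact value is used, not a rounded one).
* **Bland–Altman**: mean difference, 1.96-SD limits of agreement, and the
  proportional-bias slope from regressing differences on pairwise means.
* **Threshold concordance**: 2×2 below/at-or-above tables with row
  percentages kept raw (rounding only at presentation, round-half-even
  at the printed precision) and accuracy = concordant/total. One known
  published table row prints percentages inconsistent with its own
  counts; this package always reports the computed values.
* **ROC AUC** by the Mann–Whitney midrank formula (ties half), with a
  seeded 2,000-rep bootstrap CI by default.

# Problem sizes and numerical choices

The test suite and the acceptance script use: n = 10,000 for
noiseless-limit identities; n = 20,000 for the imputation-accuracy sweep
(r² ∈ {1.0, 0.99, 0.95, 0.9}) and the ancestry-shift analyses; 2,000
replicates of n = 500 for the null calibration of the dependent-
correlation test; all 245,025 2×2 tables with margins ≤ 30 for the exact-
test enumeration; 4 populations × 120 reference samples × 500 SNPs with
800 target samples for ancestry recovery; and n = 50,000 for the
AUC-calibration check. These sizes make every Monte-Carlo tolerance a
small multiple of its standard error while keeping a full run in tens of
seconds.

The shift-recovery analysis configures a −0.9 SD mean score shift (the
magnitude reported for African-ancestry individuals in the motivating
analysis) by perturbing non-HLA effect-allele frequencies proportionally
to variant weights, with the constant solved from
$\sum_v 2 w_v \Delta q_v = \delta \cdot \mathrm{SD}_\mathrm{ref}$ and
clamped iteratively to keep frequencies inside (0.01, 0.99); the
reference SD comes from closed-form score moments (additive HWE variance
plus the exact diplotype-distribution variance). The recovery scenario
uses two populations at F = 10⁻⁴ so the configured shift is the *only*
systematic difference between them — at realistic divergence the random
Balding–Nichols drift would add to the configured shift and the
"recovered" value would conflate the two.

Other fixed numerical choices: frequency clamp 10⁻⁴ in the generator and
0.01 in the shift solver; bisection to 60 iterations for the noise SD and
40 for the AUC slope; PCA rank tolerance 10⁻⁸ relative to the leading
singular value; probability-vector validation at 10⁻⁶.

# Known limitations

Imputation is emulated, never performed: no phasing, no reference
haplotypes, no LiftOver. Case labels come from the liability simulator,
not from clinical records. The diplotype-calling precedence rule is an
explicit stand-in for an unpublished procedure. The SD unit used for
paired differences is the whole-cohort WGS-score SD (the published choice
among WGS/per-method/pooled SDs is unstated). Published headline
correlations (0.9815 / 0.99555 and kin) derive from restricted data at
n ≈ 149,000 and are not reproduction targets; the package reproduces the
*worked contingency tables* exactly and the qualitative structure
(ordering, monotonicity, calibration) everywhere else.
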