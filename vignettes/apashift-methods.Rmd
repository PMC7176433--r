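---
title: "apashift: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apashift: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`apashift` quantifies alternative polyadenylation (APA) from 3'-end
sequencing reads and integrates the result with label-free proteomics.
This vignette is the package's own account of the statistics it
implements, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical decisions a
maintainer would want written down.

## 1. From reads to site counts

Each aligned read contributes one cleavage event at its transcriptional 3'
end — the rightmost aligned base for a "+" alignment, leftmost for "-"
(`orientation = "forward"`). The opposite convention is a flag, not an
inference: which aligned end marks the poly(A) junction depends on library
chemistry and aligner dialect, and guessing it silently is how strand bugs
happen. All coordinates are 0-based half-open internally; BED files
round-trip byte-exactly.

Events from **all samples are pooled** before clustering, so that the same
feature boundaries apply to every sample. Clustering is single linkage on
one contig and strand: positions at most `gap` nt apart (inclusive;
default 15) are linked, and each cluster becomes the feature
`[min, max + 1)`. Inclusive linkage is a documented choice — distance-based
merging tools treat "within 15 nt" inclusively. Merging is idempotent,
order-independent, and monotone in `gap` (property-tested).

Features are then intersected with an annotated poly(A)-site database
(1-bp records carrying gene ids). A feature keeps all its counts if it
overlaps one annotated site; if it overlaps several, each *event* goes to
its nearest annotated site, with ties to the transcript-5'-most site. This
resolution (the source protocol is silent on it) conserves counts exactly
and keeps annotated sites distinct. Features overlapping nothing are
dropped and counted. Within a gene the retained sites get a distal-first
index: site 1 is farthest along the direction of transcription.

## 2. Count filters

Three filters run in a fixed order, each idempotent and reproducible by a
brute-force predicate (the test suite checks exact agreement):

* **Support**: a site is kept iff in at least one condition the n-1
  best-covered samples have >= 5 reads and the remaining sample has >= 1
  (`min_major = 5`, `min_minor = 1`; the printed rule for n = 3,
  generalised as (n-1, remainder) for other n).
* **Minor usage**: a site is removed iff it holds < 10% of its gene's
  reads in *both* conditions. Shares are computed on condition-summed
  counts rather than per-sample means — at the low counts where this filter
  bites, per-sample ratios are unstable; sums are the robust reading of an
  ambiguous rule.
* **Expression**: a gene is kept iff its mean total count is >= 5 in both
  conditions. Genes left with a single site are untestable for APA and are
  routed to the expression arm only (reported via an attribute).

cpm uses the sample's total count over all retained sites as denominator
(the likely reading; a per-gene variant exists as an argument for
sensitivity analyses, and the proportion-based length score below makes
the within-gene normalisation explicit where it matters).

## 3. The Dirichlet-multinomial usage test

For one gene with NS sites, the site counts of sample j follow
DM(N_j, phi * pi), with pi the usage proportions of j's condition and phi a
precision: larger phi means closer to multinomial. The log-likelihood
omits the multinomial coefficient (it cancels in likelihood ratios); an
all-zero sample contributes exactly 0. The LRT compares one shared pi
(pooled) against per-condition pi at a common phi;
`lr = 2(l1 - l0) >= 0` by nesting, referred to chi-square with
`(C - 1)(NS - 1)` df, BH-adjusted across genes.

**Proportion fitting.** At fixed phi, proportions are fit by a
multiplicative fixed point, `pi_s <- pi_s * sum_j [psi(x_sj + phi pi_s) -
psi(phi pi_s)]` renormalised, which is stationary exactly at the
constrained MLE; a halving safeguard keeps the likelihood non-decreasing.
Convergence: likelihood improvement < 1e-8 or 200 iterations (fits that
hit the cap are flagged `converged = FALSE`, reported, never dropped).
Proportions are floored at 1e-12 so structural zeros keep the likelihood
finite; `lr` is floored at 0 against optimizer noise.

**Precision estimation is the load-bearing decision.** With 3 samples per
condition, per-gene precision estimates are too unstable for a calibrated
chi-square test, and the direction of failure depends on where phi is
profiled: under the full model the 2(NS-1) nuisance proportions bias phi
upward (anticonservative — simulated type-I error near 0.14 at nominal
0.05); under the pooled model a real usage shift is absorbed into phi
(calibrated but nearly powerless); even a per-gene Cox-Reid adjusted
estimate stays anticonservative (about 0.11), and an oracle handed the
true phi sits near 0.06 — there is no headroom for per-gene noise. The
package therefore estimates **one precision per dataset**, maximising the
summed Cox-Reid adjusted profile likelihood of the full model across genes
(`estimate_precision()`; bounded search on log phi in [log 1e-2, log 1e6]).
The Cox-Reid term is 0.5 log det of the observed information of the free
proportion parameters; zero-count sites carry no information and are
excluded from it, which also makes the statistic exactly invariant to
appending an all-zero site. In the generator's world a single phi is the
truth; on real data this assumes precision does not vary wildly across
genes. This is *not* the per-gene trended moderation of dedicated DM
packages — that machinery is out of scope — and `fit_dm()` still profiles
a per-gene phi when called standalone. Pass `precision =` to `lrt_apa()`
to override.

## 4. The weighted mRNA length score

Sites indexed distal-first get weights `W_i = 1 - (i - 1)/(NS - 1)` — for
NS = 3: 1, 0.5, 0 — and a sample's score is `sum_i W_i * cpm_i`. The
relative length change is mean(treated) - mean(control); negative means
shortening. The score is computed exactly as defined, i.e. on cpm and
**not normalised per gene**, so expression changes leak into it; this is
deliberate fidelity, and `length_scores(..., proportion = TRUE)` provides
the normalised variant (weights times within-gene usage fractions, range
[0, 1]) where a scale-free quantity is required. A gene is called
shortened/lengthened when BH-adjusted p < 0.05 with the corresponding
sign. `shortening_enrichment()` is the 1-df goodness-of-fit chi-square of
(n_short, n_long) against equal expectation, excluding (and counting)
exact-zero changes; with no significant genes it returns NA with a
warning rather than an error.

## 5. UGUA motif profiles

Per gene, the loss and gain sites are the argmin/argmax of mean treated
minus mean control cpm (ties to the more distal site, flagged when all
sites tie). Flanks are `[pos - 200, pos + 200]`, reverse-complemented for
"-" genes so negative offsets are always transcript-5'; windows crossing a
contig edge are dropped and counted. The "sliding window of five" is read
as a width-5 moving average over per-offset UGUA match-start indicator
frequencies (truncated at the ends; positions within 3 nt of the end
cannot start a match). Smoothing is a discrete Gaussian (sigma = 20,
truncated at 4 sigma, kernel normalised) with reflect padding — common
1-D filter defaults — which preserves the profile mean; a direct-sum
convolution oracle confirms it to 1e-10. Groups: shortened and lengthened
as in section 4, and non-targets as non-significant genes with
|length change| <= 0.05 **on the proportion scale** — the cpm scale has no
meaningful 0.05, since null sampling noise there is orders of magnitude
larger (`apa_pipeline()` emits `length_change_prop` for exactly this).

## 6. Proteome arm

Intensities are median-normalised per sample (target: grand median of the
pre-scaling sample medians), filtered to proteins quantified in every
sample of at least one condition, log2-transformed, and completed by
drawing each missing value from Normal(mean - 2 SD, 1 SD) of **all**
measured values (the literal global reading; a width factor of 1 is the
"constant scaling factor"). Imputation is seeded and never touches
measured cells.

The moderated t-test is the canonical empirical-Bayes formulation: pooled
two-sample variance s^2 with d = n1 + n2 - 2 df; prior (d0, s0^2) by
moments on log s^2 via digamma/trigamma inversion; posterior variance
`(d0 s0^2 + d s^2)/(d0 + d)`; t with d0 + d df; BH. d0 = Inf encodes "no
variance heterogeneity detected". The test suite pins this against the
reference limma fit (agreement to 1e-6) and against closed forms at pinned
priors; `prior =` lets callers fix (d0, s0^2).

The conditional battery: (1) shortening enrichment among all significant
APA genes; (2) 3-df goodness-of-fit of the four (length sign x protein
sign) quadrant counts against uniform; (3) 1-df test of protein direction
among shortened genes. Goodness-of-fit against uniform (not a 2x2
independence test) matches the "not evenly distributed" reading; genes
with exactly zero change are excluded and counted; empty inputs yield NA
with warnings.

## 7. Simplified differential expression

Gene counts are exact sums over the gene's annotated sites
(pre-APA-filter), genes below mean count 2 across all samples are dropped,
and the test is a deliberately *simplified* NB Wald stand-in:
median-of-ratios size factors (log-scale median, zero-geomean genes
skipped), per-gene method-of-moments dispersion on within-condition
residuals — reported per gene but **averaged across genes** for the Wald
variance, since a 4-df second moment per gene makes a normal-referenced
Wald either conservative (total-variance version: the SE co-moves with
the contrast) or liberal (per-gene within-condition version: t_4 tails) —
and a 0.5 pseudocount on condition means. No dispersion shrinkage toward
a trend, no outlier or independent filtering; the output column set
(baseMean, log2FoldChange, lfcSE, stat, pvalue, adj_pvalue) mirrors the
field's standard tool so downstream code ports, but results should not be
mistaken for it.

## 8. The synthetic world

`sim_config()` defaults state one fully-specified study; they were chosen
once, before the acceptance thresholds were measured, and are not dials:

| parameter | default | why |
|---|---|---|
| n_genes / n_target_genes | 200 / 40 | desk-scale; enough null genes for calibration checks |
| sites_per_gene_range | 1-4 | the observed range; ~half of APA genes have > 2 sites |
| n_per_condition | 3 | the study design (3 vs 3) |
| depth_per_sample | 300 reads/gene | the power analysis's stated depth |
| shift_magnitude | 0.2 | stated distal-to-proximal usage shift in targets |
| precision (phi) | 50 | no empirical dispersion is published; 50 gives visible but not pathological overdispersion at N = 300 |
| NB dispersion of totals | 0.05 | mild expression noise, keeps filters non-trivial |
| jitter | Laplace scale 2 nt, truncated +/-7 | cleavage imprecision; 7 + 7 < 15 makes 15-nt merge recovery of sites >= 40 nt apart a provable property, and site spacing is 60 nt |
| motif_offset | 40 nt | a CFIm-plausible upstream placement; 4 tandem UGUA on a background scrubbed of TGTA and TACA |
| proteome baseline | log2 ~ N(25, 2) | iBAQ-like scale |
| protein_slope / noise | 0.8 / 0.25 | clear but noisy protein response in targets |
| MNAR logistic | midpoint 21, steepness 1 | missingness concentrated ~2 SD below baseline mean |

Each artifact (reference, counts, read ends, proteome) draws from its own
stream derived from the master seed, so regenerating one artifact never
perturbs another. Identical configs regenerate byte-identical files.

The generator does **not** emulate: sequencing error, adapters or
alignment; internal priming and intronic artifacts; annotation errors or
missing sites; precision varying across genes; batch effects; peptide-level
proteomics structure. A green test therefore establishes algorithmic
correctness against a stated model, not robustness to those phenomena.

## 9. Known limitations

* The DM test shares one precision across genes; datasets with strongly
  gene-dependent overdispersion will be mis-calibrated at the extremes.
* The length score on cpm confounds expression and usage shifts — use the
  proportion variant when that matters.
* No de-novo site discovery: sites absent from the annotation are
  invisible, matching the source protocol's restriction to annotated
  sites.
* The NB expression test is a labelled stand-in, not a replacement for a
  full NB GLM package.
* Genome-build conversion (liftOver) of annotations is out of scope;
  inputs must share one build.
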