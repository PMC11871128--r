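---
title: "Methods: somatic L1 calling and multi-omic models in l1rt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic L1 calling and multi-omic models in l1rt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1rt)
```

## The problem

LINE-1 (L1) is the only autonomous human retrotransposon: an intact ~6 kb
element encodes ORF1p and ORF2p, and its RNA serves both as message and as
the template for new genomic copies via target-primed reverse transcription
(TPRT). In tumors, epigenetic derepression lets L1 mobilize somatically.
Detecting these events from short-read tumor/normal WGS is hard because the
genome already contains hundreds of thousands of highly similar L1 copies;
the usable signal is concentrated at the insertion breakpoints.

`l1rt` implements a clipped-read-first caller for somatic L1 insertions,
plus the downstream statistical machinery used to relate retrotransposition
burden to locus-level L1 expression, p53 status, and other recurrently
mutated genes. Because real cohort data are controlled-access, the package
also ships two first-class generators — a mechanistic insertion/read
simulator with an oracle aligner, and a synthetic multi-omic cohort
generator — so every component is testable end to end from code alone.

## Insertion mechanism and read signal

TPRT leaves a recognizable footprint that the simulator reproduces exactly
and the caller exploits:

* staggered endonuclease nicks duplicate a short **target site** (TSD) on
  both sides of the insertion;
* reverse transcription starts at the element 3' end and extends a variable
  distance 5'-ward, so most insertions are **5' truncated**; the inserted
  segment is always 3'-anchored on the consensus;
* **twin priming** (simultaneous priming on both genomic strands) yields an
  insertion whose 5'-ward fragment is inverted relative to the 3' fragment;
* a **poly(A)** tract sits at the element/genome junction (appearing as
  poly(T) 5'-ward on the top strand for minus-strand insertions);
* read-through transcripts carry unique genomic sequence downstream of the
  source element's 3' end — a **3' transduction** — which allows the new
  copy to be traced back to its source locus.

Fragments spanning a junction produce either a **soft-clipped read** (the
read itself crosses the breakpoint; the clipped tail is insertion sequence)
or a **discordant pair** (the mate falls inside the insertion and maps to an
L1 copy elsewhere or to the consensus). With 150 bp reads the clipped tail
is long enough to be realigned to the L1 consensus, which is why the caller
prefers clips over discordant pairs: the 5'-most consensus coordinate
reached by any tail gives the inserted length directly, and
opposite-orientation tails at the two junctions diagnose twin-priming
inversions. For an inversion, a single junction can only reveal the
second-priming position, so the inserted length is reported as unresolved
with a lower bound.

## The caller

`call_insertions()` chains the stages, each exported separately:

1. **Evidence extraction** (`extract_clips()`, `extract_discordant()`).
   Soft-clipped primaries yield tails directly; hard-clipped supplementary
   alignments have their tails reconstructed from the matching primary.
   Reads that are unpaired, duplicate-flagged, mapping-quality zero, or have
   inconsistent sequence/quality strings are ignored throughout, matching
   the QC metric filters.
2. **Clustering** (`cluster_evidence()`). Same-side clips within 50 bp
   merge; a left-side and right-side cluster at most `max_tsd` (30 bp)
   apart pair into one candidate, the offset being the TSD. Negative
   offsets (target-site deletions) are recorded as TSD 0 with a flag.
   Discordant anchors within a fragment length corroborate.
3. **Resolution** (`resolve_calls()`). Tails are stripped of their
   junction-proximal poly(A)/poly(T) tract (defaults: minimum 8 nt, purity
   0.8) and realigned to the consensus. Realignment tries a full-length
   (near-)exact string match first and falls back to Smith–Waterman local
   alignment (match +2, mismatch −2, gap open −4, gap extend −1); an
   alignment is accepted at score ≥ 0.6 × the maximum attainable and
   identity ≥ 0.85, with strand ties rejected as ambiguous. A cluster is
   called with ≥ 2 clips, or 1 clip plus ≥ 2 discordant anchors — the
   published description does not print its support thresholds, so these
   conservative defaults are explicit and configurable.
4. **Transduction attribution** (`attribute_transduction()`). The tail
   segment left over after poly-tract stripping and consensus matching
   (≥ 30 nt) is matched downstream of each registered source locus (up to
   10 kb past the 3' end, 5% mismatch tolerance). Candidate sources within
   1 kb of each other are merged into a grouped id. A segment that aligns
   to the consensus, or whose mapped interval midpoint falls inside
   annotated L1 sequence, is treated as L1-multimapping: the call is kept,
   the annotation dropped, and a flag set. The midpoint rule tolerates a
   few bases of overhang at the source 3' boundary, where genuine
   transductions begin.
5. **Somatic classification** (`classify_somatic()`). One qualifying clip
   or discordant anchor in the matched normal within 50 bp (clips) /
   800 bp (anchors) makes a call pseudo-germline; fewer than 5 normal reads
   over the locus leaves it unresolved; otherwise it is somatic.

`intersect_callsets()` implements the 50 bp same-sample matching rule used
to combine two call sets (greedy nearest-neighbour, each call matched at
most once, ties broken toward the lower coordinate), and
`inversion_rate_ci()` provides the exact (Clopper–Pearson) 99% binomial
interval used for inversion rates.

## The simulator and its oracle aligner

`build_reference()` embeds full-length consensus copies (each with a
recorded unique downstream flank) in a uniform-random genome;
`apply_insertions()` realises insertion specs mechanistically
(`[target site][inverted 5' fragment?][3'-anchored L1][transduction?]
[poly(A)][target site duplicate]`, reverse-complemented on the minus
strand); `simulate_reads()` draws fragments uniformly with
Normal(450, 60) lengths truncated at twice the 150 bp read length, constant
Q30 qualities, and uniform substitution errors. `oracle_align()` then emits
the alignment a correct local aligner would produce against the
*unmodified* reference, derived from the haplotype-to-reference coordinate
map rather than from sequence search: flank reads map unclipped,
junction-spanning reads map with soft clips exactly at the breakpoint,
insertion-interior reads map to the consensus contig or go unmapped with a
mapped mate, and proper-pair flags follow FR orientation and insert-size
(≤ 100 kb) rules.

What the simulator deliberately does **not** emulate: indel or PCR errors,
quality-score variation, duplicates (duplicate filtering is exercised on
hand-built records), mappability and low-complexity artifacts, alignment
ambiguity at repetitive junctions, and polymorphic (non-reference) source
loci. Passing the recovery benchmarks therefore demonstrates the
correctness of the calling logic under clean mapping geometry, not
robustness to real-aligner artifacts; the random (rather than L1-derived)
consensus makes tail realignment *harder* than reality in one respect
(no internal homology) and easier in another (no off-target hits).
Breakpoint tolerance in all truth comparisons is ±5 bp.

## The synthetic cohort generator

`simulate_cohort()` draws, per sample: a tumor type, a p53 alteration
indicator (per-type probabilities), an LFS flag among p53-mutant samples,
additional 0/1 gene mutations, RNA-seq intronic rate, and ten WGS quality
metrics. Locus RNA is log2-normal — baseline per locus, plus `alpha_true`
(default 1.0 log2 units, the scale of the p53-mutant vs wild-type RNA
difference) for p53-mutant samples, plus a tumor-type shift; locus TRT
counts are Poisson with rate `efficiency_i × run_on_i × RNA_i ×
exp(tau_prime_true × p53)`, so that OLS on log2 scales recovers the planted
effects; total RT burden adds a Poisson background (mean 5). Observed
values carry technical contamination: log2 RNA gains
`2 × (intronic − 0.2)`, total RT gains `0.02` per fold of tumor coverage —
the slopes the QC-adjustment step must remove. A 0.5 pseudocount is used
before any log2 of counts or TPM.

`simulate_p53_scenario()` provides the three generative hypotheses used to
test whether the mediation decomposition can tell regulation modes apart:
`expression_only` (p53 acts on transcription only), `rt_selection` (no
transcriptional effect, but wild-type p53 removes cells whose RT burden
exceeds a survival threshold, default 20 events; censored samples are
redrawn to preserve n, and only wild-type samples are ever censored), and
`dual` (both effects). Scenario cohorts draw p53 independently of tumor
type so that no type-confounded association masquerades as a p53 effect.

## QC adjustment

`adjust_rna()` regresses log2(TPM + 0.5) on RNA-seq intronic rate;
`adjust_rt()` regresses log2(count + 0.5) jointly on the ten WGS metrics
(read length, coverage, base quality, chimeric fraction, clipped-base
fraction, for tumor and paired normal); the residuals are the adjusted
estimates. The log2 transform must precede residualization — residuals can
be negative, so the reverse order is undefined. Residualization is
idempotent and invariant to affine rescaling of covariates; a constant
covariate degenerates to centering with a warning rather than an error.

## Locus-level models

* **Activity matrix and clustering** (`build_activity_matrix()`,
  `cluster_loci()`): per-tumor-type means of adjusted log2 RNA and TRT per
  locus, with global locus means weighting every type equally. Two
  average-linkage Euclidean dendrograms (RNA and TRT) are cut at half the
  tree height — the linkage, metric, and cut are unspecified in the source
  description and are exposed as arguments — and a third annotation flags
  loci with mean TRT below 0.0018. Loci sharing all three annotations form
  one final cluster.
* **Efficiency model** (`fit_efficiency_model()`): one OLS over all
  sample × locus observations with a per-locus RNA slope (the efficiency)
  and shared tumor-type/p53 coefficients. A constant p53 column is dropped
  from the design rather than inverted against.
* **Permutation background** (`efficiency_background()`): the locus label
  of each observation is permuted (each observation keeps its TRT/RNA pair)
  and the model refitted, default 1000 times; the pooled slopes form the
  empirical null and the per-permutation variances the null for efficiency
  heterogeneity.
* **Categorization** (`categorize_loci()`): one-sided empirical p in the
  observed direction with the (r+1)/(N+1) estimator (no zero p-values),
  Bonferroni-corrected across all loci treated as hypotheses (the source
  phrasing counts every locus as a possible hypothesis, which is the
  Bonferroni reading); non-significant values outside the background IQR
  are `slightly_high`/`slightly_low`, the rest `typical`.
* **Total-RT models** (`fit_total_rt_models()`): one simple OLS of total RT
  burden on each locus's RNA. The background resamples observations with
  replacement across any sample and locus and permutes the locus
  assignment of the RNA, so each background model sees pairs from the
  pooled cloud; this is what makes a genuinely driving locus stand out.
* **Cluster model** (`fit_cluster_model()`): multivariate OLS of total RT
  on per-cluster RNA sums (summed on the TPM scale, then log2 with the 0.5
  pseudocount), reporting coefficients with CIs and the observed-vs-fitted
  correlation.

## Mediation and cohort tests

`fit_mediation()` fits the five OLS equations relating RT burden, RNA, and
the 0/1 p53 indicator, and decomposes the total p53→RT effect τ into a
mediated part αβ′ (algebraically τ − τ′, an identity that holds to machine
precision on any input) and a direct part τ′, with mediated/unmediated
fractions αβ′/τ and τ′/τ. Coefficients are standardized; the default
multiplies by sd(predictor)/sd(outcome), which is invariant to affine
rescaling of every variable (including recoding the indicator {0,1}→{0,c}).
The quoted description of the standardization uses the reciprocal ratio,
which is not rescaling-invariant and is inconsistent with the magnitudes it
accompanies; it remains available as `standardization = "as-quoted"`, and
the fractions are ratios and identical under either choice. Percentile
bootstrap CIs (default 1000 resamples of samples with replacement) cover
the standardized effects and fractions. The "p53 mutation score" is the
binary altered/wild-type indicator; no continuous score is modeled.

`quintile_stratified_test()` splits samples into five equal RNA quintiles
and runs two-sided Mann–Whitney U tests of RT by p53 within each,
Bonferroni-corrected over the five tests. `lfs_bootstrap_compare()` draws
10,000 resamplings of non-LFS p53-mutant samples matched exactly to the LFS
tumor-type composition and compares bootstrap means with the true LFS set
by a two-sided t-test. `gene_stratified_tests()` runs the two-pass
Mann–Whitney family (all samples for every gene; then the non-TP53 genes
within p53 strata), Bonferroni-corrected within the full family, with a
pass requiring corrected p < 0.01 *and* an absolute median difference at
least as large as the endpoint's overall standard deviation.
`normal_rna_to_p53()` is the reverse-direction check: a linear probability
model of tumor p53 status on normal-tissue RNA with tumor type categorical,
dropping types with a uniform outcome.

## Numerical choices and conventions

* Coordinates are 0-based half-open internally (breakpoints, truth tables,
  BED); SAM/VCF outputs are 1-based. A call's position is the 1-based
  leftmost target-site coordinate; the TSD is the right-clip minus
  left-clip breakpoint offset.
* Clopper–Pearson intervals are computed by beta-quantile inversion of the
  binomial tails, with the k = 0 and k = n boundaries pinned to 0 and 1.
* Deep clusters realign at most 12 tails per side (the longest ones, which
  reach furthest into the element); support counts still use all evidence.
* Rank-deficient designs fall back to minimum-norm fits with a warning
  where the contract allows (QC adjustment, cluster model) and abort with
  the collinear column names where it does not (efficiency model).
* Base qualities in the simulator are constant Q30; the read filters are
  still exercised on hand-built records.

## Problem sizes used by the tests

The bundled checks run the caller on 200 mixed insertions (50% canonical
with truncations over 100–6000 nt, 35% inversions, 15% transduction-
bearing, TSDs 5–20 nt) at 30× coverage with 0.1% base error, and on an
error-free 50 germline + 50 tumor-only fixture for somatic labeling and
length inference; the statistical models run at 40 loci × 500 samples
(efficiency recovery), 200 permutation/resampling replicates at reduced
sample size (background calibration), and 100 mediation replicates at
n = 2000 with n = 3000 scenario-discrimination replicates, chosen so the
direct-effect test has adequate power at the planted effect size. The
parameter-recovery experiments hold the generative universe (locus
baselines, efficiencies, type shifts) fixed across replicates so that
bootstrap CIs are compared against a single well-defined truth, estimated
once at n = 100,000.

## Limitations

The caller is developed and validated against the bundled oracle-aligned
simulations; running it on real BAMs requires alignments whose clip and
supplementary conventions match bwa-mem-style output, and its default
support thresholds stand in for unpublished ones. Only L1 is modeled — no
Alu/SVA/ERV calling, no genotype likelihoods, no long-read support, and no
allele-frequency estimation beyond the pseudo-germline label. The cohort
generator makes no attempt to mimic empirical marginal distributions of any
real cohort; it exists to give the statistical models a ground truth.
Mediation assumes the usual no-unmeasured-confounding conditions and
integrates quantities that operate on different time scales (mutation
status, RNA at sampling, accumulated RT burden), so effect estimates on
real data should be read as associations decomposed, not causal effects
established.
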