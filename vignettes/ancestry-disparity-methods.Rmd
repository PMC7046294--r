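---
title: "Methods: ancestry-differential tumor genomics with ancestrydisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-differential tumor genomics with ancestrydisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestrydisp)
```

# Scope

`ancestrydisp` is a pipeline for asking whether tumor genomic and
transcriptomic features differ between genetic-ancestry groups in a cancer
cohort: supervised ancestry inference from genotypes, mutational-signature
refitting, the weighted genome instability index (wGII), a margin-preserving
permutation test for ancestry-differential recurrent focal copy-number
alterations, propensity-adjusted association statistics, a simplified
negative-binomial differential-expression stage, pre-ranked gene-set and
sample-set enrichment, and lncRNA locus annotation. A synthetic-data module
generates every input with planted ground truth, so each stage is validated
end to end without external downloads.

This vignette explains each model, its assumptions, the tunable parameters,
and the numerical decisions taken where the design was genuinely open.

# Supervised ancestry inference

## Reference-only principal components

`fit_reference_pca()` standardizes SNP dosages by the EIGENSTRAT
convention — center `2p`, scale `sqrt(2p(1-p))` with `p` the panel allele
frequency — and takes eigenvectors of the *reference panel only*. Study
samples are projected into that space by `project_samples()` and never
influence the axes, so cohort-specific structure (batch, relatedness)
cannot rotate the reference frame. Ten axes are retained by default,
mirroring the conventional top-ten output of reference PCA tools;
`n_axes` is configurable. Eigenvector sign is fixed by making each
loading's largest-magnitude entry positive, so results are reproducible
across BLAS implementations.

Missing dosages are mean-imputed at projection (a missing genotype
contributes exactly zero after centering). This is unbiased at the panel
centroid and requires no model; it attenuates coordinates of samples with
substantial missingness rather than displacing them. No LD pruning or MAF
filter is applied by default; the panel filter drops monomorphic SNPs and
SNPs above a missing-rate cap (5%).

## k-NN calls and the "other" rule

`classify_knn()` uses Euclidean distance on the retained axes with `k = 5`:
small, odd, robust to a single mislabeled reference neighbor, and
configurable. Exact vote ties are resolved by the nearest population
centroid and flagged. An optional rule calls a sample `other` when its
nearest-reference distance exceeds a chosen quantile of the panel's own
nearest-same-population-neighbor distances; it is off by default because
the cutoff is a policy choice, not an estimate.

## Supervised admixture fractions

`estimate_admixture()` maximizes the binomial likelihood of a sample's
dosages under the per-SNP mixture frequency `sum_a q_a f_{a,snp}`, with the
population frequencies `f` fixed at panel estimates, by EM on the
probability simplex from a uniform start. This is deliberately a
*supervised* estimator: it asks "what mixture of these reference
populations best explains this genome?", not "what populations exist?".
The EM log-likelihood is monotone; iteration stops when the mean
per-iteration improvement over a 10-iteration block falls below `tol`
(default `1e-8`), with the block evaluation chosen because the
log-likelihood is the only expensive quantity in an otherwise
matrix-multiply-only update. Samples still improving at the cap (default
5,000 iterations) are flagged, not dropped — in practice these are samples
at a vertex of the simplex, whose fraction estimates are stable long
before the likelihood stalls numerically. Duplicate reference populations
make the optimum non-unique; the estimator flags this degeneracy and
returns the symmetric solution.

# Mutational-signature refitting

Catalogs are 96-channel counts in substitution-major order (C>A, C>G, C>T,
T>A, T>C, T>G), flanks alphabetical, purine-reference records
reverse-complemented into the pyrimidine representation. The ordering is
fixed and stable across versions.

`refit_signatures()` fits the normalized spectrum onto candidate
signatures by non-negative least squares, normalizes the coefficients to
weights, then applies two rules: weights below `discard_below = 0.06` are
removed, and remaining signatures are pruned greedily — lowest weight
first — whenever refitting without a signature lowers the reconstruction
cosine similarity by at most `prune_gain = 0.02`. The greedy
lowest-weight-first order makes the procedure deterministic where the
removal order was otherwise unspecified. Raw surviving coefficients
(summing to at most ~1) and a renormalized view are both reported, along
with the final cosine similarity. The built-in `builtin_signatures()` set
is three clearly distinct synthetic spectra used by the tests and the
demo; any 96 x S signature TSV can be supplied instead.

# Copy-number analyses

## Scale

All copy-number computation happens on one scale: log2 ratio centered at
0. The `read_seg(scale = "absolute")` switch converts absolute copy
numbers (`log2(CN/2)`) on load. A single scale keeps the +/-0.25
binarization threshold, the 0.3 wGII deviation and the length-weighted
"ploidy" internally consistent.

## wGII

Per sample, ploidy is the length-weighted median segment value; each
chromosome's GII is the fraction of its *covered* length (the sum of
segment lengths, robust to uncovered telomeres) deviating from ploidy by
more than `deviation = 0.3`; wGII is the unweighted mean over the included
autosomes, so chromosome 21 counts as much as chromosome 1. Splitting any
segment into adjacent halves cannot change the score (refinement
invariance), which the tests assert on random profiles. Samples with more
than 2,000 segments are excluded first (`filter_hypersegmented()`;
exactly 2,000 is retained).

## The alteration matrix and the permutation test

For each focal region, `c_ij` is the overlap-length-weighted mean segment
value; `X_ij = 1` when an amplification region has `c_ij >= 0.25` or a
deletion region has `c_ij <= -0.25` (boundaries altered). Uncovered
regions count as unaltered, with a warning.

The association test conditions on both margins of `X`: each tumor's
alteration burden and each region's alteration frequency are held fixed,
separately within amplification columns and deletion columns, so a region
can only look ancestry-differential if its *placement* across tumors is
unusual — not because one group is globally more disrupted. The observed
statistic per region is the Wald Z of the alteration column in
`group ~ X_j + propensity`; the same model is refit on each permuted
matrix, and the two-sided empirical p is `(1 + #{|Z_null| >= |Z_obs|}) /
(n_null + 1)`, never exactly zero. BH q-values are computed across regions
and flagged at `q < 0.25` by default.

### Sampler design

The permutation engine is a checkerboard-swap Markov chain: a uniformly
proposed 2x2 submatrix is swapped when it equals `[[1,0],[0,1]]` or
`[[0,1],[1,0]]`. Three numerical decisions matter here.

* **Trial swaps, not forced swaps.** The chain counts *proposals*; a
  variant that re-proposes until a swap succeeds would transition with
  probability `1/#swappable(x)` and therefore over-visit states with few
  swappable submatrices. Counting proposals keeps the kernel symmetric and
  the stationary distribution exactly uniform over the fixed-margin class,
  which the test-suite verifies against complete enumeration of small
  classes.
* **Laziness.** Each proposal is skipped with probability 1/2, so the
  chain is aperiodic even on two-state classes where every proposal would
  succeed.
* **Calibrated thinning.** On sparse matrices almost all proposals fail,
  so a fixed proposal count per emission would produce near-identical
  consecutive matrices. Burn-in runs until `10 * (number of ones)` swaps
  have occurred and estimates the per-proposal success rate; emissions are
  then separated by a fixed proposal budget sized to deliver about
  `(number of ones)` swaps each. The budget is fixed after calibration, so
  the emission kernel is homogeneous. Matrices admitting no swap (e.g.
  all ones) are emitted unchanged with a degeneracy flag.

### What the q < 0.25 flag means under a global null

BH controls the false-discovery rate, not the probability of any
discovery: with m regions and uniform p-values, the chance that *some*
region reaches `q < 0.25` under a complete null is close to 0.25 (Simes'
identity), and the test-suite's null-calibration block documents exactly
this family-wise behavior. Users should read the flag as an FDR statement
across the flagged set, not as per-experiment type-I control.

# Covariate adjustment

Age (continuous, years) and tumor grade (ordinal categories coded by
integer rank) are collapsed into one propensity score — the fitted
probability of group membership from a logistic model — included as a
covariate in every downstream model, mirroring the
single-covariate-adjustment design rather than matching or weighting. The
score can be refit per molecular platform when sample sets differ. Perfect
separation falls back to a lightly ridge-penalized fit (`lambda = 0.01` on
non-intercept terms) and is flagged. Burden-style outcomes are
inverse-normal transformed (Blom 3/8 offset, ties averaged) before linear
modeling, making those tests invariant to monotone transforms of the raw
burden. Fisher's exact test reports the exact two-sided p together with
the sample odds ratio; the Haldane 0.5 correction applies to the odds
ratio and its interval only (never the p) when a cell is zero, and is
flagged.

# Differential expression

`nb_wald_de()` is an explicitly simplified stand-in for a full
shrinkage-based DE engine: median-of-ratios size factors, per-gene
negative-binomial GLM with `log(size factor)` offsets, per-gene
method-of-moments dispersion pooled within groups and floored at `1e-8`,
and a Wald test on the group coefficient. There is no dispersion
shrinkage, no fold-change shrinkage, and no independent filtering. The
omissions trade power at small n for transparency; the null-calibration
and planted-truth tests define exactly what the stand-in delivers (at
n = 40 + 40, dispersion 0.05: uniform null p, sensitivity above 0.8 and
empirical FDR below 0.15 for 2-fold changes at q < 0.1). Any external DE
result table with the same columns can be substituted downstream. Both
propensity-adjusted and unadjusted runs are emitted by the pipeline along
with their intersection. Paired tumor/normal designs reuse the same
machinery with tissue as the design variable; pairing is not modeled.

# Enrichment

`preranked_gsea()` ranks by the supplied metric (descending, ties broken
deterministically by id), walks the list with hit increments proportional
to `|metric|^weight` (default weight 1; weight 0 is the classical
Kolmogorov-Smirnov-style statistic) and uniform miss decrements, and takes
the extremum as ES. The null is random member sets of the same size
(the pre-ranked convention); NES normalizes by the mean `|null ES|` of
matching sign, and the permutation p is the sign-matched one-sided
fraction with add-one smoothing — a sign-conditional p doubled would pile
half its null mass at 1 and lose uniformity. BH is applied across sets,
a deliberate divergence from tools that report their own permutation FDR.

SSEA applies the identical walk to samples ranked by one gene's
expression, one analysis per cancer-type sample set; `fractional_ranks()`
converts within-type NES values to `(0, 1]` percentiles (ascending rank /
n, ties averaged), so 0.95 means the top 5th percentile.

`category_enrichment()` crosses DEG status at each FDR level (0.1, 0.01,
0.001) with a gene category by Fisher's exact test;
`gwas_proximity_genes()` flags genes within 1 Mb of risk SNPs, boundary
inclusive.

# lncRNA annotation

Locus classes follow the hierarchy `exonic > intronic > antisense >
intergenic`, evaluated per transcript and lifted to the gene by the
hierarchy. Antisense requires opposite-strand span overlap *only* — any
same-strand overlap routes the transcript to exonic (at least 1 bp of
shared exonic sequence) or intronic (overlap confined to introns).
Gene-span overlap defines antisense/intergenic; exon sharing defines
exonic. Distances are gap distances between intervals after normalizing
GTF (1-based inclusive) and BED (0-based half-open) input to one internal
convention; the 10 kb chromatin-state window is measured from the gene
span (configurable), boundary inclusive to the base pair. RCI
(cytoplasmic/nuclear concentration index) values are external inputs;
`rci_compare()` applies a pooled-variance t-test between DE and non-DE
genes. `calibrate_arg_cutoff()` picks the largest fold-change cutoff
keeping sensitivity on positive-control genes at or above a floor
(default 0.85); `classify_args()` then calls a gene AR-regulated when its
stimulation fold change is `>= cutoff` or `<= 1/cutoff` (default 1.2,
boundaries inclusive). `tss_aggregate()` averages signal in TSS-relative
coordinates with minus-strand windows mirrored so that relative position
`r` always maps to genomic `TSS + r` on the plus strand and `TSS - r` on
the minus strand.

# The synthetic-data module

The generators emulate the *statistical structure* the pipeline consumes,
not the biology of real genomes:

* Population structure by the Balding-Nichols model —
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` population frequencies around ancestral
  `p`, binomial dosages — with admixture by per-allele-copy population
  draws. There is no linkage disequilibrium; SNPs are exchangeable.
* Mutation catalogs as multinomial draws from signature mixtures; no
  genomic placement, no selection.
* Segment profiles tiling each chromosome exactly, baseline 0 plus
  Gaussian per-segment noise, planted focal events of `|effect| >= 0.5`
  (so +/-0.25 binarization is unambiguous) with Bernoulli carrier status
  at group-specific probabilities.
* Negative-binomial counts with log-normal baselines and size factors and
  planted log2 fold changes; confounding is injected by shifting group-1
  age (Gaussian) and grade (re-weighted ordinal categories), which is what
  the propensity machinery must undo.
* Gene models with classes true *by construction*, including intergenic
  loci placed more than 10 kb from any coding gene.

Passing tests therefore demonstrate correct computation and calibrated
inference under these mechanisms; they do not demonstrate robustness to
LD, copy-number-driven expression, signature collinearity beyond the
built-in set, or annotation errors in real references.

Every generator is a pure function of its parameters and a single seed,
and the demo bundle is written as plain TSV/SEG/GTF/BED text, so any run
is reproducible byte for byte.

# Problem sizes used by the validation suite

The bundled demo and the validation suite use: 3 reference populations of
150 samples, 5,000 SNPs, Fst 0.1; 400 study samples with a 60/340 group
split; 2,000 genes with 200 planted 2-fold changes at n = 40 + 40 for the
DE calibration; 20 focal regions at n = 200 + 200 with a planted 0.30 vs
0.10 region for the permutation test (1,000 permutations per replicate —
empirical-p resolution 1/1001, ample for a q < 0.25 decision; the
function default remains 10,000); 8 x 5 matrices with enumerable margin
classes for the sampler audit. These sizes were chosen so every property
the suite asserts is measured at meaningful power while the whole suite
runs on a laptop.

# Known limitations

* The admixture estimator is supervised and treats panel frequencies as
  known; small panels propagate frequency noise into fraction estimates.
* The DE stand-in underperforms shrinkage-based engines at small n and is
  not intended to reproduce their numerics.
* The permutation test conditions on margins; with very sparse regions the
  conditional null is coarse and empirical p-values are discrete.
* lncRNA classification trusts the input gene models; fragmented
  transcripts bias classes toward intergenic/intronic.
* No survival analysis, no local-ancestry inference, no de novo signature
  extraction, and no peak discovery: peak regions, clonality labels and
  regulatory classes are inputs.
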