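---
title: "Methods: SSR panel structure, diversity and LD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SSR panel structure, diversity and LD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the choices made where the methodology was genuinely open, and
the limits of what its tests demonstrate.

## The setting

The package targets inbred plant germplasm panels genotyped with
multiallelic SSR markers: a table of varieties by loci whose entries are
diploid allele-size calls, a genetic map in centimorgans, and (for rice)
the six morphological traits of Cheng's indica/japonica index. The
questions are the standard pre-association-mapping ones: how is the panel
structured, how diverse and diverged are the subgroups, how many markers
suffice to see the structure, and how far does linkage disequilibrium
extend.

All positions are genetic (cM); the package deliberately carries no
physical coordinates.

## Diversity statistics

Allele frequencies count allele copies — two per variety, both alleles of
a heterozygote — within each group at each locus, with pairwise deletion
of missing calls (the gene count behind every frequency vector is
reported; nothing is imputed). On a frequency vector $p$:

* gene diversity $H_e = 1 - \sum_i p_i^2$;
* $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, evaluated
  through the algebraic identity
  $\sum_{i<j} 2p_i^2p_j^2 = (\sum_i p_i^2)^2 - \sum_i p_i^4$ (the tests
  check it against the literal double sum);
* modified Rogers distance over $m$ loci
  $\mathrm{MRD} = \sqrt{\tfrac{1}{2m}\sum_\ell\sum_a (p_a - q_a)^2}$,
  with alleles absent from one group entering at frequency 0 — a metric,
  and Euclidean-embeddable, which is why principal coordinate analysis of
  the variety-pairwise MRD matrix has no meaningfully negative
  eigenvalues;
* Nei's $G_{st} = (H_t - H_s)/H_t$ with $H_s$ the sample-size-weighted
  mean within-group diversity and $H_t$ the diversity of the pooled
  frequencies, both averaged over the loci observed in every group.
  $H_t = 0$ (all groups monomorphic for one allele) makes $G_{st}$
  undefined; it is returned as `NA`, not 0.

Genome scans compute $H_e$ per group and MRD between two groups locus by
locus; standard errors come from bootstrap resampling of varieties within
groups (default 1000 replicates, seeded). A monomorphic locus has SE
exactly 0. The whole-panel MRD equals the root mean square of the
per-locus values, which the tests assert as a consistency identity.

One reporting convention needs flagging: the per-group "mean allele
frequency" column is implemented as the mean over loci of $1/k_\ell$
(the mean frequency of a locus's $k_\ell$ alleles). The quantity is not
defined unambiguously in the literature this layout follows; this
interpretation reproduces its qualitative behaviour (more alleles, lower
value) and is deliberately simple.

## Cheng's index

Four traits arrive pre-scored 0–4; rachis internode length (cm) and grain
length/width are scored from the measurement. The printed scoring
intervals leave small gaps (e.g. rachis 2.01–2.09 cm between "<2.0" and
"2.1–2.5"), so the implementation uses half-open bins anchored so that
every printed boundary keeps its printed score and gap values fall to the
adjacent lower-magnitude bin: rachis ≤2.0→0, ≤2.5→1, ≤3.0→2, ≤3.5→3,
else 4; grain >3.5→0, ≥3.1→1, ≥2.6→2, ≥2.1→3, else 4. The index is the
sum of the six scores; class thresholds are ≤7 / 8–13 / 14–17 / ≥18.
Index 0 — attainable when every score is 0, although the printed ranges
start at 1 — is classified typical indica by monotone extension.

## Structure inference

**Encoding.** Each variety becomes a row of within-variety allele
frequencies: one column per (locus, allele), 1 for a homozygote, 0.5/0.5
for a heterozygote, so each locus block sums to 1. Missing blocks are
mean-filled for ordination and clustering (the flag is kept); the
variety-pairwise MRD matrix instead uses pairwise deletion.

**Ordinations.** PCA on the column-centred encoding; PCoA by Gower double
centring (`stats::cmdscale`), with negative eigenvalues reported but
unused; a Laplacian embedding whose similarity graph connects varieties
with Pearson correlation ≥ `eps` (default 0.8, the published setting).
The leading (trivial) eigenvector of the symmetric normalised Laplacian
is dropped, so for a disconnected graph the returned lapvectors are the
component indicators; isolated varieties keep a unit self-loop and raise
a warning. A lapvector's "variance explained" is the share of the centred
encoding's total variance captured by projecting onto it.

**Mixture clustering.** Gaussian mixtures are fitted by EM (the mclust
engine) for each K (default 1–30) and six covariance families —
spherical equal/varying, diagonal equal/varying, full shared/varying
(EII, VII, EEI, VVI, EEE, VVV) — and the (K, family) pair maximising BIC
in its larger-is-better form $2\log L - \nu\log n$ is selected. With
$n \approx 150$ varieties and an allele space of order $10^3$ columns,
full-covariance families are singular on the raw encoding, so clustering
operates on the top principal components (default 10). The number of
retained components genuinely matters for model selection on panels that
contain a block of admixed varieties: the admixed form a bridge between
the subpopulation clusters, and whether BIC grants them a third component
depends on how much of the noise space is retained — see "Known
behaviour" below.

**ΔK.** Evanno's statistic
$\Delta K = \overline{|L(K{+}1) - 2L(K) + L(K{-}1)|}\,/\,\mathrm{sd}\,L(K)$
consumes any (K, replicate, log-likelihood) table — externally produced
series are accepted via the same tibble interface — and is defined for
interior K with positive replicate standard deviation; zero-sd entries
are flagged undefined rather than treated as infinite. Internally,
replicate series come from EM restarts at seeded random soft
initialisations: runs that converge to the same optimum differ only at
the convergence tolerance, which makes the K at the likelihood elbow
stand out sharply, the behaviour the statistic exploits.

**Membership and assignment.** Two kinds of membership are kept apart
deliberately. The mixture posterior supplies the max-probability labels.
But threshold-style membership — "retain below 0.80 in the admixed
group" — is meaningful only for admixture *proportions*: Gaussian
posteriors are numerically sharp (near 0/1) even for genuinely
intermediate varieties. `estimate_admixture()` therefore fits the
maximum-likelihood admixture model by block EM: an allele copy $a$ of
variety $i$ has likelihood $\sum_k q_{ik} f_k(a)$; the E-step computes
per-copy responsibilities and the M-step updates both each variety's $q$
(mean responsibility) and each group's allele frequencies $f_k$
(responsibility-weighted counts), so intermediate varieties do not
contaminate the frequency pools. A floor of $10^{-3}$ per allele keeps
private alleles from zeroing likelihoods; EM stops when the largest $q$
move is below $10^{-5}$. The threshold rule is inclusive (max $q \ge
0.80$ assigns; below, the variety is retained as `AD`), and arg-max ties
break toward the lowest subgroup index with a message.

**Correspondence.** Agreement between two labelings is the maximum
fraction of varieties matched over injective relabelings of the smaller
alphabet into the larger, computed exactly by bitmask dynamic programming
on the confusion matrix; unmatched labels count as disagreement and the
admixed label is a label like any other. The tests check it against
exhaustive permutation search.

**Trees.** Neighbor-joining (via ape) on the variety MRD matrix, with
negative branches clamped to zero and the deficit moved to the sister
branch so parent-path lengths are preserved; output is Newick text. Ward
clustering (ward.D2 on Euclidean distances) of the six trait scores plus
the index mirrors the morphology-based clustering.

## Marker-number sufficiency

Subsets of 12, 24, … markers are drawn either uniformly at random or
stratified: per-chromosome quotas proportional to chromosome marker
counts (largest-remainder rounding), then within each chromosome loci
closest to an evenly spaced target grid. The target grid carries a
seed-random phase. A fully deterministic spacing rule would make
stratified subsets identical across repetitions, collapsing the
coefficient of variation of MRD to exactly zero wherever quotas have no
remainder and destroying the CV-versus-size curve the analysis exists to
measure; the random phase keeps repetitions exchangeable while preserving
even genome coverage.

For each size, strategy and repetition the mixture clustering is refitted
on the subset and compared (by correspondence) to the full-panel
assignment, and the pairwise MRD is recomputed; the per-pair CV across
repetitions (population SD over mean, zero-mean pairs excluded) is
averaged over pairs. Repetition seeds derive deterministically from the
master seed and are shared between strategies, so the random/stratified
comparison is paired. The plateau size is the smallest grid size whose
mean correspondence reaches 0.95. Because Monte-Carlo curves at 25
repetitions are noise-limited step to step, the monotonicity checks in
the test suite compare the curve endpoints (smallest vs largest size)
rather than every adjacent pair.

## Linkage disequilibrium

Inbred varieties are treated as haploid for LD: homozygotes project to
their allele, residual heterozygotes (about 5% under the default selfing
rate) become missing — no phasing is attempted. Alleles with count < 2
are pooled into an "other" class before testing (configurable off).

From the two-locus haplotype table with frequencies $x_{ij}$ and margins
$p_i, q_j$: $D_{ij} = x_{ij} - p_i q_j$;
$D'_{ij} = |D_{ij}|/D^{max}_{ij}$ with the usual positive/negative-case
maximum; the weighted coefficients are $D' = \sum_{ij} p_i q_j D'_{ij}$
and $r^2 = \sum_{ij} p_i q_j r_{ij}^2$ with
$r_{ij} = D_{ij}/\sqrt{p_i(1-p_i)q_j(1-q_j)}$. For biallelic pairs both
reduce exactly to the classical definitions, which the tests verify
against an indicator-correlation oracle. Significance is Fisher's exact
test for 2×2 tables and otherwise a seeded Monte-Carlo permutation of one
call vector (default 10,000 shuffles; statistic, the table chi-square;
add-one numerator so p > 0). The type-I rate of this machinery on
structure-free panels is checked against its nominal level in the
acceptance suite.

Summaries report the percentage of linked (same chromosome) and unlinked
pairs significant at α = 0.05 and their ratio. Decay analysis sets the
threshold at the linearly interpolated 75th percentile of unlinked $r^2$,
bins linked pairs in sliding windows $[\ell, \ell + 5)$ cM advanced by 1
cM, and reports the left edge of the first window whose mean $r^2$ is
below the threshold with every later non-empty window also below; 0 if
already the first window qualifies, `Inf` ("beyond map extent") if none
does. Window width and step are reporting conventions, not fitted
parameters. LD blocks are maximal runs (≥ 2 loci, configurable) of
map-adjacent loci whose every consecutive pair is significant; the
group-level mean block length is emitted under both defensible averaging
rules — over chromosomes that have blocks, and over all chromosomes with
blockless ones contributing zero — because published per-chromosome
tables are reproducible under one rule for some groups and the other for
the rest.

## The synthetic generator

No genotype matrix ships with the package, so a seeded generator supplies
panels with the statistical structure the estimators consume. Ancestral
allele frequencies per locus are flat-Dirichlet; subpopulation
frequencies are Dirichlet around the ancestral vector with concentration
$(1-F)/F$ (Balding–Nichols), so $F \in [0,1)$ controls divergence;
`calibrate_divergence()` bisects $F$ against the realised
between-subpopulation MRD because the finite-allele map from $F$ to MRD
is configuration dependent. An admixed variety draws each allele copy
from $q\,p_1 + (1-q)\,p_2$ with its own $q \sim U(0.2, 0.8)$. Varieties
are homozygous with probability 0.95 (selfing), missing calls are
injected at 2%, and map gaps are uniform within ±50% of each chromosome's
mean spacing. Defaults mirror the published panel's shape: 111/20/19
varieties, per-chromosome marker counts summing to 274, mean spacings
4.7–9.4 cM, and truncated-geometric allele counts on 2–12 with mean near
3.9. Under the flat ancestral prior the large-$F$ limit of expected
squared MRD is $F/3$, so even near-complete divergence caps MRD near
0.57 — a property of the prior, asserted in the tests.

Class-conditional traits draw each of the six scores Binomial(4, p) with
p = 0.12 / 0.88 / 0.5 for the two subpopulations and the admixed group,
and draw the two numeric measurements uniformly inside the interval that
scores at the drawn level, so re-scoring reproduces it.

What the generator does **not** emulate: linkage-generated LD beyond what
subpopulation mixing induces (sufficient to exercise the LD machinery and
the structure-inflation contrast, but decay-versus-distance curves on
synthetic panels carry no within-chromosome signal), stepwise mutation,
genealogical correlation, genotyping error beyond uniform missingness.
Passing tests therefore demonstrate correctness of the estimators and the
qualitative behaviours that follow from population mixing — not that any
particular real panel's numbers are recovered.

## Known behaviour and limitations

* On generated panels with a coherent block of intermediate varieties
  (~13% admixed, $q \sim U(0.2, 0.8)$), BIC model selection is genuinely
  bimodal between K = 2 and K = 3: the third component captures the
  admixed bridge, which *is* a real group under the generator's truth.
  ΔK, which keys on the dominant likelihood jump, identifies K = 2
  essentially always. The acceptance suite records both behaviours; the
  threshold-rule recovery path fixes K at the ΔK arg-max before
  estimating admixture proportions, which is the classical analysis
  order.
* The admixture EM is a point estimator; it reports no uncertainty on Q.
* Bootstrap SEs resample varieties, not loci; they quantify sampling of
  individuals at fixed markers.
* Exact correspondence matching is limited to ≤ 20 labels (bitmask DP);
  far beyond any realistic subgroup count here.
* Test problem sizes are the package's own choices: oracle checks run at
  100 random cases; the recovery study at 100 seeds of 150 × 274 panels;
  the sufficiency study at 25 repetitions on a step-24 grid; the LD
  calibration at 60 independent loci with 300 permutation shuffles.
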