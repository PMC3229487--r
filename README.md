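# ssrpop

Population structure, genetic diversity and linkage disequilibrium (LD)
analysis for multiallelic SSR (microsatellite) genotype panels from inbred
plant germplasm collections — the marker-panel workflow used to
characterise rice core collections before association mapping: are there
subpopulations (indica vs japonica), how diverged are they, how many
markers are enough, and how far does LD extend?

The package is aimed at plant population geneticists working with
varieties-by-loci tables of allele fragment sizes. Everything is
data-frame first: genotype panels, maps and trait tables are tibbles,
results come back as tibbles or small result objects with `tidy()`,
`glance()` and `autoplot()` methods.

## What it computes

* **Morphological classification** — Cheng's index: six 0–4 trait scores
  (glume hair, phenol reaction, rachis internode length, glume colour,
  leaf hair, grain length/width) summed to an index I ∈ 0–24 and
  classified typical *indica* (≤7), *indica*-clined (8–13),
  *japonica*-clined (14–17), typical *japonica* (≥18).
* **Diversity and divergence** — allele frequencies by allele-copy
  counting; gene diversity `He = 1 − Σpᵢ²`; polymorphism information
  content `PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ²`; modified Rogers distance
  `MRD = √(Σₗ Σₐ (pₐ − qₐ)² / 2m)`; Nei's `Gst = (Ht − Hs)/Ht`; per-locus
  genome scans with bootstrap standard errors.
* **Population structure** — within-variety allele-frequency encoding;
  PCA, principal coordinate analysis on MRD, Laplacian embedding;
  Gaussian-mixture clustering over K = 1…30 and six covariance families
  with BIC model selection (via mclust); Evanno's
  `ΔK = mean|L(K+1) − 2L(K) + L(K−1)| / sd L(K)`; maximum-likelihood
  admixture proportions Q by block EM; assignment by maximum membership
  or the 0.80 threshold (below it a variety is retained in the admixed
  group); optimal-matching correspondence between assignments;
  neighbor-joining trees and Ward clustering of trait scores.
* **Marker sufficiency** — random vs genome-stratified marker subsets
  (12, 24, … markers), refitting the clustering per subset and tracking
  correspondence to the full-panel assignment and the coefficient of
  variation of pairwise MRD across repetitions.
* **Multiallelic LD** — for each locus pair, from two-locus haplotype
  frequencies `xᵢⱼ`: `Dᵢⱼ = xᵢⱼ − pᵢqⱼ`, weighted
  `D' = Σᵢⱼ pᵢqⱼ |Dᵢⱼ|/Dmax`, weighted `r² = Σᵢⱼ pᵢqⱼ rᵢⱼ²`; Fisher exact
  (2×2) or seeded permutation significance; percent of linked/unlinked
  pairs in significant LD and their ratio; LD decay distance against the
  75th percentile of unlinked r²; LD blocks (maximal runs of map-adjacent
  loci with every consecutive pair significant at P < 0.05).
* **Synthetic panels** — a seeded Balding–Nichols-style generator for a
  two-subpopulation selfing panel (defaults: 111 + 20 + 19 varieties, 274
  SSRs on 12 chromosomes, 2–12 alleles per locus, 95% homozygosity,
  admixture proportions U(0.2, 0.8)), with `calibrate_divergence()` to
  hit a target between-subpopulation MRD, plus class-conditional
  morphological traits. Since no real genotype matrix ships with the
  package, this generator is what makes every stage testable end to end.

## Worked example

Simulate a panel under the study conditions (divergence calibrated so the
between-subpopulation MRD ≈ 0.44), scan diversity, infer structure and
assign varieties:

```r
library(ssrpop)
library(dplyr)

cfg <- sim_config(divergence = 0.355, seed = 42)
sim <- simulate_panel(cfg)
sim$panel
#> <ssr_panel> 150 varieties x 274 loci

scan <- diversity_scan(sim$panel, sim$truth[c("variety_id", "group")],
                       mrd_groups = c("subpop1", "subpop2"),
                       n_bootstrap = 200, seed = 1)
scan
#> <diversity_scan> 274 loci, groups: admixed, subpop1, subpop2
#>   overall MRD: 0.4287
#>   Gst: 0.1208

pcs <- pca_panel(encode_panel(sim$panel), n_components = 10)
fit <- fit_mixture(pcs, K_range = 1:6)
fit
#> <mixture_fit> K = 2 (EII), n = 150, loglik = -2503.9

dk <- delta_k(mixture_runs(pcs, K_range = 1:5, n_reps = 3, seed = 7))
dk$K_hat
#> [1] 2

q <- estimate_admixture(sim$panel, assign_membership(fit$membership, "max"))
assignment <- assign_membership(q, rule = "threshold", threshold = 0.80)
count(assignment, label)
#> # A tibble: 3 × 2
#>   label     n
#>   <chr> <int>
#> 1 AD       18
#> 2 SG1     112
#> 3 SG2      20

correspondence(setNames(sim$truth$group, sim$truth$variety_id), assignment)
#> [1] 0.9933333
```

Reading the output: the overall MRD between the two simulated
subpopulations is 0.43 (the calibration target); BIC picks two subgroups
and ΔK agrees; the 0.80-threshold rule on the admixture proportions Q
recovers 112 + 20 varieties in the two subgroups with 18 retained as
admixed, and the assignment agrees with the generating truth for 99.3% of
varieties under optimal label matching.

The full pipeline — classification, diversity, structure, resampling and
LD, with TSV outputs and a manifest — runs through one call:

```r
res <- run_analysis(analysis_config(sim = cfg, seed = 42), outdir = "run1")
```

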