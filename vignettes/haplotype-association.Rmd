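---
title: "Haplotype-window association and joint-SNP anchored meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-window association and joint-SNP anchored meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapanchor)
```

## The problem

Single-SNP genome-wide association studies test each variant marginally and
can miss risk that is carried by a *functional chromosomal unit* — a
haplotype spanning a gene together with its cis-regulatory elements.
hapanchor implements a haplotype-block association workflow for phased
case–control cohorts, built around the design used for monoclonal
gammopathy of unknown significance (MGUS), a premalignant plasma-cell
condition preceding multiple myeloma: several European populations, each
genotyped on a different array, phased with SHAPEIT, scanned with
sliding-window haplotype markers, and combined by meta-analysis.

The central obstacle is that haplotypes are rarely *identical* across
populations: SNP content differs by array and imputation, so the same
underlying risk haplotype surfaces as slightly different windows in each
cohort. Conventional meta-analysis over shared markers therefore fails.
The workflow solves this with a **joint SNP**: a SNP contained in the
associated haplotypes of *every* population serves as an anchor, and the
per-population haplotype estimates tied to that anchor are pooled. The
joint SNP is only a label — the pooled p-value, odds ratio and frequency
all describe the haplotypes it represents.

## The procedure

1. **SNP filter.** Variants with folded minor allele frequency
   `min(f, 1 - f) < 0.05` are excluded (boundary kept). Frequencies are
   folded because strand-of-reference is arbitrary; this is noted as an
   interpretation, since tool conventions differ.
2. **Windows.** Per chromosome, windows of 15 consecutive SNPs are laid at
   SNP offsets 0, 2, 4, …; a trailing stretch shorter than 15 SNPs is not
   emitted, keeping every marker the same width. Fifteen SNPs of typical
   GWAS density span roughly one 20 kb LD block. Each window's *block
   coordinate* is the floored mean of its first and last bp (floored so
   that map/BED output stays integer).
3. **Haplotype alleles.** Every distinct phased sequence over a window is
   one *haplotype allele*. Each allele is recoded one-vs-rest as a
   pseudo-biallelic marker: per sample the number of copies carried
   (0/1/2) maps to genotypes NN/NH/HH (H = this allele, N = all others).
   Alleles with frequency below 0.01 — or above 0.99, the mirror-image
   case, equally uninformative for a biallelic recoding — are dropped.
   Alleles are ordered by descending frequency with lexicographic
   tie-breaks, so output is deterministic.
4. **Per-population association.** Each marker is tested with additive
   logistic regression `logit P(case) = b0 + beta·count + b_sex·sex`,
   the standard sex-adjusted model for this design. The fit is by IRLS
   (max |score| < 1e-8 or parameter change < 1e-10, at most 50
   iterations); SEs come from the inverse observed information.
   Monomorphic markers, single-class phenotypes, and separated fits
   (|beta| > 15 or non-convergence) are reported as skip records rather
   than numbers — a separated marker has no estimable OR and cannot anchor
   a meta-analysis. P-values are held in log10 space throughout, since
   genome-wide tails underflow double precision.
5. **Anchored meta-analysis.** For every SNP present in at least one
   estimable haplotype of *each* population, each population contributes
   its most significant haplotype containing that SNP (the choice when an
   anchor sits in several windows of one population is a design decision;
   the procedure this package follows is smallest p first, marker id as
   tie-break). The contributed log ORs are pooled with the
   DerSimonian–Laird random-effects inverse-variance model:
   fixed weights `w_i = 1/se_i^2`, Cochran's
   `Q = Σ w_i (b_i − b_fix)^2` on `k − 1` df,
   `tau² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, re-weights
   `1/(se_i² + tau²)`, and `I² = max(0, (Q − (k−1))/Q)·100`.
   "Most significant" for joint-SNP selection means the smallest *pooled*
   p — the anchor represents the haplotype, so significance is
   haplotype-level, not single-SNP-level; the single-SNP reading is noted
   as the alternative. Ties break by smaller bp, then SNP id.
6. **Regions.** An anchored haplotype is reportable when the pooled p is
   strictly below 5e-8, the per-population log OR is positive in every
   population, and every population contributed. Per-population
   *significance* is deliberately not demanded — in forest plots of this
   kind single-population CIs routinely cross 1, so direction is the only
   defensible cross-population criterion. Reportable haplotypes that
   overlap on a chromosome are grouped transitively, and each region spans
   the lowest start to the highest end *among all its member haplotypes*,
   represented by its most significant joint SNP. Merging never crosses a
   chromosome. Outputs are a summary table (joint SNP, chr, bp, OR, CI,
   p), a BED file (1-based inclusive regions convert to 0-based half-open)
   and forest-plot data (one row per population plus the pooled summary).

Positions are 1-based inclusive everywhere in memory and in haps/VCF
output; only BED converts. On real phased input, any sample with
missingness inside a window would be dropped from that window's markers
with an adjusted denominator; the synthetic generator produces no missing
entries.

## The synthetic cohort generator

Individual-level data for studies of this kind are access-restricted, so
the generator is a first-class module: every downstream stage is exercised
against cohorts with the statistical structure the analysis assumes.

The model is a **mosaic founder copy**, not a coalescent: a small set of
ancestral haplotypes is drawn site-wise from per-SNP frequencies
`U(0.1, 0.9)`; a founder pool (default 20) is built as recombinant mosaics
of those ancestors; each individual's two haplotypes are again mosaics of
founders, switching source with probability `recomb_rate` (default 0.01)
per adjacent-SNP interval and flipping alleles with probability
`mutation_rate` (default 0.001) per site. The two-level ancestry matters:
with founders drawn site-independently, a 15-SNP window shows maximal
haplotype diversity and its modal allele is unrealistically rare (~6%);
descending from a handful of ancestors reproduces what real ~20 kb windows
look like — limited diversity, common haplotype alleles in the 0.2–0.45
range, strong local LD.

Disease status follows
`logit P(case) = logit(prevalence) + beta_H·dose + beta_sex·sex`, where
`dose` counts copies of a designated causal haplotype allele (the modal
ancestral sequence over one chosen window). Cases and controls are then
*ascertained by rejection* until the configured quotas are met, matching
retrospective case–control sampling. If the causal allele's frequency
falls below 1% in any population the founder pool is redrawn; ten failures
signal an infeasible configuration. Each population drops a disjoint
random share `1 − snp_overlap_fraction` of SNPs (causal-window SNPs are
protected, so a common anchor always exists), then applies the MAF floor.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| `n_populations` | 3 | three-cohort design |
| `n_cases` / `n_controls` | 331 / 970 | ≈ 992 cases / 2910 controls split evenly across three populations |
| `n_snps` | 150 | one chromosome segment (~75 windows) — desk-scale |
| `founder_pool_size` | 20 | enough window diversity without rare-allele explosion |
| `recomb_rate` | 0.01 | ~14% of window copies recombinant, realistic block decay |
| `mutation_rate` | 0.001 | rare singleton noise |
| `maf_floor` | 0.05 | the 5% QC rule |
| `sex_logOR` | log(1.3) | a modest covariate effect; no published value to match |
| `baseline_prevalence` | 0.03 | MGUS prevalence in older adults ≈ 3% |
| `snp_overlap_fraction` | 0.8 | populations share a core but differ in content |

What the generator does **not** emulate: population-specific allele
frequencies and LD (all populations share one founder pool), genotyping or
imputation error, variable SNP density, multiple chromosomes per run, and
demographic history. Passing tests therefore show that the pipeline
recovers effects under its own assumptions — clean phasing, shared
ancestral structure, a single causal window — not that it is robust to
array artefacts or fine-scale population structure.

## Validation design and problem sizes

The test suite validates each layer against an independent route:

* **Closed forms.** The saturated 2×2 logistic fit must reproduce the
  Woolf log-OR and SE to 1e-6; IRLS must agree with `stats::glm` to 1e-6
  on random data; the DL pooling must match a hand-evaluated three-study
  example to 1e-3 and `metafor::rma(method = "DL")` to 1e-8.
* **Published-summary consistency.** For the bundled 23-row MGUS region
  table, beta and SE rebuilt from each printed OR/CI reproduce the printed
  p-value within print rounding (all rows within 0.21 log10 units), and
  every recomputed p clears 5e-8.
* **Calibration.** Permuted-label p-values pass a KS uniformity check; the
  pooled marginal type-I rate over 100 null panels sits near 0.05.
* **Recovery.** 500 three-population meta replicates around OR 2 (SEs
  0.10/0.15/0.12, between-population tau 0.06 — mild heterogeneity, chosen
  so that the known small-k behaviour of the DL estimator keeps nominal
  coverage) recover the mean log OR within 0.02 with CI coverage in
  [0.92, 0.97]. End-to-end, 100 replicates of three populations × (500
  cases + 500 controls) on a 120-SNP segment with a causal haplotype of
  OR 2.5 must yield a genome-wide region containing the causal window in
  ≥ 95 replicates, and ≤ 1 false region in 100 null replicates. These
  sizes are the package's desk-scale study design; power at OR 2.5 with
  a causal-allele frequency of 0.2–0.45 is effectively complete.

## Known limitations

* The DL estimator at `k = 3` is noisy in tau²; pooled CIs undercover when
  heterogeneity is large. This is a property of the estimator, kept
  deliberately because it is the default behind the standard
  random-effects IVW meta in GWAS toolchains.
* One-vs-rest recoding makes markers within a window linearly dependent
  (counts sum to 2); marker-level p-values are valid marginally but not
  independent, and no multiplicity correction beyond the genome-wide
  threshold is applied.
* For a window with exactly two alleles the complement marker carries the
  identical test with flipped sign; anchoring chooses by significance and
  may pick either label, though direction filtering keeps only
  risk-increasing representations in reports.
* Regions on a short simulated segment chain readily into one overlap
  group; on real genome-wide data groups are local.
* No LD-based (Gabriel-style) variable-length blocks, no mixed models or
  PC covariates, no permutation p-values, no conditional analysis, and no
  functional annotation of reported regions.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(n_cases = 200, n_controls = 200, n_snps = 80,
                   causal_window_index = 15,
                   causal_allele_logOR = log(2.5), seed = 4),
  out_dir = "hapanchor_demo")
res <- run_pipeline(cfg)
res$regions
plot_forest(res$regions, res$meta)
```
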