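---
title: "Triangulating blood causal genes from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating blood causal genes from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrtriad)
```

## The problem

Genome-wide association studies of a complex disease such as Alzheimer's
disease identify loci, not genes, and certainly not mechanisms. When the
same locus also regulates the blood expression of a nearby gene (a
cis-eQTL) and the methylation of a nearby CpG (a cis-mQTL), three layers
of summary statistics can be triangulated to ask a sharper question: does
genetically lowered methylation raise expression, and does genetically
raised expression raise disease risk? `smrtriad` implements that
triangulation as a reusable, fully tested pipeline operating purely on
per-variant summary statistics (beta, SE, p, n) plus an external LD
reference — no individual-level data are required.

The stages are:

1. **Meta-analysis** — fixed-effects inverse-variance-weighted pooling of
   several disease GWAS (`ivw_meta`, `meta_analyze`), a minor-allele
   frequency filter (default MAF ≥ 0.5%), and greedy 500-kb distance
   clumping of genome-wide significant variants into loci (`define_loci`,
   threshold 5e-8), with an allele-harmonized directional-concordance
   check against an independent replication cohort
   (`replication_concordance`).
2. **Two-sample MR** — per gene, cis instruments (within 1 Mb of the TSS,
   BH-FDR < 0.05 *and* p < 1e-5, LD-pruned at r² < 0.1) feed a Wald-ratio
   or IVW estimate of the expression→disease effect (`ivw_mr`), with
   instrument strength (`r² = z²/(z²+n−2)`, F statistic) and Steiger
   directionality filtering (`steiger_filter`).
3. **Three-step SMR + HEIDI** — the top-cis-QTL ratio test
   (`smr_test`: T = z₁²z₂²/(z₁²+z₂²) ~ χ²₁) applied in three
   directions: expression→disease, methylation→disease and
   methylation→expression, each followed by the HEIDI heterogeneity test
   (`heidi_test`) that separates a single shared causal variant from
   linkage of distinct variants.
4. **Colocalization** — Wakefield approximate Bayes factors per variant
   (`wakefield_labf`) enumerated into posteriors PP.H0–PP.H4
   (`coloc_abf`); PP.H4 > 0.5 is the shared-variant gate.
5. **Sign-chain interpretation** — a candidate chain is directionally
   coherent when sign(methylation→disease) equals
   sign(methylation→expression) × sign(expression→disease)
   (`infer_sign_chain`).

## Gating logic

`run_three_step` emits one row per (probe, gene) pair and a `candidate`
flag that requires all of:

* `fdr_all3` — BH-FDR q < 0.05 in each step, computed within each step
  across the tests actually performed there (the spec of the test
  universe is a genuine design choice; we chose the per-step universe so
  that adding unrelated probes cannot rescue a gene);
* `p_all_datasets` — the top instrument reaches p < 1e-5 in the eQTL and
  mQTL data, and the GWAS reaches p < 1e-5 at the stronger of the two top
  SNPs (which SNP carries the GWAS gate is not defined by the
  three-layer design; we take the minimum of the two);
* `heidi_all3` — every *computable* HEIDI p exceeds 0.05. Pairs whose
  HEIDI is untestable (fewer than 3 eligible cis SNPs, or no LD matrix)
  are retained with an explicit `heidi_untestable` flag by default;
  `triad_config(heidi_untestable_pass = FALSE)` flips this to exclusion;
* the colocalization gate PP.H4 > 0.5 (on by default,
  `coloc_gate_on = FALSE` disables it).

Step 3 (methylation→expression) is only run for pairs significant in
steps 1 and 2, and only when the probe lies within the gene's 1-Mb cis
window — restricting the probe universe *after* step-2 significance
rather than before, which keeps step 2 interpretable as a genome-wide
methylation screen.

## The HEIDI test in detail

Eligible SNPs have exposure p < 1.57e-3 (|z| > 3.16) and LD r² with the
top SNP in [0.05, 0.9]; the 20 smallest-p SNPs are kept and the top SNP
itself is excluded from the difference set. For each eligible SNP the
deviation d from the top-SNP ratio is formed, its covariance obtained by
the first-order delta method with within-dataset SNP-SNP covariance
r·se·se and independence across datasets, and T = Σ(d/sd)² referred to a
weighted sum of χ²₁ variables whose weights are the eigenvalues of the
correlation matrix of the standardized deviations. The tail is evaluated
by three-moment (Liu-type) matching to a noncentral chi-square
(`pchisqsum_liu`) — accurate to about ±0.02 against a 200,000-draw
Monte-Carlo quadratic-form oracle on small panels, which the test suite
verifies; homogeneous input gives T = 0 and p = 1 exactly. All four
eligibility constants are exposed in `triad_config` because they are
method conventions, not properties of the data.

A structural consequence worth knowing: the three per-step HEIDI tests
are nearly independent (each pair of steps shares only one of the three
datasets), so demanding p > 0.05 three times bounds the expected
all-gates pass rate of a *true* mediated chain at about 0.95³ ≈ 0.86.
Raising per-test specificity (a smaller `heidi_alpha`) or pooling the
three tests would trade power differently; we keep the conventional 0.05
gate and report the joint behavior honestly in the recovery metrics.

## The simulator

`simulate_locus` generates the three coupled layers directly on the
standardized scale: with LD matrix R (AR(1), r_jk = ρ^|j−k|, or any
user-supplied PSD matrix), per-SNP total effects b on each layer, and
marginal effects Rb, the observed z-vector of a layer with sample size n
is one draw of MVN(√n·Rb, R); betas are z/√n with se 1/√n. Layers are
independent given the truth; child seeds per layer derive from one
master seed, so output is bit-reproducible. Allele pairs are drawn
non-palindromic (A/G or C/T) so that harmonization exercises the flip
logic but never drops simulated variants; EAF is Uniform(0.05, 0.5) and
is carried but does not enter the effect model.

Scenario defaults (chosen once, as representative blood-QTL/GWAS
conditions, and fixed):

| scenario   | α (SNP→meth) | γ (meth→expr) | c (expr→disease) | π (direct) | ρ | notes |
|------------|------|-----|------|------|-----|-------|
| mediated   | 0.15 | 0.5 | 0.3  | 0    | 0.8 | one causal SNP (panel midpoint) |
| pleiotropy | 0.15 | 0.5 | 0    | 0.05 | 0.8 | same SNP hits disease directly |
| linkage    | 0.20 | 0.5 | 0    | 0.05 | 0.9 | disease causal 5 SNPs away, LD r = 0.9⁵ ≈ 0.59 |
| null       | 0    | 0   | 0    | 0    | 0.8 | calibration |
| reverse    | 0    | 0   | 0    | 0.15 | 0.8 | expression is a 0.5× readout of the disease signal |

Sample sizes default to 20,000 (mQTL), 20,000 (eQTL) and 200,000 (GWAS);
panels are 100 SNPs spaced 2 kb. Under the mediated topology the three
SMR steps estimate c (step 1), γ·c (step 2) and γ (step 3), which is
what `evaluate_recovery` scores.

What the simulator deliberately does **not** emulate: realistic MAF/LD
drawn from reference panels, case-control liability-threshold sampling
(the disease "beta" lives on the same linear standardized scale), sample
overlap between layers, and multi-feature loci (compose several
single-feature loci instead). Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the assumed model,
not that real cohort data meet those assumptions.

## Numerical choices

* p-values via the log-scale normal survival function (`wald_p`), exact
  far beyond |z| = 37; `log.p = TRUE` is available where products would
  underflow.
* Colocalization entirely in log space with `logsumexp`; the H3 evidence
  uses a log-difference with tiny negative arguments clamped to −∞ (the
  single-SNP / degenerate-panel case).
* BH q-values delegate to `stats::p.adjust(method = "BH")`; the test
  suite pins it against a brute-force O(m²) step-up oracle.
* Clumping ties on minimum p break by (chrom, pos) order; instrument
  pruning ties break by p then variant id — both for determinism.
* Records whose printed p disagrees with 2·Φ(−|β/se|) by more than 5%
  (relative) are kept with p recomputed and the printed value preserved
  as `p_reported`, since downstream ratio tests require internally
  consistent (β, se, p).
* Missing EAF survives the MAF filter with a `maf_unknown` flag;
  palindromic variants with EAF within ±0.08 of 0.5 are dropped at
  harmonization.

## Problem sizes used by the checks

The shipped tests and the acceptance script use 200-replicate scenario
batches (100-SNP panels), 1,000–2,000-replicate calibration runs on
10–20-SNP panels, and 50,000–200,000-draw Monte-Carlo oracles for the
HEIDI tail — sizes at which every Monte-Carlo bound in the suite has
comfortable slack while a full run stays in the minutes range on one
core.

## A worked run

```{r example}
loc <- simulate_locus("mediated", seed = 7)
res <- run_three_step(loc$eqtl, loc$mqtl, loc$gwas, loc$ld,
                      loc$annotation, gene_filter = "gene1")
res$chains[, c("probe_id", "gene_id", "b_step1", "b_step2", "b_step3",
               "coloc_pph4", "candidate", "sign_consistent")]
infer_sign_chain(res$chains$b_step1, res$chains$b_step2,
                 res$chains$b_step3)$statement
```

## Known limitations

Single-SNP SMR inherits the usual caveat that causality and horizontal
pleiotropy at the *same* variant are indistinguishable (HEIDI only
excludes linkage); the coloc enumeration assumes at most one causal
variant per trait in the window; the IVW-MR weights ignore exposure
noise beyond first order (instruments are gated at p < 1e-5 where that
is negligible); and LD-based pruning/HEIDI assume the reference LD signs
match the harmonized allele orientation.
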