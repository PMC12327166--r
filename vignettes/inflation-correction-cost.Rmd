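---
title: "The cost of genomic-inflation correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cost of genomic-inflation correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasinflate)
```

## The problem

Large GWAS meta-analyses show inflated association test statistics. Two
mechanisms produce the same symptom: residual confounding (population
stratification, cryptic relatedness), which inflates every statistic, and
genuine polygenicity, which lifts the bulk of the chi-square distribution
because thousands of variants carry small true effects. Two corrections are in
routine use:

* **Genomic control (GC)** divides every chi-square statistic by the inflation
  factor `lambda = median(chisq) / 0.4549`, where 0.4549 is the median of the
  chi-square distribution with one degree of freedom. Under high polygenicity
  the median itself is shifted by true signal, so lambda over-estimates
  confounding and GC over-corrects.
* **LD-score regression (LDSR)** regresses per-variant chi-square statistics
  on LD scores `l_j` (the sum of squared correlations of variant j with its
  neighbours). Under the model `E[chisq_j] = c + N h2 l_j / M` true polygenic
  signal scales with `l_j` while confounding does not, so the intercept `c`
  isolates confounding and is the less conservative divisor.

This package quantifies what each correction costs: how many associations that
replicate in a later, larger study ("robust associations") and how many
independent loci are lost when the earlier study's p-values are corrected.
Everything the analysis needs — inflation estimation, p-value un-/re-correction,
LDSC-style intercept fitting, study harmonization, confusion-matrix accounting,
leave-one-chromosome-out resampling, and PLINK-style clumping — is implemented
here over plain tibbles, with a synthetic-data generator supplying ground truth.

## Working on the chi-square / log scale

Meta-analyses contain p-values far below the smallest positive double
(p ~ 1e-300 and beyond). All conversions therefore run through
`qchisq()`/`pchisq()` with `log.p = TRUE`, and p-values are stored as
`-log10 p` alongside the equivalent chi-square. Corrections multiply or divide
chi-square values; p-values are always recomputed, never manipulated directly.
The chi-square(1) median is used at full precision (0.45494); the conventional
0.454 is a truncated display value, and using it would corrupt lambda in the
third decimal. Significance comparisons use `-log10 p >= 7.30103...` with
boundary equality counting as significant, so no float ambiguity arises at
p = 5e-8.

By default GC and intercept corrections apply only when the divisor exceeds 1
(no deflation correction, the standard GC convention); `force = TRUE` applies
them unconditionally, which the un-correct/re-correct round trip of published
double-GC-corrected statistics requires. Corrections touch test statistics
only — effect sizes and standard errors are left alone.

## The synthetic generator

`synth_config()` fixes the study conditions; `simulate_panel()`,
`simulate_sumstats()` and `simulate_study_pair()` generate from them.

**Haplotype panel.** Variants sit in LD blocks. Within a block all variants
share one MAF drawn from a beta-shaped spectrum floored at 0.5% (mirroring the
MAF >= 0.5% filters of the large meta-analyses), and alleles follow a
copy-with-refresh Markov chain: each haplotype copies the previous variant's
allele with probability rho, else redraws. For equal-frequency binary alleles
this yields adjacent correlation exactly rho and AR(1)-like decay, which a
Gaussian-copula construction would not (dichotomising attenuates correlation
well below rho). Sharing the MAF within a block is what makes the chain exact;
the MAF spectrum is expressed across blocks. Blocks span a few kb and sit more
than 1 Mb apart, so they are independent and never straddle a clumping window.
Columns drawn monomorphic at the MAF floor are made polymorphic by flipping a
single haplotype.

**Heterogeneous LD.** `rho` defaults to the range `c(0, 0.9)`: each block's
adjacent correlation is drawn uniformly, emulating the alternation of
recombination hotspots and long haplotype blocks in real genomes. This matters
statistically: with a single strong rho all LD scores cluster in a narrow band
(roughly 5–9.5) and the LDSR intercept — the regression value at `l = 0` —
becomes a long, fragile extrapolation. The heterogeneous default spreads LD
scores over ~1–10 and anchors the intercept near data. A scalar rho remains
available and is what the fixed-rho panel tests use.

**Summary statistics.** The baseline generator is the exact LDSR variance
form: `z_j ~ N(0, sqrt(c + N h2 l_j / M))`, independent across variants given
the LD scores. This is deliberately the model both estimators assume, giving
clean parameter-recovery tests: `compute_lambda()` on null draws (c = 1,
h2 = 0) is 1.00 within Monte-Carlo error, and `ldsr_fit()` recovers the
generating `c`. An optional MAF-power modulation (`maf_power = TRUE`) scales
each variant's polygenic term by `2 maf (1 - maf)` (unit mean), the
additive-coding genotype variance; it exists to reproduce the qualitative rise
of lambda as low-MAF variants are filtered (`lambda_maf_profile()`), and it is
off by default because it departs from the pure LDSR form and couples the
signal to the noisy rare-variant LD-score estimates.

**Study pairs.** `simulate_study_pair()` draws one set of true effects —
causal indicators at rate `prop_causal` (default 0.3, a highly polygenic
trait), effect variance proportional to `h2 l_j / M` — and two z-score vectors
`sqrt(N_s) * effect + noise_s` with study-specific confounding variance `c_s`.
Noise is independent between studies by default; `overlap` sets its
correlation for sample-overlap experiments. Default sample sizes (20,000 and
80,000 against M = 20,000 variants) keep the per-variant signal `N h2 / M` in
the regime of real meta-analyses (inflation factors ~1.4–1.8, mean chi-square
near 2). Scaling real-study sample sizes directly onto a desk-scale M would push
causal non-centralities past the LDSC chi-square cap and distort every
estimate; when the generator is run at M = 100,000 the defaults should be
scaled accordingly (the acceptance script uses N = 100,000 / 400,000 there).
Under these conditions the synthetic pairs reproduce the structure seen in
real data: lambda well above the LDSR intercept, with the intercept close to
the generating confounding level.

What the generator does **not** emulate: LD between the z-scores themselves
(effects are independent given l), imputation quality, allele-frequency drift
between studies, and case-control sampling at the phenotype level. Passing
tests therefore demonstrate correctness of the estimators and accounting under
the assumed model, not robustness to real-data pathologies.

## The LDSR fit

`ldsr_fit()` follows the standard LDSC recipe: variants with
`chisq > max(80, 0.001 N)` are removed; an initial weighted fit (reciprocal LD
score, counteracting over-counting of correlated variants) supplies expected
chi-squares; the final weights are `1 / (2 expected^2 max(l, 1))`, combining
the heteroskedasticity of chi-square variables with the over-counting term.
A delete-a-block jackknife over 200 contiguous blocks gives the optional
intercept standard error. Expected values in the weights are floored at 0.1 to
keep early-iteration weights finite. `h2_est = slope * M / N` is reported for
completeness; heritability accuracy is not a goal.

## Pairwise confirmation and its accounting

`harmonize_pair()` joins studies on (chromosome, position) and aligns alleles,
flipping the later study's beta and EAF when its allele order is swapped;
records with incompatible allele sets (including multi-allelic leftovers) are
dropped and tallied. `classify_pair()` labels each shared variant TP (robust:
significant in both with consistent direction), FP (earlier-only, or
both-significant with opposite directions), FN (later-only) or TN. A beta of
exactly zero on a doubly-significant variant counts as inconsistent (an
explicit, logged policy). Only the earlier study is ever corrected; the later
study is the confirmation reference and stays untouched.

`run_pairwise()` recomputes lambda and the intercept on the harmonized shared
variant set — published per-study values reflect different filtering, so
reusing them would not be comparable — then classifies before and after each
correction, computes percent-robust / percent-lost / FPR / TPR, runs the LOCO
resampling per state, and maps lost robust associations to clumps.

## LOCO resampling

For each chromosome, the observed confirmation rate `TP / (TP + FP)` over its
earlier-significant variants is compared with the rates of repeated draws of
an equal number of earlier-significant variants from all other chromosomes
(without replacement within a draw). Since every drawn variant is either
confirmed or not, the confirmed count in a draw is hypergeometric, which is
how the draws are generated — equivalent in distribution to enumerating
subsets, and validated in the tests against exact C(10,3) enumeration. The
empirical p-value is the min-tail form
`min(#{C_s <= c_obs}, #{C_s > c_obs}) / N`, with ties in the lower tail; its
maximum attainable value is 0.5. Chromosomes without earlier-significant
variants are reported absent rather than as zero, and a chromosome holding
more than half of all significant variants gets `NA` (no feasible null).
The default 100,000 samplings cost little; the reporting threshold defaults to
0.05 divided by the number of testable chromosomes.

## Clumping and loci loss

`greedy_clump()` implements the PLINK-style greedy rule: smallest-p unassigned
variant above the index threshold (5e-8) becomes an index; unassigned variants
above the secondary threshold (5e-6), within the window and with `r2 >= 0.20`
to the index, join its clump. "500 kb window" is read as a ±500 kb radius
around the index (the PLINK `--clump-kb` convention). Ties on p are broken by
(chromosome, position) ascending, making output invariant to row order. The
LD provider is either a haplotype panel (r2 from squared haplotype
correlation) or a printed pairwise r2 table, so toy fixtures are exact.
Variants absent from the provider become single-variant clumps flagged as
such.

Loci-loss accounting follows the workflow: tag clumps containing a
study-defined index variant (membership, never proximity); drop lost robust
associations inside the MHC interval chr6:28,477,797–33,448,354 (GRCh37),
where extreme LD defeats locus assignment (the MHC filter applies only to the
lost list, not to clump formation); exclude those in LD-absent single-variant
clumps; count the unique untagged clumps among the rest. The loss percentage
divides by lost-plus-identified loci, the total before correction.
Percentages are reported at full precision; any display rounding is left to
the caller. In a fully synthetic run the index list must be chosen with care:
deriving it from the same clump scan tags every clump and makes the metric
vacuously zero, so the acceptance analysis derives the index list at a
one-order-stricter threshold (5e-9), emulating the conservative character of
published loci lists. With a single borderline band both corrections sweep
the same untagged clumps, so the synthetic loci-loss percentages for GC and
LDSR can coincide even though GC always loses at least as many robust
associations.

## Numerical and design choices

* Medians of even-length samples are midpoints of the central order
  statistics.
* LD scores use a ±1 Mb physical window (a stand-in for LDSC's 1 cM; no
  genetic map is in scope) and the small-panel bias adjustment
  `r2 - (1 - r2)/(n_hap - 2)`, so scores may dip slightly below 1.
* Every stochastic operation takes an explicit integer seed; compound
  operations seed once and let sub-steps consume the stream, so identical
  configurations reproduce byte-identical outputs. Distinct stages use
  disjoint seed blocks — reusing one seed for the panel and the z-scores would
  replay the same underlying stream and couple signal to LD structure.
* The LOCO empirical p-value is deliberately two-sided in min-tail form, with
  ties between a sampled and the observed rate counted in the lower tail:
  a chromosome can be flagged for confirming either unusually well or
  unusually poorly, and the statistic's ceiling of 0.5 makes "perfectly
  typical" explicit. One-sided variants are a trivial change but are not what
  the reported tables assume.
* LOCO resampling is without replacement within each draw — the natural
  meaning of sampling a set of variants — which is exactly what the
  hypergeometric draw implements; draws are independent of one another.
* Published lambda values are accepted as inputs to `gc_uncorrect()`; whether
  they should ever be composed with a recomputed lambda is left to the caller,
  with both exposed as explicit parameters.

## Problem sizes

The test suite runs the generator at M = 20,000 (recovery, calibration) and
one end-to-end pair at M = 100,000 with 10,000 LOCO samplings; the acceptance
script uses M = 100,000 with the full 100,000 samplings and five independent
recovery simulations. These sizes give Monte-Carlo error comfortably inside
the stated tolerances (per-fit intercept sd ~0.07 at the recovery conditions)
while keeping a full run in minutes on one core.

## Limitations

The loci-loss metric depends on the provenance of the index-variant list, as
discussed above. The intercept estimator inherits LDSC's known fragilities:
with sparse causal architectures and large per-variant signal the chi-square
cap truncates true signal at high LD scores and biases the intercept upward —
visible here if the sample sizes are scaled far beyond the default regime, and
analogous to the real-data mismatch between reference-panel LD and
low-frequency variants. No multi-ancestry machinery, attenuation-ratio
diagnostics, or per-cohort (single) GC correction is included.
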