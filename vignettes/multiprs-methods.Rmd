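---
title: "Methods: multi-PRS analysis of general and specific child psychopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-PRS analysis of general and specific child psychopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiprs)
```

## The analysis this package implements

`multiprs` implements a multi-cohort analysis of how polygenic risk scores
(PRSs) for many psychiatric and psychological traits relate to general and
domain-specific psychopathology in children. The pipeline has five stages:

1. **C+T polygenic scoring.** For each discovery GWAS, summary statistics
   are QC-filtered (MAF ≥ 1%, INFO ≥ 0.80), harmonized to the target
   cohort's counted alleles, LD-clumped greedily (smallest p first,
   removing neighbours within a window whose dosage r² exceeds a cutoff),
   and summed into scores `PRS_i(T) = Σ_{j: p_j ≤ T} dosage_ij · β_j` at a
   grid of 15 p-value thresholds (1 down to 1e-8).
2. **Bifactor outcomes.** Symptom subscales from both internalizing and
   externalizing domains are modelled with one general factor loading on
   every subscale plus two orthogonal domain-specific factors; regression
   (Thurstone) factor scores `L' Σ⁻¹ y` serve as outcomes.
3. **Separate PRS models.** Each factor score is regressed on each PRS at
   each threshold (outcome and PRS z-scored, so coefficients are in SD
   units), adjusting for sex, age, and four ancestry components, with
   ΔR² versus the covariates-only model.
4. **Meta-analysis and multiplicity.** Per-cohort coefficients are pooled
   with DerSimonian–Laird between-study variance and inverse-variance
   weights; the p-value comes from the Han–Eskin RE2 likelihood-ratio test
   with its ½χ²₁ + ½χ²₂ asymptotic null. The number of effective tests is
   the Li–Ji count from the eigenvalues of the correlation matrix of all
   PRS columns in the largest cohort, giving a Bonferroni threshold α/Meff.
5. **Mutual adjustment and joint prediction.** All PRSs enter one
   regression at their best separate-model thresholds; a PRS is flagged as
   contributing *independently* when it is adjusted-significant separately
   and nominally significant (p < .05) mutually. The joint predictive
   value is a repeated (default 100×) 10-fold cross-validated ΔR².

The DL-dispersion/RE2-p combination in stage 4 is deliberate: reported
pooled coefficients, between-study SD τ and pooled SE use the moment
estimator, while significance uses the likelihood-ratio mixture test. On
published per-cohort estimates this combination reproduces the
corresponding published pooled cells within input-rounding error, whereas
a pure-ML pooling does not.

## The synthetic-data generator

No individual-level cohort data ship with the package; a generator
produces every input with known ground truth, under defaults chosen to
mirror the target study design: three cohorts of 6575/2418/254 children
(9247 total), 16 discovery traits with average pairwise genetic
correlation 0.4, twelve symptom subscales (six per domain), and the
15-threshold grid.

**Genotypes.** Dosages are sums of two independent haplotypes. Within an
LD block a haplotype is a first-order Markov chain of Bernoulli alleles:
the transition probabilities preserve the block's allele frequency exactly
and give adjacent-allele correlation exactly `within_block_rho` (default
0.8), so LD decays as `rho^distance` inside a block and vanishes across
blocks. One MAF is drawn per block (uniform on 0.05–0.5), which keeps any
requested correlation attainable; a Gaussian-copula construction was
rejected because its latent correlation is attenuated at the binary
margin and would not deliver the documented `r² ≈ rho²` between adjacent
dosages. Allele pairs follow a transition:transversion ratio of 2, so
strand-ambiguous A/T and C/G variants are ~1/6 of the panel, as on real
arrays. Blocks of 5 SNPs at 5 kb spacing start every 150 kb, so a ±250 kb
clumping window spans neighbouring blocks.

**Discovery GWAS.** A shared causal set (default 5% of SNPs) carries
per-trait effects drawn multivariate-normally with the configured genetic
correlation, scaled so the causal SNPs explain `h2_trait` (default 0.10)
of each trait. Reported estimates are *marginal* single-SNP effects — the
LD-weighted sum `Σ_k rho^|j-k| β_k` within the block — plus noise with
SE `1/sqrt(2·N·f(1−f))` (default N = 500,000). Marginal rather than
direct effects matter: C+T scoring relies on retained index SNPs tagging
the effects of clumped or dropped neighbours, which is exactly how real
summary statistics behave.

**Phenotypes.** The general factor is a weighted sum of the traits' true
standardized polygenic values plus Gaussian residual, scaled to unit
variance; specific factors are built the same way from their own weights
and residuals, so the three factors are orthogonal unless effects are
planted on the same trait for two factors. Subscales are
`λ_g·g + λ_s·s_domain + unique noise` with unit variance. Covariates are
sex, a cohort-specific uniform age window, and four standard-normal
ancestry components, with an optional planted confounding path from the
first component into the general factor (default 0). Default loadings
vary across subscales (general 0.45–0.70, specific 0.30–0.50). The
heterogeneity is not cosmetic: with exactly two specific factors and
loadings constant within domains, the bifactor model is under-identified —
a one-parameter family of loading patterns reproduces the covariance
matrix exactly — whereas heterogeneous loadings identify it generically.

**What the generator does not emulate:** realistic human LD maps and
allele-frequency spectra, pedigree structure, X-chromosome, imputation
artifacts, informant-specific method variance, or age-varying genetic
effects. Passing tests therefore demonstrate the statistical machinery is
correct under the assumed generative model, not that the pipeline is
robust to every pathology of real cohort data.

## Numerical and design choices

**Bifactor estimation.** Maximum likelihood on the sample correlation
matrix, minimizing `log det Σ + tr(SΣ⁻¹) − log det S − p` by L-BFGS-B
over general loadings, specific loadings and log-uniquenesses, with
analytic gradients (`∂F/∂Σ = Σ⁻¹(Σ−S)Σ⁻¹` chained through the loading
structure). The start is deterministic: general loadings from the first
principal component, specific loadings 0.2. Uniquenesses are bounded below
at 1e-4; a solution at the floor is reported as a Heywood case with a
warning, non-convergence is flagged rather than thrown, and an input with
essentially no common variance (all |off-diagonal| < .01) returns the
null fit with a degeneracy warning. Gradient tolerance 1e-8.

**Factor scores.** Regression scores are linear, closed-form and
testable, which is why they are used. They are *not* orthogonal across
factors even when the latent factors are: with the true loadings the
population correlation between an estimated specific score and the true
general factor is `[L'Σ⁻¹L]_{s,g}/√([L'Σ⁻¹L]_{s,s})`, around 0.3–0.4 at
the default loadings. Tests assert agreement with this closed form rather
than a spurious orthogonality.

**Clumping.** LD is computed in the target panel itself (as PRSice does
when no external reference is given). Ties on p break by ascending
(chromosome, position), making output invariant to input row order. The
window is ±`window_kb` around the index position; monomorphic variants
get r² = 0 with a warning. Strand-ambiguous variants are dropped, never
frequency-resolved, and counted in the harmonization report.

**Standardization.** PRS columns are z-scored before regression. The
study this emulates reports standardized coefficients, for which scaling
of the PRS is immaterial; standardizing also makes score columns
comparable across thresholds. Outcome and PRS are z-scored inside the
regression; covariates are left on their natural scales.

**Cross-validation.** Folds are a simple random partition per repeat;
out-of-fold R² is pooled as `1 − SSE/SST` across folds within a repeat
(lower variance than per-fold averaging), then averaged over repeats,
for the full and covariates-only models separately. Deterministic given
the seed. In-sample ΔR² is reported for separate per-PRS models and
cross-validated ΔR² for the joint model, matching the reporting
convention of the study design.

**Han–Eskin RE2.** The likelihood is maximized by profiling β out
analytically and optimizing the one-dimensional profile in τ² (boundary
τ² = 0 checked explicitly; grid-search fallback on optimizer failure).
The asymptotic mixture null is used throughout; the tabulated small-study
corrections are out of scope. A known consequence, quantified in the test
suite: at ten studies the asymptotic null is conservative — empirical
type-I error ≈ 0.03 at nominal 0.05 — so RE2 p-values near the threshold
are slightly cautious for few-cohort meta-analyses.

**Li–Ji Meff.** `ceiling(Σ f(|λ|))` with `f(x) = 1(x≥1) + (x − ⌊x⌋)`.
Eigenvalues are rounded at the tenth decimal first: `f` is discontinuous
at integers and floating-point fuzz below an exact eigenvalue of k would
otherwise inflate the count by ~1.

**Seeds.** A master seed deterministically derives per-stage seeds by
hashing stage labels, so cohorts share one variant map while drawing
independent dosages, and any stage can be re-run in isolation.

## Problem sizes used in the shipped tests

Unit tests run at n up to 10,000 individuals with small panels (tens to
hundreds of SNPs) for distributional checks. The end-to-end
parameter-recovery test uses three cohorts of 6,000, a 2,000-SNP panel,
identity genetic correlation (so non-planted traits are genuine nulls)
and a planted 0.10 SD general-factor effect for one trait; at this scale
a chance overlap of causal-effect vectors still induces real small
associations for "null" traits (sd ≈ 0.01 SD), which is why null-trait
assertions are bounds rather than exact rates. Calibration tests use
2,000 replicates. The worked meta-analysis examples run from published
per-cohort summary estimates and need no simulation.

## Known limitations

- Binary discovery traits are emulated on the observed scale; log-OR
  subtleties are ignored (the pipeline consumes effect sizes generically).
- Per-cohort bifactor models are fitted independently; no cross-cohort
  measurement-invariance constraints.
- The Clogg z-test treats the general- and specific-factor coefficient
  estimates as independent, justified here by construction-orthogonal
  factors; with strongly correlated factor scores it would be
  anti-conservative.
- RE2 p-values use the asymptotic null (see above).
- No mixed models for family structure, no interaction analyses, no
  Bayesian shrinkage scores.
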