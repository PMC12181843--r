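---
title: "Methods: DMR discovery, cohort validation and diagnostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR discovery, cohort validation and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrpipe)
```

# Scope and data model

`dmrpipe` implements a three-stage blood-methylation biomarker analysis for
a two-group (cognitively normal, CN, versus Alzheimer's disease, AD) design,
starting from per-CpG methylation calls — the pair (methylated reads, total
reads) per CpG site and sample, as produced by standard bisulfite aligners.
Read trimming, alignment and methylation extraction are out of scope; the
pipeline begins where the cytosine report ends.

Internally all coordinates are 1-based inclusive and keyed to the
plus-strand cytosine of the CpG dinucleotide; minus-strand calls at the
position one base 3' are summed onto it (CpG methylation is
strand-symmetric). The 0-based half-open convention appears only at the BED
boundary. A site missing from a sample is stored as coverage 0 and removed
by the coverage filter rather than imputed.

# Stage 1 — discovery: DMP calling and sliding-window DMR detection

## Per-CpG test

The default per-site test is a binomial-logistic likelihood-ratio test of
the group term, with one observation per sample (methylated successes out
of coverage). Because group is the only covariate, the fitted probability
of every sample is its group's pooled proportion, so the deviance
difference has a closed form and is computed vectorised across sites; it is
numerically identical to the `glm()` route (the test-suite checks this).
The binomial likelihood carries no overdispersion term; an optional
McCullagh–Nelder correction (`overdispersion = "MN"`) rescales the LRT
statistic by the Pearson dispersion of the full model and is recommended
when between-replicate variability is visible. A pooled Fisher's exact test
is available as `test = "fisher"`; with about a dozen replicates per group
the replicate-aware LRT is the default.

DMP thresholds default to coverage ≥ 10 in every sample, |Δβ| ≥ 0.15 and
BH q ≤ 0.01, where β is the methylation level (methylated/total, in
[0, 1]) and Δβ = mean β in AD minus mean β in CN (unweighted means of
per-sample rates). Multiple-testing correction is Benjamini–Hochberg over
exactly the tested (filter-passing) sites. Sex-chromosome exclusion is a
separate, explicit step (`exclude_regions`) applied to the DMP list, so its
removal count is reported on its own.

## Window criteria and the merge rule

A *window* is any genomic interval whose positional span is at most
`window_bp` (default 1000 bp, inclusive arithmetic: max − min ≤ 1000). A
window *qualifies* if it contains at least `k_lo = 5` same-direction DMPs
with |Δβ| ≥ 0.15, or at least `k_hi = 3` with |Δβ| ≥ 0.25. Only windows
whose endpoints are DMP positions need to be enumerated. All qualifying
windows on a chromosome and direction are merged transitively whenever they
overlap or share a DMP; each merged component is one DMR whose reported
span is the min/max position of its member DMPs (the span amplicons would
be designed against), which may well exceed 1 kb.

This enumerate-and-merge formulation is equivalent to "sliding" a
qualifying window outward in either direction for as long as some window
keeps qualifying: any chain of qualifying windows produced by sliding is a
chain of overlapping windows and lands in one merged component, while
qualifying windows separated by more than `window_bp` never touch and never
merge. Opposite-direction DMRs may abut but are never merged. Two
implementation notes are deliberate: (i) `call_dmrs` only inspects, for
each left endpoint, the *maximal* in-window right endpoint — counts are
monotone in the right endpoint, so a window starting at i qualifies iff the
maximal one does, and the maximal window contains every member that any
qualifying window starting at i contributes; (ii) `brute_force_dmrs`
ignores that optimisation and tests every index pair, with an explicit
interval-union merge. The two routes share nothing but the output contract,
and their equivalence on randomized instances is the module's central
acceptance property.

The count thresholds are plain configuration (`window_criteria()`); 5-at-
0.15 / 3-at-0.25 in 1 kb is the default, and stricter variants (e.g. 7/5)
are a one-argument change.

# Stage 2 — validation: Bonferroni screen, burden test, FDR, meta-analysis

Validation assumes deep targeted amplicon data over the candidate DMRs in
independent cohorts.

*Per-CpG screen.* Welch's t-test on per-sample methylation rates, two-sided,
with a Bonferroni flag whose denominator is the total number of CpGs
analysed in that cohort (not per DMR). Welch on rates was chosen because at
amplicon depth (~10³ reads) the binomial sampling noise is negligible
relative to between-subject variation, making a rate-level t-test the
natural test family; a count-level option exists for the discovery scale.
Sites with zero variance in both groups return p = 1 when the means agree
and are flagged degenerate otherwise.

*Burden test.* The methylation rates of the CpGs in one DMR are collapsed
into a per-sample burden `B_i = Σ_j w_j rate_ij` (flat weights by default)
and tested against the phenotype with a 1-df score test under the null
logistic model `phenotype ~ sex + age`:

    U   = Σ_i (y_i − μ̂_i) B_i
    Var = B'VB − B'VX (X'VX)⁻¹ X'VB,   V = diag(μ̂(1−μ̂))
    Q   = U² / Var  ~  χ²(1)

Flat weights are the default because rare-variant-style Beta-density
kernels, designed for allele frequencies near zero, are nearly constant
over intermediately methylated CpGs and a constant rescaling cannot change
a 1-df score test (the suite asserts this scale invariance); the
`weights = "beta"` option is kept for users who want the rare-variant
kernel form. Two numerical guards matter: a burden that is constant across
samples returns statistic 0 / p 1, and separation in the null fit triggers
a ridge-penalised IRLS refit (flagged in the result).

*Small samples.* The χ²(1) reference is an asymptotic approximation whose
error is O(1/n) — noticeable below a few dozen samples. When the null
model is intercept-only and the number of case/control arrangements is
enumerable (`choose(n, n_cases)` up to 2×10⁶), `burden_test` therefore
computes the *exact* permutation tail of the score statistic by complete
enumeration instead (`method = "auto"`); with covariates, where permutation
is not exchangeable, the asymptotic formula is used and its calibration at
n = 96 is verified by simulation in the test-suite.

*FDR and meta-analysis.* Burden p-values are converted to q-values with
Benjamini–Hochberg within a cohort. Cross-cohort combination uses signed
Stouffer: `z_k = Φ⁻¹(1 − p_k/2) · sign(Δβ_k)`, `z = Σ w_k z_k / √(Σ w_k²)`
with `w_k = √n_k`, reported two-sided. The two-sided-to-z conversion with
an explicit direction sign is used so that antagonistic evidence cancels;
a pooled alternative (refit on concatenated cohorts with a cohort
covariate) can be run through `burden_test` directly.

*Confirmation.* A DMR is confirmed when (1) at least 3 member CpGs pass the
per-CpG Bonferroni screen in cohort 2, (2) its burden BH q across the
eligible DMRs of cohort 2 is below 0.05, and (3) the cross-cohort meta p is
below 0.05. Each step is configurable.

# Stage 3 — diagnosis: marker selection, subset search, held-out AUC

Marker CpGs are those Bonferroni-significant in *both* validation cohorts
with concordant Δβ sign. Pooled samples are split into discovery (4/5,
stratified by label, seeded) and held-out validation (1/5). The model space
is every nonempty subset of the marker DMRs (one feature per member CpG,
i.e. 2^d − 1 candidates for d DMRs, refused above d = 20) plus the
covariate-only base model (age, sex, APOE ε4 allele count as a single
ordinal 0/1/2 feature). Each candidate is an elastic-net logistic
regression (mixing 0.5) whose penalty strength C ∈ {0.1, 1, 10, 100}
(`lambda = 1/(n·C)` in `glmnet` terms) is chosen on the same stratified CV
folds (3 by default) used to rank candidates by mean CV AUC; the winner is
refit on the full discovery set. Standardisation is glmnet's internal
scaling, fitted on whatever data the model is fitted on — training folds
during CV, the full discovery set for the final refit — never on held-out
data; a test asserts that appending pure-noise DMRs to a winning subset
buys no CV AUC beyond fold noise.

AUC is the Mann–Whitney statistic with midrank tie handling (equal, on
every instance, to exhaustive concordant-pair counting — an oracle test);
the 95% CI uses DeLong's method via pROC. Score orientation is fixed
(higher = AD), so a genuinely anti-predictive model reports AUC < 0.5
rather than being silently flipped. The fold-count sensitivity analysis
re-runs the search at 3, 5 and 10 folds and flags when the selected subset
changes — a useful overfitting smell at small n.

# The synthetic cohort generator

The generator is first-class, tested code: it defines the statistical
conditions under which every calibration and power claim in the test-suite
is made.

Per CpG j and sample i, coverage `c_ij` is drawn from the coverage model
and the methylated count from `BetaBinomial(c_ij, μ_ij, ρ)` with
`μ_ij = clip(π_j + Δ_j·I(AD_i) + slope_j·(age_i − mean age), [0,1])`.
Group effects are additive on the β scale (effect sizes throughout the
field are reported as percentage-point differences); a logit-scale option
exists but is off by default. Baselines π_j come from a three-component
Beta mixture — low (mean 0.05), intermediate (Beta(10,10)) and high (mean
0.95) with default weights 0.3/0.4/0.3 — reflecting that informative
blood markers tend to sit in intermediately methylated regions where a
level shift is visible.

Defaults, with reasons:

* **ρ = 0.01.** No per-CpG variance estimates exist to fit against, so
  this is a realism choice fixed up front: blood leukocyte methylation
  rates vary only modestly between subjects, and Δβ of ~5 percentage
  points at n = 48/48 should be strongly detectable per CpG at amplicon
  depth — which requires a per-sample rate SD around 0.05 at intermediate
  methylation, i.e. ρ ≈ 0.01.
* **Coverage.** `"mcseq"`: negative binomial, mean 30, dispersion 0.3
  (variance = mean + 0.3·mean²), emulating capture-sequencing depth
  heterogeneity — about 93% of sites reach 10× per sample, so the
  all-sample intersection filter keeps roughly 1/6 of sites at 24
  samples, a realistic attrition. `"amplicon"`: Poisson(1000).
  `"fixed"` (constant depth) is used for controlled calibration
  experiments where filter attrition would be a confound.
* **Demographics** follow the three cohort presets (group-wise age
  mean/SD, male fraction, APOE ε4 genotype frequencies). APOE is generated
  independent of methylation; its group-conditional frequencies alone give
  a covariate-only model a validation AUC near 0.78, matching the analytic
  Mann–Whitney AUC of the two genotype distributions (a test asserts
  this).
* **Sex chromosomes**: a configurable fraction of CpGs (default 0) can be
  placed on chrX/chrY purely to exercise the exclusion filter.

`config$seed` fully determines the output. The CpG layout and baselines
derive from the seed alone, so `cpg_layout()` lets you anchor implanted
DMR spans (`true_dmr_spec`) on real positions before simulating;
`resample_seed` (and `layout_seed` for amplicon cohorts) redraws only the
sampling stage over identical sites — the device used for replication and
winner's-curse experiments.

What the generator does *not* emulate: read-level artefacts (bisulfite
conversion failure, PCR duplicates, mapping bias), SNP-induced false
calls, cell-composition shifts, batch effects, and spatial correlation of
methylation beyond the implanted DMRs (non-DMR CpGs are independent).
Passing tests therefore demonstrate the statistical machinery under the
stated generative model, not robustness to those artefacts on real data.

# Numerical choices and degenerate inputs

* 0·log 0 = 0 in the likelihood; LRT statistics are floored at 0; sites
  with no variation return p = 1.
* μ is clipped to [10⁻⁶, 1 − 10⁻⁶] before beta-binomial sampling.
* BH uses `stats::p.adjust`; NA p-values are an error, never dropped
  silently.
* Meta-analysis clamps p at 10⁻³⁰⁰ before the z transform and floors the
  combined p at the smallest positive double.
* Exact burden enumeration is capped at 2×10⁶ arrangements
  (`choose(20, 10) = 184 756` enumerates in well under a second).
* Stratified splits redraw (up to 100 times, warning) if a class would be
  absent on either side; model ties in the subset ranking break toward
  the earlier-enumerated (smaller) subset.

# Problem sizes used by the test-suite

The suite exercises the pipeline at deliberately chosen scales: DMR-caller
equivalence on 500 random instances of 10–300 DMPs; null calibration of
the DMP test on 10 000 sites × 24 samples across 100 seeded runs; burden
calibration on 2 000 null simulations at n = 96 plus 20 exact-vs-Monte-
Carlo comparisons at n = 20 (10⁵ permutations each); validation operating
characteristics over 100 runs of paired 48/48 amplicon cohorts at Δβ ∈
{0.02, 0.05, 0.10}; and 50 seeded model-search runs at d = 5 DMRs. These
sizes make the whole suite run in a few minutes while leaving each
statistical claim with comfortable Monte-Carlo resolution.

# Known limitations

* The default DMP test ignores overdispersion; on strongly overdispersed
  data use `overdispersion = "MN"` or validate at the rate level. Type-I
  calibration claims hold for ρ = 0 counts.
* The burden test's asymptotic path shares the usual score-test
  small-sample liberality; below ~30 samples use the exact path (the
  default when no covariates are supplied).
* Gene-relative annotation implements a deliberately small vocabulary
  (promoter / exon–intron / exon / intron / intergenic) with fixed
  precedence; it is not a transcript-model-aware annotator.
* The exhaustive subset search is exponential in the number of DMRs and
  hard-capped; a greedy mode is the obvious extension for larger marker
  sets.
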