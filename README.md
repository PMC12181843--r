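# dmrpipe

Blood DNA methylation is a practical substrate for minimally invasive
disease biomarkers: methylation levels at CpG sites can be read from a
blood draw by targeted bisulfite sequencing, and case/control differences
at clusters of neighbouring CpGs — differentially methylated regions
(DMRs) — are more reproducible than single-site hits. `dmrpipe` is an R
package for the full marker-development arc on such data, aimed at
statisticians and bioinformaticians running two-group (e.g. cognitively
normal vs Alzheimer's disease) methylation studies:

1. **Discovery** — per-CpG differential methylation calling from
   methylation counts (binomial-logistic likelihood-ratio test across
   replicates; coverage ≥ 10, |Δβ| ≥ 0.15, BH q ≤ 0.01 by default,
   where β = methylated/total reads and Δβ = β̄(AD) − β̄(CN)), followed by
   sliding-window DMR detection: a region qualifies when some window of
   ≤ 1 kb holds ≥ 5 same-direction DMPs with |Δβ| ≥ 0.15 or ≥ 3 with
   |Δβ| ≥ 0.25, and overlapping qualifying windows merge into one DMR.
   A brute-force reference caller with the identical contract guards the
   efficient implementation.
2. **Validation** — in independent deep amplicon cohorts: Welch per-CpG
   tests with explicit Bonferroni denominators, a covariate-adjusted
   burden score test per DMR
   (Q = U²/Var, U = Σᵢ(yᵢ−μ̂ᵢ)Bᵢ, Bᵢ = Σⱼ wⱼ·rateᵢⱼ, null model
   `phenotype ~ sex + age`; exact permutation enumeration at small n),
   BH FDR across DMRs, signed-Stouffer cross-cohort meta-analysis, and a
   three-step confirmation rule.
3. **Diagnosis** — exhaustive DMR-subset search with elastic-net logistic
   regression (mixing 0.5, C ∈ {0.1, 1, 10, 100}) ranked by stratified
   3-fold cross-validated AUC on a 4/5 discovery split, held-out AUC with
   DeLong CI, and fold-count sensitivity analysis against a
   clinical-covariate base model (age, sex, APOE ε4 allele count).

A seeded beta-binomial cohort simulator (`simulate_cohort`,
`simulate_amplicon_cohort`) with implanted ground-truth DMRs, capture- or
amplicon-like coverage and realistic cohort demographics backs the entire
test-suite; see the methods vignette
(`vignettes/dmr-discovery-validation.Rmd`) for the model, defaults and
their rationale.

## Worked example

Simulate a small discovery cohort (12 CN vs 12 AD at 30×) with two
implanted DMRs, discover them, validate in two 48-vs-48 amplicon cohorts,
and build the diagnostic model:

```r
library(dmrpipe)

base <- synthetic_config(n_cpgs = 4000, chroms = paste0("chr", 1:6),
                         coverage = coverage_model("fixed", mean = 30), seed = 42)
lay <- cpg_layout(base)   # anchor implanted spans on real CpG positions
pos_on <- function(ch, i, k) {
  p <- lay$sites$pos[lay$sites$chrom == ch]; c(p[i], p[i + k - 1])
}
s1 <- pos_on("chr1", 30, 8); s2 <- pos_on("chr2", 60, 8)
specs <- list(true_dmr_spec("chr1", s1[1], s1[2], -0.30),
              true_dmr_spec("chr2", s2[1], s2[2], +0.25))
cfg  <- synthetic_config(n_cpgs = 4000, chroms = paste0("chr", 1:6),
                         coverage = coverage_model("fixed", mean = 30),
                         dmr_specs = specs, seed = 42)
sim  <- simulate_cohort(cfg)
disc <- run_discover(sim$calls, sim$samples)
#> DMP calling: 4000 sites tested, 14 DMPs (|delta beta| >= 0.15, q <= 0.01)
#> discover: 4000 sites -> 4000 tested -> 14 DMPs -> 14 post-X/Y -> 2 DMRs
disc$dmrs[, c("chrom", "start", "end", "n_cpgs", "direction", "mean_delta_beta", "rule")]
#>   chrom start   end n_cpgs direction mean_delta_beta rule
#> 1  chr1 15300 16077      8      hypo          -0.286 both
#> 2  chr2 22059 22813      5     hyper           0.241   lo
```

Both implanted regions are recovered, with the observed mean Δβ close to
the implanted −0.30/+0.25. Validation in two amplicon cohorts sharing the
same loci (`layout_seed`) produces the per-DMR burden/FDR/meta table and
the confirmation calls:

```r
dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(s1[1], s2[1]),
                   end = c(s1[2], s2[2]), name = c("DMR1", "DMR2"))
regions <- cbind(dmrs[, 1:3], n_cpgs = 9L)
amp <- function(coh, s) synthetic_config(
  n_cn = 48, n_ad = 48, coverage = coverage_model("amplicon"),
  dmr_specs = specs, demographics = cohort_demographics(coh),
  cohort = coh, seed = s)
co2 <- simulate_amplicon_cohort(amp("cohort2", 101), regions, layout_seed = 900)
co3 <- simulate_amplicon_cohort(amp("cohort3", 202), regions, layout_seed = 900)
val <- run_validate(list(co2, co3), dmrs)
val$confirmed[, c("dmr_id", "n_sig_cpgs_cohort2", "burden_q2", "meta_p", "confirmed")]
#>   dmr_id n_sig_cpgs_cohort2 burden_q2    meta_p confirmed
#> 1   DMR1                  9   2.4e-22 2.23e-308      TRUE
#> 2   DMR2                  9   2.4e-22 2.23e-308      TRUE
```

(Implanted effects of 25–30 percentage points at ~1000× depth are
overwhelming by design; real validated markers live nearer 5 points.)
Finally the model search over marker CpGs:

```r
markers <- select_marker_cpgs(val$per_cohort[[1]]$cpg, val$per_cohort[[2]]$cpg)
diag <- run_diagnose(list(co2, co3), markers)
#> diagnose: 4 candidates; winner DMR1: CV AUC 1.000, validation AUC 1.000 (base 0.792)
head(diag$search$table, 4)
#>      subset n_dmrs penalty_C cv_auc rank
#> 1      DMR1      1       0.1  1.000    1
#> 2      DMR2      1       0.1  1.000    2
#> 3 DMR1+DMR2      2       0.1  1.000    3
#> 4    (base)      0       0.1  0.778    4
```

The covariate-only base model sits near AUC 0.78 — exactly what the
group-conditional APOE ε4 genotype frequencies imply on their own — while
the methylation panels separate the simulated groups completely.

A thin command-line wrapper over the same functions ships in
`inst/scripts/dmrpipe` (subcommands `simulate`, `discover`, `validate`,
`diagnose`, all YAML-configurable and seeded).

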