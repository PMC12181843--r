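test_that("sample covariate tables match their generating parameters", {
  # cohort-2-style table of 96 rows
  tab <- sample_covariates(48, 48, cohort_demographics("cohort2"), seed = 1)
  expect_equal(nrow(tab), 96)
  expect_setequal(unique(tab$group), c("CN", "AD"))
  expect_true(all(tab$apoe_e4 %in% 0:2))
  expect_true(all(tab$age > 0))

  # law of large numbers: AD homozygote fraction ~ 5/48 = 0.104
  big <- sample_covariates(10000, 10000, cohort_demographics("cohort2"), seed = 2)
  homo_frac <- mean(big$apoe_e4[big$group == "AD"] == 2)
  expect_lt(abs(homo_frac - 5 / 48), 0.01)
  ad_age <- big$age[big$group == "AD"]
  expect_lt(abs(mean(ad_age) - 71.2), 0.15)
  expect_lt(abs(sd(ad_age) - 4.0), 0.15)

  # empty and invalid inputs
  expect_equal(nrow(sample_covariates(0, 0, seed = 1)), 0)
  expect_error(sample_covariates(-1, 5, seed = 1), "non-negative")
  bad <- cohort_demographics("cohort2")
  bad$cn$apoe_probs <- c(homo = 0.5, het = 0.5, non = 0.5)
  expect_error(sample_covariates(5, 5, bad, seed = 1), "sum to 1")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- synthetic_config(n_cpgs = 500, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$samples, b$samples)
  # serialized outputs byte-identical too
  d1 <- tempfile()
  d2 <- tempfile()
  write_cohort(a, d1)
  write_cohort(b, d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(
    unname(tools::md5sum(f1)),
    unname(tools::md5sum(file.path(d2, basename(f1))))
  )
})

test_that("counts never exceed coverage and truth is passed through", {
  cfg <- synthetic_config(
    n_cpgs = 400, seed = 3,
    dmr_specs = list(true_dmr_spec("chr1", 1, 10^9, -0.2))
  )
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$calls$meth <= sim$calls$cov))
  expect_true(all(sim$calls$meth >= 0))
  expect_identical(sim$truth, cfg$dmr_specs)
})

test_that("null configuration has no systematic group difference", {
  cfg <- synthetic_config(
    n_cpgs = 10000, seed = 5, rho = 0,
    coverage = coverage_model("fixed", mean = 30)
  )
  sim <- simulate_cohort(cfg)
  grp <- sim$samples$group[match(sim$calls$samples, sim$samples$id)]
  r <- meth_rates(sim$calls)
  dbar <- rowMeans(r[, grp == "AD"]) - rowMeans(r[, grp == "CN"])
  expect_lt(abs(mean(dbar)), 0.005)
})

test_that("implanted effect size is recovered at high coverage", {
  spec <- true_dmr_spec("chr1", 1000, 1090, -0.05)
  cfg <- synthetic_config(
    n_cn = 48, n_ad = 48, rho = 0,
    coverage = coverage_model("amplicon"),
    dmr_specs = list(spec), seed = 11,
    demographics = cohort_demographics("cohort2"), cohort = "cohort2"
  )
  regions <- data.frame(chrom = "chr1", start = 1000, end = 1090, n_cpgs = 7)
  sim <- simulate_amplicon_cohort(cfg, regions)
  grp <- sim$samples$group[match(sim$calls$samples, sim$samples$id)]
  r <- meth_rates(sim$calls)
  dbar <- rowMeans(r[, grp == "AD"]) - rowMeans(r[, grp == "CN"])
  expect_lt(abs(mean(dbar) - (-0.05)), 0.01)
})

test_that("beta-binomial variance follows the overdispersion identity", {
  # var of the per-site rate at fixed coverage c:
  # pi(1-pi) (1 + (c-1) rho) / c
  set.seed(21)
  rho <- 0.05
  pi0 <- 0.5
  c0 <- 40
  x <- bb_counts(4000, 1, c0, pi0, rho)
  v_emp <- var(as.vector(x$meth) / c0)
  v_theory <- pi0 * (1 - pi0) * (1 + (c0 - 1) * rho) / c0
  expect_lt(abs(v_emp - v_theory) / v_theory, 0.12)

  # generator route: sample variance across samples at one site
  cfg <- synthetic_config(
    n_cn = 400, n_ad = 0, n_cpgs = 60, rho = rho,
    baseline_weights = c(low = 0, intermediate = 1, high = 0),
    coverage = coverage_model("fixed", mean = c0), seed = 22,
    demographics = flat_demographics()
  )
  sim <- simulate_cohort(cfg)
  lay <- cpg_layout(cfg)
  r <- meth_rates(sim$calls)
  v_emp2 <- apply(r, 1, var)
  v_th2 <- lay$pi * (1 - lay$pi) * (1 + (c0 - 1) * rho) / c0
  expect_lt(median(abs(v_emp2 - v_th2) / v_th2), 0.25)
})

test_that("amplicon cohorts have the requested shape and validity", {
  # 108 CpGs across 6 loci, 48+48 samples -> 108 x 96
  regions <- data.frame(
    chrom = rep("chr5", 6),
    start = seq(1000, 51000, by = 10000),
    end = seq(1600, 51600, by = 10000),
    n_cpgs = c(18, 18, 18, 18, 18, 18)
  )
  cfg <- synthetic_config(
    n_cn = 48, n_ad = 48, coverage = coverage_model("amplicon"),
    seed = 9, demographics = cohort_demographics("cohort2"),
    cohort = "cohort2"
  )
  sim <- simulate_amplicon_cohort(cfg, regions)
  expect_equal(dim(sim$calls), c(108, 96))

  # single region, single sample
  cfg1 <- synthetic_config(
    n_cn = 1, n_ad = 0, coverage = coverage_model("amplicon"), seed = 4,
    demographics = flat_demographics()
  )
  one <- simulate_amplicon_cohort(
    cfg1, data.frame(chrom = "chr1", start = 100, end = 200, n_cpgs = 5)
  )
  expect_equal(dim(one$calls), c(5, 1))
  r <- meth_rates(one$calls)
  expect_true(all(r >= 0 & r <= 1, na.rm = TRUE))

  expect_error(
    simulate_amplicon_cohort(cfg1, data.frame(chrom = 1, start = 1, end = 2)[0, ]),
    "nonempty"
  )
  expect_error(
    simulate_amplicon_cohort(
      cfg1, data.frame(chrom = "chr1", start = 100, end = 200, n_cpgs = 0)
    ),
    "no CpGs"
  )
})

test_that("a DMR spec spanning no CpGs is rejected by name", {
  cfg <- synthetic_config(
    n_cpgs = 50, chroms = "chr1", seed = 2,
    dmr_specs = list(true_dmr_spec("chr9", 100, 200, 0.3))
  )
  expect_error(simulate_cohort(cfg), "chr9:100-200 contains no CpGs")
})

test_that("null amplicon p-values are approximately uniform", {
  cfg <- synthetic_config(
    n_cn = 24, n_ad = 24, rho = 0, coverage = coverage_model("amplicon"),
    seed = 31, demographics = flat_demographics()
  )
  regions <- data.frame(chrom = "chr1", start = 1, end = 50000, n_cpgs = 1000)
  sim <- simulate_amplicon_cohort(cfg, regions)
  grp <- sim$samples$group[match(sim$calls$samples, sim$samples$id)]
  p <- per_cpg_test(meth_rates(sim$calls), grp)$p_raw
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("downstream detection power is monotone in effect, coverage and n", {
  power_at <- function(delta, coverage_mean, n_per_group) {
    hits <- 0
    n_aff <- 0
    for (s in 1:3) {
      cfg <- synthetic_config(
        n_cn = n_per_group, n_ad = n_per_group, n_cpgs = 400,
        chroms = "chr1", rho = 0,
        coverage = coverage_model("fixed", mean = coverage_mean),
        dmr_specs = list(true_dmr_spec("chr1", 1, 10^9, -delta)),
        demographics = flat_demographics(), seed = 100 + s
      )
      sim <- simulate_cohort(cfg)
      dmps <- suppressMessages(call_dmps(sim$calls, sim$samples))
      hits <- hits + nrow(dmps)
      n_aff <- n_aff + 400
    }
    hits / n_aff
  }
  # |delta beta| grid
  p_delta <- vapply(c(0.10, 0.20, 0.30), power_at,
    0, coverage_mean = 30, n_per_group = 12)
  expect_true(all(diff(p_delta) >= 0))
  expect_gt(p_delta[3], p_delta[1])
  # coverage grid
  p_cov <- vapply(c(10, 30, 100), function(cm) power_at(0.2, cm, 12), 0)
  expect_true(all(diff(p_cov) >= -0.02))
  expect_gt(p_cov[3], p_cov[1])
  # sample-size grid
  p_n <- vapply(c(6, 12, 24), function(n) power_at(0.2, 30, n), 0)
  expect_true(all(diff(p_n) >= -0.02))
  expect_gt(p_n[3], p_n[1])
})
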