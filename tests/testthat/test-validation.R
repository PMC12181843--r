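test_that("per-CpG Welch test matches the closed-form oracle", {
  # explicit Welch t and Satterthwaite df on a 3-vs-3 toy case
  cn <- c(0.20, 0.35, 0.30)
  ad <- c(0.50, 0.40, 0.65)
  welch_oracle <- function(x, y) {
    se2 <- var(x) / length(x) + var(y) / length(y)
    t <- (mean(y) - mean(x)) / sqrt(se2)
    df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
      (var(y) / length(y))^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  rates <- rbind(c(cn, ad))
  res <- per_cpg_test(rates, c("CN", "CN", "CN", "AD", "AD", "AD"))
  expect_equal(res$p_raw, welch_oracle(cn, ad), tolerance = 1e-12)
  expect_equal(res$p_raw, t.test(ad, cn)$p.value, tolerance = 1e-12)
  expect_equal(res$delta_beta, mean(ad) - mean(cn))

  # identical group vectors -> t = 0, p = 1
  same <- rbind(c(0.3, 0.4, 0.5, 0.3, 0.4, 0.5))
  grp <- rep(c("CN", "AD"), each = 3)
  expect_equal(per_cpg_test(same, grp)$p_raw, 1)
  const <- rbind(c(0.3, 0.3, 0.5, 0.5))
  res2 <- per_cpg_test(const, c("CN", "CN", "AD", "AD"))
  expect_equal(res2$p_raw, 0)
  expect_true(res2$degenerate)
})

test_that("Bonferroni threshold uses the explicit test count", {
  # alpha 0.05 over 1251 CpGs -> threshold ~3.997e-5
  thr <- 0.05 / 1251
  expect_equal(thr, 3.996802558e-05, tolerance = 1e-9)
  expect_true(bonferroni_flag(3.9e-5, 0.05, 1251))
  expect_false(bonferroni_flag(4.1e-5, 0.05, 1251))
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  # q-monotone in p order and discovery count equals classic step-up
  set.seed(61)
  p <- runif(200)^2
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  alpha <- 0.1
  k <- max(c(0, which(sort(p) <= alpha * seq_along(p) / length(p))))
  expect_equal(sum(q <= alpha), k)
})

test_that("burden score test handles degenerate and rescaled inputs", {
  y <- rep(c(0, 1), each = 10)
  rates <- matrix(0.42, 4, 20) # identical for every sample
  expect_equal(burden_test(rates, y)$p_value, 1)
  set.seed(71)
  rates <- matrix(runif(60, 0.2, 0.8), 3, 20)
  a <- burden_test(rates, y, weights = c(1, 1, 1), method = "asymptotic")
  b <- burden_test(rates, y, weights = c(7, 7, 7), method = "asymptotic")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  e1 <- burden_test(rates, y, weights = c(1, 2, 3), method = "exact")
  e2 <- burden_test(rates, y, weights = c(2, 4, 6), method = "exact")
  expect_equal(e1$p_value, e2$p_value)
})

test_that("exact enumeration matches a Monte-Carlo permutation of the score", {
  set.seed(81)
  n <- 16
  y <- rep(c(0, 1), each = 8)
  rates <- matrix(runif(3 * n, 0.2, 0.8), 3)
  bt <- burden_test(rates, y, method = "exact")
  B <- colSums(rates)
  u_obs <- abs(sum((y - mean(y)) * B))
  # centring: sum over cases minus n1 * mean(B)
  perm <- replicate(20000, abs(sum(B[sample.int(n, 8)]) - 8 * mean(B)))
  p_mc <- mean(perm >= u_obs - 1e-12)
  expect_lt(abs(bt$p_value - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 20000) + 1e-6)
  expect_equal(bt$method, "exact")
})

test_that("asymptotic burden p-values are valid with covariates", {
  # age drives methylation but not phenotype: p should be uniform
  set.seed(91)
  n <- 48
  p <- replicate(400, {
    y <- rep(c(0, 1), each = n)
    age <- rnorm(2 * n, 70, 3)
    sexm <- rbinom(2 * n, 1, 0.5)
    rates <- t(replicate(8, plogis(qlogis(0.5) + 0.05 * (age - 70) + rnorm(2 * n, 0, 0.2))))
    burden_test(rates, y, data.frame(sex = sexm, age = age),
      method = "asymptotic"
    )$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("covariate adjustment removes age confounding", {
  # age differs between groups AND drives methylation: unadjusted test is
  # anticonservative under no true group effect, adjusted is calibrated
  set.seed(101)
  n <- 48
  sim_p <- function(adjust) {
    replicate(300, {
      y <- rep(c(0, 1), each = n)
      age <- rnorm(2 * n, 70 + 6 * y, 2.5)
      rates <- t(replicate(
        8, plogis(qlogis(0.5) + 0.08 * (age - mean(age)) + rnorm(2 * n, 0, 0.15))
      ))
      cv <- if (adjust) data.frame(age = age) else NULL
      burden_test(rates, y, cv, method = "asymptotic")$p_value
    })
  }
  rej_unadj <- mean(sim_p(FALSE) <= 0.05)
  rej_adj <- mean(sim_p(TRUE) <= 0.05)
  expect_gt(rej_unadj, 0.20)
  expect_lt(rej_adj, 0.10)
})

test_that("separation in the null fit falls back to a penalised fit", {
  y <- rep(c(0, 1), each = 6)
  sep <- data.frame(z = y * 10) # perfectly separating covariate
  set.seed(5)
  rates <- matrix(runif(24, 0.3, 0.7), 2)
  bt <- burden_test(rates, y, sep, method = "asymptotic")
  expect_true(bt$null_penalized)
  expect_true(bt$p_value > 0 && bt$p_value <= 1)
})

test_that("signed Stouffer combination follows the closed form", {
  # two same-direction p = 0.05: z = 2 * 1.95996 / sqrt(2) = 2.7718
  m <- meta_analyze(c(0.05, 0.05), c(-1, -1))
  z <- qnorm(1 - 0.025)
  expect_equal(m$meta_z, -2 * z / sqrt(2), tolerance = 1e-9)
  expect_equal(m$meta_p, 2 * pnorm(-2 * z / sqrt(2)), tolerance = 1e-9)

  # antagonistic evidence is worse than the best single cohort
  ant <- meta_analyze(c(1e-6, 1.0), c(1, -1), weights = c(1, 1))
  expect_gt(ant$meta_p, 1e-6)

  # duplicated identical evidence strengthens it (z scales by sqrt(k))
  one <- meta_analyze(c(0.03, 0.03), c(1, 1))
  expect_lt(one$meta_p, 0.03)
  four <- meta_analyze(rep(0.03, 4), rep(1, 4))
  z1 <- qnorm(1 - 0.03 / 2)
  expect_equal(four$meta_z, sqrt(4) * z1, tolerance = 1e-9)

  expect_warning(meta_analyze(0.2, 1), "single cohort")
})

test_that("confirmation rule chain applies eligibility, FDR and meta steps", {
  mk_cohort <- function(p_burden, delta, n_sig, n = 96) {
    ids <- paste0("D", seq_along(p_burden))
    cpg <- do.call(rbind, lapply(seq_along(ids), function(k) {
      ns <- n_sig[k]
      data.frame(
        dmr_id = ids[k],
        significant_bonferroni = c(rep(TRUE, ns), rep(FALSE, 5 - ns))
      )
    }))
    burden <- data.frame(
      dmr_id = ids, p_value = p_burden, delta_beta = delta, testable = TRUE
    )
    list(cpg = cpg, burden = burden, n = n)
  }
  c2 <- mk_cohort(c(0.001, 0.002, 0.003), c(-0.05, -0.05, -0.05), c(5, 2, 5))
  c3 <- mk_cohort(c(0.04, 0.001, 0.9), c(-0.04, -0.05, 0.05), c(5, 5, 5))
  out <- confirm_dmrs(c2, c3)
  # D2 fails eligibility (only 2 significant CpGs)
  expect_false(out$eligible[out$dmr_id == "D2"])
  expect_false(out$confirmed[out$dmr_id == "D2"])
  # D1 passes all three steps
  expect_true(out$confirmed[out$dmr_id == "D1"])
  # D3: antagonistic cohort-3 evidence weakens the meta p
  expect_gt(out$meta_p[out$dmr_id == "D3"], out$meta_p[out$dmr_id == "D1"])

  # a burden q just above threshold is rejected at step 2
  c2b <- mk_cohort(c(0.06, 0.001), c(-0.05, -0.05), c(5, 5))
  c3b <- mk_cohort(c(0.5, 0.001), c(-0.05, -0.05), c(5, 5))
  out2 <- confirm_dmrs(c2b, c3b)
  q_d1 <- out2$burden_q2[out2$dmr_id == "D1"]
  expect_gt(q_d1, 0.05)
  expect_false(out2$confirmed[out2$dmr_id == "D1"])

  # a DMR absent from one cohort is excluded with a warning
  c3c <- mk_cohort(0.01, -0.05, 5)
  expect_warning(out3 <- confirm_dmrs(c2b, c3c), "absent")
  expect_equal(out3$dmr_id, "D1")
})

test_that("validate_cohort assembles per-CpG and burden results", {
  spec <- true_dmr_spec("chr1", 1000, 1120, -0.05)
  cfg <- synthetic_config(
    n_cn = 48, n_ad = 48, coverage = coverage_model("amplicon"),
    dmr_specs = list(spec), seed = 15,
    demographics = cohort_demographics("cohort2"), cohort = "cohort2"
  )
  regions <- data.frame(
    chrom = c("chr1", "chr1"), start = c(1000, 5000), end = c(1120, 5100),
    name = c("sig", "null"), n_cpgs = c(7, 7)
  )
  sim <- simulate_amplicon_cohort(cfg, regions)
  res <- suppressMessages(validate_cohort(
    sim$calls, sim$samples,
    data.frame(
      chrom = regions$chrom, start = regions$start, end = regions$end,
      name = regions$name
    )
  ))
  expect_equal(nrow(res$cpg), 14)
  expect_equal(unique(res$cpg$m_tests), 14)
  expect_equal(sort(res$burden$dmr_id), c("null", "sig"))
  expect_lt(
    res$burden$p_value[res$burden$dmr_id == "sig"],
    res$burden$p_value[res$burden$dmr_id == "null"]
  )
  expect_lt(abs(res$burden$delta_beta[res$burden$dmr_id == "sig"] + 0.05), 0.03)
})
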