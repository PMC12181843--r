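mk_cpg_results <- function(p, delta, m, dmr_id, chrom = "chr1",
                           pos = seq_along(p) * 100L) {
  data.frame(
    chrom = chrom, pos = pos, dmr_id = dmr_id, delta_beta = delta,
    p_raw = p, m_tests = m, stringsAsFactors = FALSE
  )
}

test_that("marker selection requires dual significance and concordant sign", {
  r2 <- mk_cpg_results(
    p = c(1e-6, 1e-6, 0.5, 1e-6), delta = c(-0.1, -0.1, -0.1, 0.1),
    m = 4, dmr_id = c("A", "A", "B", "B")
  )
  r3 <- mk_cpg_results(
    p = c(1e-6, 0.9, 1e-6, 1e-6), delta = c(-0.1, -0.1, -0.1, -0.1),
    m = 4, dmr_id = c("A", "A", "B", "B")
  )
  out <- select_marker_cpgs(r2, r3)
  # CpG1: sig both, same sign -> kept. CpG2: not sig in c3. CpG3: not sig
  # in c2. CpG4: sig both but opposite signs -> excluded.
  expect_equal(out$pos, 100L)
  expect_equal(out$dmr_id, "A")
  expect_equal(out$direction, "hypo")
  # all-null cohort 3 gives an empty marker set
  r3null <- mk_cpg_results(
    p = rep(0.5, 4), delta = r3$delta, m = 4, dmr_id = r3$dmr_id
  )
  expect_equal(nrow(select_marker_cpgs(r2, r3null)), 0)
  # a site present in only one cohort warns
  expect_warning(select_marker_cpgs(r2[-1, ], r3), "only one cohort")
})

test_that("the discovery/validation split is stratified and reproducible", {
  labels <- rep(c(0, 1), each = 96) # pooled cohorts 2+3
  s1 <- split_discovery_validation(labels, 0.8, seed = 3)
  s2 <- split_discovery_validation(labels, 0.8, seed = 3)
  expect_identical(s1, s2)
  expect_equal(length(s1$discovery), 154) # round(96*0.8) per class = 77
  expect_equal(length(s1$validation), 38)
  expect_equal(sum(labels[s1$discovery]), 77)
  s3 <- split_discovery_validation(rep(c(0, 1), each = 10), 0.5, seed = 1)
  expect_equal(length(s3$discovery), 10)
  expect_equal(sum(labels[s1$validation] == 0), 19)
})

test_that("AUC equals the exhaustive concordant-pair count", {
  # hand cases
  expect_equal(evaluate_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(evaluate_auc(rep(0.5, 6), rep(c(0, 1), 3))$auc, 0.5)
  # CN {0.3, 0.6}, AD {0.5, 0.9}: 3 of 4 pairs concordant
  expect_equal(evaluate_auc(c(0.3, 0.6, 0.5, 0.9), c(0, 0, 1, 1))$auc, 0.75)

  pair_count_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(201)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
    ev <- evaluate_auc(scores, labels)
    expect_equal(ev$auc, pair_count_auc(scores, labels), tolerance = 1e-12)
    expect_true(ev$ci_low <= ev$auc && ev$auc <= ev$ci_high)
  }
  expect_error(evaluate_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})


test_that("model search enumerates all subsets plus the base model", {
  s <- sim_features(40, informative = c(1, 2), seed = 211)
  search <- search_models(s$X, s$y, s$dmr, s$covar, seed = 1)
  expect_equal(nrow(search$table), 2^5) # 31 subsets + base
  expect_equal(sum(search$table$subset == "(base)"), 1)
  expect_true(all(diff(search$table$cv_auc) <= 0)) # ranked
  expect_error(
    search_models(s$X, s$y, s$dmr, s$covar, max_dmrs = 3),
    "exhaustive"
  )
})

test_that("the winner is consistent and leakage-free", {
  # informative DMRs are found
  hits <- 0
  for (i in 1:15) {
    s <- sim_features(40, informative = c(1, 2), seed = 300 + i)
    search <- search_models(s$X, s$y, s$dmr, s$covar, seed = i)
    hits <- hits + any(c("D1", "D2") %in% search$winner$subset)
  }
  expect_gte(hits / 15, 0.9)

  # adding pure-noise DMRs to the winning subset does not buy CV AUC
  # beyond fold noise (guards against selection leakage)
  diffs <- vapply(1:10, function(i) {
    s <- sim_features(40, informative = c(1), seed = 400 + i)
    search <- search_models(s$X, s$y, s$dmr, s$covar, seed = i)
    tab <- search$table
    a1 <- tab$cv_auc[tab$subset == "D1"]
    noisy <- tab$cv_auc[grepl("^D1\\+", tab$subset) | grepl("\\+D1\\+", tab$subset)]
    max(noisy) - a1
  }, 0)
  expect_lt(mean(diffs), 0.05)
})

test_that("a null base model scores near AUC 0.5 and an APOE base model near
           its analytic genotype AUC", {
  # zero signal anywhere: validation AUC of the base model ~ 0.5
  aucs <- vapply(1:8, function(i) {
    s <- sim_features(96, informative = c(), apoe_signal = FALSE, seed = 500 + i)
    sp <- split_discovery_validation(s$y, 0.8, seed = i)
    search <- search_models(
      s$X[sp$discovery, ], s$y[sp$discovery], s$dmr,
      s$covar[sp$discovery, , drop = FALSE], seed = i
    )
    evaluate_auc(
      predict_scores(search, s$X[sp$validation, ],
        s$covar[sp$validation, , drop = FALSE],
        model = "base"
      ),
      s$y[sp$validation]
    )$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)

  # with Table-1-style genotype frequencies the base model concentrates at
  # the analytic Mann-Whitney AUC of the genotype distribution
  pr_cn <- c(2, 15, 79) / 96 # homo, het, non
  pr_ad <- c(11, 49, 36) / 96
  # AUC = P(apoe_ad > apoe_cn) + 0.5 P(equal), counts ordered non<het<homo
  cn <- rev(pr_cn)
  ad <- rev(pr_ad)
  analytic <- sum(outer(seq_along(ad), seq_along(cn), function(i, j) {
    ad[i] * cn[j] * ((i > j) + 0.5 * (i == j))
  }))
  aucs2 <- vapply(1:8, function(i) {
    s <- sim_features(96, informative = c(), apoe_signal = TRUE, seed = 600 + i)
    sp <- split_discovery_validation(s$y, 0.8, seed = i)
    search <- search_models(
      s$X[sp$discovery, ], s$y[sp$discovery], s$dmr,
      s$covar[sp$discovery, , drop = FALSE], seed = i
    )
    evaluate_auc(
      predict_scores(search, s$X[sp$validation, ],
        s$covar[sp$validation, , drop = FALSE],
        model = "base"
      ),
      s$y[sp$validation]
    )$auc
  }, 0)
  expect_lt(abs(mean(aucs2) - analytic), 0.06)
})

test_that("sensitivity analysis reports one row per fold count", {
  s <- sim_features(60, informative = c(2), seed = 701)
  sp <- split_discovery_validation(s$y, 0.8, seed = 7)
  sens <- sensitivity_analysis(
    s$X, s$y, s$dmr, s$covar,
    discovery = sp$discovery, validation = sp$validation,
    folds_list = c(3, 5, 10), seed = 7
  )
  expect_equal(sens$cv_folds, c(3, 5, 10))
  expect_true(all(sens$validation_auc >= 0 & sens$validation_auc <= 1))
  expect_false(sens$subset_changed[1])
  # deterministic given the seed
  sens2 <- sensitivity_analysis(
    s$X, s$y, s$dmr, s$covar,
    discovery = sp$discovery, validation = sp$validation,
    folds_list = c(3, 5, 10), seed = 7
  )
  expect_identical(sens, sens2)
  # single-value penalty grid still works
  sens3 <- sensitivity_analysis(
    s$X, s$y, s$dmr, s$covar,
    discovery = sp$discovery, validation = sp$validation,
    folds_list = 3, penalty_grid = 1, seed = 7
  )
  expect_equal(nrow(sens3), 1)
})
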