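# Validation of candidate DMRs in independent amplicon cohorts:
# per-CpG Welch tests with Bonferroni control, a covariate-adjusted burden
# score test per DMR with BH FDR, cross-cohort meta-analysis, and the
# confirmation rule chain.

# vectorised Welch t-test across rows of two rate matrices
.welch_rows <- function(x_cn, x_ad) {
  n1 <- ncol(x_cn)
  n2 <- ncol(x_ad)
  m1 <- rowMeans(x_cn)
  m2 <- rowMeans(x_ad)
  v1 <- row_vars(x_cn)
  v2 <- row_vars(x_ad)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- is.finite(v1) & is.finite(v2) & (v1 + v2 == 0)
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  attr(p, "degenerate") <- degenerate
  p
}

#' Per-CpG group comparison on methylation rates
#'
#' Two-sided Welch t-test of per-sample methylation rates between CN and AD
#' at each site. Zero variance in both groups yields p = 1 (equal means) or
#' p = 0 flagged as degenerate (different means).
#'
#' @param rates numeric matrix, sites x samples, in `[0, 1]`.
#' @param groups group label per sample (`"CN"`/`"AD"`).
#' @return data.frame `beta_cn`, `beta_ad`, `delta_beta`, `p_raw`, plus a
#'   `degenerate` flag column.
#' @export
per_cpg_test <- function(rates, groups) {
  rates <- as.matrix(rates)
  stopifnot(
    ncol(rates) == length(groups),
    all(groups %in% c("CN", "AD")),
    sum(groups == "CN") >= 2, sum(groups == "AD") >= 2,
    all(is.na(rates) | (rates >= 0 & rates <= 1))
  )
  x_cn <- rates[, groups == "CN", drop = FALSE]
  x_ad <- rates[, groups == "AD", drop = FALSE]
  p <- .welch_rows(x_cn, x_ad)
  data.frame(
    beta_cn = rowMeans(x_cn), beta_ad = rowMeans(x_ad),
    delta_beta = rowMeans(x_ad) - rowMeans(x_cn),
    p_raw = as.numeric(p), degenerate = attr(p, "degenerate")
  )
}

#' Bonferroni significance flag
#'
#' @param p raw p-value(s).
#' @param alpha family-wise error level.
#' @param m number of tests (the explicit Bonferroni denominator, e.g. the
#'   total number of CpGs analysed in the cohort).
#' @return logical: `p <= alpha / m`.
#' @export
bonferroni_flag <- function(p, alpha = 0.05, m) {
  stopifnot(m >= 1, alpha > 0, alpha <= 1)
  p <= alpha / m
}

# ridge-penalised logistic null fit (IRLS); fallback under separation
.ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X))
  pen[1, 1] <- 0 # do not penalise the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  stats::plogis(drop(X %*% beta))
}

#' Covariate-adjusted burden score test for one DMR
#'
#' Collapses the methylation rates of the CpGs in a DMR into a per-sample
#' burden `B_i = sum_j w_j rate_ij` and tests it against the binary
#' phenotype with a 1-df score test under the null logistic model
#' `phenotype ~ covariates`: `Q = U^2 / Var(U)` with
#' `U = sum_i (y_i - mu_i) B_i` and
#' `Var = B'VB - B'VX (X'VX)^-1 X'VB`, `V = diag(mu(1-mu))`.
#'
#' With no covariates and an enumerable case/control arrangement count the
#' p-value is instead the exact permutation tail of the score statistic
#' (complete enumeration); the asymptotic chi-square(1) p is used otherwise.
#' The test is invariant to positive rescaling of the weights.
#'
#' @param rates matrix of methylation rates, CpGs x samples (a vector is
#'   treated as one CpG).
#' @param phenotype binary vector (0 = CN, 1 = AD) or `"CN"`/`"AD"` labels.
#' @param covariates data.frame of adjustment covariates (default use case:
#'   `sex` and `age`), or `NULL`.
#' @param weights `"flat"` (default), `"beta"` (Beta(1,25) density at the
#'   mean rate of each CpG, a rare-variant-style kernel), or a numeric
#'   vector.
#' @param method `"auto"` (exact when possible, default), `"exact"`, or
#'   `"asymptotic"`.
#' @param max_enumeration largest `choose(n, n_cases)` enumerated exactly.
#' @return list with `statistic` (Q), `p_value`, `n_cpgs`, `weights`
#'   (label), `method` (`"exact"`/`"asymptotic"`), `null_penalized`
#'   (TRUE when the null fit showed separation and a ridge-penalised fit
#'   was substituted).
#' @export
burden_test <- function(rates, phenotype, covariates = NULL,
                        weights = "flat",
                        method = c("auto", "exact", "asymptotic"),
                        max_enumeration = 2e6) {
  method <- match.arg(method)
  if (is.vector(rates)) rates <- matrix(rates, nrow = 1)
  rates <- as.matrix(rates)
  if (is.character(phenotype)) phenotype <- as.integer(phenotype == "AD")
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(ncol(rates) == n, all(y %in% c(0, 1)), nrow(rates) >= 1)
  if (sum(y) == 0 || sum(y) == n) stop("phenotype must have both classes")
  w_label <- "custom"
  if (is.character(weights)) {
    w_label <- weights
    weights <- switch(weights,
      flat = rep(1, nrow(rates)),
      beta = stats::dbeta(pmin(rowMeans(rates), 1 - 1e-8), 1, 25),
      stop("unknown weights: ", weights)
    )
  }
  stopifnot(length(weights) == nrow(rates), all(weights >= 0))
  B <- drop(crossprod(rates, weights))

  no_covar <- is.null(covariates) || ncol(as.data.frame(covariates)) == 0
  null_penalized <- FALSE
  if (no_covar) {
    X <- matrix(1, n, 1)
    mu <- rep(mean(y), n)
  } else {
    covariates <- as.data.frame(covariates)
    Xdf <- stats::model.matrix(~., data = covariates)
    if (qr(Xdf)$rank < ncol(Xdf)) stop("covariate matrix is rank deficient")
    fit <- suppressWarnings(stats::glm.fit(Xdf, y, family = stats::binomial()))
    mu <- fit$fitted.values
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8) || !fit$converged) {
      mu <- .ridge_logistic(Xdf, y)
      null_penalized <- TRUE
    }
    X <- Xdf
  }
  V <- mu * (1 - mu)
  U <- sum((y - mu) * B)
  XtVX <- crossprod(X, X * V)
  XtVB <- crossprod(X, V * B)
  varB <- sum(V * B^2) - drop(crossprod(XtVB, solve(XtVX, XtVB)))
  if (varB <= 1e-12 * max(1, sum(V * B^2))) {
    return(list(
      statistic = 0, p_value = 1, n_cpgs = nrow(rates), weights = w_label,
      method = "degenerate", null_penalized = null_penalized
    ))
  }
  Q <- U^2 / varB

  n1 <- sum(y)
  use_exact <- method == "exact" ||
    (method == "auto" && no_covar && choose(n, n1) <= max_enumeration)
  if (use_exact) {
    if (!no_covar) stop("exact enumeration requires an intercept-only null")
    if (choose(n, n1) > max_enumeration) {
      stop("too many case/control arrangements for exact enumeration")
    }
    # exact permutation null of the score statistic: U is monotone in the
    # case-group burden sum, so enumerate all case subsets of size n1
    cmb <- utils::combn(n, n1)
    sums <- colSums(matrix(B[cmb], nrow = n1))
    u_all <- abs(sums - n1 * sum(mu * B) / sum(mu))
    p <- mean(u_all >= abs(U) - 1e-12)
    meth_label <- "exact"
  } else {
    p <- stats::pchisq(Q, df = 1, lower.tail = FALSE)
    meth_label <- "asymptotic"
  }
  list(
    statistic = Q, p_value = p, n_cpgs = nrow(rates), weights = w_label,
    method = meth_label, null_penalized = null_penalized
  )
}

#' Combine per-cohort p-values (signed Stouffer)
#'
#' Default method: `z_k = qnorm(1 - p_k / 2) * sign_k`, meta
#' `z = sum(w_k z_k) / sqrt(sum(w_k^2))`, two-sided meta p. Direction signs
#' are taken from the per-cohort effect estimates so antagonistic evidence
#' cancels. A pooled alternative (refitting the burden test on concatenated
#' cohorts with a cohort covariate) is available through [burden_test()]
#' directly.
#'
#' @param p per-cohort two-sided p-values.
#' @param direction per-cohort signed effects (only the sign is used).
#' @param weights per-cohort weights; conventionally `sqrt(n_k)`. Default
#'   equal.
#' @return list with `meta_p`, `meta_z`, `method`.
#' @export
meta_analyze <- function(p, direction, weights = NULL) {
  k <- length(p)
  stopifnot(length(direction) == k, all(p > 0 | p == 0), all(p <= 1))
  if (k == 1) {
    warning("single cohort: meta-analysis is a passthrough")
    return(list(meta_p = p, meta_z = NA_real_, method = "passthrough"))
  }
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights > 0))
  pc <- pmin(pmax(p, 1e-300), 1)
  z <- stats::qnorm(1 - pc / 2) * sign(direction)
  meta_z <- sum(weights * z) / sqrt(sum(weights^2))
  meta_p <- max(2 * stats::pnorm(-abs(meta_z)), .Machine$double.xmin)
  list(meta_p = meta_p, meta_z = meta_z, method = "stouffer")
}

#' Validate candidate DMRs in one amplicon cohort
#'
#' Runs the per-CpG Welch screen (Bonferroni denominator = all CpGs
#' analysed in the cohort) and the sex/age-adjusted burden test per DMR
#' with BH FDR across DMRs.
#'
#' @param calls a [meth_matrix()] restricted to the amplified regions.
#' @param samples sample sheet (`id`, `group`, `sex`, `age`, ...).
#' @param dmrs data.frame of DMR intervals (`chrom`, `start`, `end`, and
#'   optionally `name`); CpGs are assigned to the DMR whose span contains
#'   them.
#' @param alpha per-CpG family-wise level for the Bonferroni flag.
#' @param min_cov sites must reach this coverage in every sample.
#' @param covariates character vector of sample-sheet columns to adjust
#'   for (default sex and age).
#' @param weights burden weights, see [burden_test()].
#' @return list with `cpg` (per-CpG results incl. `dmr_id`,
#'   `significant_bonferroni`, `m_tests`), `burden` (per-DMR statistic, p,
#'   `fdr_q`, mean `delta_beta`), and `n` (samples).
#' @export
validate_cohort <- function(calls, samples, dmrs, alpha = 0.05,
                            min_cov = 10,
                            covariates = c("sex", "age"),
                            weights = "flat") {
  stopifnot(inherits(calls, "meth_matrix"), nrow(dmrs) >= 1)
  grp <- samples$group[match(calls$samples, samples$id)]
  if (anyNA(grp)) stop("samples missing from the sample sheet")
  fm <- filter_min_coverage(calls, min_cov, mode = "all_samples")
  if (nrow(fm$sites) == 0) stop("no sites pass the coverage filter")
  rates <- fm$meth / fm$cov
  dmr_name <- if (!is.null(dmrs$name)) dmrs$name else {
    sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end)
  }
  dmr_id <- rep(NA_character_, nrow(fm$sites))
  for (k in seq_len(nrow(dmrs))) {
    inside <- fm$sites$chrom == dmrs$chrom[k] &
      fm$sites$pos >= dmrs$start[k] & fm$sites$pos <= dmrs$end[k]
    dmr_id[inside] <- dmr_name[k]
  }
  cpg <- cbind(
    fm$sites[, c("chrom", "pos")],
    dmr_id = dmr_id,
    per_cpg_test(rates, grp)
  )
  m <- nrow(cpg)
  cpg$m_tests <- m
  cpg$significant_bonferroni <- bonferroni_flag(cpg$p_raw, alpha, m)

  cov_df <- samples[match(fm$samples, samples$id), covariates, drop = FALSE]
  if ("sex" %in% names(cov_df)) {
    cov_df$sex <- as.integer(cov_df$sex == "male")
  }
  y <- as.integer(grp == "AD")
  burden <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(k) {
    idx <- which(dmr_id == dmr_name[k])
    if (length(idx) == 0) {
      return(data.frame(
        dmr_id = dmr_name[k], statistic = NA_real_, p_value = NA_real_,
        n_cpgs_used = 0L, delta_beta = NA_real_, testable = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    bt <- burden_test(rates[idx, , drop = FALSE], y, cov_df,
      weights = weights, method = "asymptotic"
    )
    data.frame(
      dmr_id = dmr_name[k], statistic = bt$statistic, p_value = bt$p_value,
      n_cpgs_used = bt$n_cpgs,
      delta_beta = mean(cpg$delta_beta[idx]),
      testable = TRUE, stringsAsFactors = FALSE
    )
  }))
  burden$fdr_q <- NA_real_
  ok <- burden$testable
  burden$fdr_q[ok] <- bh_fdr(burden$p_value[ok])
  list(cpg = cpg, burden = burden, n = length(y))
}

#' Confirm DMRs across two validation cohorts
#'
#' Rule chain (each step configurable): (1) a DMR is eligible if at least
#' `min_sig_cpgs` member CpGs pass the per-CpG Bonferroni screen in cohort
#' 2; (2) its burden-test BH q across the eligible DMRs of cohort 2 must be
#' below `fdr_alpha`; (3) the cross-cohort meta-analysis p (signed
#' Stouffer, weights `sqrt(n)`) must be below `meta_alpha`.
#'
#' @param cohort2,cohort3 results from [validate_cohort()].
#' @param min_sig_cpgs minimum Bonferroni-significant CpGs in cohort 2.
#' @param fdr_alpha burden FDR threshold in cohort 2.
#' @param meta_alpha meta-analysis threshold.
#' @return data.frame per DMR: `dmr_id`, `n_sig_cpgs_cohort2`, `eligible`,
#'   `burden_p2`, `burden_q2`, `burden_p3`, `meta_p`, `confirmed`.
#' @export
confirm_dmrs <- function(cohort2, cohort3, min_sig_cpgs = 3,
                         fdr_alpha = 0.05, meta_alpha = 0.05) {
  b2 <- cohort2$burden[cohort2$burden$testable, , drop = FALSE]
  b3 <- cohort3$burden[cohort3$burden$testable, , drop = FALSE]
  ids <- intersect(b2$dmr_id, b3$dmr_id)
  missing <- setdiff(union(b2$dmr_id, b3$dmr_id), ids)
  if (length(missing) > 0) {
    warning(
      "DMR(s) absent from a cohort, excluded: ",
      paste(missing, collapse = ", ")
    )
  }
  sig2 <- table(cohort2$cpg$dmr_id[cohort2$cpg$significant_bonferroni])
  n_sig <- as.integer(ifelse(ids %in% names(sig2), sig2[ids], 0L))
  eligible <- n_sig >= min_sig_cpgs
  p2 <- b2$p_value[match(ids, b2$dmr_id)]
  d2 <- b2$delta_beta[match(ids, b2$dmr_id)]
  p3 <- b3$p_value[match(ids, b3$dmr_id)]
  d3 <- b3$delta_beta[match(ids, b3$dmr_id)]
  q2 <- rep(NA_real_, length(ids))
  if (any(eligible)) q2[eligible] <- bh_fdr(p2[eligible])
  meta_p <- vapply(seq_along(ids), function(k) {
    meta_analyze(
      c(p2[k], p3[k]), c(d2[k], d3[k]),
      weights = sqrt(c(cohort2$n, cohort3$n))
    )$meta_p
  }, 0)
  out <- data.frame(
    dmr_id = ids, n_sig_cpgs_cohort2 = n_sig, eligible = eligible,
    burden_p2 = p2, burden_q2 = q2, burden_p3 = p3, meta_p = meta_p,
    confirmed = eligible & !is.na(q2) & q2 < fdr_alpha & meta_p < meta_alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
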