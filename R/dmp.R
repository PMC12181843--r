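# Per-CpG differential methylation calling between CN and AD.
#
# The default per-site test is the binomial-logistic likelihood-ratio test
# of the group term across replicates (one observation per sample:
# methylated successes out of coverage). Because group is the only
# covariate, the MLE fitted probability of each sample is its group's pooled
# proportion, so the LRT statistic has a closed form and is computed
# vectorised across sites; it is identical to the glm() deviance difference.

# vectorised LRT over sites; inputs are sites x samples count matrices
.lrt_binomial_rows <- function(meth_cn, cov_cn, meth_ad, cov_ad,
                               overdispersion = c("none", "MN")) {
  overdispersion <- match.arg(overdispersion)
  m1 <- rowSums(meth_cn)
  n1 <- rowSums(cov_cn)
  m2 <- rowSums(meth_ad)
  n2 <- rowSums(cov_ad)
  p1 <- ifelse(n1 > 0, m1 / n1, 0)
  p2 <- ifelse(n2 > 0, m2 / n2, 0)
  p0 <- ifelse(n1 + n2 > 0, (m1 + m2) / (n1 + n2), 0)
  ll <- function(m, n, p) xlogy(m, p) + xlogy(n - m, 1 - p)
  stat <- 2 * (ll(m1, n1, p1) + ll(m2, n2, p2) - ll(m1 + m2, n1 + n2, p0))
  stat <- pmax(stat, 0)
  if (overdispersion == "MN") {
    # McCullagh-Nelder correction: scale by the Pearson dispersion of the
    # full (two-proportion) model; guards the binomial test against
    # between-replicate overdispersion.
    pe <- function(meth, cov, p) {
      e <- cov * p
      v <- cov * p * (1 - p)
      x <- (meth - e)^2 / v
      x[!is.finite(x)] <- 0
      rowSums(x)
    }
    df <- rowSums(cov_cn > 0) + rowSums(cov_ad > 0) - 2
    phi <- (pe(meth_cn, cov_cn, p1) + pe(meth_ad, cov_ad, p2)) / pmax(df, 1)
    stat <- stat / pmax(phi, 1)
  }
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-site differential methylation test
#'
#' Likelihood-ratio test (1 df) of the CN/AD group term in a per-site
#' binomial logistic regression with one observation per sample, or
#' Fisher's exact test on group-pooled counts. Degenerate sites (no
#' variation, e.g. fully unmethylated in both groups) return p = 1.
#'
#' @param meth_cn,cov_cn methylated and total counts per CN sample.
#' @param meth_ad,cov_ad methylated and total counts per AD sample.
#' @param test `"lrt"` (default, replicate-aware) or `"fisher"` (pooled).
#' @param overdispersion `"none"` (binomial likelihood, default) or `"MN"`
#'   (scale the LRT statistic by the Pearson dispersion of the full model).
#' @return two-sided p-value.
#' @export
test_dmp_site <- function(meth_cn, cov_cn, meth_ad, cov_ad,
                          test = c("lrt", "fisher"),
                          overdispersion = c("none", "MN")) {
  test <- match.arg(test)
  stopifnot(
    length(meth_cn) == length(cov_cn), length(meth_ad) == length(cov_ad),
    any(cov_cn > 0), any(cov_ad > 0),
    all(meth_cn <= cov_cn), all(meth_ad <= cov_ad)
  )
  if (test == "fisher") {
    tab <- matrix(c(
      sum(meth_cn), sum(cov_cn) - sum(meth_cn),
      sum(meth_ad), sum(cov_ad) - sum(meth_ad)
    ), nrow = 2)
    return(stats::fisher.test(tab)$p.value)
  }
  .lrt_binomial_rows(
    matrix(meth_cn, 1), matrix(cov_cn, 1),
    matrix(meth_ad, 1), matrix(cov_ad, 1),
    overdispersion = match.arg(overdispersion)
  )
}

#' Per-site p-values for a whole matrix
#'
#' Vectorised version of [test_dmp_site()] across every site of a (already
#' coverage-filtered) matrix; useful for calibration studies that need the
#' full p-value distribution rather than the thresholded DMP list.
#'
#' @inheritParams compute_group_betas
#' @param test,overdispersion see [test_dmp_site()].
#' @return numeric vector of p-values, one per site.
#' @export
dmp_site_pvalues <- function(mat, sample_table, test = c("lrt", "fisher"),
                             overdispersion = c("none", "MN")) {
  test <- match.arg(test)
  overdispersion <- match.arg(overdispersion)
  grp <- sample_table$group[match(mat$samples, sample_table$id)]
  if (anyNA(grp) || !all(grp %in% c("CN", "AD"))) {
    stop("every sample must be assigned to group CN or AD")
  }
  cn <- grp == "CN"
  ad <- grp == "AD"
  if (test == "lrt") {
    .lrt_binomial_rows(
      mat$meth[, cn, drop = FALSE], mat$cov[, cn, drop = FALSE],
      mat$meth[, ad, drop = FALSE], mat$cov[, ad, drop = FALSE],
      overdispersion = overdispersion
    )
  } else {
    vapply(seq_len(nrow(mat$sites)), function(i) {
      test_dmp_site(
        mat$meth[i, cn], mat$cov[i, cn], mat$meth[i, ad], mat$cov[i, ad],
        test = "fisher"
      )
    }, 0)
  }
}

#' Group mean methylation levels per site
#'
#' Per-sample rate = methylated / coverage; each group's beta is the
#' unweighted mean of per-sample rates; `delta_beta = beta_AD - beta_CN`.
#' All included sites must have positive coverage in every sample (run
#' [filter_min_coverage()] first).
#'
#' @param mat a [meth_matrix()].
#' @param sample_table data.frame with `id` and `group` (`"CN"`/`"AD"`)
#'   covering every sample of `mat`.
#' @return data.frame `chrom`, `pos`, `beta_cn`, `beta_ad`, `delta_beta`.
#' @export
compute_group_betas <- function(mat, sample_table) {
  stopifnot(inherits(mat, "meth_matrix"))
  grp <- sample_table$group[match(mat$samples, sample_table$id)]
  if (anyNA(grp) || !all(grp %in% c("CN", "AD"))) {
    stop("every sample must be assigned to group CN or AD")
  }
  if (any(mat$cov == 0)) {
    stop("zero coverage at an included site; run filter_min_coverage first")
  }
  rates <- mat$meth / mat$cov
  beta_cn <- rowMeans(rates[, grp == "CN", drop = FALSE])
  beta_ad <- rowMeans(rates[, grp == "AD", drop = FALSE])
  data.frame(
    chrom = mat$sites$chrom, pos = mat$sites$pos,
    beta_cn = beta_cn, beta_ad = beta_ad,
    delta_beta = beta_ad - beta_cn,
    stringsAsFactors = FALSE
  )
}

#' Call differentially methylated positions
#'
#' The discovery screen: coverage filter, per-site test across all retained
#' sites, BH q-values over the tested sites, then the joint effect-size and
#' q-value thresholds. Defaults are the conventional stringent settings for
#' capture bisulfite data: coverage >= 10 in every sample, |delta beta| >=
#' 0.15, q <= 0.01. Sex-chromosome exclusion is applied afterwards by the
#' caller via [exclude_regions()].
#'
#' @param mat a [meth_matrix()].
#' @param sample_table sample sheet with `id` and `group`.
#' @param min_cov,min_abs_delta,max_q thresholds.
#' @param test,overdispersion passed to the per-site test, see
#'   [test_dmp_site()].
#' @return data.frame of DMP records (`chrom`, `pos`, `beta_cn`, `beta_ad`,
#'   `delta_beta`, `p_value`, `q_value`, `direction`), genomically sorted,
#'   with attribute `n_tested` (the BH denominator).
#' @export
call_dmps <- function(mat, sample_table, min_cov = 10, min_abs_delta = 0.15,
                      max_q = 0.01, test = c("lrt", "fisher"),
                      overdispersion = c("none", "MN")) {
  test <- match.arg(test)
  overdispersion <- match.arg(overdispersion)
  stopifnot(min_cov >= 1, min_abs_delta >= 0, min_abs_delta <= 1,
    max_q > 0, max_q <= 1, nrow(mat$sites) > 0)
  grp <- sample_table$group[match(mat$samples, sample_table$id)]
  if (anyNA(grp)) stop("samples missing from the sample table")
  if (sum(grp == "CN") < 2 || sum(grp == "AD") < 2) {
    stop("at least 2 samples per group are required")
  }
  fm <- filter_min_coverage(mat, min_cov, mode = "all_samples")
  empty <- data.frame(
    chrom = character(0), pos = integer(0), beta_cn = numeric(0),
    beta_ad = numeric(0), delta_beta = numeric(0), p_value = numeric(0),
    q_value = numeric(0), direction = character(0), stringsAsFactors = FALSE
  )
  if (nrow(fm$sites) == 0) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  betas <- compute_group_betas(fm, sample_table)
  cn <- grp == "CN"
  ad <- grp == "AD"
  if (test == "lrt") {
    p <- .lrt_binomial_rows(
      fm$meth[, cn, drop = FALSE], fm$cov[, cn, drop = FALSE],
      fm$meth[, ad, drop = FALSE], fm$cov[, ad, drop = FALSE],
      overdispersion = overdispersion
    )
  } else {
    p <- vapply(seq_len(nrow(fm$sites)), function(i) {
      test_dmp_site(
        fm$meth[i, cn], fm$cov[i, cn], fm$meth[i, ad], fm$cov[i, ad],
        test = "fisher"
      )
    }, 0)
  }
  q <- bh_fdr(p)
  keep <- abs(betas$delta_beta) >= min_abs_delta & q <= max_q
  out <- data.frame(
    betas[keep, , drop = FALSE],
    p_value = p[keep], q_value = q[keep],
    direction = ifelse(betas$delta_beta[keep] < 0, "hypo", "hyper"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  message(sprintf(
    "DMP calling: %d sites tested, %d DMPs (|delta beta| >= %.2f, q <= %.3g)",
    length(p), nrow(out), min_abs_delta, max_q
  ))
  attr(out, "n_tested") <- length(p)
  out
}
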