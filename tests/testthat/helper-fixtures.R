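# fixture builders shared across the suite; everything is generated in code

toy_matrix <- function() {
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 500L)
  )
  meth <- matrix(c(
    5L, 2L,
    0L, 10L,
    7L, 3L
  ), nrow = 3, byrow = TRUE)
  cov <- matrix(c(
    10L, 10L,
    12L, 20L,
    14L, 12L
  ), nrow = 3, byrow = TRUE)
  meth_matrix(sites, meth, cov, samples = c("s1", "s2"))
}

# random DMP table, sorted, unique positions per chromosome
rand_dmps <- function(n, seed, span = 50000, delta_range = c(0.1, 0.4),
                      chroms = "chr1") {
  set.seed(seed)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(span, n))
    data.frame(
      chrom = ch, pos = pos,
      delta_beta = runif(n, delta_range[1], delta_range[2]) *
        sample(c(-1, 1), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  out[order_dmps(out), , drop = FALSE]
}

order_dmps <- function(d) order(d$chrom, d$pos)

# strip the members list-column and row names for DMR comparisons
dmr_flat <- function(d) {
  d2 <- d[, setdiff(names(d), "members")]
  rownames(d2) <- NULL
  d2
}

# balanced two-group sample sheet without covariate-group association
null_sheet <- function(n_per_group, cohort = "sim") {
  data.frame(
    id = sprintf("s%03d", seq_len(2 * n_per_group)),
    group = rep(c("CN", "AD"), each = n_per_group),
    sex = rep(c("male", "female"), length.out = 2 * n_per_group),
    age = 70 + seq_len(2 * n_per_group) %% 5,
    apoe_e4 = 0L,
    cohort = cohort,
    stringsAsFactors = FALSE
  )
}

# direct beta-binomial count matrix (sites x samples) used when a test
# wants raw counts without the full cohort generator
bb_counts <- function(n_sites, n_samples, coverage, mu, rho) {
  cov <- matrix(coverage, n_sites, n_samples)
  if (rho <= 0) {
    p <- matrix(mu, n_sites, n_samples)
  } else {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    p <- matrix(rbeta(n_sites * n_samples, a, b), n_sites, n_samples)
  }
  meth <- matrix(
    rbinom(n_sites * n_samples, as.vector(cov), as.vector(p)),
    n_sites, n_samples
  )
  list(meth = meth, cov = cov)
}

# demographics with identical CN/AD distributions (no covariate signal)
flat_demographics <- function(age_mean = 70, age_sd = 3) {
  g <- list(
    age_mean = age_mean, age_sd = age_sd, male_frac = 0.5,
    apoe_probs = c(homo = 0.05, het = 0.25, non = 0.70)
  )
  list(cn = g, ad = g)
}

# shared feature generator: d DMRs x cpgs_per features; informative DMRs get
# a per-CpG shift so the per-DMR composite standardised effect is `effect`
sim_features <- function(n_per_group, d = 5, cpgs_per = 3, informative = c(),
                         effect = 0.8, apoe_signal = TRUE, seed) {
  set.seed(seed)
  n <- 2 * n_per_group
  y <- rep(c(0, 1), each = n_per_group)
  X <- matrix(rnorm(n * d * cpgs_per), n)
  dmr <- rep(paste0("D", seq_len(d)), each = cpgs_per)
  for (k in informative) {
    cols <- which(dmr == paste0("D", k))
    X[y == 1, cols] <- X[y == 1, cols] + effect / sqrt(cpgs_per)
  }
  pr_cn <- c(2, 15, 79) / 96 # pooled validation-cohort genotype mix
  pr_ad <- c(11, 49, 36) / 96
  apoe <- ifelse(
    y == 1 & apoe_signal,
    sample(c(2, 1, 0), n, TRUE, pr_ad),
    sample(c(2, 1, 0), n, TRUE, pr_cn)
  )
  list(X = X, y = y, dmr = dmr, covar = data.frame(apoe_e4 = apoe))
}
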