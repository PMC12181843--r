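#' Cohort demographic presets
#'
#' Per-group sampling parameters for the three study-style cohorts: age
#' mean/SD (years), male fraction, and APOE epsilon-4 genotype probabilities
#' (homozygote, heterozygote, non-carrier). The presets mirror the sample
#' characteristics of a small discovery cohort (12 CN / 12 AD) and two
#' validation cohorts of 48 CN / 48 AD each.
#'
#' @param cohort one of `"cohort1"`, `"cohort2"`, `"cohort3"`.
#' @return list with elements `cn` and `ad`, each a list of `age_mean`,
#'   `age_sd`, `male_frac`, `apoe_probs` (named `homo`, `het`, `non`).
#' @export
cohort_demographics <- function(cohort = c("cohort2", "cohort1", "cohort3")) {
  cohort <- match.arg(cohort)
  grp <- function(age_mean, age_sd, male_frac, apoe) {
    list(
      age_mean = age_mean, age_sd = age_sd, male_frac = male_frac,
      apoe_probs = c(homo = apoe[1], het = apoe[2], non = apoe[3])
    )
  }
  switch(cohort,
    cohort1 = list(
      cn = grp(73.3, 3.2, 4 / 12, c(0, 1, 11) / 12),
      ad = grp(74.4, 6.4, 2 / 12, c(2, 8, 2) / 12)
    ),
    cohort2 = list(
      cn = grp(70.3, 2.4, 0.5, c(1, 5, 42) / 48),
      ad = grp(71.2, 4.0, 0.5, c(5, 30, 13) / 48)
    ),
    cohort3 = list(
      cn = grp(69.8, 3.0, 0.5, c(1, 10, 37) / 48),
      ad = grp(71.8, 2.6, 0.5, c(6, 19, 23) / 48)
    )
  )
}

#' Draw a sample table of covariates
#'
#' Generates per-sample metadata (group, sex, age, APOE epsilon-4 allele
#' count, cohort label) from per-group demographic parameters. Empirical
#' moments converge to the parameters as n grows.
#'
#' @param n_cn,n_ad number of CN and AD samples (non-negative integers).
#' @param params demographic parameters as returned by
#'   [cohort_demographics()].
#' @param cohort cohort label stored in the table.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so callers embedding this in a larger seeded simulation get
#'   reproducibility for free).
#' @return data.frame with columns `id`, `group` (`"CN"`/`"AD"`), `sex`
#'   (`"male"`/`"female"`), `age`, `apoe_e4` (0/1/2), `cohort`.
#' @export
sample_covariates <- function(n_cn, n_ad, params = cohort_demographics("cohort2"),
                              cohort = "cohort2", seed = NULL) {
  if (!is.numeric(n_cn) || !is.numeric(n_ad) || n_cn < 0 || n_ad < 0 ||
    n_cn != round(n_cn) || n_ad != round(n_ad)) {
    stop("n_cn and n_ad must be non-negative integers")
  }
  for (g in c("cn", "ad")) {
    pr <- params[[g]]$apoe_probs
    if (length(pr) != 3 || any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
      stop("APOE genotype probabilities must be length 3 and sum to 1")
    }
    if (params[[g]]$age_sd < 0 || params[[g]]$age_mean <= 0) {
      stop("invalid age parameters")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, g, label) {
    p <- params[[g]]
    if (n == 0) {
      return(data.frame(
        id = character(0), group = character(0), sex = character(0),
        age = numeric(0), apoe_e4 = integer(0), cohort = character(0),
        stringsAsFactors = FALSE
      ))
    }
    data.frame(
      id = sprintf("%s_%s_%03d", cohort, label, seq_len(n)),
      group = label,
      sex = ifelse(stats::runif(n) < p$male_frac, "male", "female"),
      age = pmax(1, stats::rnorm(n, p$age_mean, p$age_sd)),
      apoe_e4 = c(2L, 1L, 0L)[sample.int(3, n, replace = TRUE, prob = p$apoe_probs)],
      cohort = cohort,
      stringsAsFactors = FALSE
    )
  }
  rbind(draw(n_cn, "cn", "CN"), draw(n_ad, "ad", "AD"))
}

#' Coverage model specification
#'
#' @param type `"mcseq"` (negative binomial, mean 30, dispersion 0.3 --
#'   var = mean + dispersion * mean^2 -- emulating capture sequencing depth
#'   heterogeneity), `"amplicon"` (Poisson with mean 1000, emulating deep
#'   amplicon sequencing), or `"fixed"` (constant depth, default 30, for
#'   controlled calibration experiments).
#' @param mean,dispersion optional overrides.
#' @return list with `dist`, `mean` and (for `nbinom`) `dispersion`.
#' @export
coverage_model <- function(type = c("mcseq", "amplicon", "fixed"), mean = NULL,
                           dispersion = NULL) {
  type <- match.arg(type)
  switch(type,
    mcseq = list(dist = "nbinom", mean = mean %||% 30, dispersion = dispersion %||% 0.3),
    amplicon = list(dist = "poisson", mean = mean %||% 1000),
    fixed = list(dist = "fixed", mean = mean %||% 30)
  )
}

#' Specification of an implanted (true) DMR
#'
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive span.
#' @param delta_beta signed group effect on the methylation level scale
#'   (AD minus CN); negative = hypomethylated in AD.
#' @param n_cpgs number of CpGs inside the span to shift; `NULL` = all.
#' @param direction optional `"hypo"`/`"hyper"`; must agree with the sign
#'   of `delta_beta`.
#' @return object of class `true_dmr_spec`.
#' @export
true_dmr_spec <- function(chrom, start, end, delta_beta, n_cpgs = NULL,
                          direction = NULL) {
  stopifnot(start <= end, abs(delta_beta) <= 1, delta_beta != 0)
  implied <- if (delta_beta < 0) "hypo" else "hyper"
  if (!is.null(direction) && direction != implied) {
    stop("direction does not match the sign of delta_beta")
  }
  structure(
    list(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      delta_beta = delta_beta, n_cpgs = n_cpgs, direction = implied
    ),
    class = "true_dmr_spec"
  )
}

#' Synthetic cohort configuration
#'
#' Collects every knob of the generative model. Per CpG j and sample i the
#' model draws coverage `c_ij` from the coverage model and a methylated count
#' from `BetaBinomial(c_ij, mu_ij, rho)` where
#' `mu_ij = clip(pi_j + delta_j * I(AD_i) + slope_j * (age_i - mean age))`.
#' Baseline levels `pi_j` come from a three-component mixture (low ~0.05,
#' intermediate ~0.5, high ~0.95); by default 40% of CpGs sit in the
#' intermediate band where validated markers are typically found.
#'
#' @param n_cn,n_ad samples per group.
#' @param n_cpgs number of CpG sites.
#' @param chroms autosome names over which CpGs are laid out.
#' @param spacing_mean mean inter-CpG spacing in bp (exponential spacing).
#' @param sex_chrom_fraction fraction of CpGs placed on chrX/chrY to
#'   exercise the sex-chromosome exclusion filter (4:1 X:Y).
#' @param baseline_weights mixture weights, named `low`/`intermediate`/`high`.
#' @param rho beta-binomial overdispersion in `[0, 1)`; 0 = pure binomial.
#'   The default 0.01 reflects the modest between-subject variability of
#'   blood methylation rates.
#' @param coverage a [coverage_model()].
#' @param dmr_specs list of [true_dmr_spec()]; spans must not overlap and
#'   must contain at least one CpG each.
#' @param age_effect per-CpG age slope (fraction/year); scalar or length
#'   `n_cpgs`.
#' @param effect_scale `"beta"` (additive on the methylation level with
#'   clipping; default) or `"logit"` (additive on log-odds).
#' @param demographics per-group covariate parameters
#'   ([cohort_demographics()]).
#' @param cohort cohort label.
#' @param seed mandatory integer seed (`0 <= seed < 2^31 - 1`); together
#'   with the config it fully determines the output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cn = 12, n_ad = 12, n_cpgs = 10000,
                             chroms = paste0("chr", 1:22),
                             spacing_mean = 150,
                             sex_chrom_fraction = 0,
                             baseline_weights = c(low = 0.3, intermediate = 0.4, high = 0.3),
                             rho = 0.01,
                             coverage = coverage_model("mcseq"),
                             dmr_specs = list(),
                             age_effect = 0,
                             effect_scale = c("beta", "logit"),
                             demographics = cohort_demographics("cohort1"),
                             cohort = "cohort1",
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(
    seed >= 0, seed < 2^31 - 2, seed == round(seed),
    rho >= 0, rho < 1,
    n_cpgs >= 1, spacing_mean > 0,
    sex_chrom_fraction >= 0, sex_chrom_fraction < 1,
    length(baseline_weights) == 3, all(baseline_weights >= 0),
    sum(baseline_weights) > 0
  )
  effect_scale <- match.arg(effect_scale)
  if (length(dmr_specs) > 0) {
    if (inherits(dmr_specs, "true_dmr_spec")) dmr_specs <- list(dmr_specs)
    stopifnot(all(vapply(dmr_specs, inherits, TRUE, "true_dmr_spec")))
    key <- vapply(dmr_specs, function(s) s$chrom, "")
    for (ch in unique(key)) {
      ss <- dmr_specs[key == ch]
      iv <- do.call(rbind, lapply(ss, function(s) c(s$start, s$end)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        stop("DMR spans must not overlap")
      }
    }
  }
  structure(
    list(
      n_cn = n_cn, n_ad = n_ad, n_cpgs = n_cpgs, chroms = chroms,
      spacing_mean = spacing_mean, sex_chrom_fraction = sex_chrom_fraction,
      baseline_weights = baseline_weights / sum(baseline_weights),
      rho = rho, coverage = coverage, dmr_specs = dmr_specs,
      age_effect = age_effect, effect_scale = effect_scale,
      demographics = demographics, cohort = cohort, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Deterministic CpG layout of a synthetic configuration
#'
#' Positions and baseline methylation levels are drawn from `config$seed`
#' alone, so the layout can be inspected first (e.g. to anchor
#' [true_dmr_spec()] spans on real positions) and [simulate_cohort()] will
#' reproduce it exactly.
#'
#' @param config a [synthetic_config()].
#' @return list with `sites` (data.frame `chrom`, `pos`, `strand`) and `pi`
#'   (baseline methylation level per CpG).
#' @export
cpg_layout <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cpgs
  n_sex <- round(n * config$sex_chrom_fraction)
  n_x <- round(n_sex * 0.8)
  n_y <- n_sex - n_x
  n_auto <- n - n_sex
  chroms <- config$chroms
  alloc <- table(factor(
    sample(chroms, n_auto, replace = TRUE),
    levels = chroms
  ))
  counts <- c(as.integer(alloc), n_x, n_y)
  names(counts) <- c(chroms, "chrX", "chrY")
  counts <- counts[counts > 0]
  sites <- do.call(rbind, lapply(names(counts), function(ch) {
    k <- counts[[ch]]
    gaps <- pmax(2, round(stats::rexp(k, 1 / config$spacing_mean)))
    data.frame(
      chrom = ch, pos = as.integer(10000 + cumsum(gaps)),
      stringsAsFactors = FALSE
    )
  }))
  o <- order_genomic(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  sites$strand <- "+"
  rownames(sites) <- NULL
  w <- config$baseline_weights
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  pi <- numeric(n)
  pi[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 38) # low, mean ~0.05
  pi[comp == 2] <- stats::rbeta(sum(comp == 2), 10, 10) # intermediate
  pi[comp == 3] <- stats::rbeta(sum(comp == 3), 38, 2) # high, mean ~0.95
  list(sites = sites, pi = pi)
}

# beta-binomial sampler; size, mu vectors recycled to common length
rbetabinom <- function(n, size, mu, rho) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  if (rho <= 0) {
    return(stats::rbinom(n, size, mu))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

# group/age adjusted mean methylation matrix (sites x samples)
.mu_matrix <- function(pi, delta, samples, age_effect, effect_scale) {
  n_sites <- length(pi)
  is_ad <- samples$group == "AD"
  age_c <- samples$age - mean(samples$age)
  slope <- rep_len(age_effect, n_sites)
  if (effect_scale == "beta") {
    mu <- matrix(pi, n_sites, nrow(samples))
    mu <- mu + outer(delta, as.numeric(is_ad))
    mu <- mu + outer(slope, age_c)
  } else {
    eta <- matrix(stats::qlogis(pmin(pmax(pi, 1e-6), 1 - 1e-6)), n_sites, nrow(samples))
    eta <- eta + outer(delta, as.numeric(is_ad)) + outer(slope, age_c)
    mu <- stats::plogis(eta)
  }
  pmin(pmax(mu, 1e-6), 1 - 1e-6)
}

# per-site signed effect vector from dmr specs; errors on empty spans
.effect_vector <- function(sites, dmr_specs) {
  delta <- numeric(nrow(sites))
  for (s in dmr_specs) {
    idx <- which(sites$chrom == s$chrom & sites$pos >= s$start & sites$pos <= s$end)
    if (length(idx) == 0) {
      stop(sprintf(
        "DMR spec %s:%d-%d contains no CpGs", s$chrom, s$start, s$end
      ))
    }
    if (!is.null(s$n_cpgs) && s$n_cpgs < length(idx)) {
      idx <- sort(sample(idx, s$n_cpgs))
    }
    delta[idx] <- s$delta_beta
  }
  delta
}

.draw_coverage <- function(model, n) {
  switch(model$dist,
    nbinom = stats::rnbinom(n, size = 1 / model$dispersion, mu = model$mean),
    poisson = stats::rpois(n, model$mean),
    fixed = rep.int(as.integer(round(model$mean)), n),
    stop("unknown coverage distribution: ", model$dist)
  )
}

#' Simulate a bisulfite-sequencing cohort
#'
#' Generates a [meth_matrix()] of beta-binomial methylation counts, a sample
#' covariate table and the ground-truth list of implanted DMRs. Identical
#' `config` (including `seed`) yields byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @param resample_seed optional seed for the sampling stage (covariates,
#'   coverage, counts) only; the CpG layout and baselines still derive from
#'   `config$seed`, so two calls differing only in `resample_seed` are
#'   independent cohorts over identical sites -- a replication experiment.
#' @return list with elements `calls` ([meth_matrix()]), `samples`
#'   (covariate data.frame) and `truth` (the `dmr_specs` of the config).
#' @export
simulate_cohort <- function(config, resample_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- cpg_layout(config) # seeds with config$seed
  set.seed(resample_seed %||% (config$seed + 1L))
  samples <- sample_covariates(
    config$n_cn, config$n_ad, config$demographics,
    cohort = config$cohort
  )
  if (nrow(samples) == 0) stop("cohort has no samples")
  delta <- .effect_vector(layout$sites, config$dmr_specs)
  mu <- .mu_matrix(layout$pi, delta, samples, config$age_effect, config$effect_scale)
  n_cell <- length(mu)
  cov <- matrix(.draw_coverage(config$coverage, n_cell), nrow(mu), ncol(mu))
  meth <- matrix(rbetabinom(n_cell, cov, mu, config$rho), nrow(mu), ncol(mu))
  calls <- meth_matrix(layout$sites, meth, cov, samples = samples$id)
  list(calls = calls, samples = samples, truth = config$dmr_specs)
}

#' Simulate a deep amplicon validation cohort
#'
#' Same generative model as [simulate_cohort()], but CpGs are restricted to
#' a set of target regions (amplicons), with high-depth coverage.
#'
#' @param config a [synthetic_config()]; its `coverage` should normally be
#'   `coverage_model("amplicon")`.
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name` and `n_cpgs` (CpGs placed evenly in
#'   the region; default one per ~15 bp, minimum 2).
#' @param seed integer seed for the sampling stage; defaults to
#'   `config$seed`.
#' @param layout_seed seed for the baseline methylation levels; give two
#'   cohorts the same `layout_seed` (and regions) to make them measure the
#'   same loci with identical baselines, as real validation cohorts do.
#' @return list with `calls` ([meth_matrix()]) and `samples`.
#' @export
simulate_amplicon_cohort <- function(config, regions, seed = config$seed,
                                     layout_seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(regions) || nrow(regions) == 0) stop("regions must be nonempty")
  sites <- do.call(rbind, lapply(seq_len(nrow(regions)), function(k) {
    r <- regions[k, ]
    nk <- if (!is.null(regions$n_cpgs)) r$n_cpgs else max(2, floor((r$end - r$start) / 15))
    if (is.na(nk) || nk < 1) {
      stop(sprintf("region %s:%d-%d has no CpGs", r$chrom, r$start, r$end))
    }
    pos <- unique(as.integer(round(seq(r$start, r$end, length.out = nk))))
    if (length(pos) < nk) {
      stop(sprintf("region %s:%d-%d too short for %d CpGs", r$chrom, r$start, r$end, nk))
    }
    data.frame(chrom = r$chrom, pos = pos, stringsAsFactors = FALSE)
  }))
  o <- order_genomic(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  sites$strand <- "+"
  rownames(sites) <- NULL
  set.seed(layout_seed)
  w <- config$baseline_weights
  n <- nrow(sites)
  comp <- sample.int(3, n, replace = TRUE, prob = w)
  pi <- numeric(n)
  pi[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 38)
  pi[comp == 2] <- stats::rbeta(sum(comp == 2), 10, 10)
  pi[comp == 3] <- stats::rbeta(sum(comp == 3), 38, 2)
  set.seed(seed + 1L)
  samples <- sample_covariates(
    config$n_cn, config$n_ad, config$demographics,
    cohort = config$cohort
  )
  if (nrow(samples) == 0) stop("cohort has no samples")
  delta <- .effect_vector(sites, config$dmr_specs)
  mu <- .mu_matrix(pi, delta, samples, config$age_effect, config$effect_scale)
  n_cell <- length(mu)
  cov <- matrix(.draw_coverage(config$coverage, n_cell), nrow(mu), ncol(mu))
  meth <- matrix(rbetabinom(n_cell, cov, mu, config$rho), nrow(mu), ncol(mu))
  list(
    calls = meth_matrix(sites, meth, cov, samples = samples$id),
    samples = samples
  )
}

#' Write a simulated cohort to disk
#'
#' Emits one Bismark-style cytosine report per sample, a TSV sample sheet
#' and (when ground truth is present) a BED file of implanted DMRs -- the
#' same formats the readers of the package consume.
#'
#' @param sim result of [simulate_cohort()] or [simulate_amplicon_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (id in sim$calls$samples) {
    f <- file.path(dir, paste0(id, ".cytosine.txt"))
    write_cytosine_report(sim$calls, id, f)
    files <- c(files, f)
  }
  sheet <- file.path(dir, "sample_sheet.tsv")
  data.table::fwrite(sim$samples, sheet, sep = "\t")
  files <- c(files, sheet)
  if (!is.null(sim$truth) && length(sim$truth) > 0) {
    truth <- data.frame(
      chrom = vapply(sim$truth, `[[`, "", "chrom"),
      start = vapply(sim$truth, `[[`, 0L, "start"),
      end = vapply(sim$truth, `[[`, 0L, "end"),
      name = vapply(sim$truth, `[[`, "", "direction"),
      mean_delta_beta = vapply(sim$truth, `[[`, 0, "delta_beta"),
      stringsAsFactors = FALSE
    )
    bed <- file.path(dir, "truth.bed")
    write_bed(truth, bed)
    files <- c(files, bed)
  }
  invisible(files)
}
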