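# Pipeline orchestration: discover -> validate -> diagnose, with YAML
# configs, structured per-stage logging and reproducible artifacts.

#' Default pipeline configuration
#'
#' Every stage threshold defaults to the study-style values: coverage 10 /
#' |delta beta| 0.15 / q 0.01 for DMP calling; a 1-kb window needing 5 DMPs
#' at 0.15 or 3 at 0.25 for DMR calling; Bonferroni 0.05 and burden FDR
#' 0.05 for validation; 0.8 discovery split and threefold CV with C in
#' {0.1, 1, 10, 100} for modelling; chrX/chrY excluded.
#'
#' @param seed global seed.
#' @return nested list, YAML-serialisable.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    discover = list(
      min_cov = 10, min_abs_delta = 0.15, max_q = 0.01,
      window_bp = 1000, k_lo = 5, delta_lo = 0.15, k_hi = 3, delta_hi = 0.25,
      exclude_chroms = c("chrX", "chrY")
    ),
    validate = list(
      min_cov = 10, cpg_alpha = 0.05, min_sig_cpgs = 3,
      fdr_alpha = 0.05, meta_alpha = 0.05, covariates = c("sex", "age")
    ),
    diagnose = list(
      fraction = 0.8, cv_folds = 3, penalty_grid = c(0.1, 1, 10, 100),
      mixing = 0.5, folds_list = c(3, 5, 10)
    )
  )
}

.write_manifest <- function(out_dir, config, artifacts) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("dmrpipe")),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts)), basename(artifacts)
    ))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Discovery stage
#'
#' Coverage filter, DMP calling, sex-chromosome exclusion, sliding-window
#' DMR calling, direction tally and (optionally) gene-relative annotation.
#' Logs one line per filter with the counts at each step.
#'
#' @param calls a [meth_matrix()] (e.g. [read_cytosine_report()] output or
#'   a simulated cohort).
#' @param samples sample sheet data.frame.
#' @param config pipeline configuration ([default_pipeline_config()]).
#' @param gene_model optional gene model for annotation
#'   ([annotate_relative_location()]).
#' @param out_dir optional output directory: writes `dmps.tsv`, `dmrs.tsv`,
#'   `dmrs.bed`, `summary.yaml`, `config.yaml` and `manifest.yaml`.
#' @return list with `dmps`, `dmrs`, `summary` (stage counts incl. the
#'   sex-chromosome exclusion tally).
#' @export
run_discover <- function(calls, samples, config = default_pipeline_config(),
                         gene_model = NULL, out_dir = NULL) {
  cfg <- config$discover
  n_sites <- nrow(calls$sites)
  dmps_all <- call_dmps(
    calls, samples,
    min_cov = cfg$min_cov, min_abs_delta = cfg$min_abs_delta,
    max_q = cfg$max_q
  )
  n_tested <- attr(dmps_all, "n_tested")
  dmps <- exclude_regions(dmps_all, cfg$exclude_chroms)
  n_xy <- attr(dmps, "n_excluded")
  criteria <- window_criteria(
    window_bp = cfg$window_bp, k_lo = cfg$k_lo, delta_lo = cfg$delta_lo,
    k_hi = cfg$k_hi, delta_hi = cfg$delta_hi
  )
  dmrs <- call_dmrs(dmps, criteria)
  dmrs <- annotate_relative_location(dmrs, gene_model)
  tally <- classify_and_tally(dmrs)
  summary <- list(
    sites_read = n_sites, sites_tested = n_tested,
    dmps_total = nrow(dmps_all), dmps_excluded_xy = n_xy,
    dmps_retained = nrow(dmps), dmrs = nrow(dmrs),
    n_hypo = tally$n_hypo, n_hyper = tally$n_hyper,
    fraction_hypo = tally$fraction_hypo,
    locations = as.list(table(dmrs$location))
  )
  message(sprintf(
    "discover: %d sites -> %d tested -> %d DMPs -> %d post-X/Y -> %d DMRs",
    n_sites, n_tested, nrow(dmps_all), nrow(dmps), nrow(dmrs)
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_dmps <- file.path(out_dir, "dmps.tsv")
    f_dmrs <- file.path(out_dir, "dmrs.tsv")
    f_bed <- file.path(out_dir, "dmrs.bed")
    f_sum <- file.path(out_dir, "summary.yaml")
    data.table::fwrite(dmps, f_dmps, sep = "\t")
    flat <- dmrs[, setdiff(names(dmrs), "members")]
    data.table::fwrite(flat, f_dmrs, sep = "\t")
    write_bed(dmrs, f_bed)
    yaml::write_yaml(summary, f_sum)
    .write_manifest(out_dir, config, c(f_dmps, f_dmrs, f_bed, f_sum))
  }
  list(dmps = dmps, dmrs = dmrs, summary = summary)
}

#' Validation stage
#'
#' Per-CpG and burden/FDR/meta analysis of candidate DMRs in one or two
#' amplicon cohorts, plus the confirmation rule chain when two cohorts are
#' supplied. The result table has one row per DMR and cohort plus a
#' meta-analysis row, with the methylation difference on the percent scale
#' (mean of per-CpG differences).
#'
#' @param cohorts list of one or two cohorts, each a list with `calls`
#'   ([meth_matrix()]) and `samples` (sample sheet).
#' @param dmrs DMR intervals to validate (`chrom`, `start`, `end`,
#'   optional `name`).
#' @param config pipeline configuration.
#' @param out_dir optional output directory (`validation_table.tsv`,
#'   `confirmed_dmrs.tsv`).
#' @return list with `per_cohort` (full [validate_cohort()] results),
#'   `table` (the long summary table), `confirmed` (confirmation
#'   data.frame, or `NULL` for a single cohort).
#' @export
run_validate <- function(cohorts, dmrs, config = default_pipeline_config(),
                         out_dir = NULL) {
  cfg <- config$validate
  stopifnot(length(cohorts) >= 1)
  res <- lapply(cohorts, function(co) {
    validate_cohort(
      co$calls, co$samples, dmrs,
      alpha = cfg$cpg_alpha, min_cov = cfg$min_cov,
      covariates = cfg$covariates
    )
  })
  if (is.null(names(res)) || any(!nzchar(names(res)))) {
    names(res) <- paste0("cohort", seq_along(res) + 1)
  }
  rows <- list()
  ids <- res[[1]]$burden$dmr_id
  for (id in ids) {
    for (cn in names(res)) {
      b <- res[[cn]]$burden
      r <- b[b$dmr_id == id, , drop = FALSE]
      if (nrow(r) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        dmr_id = id, group = cn, p_value = r$p_value, fdr = r$fdr_q,
        meth_diff_pct = 100 * r$delta_beta, stringsAsFactors = FALSE
      )
    }
    if (length(res) >= 2) {
      ps <- vapply(res, function(x) {
        x$burden$p_value[x$burden$dmr_id == id][1]
      }, 0)
      ds <- vapply(res, function(x) {
        x$burden$delta_beta[x$burden$dmr_id == id][1]
      }, 0)
      ns <- vapply(res, function(x) x$n, 0)
      mp <- if (all(is.finite(ps))) {
        meta_analyze(ps, ds, weights = sqrt(ns))$meta_p
      } else {
        NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        dmr_id = id, group = "meta-analysis", p_value = mp, fdr = NA_real_,
        meth_diff_pct = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  confirmed <- NULL
  if (length(res) >= 2) {
    confirmed <- confirm_dmrs(
      res[[1]], res[[2]],
      min_sig_cpgs = cfg$min_sig_cpgs,
      fdr_alpha = cfg$fdr_alpha, meta_alpha = cfg$meta_alpha
    )
  } else {
    message("single cohort supplied: meta-analysis column absent")
  }
  untestable <- res[[1]]$burden$dmr_id[!res[[1]]$burden$testable]
  if (length(untestable) > 0) {
    message(
      "untestable DMR(s) (no covered CpGs): ",
      paste(untestable, collapse = ", ")
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(tab, file.path(out_dir, "validation_table.tsv"), sep = "\t")
    if (!is.null(confirmed)) {
      data.table::fwrite(
        confirmed, file.path(out_dir, "confirmed_dmrs.tsv"),
        sep = "\t"
      )
    }
  }
  list(per_cohort = res, table = tab, confirmed = confirmed)
}

#' Assemble a marker feature matrix from methylation calls
#'
#' One column per marker CpG (methylation rate); cells with zero coverage
#' are imputed with the feature mean.
#'
#' @param calls a [meth_matrix()].
#' @param markers marker CpGs from [select_marker_cpgs()].
#' @return numeric matrix samples x markers with `dmr` attribute giving the
#'   DMR id per column.
#' @export
marker_feature_matrix <- function(calls, markers) {
  idx <- match(
    paste(markers$chrom, markers$pos),
    paste(calls$sites$chrom, calls$sites$pos)
  )
  if (anyNA(idx)) stop("marker CpG(s) absent from the call matrix")
  r <- meth_rates(calls)[idx, , drop = FALSE]
  X <- t(r)
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- mean(X[, j], na.rm = TRUE)
  }
  colnames(X) <- paste(markers$chrom, markers$pos, sep = ":")
  attr(X, "dmr") <- as.character(markers$dmr_id)
  X
}

# numeric clinical covariate encoding: age (years), sex (male = 1),
# apoe_e4 allele count (0/1/2)
encode_covariates <- function(samples) {
  data.frame(
    age = samples$age,
    sex = as.integer(samples$sex == "male"),
    apoe_e4 = as.integer(samples$apoe_e4)
  )
}

#' Diagnostic modelling stage
#'
#' Pools the validation cohorts, splits discovery/validation (stratified
#' four-fifths), runs the exhaustive DMR-subset search, evaluates the
#' winner and the covariate-only base model on the held-out split, and
#' reports fold-count sensitivity.
#'
#' @param cohorts list of cohorts (as in [run_validate()]) pooled for
#'   modelling.
#' @param markers marker CpGs from [select_marker_cpgs()]; an empty set is
#'   an explicit error.
#' @param config pipeline configuration.
#' @param out_dir optional output directory (`model_table.tsv`,
#'   `sensitivity.tsv`, `roc.png`).
#' @return list with `search`, `winner_validation`, `base_validation`,
#'   `sensitivity`, `split`.
#' @export
run_diagnose <- function(cohorts, markers,
                         config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.null(markers) || nrow(markers) == 0) {
    stop("no markers survive selection")
  }
  cfg <- config$diagnose
  feats <- lapply(cohorts, function(co) marker_feature_matrix(co$calls, markers))
  features <- do.call(rbind, feats)
  samples <- do.call(rbind, lapply(cohorts, `[[`, "samples"))
  covar <- encode_covariates(samples)
  labels <- as.integer(samples$group == "AD")
  feature_dmr <- attr(feats[[1]], "dmr")
  split <- split_discovery_validation(
    labels,
    fraction = cfg$fraction, seed = config$seed
  )
  search <- search_models(
    features[split$discovery, , drop = FALSE], labels[split$discovery],
    feature_dmr, covar[split$discovery, , drop = FALSE],
    cv_folds = cfg$cv_folds, penalty_grid = cfg$penalty_grid,
    mixing = cfg$mixing, seed = config$seed
  )
  wv <- evaluate_auc(
    predict_scores(
      search, features[split$validation, , drop = FALSE],
      covar[split$validation, , drop = FALSE]
    ),
    labels[split$validation]
  )
  bv <- evaluate_auc(
    predict_scores(
      search, features[split$validation, , drop = FALSE],
      covar[split$validation, , drop = FALSE],
      model = "base"
    ),
    labels[split$validation]
  )
  sens <- sensitivity_analysis(
    features, labels, feature_dmr, covar,
    discovery = split$discovery, validation = split$validation,
    folds_list = cfg$folds_list, penalty_grid = cfg$penalty_grid,
    mixing = cfg$mixing, seed = config$seed
  )
  message(sprintf(
    "diagnose: %d candidates; winner %s: CV AUC %.3f, validation AUC %.3f (base %.3f)",
    nrow(search$table), paste(search$winner$subset, collapse = "+"),
    search$winner$cv_auc, wv$auc, bv$auc
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(
      search$table, file.path(out_dir, "model_table.tsv"),
      sep = "\t"
    )
    data.table::fwrite(sens, file.path(out_dir, "sensitivity.tsv"), sep = "\t")
    grDevices::png(file.path(out_dir, "roc.png"), width = 600, height = 600)
    plot(wv$roc$fpr, wv$roc$tpr,
      type = "l", col = "steelblue", lwd = 2,
      xlab = "False positive rate", ylab = "True positive rate",
      main = sprintf("Winner AUC %.2f / base AUC %.2f", wv$auc, bv$auc)
    )
    graphics::lines(bv$roc$fpr, bv$roc$tpr, col = "grey50", lwd = 2)
    graphics::abline(0, 1, lty = 3)
    grDevices::dev.off()
  }
  list(
    search = search, winner_validation = wv, base_validation = bv,
    sensitivity = sens, split = split
  )
}
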