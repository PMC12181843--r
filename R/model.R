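# Diagnostic model construction: marker CpG selection across cohorts,
# stratified discovery/validation split, exhaustive DMR-subset search with
# elastic-net logistic regression and cross-validated AUC, held-out AUC
# with DeLong CI, and fold-count sensitivity analysis.

#' Select marker CpGs replicated across two cohorts
#'
#' Keeps CpGs that are Bonferroni-significant in both validation cohorts
#' with the same direction of methylation change.
#'
#' @param cohort2_results,cohort3_results per-CpG data.frames from
#'   [validate_cohort()]`$cpg` (columns `chrom`, `pos`, `dmr_id`,
#'   `delta_beta`, `p_raw`, `m_tests`).
#' @param alpha family-wise level for the per-cohort Bonferroni screens.
#' @return data.frame of marker CpGs (`chrom`, `pos`, `dmr_id`,
#'   `direction`), with a per-DMR count table as attribute `per_dmr`.
#' @export
select_marker_cpgs <- function(cohort2_results, cohort3_results,
                               alpha = 0.05) {
  key2 <- paste(cohort2_results$chrom, cohort2_results$pos)
  key3 <- paste(cohort3_results$chrom, cohort3_results$pos)
  only <- sum(!key2 %in% key3) + sum(!key3 %in% key2)
  if (only > 0) {
    warning(only, " CpG(s) present in only one cohort are ineligible")
  }
  shared <- intersect(key2, key3)
  i2 <- match(shared, key2)
  i3 <- match(shared, key3)
  sig2 <- bonferroni_flag(
    cohort2_results$p_raw[i2], alpha, cohort2_results$m_tests[i2][1]
  )
  sig3 <- bonferroni_flag(
    cohort3_results$p_raw[i3], alpha, cohort3_results$m_tests[i3][1]
  )
  d2 <- cohort2_results$delta_beta[i2]
  d3 <- cohort3_results$delta_beta[i3]
  keep <- sig2 & sig3 & (sign(d2) == sign(d3)) & d2 != 0
  out <- data.frame(
    chrom = cohort2_results$chrom[i2][keep],
    pos = cohort2_results$pos[i2][keep],
    dmr_id = cohort2_results$dmr_id[i2][keep],
    direction = ifelse(d2[keep] < 0, "hypo", "hyper"),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$dmr_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_dmr") <- table(out$dmr_id)
  out
}

#' Stratified discovery/validation split
#'
#' Random split stratified by class label: per class,
#' `round(n_class * fraction)` samples go to discovery. Seed-reproducible;
#' redrawn (up to 100 times) if a class would be absent from either side.
#'
#' @param labels class label per sample (two classes required).
#' @param fraction discovery fraction in (0, 1); default four-fifths.
#' @param seed integer seed.
#' @return list with integer index vectors `discovery` and `validation`.
#' @export
split_discovery_validation <- function(labels, fraction = 0.8, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, length(unique(labels)) >= 2)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(100)) {
    disc <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- round(length(idx) * fraction)
      disc <- c(disc, sample(idx, k))
    }
    disc <- sort(disc)
    val <- setdiff(seq_along(labels), disc)
    if (length(unique(labels[disc])) >= 2 && length(unique(labels[val])) >= 2) {
      return(list(discovery = disc, validation = val))
    }
    warning("degenerate split, redrawing")
  }
  stop("could not produce a split containing both classes on each side")
}

# fit a (possibly penalised) logistic model and return a scoring closure.
# C follows the inverse-regularisation convention; lambda = 1 / (n * C).
.fit_logistic <- function(X, y, C, mixing) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) >= 2) {
    lam <- 1 / (nrow(X) * C)
    fit <- glmnet::glmnet(X, y,
      family = "binomial", alpha = mixing,
      lambda = lam, standardize = TRUE
    )
    function(Xnew) {
      Xnew <- as.matrix(Xnew)
      colnames(Xnew) <- paste0("f", seq_len(ncol(Xnew)))
      drop(stats::predict(fit, Xnew, type = "link"))
    }
  } else {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    function(Xnew) {
      Xnew <- as.matrix(Xnew)
      colnames(Xnew) <- paste0("f", seq_len(ncol(Xnew)))
      drop(stats::predict(fit, newdata = as.data.frame(Xnew), type = "link"))
    }
  }
}

#' Exhaustive DMR-combination model search
#'
#' Enumerates all `2^d - 1` nonempty DMR subsets plus the covariate-only
#' base model. Each candidate is an elastic-net-penalised logistic
#' regression (mixing fixed, default 0.5) on the covariates plus the
#' member-CpG methylation rates of the subset; the penalty strength is
#' chosen from `penalty_grid` on the same stratified CV folds used to rank
#' subsets by mean CV AUC. The winner is refit on the full discovery set.
#' Standardisation is fitted inside each training fold (never on held-out
#' data).
#'
#' @param features numeric matrix, samples x marker-CpG features
#'   (discovery set).
#' @param labels binary outcome (0/1 or CN/AD) per sample.
#' @param feature_dmr DMR id per feature column (defines the subsets).
#' @param covariates numeric matrix/data.frame of clinical covariates
#'   (e.g. age, sex, APOE e4 count), or `NULL`.
#' @param cv_folds number of stratified CV folds (default 3).
#' @param penalty_grid inverse-regularisation values C (default
#'   0.1, 1, 10, 100).
#' @param mixing elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param seed seed fixing fold assignment.
#' @param max_dmrs refuse exhaustive enumeration beyond this many DMRs.
#' @return object of class `model_search`: list with `table` (one row per
#'   candidate: `subset`, `penalty_C`, `cv_auc`, ranked), `winner` (refit
#'   on all discovery data; includes the scoring function), `folds`,
#'   `base_cv_auc`.
#' @export
search_models <- function(features, labels, feature_dmr, covariates = NULL,
                          cv_folds = 3, penalty_grid = c(0.1, 1, 10, 100),
                          mixing = 0.5, seed = NULL, max_dmrs = 20) {
  features <- as.matrix(features)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "AD")
  }
  y <- as.numeric(labels)
  stopifnot(
    nrow(features) == length(y), all(y %in% c(0, 1)),
    length(feature_dmr) == ncol(features)
  )
  dmr_levels <- unique(as.character(feature_dmr))
  d <- length(dmr_levels)
  if (d < 1) stop("at least one DMR is required")
  if (d > max_dmrs) {
    stop(
      "refusing exhaustive enumeration over ", d,
      " DMRs (2^d subsets); reduce the marker set or raise max_dmrs"
    )
  }
  covar_mat <- if (is.null(covariates)) {
    matrix(numeric(0), nrow(features), 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, cv_folds)

  subsets <- c(
    list(character(0)), # covariate-only base model
    unlist(lapply(seq_len(d), function(k) {
      asplit(utils::combn(dmr_levels, k), 2)
    }), recursive = FALSE)
  )
  design_for <- function(subset) {
    cols <- as.character(feature_dmr) %in% subset
    cbind(covar_mat, features[, cols, drop = FALSE])
  }
  eval_subset <- function(subset) {
    X <- design_for(subset)
    if (ncol(X) == 0) {
      return(c(cv_auc = 0.5, penalty_C = penalty_grid[1]))
    }
    auc_by_c <- matrix(NA_real_, cv_folds, length(penalty_grid))
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      te <- !tr
      for (ci in seq_along(penalty_grid)) {
        score <- .fit_logistic(
          X[tr, , drop = FALSE], y[tr], penalty_grid[ci], mixing
        )
        auc_by_c[k, ci] <- auc_mw(score(X[te, , drop = FALSE]), y[te])
      }
    }
    mean_auc <- colMeans(auc_by_c)
    best <- which.max(mean_auc)
    c(cv_auc = mean_auc[best], penalty_C = penalty_grid[best])
  }
  res <- t(vapply(subsets, eval_subset, c(cv_auc = 0, penalty_C = 0)))
  tab <- data.frame(
    subset = vapply(subsets, function(s) {
      if (length(s) == 0) "(base)" else paste(s, collapse = "+")
    }, ""),
    n_dmrs = vapply(subsets, length, 0L),
    penalty_C = res[, "penalty_C"],
    cv_auc = res[, "cv_auc"],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$cv_auc), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  win_row <- tab[tab$subset != "(base)", , drop = FALSE][1, ]
  win_subset <- strsplit(win_row$subset, "+", fixed = TRUE)[[1]]
  Xw <- design_for(win_subset)
  winner <- list(
    subset = win_subset,
    penalty_C = win_row$penalty_C,
    cv_auc = win_row$cv_auc,
    feature_cols = which(as.character(feature_dmr) %in% win_subset),
    score = .fit_logistic(Xw, y, win_row$penalty_C, mixing)
  )
  base_score <- if (ncol(covar_mat) > 0) {
    .fit_logistic(covar_mat, y, tab$penalty_C[tab$subset == "(base)"], mixing)
  } else {
    NULL
  }
  structure(
    list(
      table = tab, winner = winner, folds = fold,
      base_cv_auc = tab$cv_auc[tab$subset == "(base)"],
      base_score = base_score, mixing = mixing,
      feature_dmr = as.character(feature_dmr),
      n_covariates = ncol(covar_mat)
    ),
    class = "model_search"
  )
}

#' @export
print.model_search <- function(x, ...) {
  cat(sprintf(
    "model_search: %d candidates; winner %s (C = %g, CV AUC = %.3f)\n",
    nrow(x$table), paste(x$winner$subset, collapse = "+"),
    x$winner$penalty_C, x$winner$cv_auc
  ))
  invisible(x)
}

# score new samples with the winning (or base) model of a search
predict_scores <- function(search, features, covariates = NULL,
                           model = c("winner", "base")) {
  model <- match.arg(model)
  covar_mat <- if (is.null(covariates)) {
    matrix(numeric(0), nrow(as.matrix(features)), 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  if (model == "base") {
    if (is.null(search$base_score)) stop("no covariates: no base model")
    return(search$base_score(covar_mat))
  }
  cols <- search$feature_dmr %in% search$winner$subset
  X <- cbind(covar_mat, as.matrix(features)[, cols, drop = FALSE])
  search$winner$score(X)
}

#' Held-out AUC with DeLong confidence interval
#'
#' Point estimate is the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` with midrank tie correction; the 95% CI uses DeLong's
#' method. The score orientation is fixed (higher score = AD), so an AUC
#' below 0.5 is reported as such rather than silently flipped.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (0/1 or CN/AD); both classes required.
#' @param conf_level CI level.
#' @return list with `auc`, `ci_low`, `ci_high`, `roc` (data.frame of
#'   `fpr`, `tpr` points).
#' @export
evaluate_auc <- function(scores, labels, conf_level = 0.95) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "AD")
  }
  if (length(unique(labels)) < 2) {
    stop("validation set must contain both classes")
  }
  auc <- auc_mw(scores, labels)
  roc_obj <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(roc_obj, method = "delong", conf.level = conf_level)
  ))
  list(
    auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[3], auc),
    roc = data.frame(
      fpr = 1 - roc_obj$specificities,
      tpr = roc_obj$sensitivities
    )
  )
}

#' Sensitivity of the model search to CV fold count
#'
#' Re-runs [search_models()] for each fold count, evaluates each winner on
#' the held-out validation split, and flags when the selected DMR subset
#' changes across fold counts.
#'
#' @param features,labels,feature_dmr,covariates as in [search_models()],
#'   for the full (discovery + validation) sample set.
#' @param discovery,validation integer index vectors from
#'   [split_discovery_validation()].
#' @param folds_list fold counts to examine (default 3, 5, 10).
#' @param penalty_grid,mixing,seed passed to [search_models()].
#' @return data.frame with one row per fold count: `cv_folds`, `subset`,
#'   `penalty_C`, `cv_auc`, `validation_auc`, `subset_changed`.
#' @export
sensitivity_analysis <- function(features, labels, feature_dmr,
                                 covariates = NULL, discovery, validation,
                                 folds_list = c(3, 5, 10),
                                 penalty_grid = c(0.1, 1, 10, 100),
                                 mixing = 0.5, seed = NULL) {
  features <- as.matrix(features)
  covar <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  rows <- lapply(folds_list, function(k) {
    s <- search_models(
      features[discovery, , drop = FALSE], labels[discovery], feature_dmr,
      covariates = if (is.null(covar)) NULL else covar[discovery, , drop = FALSE],
      cv_folds = k, penalty_grid = penalty_grid, mixing = mixing, seed = seed
    )
    val <- evaluate_auc(
      predict_scores(
        s, features[validation, , drop = FALSE],
        if (is.null(covar)) NULL else covar[validation, , drop = FALSE]
      ),
      labels[validation]
    )
    data.frame(
      cv_folds = k, subset = paste(s$winner$subset, collapse = "+"),
      penalty_C = s$winner$penalty_C, cv_auc = s$winner$cv_auc,
      validation_auc = val$auc, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$subset_changed <- out$subset != out$subset[1]
  out
}
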