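#' Multi-sample methylation call matrix
#'
#' The central container of the package: an ordered list of CpG sites
#' (plus-strand C positions, 1-based) together with per-sample methylated
#' counts and total coverage. A site missing from a sample is represented by
#' coverage 0 and is removed by [filter_min_coverage()] rather than imputed.
#'
#' @param sites data.frame with columns `chrom` (character) and `pos`
#'   (1-based integer position of the C on the plus strand). Rows are
#'   reordered genomically; positions must be unique within a chromosome.
#' @param meth integer matrix, sites x samples, methylated read counts.
#' @param cov integer matrix, sites x samples, total read counts;
#'   `meth <= cov` elementwise.
#' @param samples character vector of sample ids (defaults to
#'   `colnames(cov)`).
#' @return an object of class `meth_matrix`: a list with elements `sites`
#'   (data.frame `chrom`, `pos`, `strand = "+"`), `meth`, `cov`, `samples`.
#' @seealso [read_cytosine_report()], [meth_rates()]
#' @export
meth_matrix <- function(sites, meth, cov, samples = colnames(cov)) {
  meth <- as.matrix(meth)
  cov <- as.matrix(cov)
  stopifnot(
    is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)),
    nrow(sites) == nrow(meth), nrow(sites) == nrow(cov),
    ncol(meth) == ncol(cov)
  )
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(cov)))
  stopifnot(length(samples) == ncol(cov), !anyDuplicated(samples))
  if (any(meth < 0) || any(cov < 0)) stop("negative counts")
  if (any(meth > cov)) stop("methylated count exceeds coverage")
  if (any(meth != round(meth)) || any(cov != round(cov))) {
    stop("counts must be integers")
  }
  o <- order_genomic(sites$chrom, sites$pos)
  sites <- data.frame(
    chrom = as.character(sites$chrom)[o],
    pos = as.integer(sites$pos)[o],
    strand = rep("+", length(o)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stop("duplicate sites after ordering")
  }
  meth <- meth[o, , drop = FALSE]
  cov <- cov[o, , drop = FALSE]
  dimnames(meth) <- dimnames(cov) <- list(NULL, samples)
  structure(
    list(sites = sites, meth = meth, cov = cov, samples = samples),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "meth_matrix: %d CpG sites x %d samples (%d chromosomes)\n",
    nrow(x$sites), length(x$samples), length(unique(x$sites$chrom))
  ))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a methylation matrix by site and/or sample
#'
#' @param x a [meth_matrix()].
#' @param i site index (integer/logical).
#' @param j sample index (integer/logical/character ids).
#' @param ... unused.
#' @export
`[.meth_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  if (anyNA(j)) stop("unknown sample id")
  meth_matrix(
    x$sites[i, c("chrom", "pos"), drop = FALSE],
    x$meth[i, j, drop = FALSE],
    x$cov[i, j, drop = FALSE],
    samples = x$samples[j]
  )
}

#' Per-sample methylation rates
#'
#' Methylation level beta = methylated / coverage per cell; cells with zero
#' coverage are `NA`.
#'
#' @param x a [meth_matrix()].
#' @return numeric matrix, sites x samples.
#' @export
meth_rates <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  r <- x$meth / x$cov
  r[x$cov == 0] <- NA_real_
  r
}
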