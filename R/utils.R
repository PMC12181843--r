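# internal helpers shared across modules

# natural chromosome ordering: chr1..chr22, chrX, chrY, then anything else
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(base))
  ifelse(!is.na(num), num,
    ifelse(base == "X", 23L, ifelse(base == "Y", 24L, ifelse(base == "M", 25L, 26L)))
  )
}

order_genomic <- function(chrom, pos) order(chrom_rank(chrom), chrom, pos)

# x * log(y) with the 0 * log(0) = 0 convention
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order and
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`/`NaN` are rejected.
#' @return numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03)) # 0.03 0.04 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("bh_fdr: p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Mann-Whitney AUC with midrank tie correction.
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("auc_mw: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic stratified fold assignment; labels logical/2-level
stratified_folds <- function(labels, k) {
  labels <- as.integer(as.factor(labels))
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
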