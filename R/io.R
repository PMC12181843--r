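# Readers and writers for standard methylation-call formats.
#
# Internal coordinates are 1-based inclusive, keyed to the plus-strand C of
# each CpG dinucleotide; minus-strand calls at pos+1 are collapsed onto it.
# BED output is the only place 0-based half-open coordinates appear.

.read_one_call_file <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(data.table::data.table(
      chrom = character(0), pos = integer(0), strand = character(0),
      meth = integer(0), unmeth = integer(0)
    ))
  }
  methylkit <- grepl("coverage", first) && grepl("freqC", first)
  if (methylkit) {
    dt <- data.table::fread(path, header = TRUE, colClasses = list(character = "chr"))
    need <- c("chr", "base", "strand", "coverage", "freqC")
    if (!all(need %in% names(dt))) {
      stop(sprintf("%s: malformed methylKit header", path))
    }
    bad <- which(!dt$strand %in% c("F", "R", "+", "-"))
    if (length(bad)) {
      stop(sprintf("%s: malformed row at line %d (unknown strand)", path, bad[1] + 1L))
    }
    bad <- which(!is.finite(dt$coverage) | dt$coverage < 0 |
      dt$coverage != round(dt$coverage) | !is.finite(dt$freqC))
    if (length(bad)) {
      stop(sprintf("%s: malformed row at line %d (bad counts)", path, bad[1] + 1L))
    }
    meth <- as.integer(round(dt$coverage * dt$freqC / 100))
    out <- data.table::data.table(
      chrom = as.character(dt$chr), pos = as.integer(dt$base),
      strand = ifelse(dt$strand %in% c("F", "+"), "+", "-"),
      meth = meth, unmeth = as.integer(dt$coverage) - meth
    )
  } else {
    dt <- data.table::fread(path, header = FALSE, colClasses = list(character = 1))
    if (ncol(dt) < 5) stop(sprintf("%s: expected a 7-column cytosine report", path))
    names(dt)[1:5] <- c("chrom", "pos", "strand", "meth", "unmeth")
    bad <- which(!dt$strand %in% c("+", "-"))
    if (length(bad)) {
      stop(sprintf("%s: malformed row at line %d (unknown strand)", path, bad[1]))
    }
    for (colm in c("pos", "meth", "unmeth")) {
      v <- suppressWarnings(as.numeric(dt[[colm]]))
      bad <- which(!is.finite(v) | v < 0 | v != round(v))
      if (length(bad)) {
        stop(sprintf("%s: malformed row at line %d (non-integer %s)", path, bad[1], colm))
      }
    }
    if (ncol(dt) >= 6) {
      names(dt)[6] <- "context"
      dt <- dt[dt$context %in% c("CpG", "CG"), ]
    }
    out <- data.table::data.table(
      chrom = as.character(dt$chrom), pos = as.integer(dt$pos),
      strand = as.character(dt$strand),
      meth = as.integer(dt$meth), unmeth = as.integer(dt$unmeth)
    )
  }
  if (anyDuplicated(out[, c("chrom", "pos", "strand")])) {
    stop(sprintf("%s: duplicate (chrom, pos, strand) records", path))
  }
  out
}

#' Read methylation call files into a matrix
#'
#' Accepts Bismark-style cytosine reports (7 headerless columns: chrom,
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide; non-CpG rows dropped) or methylKit-style TSVs
#' (auto-detected by header). Plus- and minus-strand calls of one CpG
#' dinucleotide are summed onto the plus-strand C position; the site list is
#' the union across samples, with missing sites at coverage 0. Malformed
#' rows raise an error naming file and line rather than being coerced.
#'
#' @param paths character vector of input files.
#' @param sample_ids sample names; defaults to file basenames.
#' @return a [meth_matrix()].
#' @export
read_cytosine_report <- function(paths, sample_ids = NULL) {
  if (length(paths) == 0) stop("no input files")
  if (is.null(sample_ids)) {
    sample_ids <- make.unique(sub("\\..*$", "", basename(paths)))
  }
  stopifnot(length(sample_ids) == length(paths))
  per_sample <- lapply(paths, function(p) {
    dt <- .read_one_call_file(p)
    # strand collapse: a minus-strand C sits one bp 3' of the plus-strand C
    dt$pos <- ifelse(dt$strand == "-", dt$pos - 1L, dt$pos)
    dt <- dt[, list(meth = sum(meth), cov = sum(meth + unmeth)),
      by = c("chrom", "pos")
    ]
    dt
  })
  all_sites <- unique(data.table::rbindlist(
    lapply(per_sample, function(d) d[, c("chrom", "pos")])
  ))
  o <- order_genomic(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[o, ]
  key <- paste(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  meth <- cov <- matrix(0L, n, length(paths))
  for (j in seq_along(per_sample)) {
    d <- per_sample[[j]]
    i <- match(paste(d$chrom, d$pos), key)
    meth[i, j] <- d$meth
    cov[i, j] <- d$cov
  }
  meth_matrix(as.data.frame(all_sites), meth, cov, samples = sample_ids)
}

#' Write one sample as a Bismark-style cytosine report
#'
#' Deterministic, tab-separated, headerless: chrom, pos, strand (always
#' `+`), methylated count, unmethylated count, context (`CpG`),
#' trinucleotide placeholder. Sites with zero coverage in the sample are
#' omitted and re-imputed as missing on read.
#'
#' @param mat a [meth_matrix()].
#' @param sample_id sample to export.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cytosine_report <- function(mat, sample_id, path) {
  stopifnot(inherits(mat, "meth_matrix"))
  j <- match(sample_id, mat$samples)
  if (is.na(j)) stop("unknown sample id: ", sample_id)
  keep <- mat$cov[, j] > 0
  out <- data.table::data.table(
    chrom = mat$sites$chrom[keep],
    pos = mat$sites$pos[keep],
    strand = "+",
    meth = mat$meth[keep, j],
    unmeth = mat$cov[keep, j] - mat$meth[keep, j],
    context = "CpG",
    tri = "CGN"
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write a sample sheet
#'
#' TSV with columns `id`, `group`, `sex`, `age`, `apoe_e4`, `cohort`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("id", "group", "sex", "age", "apoe_e4", "cohort")
  if (!all(need %in% names(dt))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(dt$group %in% c("CN", "AD"))) stop("group must be CN or AD")
  if (!all(dt$apoe_e4 %in% 0:2)) stop("apoe_e4 must be 0, 1 or 2")
  as.data.frame(dt)
}

#' Coverage filter
#'
#' Retains sites meeting a minimum-coverage rule. `mode = "all_samples"`
#' (default, unite-style) keeps a site only if every sample has at least
#' `min_cov` reads; `mode = "per_group_all"` applies the same rule within
#' each group of `groups`, ignoring samples without a group label.
#'
#' @param mat a [meth_matrix()].
#' @param min_cov minimum coverage (>= 1).
#' @param mode filtering rule.
#' @param groups optional group label per sample (required for
#'   `per_group_all`).
#' @return filtered [meth_matrix()] with attribute `n_dropped`.
#' @export
filter_min_coverage <- function(mat, min_cov = 10,
                                mode = c("all_samples", "per_group_all"),
                                groups = NULL) {
  stopifnot(inherits(mat, "meth_matrix"), min_cov >= 1)
  mode <- match.arg(mode)
  if (mode == "all_samples") {
    keep <- rowSums(mat$cov >= min_cov) == ncol(mat$cov)
  } else {
    if (is.null(groups)) stop("per_group_all requires group labels")
    stopifnot(length(groups) == length(mat$samples))
    use <- !is.na(groups)
    keep <- rowSums(mat$cov[, use, drop = FALSE] >= min_cov) == sum(use)
  }
  message(sprintf(
    "coverage filter (>= %d, %s): retained %d of %d sites",
    min_cov, mode, sum(keep), length(keep)
  ))
  out <- mat[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

.item_coords <- function(x) {
  if (inherits(x, "meth_matrix")) {
    data.frame(chrom = x$sites$chrom, start = x$sites$pos, end = x$sites$pos)
  } else if (all(c("chrom", "start", "end") %in% names(x))) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end)
  } else if (all(c("chrom", "pos") %in% names(x))) {
    data.frame(chrom = x$chrom, start = x$pos, end = x$pos)
  } else {
    stop("items must carry coordinates (chrom + pos or chrom + start/end)")
  }
}

#' Remove items on excluded chromosomes or regions
#'
#' Drops sites, DMPs or DMRs lying on named chromosomes (e.g. `c("chrX",
#' "chrY")` for the sex-chromosome exclusion) or overlapping a region set.
#' The number of removals is attached as attribute `n_excluded`.
#'
#' @param x a [meth_matrix()] or a data.frame with `chrom` + `pos` or
#'   `chrom` + `start`/`end` columns.
#' @param exclude character vector of chromosome names, or a data.frame /
#'   `GRanges` of regions (1-based inclusive).
#' @return `x` filtered, with attribute `n_excluded`.
#' @export
exclude_regions <- function(x, exclude) {
  co <- .item_coords(x)
  if (is.character(exclude)) {
    drop <- co$chrom %in% exclude
  } else if (length(exclude) == 0 || (is.data.frame(exclude) && nrow(exclude) == 0)) {
    drop <- rep(FALSE, nrow(co))
  } else {
    if (is.data.frame(exclude)) {
      exclude <- GenomicRanges::GRanges(
        exclude$chrom, IRanges::IRanges(exclude$start, exclude$end)
      )
    }
    items <- GenomicRanges::GRanges(co$chrom, IRanges::IRanges(co$start, co$end))
    drop <- IRanges::overlapsAny(items, exclude)
  }
  out <- if (inherits(x, "meth_matrix")) x[!drop, ] else x[!drop, , drop = FALSE]
  if (is.data.frame(out)) rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  message(sprintf("excluded %d of %d items", sum(drop), nrow(co)))
  out
}

#' Write regions or DMRs as BED6
#'
#' Converts internal 1-based inclusive spans to BED's 0-based half-open
#' convention. The score column is `min(1000, round(|mean delta beta| *
#' 1000))` when a `mean_delta_beta` column is present, otherwise 0; strand
#' is `"."`. An empty input yields a file containing only the header
#' comment.
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`
#'   and `mean_delta_beta`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: chrom start(0-based) end name score strand", con)
  if (is.null(x) || nrow(x) == 0) {
    return(invisible(path))
  }
  start0 <- x$start - 1L
  if (any(start0 < 0)) stop("coordinate conversion produced start < 0")
  name <- if (!is.null(x$name)) {
    x$name
  } else {
    sprintf("%s:%d-%d", x$chrom, x$start, x$end)
  }
  score <- if (!is.null(x$mean_delta_beta)) {
    pmin(1000L, as.integer(round(abs(x$mean_delta_beta) * 1000)))
  } else {
    rep(0L, nrow(x))
  }
  writeLines(
    sprintf("%s\t%d\t%d\t%s\t%d\t.", x$chrom, start0, x$end, name, score),
    con
  )
  invisible(path)
}

#' Read a BED file back to 1-based inclusive intervals
#'
#' @param path BED file (comment lines starting with `#` are skipped).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), `name`,
#'   `score`, `strand`; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      name = character(0), score = integer(0), strand = character(0),
      stringsAsFactors = FALSE
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1),
    start = as.integer(vapply(f, `[`, "", 2)) + 1L,
    end = as.integer(vapply(f, `[`, "", 3)),
    name = vapply(f, function(v) if (length(v) >= 4) v[4] else NA_character_, ""),
    score = as.integer(vapply(f, function(v) if (length(v) >= 5) v[5] else NA_character_, "")),
    strand = vapply(f, function(v) if (length(v) >= 6) v[6] else ".", ""),
    stringsAsFactors = FALSE
  )
}
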