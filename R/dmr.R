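# Sliding-window DMR detection.
#
# A window is any genomic interval of length <= window_bp (inclusive span:
# max position - min position <= window_bp); it qualifies if it contains at
# least k_lo same-direction DMPs with |delta beta| >= delta_lo, or at least
# k_hi with |delta beta| >= delta_hi. Only windows whose endpoints are DMP
# positions need to be enumerated. Qualifying windows on one chromosome and
# direction are merged transitively when they overlap or share a DMP; each
# merged component is one DMR spanning the min/max member positions. This
# enumerate-and-merge formulation captures every region reachable by
# sliding a qualifying window up to window_bp in either direction.

#' Window qualification criteria for DMR calling
#'
#' Defaults encode the two-tier rule used for capture bisulfite discovery:
#' at least 5 DMPs with |delta beta| >= 0.15, or at least 3 with
#' |delta beta| >= 0.25, within a 1-kb window, same direction required.
#'
#' @param window_bp window length in bp (> 0).
#' @param k_lo,delta_lo DMP count and effect threshold of the low tier.
#' @param k_hi,delta_hi count and effect threshold of the high tier
#'   (`delta_hi > delta_lo`, `k_hi <= k_lo`).
#' @param same_direction require all member DMPs to share the sign of
#'   `delta_beta`.
#' @return object of class `window_criteria`.
#' @export
window_criteria <- function(window_bp = 1000, k_lo = 5, delta_lo = 0.15,
                            k_hi = 3, delta_hi = 0.25,
                            same_direction = TRUE) {
  stopifnot(
    window_bp > 0, k_lo >= 1, k_hi >= 1, k_hi <= k_lo,
    delta_lo >= 0, delta_hi > delta_lo
  )
  structure(
    list(
      window_bp = window_bp, k_lo = k_lo, delta_lo = delta_lo,
      k_hi = k_hi, delta_hi = delta_hi, same_direction = same_direction
    ),
    class = "window_criteria"
  )
}

.empty_dmrs <- function() {
  out <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpgs = integer(0), n_lo = integer(0), n_hi = integer(0),
    direction = character(0), mean_delta_beta = numeric(0),
    rule = character(0), stringsAsFactors = FALSE
  )
  out$members <- list()
  out
}

.check_sorted <- function(dmps) {
  for (ch in unique(dmps$chrom)) {
    p <- dmps$pos[dmps$chrom == ch]
    if (is.unsorted(p)) stop("DMPs must be sorted by (chromosome, position)")
  }
}

# direction subsets to evaluate; each element: original row indices
.direction_subsets <- function(dmps, criteria) {
  eligible <- abs(dmps$delta_beta) >= criteria$delta_lo
  if (criteria$same_direction) {
    list(
      hypo = which(eligible & dmps$delta_beta < 0),
      hyper = which(eligible & dmps$delta_beta >= 0)
    )
  } else {
    list(any = which(eligible))
  }
}

.make_dmr_row <- function(dmps, idx, any_lo, any_hi, criteria, dirlab) {
  d <- dmps$delta_beta[idx]
  direction <- if (dirlab != "any") {
    dirlab
  } else if (all(d < 0)) {
    "hypo"
  } else if (all(d >= 0)) {
    "hyper"
  } else {
    "mixed"
  }
  row <- data.frame(
    chrom = dmps$chrom[idx[1]],
    start = min(dmps$pos[idx]), end = max(dmps$pos[idx]),
    n_cpgs = length(idx),
    n_lo = sum(abs(d) >= criteria$delta_lo),
    n_hi = sum(abs(d) >= criteria$delta_hi),
    direction = direction,
    mean_delta_beta = mean(d),
    rule = if (any_lo && any_hi) "both" else if (any_lo) "lo" else "hi",
    stringsAsFactors = FALSE
  )
  row$members <- list(sort(idx))
  row
}

.finish_dmrs <- function(rows) {
  if (length(rows) == 0) return(.empty_dmrs())
  out <- do.call(rbind, rows)
  o <- order_genomic(out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call DMRs by sliding-window aggregation of DMPs
#'
#' @param dmps data.frame of DMP records (needs `chrom`, `pos`,
#'   `delta_beta`), sorted by chromosome and position, e.g. from
#'   [call_dmps()].
#' @param criteria a [window_criteria()].
#' @return data.frame of DMRs sorted by coordinates: `chrom`, `start`,
#'   `end` (1-based inclusive member-DMP span), `n_cpgs`, `n_lo`, `n_hi`
#'   (member counts at each effect tier), `direction`, `mean_delta_beta`,
#'   `rule` (`lo`/`hi`/`both`: which tier(s) some window satisfied) and a
#'   `members` list-column of row indices into `dmps`.
#' @seealso [brute_force_dmrs()] for the exhaustive reference
#'   implementation with the identical output contract.
#' @export
call_dmrs <- function(dmps, criteria = window_criteria()) {
  stopifnot(inherits(criteria, "window_criteria"))
  if (is.null(dmps) || nrow(dmps) == 0) return(.empty_dmrs())
  .check_sorted(dmps)
  rows <- list()
  for (ch in unique(dmps$chrom)) {
    on_ch <- which(dmps$chrom == ch)
    subsets <- .direction_subsets(dmps[on_ch, , drop = FALSE], criteria)
    for (dirlab in names(subsets)) {
      orig <- on_ch[subsets[[dirlab]]]
      if (length(orig) == 0) next
      p <- dmps$pos[orig]
      hi <- abs(dmps$delta_beta[orig]) >= criteria$delta_hi
      chi <- cumsum(hi)
      n <- length(p)
      # maximal window starting at each DMP: counts are monotone in the
      # right endpoint, so checking the largest in-window endpoint suffices
      jm <- findInterval(p + criteria$window_bp, p)
      n_lo <- jm - seq_len(n) + 1L
      n_hi <- chi[jm] - c(0L, chi)[seq_len(n)]
      q_lo <- n_lo >= criteria$k_lo
      q_hi <- n_hi >= criteria$k_hi
      qual <- which(q_lo | q_hi)
      if (length(qual) == 0) next
      # merge overlapping/DMP-sharing qualifying windows (ascending starts)
      comp_start <- qual[1]
      comp_end <- jm[qual[1]]
      comp_lo <- q_lo[qual[1]]
      comp_hi <- q_hi[qual[1]]
      emit <- function(i0, i1, any_lo, any_hi) {
        rows[[length(rows) + 1L]] <<- .make_dmr_row(
          dmps, orig[i0:i1], any_lo, any_hi, criteria, dirlab
        )
      }
      for (i in qual[-1]) {
        if (i <= comp_end) { # shares a DMP / overlaps the component
          comp_end <- max(comp_end, jm[i])
          comp_lo <- comp_lo || q_lo[i]
          comp_hi <- comp_hi || q_hi[i]
        } else {
          emit(comp_start, comp_end, comp_lo, comp_hi)
          comp_start <- i
          comp_end <- jm[i]
          comp_lo <- q_lo[i]
          comp_hi <- q_hi[i]
        }
      }
      emit(comp_start, comp_end, comp_lo, comp_hi)
    }
  }
  .finish_dmrs(rows)
}

#' Exhaustive reference DMR caller
#'
#' Tests every pair of DMP indices as window endpoints and merges
#' qualifying windows by explicit interval union. Quadratic in the number
#' of DMPs per chromosome; intended as an independent oracle for
#' [call_dmrs()] on small inputs, with the identical output contract.
#'
#' @inheritParams call_dmrs
#' @return see [call_dmrs()].
#' @export
brute_force_dmrs <- function(dmps, criteria = window_criteria()) {
  stopifnot(inherits(criteria, "window_criteria"))
  if (is.null(dmps) || nrow(dmps) == 0) return(.empty_dmrs())
  .check_sorted(dmps)
  rows <- list()
  for (ch in unique(dmps$chrom)) {
    on_ch <- which(dmps$chrom == ch)
    subsets <- .direction_subsets(dmps[on_ch, , drop = FALSE], criteria)
    for (dirlab in names(subsets)) {
      orig <- on_ch[subsets[[dirlab]]]
      if (length(orig) == 0) next
      p <- dmps$pos[orig]
      hi <- abs(dmps$delta_beta[orig]) >= criteria$delta_hi
      n <- length(p)
      wins <- list()
      for (i in seq_len(n)) {
        for (j in i:n) {
          if (p[j] - p[i] > criteria$window_bp) break
          cnt_lo <- j - i + 1L
          cnt_hi <- sum(hi[i:j])
          ql <- cnt_lo >= criteria$k_lo
          qh <- cnt_hi >= criteria$k_hi
          if (ql || qh) wins[[length(wins) + 1L]] <- c(i, j, ql, qh)
        }
      }
      if (length(wins) == 0) next
      wm <- do.call(rbind, wins)
      # transitive merge of windows that overlap or share a DMP
      comp <- seq_len(nrow(wm))
      repeat {
        changed <- FALSE
        for (a in seq_len(nrow(wm))) {
          for (b in seq_len(nrow(wm))) {
            if (comp[a] != comp[b] &&
              p[wm[a, 1]] <= p[wm[b, 2]] && p[wm[b, 1]] <= p[wm[a, 2]]) {
              comp[comp == comp[b]] <- comp[a]
              changed <- TRUE
            }
          }
        }
        if (!changed) break
      }
      for (cid in unique(comp)) {
        sel <- which(comp == cid)
        members <- sort(unique(unlist(
          lapply(sel, function(a) wm[a, 1]:wm[a, 2])
        )))
        rows[[length(rows) + 1L]] <- .make_dmr_row(
          dmps, orig[members],
          any_lo = any(wm[sel, 3] == 1), any_hi = any(wm[sel, 4] == 1),
          criteria, dirlab
        )
      }
    }
  }
  .finish_dmrs(rows)
}

#' Tally DMRs by methylation direction
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @return list with `n_hypo`, `n_hyper` and `fraction_hypo` (rounded to 3
#'   decimals; `NA` when there are no directional DMRs).
#' @examples
#' # 86 hypo- and 20 hypermethylated regions -> fraction_hypo 0.811
#' @export
classify_and_tally <- function(dmrs) {
  n_hypo <- sum(dmrs$direction == "hypo")
  n_hyper <- sum(dmrs$direction == "hyper")
  list(
    n_hypo = n_hypo, n_hyper = n_hyper,
    fraction_hypo = if (n_hypo + n_hyper == 0) {
      NA_real_
    } else {
      round(n_hypo / (n_hypo + n_hyper), 3)
    }
  )
}
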