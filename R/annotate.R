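# Gene-relative annotation of DMRs.

#' Label DMRs by their position relative to gene models
#'
#' Each DMR is labelled `promoter` (overlapping the configurable region
#' upstream of a transcription start site), `exon-intron` (spanning an
#' exon/intron boundary), `exon`, `intron` or `intergenic`, with ties
#' resolved by the precedence promoter > exon-intron > exon > intron.
#' Without a gene model all DMRs are labelled `unannotated`.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param gene_model data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`+`/`-`), `feature` (`transcript` or
#'   `exon`) and `name` (transcript id grouping exons), or `NULL`.
#' @param promoter_bp upstream promoter distance in bp (default 2000).
#' @return `dmrs` with an added `location` column.
#' @export
annotate_relative_location <- function(dmrs, gene_model = NULL,
                                       promoter_bp = 2000) {
  if (nrow(dmrs) == 0) {
    dmrs$location <- character(0)
    return(dmrs)
  }
  if (is.null(gene_model)) {
    dmrs$location <- "unannotated"
    return(dmrs)
  }
  stopifnot(all(c("chrom", "start", "end", "strand", "feature", "name") %in%
    names(gene_model)))
  tx <- gene_model[gene_model$feature == "transcript", , drop = FALSE]
  ex <- gene_model[gene_model$feature == "exon", , drop = FALSE]
  gr <- function(df) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  dmr_gr <- gr(dmrs)
  tx_gr <- gr(tx)
  ex_gr <- gr(ex)
  prom <- data.frame(
    chrom = tx$chrom,
    start = ifelse(tx$strand == "+", tx$start - promoter_bp, tx$end + 1),
    end = ifelse(tx$strand == "+", tx$start - 1, tx$end + promoter_bp)
  )
  prom$start <- pmax(prom$start, 1)
  prom_gr <- gr(prom)
  in_prom <- IRanges::overlapsAny(dmr_gr, prom_gr)
  hit_tx <- GenomicRanges::findOverlaps(dmr_gr, tx_gr)
  location <- rep("intergenic", nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    txs <- S4Vectors::subjectHits(hit_tx)[S4Vectors::queryHits(hit_tx) == i]
    lab <- "intergenic"
    for (t in txs) {
      exons_t <- ex_gr[ex$name == tx$name[t]]
      piece <- GenomicRanges::pintersect(dmr_gr[i], tx_gr[t])
      ov_exon <- IRanges::overlapsAny(piece, exons_t)
      outside_exon <- sum(GenomicRanges::width(
        GenomicRanges::setdiff(piece, exons_t)
      )) > 0
      cand <- if (ov_exon && outside_exon) {
        "exon-intron"
      } else if (ov_exon) {
        "exon"
      } else {
        "intron"
      }
      rank <- c("exon-intron" = 1, exon = 2, intron = 3, intergenic = 4)
      if (rank[[cand]] < rank[[lab]]) lab <- cand
    }
    location[i] <- lab
  }
  location[in_prom] <- "promoter"
  dmrs$location <- location
  dmrs
}
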