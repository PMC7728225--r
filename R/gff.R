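#' Export an annotation to GFF3
#'
#' Writes ORFs as `CDS` features and promoter motif hits as
#' `regulatory_region` features. Internal 0-based half-open coordinates are
#' converted to the 1-based inclusive convention of GFF3. Motif-hit genomic
#' spans are reconstructed from each hit's upstream offset and the strand of
#' its ORF.
#'
#' @param genome An [genome()] object.
#' @param orfs ORF data frame from [call_orfs()].
#' @param motif_hits Optional motif-hit data frame from
#'   [scan_early_promoters()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genome, orfs, motif_hits = NULL, path) {
  g <- as_genome(genome)
  feats <- list()
  if (nrow(orfs) > 0L) {
    feats$cds <- GenomicRanges::GRanges(
      seqnames = g$id,
      ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
      strand = orfs$strand,
      type = "CDS", ID = orfs$orf_id, phase = 0L)
  }
  if (!is.null(motif_hits) && nrow(motif_hits) > 0L) {
    m <- merge(motif_hits, orfs[, c("orf_id", "start", "end", "strand")],
               by = "orf_id", sort = FALSE)
    # motif last base sits `offset` bp 5' of the start codon on the ORF strand
    gstart <- ifelse(m$strand == "+", m$start - m$offset - 8L,
                     m$end + m$offset)
    feats$motif <- GenomicRanges::GRanges(
      seqnames = g$id,
      ranges = IRanges::IRanges(start = gstart, width = 10L),
      strand = m$strand,
      type = "regulatory_region",
      ID = sprintf("%s_promoter_%d", m$orf_id, seq_len(nrow(m))),
      phase = NA_integer_)
  }
  if (length(feats) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- suppressWarnings(do.call(c, unname(feats)))
  }
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(g$length, g$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
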