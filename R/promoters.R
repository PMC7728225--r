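#' Scan ORF upstream regions for the entomopoxvirus early-promoter motif
#'
#' The early-promoter motif `TGAAAXXXXA` (positions 1-5 fixed `TGAAA`,
#' positions 6-9 any base, position 10 `A`) is conserved upstream of
#' entomopoxvirus early genes and is read on the coding strand by the virion
#' transcription machinery. For each ORF the `window` bases immediately 5'
#' of the start codon on the ORF's own strand are scanned; for minus-strand
#' ORFs this is the reverse complement of the forward-strand bases 3' of the
#' ORF's forward-coordinate end. Overlapping occurrences are all reported,
#' and windows truncated by a genome end use the available bases only.
#'
#' @param genome An [genome()] object.
#' @param orfs ORF data frame from [call_orfs()].
#' @param window Upstream window size in bp (excludes the A of ATG; an
#'   offset of 1 is the base immediately before it). Default 100.
#' @return Data frame with columns `orf_id`, `offset` (bp from the match's
#'   last base to the start codon), and `matched_seq` (the 10-mer).
#' @export
scan_early_promoters <- function(genome, orfs, window = 100) {
  g <- as_genome(genome)
  stopifnot(is.data.frame(orfs), window >= 1)
  out <- list()
  for (i in seq_len(nrow(orfs))) {
    w <- upstream_window(g, orfs$start[i], orfs$end[i], orfs$strand[i], window)
    if (nchar(w) < 10L) next
    hits <- motif_positions(w)
    if (length(hits) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      orf_id = orfs$orf_id[i],
      offset = nchar(w) - (hits + 9L) + 1L,
      matched_seq = substring(w, hits, hits + 9L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(orf_id = character(), offset = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Upstream window on the ORF's strand, 5'->3' toward the start codon.
upstream_window <- function(g, start, end, strand, window) {
  if (strand == "+") {
    lo <- max(0L, start - window)
    if (start == 0L) return("")
    substr(g$sequence, lo + 1L, start)
  } else {
    hi <- min(g$length, end + window)
    if (end >= g$length) return("")
    reverse_complement(substr(g$sequence, end + 1L, hi))
  }
}

# 1-based start positions of every (possibly overlapping) motif occurrence.
motif_positions <- function(w) {
  m <- gregexpr("(?=TGAAA[ACGTN]{4}A)", w, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}
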