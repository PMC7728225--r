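#' Call open reading frames in all six frames
#'
#' Scans each of the six reading frames for stop-to-stop segments and emits,
#' per segment, the ORF running from the *first* ATG to the stop codon
#' (longest ORF per stop). The stop codon is included in the coordinates but
#' excluded from the protein. Coordinates are 0-based, half-open, and always
#' reported on the forward strand regardless of the ORF's strand. Codons that
#' contain `N` do not translate: they terminate the scan of the current
#' segment and no ORF spanning them is emitted. Segments that run off either
#' genome end without a stop codon are not emitted.
#'
#' @param genome An [genome()] object (or a single DNA string).
#' @param min_aa Minimum protein length in amino acids (initial methionine
#'   included, stop excluded). Default 50, the conventional threshold for
#'   poxvirus annotation.
#' @return A data frame with columns `orf_id`, `start`, `end`, `strand`,
#'   `protein`, `protein_length`, ordered by `start` then `end`.
#' @examples
#' call_orfs(genome("toy", "ATGAAATAA"), min_aa = 2)
#' @export
call_orfs <- function(genome, min_aa = 50) {
  g <- as_genome(genome)
  stopifnot(is.numeric(min_aa), min_aa >= 1)
  G <- g$length
  frames <- vector("list", 6L)
  k <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$sequence else reverse_complement(g$sequence)
    for (off in 0:2) {
      k <- k + 1L
      frames[[k]] <- orfs_in_frame(s, off, strand, G, min_aa)
    }
  }
  res <- do.call(rbind, frames)
  if (is.null(res) || nrow(res) == 0L) {
    return(empty_orf_frame())
  }
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_orf_frame <- function() {
  data.frame(orf_id = character(), start = integer(), end = integer(),
             strand = character(), protein = character(),
             protein_length = integer(), stringsAsFactors = FALSE)
}

orf_identifier <- function(start, end, strand) {
  sprintf("ORF_%07d_%07d_%s", start, end, ifelse(strand == "+", "p", "m"))
}

# One reading frame of one strand. `s` is the strand-local sequence, `off`
# the frame offset (0..2), coordinates are converted back to the forward
# strand for "-" ORFs.
orfs_in_frame <- function(s, off, strand, G, min_aa) {
  n <- (nchar(s) - off) %/% 3L
  if (n < 1L) return(NULL)
  cs <- off + 3L * (seq_len(n) - 1L) + 1L          # 1-based codon starts
  codons <- substring(s, cs, cs + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])   # NA for N-containing codons
  is_stop <- !is.na(aa) & aa == "*"
  is_barrier <- is.na(aa) | is_stop                # stops and untranslatable codons
  bar <- which(is_barrier)
  if (length(bar) == 0L) return(NULL)
  prev <- c(0L, bar[-length(bar)])                 # barrier preceding each segment
  atg <- which(codons == "ATG")
  # index of first ATG strictly after the previous barrier (NA if none)
  first_atg <- if (length(atg)) atg[findInterval(prev, atg) + 1L] else rep(NA_integer_, length(bar))
  sel <- is_stop[bar] & !is.na(first_atg) & (bar - first_atg) >= min_aa
  if (!any(sel)) return(NULL)
  a <- first_atg[sel]
  b <- bar[sel]
  local_start <- off + (a - 1L) * 3L               # 0-based on local strand
  local_end <- off + b * 3L
  if (strand == "+") {
    start <- local_start; end <- local_end
  } else {
    start <- G - local_end; end <- G - local_start
  }
  protein <- mapply(function(i, j) paste(aa[i:(j - 1L)], collapse = ""),
                    a, b, USE.NAMES = FALSE)
  data.frame(orf_id = orf_identifier(start, end, strand),
             start = as.integer(start), end = as.integer(end),
             strand = strand, protein = protein,
             protein_length = as.integer(b - a),
             stringsAsFactors = FALSE)
}

#' Filter ORFs with highly repetitive protein sequences
#'
#' Replaces manual curation of low-complexity calls with two automatic rules:
#' an ORF is discarded iff its most frequent amino acid makes up at least
#' `max_single_aa_frac` of the protein, or the Shannon entropy of its
#' overlapping dipeptide distribution is below `min_dipeptide_entropy` bits.
#' Proteins shorter than 2 aa are always kept (dipeptide entropy undefined).
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @param max_single_aa_frac Discard when the top amino-acid fraction reaches
#'   this value. Default 0.5.
#' @param min_dipeptide_entropy Discard when dipeptide entropy (bits) falls
#'   below this value. Default 2.0.
#' @return List with elements `kept` and `discarded`, each an ORF data frame;
#'   together they partition the input.
#' @export
filter_repetitive <- function(orfs, max_single_aa_frac = 0.5,
                              min_dipeptide_entropy = 2.0) {
  stopifnot(is.data.frame(orfs))
  if (nrow(orfs) == 0L) return(list(kept = orfs, discarded = orfs))
  drop <- vapply(orfs$protein, function(p) {
    n <- nchar(p)
    if (n < 2L) return(FALSE)
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    if (max(table(chars)) / n >= max_single_aa_frac) return(TRUE)
    dipeptide_entropy(p) < min_dipeptide_entropy
  }, logical(1), USE.NAMES = FALSE)
  list(kept = orfs[!drop, , drop = FALSE],
       discarded = orfs[drop, , drop = FALSE])
}

# Shannon entropy (bits) of the overlapping dipeptide distribution.
dipeptide_entropy <- function(protein) {
  n <- nchar(protein)
  if (n < 2L) return(NA_real_)
  dip <- substring(protein, 1:(n - 1L), 2:n)
  p <- as.numeric(table(dip)) / (n - 1L)
  -sum(p * log2(p))
}
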