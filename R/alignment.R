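#' Construct a protein alignment object
#'
#' @param seqs Named character vector of aligned protein sequences (gap
#'   symbol `-`; `.` is also treated as a gap), all the same length, at
#'   least two taxa.
#' @return Object of class `protein_alignment`: list with `taxa` and a
#'   taxa-by-columns character `matrix`.
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 taxa")
  if (anyDuplicated(names(seqs))) stop("duplicated taxon labels")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences differ in length")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  structure(list(taxa = names(seqs), matrix = m), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d taxa x %d columns\n",
              length(x$taxa), ncol(x$matrix)))
  invisible(x)
}

aln_width <- function(aln) ncol(aln$matrix)

aln_to_strings <- function(aln) {
  s <- apply(aln$matrix, 1L, paste, collapse = "")
  names(s) <- aln$taxa
  s
}

#' Read a protein alignment from multi-FASTA
#'
#' @param path Path to an aligned multi-FASTA file.
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("alignment file is empty: ", path)
  seqs <- as.character(recs)
  names(seqs) <- sub("\\s.*$", "", names(recs))
  protein_alignment(seqs)
}

#' Write a protein alignment to multi-FASTA
#'
#' @param aln A [protein_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_alignment <- function(aln, path) {
  s <- Biostrings::BStringSet(aln_to_strings(aln))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Trim gap-rich alignment columns
#'
#' Retains exactly the columns whose gap fraction is at most `max_gap_frac`;
#' columns where *more* than that fraction of taxa carry a gap are removed
#' (strict inequality, so a 4-taxon column with exactly 2 gaps survives the
#' default 0.5 threshold). Row order is preserved. Idempotent.
#'
#' @param aln A [protein_alignment()].
#' @param max_gap_frac Maximum tolerated per-column gap fraction. Default 0.5.
#' @return The trimmed [protein_alignment()].
#' @export
trim_alignment <- function(aln, max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "protein_alignment"),
            max_gap_frac >= 0, max_gap_frac <= 1)
  gap_frac <- colMeans(aln$matrix == "-" | aln$matrix == ".")
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) stop("all alignment columns removed; degenerate alignment")
  structure(list(taxa = aln$taxa,
                 matrix = aln$matrix[, keep, drop = FALSE]),
            class = "protein_alignment")
}

#' Concatenate alignments into a supermatrix
#'
#' Column-wise concatenation in input order; all alignments must share the
#' identical taxon set (rows are reordered to the first alignment's taxa).
#'
#' @param alns List of [protein_alignment()] objects.
#' @return One [protein_alignment()] whose width is the sum of the inputs'.
#' @export
concatenate_alignments <- function(alns) {
  stopifnot(is.list(alns), length(alns) >= 1L)
  ref <- alns[[1]]$taxa
  for (i in seq_along(alns)) {
    diff <- c(setdiff(ref, alns[[i]]$taxa), setdiff(alns[[i]]$taxa, ref))
    if (length(diff) > 0L) {
      stop("alignment ", i, " taxon set differs; mismatched taxa: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  mats <- lapply(alns, function(a) a$matrix[ref, , drop = FALSE])
  structure(list(taxa = ref, matrix = do.call(cbind, mats)),
            class = "protein_alignment")
}
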