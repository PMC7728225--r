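#' Construct a genome object
#'
#' A genome is a single linear double-stranded DNA sequence identified by a
#' text label. Sequences are uppercased and restricted to the 5-letter DNA
#' alphabet `A,C,G,T,N` (N = unknown base). Poxvirus genomes are linear dsDNA
#' molecules, so one record corresponds to one genome.
#'
#' @param id Text label for the genome.
#' @param sequence DNA sequence as a single character string.
#' @return An object of class `epv_genome` with elements `id`, `sequence`
#'   (uppercase) and `length` (bp).
#' @examples
#' g <- genome("toy", "acgtACGT")
#' g$length
#' @export
genome <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  validate_dna(sequence, id)
  if (nchar(sequence) < 1L) {
    stop("genome '", id, "' has an empty sequence")
  }
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "epv_genome")
}

#' @export
print.epv_genome <- function(x, ...) {
  cat(sprintf("<epv_genome> %s: %d bp\n", x$id, x$length))
  invisible(x)
}

# Coerce a character string or epv_genome to epv_genome.
as_genome <- function(x, id = "genome") {
  if (inherits(x, "epv_genome")) return(x)
  if (is.character(x) && length(x) == 1L) return(genome(id, x))
  stop("expected an 'epv_genome' or a single DNA string")
}

# Error if a sequence contains anything outside {A,C,G,T,N}; names the record
# and the first offending character. U is deliberately rejected (DNA only).
validate_dna <- function(sequence, id) {
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("record '", id, "' contains non-DNA character '",
         substr(bad, 1L, 1L), "'")
  }
  invisible(TRUE)
}

#' Read genomes from a FASTA file
#'
#' Each FASTA record becomes one [genome()]. Sequences are uppercased; any
#' character outside `A,C,G,T,N` (including `U`) is an error that names the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `epv_genome` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- genome(ids[i], as.character(recs[[i]]))
  }
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes A single `epv_genome` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "epv_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Vectorised
#' over its input. Accepts an `epv_genome`, in which case the reverse
#' complement of its sequence is returned as a string.
#'
#' @param seq Character vector of DNA strings (alphabet `A,C,G,T,N`), or an
#'   `epv_genome`.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "epv_genome")) seq <- seq$sequence
  stopifnot(is.character(seq))
  seq <- toupper(seq)
  for (i in seq_along(seq)) validate_dna(seq[i], paste0("input[", i, "]"))
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}
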