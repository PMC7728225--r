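#' Detect inverted terminal repeats
#'
#' Linear poxvirus genomes end in inverted terminal repeats (ITRs): the
#' reverse complement of the right terminus matches the left terminus.
#' Detection is anchored at position 0: the genome prefix is compared
#' base-by-base against the reverse complement of the genome (whose prefix is
#' the reverse complement of the suffix). The first `min_seed` bases must
#' match exactly; the repeat is then the *maximal* length
#' `L <= floor(G/2)` at which the cumulative mismatch fraction stays at or
#' below `max_mismatch_frac`.
#'
#' @param genome An [genome()] object (or DNA string) of length at least
#'   `2 * min_seed`.
#' @param min_seed Exact-match seed length in bp anchored at the termini.
#'   Default 25.
#' @param max_mismatch_frac Maximum tolerated cumulative mismatch fraction
#'   during extension. Default 0.02. Use 0 for exact repeats.
#' @return An object of class `epv_itr` with elements `length`, `identity`,
#'   `left_span` and `right_span` (0-based half-open intervals), or `NULL`
#'   when the termini do not seed.
#' @export
detect_itrs <- function(genome, min_seed = 25, max_mismatch_frac = 0.02) {
  g <- as_genome(genome)
  G <- g$length
  stopifnot(min_seed >= 1, max_mismatch_frac >= 0, max_mismatch_frac < 1)
  if (G < 2 * min_seed) {
    stop("genome shorter than 2 * min_seed (", 2 * min_seed, " bp)")
  }
  half <- G %/% 2L
  a <- strsplit(substr(g$sequence, 1L, half), "", fixed = TRUE)[[1]]
  rc <- reverse_complement(substring(g$sequence, G - half + 1L, G))
  b <- strsplit(rc, "", fixed = TRUE)[[1]]
  mm <- cumsum(a != b)
  if (mm[min_seed] > 0L) return(NULL)
  L_all <- seq.int(min_seed, half)
  ok <- L_all[mm[L_all] <= max_mismatch_frac * L_all]
  L <- max(ok)
  structure(list(length = L,
                 identity = 1 - mm[L] / L,
                 left_span = c(0L, L),
                 right_span = c(G - L, G)),
            class = "epv_itr")
}

#' @export
print.epv_itr <- function(x, ...) {
  cat(sprintf("<epv_itr> length %d bp, identity %.4f; left [%d,%d), right [%d,%d)\n",
              x$length, x$identity, x$left_span[1], x$left_span[2],
              x$right_span[1], x$right_span[2]))
  invisible(x)
}
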