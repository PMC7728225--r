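#' Compute per-genome summary metrics
#'
#' GC content is computed over called bases only (`N` excluded from the
#' denominator: an unknown base carries no composition information). Coding
#' density is the fraction of the genome covered by the union of ORF
#' intervals, both strands pooled, so overlapping ORFs are not counted twice.
#'
#' @param genome An [genome()] object.
#' @param orfs ORF data frame from [call_orfs()] (may be empty).
#' @param itr An `epv_itr` from [detect_itrs()], or `NULL` for none.
#' @return One-row data frame with columns `genome_id`, `length_bp`,
#'   `gc_percent`, `coding_density_percent`, `orf_count`, `itr_length_bp`.
#' @export
compute_genome_metrics <- function(genome, orfs, itr = NULL) {
  g <- as_genome(genome)
  stopifnot(is.data.frame(orfs))
  if (nrow(orfs) > 0L) {
    stopifnot(all(orfs$start >= 0L), all(orfs$end <= g$length),
              all(orfs$start < orfs$end))
  }
  base_counts <- table(factor(strsplit(g$sequence, "", fixed = TRUE)[[1]],
                              levels = c("A", "C", "G", "T", "N")))
  called <- g$length - base_counts[["N"]]
  if (called == 0L) stop("genome '", g$id, "' is all N; GC content undefined")
  gc <- 100 * (base_counts[["G"]] + base_counts[["C"]]) / called
  covered <- if (nrow(orfs) == 0L) 0L else {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = orfs$start + 1L, end = orfs$end))))
  }
  data.frame(genome_id = g$id,
             length_bp = g$length,
             gc_percent = gc,
             coding_density_percent = 100 * covered / g$length,
             orf_count = nrow(orfs),
             itr_length_bp = if (is.null(itr)) 0L else itr$length,
             stringsAsFactors = FALSE)
}
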