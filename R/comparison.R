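#' Cross-genome comparison table with mean +/- SD summaries
#'
#' Tabulates per-genome metrics and summarises each numeric column as the
#' mean and sample standard deviation (n-1 denominator) over all genomes
#' *except* a designated focal genome, so that the focal genome can be
#' contrasted against the background of its relatives (e.g. a gene-sparse
#' genome against the typical coding density of its family).
#'
#' @param metrics Data frame with a `genome_id` column and numeric metric
#'   columns (e.g. rows from [compute_genome_metrics()], or gene-family copy
#'   numbers per genome).
#' @param focal_id `genome_id` of the focal genome excluded from the
#'   summaries. Use `NULL` to summarise all rows.
#' @return List of class `genome_comparison` with `rows` (the input),
#'   `focal` (the focal row or `NULL`) and `summary`: one row per metric
#'   with `mean`, `sd` (NA when fewer than 2 non-focal genomes) and
#'   `n_other`.
#' @export
comparison_table <- function(metrics, focal_id = NULL) {
  stopifnot(is.data.frame(metrics), "genome_id" %in% names(metrics))
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  if (length(num_cols) == 0L) stop("no numeric metric columns to summarise")
  other <- metrics
  focal <- NULL
  if (!is.null(focal_id)) {
    if (!focal_id %in% metrics$genome_id) {
      stop("focal genome '", focal_id, "' not found")
    }
    focal <- metrics[metrics$genome_id == focal_id, , drop = FALSE]
    other <- metrics[metrics$genome_id != focal_id, , drop = FALSE]
  }
  if (nrow(other) < 1L) stop("no non-focal genomes to summarise")
  summary <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cl) mean(other[[cl]]), 0),
    sd = vapply(num_cols, function(cl) {
      if (nrow(other) < 2L) NA_real_ else stats::sd(other[[cl]])
    }, 0),
    n_other = nrow(other),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(rows = metrics, focal = focal, summary = summary),
            class = "genome_comparison")
}

#' @export
print.genome_comparison <- function(x, ...) {
  if (!is.null(x$focal)) {
    cat("focal genome:", x$focal$genome_id, "\n")
  }
  cat(sprintf("background: %d genome(s)\n", x$summary$n_other[1]))
  print(x$summary)
  invisible(x)
}
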