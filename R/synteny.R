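#' Build an ortholog dot plot between two genomes
#'
#' Each point is a gene shared between the two position maps, plotted at its
#' genomic position (conventionally the gene's interval midpoint on the
#' forward strand) in each genome. The dot plot is the substrate for
#' collinear-block (synteny) detection.
#'
#' @param map_a,map_b Gene position maps: either a named numeric vector
#'   (names = gene, values = bp position) or a data frame with columns
#'   `gene` and `pos`.
#' @param genome_a_id,genome_b_id Labels for the two genomes.
#' @return Data frame of class `ortholog_dotplot` with columns `gene`,
#'   `pos_a`, `pos_b`, ordered by `pos_a`; genome labels stored as
#'   attributes `genome_a_id` / `genome_b_id`.
#' @export
build_dotplot <- function(map_a, map_b, genome_a_id = "A", genome_b_id = "B") {
  a <- as_gene_map(map_a)
  b <- as_gene_map(map_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    stop("no shared genes between '", genome_a_id, "' and '", genome_b_id, "'")
  }
  pts <- data.frame(gene = shared, pos_a = unname(a[shared]),
                    pos_b = unname(b[shared]), stringsAsFactors = FALSE)
  pts <- pts[order(pts$pos_a), , drop = FALSE]
  rownames(pts) <- NULL
  attr(pts, "genome_a_id") <- genome_a_id
  attr(pts, "genome_b_id") <- genome_b_id
  class(pts) <- c("ortholog_dotplot", "data.frame")
  pts
}

as_gene_map <- function(m) {
  if (is.data.frame(m)) {
    stopifnot(all(c("gene", "pos") %in% names(m)))
    v <- m$pos
    names(v) <- m$gene
    m <- v
  }
  stopifnot(is.numeric(m), !is.null(names(m)))
  if (anyDuplicated(names(m))) stop("duplicated gene names in position map")
  m
}

#' Midpoint position map from an ORF or annotation table
#'
#' @param features Data frame with `start`, `end` (0-based half-open) and a
#'   gene name column.
#' @param name_col Column holding gene names. Default `"core_gene_name"`.
#' @return Named numeric vector of interval midpoints (bp).
#' @export
gene_midpoints <- function(features, name_col = "core_gene_name") {
  stopifnot(is.data.frame(features), name_col %in% names(features))
  keep <- !is.na(features[[name_col]]) & features[[name_col]] != ""
  v <- (features$start[keep] + features$end[keep]) / 2
  names(v) <- features[[name_col]][keep]
  v
}

#' Find collinear gene blocks in a dot plot
#'
#' A collinear block is a maximal-cardinality chain of dots monotone in both
#' genomes: increasing in both (`same` orientation) or increasing in A while
#' decreasing in B (`inverted`, the "negative linear arrangement" signature
#' of an inverted syntenic segment). Chains are extracted greedily: the
#' longest monotone chain over both orientations is reported and its points
#' removed, until no chain of `min_genes` points remains. Ties are broken by
#' the smaller starting position in genome A, then by `same` orientation.
#'
#' @param points An `ortholog_dotplot` from [build_dotplot()].
#' @param min_genes Minimum genes per reported block. Default 4.
#' @return Data frame with one row per block: `n_genes`, `orientation`,
#'   `a_start`, `a_end`, `b_start`, `b_end` (bp spans) and a list column
#'   `genes` (gene names ordered by position in A), longest block first.
#' @export
find_collinear_blocks <- function(points, min_genes = 4) {
  stopifnot(is.data.frame(points), min_genes >= 1)
  pts <- as.data.frame(points)[order(points$pos_a), , drop = FALSE]
  remaining <- seq_len(nrow(pts))
  blocks <- list()
  while (length(remaining) >= min_genes) {
    v <- pts$pos_b[remaining]
    chain_same <- longest_monotone_chain(v, decreasing = FALSE)
    chain_inv <- longest_monotone_chain(v, decreasing = TRUE)
    pick <- choose_chain(chain_same, chain_inv, pts$pos_a[remaining])
    chain <- pick$chain
    if (length(chain) < min_genes) break
    sel <- remaining[chain]
    blocks[[length(blocks) + 1L]] <- list(
      genes = pts$gene[sel],
      orientation = pick$orientation,
      a_start = min(pts$pos_a[sel]), a_end = max(pts$pos_a[sel]),
      b_start = min(pts$pos_b[sel]), b_end = max(pts$pos_b[sel]),
      n_genes = length(sel))
    remaining <- setdiff(remaining, sel)
  }
  if (length(blocks) == 0L) {
    return(data.frame(n_genes = integer(), orientation = character(),
                      a_start = numeric(), a_end = numeric(),
                      b_start = numeric(), b_end = numeric(),
                      genes = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    n_genes = vapply(blocks, `[[`, 0L, "n_genes"),
    orientation = vapply(blocks, `[[`, "", "orientation"),
    a_start = vapply(blocks, `[[`, 0, "a_start"),
    a_end = vapply(blocks, `[[`, 0, "a_end"),
    b_start = vapply(blocks, `[[`, 0, "b_start"),
    b_end = vapply(blocks, `[[`, 0, "b_end"),
    stringsAsFactors = FALSE)
  df$genes <- I(lapply(blocks, `[[`, "genes"))
  df <- df[order(-df$n_genes, df$a_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

choose_chain <- function(chain_same, chain_inv, pos_a) {
  ls <- length(chain_same); li <- length(chain_inv)
  if (ls > li) return(list(chain = chain_same, orientation = "same"))
  if (li > ls) return(list(chain = chain_inv, orientation = "inverted"))
  if (ls == 0L) return(list(chain = integer(0), orientation = "same"))
  if (pos_a[chain_inv[1]] < pos_a[chain_same[1]]) {
    list(chain = chain_inv, orientation = "inverted")
  } else {
    list(chain = chain_same, orientation = "same")
  }
}

# Longest strictly monotone subsequence (indices); O(n^2) dynamic program.
# Deterministic: among equal-length chains the earliest-starting one wins.
longest_monotone_chain <- function(v, decreasing = FALSE) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  if (decreasing) v <- -v
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (v[j] < v[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len)  # first maximum -> earliest end
  chain <- integer(len[end])
  k <- len[end]
  while (!is.na(end)) {
    chain[k] <- end
    k <- k - 1L
    end <- prev[end]
  }
  chain
}

#' Plot an ortholog dot plot
#'
#' @param x An `ortholog_dotplot`.
#' @param ... Passed to [graphics::plot()].
#' @method plot ortholog_dotplot
#' @export
plot.ortholog_dotplot <- function(x, ...) {
  graphics::plot(x$pos_a / 1000, x$pos_b / 1000,
                 xlab = paste0(attr(x, "genome_a_id"), " position (kb)"),
                 ylab = paste0(attr(x, "genome_b_id"), " position (kb)"),
                 pch = 19, ...)
  invisible(x)
}
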