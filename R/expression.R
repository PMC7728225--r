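#' Construct an expression study
#'
#' Bundles a gene-by-sample integer count matrix with per-gene transcript
#' lengths and a per-sample host label. The two hosts are the wasp venom
#' gland (where the virus amplifies) and the parasitized fly (where it is
#' virulent); labels must be `"wasp"` and `"fly"`.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param gene_lengths Positive lengths in bp, one per gene.
#' @param sample_group Character vector over `{"wasp","fly"}`, one per
#'   sample; both groups must be present.
#' @return Object of class `expression_study`.
#' @export
expression_study <- function(counts, gene_lengths, sample_group) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)),
            length(gene_lengths) == nrow(counts),
            all(gene_lengths > 0),
            length(sample_group) == ncol(counts))
  if (!all(sample_group %in% c("wasp", "fly"))) {
    stop("sample_group labels must be 'wasp' or 'fly'")
  }
  if (length(unique(sample_group)) < 2L) {
    stop("both host groups must be present")
  }
  structure(list(counts = counts,
                 gene_lengths = as.numeric(gene_lengths),
                 sample_group = as.character(sample_group)),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%d wasp, %d fly)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$sample_group == "wasp"), sum(x$sample_group == "fly")))
  invisible(x)
}

#' Fragments per kilobase per million mapped fragments (FPKM)
#'
#' `fpkm[g, s] = counts[g, s] / ((length_g / 1e3) * (total_s / 1e6))` with
#' `total_s` the column sum of the count matrix, i.e. expression normalised
#' for transcript length and sequencing depth.
#'
#' @param counts Gene-by-sample count matrix.
#' @param gene_lengths Transcript lengths in bp, one per gene.
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts / (gene_lengths / 1e3), 2L, totals / 1e6, "/")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * n / j)`, clipped at 1 and mapped back to input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression test
#'
#' Per gene, expression is summarised as `y = log2(FPKM + pseudocount)` and
#' the wasp and fly groups are compared with a Welch two-sample t-test; the
#' log2 fold change is the difference of group means of `y` (wasp over fly).
#' P-values are adjusted with [bh_fdr()] and genes with `q < alpha` are
#' flagged significant. A gene with zero variance in both groups gets
#' `p = 1` when the group means are equal (no evidence of change) and
#' `p = 0` when they differ (a degenerate, noiseless difference).
#'
#' @param study An [expression_study()] with at least 2 replicates per group.
#' @param alpha FDR significance threshold. Default 0.05.
#' @param pseudocount Added to FPKM before the log. Default 1.
#' @return Data frame of class `epv_de`: `gene_id`, `mean_fpkm_wasp`,
#'   `mean_fpkm_fly`, `log2fc`, `p`, `q`, `significant`, `cluster`
#'   (`NA` until [cluster_genes()] labels are attached; see
#'   [run_expression_analysis()]).
#' @export
de_test <- function(study, alpha = 0.05, pseudocount = 1.0) {
  stopifnot(inherits(study, "expression_study"))
  w <- study$sample_group == "wasp"
  f <- study$sample_group == "fly"
  if (sum(w) < 2L || sum(f) < 2L) {
    stop("at least 2 replicates per group are required")
  }
  fpkm <- compute_fpkm(study$counts, study$gene_lengths)
  y <- log2(fpkm + pseudocount)
  p <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    yw <- y[i, w]; yf <- y[i, f]
    if (stats::var(yw) == 0 && stats::var(yf) == 0) {
      p[i] <- if (mean(yw) == mean(yf)) 1 else 0
    } else {
      p[i] <- tryCatch(stats::t.test(yw, yf)$p.value,
                       error = function(e) {
                         if (isTRUE(all.equal(mean(yw), mean(yf)))) 1 else 0
                       })
    }
  }
  q <- bh_fdr(p)
  res <- data.frame(
    gene_id = rownames(study$counts),
    mean_fpkm_wasp = rowMeans(fpkm[, w, drop = FALSE]),
    mean_fpkm_fly = rowMeans(fpkm[, f, drop = FALSE]),
    log2fc = rowMeans(y[, w, drop = FALSE]) - rowMeans(y[, f, drop = FALSE]),
    p = p, q = q, significant = q < alpha,
    cluster = NA_character_,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("epv_de", "data.frame")
  res
}

#' Cluster genes into expression groups (Ward linkage)
#'
#' Hierarchical agglomerative clustering with the Ward criterion
#' (Lance-Williams `ward.D2` on Euclidean distances) of
#' `log10(FPKM + pseudocount)` row vectors, cut at `k` clusters. With
#' `k = 2` the clusters are named by effect sign: the cluster with the
#' higher mean log2 fold change is `up_in_wasp`, the other `down_in_wasp`;
#' a tie is resolved by placing the lexicographically first gene's cluster
#' in `up_in_wasp`.
#'
#' @param fpkm FPKM matrix of the genes to cluster (rownames = gene ids).
#' @param log2fc Per-gene log2 fold changes (wasp over fly), same order.
#' @param k Number of clusters. Default 2.
#' @param pseudocount Added to FPKM before the log. Default 1.
#' @return Named character vector of cluster labels.
#' @export
cluster_genes <- function(fpkm, log2fc, k = 2, pseudocount = 1.0) {
  fpkm <- as.matrix(fpkm)
  stopifnot(nrow(fpkm) >= 1, length(log2fc) == nrow(fpkm))
  if (k > nrow(fpkm)) stop("k exceeds the number of genes")
  x <- log10(fpkm + pseudocount)
  ct <- if (nrow(fpkm) == 1L) {
    stats::setNames(1L, rownames(fpkm))
  } else {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    stats::cutree(hc, k = k)
  }
  if (k == 2L) {
    m <- tapply(log2fc, ct, mean)
    up_cl <- if (m[["1"]] != m[["2"]]) {
      as.integer(names(which.max(m)))
    } else {
      ct[[order(rownames(fpkm))[1]]]  # tie: first gene lexicographically
    }
    labels <- ifelse(ct == up_cl, "up_in_wasp", "down_in_wasp")
  } else {
    labels <- paste0("cluster_", ct)
  }
  stats::setNames(labels, rownames(fpkm))
}

#' Differential expression with cluster labels attached
#'
#' Convenience wrapper: runs [de_test()], clusters the significant genes
#' with [cluster_genes()] (k = 2), and fills the `cluster` column.
#'
#' @inheritParams de_test
#' @param k Number of expression clusters. Default 2.
#' @return The [de_test()] result with `cluster` filled for significant
#'   genes.
#' @export
run_expression_analysis <- function(study, alpha = 0.05, pseudocount = 1.0,
                                    k = 2) {
  de <- de_test(study, alpha = alpha, pseudocount = pseudocount)
  sig <- which(de$significant)
  if (length(sig) >= k) {
    fpkm <- compute_fpkm(study$counts, study$gene_lengths)
    labels <- cluster_genes(fpkm[sig, , drop = FALSE], de$log2fc[sig],
                            k = k, pseudocount = pseudocount)
    de$cluster[sig] <- unname(labels)
  }
  de
}

#' Category-by-cluster partition summary
#'
#' The headline bookkeeping of the dual-host analysis: what fraction of
#' genes are differentially expressed, how the two expression clusters are
#' populated, and how the functional categories (core replication vs the
#' virulence subcategories) distribute across `up_in_wasp` / `down_in_wasp`
#' / not-DE. Percentages are rounded to `round_dp` decimals.
#'
#' @param annotations Annotation data frame from [assign_categories()] (or
#'   any data frame with `orf_id` and `category`). Genes in the DE table
#'   with no annotation row are treated as `unknown`.
#' @param de DE data frame with cluster labels (see
#'   [run_expression_analysis()]).
#' @param round_dp Decimal places for percentages. Default 1.
#' @return List of class `epv_partition`: `n_genes`, `n_de`, `pct_de`,
#'   `n_up`, `n_down`, `contingency` (category x `{up_in_wasp,
#'   down_in_wasp, not_de}`), `pct_core_in_up`, `pct_virulence_in_down`,
#'   `mean_log2fc` and `mean_abs_log2fc` per cluster.
#' @export
partition_summary <- function(annotations, de, round_dp = 1) {
  stopifnot(is.data.frame(annotations), is.data.frame(de),
            all(c("orf_id", "category") %in% names(annotations)))
  category <- annotations$category[match(de$gene_id, annotations$orf_id)]
  category[is.na(category)] <- "unknown"
  category <- factor(category, levels = CATEGORY_LEVELS)
  status <- ifelse(!de$significant, "not_de", de$cluster)
  status <- factor(status, levels = c("up_in_wasp", "down_in_wasp", "not_de"))
  cont <- table(category = category, status = status)
  n_genes <- nrow(de)
  n_de <- sum(de$significant)
  n_up <- sum(status == "up_in_wasp", na.rm = TRUE)
  n_down <- sum(status == "down_in_wasp", na.rm = TRUE)
  pct <- function(num, den) {
    if (den == 0L) return(NA_real_)
    round(100 * num / den, round_dp)
  }
  vir_cats <- c("virulence_bro", "virulence_homology", "virulence_promoter")
  core <- category == "core_replication"
  vir <- category %in% vir_cats
  up <- status == "up_in_wasp"
  down <- status == "down_in_wasp"
  mean_by_cluster <- function(f) c(
    up_in_wasp = if (n_up) f(de$log2fc[up]) else NA_real_,
    down_in_wasp = if (n_down) f(de$log2fc[down]) else NA_real_)
  structure(list(
    n_genes = n_genes, n_de = n_de,
    pct_de = pct(n_de, n_genes),
    n_up = n_up, n_down = n_down,
    contingency = cont,
    pct_core_in_up = pct(sum(core & up), sum(core)),
    pct_virulence_in_down = pct(sum(vir & down), sum(vir)),
    mean_log2fc = mean_by_cluster(mean),
    mean_abs_log2fc = mean_by_cluster(function(z) mean(abs(z)))),
    class = "epv_partition")
}

#' @export
print.epv_partition <- function(x, ...) {
  cat(sprintf("%d/%d genes differentially expressed (%.1f%%)\n",
              x$n_de, x$n_genes, x$pct_de))
  cat(sprintf("clusters: %d up_in_wasp, %d down_in_wasp\n", x$n_up, x$n_down))
  cat(sprintf("core replication genes in up_in_wasp:   %.1f%%\n",
              x$pct_core_in_up))
  cat(sprintf("virulence genes in down_in_wasp:        %.1f%%\n",
              x$pct_virulence_in_down))
  cat(sprintf("mean |log2FC|: up %.2f, down %.2f\n",
              x$mean_abs_log2fc[["up_in_wasp"]],
              x$mean_abs_log2fc[["down_in_wasp"]]))
  print(x$contingency)
  invisible(x)
}
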