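#' Configuration for a synthetic poxvirus-like genome
#'
#' Defaults describe a ~1/5-scale model of a gene-sparse, AT-rich linear
#' entomopoxvirus genome: 50 kb with 2 kb inverted terminal repeats and 40
#' non-overlapping ORFs whose functional-category proportions mirror a
#' 193-gene annotation (45 core / 27 BRO / 6 homology / 34 promoter-only
#' virulence genes, remainder other/unknown), at 30.1% GC.
#'
#' @param genome_length Total genome length in bp.
#' @param itr_length Length of each inverted terminal repeat in bp.
#' @param n_orfs Number of planted ORFs.
#' @param orf_length_range Protein length range in aa (min, max).
#' @param category_counts Named integer vector over the functional
#'   categories; must sum to `n_orfs`.
#' @param gc_target Background GC fraction for intergenic and ITR sequence.
#' @param spacer_range Intergenic spacer length range in bp; the minimum
#'   must be at least 103 so that every 100 bp upstream window lies in
#'   scrubbed spacer sequence.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(genome_length = 50000,
                                    itr_length = 2000,
                                    n_orfs = 40,
                                    orf_length_range = c(60, 400),
                                    category_counts = c(core_replication = 9,
                                                        virulence_bro = 6,
                                                        virulence_homology = 2,
                                                        virulence_promoter = 7,
                                                        other_function = 4,
                                                        unknown = 12),
                                    gc_target = 0.301,
                                    spacer_range = c(120, 260),
                                    seed = 1) {
  stopifnot(genome_length >= 2 * itr_length,
            n_orfs >= 1,
            length(orf_length_range) == 2L,
            orf_length_range[1] >= 1,
            orf_length_range[1] <= orf_length_range[2],
            all(names(category_counts) %in% CATEGORY_LEVELS),
            sum(category_counts) == n_orfs,
            spacer_range[1] >= 103, spacer_range[1] <= spacer_range[2],
            gc_target > 0, gc_target < 1)
  structure(as.list(environment()), class = "synthetic_genome_config")
}

#' Configuration for synthetic two-host expression counts
#'
#' Defaults reproduce the study conditions of the dual-host design: 6
#' biological replicates per host, negative-binomial counts with dispersion
#' 0.05 (variance `mu + phi * mu^2`), and planted category-level log2 fold
#' changes of +2.3 for core replication genes and -3.4 for every virulence
#' subcategory (wasp over fly), with per-gene jitter (SD 0.5, log2 scale)
#' on the affected categories so clustering is non-trivial.
#'
#' @param replicates_per_group Replicates per host. Default 6.
#' @param base_mean_range Range of per-gene fly-group mean counts; means are
#'   drawn log-uniformly. Default `c(50, 500)`.
#' @param dispersion Negative-binomial dispersion `phi >= 0`
#'   (`variance = mu + phi * mu^2`); 0 gives Poisson counts. Default 0.05.
#' @param planted_log2fc Named vector of category-level planted log2 fold
#'   changes (wasp over fly); unlisted categories get 0.
#' @param jitter_sd Per-gene SD added to nonzero planted effects. Default 0.5.
#' @param seed Integer seed.
#' @return A list of class `synthetic_expression_config`.
#' @export
synthetic_expression_config <- function(replicates_per_group = 6,
                                        base_mean_range = c(50, 500),
                                        dispersion = 0.05,
                                        planted_log2fc = c(core_replication = 2.3,
                                                           virulence_bro = -3.4,
                                                           virulence_homology = -3.4,
                                                           virulence_promoter = -3.4,
                                                           other_function = 0,
                                                           unknown = 0),
                                        jitter_sd = 0.5,
                                        seed = 1) {
  stopifnot(replicates_per_group >= 2, dispersion >= 0,
            length(base_mean_range) == 2L, base_mean_range[1] > 0,
            base_mean_range[1] <= base_mean_range[2], jitter_sd >= 0)
  structure(as.list(environment()), class = "synthetic_expression_config")
}

# Uniform integers in [lo, hi]; safe when lo == hi (unlike sample(lo:hi)).
sample_int_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Random DNA (no N) at a target GC fraction.
random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Remove every TGAAA / TTTCA occurrence (the motif anchor on either strand)
# so spacers cannot carry accidental early-promoter motifs. Substitution of
# the middle base can in principle create a new occurrence, so iterate.
scrub_motifs <- function(s) {
  repeat {
    hit <- regexpr("TGAAA|TTTCA", s)
    if (hit == -1L) return(s)
    mid <- hit + 2L
    old <- substr(s, mid, mid)
    substr(s, mid, mid) <- if (old == "A") "C" else "G"
  }
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# A coding cassette on the + orientation: in-frame stop barrier, ATG, random
# non-stop codons, stop. The barrier guarantees the downstream ATG is the
# first ATG of its stop-to-stop segment, so the deterministic caller recovers
# the planted coordinates exactly.
random_cassette <- function(aa_len) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  body <- if (aa_len > 1L) {
    paste(sample(sense, aa_len - 1L, replace = TRUE), collapse = "")
  } else ""
  paste0("TAA", "ATG", body, sample(STOP_CODONS, 1L))
}

#' Generate a synthetic genome with known ground truth
#'
#' Emits `ITR | interior | revcomp(ITR)` with non-overlapping planted ORFs
#' (valid ATG...stop structure, both strands) separated by motif-scrubbed
#' spacers. Every gene of the `virulence_promoter` category receives exactly
#' one `TGAAAXXXXA` motif planted on its strand within the 100 bp upstream
#' window; spacers elsewhere are guaranteed motif-free. The interior bases
#' adjacent to the ITRs are forced to break terminal self-complementarity so
#' the planted repeat length is exactly recoverable. Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_genome_config()].
#' @return List of class `epv_truth`: `genome` (an [genome()]), `orfs`
#'   (planted ORF table with `category`), `motifs` (planted motif hits),
#'   `itr_length`, and the `config`.
#' @export
generate_genome <- function(config = synthetic_genome_config()) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  set.seed(config$seed)
  n <- config$n_orfs
  categories <- sample(rep(names(config$category_counts),
                           config$category_counts))
  aa_len <- sample_int_range(config$orf_length_range[1],
                             config$orf_length_range[2], n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cassettes <- vapply(seq_len(n), function(i) {
    cass <- random_cassette(aa_len[i])
    if (strand[i] == "-") reverse_complement(cass) else cass
  }, "")
  spacer_len <- sample_int_range(config$spacer_range[1],
                                 config$spacer_range[2], n + 1L)
  needed <- 2L * config$itr_length + sum(spacer_len) + sum(nchar(cassettes))
  if (needed > config$genome_length) {
    stop("infeasible packing: ", needed, " bp needed but genome_length is ",
         config$genome_length)
  }
  spacer_len[n + 1L] <- spacer_len[n + 1L] + (config$genome_length - needed)
  spacers <- vapply(spacer_len, function(L)
    scrub_motifs(random_dna(L, config$gc_target)), "")
  itr <- random_dna(config$itr_length, config$gc_target)

  # plant one motif per promoter-category gene (offsets kept <= 46 bp so the
  # upstream insertions of neighbouring genes cannot collide in one spacer)
  motif_offsets <- rep(NA_integer_, n)
  motif_seqs <- rep(NA_character_, n)
  for (i in which(categories == "virulence_promoter")) {
    middle <- "TTTC"
    while (middle == "TTTC") {  # TTTC would make the motif self-reverse-complementary
      middle <- paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE),
                      collapse = "")
    }
    motif <- paste0("TGAAA", middle, "A")
    d <- sample(5:40, 1L)
    if (strand[i] == "+") {
      sl <- nchar(spacers[i])
      e <- sl + 4L - d                     # 1-based motif end in the spacer
      substr(spacers[i], e - 9L, e) <- motif
    } else {
      f <- d - 3L                          # 1-based start in the next spacer
      substr(spacers[i + 1L], f, f + 9L) <- reverse_complement(motif)
    }
    motif_offsets[i] <- d
    motif_seqs[i] <- motif
  }

  # force a mismatch right after each ITR so seed-and-extend stops exactly
  first <- substr(spacers[1L], 1L, 1L)
  last <- substr(spacers[n + 1L], spacer_len[n + 1L], spacer_len[n + 1L])
  if (first == chartr("ACGT", "TGCA", last)) {
    substr(spacers[1L], 1L, 1L) <-
      setdiff(c("A", "C", "G"), chartr("ACGT", "TGCA", last))[1L]
  }

  pieces <- character(2L * n + 3L)
  pieces[1L] <- itr
  pos <- config$itr_length
  starts <- ends <- integer(n)
  for (i in seq_len(n)) {
    pieces[2L * i] <- spacers[i]
    pos <- pos + nchar(spacers[i])
    cass <- cassettes[i]
    if (strand[i] == "+") {
      starts[i] <- pos + 3L
      ends[i] <- pos + nchar(cass)
    } else {
      starts[i] <- pos
      ends[i] <- pos + nchar(cass) - 3L
    }
    pieces[2L * i + 1L] <- cass
    pos <- pos + nchar(cass)
  }
  pieces[2L * n + 2L] <- spacers[n + 1L]
  pieces[2L * n + 3L] <- reverse_complement(itr)
  g <- genome(sprintf("synthetic_epv_seed%d", config$seed),
              paste(pieces, collapse = ""))
  stopifnot(g$length == config$genome_length)

  orf_ids <- orf_identifier(starts, ends, strand)
  orfs <- data.frame(orf_id = orf_ids, start = starts, end = ends,
                     strand = strand, protein_length = aa_len,
                     length_bp = ends - starts, category = categories,
                     stringsAsFactors = FALSE)
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  planted <- !is.na(motif_offsets)
  motifs <- data.frame(orf_id = orf_ids[planted],
                       offset = motif_offsets[planted],
                       matched_seq = motif_seqs[planted],
                       stringsAsFactors = FALSE)
  structure(list(genome = g, orfs = orfs, motifs = motifs,
                 itr_length = config$itr_length, config = config),
            class = "epv_truth")
}

#' Ground-truth evidence table for a synthetic genome
#'
#' Encodes the planted categories as the homology/domain evidence schema:
#' core genes receive reference core-gene names (in genomic order), BRO
#' genes the Bro-N domain flag, and so on. Promoter-category and unknown
#' genes carry no evidence, as in a real annotation where they have no
#' similarity-based assignment.
#'
#' @param truth An `epv_truth` from [generate_genome()].
#' @param core_reference Core-gene names to draw from
#'   (default [poxvirus_core_genes]).
#' @return Evidence data frame for [assign_categories()].
#' @export
truth_evidence <- function(truth, core_reference = poxvirus_core_genes) {
  stopifnot(inherits(truth, "epv_truth"))
  orfs <- truth$orfs
  n_core <- sum(orfs$category == "core_replication")
  if (n_core > length(core_reference)) {
    stop("more core genes than reference names")
  }
  core_name <- rep("", nrow(orfs))
  core_name[orfs$category == "core_replication"] <- core_reference[seq_len(n_core)]
  data.frame(orf_id = orfs$orf_id,
             core_gene_name = core_name,
             bro_domain = orfs$category == "virulence_bro",
             virulence_homolog = orfs$category == "virulence_homology",
             other_function = orfs$category == "other_function",
             stringsAsFactors = FALSE)
}

#' Gene-level ground truth without a genome
#'
#' For expression-only simulations: a planted gene table with categories and
#' transcript lengths, usable directly by [simulate_counts()].
#'
#' @param category_counts Named integer vector of genes per category.
#' @param gene_length_range Transcript length range in bp.
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, `category`, `length_bp`.
#' @export
make_expression_truth <- function(category_counts,
                                  gene_length_range = c(300, 1500),
                                  seed = 1) {
  stopifnot(all(names(category_counts) %in% CATEGORY_LEVELS))
  set.seed(seed)
  n <- sum(category_counts)
  data.frame(gene_id = sprintf("G%04d", seq_len(n)),
             category = rep(names(category_counts), category_counts),
             length_bp = sample_int_range(gene_length_range[1],
                                          gene_length_range[2], n),
             stringsAsFactors = FALSE)
}

#' Simulate a two-host count matrix with planted fold changes
#'
#' Per gene, the fly-group mean is drawn log-uniformly from
#' `base_mean_range` and the wasp-group mean is the fly mean scaled by
#' `2^planted_log2fc` for the gene's category (plus per-gene jitter on
#' affected categories). Because depth normalisation (FPKM) measures
#' *relative* abundance, a fold change is identifiable only when total
#' expression is conserved between the hosts; the base abundances of the
#' down-regulated genes are therefore scaled by the unique factor that
#' balances total up- against total down-regulation (when both directions
#' are planted). This emulates the partitioning design itself — the viral
#' transcript pool shifts composition between hosts at conserved output —
#' and makes each planted log2 fold change exactly the expected FPKM-scale
#' difference. Counts are negative-binomial
#' (`variance = mu + dispersion * mu^2`; Poisson when `dispersion = 0`).
#'
#' @param truth An `epv_truth` from [generate_genome()] or a gene table from
#'   [make_expression_truth()].
#' @param config A [synthetic_expression_config()].
#' @return An [expression_study()] with an extra element `planted`: a data
#'   frame of `gene_id`, `category` and the realised per-gene
#'   `planted_log2fc`.
#' @export
simulate_counts <- function(truth, config = synthetic_expression_config()) {
  stopifnot(inherits(config, "synthetic_expression_config"))
  genes <- if (inherits(truth, "epv_truth")) truth$orfs else truth
  stopifnot(is.data.frame(genes), "category" %in% names(genes))
  ids <- if ("gene_id" %in% names(genes)) genes$gene_id else genes$orf_id
  lengths <- if ("length_bp" %in% names(genes)) genes$length_bp else
    genes$end - genes$start
  n <- length(ids)
  set.seed(config$seed)
  lfc <- unname(config$planted_log2fc[genes$category])
  lfc[is.na(lfc)] <- 0
  lfc <- lfc + stats::rnorm(n, 0, config$jitter_sd) * (lfc != 0)
  mu_fly <- exp(stats::runif(n, log(config$base_mean_range[1]),
                             log(config$base_mean_range[2])))
  # conserve total expression across hosts so fold changes survive
  # depth normalisation: scale down-regulated base abundances to balance
  up <- lfc > 0
  down <- lfc < 0
  gain <- sum(mu_fly[up] * (2^lfc[up] - 1))
  loss <- sum(mu_fly[down] * (1 - 2^lfc[down]))
  if (gain > 0 && loss > 0) {
    mu_fly[down] <- mu_fly[down] * (gain / loss)
  }
  mu_wasp <- mu_fly * 2^lfc
  R <- config$replicates_per_group
  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  counts <- cbind(
    matrix(unlist(lapply(seq_len(R), function(r) draw(mu_wasp))), ncol = R),
    matrix(unlist(lapply(seq_len(R), function(r) draw(mu_fly))), ncol = R))
  dimnames(counts) <- list(ids, c(sprintf("wasp_%d", seq_len(R)),
                                  sprintf("fly_%d", seq_len(R))))
  study <- expression_study(counts, lengths,
                            rep(c("wasp", "fly"), each = R))
  study$planted <- data.frame(gene_id = ids, category = genes$category,
                              planted_log2fc = lfc,
                              stringsAsFactors = FALSE)
  study
}

#' Evaluate recovery of planted expression effects
#'
#' Compares differential-expression results against the planted ground
#' truth: per-category mean estimated versus planted log2 fold change, the
#' adjusted Rand index between the recovered expression clusters and the
#' planted effect directions (restricted to significant genes with a
#' nonzero planted effect), and detection sensitivity / empirical false
#' discovery rate.
#'
#' @param truth An [expression_study()] produced by [simulate_counts()] (its
#'   `planted` table is used) or the planted gene table itself (columns
#'   `gene_id`, `category`, `planted_log2fc`).
#' @param de DE data frame with cluster labels
#'   (see [run_expression_analysis()]).
#' @return List with `by_category` (estimated/planted mean log2fc and their
#'   difference), `ari`, `sensitivity`, `fdr`.
#' @export
evaluate_recovery <- function(truth, de) {
  planted <- if (inherits(truth, "expression_study")) truth$planted else truth
  stopifnot(is.data.frame(planted),
            all(c("gene_id", "category", "planted_log2fc") %in% names(planted)))
  idx <- match(planted$gene_id, de$gene_id)
  if (anyNA(idx)) stop("gene ids in truth and DE results do not align")
  de <- de[idx, , drop = FALSE]
  by_category <- do.call(rbind, lapply(split(seq_len(nrow(planted)),
                                             planted$category), function(ii) {
    data.frame(category = planted$category[ii[1]],
               n = length(ii),
               mean_log2fc_est = mean(de$log2fc[ii]),
               mean_log2fc_planted = mean(planted$planted_log2fc[ii]),
               stringsAsFactors = FALSE)
  }))
  by_category$error <- by_category$mean_log2fc_est -
    by_category$mean_log2fc_planted
  rownames(by_category) <- NULL
  nonnull <- planted$planted_log2fc != 0
  sig <- de$significant
  sel <- sig & nonnull & !is.na(de$cluster)
  ari <- if (sum(sel) >= 2L) {
    mclust::adjustedRandIndex(
      de$cluster[sel],
      ifelse(planted$planted_log2fc[sel] > 0, "up", "down"))
  } else NA_real_
  list(by_category = by_category,
       ari = ari,
       sensitivity = if (any(nonnull)) sum(sig & nonnull) / sum(nonnull)
                     else NA_real_,
       fdr = sum(sig & !nonnull) / max(1L, sum(sig)))
}
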