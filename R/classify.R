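#' Poxvirus core-gene reference names
#'
#' A 49-name reference list of genes conserved across all sequenced
#' poxviruses, written in the vaccinia virus (VACV) locus naming convention
#' (e.g. `E9L` = DNA polymerase, `J6R` = RNA polymerase large subunit,
#' `A32L` = DNA-packaging ATPase). This synthetic reference enumerates
#' plausible VACV-style locus tags for use with [census_core_genes()] and the
#' synthetic-genome generator; any 49-name list in the same convention can be
#' supplied instead.
#'
#' @format Character vector of 49 unique locus names.
#' @export
poxvirus_core_genes <- c(
  "E9L", "E6R", "E1L", "E4L", "E10R",
  "I1L", "I2L", "I3L", "I6L", "I7L", "I8R",
  "G1L", "G3L", "G4L", "G5R", "G6R", "G7L", "G9R",
  "J1R", "J3R", "J4R", "J5L", "J6R",
  "H1L", "H2R", "H3L", "H4L", "H6R",
  "D1R", "D2L", "D3R", "D4R", "D5R", "D6R", "D7R", "D10R", "D11R", "D12L", "D13L",
  "A1L", "A2L", "A7L", "A24R", "A29L", "A32L",
  "L1R", "L3L", "L4R", "L5R")

CATEGORY_LEVELS <- c("core_replication", "virulence_bro", "virulence_homology",
                     "virulence_promoter", "other_function", "unknown")

#' Assign functional categories to ORFs
#'
#' Joins ORFs with externally supplied homology/domain evidence and promoter
#' motif hits, and assigns exactly one functional category per gene using the
#' priority order: core gene name > Bro-N domain > virulence homology >
#' other assigned function > early-promoter motif (with no other evidence) >
#' unknown. A gene in the `virulence_promoter` category is a putative early
#' (virulence) gene identified solely by its conserved promoter.
#'
#' @param orfs ORF data frame from [call_orfs()].
#' @param evidence Data frame with columns `orf_id`, `core_gene_name`
#'   (empty string or `NA` when none), `bro_domain`, `virulence_homolog`,
#'   `other_function` (logicals). Each `orf_id` may appear at most once and
#'   must exist among the ORFs.
#' @param motif_hits Motif-hit data frame from [scan_early_promoters()].
#' @return Annotation data frame: the ORF columns (minus the protein) plus
#'   `core_gene_name`, `category` and `motif_hit_count`.
#' @export
assign_categories <- function(orfs, evidence, motif_hits) {
  stopifnot(is.data.frame(orfs), is.data.frame(evidence),
            is.data.frame(motif_hits))
  if (anyDuplicated(evidence$orf_id)) {
    stop("duplicated orf_id in evidence table: ",
         paste(unique(evidence$orf_id[duplicated(evidence$orf_id)]),
               collapse = ", "))
  }
  unknown_ids <- setdiff(evidence$orf_id, orfs$orf_id)
  if (length(unknown_ids) > 0L) {
    stop("evidence refers to unknown orf_id(s): ",
         paste(unknown_ids, collapse = ", "))
  }
  idx <- match(orfs$orf_id, evidence$orf_id)
  core_name <- as.character(evidence$core_gene_name[idx])
  core_name[is.na(core_name)] <- ""
  bro <- evidence$bro_domain[idx] %in% TRUE
  vh <- evidence$virulence_homolog[idx] %in% TRUE
  of <- evidence$other_function[idx] %in% TRUE
  hit_tab <- table(motif_hits$orf_id)
  mhc <- as.integer(hit_tab[orfs$orf_id])
  mhc[is.na(mhc)] <- 0L
  category <- ifelse(core_name != "", "core_replication",
              ifelse(bro, "virulence_bro",
              ifelse(vh, "virulence_homology",
              ifelse(of, "other_function",
              ifelse(mhc >= 1L, "virulence_promoter", "unknown")))))
  keep <- setdiff(names(orfs), "protein")
  ann <- orfs[, keep, drop = FALSE]
  ann$core_gene_name <- core_name
  ann$category <- category
  ann$motif_hit_count <- mhc
  rownames(ann) <- NULL
  ann
}

#' Census of poxvirus core genes in an annotation
#'
#' Compares the core-gene names recovered in an annotation against a
#' reference list of the genes conserved across all sequenced poxviruses.
#' When two ORFs carry the same reference name it is counted once and a
#' warning is issued.
#'
#' @param annotations Annotation data frame from [assign_categories()].
#' @param reference_list Character vector of unique core-gene names
#'   (default [poxvirus_core_genes], 49 names).
#' @return List of class `core_gene_census` with `reference_total`,
#'   `identified` and `missing` (disjoint name vectors).
#' @export
census_core_genes <- function(annotations, reference_list = poxvirus_core_genes) {
  stopifnot(is.data.frame(annotations), is.character(reference_list))
  if (anyDuplicated(reference_list)) {
    stop("reference_list contains duplicated names")
  }
  found <- annotations$core_gene_name[annotations$category == "core_replication"]
  found <- found[found %in% reference_list]
  if (anyDuplicated(found)) {
    dup <- unique(found[duplicated(found)])
    warning("core gene name(s) assigned to multiple ORFs (counted once): ",
            paste(dup, collapse = ", "))
  }
  identified <- reference_list[reference_list %in% found]
  structure(list(reference_total = length(reference_list),
                 identified = identified,
                 missing = setdiff(reference_list, identified)),
            class = "core_gene_census")
}

#' @export
print.core_gene_census <- function(x, ...) {
  cat(sprintf("<core_gene_census> %d/%d reference core genes identified\n",
              length(x$identified), x$reference_total))
  if (length(x$missing)) {
    cat("missing:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise putative virulence genes by subcategory
#'
#' Counts the three virulence subcategories (BRO-domain genes, genes with
#' similarity to known virulence genes, and early-promoter genes with no
#' other assigned function) and their total.
#'
#' @param annotations Annotation data frame from [assign_categories()].
#' @return Named list with `bro`, `homology`, `promoter`, `total`.
#' @export
summarize_virulence <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  n <- function(cat) sum(annotations$category == cat)
  counts <- list(bro = n("virulence_bro"),
                 homology = n("virulence_homology"),
                 promoter = n("virulence_promoter"))
  counts$total <- counts$bro + counts$homology + counts$promoter
  counts
}

#' Read a tab-separated homology/domain evidence table
#'
#' Expected columns: `orf_id`, `core_gene_name`, `bro_domain`,
#' `virulence_homolog`, `other_function`.
#'
#' @param path Path to a TSV file.
#' @return Evidence data frame suitable for [assign_categories()].
#' @export
read_evidence_tsv <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(orf_id = "character",
                                         core_gene_name = "character"))
  required <- c("orf_id", "core_gene_name", "bro_domain",
                "virulence_homolog", "other_function")
  miss <- setdiff(required, names(ev))
  if (length(miss)) stop("evidence table missing column(s): ",
                         paste(miss, collapse = ", "))
  ev$core_gene_name[is.na(ev$core_gene_name)] <- ""
  for (col in c("bro_domain", "virulence_homolog", "other_function")) {
    ev[[col]] <- as.logical(ev[[col]])
  }
  ev
}
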