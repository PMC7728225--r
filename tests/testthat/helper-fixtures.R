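# A 193-gene annotation/DE fixture reproducing the published marginal
# counts of the dual-host study: 176 of 193 genes differentially expressed
# (86 up in wasp, 90 down), 37 of 45 core replication genes in the up
# cluster, and 53 of 67 virulence genes (22 BRO, 5 homology, 26 promoter)
# in the down cluster. The within-margin allocation is one consistent
# completion; every summary the tests assert depends only on the margins.
printed_partition_fixture <- function() {
  spec <- list(
    core_replication = c(up = 37, down = 4, not_de = 4),     # 45
    virulence_bro = c(up = 3, down = 22, not_de = 2),        # 27
    virulence_homology = c(up = 1, down = 5, not_de = 0),    # 6
    virulence_promoter = c(up = 6, down = 26, not_de = 2),   # 34
    other_function = c(up = 5, down = 4, not_de = 2),        # 11
    unknown = c(up = 34, down = 29, not_de = 7))             # 70
  category <- character(0)
  status <- character(0)
  for (cat in names(spec)) {
    for (st in names(spec[[cat]])) {
      category <- c(category, rep(cat, spec[[cat]][[st]]))
      status <- c(status, rep(st, spec[[cat]][[st]]))
    }
  }
  n <- length(category)
  ids <- sprintf("G%03d", seq_len(n))
  annotations <- data.frame(orf_id = ids, category = category,
                            stringsAsFactors = FALSE)
  sig <- status != "not_de"
  de <- data.frame(
    gene_id = ids,
    mean_fpkm_wasp = 100, mean_fpkm_fly = 100,
    log2fc = ifelse(status == "up", 2.3, ifelse(status == "down", -3.4, 0)),
    p = ifelse(sig, 1e-4, 0.8),
    q = ifelse(sig, 1e-3, 0.9),
    significant = sig,
    cluster = ifelse(status == "up", "up_in_wasp",
                     ifelse(status == "down", "down_in_wasp", NA_character_)),
    stringsAsFactors = FALSE)
  list(annotations = annotations, de = de)
}
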