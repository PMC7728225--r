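small_genome_config <- function(seed) {
  synthetic_genome_config(
    genome_length = 10000, itr_length = 500, n_orfs = 8,
    orf_length_range = c(60, 150),
    category_counts = c(core_replication = 2, virulence_bro = 1,
                        virulence_homology = 1, virulence_promoter = 2,
                        other_function = 1, unknown = 1),
    seed = seed)
}

test_that("generate_genome is deterministic and meets its construction contract", {
  cfg <- small_genome_config(seed = 5)
  t1 <- generate_genome(cfg)
  t2 <- generate_genome(cfg)
  expect_identical(t1$genome$sequence, t2$genome$sequence)
  expect_identical(t1$orfs, t2$orfs)
  expect_equal(t1$genome$length, 10000L)
  # planted ITR length is recovered exactly under exact matching
  itr <- detect_itrs(t1$genome, max_mismatch_frac = 0)
  expect_equal(itr$length, 500L)
  expect_equal(itr$identity, 1.0)
  # background composition stays near the GC target (checked on the ITR)
  itr_gc <- mean(strsplit(substr(t1$genome$sequence, 1, 500), "")[[1]] %in%
                   c("G", "C"))
  expect_lt(abs(itr_gc - 0.301), 0.05)
})

test_that("the ORF caller recovers every planted ORF at its planted coordinates", {
  for (seed in c(5, 23)) {
    truth <- generate_genome(small_genome_config(seed))
    called <- call_orfs(truth$genome, min_aa = 50)
    expect_true(all(truth$orfs$orf_id %in% called$orf_id),
                info = paste("seed", seed))
    m <- match(truth$orfs$orf_id, called$orf_id)
    expect_equal(called$start[m], truth$orfs$start)
    expect_equal(called$end[m], truth$orfs$end)
    expect_equal(called$strand[m], truth$orfs$strand)
    expect_equal(called$protein_length[m], truth$orfs$protein_length)
  }
})

test_that("planted promoter motifs are found for promoter genes and only them", {
  truth <- generate_genome(small_genome_config(seed = 8))
  called <- call_orfs(truth$genome, min_aa = 50)
  planted <- called[match(truth$orfs$orf_id, called$orf_id), ]
  hits <- scan_early_promoters(truth$genome, planted)
  prom <- truth$orfs$orf_id[truth$orfs$category == "virulence_promoter"]
  expect_true(all(prom %in% hits$orf_id))
  expect_length(setdiff(hits$orf_id, prom), 0L)
  # recovered offsets and sequences include the planted ones
  m <- merge(truth$motifs, hits, by = c("orf_id", "offset"))
  expect_equal(nrow(m), nrow(truth$motifs))
  expect_equal(m$matched_seq.x, m$matched_seq.y)
})

test_that("assign_categories recovers every planted category from truth evidence", {
  truth <- generate_genome(synthetic_genome_config(seed = 7))
  called <- call_orfs(truth$genome, min_aa = 50)
  hits <- scan_early_promoters(truth$genome, called)
  ann <- assign_categories(called, truth_evidence(truth), hits)
  got <- ann$category[match(truth$orfs$orf_id, ann$orf_id)]
  expect_equal(got, truth$orfs$category)
})

test_that("simulate_counts is seeded, centred under the null, and Poisson at phi=0", {
  truth <- make_expression_truth(c(unknown = 400), seed = 40)
  cfg <- synthetic_expression_config(seed = 41)
  s1 <- simulate_counts(truth, cfg)
  s2 <- simulate_counts(truth, cfg)
  expect_identical(s1$counts, s2$counts)
  expect_equal(dim(s1$counts), c(400L, 12L))
  # no planted effect: mean estimated log2fc across genes is near 0
  de <- de_test(s1)
  expect_lt(abs(mean(de$log2fc)), 0.1)
  # dispersion 0 gives Poisson counts: variance tracks the mean
  s0 <- simulate_counts(truth, synthetic_expression_config(seed = 42,
                                                           dispersion = 0))
  wasp <- s0$counts[, 1:6]
  ratio <- apply(wasp, 1, stats::var) / rowMeans(wasp)
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("planted fold changes are recovered within tolerance at study scale", {
  truth <- make_expression_truth(
    c(core_replication = 120, virulence_bro = 70, virulence_homology = 15,
      virulence_promoter = 85, other_function = 30, unknown = 180),
    seed = 50)
  study <- simulate_counts(truth, synthetic_expression_config(seed = 51))
  de <- run_expression_analysis(study)
  rec <- evaluate_recovery(study, de)
  core <- rec$by_category[rec$by_category$category == "core_replication", ]
  expect_lt(abs(core$mean_log2fc_est - 2.3), 0.3)
  vir <- rec$by_category[grepl("^virulence", rec$by_category$category), ]
  vir_mean <- sum(vir$mean_log2fc_est * vir$n) / sum(vir$n)
  expect_lt(abs(vir_mean - (-3.4)), 0.4)
  expect_gte(rec$ari, 0.9)
  expect_gte(rec$sensitivity, 0.95)
})

test_that("evaluate_recovery's adjusted Rand index behaves at its extremes", {
  n <- 500
  set.seed(60)
  planted <- data.frame(
    gene_id = sprintf("G%03d", 1:n),
    category = rep(c("core_replication", "virulence_bro"), each = n / 2),
    planted_log2fc = rep(c(2.3, -3.4), each = n / 2),
    stringsAsFactors = FALSE)
  mk_de <- function(cluster) data.frame(
    gene_id = planted$gene_id, mean_fpkm_wasp = 1, mean_fpkm_fly = 1,
    log2fc = planted$planted_log2fc, p = 0, q = 0, significant = TRUE,
    cluster = cluster, stringsAsFactors = FALSE)
  perfect <- mk_de(ifelse(planted$planted_log2fc > 0, "up_in_wasp",
                          "down_in_wasp"))
  expect_equal(evaluate_recovery(planted, perfect)$ari, 1.0)
  random <- mk_de(sample(c("up_in_wasp", "down_in_wasp"), n, replace = TRUE))
  expect_lt(abs(evaluate_recovery(planted, random)$ari), 0.1)
  onecluster <- mk_de("up_in_wasp")
  expect_equal(evaluate_recovery(planted, onecluster)$ari, 0)
})

test_that("the full synthetic pipeline reproduces the functional partition", {
  truth <- generate_genome(synthetic_genome_config(seed = 70))
  called <- call_orfs(truth$genome, min_aa = 50)
  hits <- scan_early_promoters(truth$genome, called)
  ann <- assign_categories(called, truth_evidence(truth), hits)
  study <- simulate_counts(truth, synthetic_expression_config(seed = 71))
  de <- run_expression_analysis(study)
  part <- partition_summary(ann, de)
  expect_gt(part$pct_core_in_up, 75)
  expect_gt(part$pct_virulence_in_down, 75)
  expect_equal(part$n_up + part$n_down, part$n_de)
})
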