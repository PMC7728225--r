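test_that("read_fasta normalises case, preserves record order, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g", "acgt"), f)
  gs <- read_fasta(f)
  expect_length(gs, 1L)
  expect_equal(gs[[1]]$id, "g")
  expect_equal(gs[[1]]$sequence, "ACGT")
  expect_equal(gs[[1]]$length, 4L)

  writeLines(c(">g1", "ACGTN", ">g2", "ttaa"), f)
  gs <- read_fasta(f)
  expect_equal(names(gs), c("g1", "g2"))
  expect_equal(gs[[2]]$sequence, "TTAA")

  writeLines(c(">g", "ACXGT"), f)
  expect_error(read_fasta(f), "'g'.*'X'")
  writeLines(c(">rna", "ACGU"), f)
  expect_error(read_fasta(f), "'rna'.*'U'")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("reverse_complement complements, handles N, and is an involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AANT"), "ANTT")
  expect_error(reverse_complement("ATXG"), "'X'")
  set.seed(42)
  for (i in 1:20) {
    s <- random_dna_string(sample(1:200, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("call_orfs follows the first-ATG-per-stop rule on hand cases", {
  res <- call_orfs(genome("t", "ATGAAATAA"), min_aa = 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 0L)
  expect_equal(res$end, 9L)
  expect_equal(res$strand, "+")
  expect_equal(res$protein, "MK")
  expect_equal(res$protein_length, 2L)

  expect_equal(nrow(call_orfs(genome("t", "ATGAAATAA"), min_aa = 50)), 0L)

  # a second in-frame ATG never starts its own ORF (same stop)
  res <- call_orfs(genome("t", "ATGATGAAATAA"), min_aa = 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 0L)
  expect_equal(res$protein, "MMK")

  # an N-containing codon kills the segment: no ORF spans it
  res <- call_orfs(genome("t", "ATGAANAAATAA"), min_aa = 1)
  expect_false(any(res$strand == "+" & res$start == 0L))

  # a frame running off the genome end without a stop is not emitted
  expect_equal(nrow(call_orfs(genome("t", "ATGAAAAAAAAA"), min_aa = 1)), 0L)
})

test_that("call_orfs matches the brute-force six-frame oracle on random genomes", {
  set.seed(101)
  for (i in 1:30) {
    s <- random_dna_string(sample(500:4000, 1), gc = runif(1, 0.25, 0.55))
    got <- call_orfs(genome("r", s), min_aa = 20)
    want <- oracle_orfs(s, min_aa = 20)
    expect_equal(got[, c("start", "end", "strand", "protein", "protein_length")],
                 want, info = paste("genome", i))
  }
})

test_that("call_orfs is strand symmetric", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna_string(2000)
    G <- nchar(s)
    a <- call_orfs(genome("f", s), min_aa = 15)
    b <- call_orfs(genome("r", reverse_complement(s)), min_aa = 15)
    flipped <- data.frame(start = G - b$end, end = G - b$start,
                          strand = ifelse(b$strand == "+", "-", "+"),
                          protein = b$protein, stringsAsFactors = FALSE)
    flipped <- flipped[order(flipped$start, flipped$end, flipped$strand), ]
    rownames(flipped) <- NULL
    expect_equal(a[, c("start", "end", "strand", "protein")], flipped)
  }
})

test_that("filter_repetitive discards low-complexity proteins by either rule", {
  mk <- function(p) data.frame(orf_id = "x", start = 0L,
                               end = (nchar(p) + 1L) * 3L, strand = "+",
                               protein = p, protein_length = nchar(p),
                               stringsAsFactors = FALSE)
  # single-residue runs fail the frequency rule
  out <- filter_repetitive(mk(strrep("K", 20)))
  expect_equal(nrow(out$discarded), 1L)
  # all 20 distinct residues: frequency 0.05, dipeptide entropy log2(19) > 2
  out <- filter_repetitive(mk("MSKEALVRTGQDINFHWYPC"))
  expect_equal(nrow(out$kept), 1L)
  # two-letter alternation of length 40: 20x"AR" + 19x"RA" -> entropy
  # -(20/39 log2 20/39 + 19/39 log2 19/39) = 0.99953 bits < 2, and the
  # top single-residue fraction is 0.5 >= 0.5, so both rules fire
  out <- filter_repetitive(mk(strrep("AR", 20)))
  expect_equal(nrow(out$discarded), 1L)
  # entropy rule alone: relax the frequency rule and it must still go
  out <- filter_repetitive(mk(strrep("AR", 20)), max_single_aa_frac = 0.9)
  expect_equal(nrow(out$discarded), 1L)
  # proteins under 2 aa are kept (entropy undefined guard)
  out <- filter_repetitive(mk("M"))
  expect_equal(nrow(out$kept), 1L)
  # partition property
  orfs <- rbind(mk("MSKEALVRTGQDINFHWYPC"), mk(strrep("K", 30)))
  orfs$orf_id <- c("a", "b")
  out <- filter_repetitive(orfs)
  expect_equal(sort(c(out$kept$orf_id, out$discarded$orf_id)), c("a", "b"))
})

test_that("detect_itrs recovers a planted repeat and rejects random termini", {
  set.seed(13)
  itr <- random_dna_string(1000)
  core <- random_dna_string(8000)
  # force a mismatch right after the repeat so the planted length is maximal
  if (substr(core, 1, 1) == chartr("ACGT", "TGCA", substr(core, 8000, 8000))) {
    substr(core, 1, 1) <- setdiff(c("A", "C", "G", "T"),
      c(substr(core, 1, 1), chartr("ACGT", "TGCA", substr(core, 8000, 8000))))[1]
  }
  g <- genome("planted", paste0(itr, core, reverse_complement(itr)))
  hit <- detect_itrs(g, max_mismatch_frac = 0)
  expect_equal(hit$length, 1000L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$left_span, c(0L, 1000L))
  expect_equal(hit$right_span, c(9000L, 10000L))
  # default tolerance can only extend past the planted repeat, never shrink
  hit2 <- detect_itrs(g)
  expect_gte(hit2$length, 1000L)
  expect_gte(hit2$identity, 0.98)
  # uniform-random termini: a 25 bp exact terminal match is vanishingly rare
  expect_null(detect_itrs(genome("rand", random_dna_string(10000))))
  # symmetry: the reverse complement has the same repeat structure
  rc <- genome("rc", reverse_complement(g$sequence))
  expect_equal(detect_itrs(rc, max_mismatch_frac = 0)$length, 1000L)
})

test_that("genome metrics use N-free GC and strand-pooled interval union", {
  g1k <- genome("g", random_dna_string(1000))
  orf <- function(s, e) data.frame(orf_id = sprintf("o%d", s), start = s,
                                   end = e, strand = "+", protein = "M",
                                   protein_length = 1L,
                                   stringsAsFactors = FALSE)
  m <- compute_genome_metrics(g1k, orf(0L, 300L))
  expect_equal(m$coding_density_percent, 30.0)
  m <- compute_genome_metrics(g1k, rbind(orf(0L, 300L), orf(150L, 450L)))
  expect_equal(m$coding_density_percent, 45.0)  # union, not sum
  expect_equal(compute_genome_metrics(genome("s", "ATGC"),
                                      empty <- call_orfs(genome("s", "ATGC")))$gc_percent, 50.0)
  # N excluded from the GC denominator
  expect_equal(compute_genome_metrics(genome("n", "ATGCNN"), empty)$gc_percent, 50.0)
  expect_error(compute_genome_metrics(genome("nn", "NNNN"), empty), "all N")
})

test_that("coding density is monotone in added ORFs and order invariant", {
  set.seed(3)
  g <- genome("g", random_dna_string(5000))
  orfs <- call_orfs(g, min_aa = 10)
  skip_if(nrow(orfs) < 3L)
  dens <- vapply(seq_len(nrow(orfs)), function(k) {
    compute_genome_metrics(g, orfs[seq_len(k), ])$coding_density_percent
  }, 0)
  expect_true(all(diff(dens) >= 0))
  shuffled <- orfs[sample(nrow(orfs)), ]
  expect_equal(compute_genome_metrics(g, shuffled)$coding_density_percent,
               dens[length(dens)])
})

test_that("promoter scan matches the sliding-window oracle and respects strand", {
  orf_seq <- "ATGAAAAAAAAAAAATAA"   # MKKKK, protein length 5
  mk_genome <- function(upstream) {
    genome("p", paste0(upstream, orf_seq))
  }
  up <- paste0(strrep("C", 90), "TGAAACGTAA")
  g <- mk_genome(up)
  orfs <- call_orfs(g, min_aa = 2)
  hits <- scan_early_promoters(g, orfs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$matched_seq, "TGAAACGTAA")
  expect_equal(hits$offset, 1L)   # motif ends immediately before the ATG

  # no anchor, no hits
  g0 <- mk_genome(strrep("T", 100))
  expect_equal(nrow(scan_early_promoters(g0, call_orfs(g0, min_aa = 2))), 0L)

  # overlapping matches counted, equivalence with the brute-force oracle
  up2 <- paste0(strrep("G", 80), "TGAAATGAAACCCCA")
  g2 <- mk_genome(up2)
  orfs2 <- call_orfs(g2, min_aa = 2)
  orfs2 <- orfs2[orfs2$strand == "+" & orfs2$end == g2$length, , drop = FALSE]
  hits2 <- scan_early_promoters(g2, orfs2)
  want <- oracle_motif_starts(substr(g2$sequence, 1, orfs2$start[1]))
  expect_equal(sort(nchar(up2) - (want + 9L) + 1L), sort(hits2$offset))

  # minus-strand ORF: same hits through the reverse complement
  g3 <- genome("m", reverse_complement(g2$sequence))
  orfs3 <- call_orfs(g3, min_aa = 2)
  orfs3 <- orfs3[orfs3$strand == "-" & orfs3$start == 0L, , drop = FALSE]
  hits3 <- scan_early_promoters(g3, orfs3)
  expect_equal(sort(hits3$offset), sort(hits2$offset))
  expect_equal(sort(hits3$matched_seq), sort(hits2$matched_seq))

  # window truncated at the genome start: too short for any 10-mer
  g4 <- genome("s", paste0("CGTAA", orf_seq))
  expect_equal(nrow(scan_early_promoters(g4, call_orfs(g4, min_aa = 2))), 0L)

  # random-window fuzz against the oracle
  set.seed(20)
  for (i in 1:25) {
    up <- random_dna_string(sample(10:120, 1), gc = 0.3)
    up <- gsub("ATG", "CTG", up, fixed = TRUE)  # keep the planted ORF first
    gg <- genome("f", paste0(up, orf_seq))
    oo <- call_orfs(gg, min_aa = 2)
    oo <- oo[oo$strand == "+" & oo$end == gg$length, , drop = FALSE]
    hh <- scan_early_promoters(gg, oo)
    w <- substr(gg$sequence, max(1, oo$start - 99), oo$start)
    want <- oracle_motif_starts(w)
    expect_equal(sort(hh$offset), sort(nchar(w) - (want + 9L) + 1L))
  }
})
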