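# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

random_dna_string <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Enumerate every ATG in every frame on both strands, translate codon by
# codon until a stop (abort on N codons or running off the end), then keep
# the earliest ATG per (strand, stop) pair. Independent of the package's
# segment-walk implementation.
oracle_orfs <- function(seq, min_aa) {
  G <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else epvkit::reverse_complement(seq)
    m <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    starts <- if (m[1] == -1L) integer(0) else as.integer(m)
    found <- list()
    for (p in starts) {
      q <- p
      prot <- character(0)
      repeat {
        if (q + 2L > nchar(s)) { prot <- NULL; break }
        a <- unname(Biostrings::GENETIC_CODE[substr(s, q, q + 2L)])
        if (is.na(a)) { prot <- NULL; break }
        if (a == "*") break
        prot <- c(prot, a)
        q <- q + 3L
      }
      if (is.null(prot) || length(prot) < min_aa) next
      key <- as.character(q)
      if (is.null(found[[key]]) || p < found[[key]]$p) {
        found[[key]] <- list(p = p, q = q, prot = paste(prot, collapse = ""))
      }
    }
    for (f in found) {
      ls <- f$p - 1L
      le <- f$q + 2L
      if (strand == "+") { st <- ls; en <- le } else { st <- G - le; en <- G - ls }
      out[[length(out) + 1L]] <- data.frame(
        start = st, end = en, strand = strand, protein = f$prot,
        protein_length = nchar(f$prot), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein = character(),
                      protein_length = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Slide a 10 bp window over a string; return 1-based start positions of
# every (overlapping) TGAAAXXXXA occurrence.
oracle_motif_starts <- function(w) {
  if (nchar(w) < 10L) return(integer(0))
  hits <- integer(0)
  for (j in 1:(nchar(w) - 9L)) {
    ten <- substr(w, j, j + 9L)
    if (substr(ten, 1L, 5L) == "TGAAA" && substr(ten, 10L, 10L) == "A") {
      hits <- c(hits, j)
    }
  }
  hits
}

# Longest strictly increasing subsequence length via patience sorting
# (replace the first pile tail >= x), independent of the package's O(n^2)
# chain dynamic program.
oracle_lis_length <- function(v) {
  tails <- numeric(0)
  for (x in v) {
    i <- which(tails >= x)[1]
    if (is.na(i)) tails <- c(tails, x) else tails[i] <- x
  }
  length(tails)
}

# Benjamini-Hochberg step-up by direct min-over-tails computation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  qs <- vapply(seq_len(n),
               function(i) min(sorted[i:n] * n / (i:n)), 0)
  qs <- pmin(qs, 1)
  q <- numeric(n)
  q[o] <- qs
  q
}

# Welch two-sample t-test p-value from the textbook formulas.
oracle_welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}
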