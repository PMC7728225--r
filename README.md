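# epvkit

Annotation and dual-host expression partitioning of entomopoxvirus
genomes.

Parasitoid wasps can carry a heritable, beneficial poxvirus in the venom
gland: the virus amplifies in wasp tissue, is injected into the wasp's
fly host during oviposition, and is virulent only there. The genomic
signature of this symbiosis is **functional partitioning** — replication
genes up-regulated in the wasp, virulence genes up-regulated in the
parasitized fly. epvkit provides the full desk-scale toolchain to
quantify that signature for a linear double-stranded DNA (poxvirus-like)
genome:

- **Genome annotation** — six-frame ORF calling (first ATG per
  stop-to-stop segment, `≥ 50` aa), low-complexity ORF filtering,
  inverted terminal repeat (ITR) detection by terminal seed-and-extend,
  genome metrics (N-free GC%, union coding density), and scanning of
  100 bp upstream windows for the conserved entomopoxvirus early-promoter
  motif `TGAAAXXXXA`; GFF3/TSV export.
- **Functional classification** — priority-based category assignment from
  homology/domain evidence tables (core replication → BRO domain →
  virulence homology → other function → early-promoter-only → unknown),
  a 49-gene poxvirus core-gene census, and virulence subtotals.
- **Comparative genomics** — core-gene synteny dot plots, collinear-block
  detection via longest monotone chains (`same` and `inverted`
  orientations), alignment gap-column trimming (strict > 50% rule) and
  supermatrix concatenation, and mean ± SD comparison tables excluding a
  focal genome.
- **Expression partitioning** — FPKM
  (`count / ((len/10^3)(total/10^6))`), per-gene Welch t-tests on
  `log2(FPKM + 1)` with Benjamini–Hochberg FDR (`q < 0.05`), Ward
  (`ward.D2`) clustering of significant genes into `up_in_wasp` /
  `down_in_wasp`, and the category × cluster partition summary.
- **Synthetic data** — seeded generators for genomes with planted ITRs,
  ORFs, categories and promoter motifs, and negative-binomial count
  matrices (`var = mu + phi mu^2`) with planted category-level log2 fold
  changes (+2.3 replication, −3.4 virulence; 6 vs 6 replicates), plus
  recovery metrics (category effect recovery, cluster-vs-truth adjusted
  Rand index, sensitivity/FDR).
- **Pipeline** — `run_pipeline()` orchestrates
  simulate → annotate → classify → express from a config list or YAML
  file and writes a manifest; a thin CLI wrapper lives in
  `inst/scripts/epvkit.R`.

## Worked example

Generate a 50 kb synthetic genome (2 kb ITRs, 40 planted ORFs in
study-like category proportions), annotate it, and quantify the
expression partition from a simulated 6 vs 6 count matrix:

```r
library(epvkit)

truth <- generate_genome(synthetic_genome_config(seed = 7))
orfs  <- filter_repetitive(call_orfs(truth$genome, min_aa = 50))$kept
itr   <- detect_itrs(truth$genome, max_mismatch_frac = 0)
compute_genome_metrics(truth$genome, orfs, itr)
#>             genome_id length_bp gc_percent coding_density_percent orf_count itr_length_bp
#> 1 synthetic_epv_seed7     50000     42.052                 61.342        98          2000

hits <- scan_early_promoters(truth$genome, orfs)
ann  <- assign_categories(orfs, truth_evidence(truth), hits)
study <- simulate_counts(truth, synthetic_expression_config(seed = 3))
de    <- run_expression_analysis(study)
partition_summary(ann, de)
#> 25/40 genes differentially expressed (62.5%)
#> clusters: 8 up_in_wasp, 17 down_in_wasp
#> core replication genes in up_in_wasp:   88.9%
#> virulence genes in down_in_wasp:        100.0%
#> mean |log2FC|: up 2.31, down 3.25
#>                     status
#> category             up_in_wasp down_in_wasp not_de
#>   core_replication            8            1      0
#>   virulence_bro               0            6      0
#>   virulence_homology          0            2      0
#>   virulence_promoter          0            7      0
#>   other_function              0            0      4
#>   unknown                     0            1     11
```

Reading the output: the planted 2000 bp ITR is recovered exactly; the 98
called ORFs include all 40 planted ones (the rest are chance background
ORFs, classified `unknown` or promoter-only). Of the 40 genes with
counts, 25 are differentially expressed between hosts; 8 of the 9 planted
core-replication genes land in the cluster up-regulated in the wasp and
all 15 virulence genes in the cluster down-regulated in the wasp — the
functional partition the package is built to measure. The mean absolute
log2 fold changes per cluster (2.31 up, 3.25 down) recover the planted
+2.3 / −3.4 category effects.

The same run as a one-liner writing FASTA/GFF3/TSV/JSON artifacts and a
manifest:

```r
run_pipeline(list(out_dir = "run1", seed = 7))
```

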