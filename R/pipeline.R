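#' Run the annotation and expression-partition pipeline
#'
#' Orchestrates the stages in dependency order — `simulate` (optional) →
#' `annotate` → `classify` → `express` — writing tabular artifacts and a
#' manifest to `out_dir`. Referenced inputs are validated before any stage
#' runs; a stage failure halts the run with an error naming the stage. All
#' randomness flows from the config seed, so a re-run with the same config
#' is reproducible.
#'
#' Configuration fields (list or YAML file): `out_dir`; `stages` (character
#' subset of `simulate`, `annotate`, `classify`, `express`, in any order —
#' dependency order is imposed); `seed`; input paths `fasta`, `evidence`,
#' `counts`, `samples` (required when the producing `simulate` stage is not
#' enabled); and stage parameters `min_aa`, `window`, `min_seed`,
#' `max_mismatch_frac`, `alpha`, `pseudocount`.
#'
#' @param config A named list or the path to a YAML file.
#' @return The manifest (list), invisibly. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(stages = c("simulate", "annotate", "classify", "express"),
                   seed = 1L, min_aa = 50, window = 100, min_seed = 25,
                   max_mismatch_frac = 0.02, alpha = 0.05, pseudocount = 1.0)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stages <- intersect(c("simulate", "annotate", "classify", "express"),
                      config$stages)
  if (length(stages) == 0L) stop("no recognised stages enabled")

  # validate inputs before any stage runs
  required <- character(0)
  if (!"simulate" %in% stages) {
    if (any(c("annotate", "classify") %in% stages)) {
      required <- c(required, "fasta")
    }
    if ("classify" %in% stages) required <- c(required, "evidence")
    if ("express" %in% stages) required <- c(required, "counts", "samples")
  }
  for (nm in required) {
    if (is.null(config[[nm]])) {
      stop("config$", nm, " is required for the enabled stages")
    }
    if (!file.exists(config[[nm]])) {
      stop("input file for '", nm, "' not found: ", config[[nm]])
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  evidence_path <- config$evidence
  counts_path <- config$counts
  samples_path <- config$samples
  fasta_path <- config$fasta
  study <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      gcfg <- do.call(synthetic_genome_config,
                      c(config$genome_config, list(seed = config$seed)))
      truth <- generate_genome(gcfg)
      ecfg <- do.call(synthetic_expression_config,
                      c(config$expression_config, list(seed = config$seed)))
      study <- simulate_counts(truth, ecfg)
      fasta_path <- out("genome.fasta")
      write_genome_fasta(truth$genome, fasta_path)
      utils::write.table(truth$orfs, out("truth_orfs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      evidence_path <- out("evidence.tsv")
      utils::write.table(truth_evidence(truth), evidence_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      counts_path <- out("counts.tsv")
      cdf <- data.frame(gene_id = rownames(study$counts),
                        length = study$gene_lengths, study$counts,
                        check.names = FALSE)
      utils::write.table(cdf, counts_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      samples_path <- out("samples.tsv")
      utils::write.table(data.frame(sample_id = colnames(study$counts),
                                    group = study$sample_group),
                         samples_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts <- c(artifacts, fasta_path, out("truth_orfs.tsv"),
                      evidence_path, counts_path, samples_path)
    })
  }

  genomes <- orfs <- motifs <- annotations <- NULL
  if (any(c("annotate", "classify") %in% stages)) {
    genomes <- run_stage("annotate", read_fasta(fasta_path))
  }
  if ("annotate" %in% stages || "classify" %in% stages) {
    run_stage("annotate", {
      g <- genomes[[1]]
      orfs <- filter_repetitive(call_orfs(g, min_aa = config$min_aa))$kept
      itr <- detect_itrs(g, min_seed = config$min_seed,
                         max_mismatch_frac = config$max_mismatch_frac)
      motifs <- scan_early_promoters(g, orfs, window = config$window)
      metrics <- compute_genome_metrics(g, orfs, itr)
      utils::write.table(metrics, out("metrics.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_annotation_gff3(g, orfs, motifs, out("annotation.gff3"))
      artifacts <- c(artifacts, out("metrics.tsv"), out("annotation.gff3"))
    })
  }
  if ("classify" %in% stages) {
    run_stage("classify", {
      evidence <- read_evidence_tsv(evidence_path)
      evidence <- evidence[evidence$orf_id %in% orfs$orf_id, , drop = FALSE]
      annotations <- assign_categories(orfs, evidence, motifs)
      utils::write.table(annotations, out("annotations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      census <- census_core_genes(annotations)
      report <- list(
        categories = as.list(table(annotations$category)),
        virulence = summarize_virulence(annotations),
        core = list(reference_total = census$reference_total,
                    identified = length(census$identified),
                    missing = census$missing))
      jsonlite::write_json(report, out("classification.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      artifacts <- c(artifacts, out("annotations.tsv"),
                      out("classification.json"))
    })
  }
  if ("express" %in% stages) {
    run_stage("express", {
      if (is.null(study)) {
        cdf <- utils::read.delim(counts_path, check.names = FALSE)
        sdf <- utils::read.delim(samples_path)
        counts <- as.matrix(cdf[, setdiff(names(cdf), c("gene_id", "length")),
                                drop = FALSE])
        rownames(counts) <- cdf$gene_id
        study <- expression_study(counts, cdf$length,
                                  sdf$group[match(colnames(counts),
                                                  sdf$sample_id)])
      }
      de <- run_expression_analysis(study, alpha = config$alpha,
                                    pseudocount = config$pseudocount)
      utils::write.table(de, out("de_results.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ann <- if (!is.null(annotations)) annotations else
        data.frame(orf_id = de$gene_id, category = "unknown",
                   stringsAsFactors = FALSE)
      part <- partition_summary(ann, de)
      jsonlite::write_json(
        list(n_genes = part$n_genes, n_de = part$n_de, pct_de = part$pct_de,
             n_up = part$n_up, n_down = part$n_down,
             pct_core_in_up = part$pct_core_in_up,
             pct_virulence_in_down = part$pct_virulence_in_down,
             mean_abs_log2fc = as.list(part$mean_abs_log2fc)),
        out("partition.json"), auto_unbox = TRUE, pretty = TRUE)
      artifacts <- c(artifacts, out("de_results.tsv"), out("partition.json"))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("epvkit")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = stages,
    parameters = config[c("min_aa", "window", "min_seed",
                          "max_mismatch_frac", "alpha", "pseudocount")],
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) list(path = f,
                                        md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
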