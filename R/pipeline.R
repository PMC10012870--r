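# End-to-end orchestration: counts + read-start profiles + genome ->
# stimulon -> TSSs -> promoter calls -> regulon + consensus, with every
# stage's output written to disk before the next stage runs.

#' Build and validate a pipeline configuration
#'
#' @param genome,gff,starts_fwd,starts_rev,counts,conditions Input paths.
#' @param overrides Optional path to an override TSV (columns `gene_id`,
#'   `class`); `NULL` disables overrides.
#' @param out_dir Output directory.
#' @param reference,treatment Condition labels in the condition map.
#' @param m_cutoff,padj_cutoff DGE cutoffs (defaults 1, 0.01).
#' @param ratio_threshold,min_starts,dedup_window,max_distance TSS
#'   parameters (defaults 10, 10, 3, 500).
#' @param gtt_start_range,spacer_range,max_core_mismatches Matcher
#'   parameters (defaults c(-13,-7), c(18,19), 1).
#' @param consensus_upper,consensus_lower Consensus case thresholds
#'   (defaults 0.9, 0.4).
#' @param feature_type GFF3 feature type anchoring start codons.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, gff, starts_fwd, starts_rev, counts,
                            conditions, overrides = NULL,
                            out_dir = "sigregulon_out",
                            reference = "reference",
                            treatment = "deletion",
                            m_cutoff = 1.0, padj_cutoff = 0.01,
                            ratio_threshold = 10, min_starts = 10,
                            dedup_window = 3L, max_distance = 500L,
                            gtt_start_range = c(-13L, -7L),
                            spacer_range = c(18L, 19L),
                            max_core_mismatches = 1L,
                            consensus_upper = 0.9, consensus_lower = 0.4,
                            feature_type = "gene") {
  cfg <- as.list(environment())
  paths <- c(genome = genome, gff = gff, starts_fwd = starts_fwd,
             starts_rev = starts_rev, counts = counts,
             conditions = conditions)
  if (!is.null(overrides)) paths <- c(paths, overrides = overrides)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(names(missing), "=", missing, collapse = ", "))
  }
  stopifnot(m_cutoff > 0, padj_cutoff > 0, padj_cutoff <= 1,
            ratio_threshold > 0, min_starts > 0, dedup_window >= 1,
            max_distance >= 0, max_core_mismatches >= 0,
            consensus_lower > 0, consensus_lower < consensus_upper,
            consensus_upper <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full regulon-definition pipeline
#'
#' Stages, in order: differential expression, TSS calling, promoter
#' window extraction and scanning, regulon assembly, and per-class
#' consensus derivation. Each stage's table is written to the output
#' directory before the next stage runs; a rerun with the same inputs
#' produces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage banners (default FALSE).
#' @return A regulon report: the [assemble_regulon()] fields plus
#'   `n_tss`, `n_genes_with_tss`, `n_up_without_tss`, consensus strings
#'   per promoter class, and the per-stage tables (`dge`, `tss`,
#'   `promoters`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[sigregulon] ", ...)

  say("stage dge: reading counts")
  counts <- read_counts(config$counts)
  conditions <- read_conditions(config$conditions)
  dge <- run_dge(counts, conditions, reference = config$reference,
                 treatment = config$treatment,
                 m_cutoff = config$m_cutoff,
                 padj_cutoff = config$padj_cutoff)
  write_tsv_report(dge[, c("gene_id", "a_value", "m_value", "p", "padj",
                           "status")],
                   file.path(config$out_dir, "dge.tsv"))
  say("stage dge: ", sum(dge$status == "up"), " up, ",
      sum(dge$status == "down"), " down of ", nrow(dge), " genes")

  say("stage tss: reading genome, annotation and read starts")
  genome <- read_fasta(config$genome)
  genes <- read_gff3(config$gff, feature_type = config$feature_type)
  profiles <- read_bedgraph_pair(config$starts_fwd, config$starts_rev,
                                 stats::setNames(nchar(genome),
                                                 names(genome)))
  tss <- run_tss_stage(profiles, genes,
                       ratio_threshold = config$ratio_threshold,
                       min_starts = config$min_starts,
                       window = config$dedup_window,
                       max_distance = config$max_distance)
  write_bed_tss(tss, file.path(config$out_dir, "tss.bed"))
  write_tsv_report(tss, file.path(config$out_dir, "tss.tsv"))
  say("stage tss: ", nrow(tss), " TSS calls, ",
      length(unique(stats::na.omit(tss$gene_id))), " genes with a TSS")

  say("stage promoters: scanning -50..-1 windows")
  overrides <- if (is.null(config$overrides)) NULL else
    utils::read.delim(config$overrides, stringsAsFactors = FALSE)
  windows <- extract_window(genome, tss)
  promoters <- scan_promoters(windows, overrides = overrides,
                              gtt_start_range = config$gtt_start_range,
                              spacer_range = config$spacer_range,
                              max_core_mismatches =
                                config$max_core_mismatches)
  write_tsv_report(promoters,
                   file.path(config$out_dir, "promoters.tsv"))
  say("stage promoters: ",
      sum(promoters$class == "dual_sigHE"), " dual, ",
      sum(promoters$class == "sigH_only"), " sigH-only, ",
      sum(promoters$class == "sigA_like"), " sigA-like")

  say("stage regulon: assembling")
  regulon <- assemble_regulon(dge, promoters)

  consensus <- list()
  for (cls in c("dual_sigHE", "sigH_only")) {
    sel <- promoters[promoters$class == cls & promoters$gate_pass %in% TRUE,
                     , drop = FALSE]
    if (nrow(sel) > 0L) {
      consensus[[cls]] <- element_consensus(sel,
                                            upper = config$consensus_upper,
                                            lower = config$consensus_lower)
    }
  }
  cons_lines <- vapply(names(consensus), function(cls) {
    paste0(cls, "\t-35 ", consensus[[cls]]$m35, "\t-10 ",
           consensus[[cls]]$m10)
  }, character(1L))
  writeLines(c("class\tconsensus", cons_lines),
             file.path(config$out_dir, "consensus.txt"))

  up <- regulon$n_up
  n_binned <- regulon$n_regulon_genes + length(regulon$sigH_only_genes) +
    length(regulon$sigA_only_genes) + length(regulon$no_promoter_genes)
  stopifnot(up == n_binned)  # report tallies must be internally consistent

  report <- c(regulon, list(
    n_tss = nrow(tss),
    n_genes_with_tss = length(unique(stats::na.omit(tss$gene_id))),
    n_up_without_tss = sum(!dge$gene_id[dge$status == "up"] %in%
                             tss$gene_id),
    consensus = consensus,
    dge = dge, tss = tss, promoters = promoters
  ))
  report_lines <- c(
    paste0("n_up\t", report$n_up),
    paste0("n_down\t", report$n_down),
    paste0("n_tss\t", report$n_tss),
    paste0("n_genes_with_tss\t", report$n_genes_with_tss),
    paste0("n_up_without_tss\t", report$n_up_without_tss),
    paste0("n_regulon_genes\t", report$n_regulon_genes),
    paste0("n_dual_promoters\t", report$n_dual_promoters),
    paste0("regulon_genes\t", paste(report$regulon_genes, collapse = ","))
  )
  writeLines(report_lines, file.path(config$out_dir, "regulon_report.tsv"))
  say("done: ", report$n_regulon_genes, " regulon genes")
  report
}

#' Run the shipped fixture tables through the classification machinery
#'
#' Applies the candidate gate, the -31 discriminator (with the shipped
#' amtR override), and the element-anchored consensus to the installed
#' dual sigmaH/sigmaE and exclusively-sigmaH motif tables.
#'
#' @param spacer_range,max_core_mismatches Gate parameters (defaults
#'   c(18,19), 1).
#' @param upper,lower Consensus case thresholds (defaults 0.9, 0.4).
#' @return A list: `dual` and `sigH` (each with `records`, `matches`,
#'   `classes`, `consensus`), `n_gate_pass_dual`, `n_regulon_genes`,
#'   `control_classes` (the four tested sigmaH-only control promoters).
#' @export
run_fixture_mode <- function(spacer_range = c(18L, 19L),
                             max_core_mismatches = 1L,
                             upper = 0.9, lower = 0.4) {
  read_fixture <- function(file) {
    read_motif_table(system.file("extdata", file, package = "sigregulon"))
  }
  overrides <- shipped_overrides()
  process <- function(tab) {
    matches <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      match_from_record(tab[i, ], spacer_range = spacer_range,
                        max_core_mismatches = max_core_mismatches)
    }))
    classes <- vapply(seq_len(nrow(tab)), function(i) {
      classify_promoter(matches[i, ], gene_id = tab$gene_id[i],
                        overrides = overrides)$class
    }, character(1L))
    list(records = tab, matches = matches, classes = classes,
         consensus = element_consensus(matches[matches$gate_pass, ,
                                               drop = FALSE],
                                       upper = upper, lower = lower))
  }
  dual <- process(read_fixture("table_dual_sigHE.tsv"))
  sigh <- process(read_fixture("table_sigH_only.tsv"))
  controls <- c("mca", "uvrD3", "mshC", "sufR")
  list(
    dual = dual, sigH = sigh,
    n_gate_pass_dual = sum(dual$matches$gate_pass),
    n_regulon_genes = length(unique(
      dual$records$gene_id[dual$matches$gate_pass &
                             dual$classes == "dual_sigHE"])),
    control_classes = stats::setNames(
      sigh$classes[match(controls, sigh$records$name)], controls)
  )
}
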