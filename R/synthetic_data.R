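# Synthetic genomes with planted promoters, TSS read-start pileups, and
# negative-binomial count matrices, all with exact ground truth so every
# downstream stage can be validated without external data.

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

PROMOTER_CLASSES <- c("dual_sigHE", "sigH_only", "sigA_like", "none")

# Build one promoter window (-50..-1, transcription orientation) with the
# class-specific elements planted; returns the window plus the element
# coordinates (promoter-local) for the truth table.
plant_promoter <- function(class, spacer, gtt_window) {
  win <- strsplit(random_dna(50L), "")[[1L]]
  pos2idx <- function(pos) pos + 51L  # promoter pos -50..-1 -> index 1..50
  truth <- list(class = class, minus35 = NA_character_, spacer = NA_integer_,
                minus10 = NA_character_, base_minus31 = NA_character_,
                gtt_pos = NA_integer_)
  if (class %in% c("dual_sigHE", "sigH_only")) {
    gtt_pos <- sample(seq(gtt_window[1L], gtt_window[2L]), 1L)
    pent <- if (class == "dual_sigHE") "GGAAC" else
      paste0("GGAA", sample(c("T", "T", "T", "G", "A"), 1L))
    spacer_seq <- strsplit(random_dna(spacer), "")[[1L]]
    if (class == "dual_sigHE") spacer_seq[spacer] <- "C"  # -11 base
    pent_start <- gtt_pos - spacer - 5L
    win[pos2idx(pent_start):pos2idx(pent_start + 4L)] <- strsplit(pent, "")[[1L]]
    win[pos2idx(pent_start + 5L):pos2idx(gtt_pos - 1L)] <- spacer_seq
    win[pos2idx(gtt_pos):pos2idx(gtt_pos + 2L)] <- c("G", "T", "T")
    truth$minus35 <- pent
    truth$spacer <- spacer
    truth$minus10 <- paste0(spacer_seq[spacer], "GTT")
    truth$base_minus31 <- substr(pent, 5L, 5L)
    truth$gtt_pos <- gtt_pos
  } else if (class == "sigA_like") {
    # TANAAT-like -10 hexamer ending at -7 and a TTG trimer 17 nt upstream
    hex <- c("T", "A", sample(DNA_BASES, 1L), "A", "A", "T")
    end_pos <- -7L
    start_pos <- end_pos - 5L
    win[pos2idx(start_pos):pos2idx(end_pos)] <- hex
    ttg_end <- start_pos - 18L  # 17-nt gap between TTG and the hexamer
    win[pos2idx(ttg_end - 2L):pos2idx(ttg_end)] <- c("T", "T", "G")
    truth$minus10 <- paste(hex, collapse = "")
  }
  list(window = paste(win, collapse = ""), truth = truth)
}

#' Generate a synthetic genome with planted promoters and ground truth
#'
#' Lays out `n_genes` gene cassettes (a 50-nt promoter window, a 5' UTR,
#' and a gene body) on alternating strands of a single contig, separated
#' by motif-free intergenic spacers. Each gene is assigned a promoter
#' class; stress classes get a GGAAC/GGAAT pentamer, a spacer of 18 or 19
#' nt, and the GTT trimer planted with its G inside the configured -10
#' window. A fraction of genes are operon members with no TSS or promoter
#' of their own. Dual-class genes always carry a positive planted log2
#' fold change (the sigmaE regulon is active in the anti-sigma deletion);
#' an additional fraction of the remaining genes are differentially
#' expressed in either direction.
#'
#' @param n_genes Number of genes (default 60).
#' @param class_mix Named proportions over
#'   `c("dual_sigHE","sigH_only","sigA_like","none")`; must sum to 1.
#' @param spacer_distribution Named proportions over spacers 18 and 19.
#' @param operon_fraction Fraction of genes that are operon members
#'   without their own TSS (default 0.2).
#' @param de_fraction Fraction of non-dual genes that are differentially
#'   expressed (default 0.1), with |log2FC| drawn from `lfc_range`.
#' @param lfc_range Range of planted |log2 fold changes| (default 1-3).
#' @param utr_range Range of TSS-to-start-codon distances in nt.
#' @param gene_body Gene body length in nt.
#' @param intergenic Minimum intergenic spacing in nt (default 150, so
#'   promoter windows never overlap the upstream gene).
#' @param gtt_window Promoter-local window for the G of the planted GTT.
#' @param contig Contig name.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with `genome` (named character vector of length 1) and
#'   `truth`, itself a list with `genes`, `tss_truth`, `promoter_truth`,
#'   `de_truth`, `operon_members`, `contig`, `length` and `seed`.
#' @export
generate_genome <- function(n_genes = 60L,
                            class_mix = c(dual_sigHE = 0.25, sigH_only = 0.25,
                                          sigA_like = 0.30, none = 0.20),
                            spacer_distribution = c("18" = 0.5, "19" = 0.5),
                            operon_fraction = 0.2,
                            de_fraction = 0.1,
                            lfc_range = c(1, 3),
                            utr_range = c(20L, 120L),
                            gene_body = 300L,
                            intergenic = 150L,
                            gtt_window = c(-13L, -7L),
                            contig = "chrS",
                            seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% PROMOTER_CLASSES),
            all(names(spacer_distribution) %in% c("18", "19")),
            n_genes >= 1L, intergenic >= 120L)
  set.seed(seed)
  classes <- sample(names(class_mix), n_genes, replace = TRUE,
                    prob = class_mix)
  is_operon <- stats::runif(n_genes) < operon_fraction
  classes[is_operon] <- "none"
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  pieces <- character(0L)
  offset <- 0L
  genes <- vector("list", n_genes)
  tss_rows <- vector("list", n_genes)
  prom_rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("sg%04d", i)
    cls <- classes[i]
    strand <- strands[i]
    d <- sample(utr_range[1L]:utr_range[2L], 1L)
    spacer <- as.integer(sample(names(spacer_distribution), 1L,
                                prob = spacer_distribution))
    planted <- plant_promoter(cls, spacer, gtt_window)
    body <- paste0("ATG", random_dna(gene_body - 3L))
    cassette <- paste0(planted$window, random_dna(d), body)
    lc <- nchar(cassette)
    gap <- random_dna(intergenic)
    o <- offset + intergenic + 1L  # 1-based genome start of cassette
    pieces <- c(pieces, gap,
                if (strand == "+") cassette else revcomp_dna(cassette))
    offset <- o + lc - 1L

    if (strand == "+") {
      tss_pos <- o + 50L
      start_codon <- tss_pos + d
      gene_start <- start_codon
      gene_end <- start_codon + gene_body - 1L
    } else {
      tss_pos <- o + lc - 51L
      start_codon <- tss_pos - d
      gene_start <- start_codon - gene_body + 1L
      gene_end <- start_codon
    }
    genes[[i]] <- data.frame(gene_id = gid, contig = contig, strand = strand,
                             start = gene_start, end = gene_end,
                             start_codon_pos = start_codon,
                             name = NA_character_, product = NA_character_,
                             stringsAsFactors = FALSE)
    if (!is_operon[i]) {
      tss_rows[[i]] <- data.frame(gene_id = gid, contig = contig,
                                  pos = tss_pos, strand = strand,
                                  distance = d, stringsAsFactors = FALSE)
      tr <- planted$truth
      prom_rows[[i]] <- data.frame(gene_id = gid, class = tr$class,
                                   minus35 = tr$minus35, spacer = tr$spacer,
                                   minus10 = tr$minus10,
                                   base_minus31 = tr$base_minus31,
                                   gtt_pos = tr$gtt_pos,
                                   window = planted$window,
                                   stringsAsFactors = FALSE)
    }
  }
  genome <- paste(c(pieces, random_dna(intergenic)), collapse = "")

  lfc <- numeric(n_genes)
  dual <- classes == "dual_sigHE" & !is_operon
  lfc[dual] <- stats::runif(sum(dual), lfc_range[1L], lfc_range[2L])
  rest <- which(!dual)
  de_rest <- rest[stats::runif(length(rest)) < de_fraction]
  lfc[de_rest] <- sample(c(-1, 1), length(de_rest), replace = TRUE) *
    stats::runif(length(de_rest), lfc_range[1L], lfc_range[2L])
  # half of the operon members ride on an upstream stress promoter: DE up
  op_up <- which(is_operon)[stats::runif(sum(is_operon)) < 0.5]
  lfc[op_up] <- stats::runif(length(op_up), lfc_range[1L], lfc_range[2L])

  truth <- list(
    genes = do.call(rbind, genes),
    tss_truth = do.call(rbind, tss_rows[!vapply(tss_rows, is.null, TRUE)]),
    promoter_truth = do.call(rbind,
                             prom_rows[!vapply(prom_rows, is.null, TRUE)]),
    de_truth = data.frame(gene_id = sprintf("sg%04d", seq_len(n_genes)),
                          log2fc = lfc, stringsAsFactors = FALSE),
    operon_members = sprintf("sg%04d", which(is_operon)),
    contig = contig,
    length = nchar(genome),
    seed = seed
  )
  list(genome = stats::setNames(genome, contig), truth = truth)
}

#' Simulate a stranded 5'-read-start profile from ground truth
#'
#' Counts at every true +1 position are drawn from a negative binomial
#' with mean `depth_at_tss`; all other positions on both strands receive
#' Poisson background.
#'
#' @param truth Truth object from [generate_genome()].
#' @param depth_at_tss Expected read-start count at a true TSS.
#' @param background_rate Poisson mean at non-TSS positions.
#' @param dispersion Negative-binomial dispersion of the TSS peak heights
#'   (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return A [stranded_profile()] for the synthetic contig.
#' @export
simulate_read_starts <- function(truth, depth_at_tss = 100,
                                 background_rate = 0.1,
                                 dispersion = 0.2, seed = 1L) {
  stopifnot(depth_at_tss >= 0, background_rate >= 0, dispersion >= 0)
  set.seed(seed)
  L <- truth$length
  fwd <- stats::rpois(L, background_rate)
  rev <- stats::rpois(L, background_rate)
  tt <- truth$tss_truth
  if (!is.null(tt) && nrow(tt) > 0L && depth_at_tss > 0) {
    peak <- if (dispersion > 0) {
      stats::rnbinom(nrow(tt), mu = depth_at_tss, size = 1 / dispersion)
    } else {
      stats::rpois(nrow(tt), depth_at_tss)
    }
    on_fwd <- tt$strand == "+"
    fwd[tt$pos[on_fwd]] <- fwd[tt$pos[on_fwd]] + peak[on_fwd]
    rev[tt$pos[!on_fwd]] <- rev[tt$pos[!on_fwd]] + peak[!on_fwd]
  }
  stranded_profile(truth$contig, L, fwd = fwd, rev = rev)
}

#' Simulate a two-condition negative-binomial count matrix
#'
#' Emulates the study design: a reference strain versus an anti-sigma
#' deletion strain, each with `n_replicates` biological replicates. The
#' deletion-condition mean of each gene is the reference mean times
#' 2^(planted log2 fold change).
#'
#' @param truth Truth object from [generate_genome()].
#' @param n_replicates Replicates per condition (default 3).
#' @param base_mean_range Range of reference-condition base means; drawn
#'   log-uniformly.
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix) and
#'   `conditions` (data.frame with columns `sample`, `condition`; levels
#'   `reference` and `deletion`).
#' @export
simulate_counts <- function(truth, n_replicates = 3L,
                            base_mean_range = c(50, 2000),
                            nb_dispersion = 0.05, seed = 1L) {
  stopifnot(n_replicates >= 2L, all(base_mean_range > 0))
  set.seed(seed)
  de <- truth$de_truth
  n <- nrow(de)
  base <- exp(stats::runif(n, log(base_mean_range[1L]),
                           log(base_mean_range[2L])))
  mu_ref <- base
  mu_del <- base * 2^de$log2fc
  draw <- function(mu) {
    if (nb_dispersion > 0) {
      matrix(stats::rnbinom(n * n_replicates, mu = rep(mu, n_replicates),
                            size = 1 / nb_dispersion), nrow = n)
    } else {
      matrix(stats::rpois(n * n_replicates, rep(mu, n_replicates)), nrow = n)
    }
  }
  counts <- cbind(draw(mu_ref), draw(mu_del))
  samples <- c(paste0("ref_", seq_len(n_replicates)),
               paste0("del_", seq_len(n_replicates)))
  dimnames(counts) <- list(de$gene_id, samples)
  storage.mode(counts) <- "integer"
  conditions <- data.frame(
    sample = samples,
    condition = rep(c("reference", "deletion"), each = n_replicates),
    stringsAsFactors = FALSE
  )
  list(counts = counts, conditions = conditions)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates a genome with [generate_genome()], a read-start profile with
#' [simulate_read_starts()], and a count matrix with [simulate_counts()],
#' and writes them as FASTA, GFF3, a bedGraph pair, and TSVs (counts,
#' conditions, truth tables) so the full pipeline can run from files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed used for all three generators.
#' @param ... Passed to [generate_genome()].
#' @param depth_at_tss,background_rate Passed to [simulate_read_starts()].
#' @param n_replicates,nb_dispersion Passed to [simulate_counts()].
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `truth`, `profile`, `counts`, `conditions`) and the file `paths`.
#' @export
write_synthetic_dataset <- function(dir, seed = 1L, ...,
                                    depth_at_tss = 100,
                                    background_rate = 0.1,
                                    n_replicates = 3L,
                                    nb_dispersion = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(seed = seed, ...)
  profile <- simulate_read_starts(gen$truth, depth_at_tss = depth_at_tss,
                                  background_rate = background_rate,
                                  seed = seed)
  cts <- simulate_counts(gen$truth, n_replicates = n_replicates,
                         nb_dispersion = nb_dispersion, seed = seed)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "genes.gff3"),
    starts_fwd = file.path(dir, "starts_fwd.bedgraph"),
    starts_rev = file.path(dir, "starts_rev.bedgraph"),
    counts = file.path(dir, "counts.tsv"),
    conditions = file.path(dir, "conditions.tsv"),
    tss_truth = file.path(dir, "truth_tss.tsv"),
    promoter_truth = file.path(dir, "truth_promoters.tsv"),
    de_truth = file.path(dir, "truth_de.tsv")
  )
  write_fasta(gen$genome, paths$genome)
  write_gff3_genes(gen$truth$genes, paths$gff)
  write_bedgraph_pair(profile, paths$starts_fwd, paths$starts_rev)
  write_tsv_report(data.frame(gene_id = rownames(cts$counts), cts$counts,
                              check.names = FALSE), paths$counts)
  write_tsv_report(cts$conditions, paths$conditions)
  write_tsv_report(gen$truth$tss_truth, paths$tss_truth)
  write_tsv_report(gen$truth$promoter_truth, paths$promoter_truth)
  write_tsv_report(gen$truth$de_truth, paths$de_truth)
  invisible(list(genome = gen$genome, truth = gen$truth, profile = profile,
                 counts = cts$counts, conditions = cts$conditions,
                 paths = paths))
}
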