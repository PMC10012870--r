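test_that("planted promoter elements read back verbatim from the genome", {
  gen <- generate_genome(n_genes = 20L,
                         class_mix = c(dual_sigHE = 1, sigH_only = 0,
                                       sigA_like = 0, none = 0),
                         operon_fraction = 0, seed = 5L)
  tr <- gen$truth
  expect_equal(nrow(tr$promoter_truth), 20L)
  windows <- extract_window(gen$genome, tr$tss_truth)
  expect_equal(nrow(windows), 20L)
  for (i in seq_len(nrow(windows))) {
    pt <- tr$promoter_truth[tr$promoter_truth$gene_id ==
                              windows$gene_id[i], ]
    expect_equal(windows$sequence[i], pt$window)
    # elements at the recorded coordinates
    idx <- function(pos) pos + 51L
    expect_equal(substr(pt$window, idx(pt$gtt_pos), idx(pt$gtt_pos + 2L)),
                 "GTT")
    p_start <- pt$gtt_pos - pt$spacer - 5L
    expect_equal(substr(pt$window, idx(p_start), idx(p_start + 4L)),
                 pt$minus35)
    expect_true(pt$spacer %in% c(18L, 19L))
    expect_equal(substr(pt$minus10, 4L, 4L), "T")
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_genome(n_genes = 15L, seed = 11L)
  b <- generate_genome(n_genes = 15L, seed = 11L)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_read_starts(a$truth, seed = 3L),
                   simulate_read_starts(b$truth, seed = 3L))
  expect_identical(simulate_counts(a$truth, seed = 3L),
                   simulate_counts(b$truth, seed = 3L))
})

test_that("operon members have no TSS and truth tables are consistent", {
  gen <- generate_genome(n_genes = 50L, operon_fraction = 0.4, seed = 2L)
  tr <- gen$truth
  expect_length(intersect(tr$operon_members, tr$tss_truth$gene_id), 0L)
  dual <- tr$promoter_truth$gene_id[tr$promoter_truth$class == "dual_sigHE"]
  lfc <- tr$de_truth$log2fc[match(dual, tr$de_truth$gene_id)]
  expect_true(all(lfc >= 1))
})

test_that("the matcher recovers planted classes from truth windows", {
  gen <- generate_genome(n_genes = 120L, operon_fraction = 0, seed = 8L)
  pt <- gen$truth$promoter_truth
  stress <- pt[pt$class %in% c("dual_sigHE", "sigH_only"), ]
  got <- vapply(seq_len(nrow(stress)), function(i) {
    classify_promoter(find_bipartite(stress$window[i]))$class
  }, character(1L))
  expect_gte(mean(got == stress$class), 0.99)

  siga <- pt[pt$class == "sigA_like", ]
  got_a <- vapply(seq_len(nrow(siga)), function(i) {
    m <- match_sigA(siga$window[i])
    !is.null(m)
  }, logical(1L))
  expect_gte(mean(got_a), 0.95)
})

test_that("promoter-free genomes yield matches only at background rate", {
  gen <- generate_genome(n_genes = 150L,
                         class_mix = c(dual_sigHE = 0, sigH_only = 0,
                                       sigA_like = 0, none = 1),
                         operon_fraction = 0, seed = 13L)
  pt <- gen$truth$promoter_truth
  hits <- vapply(seq_len(nrow(pt)), function(i) {
    !is.null(find_bipartite(pt$window[i]))
  }, logical(1L))
  # ~14 placements x P(GTT exact) x P(<=1 core mismatch) ~ 1% of windows
  expect_lte(mean(hits), 0.05)
})

test_that("read-start peaks dominate background by the expected margin", {
  gen <- generate_genome(n_genes = 40L, operon_fraction = 0, seed = 4L)
  prof <- simulate_read_starts(gen$truth, depth_at_tss = 100,
                               background_rate = 0.1, seed = 4L)
  tt <- gen$truth$tss_truth
  at_tss <- ifelse(tt$strand == "+", prof$fwd[tt$pos], prof$rev[tt$pos])
  expect_gte(mean(at_tss >= 10), 0.95)
  expect_lt(mean(prof$fwd) , 1)  # background stays sparse

  flat <- simulate_read_starts(gen$truth, depth_at_tss = 0,
                               background_rate = 0.1, seed = 4L)
  at_tss0 <- ifelse(tt$strand == "+", flat$fwd[tt$pos], flat$rev[tt$pos])
  expect_lt(mean(at_tss0), 2)
})

test_that("simulated counts carry the planted fold changes", {
  gen <- generate_genome(n_genes = 400L, operon_fraction = 0,
                         de_fraction = 0, seed = 6L,
                         class_mix = c(dual_sigHE = 0.5, sigH_only = 0,
                                       sigA_like = 0, none = 0.5))
  cts <- simulate_counts(gen$truth, n_replicates = 3L,
                         nb_dispersion = 0.05, seed = 6L)
  lfc <- gen$truth$de_truth$log2fc
  ref <- rowMeans(cts$counts[, 1:3])
  del <- rowMeans(cts$counts[, 4:6])
  m_hat <- log2((del + 0.5) / (ref + 0.5))
  null_genes <- lfc == 0
  expect_lt(abs(mean(m_hat[null_genes])), 0.1)
  # planted effects recovered within sampling error on average
  expect_lt(mean(abs(m_hat[!null_genes] - lfc[!null_genes])), 0.5)
})

test_that("zero dispersion reduces counts to Poisson-like variance", {
  gen <- generate_genome(n_genes = 200L, operon_fraction = 0,
                         de_fraction = 0, seed = 9L,
                         class_mix = c(dual_sigHE = 0, sigH_only = 0,
                                       sigA_like = 0, none = 1))
  cts <- simulate_counts(gen$truth, n_replicates = 10L,
                         base_mean_range = c(100, 100),
                         nb_dispersion = 0, seed = 9L)
  v <- apply(cts$counts[, 1:10], 1L, var)
  # Poisson: var/mean ratio near 1 on average
  expect_lt(abs(mean(v / rowMeans(cts$counts[, 1:10])) - 1), 0.15)
})

test_that("written fixture files re-read to the in-memory objects", {
  dir <- withr::local_tempdir()
  fx <- write_synthetic_dataset(dir, seed = 21L, n_genes = 25L)
  expect_identical(read_fasta(fx$paths$genome), fx$genome)
  genes <- read_gff3(fx$paths$gff)
  expect_equal(genes$gene_id, fx$truth$genes$gene_id)
  expect_equal(genes$start_codon_pos, fx$truth$genes$start_codon_pos)
  expect_equal(genes$strand, fx$truth$genes$strand)
  prof <- read_bedgraph_pair(fx$paths$starts_fwd, fx$paths$starts_rev,
                             setNames(fx$truth$length, fx$truth$contig))
  expect_identical(prof[[1L]]$fwd, fx$profile$fwd)
  expect_identical(prof[[1L]]$rev, fx$profile$rev)
  cts <- read_counts(fx$paths$counts)
  expect_equal(cts, fx$counts)
})
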