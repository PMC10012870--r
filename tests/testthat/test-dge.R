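make_conditions <- function(n_rep = 3L) {
  data.frame(sample = c(paste0("ref_", seq_len(n_rep)),
                        paste0("del_", seq_len(n_rep))),
             condition = rep(c("reference", "deletion"), each = n_rep),
             stringsAsFactors = FALSE)
}

test_that("median-of-ratios matches the hand-computed worked example", {
  cts <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  nf <- normalize_median_of_ratios(cts)
  # geometric means sqrt(200), sqrt(800), sqrt(1800); ratio medians 1/sqrt2, sqrt2
  expect_equal(nf$size_factors, c(s1 = 1 / sqrt(2), s2 = sqrt(2)),
               tolerance = 1e-12)
  expect_equal(nf$normalized[, 1], nf$normalized[, 2])
})

test_that("normalization is invariant to scaling a sample, and degenerate
           inputs behave", {
  set.seed(3)
  cts <- matrix(rpois(60, 50) + 1L, ncol = 4)
  rownames(cts) <- paste0("g", 1:15)
  colnames(cts) <- paste0("s", 1:4)
  base <- normalize_median_of_ratios(cts)$normalized
  scaled <- cts
  scaled[, 2] <- cts[, 2] * 5L
  renorm <- normalize_median_of_ratios(scaled)$normalized
  # identical up to one global scalar: library scaling cannot change any
  # relative expression value
  ratio <- renorm / base
  expect_lt(diff(range(ratio)), 1e-9)

  same <- cbind(s1 = cts[, 1], s2 = cts[, 1])
  nf <- normalize_median_of_ratios(same)
  expect_equal(unname(nf$size_factors[1]), unname(nf$size_factors[2]))

  single <- cts[, 1, drop = FALSE]
  expect_equal(unname(normalize_median_of_ratios(single)$size_factors), 1)

  nohope <- matrix(c(0L, 5L, 3L, 0L), ncol = 2)
  expect_error(normalize_median_of_ratios(nohope), "no gene")
})

test_that("A and M values follow the pseudocounted log2 definitions", {
  norm <- matrix(c(100, 100, 100, 200, 200, 200), nrow = 1,
                 dimnames = list("g1", make_conditions()$sample))
  ma <- compute_ma(norm, make_conditions())
  expect_equal(ma$m_value, log2(200.5 / 100.5), tolerance = 1e-9)
  expect_equal(ma$a_value, log2(150.5), tolerance = 1e-9)

  eq <- matrix(rep(80, 6), nrow = 1,
               dimnames = list("g1", make_conditions()$sample))
  expect_equal(compute_ma(eq, make_conditions())$m_value, 0)

  zero <- matrix(c(100, 100, 100, 0, 0, 0), nrow = 1,
                 dimnames = list("g1", make_conditions()$sample))
  m <- compute_ma(zero, make_conditions())$m_value
  expect_true(is.finite(m))
  expect_equal(m, log2(0.5 / 100.5), tolerance = 1e-9)

  expect_error(compute_ma(norm, make_conditions(), treatment = "mutant"),
               "mutant")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1L))
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("status labels respect inclusive cutoffs", {
  rec <- data.frame(m_value = c(1.0, -2, 0.99, -1.0, 3),
                    padj = c(0.01, 0.5, 0.001, 0.01, 0.2))
  out <- classify_dge(rec)
  expect_equal(out$status, c("up", "ns", "ns", "down", "ns"))
})

test_that("all-zero genes get p = 1 and the Wald stage runs end to end", {
  set.seed(5)
  cts <- rbind(matrix(rpois(30, 100), ncol = 6), 0L)
  rownames(cts) <- paste0("g", 1:6)
  colnames(cts) <- make_conditions()$sample
  res <- run_dge(cts, make_conditions())
  expect_equal(res$p[6], 1)
  expect_equal(res$status[6], "ns")
  expect_true(all(res$padj >= res$p))
})

test_that("the full stage controls false positives and finds planted
           two-fold-plus effects", {
  # 6000 null genes + 600 planted |log2FC| = 2 genes, 3v3, dispersion 0.05
  set.seed(17)
  ng <- 6000L; nde <- 600L; nr <- 3L
  mu <- exp(runif(ng, log(50), log(2000)))
  null_block <- cbind(
    matrix(rnbinom(ng * nr, mu = rep(mu, nr), size = 20), ng),
    matrix(rnbinom(ng * nr, mu = rep(mu, nr), size = 20), ng))
  sgn <- rep(c(1, -1), length.out = nde)
  de_block <- cbind(
    matrix(rnbinom(nde * nr, mu = 500, size = 20), nde),
    matrix(rnbinom(nde * nr, mu = rep(500 * 4^sgn, nr), size = 20), nde))
  cts <- rbind(null_block, de_block)
  rownames(cts) <- paste0("g", seq_len(ng + nde))
  colnames(cts) <- make_conditions()$sample
  res <- run_dge(cts, make_conditions())

  null_status <- res$status[seq_len(ng)]
  expect_lte(mean(null_status != "ns"), 0.02)  # <= 2x the 0.01 padj level

  de_status <- res$status[ng + seq_len(nde)]
  want <- ifelse(sgn > 0, "up", "down")
  expect_gte(mean(de_status == want), 0.95)    # sign-correct recovery
})

test_that("size factors agree with an independent median-of-ratios
           implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  # odd gene count so the ratio median commutes with the log transform
  cts <- matrix(rnbinom(606, mu = 200, size = 10) + 1L, ncol = 6)
  rownames(cts) <- paste0("g", 1:101)
  colnames(cts) <- make_conditions()$sample
  ours <- normalize_median_of_ratios(cts)$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(cts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})
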