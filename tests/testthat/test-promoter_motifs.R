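test_that("promoter windows obey the coordinate contract on both strands", {
  genome <- c(ctg = random_dna_str(300))
  tss <- data.frame(gene_id = c("gP", "gM"), contig = "ctg",
                    pos = c(100L, 100L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  win <- extract_window(genome, tss)
  expect_equal(win$sequence[1], substr(genome[["ctg"]], 50L, 99L))
  expect_equal(win$sequence[2],
               unname(revcomp_dna(substr(genome[["ctg"]], 101L, 150L))))

  edge <- data.frame(gene_id = "gE", contig = "ctg", pos = 30L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- extract_window(genome, edge), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("a planted stress element is found with the expected fields", {
  set.seed(41)
  spacer <- c(strsplit(random_dna_str(16L), "")[[1L]], "C")
  spacer[1L] <- "T"  # -30 base
  win <- build_window("GGAAC", c("T", spacer), gtt_pos = -10L)
  m <- find_bipartite(win)
  expect_equal(m$pentamer, "GGAAC")
  expect_equal(m$core_mismatches, 0L)
  expect_equal(m$spacer, 18L)
  expect_equal(m$base_minus31, "C")
  expect_equal(m$base_minus11, "C")
  expect_equal(m$gtt_start, -10L)

  expect_null(find_bipartite(strrep("A", 50L)))
})

test_that("all dual-table records pass the gate; all sigH-table records pass
           the sigH gate", {
  dual <- dual_fixture()
  md <- do.call(rbind, lapply(seq_len(nrow(dual)), function(i)
    match_from_record(dual[i, ])))
  expect_true(all(md$gate_pass))
  expect_equal(nrow(md), 16L)
  expect_true(all(md$spacer %in% 18:19))
  expect_true(all(md$core_mismatches <= 1L))

  sigh <- sigh_fixture()
  ms <- do.call(rbind, lapply(seq_len(nrow(sigh)), function(i)
    match_from_record(sigh[i, ])))
  expect_true(all(ms$gate_pass))
  expect_equal(nrow(ms), 6L)
})

test_that("the -31 discriminator separates the two fixture tables", {
  dual <- dual_fixture()
  md <- do.call(rbind, lapply(seq_len(nrow(dual)), function(i)
    match_from_record(dual[i, ])))
  not_c <- which(md$base_minus31 != "C")
  expect_length(not_c, 1L)
  expect_equal(dual$name[not_c], "amtR")
  expect_equal(md$base_minus31[not_c], "A")

  sigh <- sigh_fixture()
  ms <- do.call(rbind, lapply(seq_len(nrow(sigh)), function(i)
    match_from_record(sigh[i, ])))
  expect_true(all(ms$base_minus31 != "C"))
})

test_that("record-mode spacers follow the printed-notation mapping", {
  cseE <- match_from_record(list(hexamer = "GGAACT", n_count = 16L,
                                 tail = "CGTT"))
  expect_equal(cseE$spacer, 18L)
  amtR <- match_from_record(list(hexamer = "GGAAAC", n_count = 17L,
                                 tail = "CGTT"))
  expect_equal(amtR$spacer, 19L)
  expect_equal(amtR$pentamer, "GGAAA")
  expect_equal(amtR$base_minus31, "A")
  sufR <- match_from_record(list(hexamer = "GGAATG", n_count = 18L,
                                 tail = "GTT"))
  expect_equal(sufR$spacer, 19L)
  expect_equal(sufR$base_minus31, "T")
  expect_true(is.na(sufR$base_minus11))  # bare GTT tail leaves -11 unknown

  out_of_range <- match_from_record(list(hexamer = "GGAACT", n_count = 13L,
                                         tail = "CGTT"))
  expect_false(out_of_range$gate_pass)
  expect_error(match_from_record(list(hexamer = "GGA", n_count = 16L,
                                      tail = "CGTT")), "malformed")
})

test_that("classification follows the -31 base with explicit overrides", {
  dual_m <- match_from_record(list(hexamer = "GGAACT", n_count = 16L,
                                   tail = "CGTT"))
  expect_equal(classify_promoter(dual_m)$class, "dual_sigHE")

  trxB1 <- match_from_record(list(hexamer = "GGAATA", n_count = 17L,
                                  tail = "GTT"))
  expect_equal(classify_promoter(trxB1)$class, "sigH_only")

  ov <- shipped_overrides()
  amtR <- match_from_record(list(hexamer = "GGAAAC", n_count = 17L,
                                 tail = "CGTT"))
  res <- classify_promoter(amtR, gene_id = "cg0986", overrides = ov)
  expect_equal(res$class, "dual_sigHE")
  expect_true(res$override_applied)

  expect_equal(classify_promoter(NULL)$class, "none")
  expect_error(classify_promoter(NULL, gene_id = "cg0986", overrides = ov),
               "no qualifying")
})

test_that("find_bipartite equals brute-force enumeration on random windows", {
  set.seed(47)
  n_checked <- 0L
  for (i in 1:1000) {
    win <- random_dna_str(50L)
    # seed some GTTs so matches are not vanishingly rare
    if (i %% 2L == 0L) {
      g <- sample(-13:-7, 1L)
      substr(win, g + 51L, g + 53L) <- "GTT"
    }
    got <- find_bipartite(win)
    want <- bipartite_brute_force(win)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_checked <- n_checked + 1L
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
  expect_gte(n_checked, 20L)  # the comparison exercised real matches
})

test_that("minus-strand classification equals plus-strand classification of
           the reverse-complement construction", {
  set.seed(53)
  for (i in 1:20) {
    win <- build_window(sample(c("GGAAC", "GGAAT"), 1L),
                        strsplit(random_dna_str(18L), "")[[1L]],
                        gtt_pos = sample(-13:-7, 1L))
    pad <- random_dna_str(60L)
    genome_plus <- c(ctg = paste0(pad, win, random_dna_str(60L)))
    tss_plus <- data.frame(gene_id = "g", contig = "ctg",
                           pos = nchar(pad) + 51L, strand = "+",
                           stringsAsFactors = FALSE)
    genome_minus <- c(ctg = revcomp_dna(genome_plus[[1L]]))
    tss_minus <- data.frame(gene_id = "g", contig = "ctg",
                            pos = nchar(genome_minus[[1L]]) - nchar(pad) - 50L,
                            strand = "-", stringsAsFactors = FALSE)
    wp <- extract_window(genome_plus, tss_plus)
    wm <- extract_window(genome_minus, tss_minus)
    expect_equal(wm$sequence, wp$sequence)
    expect_equal(classify_promoter(find_bipartite(wm$sequence))$class,
                 classify_promoter(find_bipartite(wp$sequence))$class)
  }
})

test_that("sigmaA-like -10 elements match with the documented budgets", {
  win_fix <- function(hex, end_pos) {
    chars <- strsplit(strrep("G", 50L), "")[[1L]]  # G-rich: no spurious match
    idx <- function(pos) pos + 51L
    chars[idx(end_pos - 5L):idx(end_pos)] <- strsplit(hex, "")[[1L]]
    paste(chars, collapse = "")
  }
  m1 <- match_sigA(win_fix("CAAAAT", -7L))
  expect_equal(m1$mismatches, 1L)
  expect_equal(m1$hexamer, "CAAAAT")

  m2 <- match_sigA(win_fix("TAATCT", -8L))
  expect_equal(m2$mismatches, 2L)

  expect_null(match_sigA(strrep("G", 50L)))

  # a TTG trimer 16-19 nt upstream is reported when present
  chars <- strsplit(strrep("C", 50L), "")[[1L]]
  idx <- function(pos) pos + 51L
  chars[idx(-12L):idx(-7L)] <- strsplit("TATAAT", "")[[1L]]
  chars[idx(-32L):idx(-30L)] <- c("T", "T", "G")  # gap of 17 nt
  m3 <- match_sigA(paste(chars, collapse = ""))
  expect_equal(m3$mismatches, 0L)
  expect_equal(m3$ttg_start, -32L)
})

test_that("regulon assembly partitions upregulated genes consistently", {
  dge <- data.frame(gene_id = paste0("g", 1:6),
                    status = c("up", "up", "up", "up", "down", "ns"),
                    stringsAsFactors = FALSE)
  pc <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g5"),
                   class = c("dual_sigHE", "sigH_only", "sigH_only",
                             "sigA_like", "dual_sigHE"),
                   stringsAsFactors = FALSE)
  reg <- assemble_regulon(dge, pc)
  expect_equal(reg$regulon_genes, "g1")
  expect_equal(reg$sigH_only_genes, "g2")
  expect_equal(reg$sigA_only_genes, "g3")
  expect_equal(reg$no_promoter_genes, "g4")  # up but no promoter call
  expect_equal(reg$n_up, reg$n_regulon_genes + length(reg$sigH_only_genes) +
                 length(reg$sigA_only_genes) +
                 length(reg$no_promoter_genes))

  none <- assemble_regulon(
    data.frame(gene_id = "g1", status = "ns", stringsAsFactors = FALSE), pc)
  expect_equal(none$n_regulon_genes, 0L)
})
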