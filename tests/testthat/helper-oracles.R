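# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each rule position by position
# rather than reusing package internals.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Step-up Benjamini-Hochberg, written out longhand.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  scaled <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Enumerate every bipartite placement in a window and apply the tie-break
# chain by sorting, independently of find_bipartite's incremental "best".
bipartite_brute_force <- function(window, gtt_start_range = c(-13L, -7L),
                                  spacer_range = c(18L, 19L),
                                  max_core_mismatches = 1L) {
  chars <- strsplit(toupper(window), "")[[1L]]
  W <- length(chars)
  idx <- function(pos) pos + W + 1L
  cand <- list()
  for (g in seq(gtt_start_range[1L], gtt_start_range[2L])) {
    for (s in seq(spacer_range[1L], spacer_range[2L])) {
      gi <- idx(g)
      pi <- idx(g - s - 5L)
      if (pi < 1L || gi + 2L > W) next
      if (paste(chars[gi:(gi + 2L)], collapse = "") != "GTT") next
      pent <- chars[pi:(pi + 4L)]
      mm <- sum(pent[1:4] != c("G", "G", "A", "A"))
      if (mm > max_core_mismatches) next
      cand[[length(cand) + 1L]] <- data.frame(
        pentamer = paste(pent, collapse = ""), pentamer_start = g - s - 5L,
        base_minus31 = pent[5L], base_minus30 = chars[pi + 5L],
        core_mismatches = mm, spacer = s, gtt_start = g,
        base_minus11 = chars[gi - 1L], gate_pass = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  ord <- order(cand$core_mismatches, abs(cand$spacer - 18L),
               abs(cand$gtt_start + 8L), cand$base_minus31 != "C",
               cand$gtt_start)
  cand[ord[1L], , drop = FALSE]
}

# All exact pentamer + spacer + GTT placements in a sequence.
upstream_brute_force <- function(seq, pentamer, spacer_range) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  k <- nchar(pentamer)
  hits <- list()
  for (p in seq_len(max(L - k + 1L, 0L))) {
    if (paste(chars[p:(p + k - 1L)], collapse = "") != pentamer) next
    for (s in seq(spacer_range[1L], spacer_range[2L])) {
      g <- p + k + s
      if (g + 2L > L) next
      if (paste(chars[g:(g + 2L)], collapse = "") == "GTT") {
        hits[[length(hits) + 1L]] <- c(p, s, g)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(pentamer_start = integer(0), spacer = integer(0),
                      gtt_start = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(pentamer_start = m[, 1L], spacer = m[, 2L], gtt_start = m[, 3L])
}

# Position-by-position evaluation of the TSS +1/-1 rule.
tss_brute_force <- function(profile, ratio_threshold = 10, min_starts = 10) {
  rows <- list()
  for (strand in c("+", "-")) {
    counts <- if (strand == "+") profile$fwd else profile$rev
    for (pos in seq_len(profile$length)) {
      minus1 <- if (strand == "+") {
        if (pos > 1L) counts[pos - 1L] else 0L
      } else {
        if (pos < profile$length) counts[pos + 1L] else 0L
      }
      if (counts[pos] >= min_starts &&
          counts[pos] >= ratio_threshold * minus1) {
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, strand = strand, starts_plus1 = counts[pos],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      starts_plus1 = integer(0)))
  }
  do.call(rbind, rows)
}

# A window with the given elements planted at exact promoter positions.
build_window <- function(pentamer, spacer_seq, gtt_pos, width = 50L) {
  chars <- strsplit(random_dna_str(width), "")[[1L]]
  idx <- function(pos) pos + width + 1L
  s <- length(spacer_seq)
  p_start <- gtt_pos - s - 5L
  chars[idx(p_start):idx(p_start + 4L)] <- strsplit(pentamer, "")[[1L]]
  if (s > 0L) chars[idx(p_start + 5L):idx(gtt_pos - 1L)] <- spacer_seq
  chars[idx(gtt_pos):idx(gtt_pos + 2L)] <- c("G", "T", "T")
  paste(chars, collapse = "")
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "sigregulon")
}

dual_fixture <- function() read_motif_table(fixture_path("table_dual_sigHE.tsv"))
sigh_fixture <- function() read_motif_table(fixture_path("table_sigH_only.tsv"))
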