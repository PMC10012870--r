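# Bipartite stress-promoter matching. The -35 element is treated as the
# GGAAC/GGAAT-family pentamer occupying positions -35..-31 in a canonical
# placement, so the 5th pentamer letter is the base at -31: C there marks a
# promoter recognizable by both sigmaH and sigmaE, any other base an
# exclusively sigmaH promoter. The -10 core is the GTT trimer; the spacer
# is counted strictly between the pentamer end and the G of GTT. In
# printed HEXAMER-Nk-TAIL records that spacer equals k + 2 for 4-letter
# tails (the hexamer's 6th letter and the tail's first letter are spacer
# positions) and k + 1 for bare GTT tails.

CORE_GGAA <- c("G", "G", "A", "A")

# promoter-local position (-W..-1) <-> window string index (1..W)
prom_pos_to_idx <- function(pos, width) pos + width + 1L

#' Extract a promoter window upstream of a TSS
#'
#' Returns the `length` nt immediately 5' of the +1 position in
#' transcription orientation (+1 itself excluded; for minus-strand TSSs
#' the genomic slice 3' of the position is reverse-complemented). Windows
#' that would run past the contig edge are skipped with a warning.
#'
#' @param genome Named character vector of contig sequences.
#' @param tss Data.frame of TSS calls with columns `contig`, `pos`,
#'   `strand` and optionally `gene_id`.
#' @param length Window length in nt (default 50, promoter positions
#'   -50..-1).
#' @return Data.frame with columns `gene_id`, `contig`, `pos`, `strand`,
#'   `sequence`; skipped rows are dropped.
#' @export
extract_window <- function(genome, tss, length = 50L) {
  stopifnot(length >= 1L)
  seqs <- character(nrow(tss))
  keep <- logical(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    ctg <- tss$contig[i]
    if (!ctg %in% names(genome)) stop("unknown contig '", ctg, "'")
    L <- nchar(genome[[ctg]])
    pos <- tss$pos[i]
    if (tss$strand[i] == "+") {
      if (pos - length < 1L) {
        warning("window -", length, "..-1 for TSS at ", ctg, ":", pos,
                ":+ extends past the contig start; skipped")
        next
      }
      seqs[i] <- substr(genome[[ctg]], pos - length, pos - 1L)
    } else {
      if (pos + length > L) {
        warning("window -", length, "..-1 for TSS at ", ctg, ":", pos,
                ":- extends past the contig end; skipped")
        next
      }
      seqs[i] <- revcomp_dna(substr(genome[[ctg]], pos + 1L, pos + length))
    }
    keep[i] <- TRUE
  }
  out <- data.frame(
    gene_id = if ("gene_id" %in% names(tss)) tss$gene_id else NA_character_,
    contig = tss$contig, pos = tss$pos, strand = tss$strand,
    sequence = seqs, stringsAsFactors = FALSE
  )
  out[keep, , drop = FALSE]
}

empty_match <- function() {
  data.frame(pentamer = NA_character_, pentamer_start = NA_integer_,
             base_minus31 = NA_character_, base_minus30 = NA_character_,
             core_mismatches = NA_integer_, spacer = NA_integer_,
             gtt_start = NA_integer_, base_minus11 = NA_character_,
             gate_pass = FALSE, stringsAsFactors = FALSE)
}

#' Find the best bipartite -35/-10 stress-promoter placement in a window
#'
#' Enumerates every placement with an exact GTT whose G lies inside
#' `gtt_start_range`, a spacer (bases strictly between pentamer end and
#' the G) inside `spacer_range`, the pentamer fully inside the window,
#' and at most `max_core_mismatches` mismatches of the first four
#' pentamer letters against GGAA. The 5th pentamer letter (the -31 base,
#' the regulon discriminator) is never counted as a mismatch. Among
#' qualifying placements the best has the fewest core mismatches, then
#' the spacer closest to 18, then the G of GTT closest to position -8,
#' then a C at the 5th pentamer letter, then the most upstream placement.
#'
#' @param window A 50-nt (or longer) promoter window string, positions
#'   -n..-1 in transcription orientation.
#' @param gtt_start_range Promoter-local range allowed for the G of GTT
#'   (default c(-13, -7)).
#' @param spacer_range Allowed spacer lengths (default c(18, 19)).
#' @param max_core_mismatches Mismatch budget over GGAA (default 1).
#' @return One-row data.frame (see [match_from_record()] for columns)
#'   with `gate_pass = TRUE`, or `NULL` if no placement qualifies.
#' @export
find_bipartite <- function(window, gtt_start_range = c(-13L, -7L),
                           spacer_range = c(18L, 19L),
                           max_core_mismatches = 1L) {
  stopifnot(is.character(window), length(window) == 1L,
            gtt_start_range[1L] <= gtt_start_range[2L],
            spacer_range[1L] <= spacer_range[2L], max_core_mismatches >= 0L)
  W <- nchar(window)
  chars <- strsplit(toupper(window), "")[[1L]]
  best <- NULL
  for (g in seq(gtt_start_range[1L], gtt_start_range[2L])) {
    gi <- prom_pos_to_idx(g, W)
    if (gi < 1L || gi + 2L > W) next
    if (!identical(chars[gi:(gi + 2L)], c("G", "T", "T"))) next
    for (s in seq(spacer_range[1L], spacer_range[2L])) {
      p_start <- g - s - 5L   # promoter position of pentamer letter 1
      pi <- prom_pos_to_idx(p_start, W)
      if (pi < 1L) next
      pent <- chars[pi:(pi + 4L)]
      mm <- sum(pent[1:4] != CORE_GGAA)
      if (mm > max_core_mismatches) next
      cand <- data.frame(
        pentamer = paste(pent, collapse = ""),
        pentamer_start = p_start,
        base_minus31 = pent[5L],
        base_minus30 = chars[pi + 5L],
        core_mismatches = mm,
        spacer = s,
        gtt_start = g,
        base_minus11 = chars[gi - 1L],
        gate_pass = TRUE,
        stringsAsFactors = FALSE
      )
      if (is.null(best) || better_match(cand, best)) best <- cand
    }
  }
  best
}

# TRUE if candidate a beats b under the documented tie-break chain
better_match <- function(a, b) {
  if (a$core_mismatches != b$core_mismatches)
    return(a$core_mismatches < b$core_mismatches)
  if (abs(a$spacer - 18L) != abs(b$spacer - 18L))
    return(abs(a$spacer - 18L) < abs(b$spacer - 18L))
  if (abs(a$gtt_start + 8L) != abs(b$gtt_start + 8L))
    return(abs(a$gtt_start + 8L) < abs(b$gtt_start + 8L))
  a_c <- a$base_minus31 == "C"
  b_c <- b$base_minus31 == "C"
  if (a_c != b_c) return(a_c)
  a$gtt_start < b$gtt_start
}

#' Build a motif match from a printed HEXAMER-Nk-TAIL record
#'
#' The pentamer is the hexamer's first five letters (so the 5th letter is
#' the -31 base and the 6th the -30 base); the -11 base is the tail's
#' first letter when the tail has four letters, otherwise unknown. The
#' spacer is `n_count + 2` for 4-letter tails and `n_count + 1` for bare
#' GTT tails. The same candidate gate as [find_bipartite()] (GTT exact by
#' construction, core mismatches within budget, spacer within range) is
#' applied; a non-qualifying record is returned with `gate_pass = FALSE`.
#'
#' @param record A list or one-row data.frame with fields `hexamer`,
#'   `n_count`, `tail` (see [parse_motif_notation()]).
#' @param spacer_range Allowed spacer lengths (default c(18, 19)).
#' @param max_core_mismatches Mismatch budget over GGAA (default 1).
#' @return One-row data.frame with columns `pentamer`, `pentamer_start`
#'   (NA in record mode), `base_minus31`, `base_minus30`,
#'   `core_mismatches`, `spacer`, `gtt_start` (NA), `base_minus11`,
#'   `gate_pass`.
#' @export
match_from_record <- function(record, spacer_range = c(18L, 19L),
                              max_core_mismatches = 1L) {
  hexamer <- record$hexamer
  tail <- record$tail
  if (is.null(hexamer) || !grepl("^[ACGT]{6}$", hexamer) ||
      is.null(tail) || !grepl("^[ACGT]{3,4}$", tail) ||
      substr(tail, nchar(tail) - 2L, nchar(tail)) != "GTT" ||
      is.null(record$n_count) || record$n_count < 0L) {
    stop("malformed motif record",
         if (!is.null(record$gene_id)) paste0(" for gene ", record$gene_id))
  }
  pent <- strsplit(substr(hexamer, 1L, 5L), "")[[1L]]
  spacer <- record$n_count + (nchar(tail) - 2L)
  mm <- sum(pent[1:4] != CORE_GGAA)
  data.frame(
    pentamer = paste(pent, collapse = ""),
    pentamer_start = NA_integer_,
    base_minus31 = pent[5L],
    base_minus30 = substr(hexamer, 6L, 6L),
    core_mismatches = mm,
    spacer = spacer,
    gtt_start = NA_integer_,
    base_minus11 = if (nchar(tail) == 4L) substr(tail, 1L, 1L)
                   else NA_character_,
    gate_pass = mm <= max_core_mismatches &&
      spacer >= spacer_range[1L] && spacer <= spacer_range[2L],
    stringsAsFactors = FALSE
  )
}

#' Classify a promoter match as dual sigmaH/sigmaE or exclusively sigmaH
#'
#' A qualifying match with C at position -31 is `dual_sigHE`; any other
#' base gives `sigH_only`. An explicit experimental-evidence override
#' replaces the sequence-derived class (the package ships the documented
#' amtR exception, whose A at -31 would otherwise mark it sigmaH-only).
#' No match gives class `none`.
#'
#' @param match One-row data.frame from [find_bipartite()] or
#'   [match_from_record()], or `NULL`.
#' @param gene_id Gene identifier used for override lookup.
#' @param overrides Optional data.frame with columns `gene_id`, `class`.
#' @return A list with `class` (one of `dual_sigHE`, `sigH_only`,
#'   `none`) and `override_applied`.
#' @export
classify_promoter <- function(match, gene_id = NA_character_,
                              overrides = NULL) {
  has_match <- !is.null(match) && nrow(match) == 1L &&
    isTRUE(match$gate_pass)
  ov <- NULL
  if (!is.null(overrides) && !is.na(gene_id) &&
      gene_id %in% overrides$gene_id) {
    ov <- overrides$class[match(gene_id, overrides$gene_id)]
  }
  if (!has_match) {
    if (!is.null(ov)) {
      stop("override supplied for gene '", gene_id,
           "' which has no qualifying promoter match")
    }
    return(list(class = "none", override_applied = FALSE))
  }
  if (!is.null(ov)) return(list(class = ov, override_applied = TRUE))
  list(class = if (match$base_minus31 == "C") "dual_sigHE" else "sigH_only",
       override_applied = FALSE)
}

#' Shipped experimental-evidence overrides
#'
#' Returns the override table installed with the package: promoters whose
#' regulon membership was established experimentally in spite of their
#' sequence-derived class (the amtR promoter, with A at -31, is dual).
#'
#' @return Data.frame with columns `gene_id`, `class`, `reason`.
#' @export
shipped_overrides <- function() {
  utils::read.delim(system.file("extdata", "overrides.tsv",
                                package = "sigregulon"),
                    stringsAsFactors = FALSE)
}

#' Match a sigmaA-like -10 element (and optional TTG -35) in a window
#'
#' Searches for a hexamer matching TANAAT (position 3 unconstrained) with
#' at most `tanaat_max_mismatches` mismatches and its 3' end inside
#' `minus10_end_range`; optionally reports a TTG trimer 16-19 nt upstream
#' of the hexamer. Best = fewest mismatches, then 3' end closest to -7.
#'
#' @param window Promoter window string (positions -n..-1).
#' @param tanaat_max_mismatches Mismatch budget over the five constrained
#'   TANAAT positions (default 2).
#' @param minus10_end_range Allowed promoter-local positions of the
#'   hexamer's 3' end (default c(-9, -6)).
#' @param report_ttg Also look for a TTG trimer with a 16-19 nt gap to
#'   the hexamer (default TRUE).
#' @return One-row data.frame with columns `hexamer`, `start`, `end`,
#'   `mismatches`, `ttg_start` (NA if absent or not requested), or `NULL`
#'   if nothing qualifies.
#' @export
match_sigA <- function(window, tanaat_max_mismatches = 2L,
                       minus10_end_range = c(-9L, -6L),
                       report_ttg = TRUE) {
  W <- nchar(window)
  chars <- strsplit(toupper(window), "")[[1L]]
  ref <- c("T", "A", NA, "A", "A", "T")  # NA = unconstrained position
  best <- NULL
  for (end in seq(minus10_end_range[1L], minus10_end_range[2L])) {
    start <- end - 5L
    si <- prom_pos_to_idx(start, W)
    if (si < 1L || si + 5L > W) next
    hex <- chars[si:(si + 5L)]
    mm <- sum(hex != ref, na.rm = TRUE)
    if (mm > tanaat_max_mismatches) next
    ttg_start <- NA_integer_
    if (report_ttg) {
      for (gap in 16:19) {
        ts <- start - gap - 3L  # promoter position of the T of TTG
        ti <- prom_pos_to_idx(ts, W)
        if (ti < 1L) next
        if (identical(chars[ti:(ti + 2L)], c("T", "T", "G"))) {
          ttg_start <- ts
          break
        }
      }
    }
    cand <- data.frame(hexamer = paste(hex, collapse = ""), start = start,
                       end = end, mismatches = mm, ttg_start = ttg_start,
                       stringsAsFactors = FALSE)
    if (is.null(best) || cand$mismatches < best$mismatches ||
        (cand$mismatches == best$mismatches &&
           abs(cand$end + 7L) < abs(best$end + 7L))) {
      best <- cand
    }
  }
  best
}

#' Scan promoter windows and classify each promoter
#'
#' Applies [find_bipartite()], [classify_promoter()] and [match_sigA()]
#' to every window; windows without a stress match but with a sigmaA-like
#' -10 element are classed `sigA_like`.
#'
#' @param windows Data.frame from [extract_window()].
#' @param overrides Optional override table (see [classify_promoter()]).
#' @param gtt_start_range,spacer_range,max_core_mismatches Passed to
#'   [find_bipartite()].
#' @param sigA_params List of arguments passed to [match_sigA()].
#' @return Data.frame with one row per window: the match columns,
#'   `sigA_hexamer`, `sigA_mismatches`, `class`, `override_applied`.
#' @export
scan_promoters <- function(windows, overrides = NULL,
                           gtt_start_range = c(-13L, -7L),
                           spacer_range = c(18L, 19L),
                           max_core_mismatches = 1L,
                           sigA_params = list()) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    m <- find_bipartite(windows$sequence[i], gtt_start_range, spacer_range,
                        max_core_mismatches)
    cl <- classify_promoter(m, windows$gene_id[i], overrides)
    sa <- do.call(match_sigA, c(list(windows$sequence[i]), sigA_params))
    out <- if (is.null(m)) empty_match() else m
    out$sigA_hexamer <- if (is.null(sa)) NA_character_ else sa$hexamer
    out$sigA_mismatches <- if (is.null(sa)) NA_integer_ else sa$mismatches
    out$class <- if (cl$class == "none" && !is.null(sa)) "sigA_like"
                 else cl$class
    out$override_applied <- cl$override_applied
    out
  })
  cbind(windows[, c("gene_id", "contig", "pos", "strand")],
        do.call(rbind, rows))
}

#' Assemble the regulon report from DGE records and promoter calls
#'
#' Partitions upregulated genes into dual sigmaH/sigmaE regulon members
#' (at least one dual promoter), exclusively-sigmaH genes, sigmaA-only
#' genes, and genes without a TSS-anchored promoter (operon members).
#' Distinct genes and promoters are counted separately: a gene may carry
#' two qualifying promoters.
#'
#' @param dge_records Data.frame from [run_dge()] (columns `gene_id`,
#'   `status`).
#' @param promoter_calls Data.frame from [scan_promoters()] (columns
#'   `gene_id`, `class`).
#' @return A list: `n_up`, `n_down`, `regulon_genes` (character vector),
#'   `n_regulon_genes`, `n_dual_promoters`, `sigH_only_genes`,
#'   `sigA_only_genes`, `no_promoter_genes`, and `promoter_class_tally`.
#' @export
assemble_regulon <- function(dge_records, promoter_calls) {
  up <- dge_records$gene_id[dge_records$status == "up"]
  down <- dge_records$gene_id[dge_records$status == "down"]
  pc <- promoter_calls[!is.na(promoter_calls$gene_id), , drop = FALSE]
  class_of <- function(gid, cls) {
    unique(pc$gene_id[pc$class == cls & pc$gene_id %in% gid])
  }
  dual <- class_of(up, "dual_sigHE")
  sigh <- setdiff(class_of(up, "sigH_only"), dual)
  siga <- setdiff(class_of(up, "sigA_like"), c(dual, sigh))
  none <- setdiff(up, c(dual, sigh, siga))
  tally <- table(factor(pc$class,
                        levels = c("dual_sigHE", "sigH_only", "sigA_like",
                                   "none")))
  list(
    n_up = length(up), n_down = length(down),
    regulon_genes = sort(dual), n_regulon_genes = length(dual),
    n_dual_promoters = sum(pc$class == "dual_sigHE" & pc$gene_id %in% up),
    sigH_only_genes = sort(sigh),
    sigA_only_genes = sort(siga),
    no_promoter_genes = sort(none),
    promoter_class_tally = tally
  )
}
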