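# Position-frequency matrices and case-encoded consensus strings for
# promoter element sets, aligned either at the GTT trimer (full windows)
# or as stacked -35 / -10 element blocks (printed motif records, whose
# unspecified spacer positions contribute nothing).

zero_counts <- function(ncol) {
  matrix(0L, 4L, ncol, dimnames = list(DNA_BASES, NULL))
}

new_position_matrix <- function(labels, counts, n_sequences,
                                blocks = NULL) {
  stopifnot(nrow(counts) == 4L, ncol(counts) == length(labels))
  rownames(counts) <- DNA_BASES
  structure(list(columns = labels, counts = counts,
                 coverage = colSums(counts),
                 n_sequences = n_sequences, blocks = blocks),
            class = "position_matrix")
}

add_letters <- function(counts, col_idx, letters) {
  for (k in seq_along(col_idx)) {
    b <- letters[k]
    if (b %in% DNA_BASES) {
      counts[b, col_idx[k]] <- counts[b, col_idx[k]] + 1L
    }
  }
  counts
}

#' Align promoter sequences or motif records at the GTT trimer
#'
#' Columns are indexed relative to the G of GTT (column 0 is the G).
#' Full windows contribute every position they cover; motif records
#' contribute only their specified element positions (pentamer, the -30
#' base, the -11 base for 4-letter tails, and GTT), so spacer columns
#' have partial or zero coverage.
#'
#' Input modes: a data.frame with columns `sequence` and `gtt_start`
#' (promoter-local position of the G, as from [find_bipartite()] joined
#' to its window), or a data.frame of motif matches with columns
#' `pentamer`, `base_minus30`, `base_minus11`, `spacer` (as from
#' [match_from_record()]).
#'
#' @param x Input data.frame (see above).
#' @return A `position_matrix` with GTT-relative column labels.
#' @export
anchor_align <- function(x) {
  if ("sequence" %in% names(x)) {
    if (anyNA(x$gtt_start)) {
      bad <- which(is.na(x$gtt_start))[1L]
      stop("input row ", bad, " has no located GTT")
    }
    # GTT-relative offset of window position j (1..W): (j - W - 1) - gtt
    offsets <- lapply(seq_len(nrow(x)), function(i) {
      W <- nchar(x$sequence[i])
      seq_len(W) - W - 1L - x$gtt_start[i]
    })
    rng <- range(unlist(offsets))
    labels <- seq(rng[1L], rng[2L])
    counts <- zero_counts(length(labels))
    for (i in seq_len(nrow(x))) {
      letters <- strsplit(toupper(x$sequence[i]), "")[[1L]]
      counts <- add_letters(counts, match(offsets[[i]], labels), letters)
    }
    return(new_position_matrix(labels, counts, nrow(x)))
  }
  if (anyNA(x$spacer)) stop("motif record without a spacer")
  # pentamer occupies offsets -(spacer+5) .. -(spacer+1); -30 base is the
  # first spacer position; -11 base (if known) the last; GTT is 0..2
  min_off <- -(max(x$spacer) + 5L)
  labels <- seq(min_off, 2L)
  counts <- zero_counts(length(labels))
  for (i in seq_len(nrow(x))) {
    s <- x$spacer[i]
    pent <- strsplit(x$pentamer[i], "")[[1L]]
    counts <- add_letters(counts, match(seq(-(s + 5L), -(s + 1L)), labels),
                          pent)
    counts <- add_letters(counts, match(-s, labels), x$base_minus30[i])
    if (!is.na(x$base_minus11[i])) {
      counts <- add_letters(counts, match(-1L, labels), x$base_minus11[i])
    }
    counts <- add_letters(counts, match(0:2, labels), c("G", "T", "T"))
  }
  new_position_matrix(labels, counts, nrow(x))
}

#' Stack -35 and -10 elements directly (element-anchored alignment)
#'
#' Unequal spacers smear the -35 columns of a GTT-anchored alignment;
#' this mode instead stacks the pentamer positions 1-5 directly and,
#' separately, the (-11, GTT) block, with per-column coverage
#' bookkeeping. The -11 column only gains coverage from records whose
#' tail specifies that base.
#'
#' @param matches Data.frame of motif matches (columns `pentamer`,
#'   `base_minus11`).
#' @return A `position_matrix` with columns `m35_1`..`m35_5` (promoter
#'   positions -35..-31 in the canonical placement), `m10_m11`, `m10_G`,
#'   `m10_T1`, `m10_T2`, and a `blocks` attribute separating the -35 and
#'   -10 blocks.
#' @export
element_align <- function(matches) {
  labels <- c(paste0("m35_", 1:5), "m10_m11", "m10_G", "m10_T1", "m10_T2")
  blocks <- c(rep("m35", 5L), rep("m10", 4L))
  counts <- zero_counts(length(labels))
  for (i in seq_len(nrow(matches))) {
    pent <- strsplit(matches$pentamer[i], "")[[1L]]
    counts <- add_letters(counts, 1:5, pent)
    if (!is.na(matches$base_minus11[i])) {
      counts <- add_letters(counts, 6L, matches$base_minus11[i])
    }
    counts <- add_letters(counts, 7:9, c("G", "T", "T"))
  }
  new_position_matrix(labels, counts, nrow(matches), blocks = blocks)
}

#' Per-column information content of a position matrix
#'
#' IC_j = 2 + sum_b f_jb log2 f_jb over bases with positive frequency,
#' in bits (0 for a uniform column, 2 for a perfectly conserved one).
#' The optional small-sample correction subtracts 3 / (2 ln(2) n_j)
#' where n_j is the column's coverage.
#'
#' @param pm A `position_matrix`.
#' @param small_sample_correction Apply the correction (default FALSE).
#' @return Named numeric vector of bits; NA for zero-coverage columns.
#' @export
information_content <- function(pm, small_sample_correction = FALSE) {
  ic <- vapply(seq_along(pm$columns), function(j) {
    n <- pm$coverage[j]
    if (n == 0L) return(NA_real_)
    f <- pm$counts[, j] / n
    f <- f[f > 0]
    val <- 2 + sum(f * log2(f))
    if (small_sample_correction) val <- val - 3 / (2 * log(2) * n)
    val
  }, numeric(1L))
  stats::setNames(ic, pm$columns)
}

#' Case-encoded consensus string from a position matrix
#'
#' Per column the most frequent base is reported: upper case if its
#' frequency is at least `upper`, lower case if in `[lower, upper)`, and
#' `n` otherwise or on a tie for the maximum. Zero-coverage columns are
#' dropped from the consensus string (they are retained, as NA, in the
#' per-column table).
#'
#' @param pm A `position_matrix`.
#' @param upper Upper-case frequency threshold (default 0.9).
#' @param lower Lower-case frequency threshold (default 0.4).
#' @return A list with `consensus` (string), `per_column` (data.frame
#'   with column label, coverage, top base, top frequency, letter, IC in
#'   bits) and `thresholds`.
#' @export
consensus_string <- function(pm, upper = 0.9, lower = 0.4) {
  stopifnot(lower > 0, lower < upper, upper <= 1)
  ic <- information_content(pm)
  letters <- character(length(pm$columns))
  top_base <- rep(NA_character_, length(pm$columns))
  top_freq <- rep(NA_real_, length(pm$columns))
  for (j in seq_along(pm$columns)) {
    n <- pm$coverage[j]
    if (n == 0L) {
      letters[j] <- NA_character_
      next
    }
    f <- pm$counts[, j] / n
    fm <- max(f)
    tied <- sum(f == fm) > 1L
    b <- DNA_BASES[which.max(f)]
    top_base[j] <- b
    top_freq[j] <- fm
    letters[j] <- if (tied || fm < lower) "n"
                  else if (fm >= upper) b
                  else tolower(b)
  }
  per_column <- data.frame(column = pm$columns, coverage = pm$coverage,
                           base = top_base, frequency = top_freq,
                           letter = letters, ic_bits = unname(ic),
                           stringsAsFactors = FALSE)
  list(consensus = paste(letters[!is.na(letters)], collapse = ""),
       per_column = per_column,
       thresholds = c(upper = upper, lower = lower))
}

#' Element-anchored consensus of a motif-match set
#'
#' Convenience wrapper: [element_align()] then [consensus_string()],
#' returning the -35 and -10 consensus strings separately.
#'
#' @inheritParams element_align
#' @inheritParams consensus_string
#' @return A list with `m35`, `m10` (strings), and the full
#'   [consensus_string()] result as `detail`.
#' @export
element_consensus <- function(matches, upper = 0.9, lower = 0.4) {
  pm <- element_align(matches)
  cs <- consensus_string(pm, upper = upper, lower = lower)
  keep <- !is.na(cs$per_column$letter)
  blk <- pm$blocks[keep]
  letters <- cs$per_column$letter[keep]
  list(m35 = paste(letters[blk == "m35"], collapse = ""),
       m10 = paste(letters[blk == "m10"], collapse = ""),
       detail = cs)
}
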