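# TSS calling from stranded 5'-read-start profiles: a position qualifies
# as +1 if its read-start count is at least min_starts and at least
# ratio_threshold times the count at position -1 (the position immediately
# 5' of +1 in transcription orientation; a zero there passes the ratio
# clause). The absolute floor plus the dedup window stand in for the
# manual curation of false positives in the original protocol.

#' Call transcription start sites from a read-start profile
#'
#' @param profile A [stranded_profile()].
#' @param ratio_threshold Required ratio of read starts at +1 over -1
#'   (default 10).
#' @param min_starts Absolute floor on read starts at +1 (default 10).
#' @return Data.frame of calls: `contig`, `pos`, `strand`, `starts_plus1`,
#'   `starts_minus1`, `ratio` (`starts_plus1 / max(starts_minus1, 1)`).
#' @export
call_tss <- function(profile, ratio_threshold = 10, min_starts = 10) {
  stopifnot(inherits(profile, "stranded_profile"),
            ratio_threshold > 0, min_starts > 0)
  L <- profile$length
  one_strand <- function(counts, strand) {
    # -1 is pos - 1 on the plus strand, pos + 1 on the minus strand
    minus1 <- if (strand == "+") c(0L, counts[-L]) else c(counts[-1L], 0L)
    hit <- counts >= min_starts & counts >= ratio_threshold * minus1
    pos <- which(hit)
    data.frame(contig = rep(profile$contig, length(pos)), pos = pos,
               strand = rep(strand, length(pos)),
               starts_plus1 = counts[pos], starts_minus1 = minus1[pos],
               ratio = counts[pos] / pmax(minus1[pos], 1L),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(profile$fwd, "+"), one_strand(profile$rev, "-"))
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Collapse clustered TSS calls
#'
#' Within any run of same-strand calls whose successive positions are
#' closer than `window` nt, only the call with the highest read-start
#' count is kept; ties are broken toward the most 5' position (smallest
#' coordinate on the plus strand, largest on the minus strand).
#'
#' @param calls Data.frame from [call_tss()].
#' @param window Minimum spacing in nt (default 3).
#' @return Filtered data.frame of calls.
#' @export
deduplicate_tss <- function(calls, window = 3L) {
  stopifnot(window >= 1L)
  if (nrow(calls) == 0L) return(calls)
  keep <- logical(nrow(calls))
  for (key in split(seq_len(nrow(calls)),
                    paste(calls$contig, calls$strand))) {
    idx <- key[order(calls$pos[key])]
    pos <- calls$pos[idx]
    cluster <- cumsum(c(1L, as.integer(diff(pos) >= window)))
    strand <- calls$strand[idx[1L]]
    for (cl in split(idx, cluster)) {
      counts <- calls$starts_plus1[cl]
      best <- cl[counts == max(counts)]
      keep[if (strand == "+") best[1L] else best[length(best)]] <- TRUE
    }
  }
  calls[keep, , drop = FALSE]
}

#' Associate TSS calls with downstream genes
#'
#' Each call is assigned the nearest same-strand, same-contig gene whose
#' start codon lies 0 to `max_distance` nt downstream of +1 (distance 0 =
#' leaderless transcript). Calls with no gene in range keep `gene_id` NA.
#' One gene may receive several TSSs.
#'
#' @param calls Data.frame from [call_tss()] / [deduplicate_tss()].
#' @param genes Data.frame of gene records (see [read_gff3()]).
#' @param max_distance Maximum TSS-to-start-codon distance in nt
#'   (default 500).
#' @return `calls` with `gene_id` and `distance_to_start` columns added.
#' @export
associate_tss <- function(calls, genes, max_distance = 500L) {
  stopifnot(max_distance >= 0L)
  calls$gene_id <- NA_character_
  calls$distance_to_start <- NA_integer_
  for (i in seq_len(nrow(calls))) {
    same <- genes$strand == calls$strand[i] &
      genes$contig == calls$contig[i]
    if (!any(same)) next
    d <- if (calls$strand[i] == "+") {
      genes$start_codon_pos - calls$pos[i]
    } else {
      calls$pos[i] - genes$start_codon_pos
    }
    ok <- same & d >= 0L & d <= max_distance
    if (any(ok)) {
      j <- which(ok)[which.min(d[ok])]
      calls$gene_id[i] <- genes$gene_id[j]
      calls$distance_to_start[i] <- d[j]
    }
  }
  calls
}

#' Run the full TSS-calling stage
#'
#' Calls, deduplicates and gene-associates TSSs for one or several
#' stranded profiles.
#'
#' @param profiles A [stranded_profile()] or a named list of them.
#' @param genes Data.frame of gene records.
#' @inheritParams call_tss
#' @inheritParams deduplicate_tss
#' @inheritParams associate_tss
#' @return Data.frame of associated TSS calls.
#' @export
run_tss_stage <- function(profiles, genes, ratio_threshold = 10,
                          min_starts = 10, window = 3L,
                          max_distance = 500L) {
  if (inherits(profiles, "stranded_profile")) profiles <- list(profiles)
  calls <- do.call(rbind, lapply(profiles, function(p) {
    deduplicate_tss(call_tss(p, ratio_threshold, min_starts), window)
  }))
  rownames(calls) <- NULL
  associate_tss(calls, genes, max_distance)
}
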