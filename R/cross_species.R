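# Cross-species survey of stress promoters in user-supplied upstream
# regions of orthologous genes: exact-pentamer bipartite scanning
# (sigmaE-type GGAAC with spacer 18-20; sigmaH-type GGAAT with spacer
# 18) and presence/absence summaries.

#' Scan an upstream region for stress-promoter motifs
#'
#' Finds every placement of an exact pentamer followed, after a spacer in
#' the allowed range, by an exact GTT trimer. Only the given (coding)
#' strand is scanned; offsets are 1-based from the sequence 5' end.
#'
#' @param seq Upstream-region DNA string in gene orientation.
#' @param mode `"sigE"` (pentamer GGAAC, spacer 18-20) or `"sigH"`
#'   (pentamer GGAAT, spacer 18).
#' @param spacer_range Override the mode's default spacer range.
#' @param pentamer Override the mode's pentamer.
#' @return Data.frame of hits: `pentamer_start`, `spacer`, `gtt_start`,
#'   `pentamer`, `element` (the matched subsequence); zero rows if none.
#' @export
scan_upstream <- function(seq, mode = c("sigE", "sigH"),
                          spacer_range = NULL, pentamer = NULL) {
  mode <- match.arg(mode)
  if (is.null(pentamer)) pentamer <- if (mode == "sigE") "GGAAC" else "GGAAT"
  if (is.null(spacer_range)) {
    spacer_range <- if (mode == "sigE") c(18L, 20L) else c(18L, 18L)
  }
  stopifnot(is.character(seq), length(seq) == 1L,
            spacer_range[1L] <= spacer_range[2L])
  out <- data.frame(pentamer_start = integer(0), spacer = integer(0),
                    gtt_start = integer(0), pentamer = character(0),
                    element = character(0), stringsAsFactors = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L) return(out)
  pent_len <- nchar(pentamer)
  if (L < pent_len + spacer_range[1L] + 3L) return(out)
  # every start position is considered, including overlapping ones
  cand <- seq_len(L - pent_len + 1L)
  starts <- cand[substring(seq, cand, cand + pent_len - 1L) == pentamer]
  if (!length(starts)) return(out)
  rows <- list()
  for (p in starts) {
    for (s in seq(spacer_range[1L], spacer_range[2L])) {
      g <- p + pent_len + s
      if (g + 2L > L) next
      if (substr(seq, g, g + 2L) == "GTT") {
        rows[[length(rows) + 1L]] <- data.frame(
          pentamer_start = p, spacer = s, gtt_start = g,
          pentamer = pentamer,
          element = substr(seq, p, g + 2L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) rbind(out, do.call(rbind, rows)) else out
}

#' Scan a set of species/gene upstream regions
#'
#' @param upstream Named character vector of upstream sequences; names of
#'   the form `species|gene_label`, or supply `species` and `gene_label`
#'   explicitly.
#' @param species,gene_label Optional character vectors parallel to
#'   `upstream`.
#' @param mode,spacer_range,pentamer Passed to [scan_upstream()].
#' @return Data.frame of scan records: `species`, `gene_label`,
#'   `sequence_length`, `n_hits`, `present`.
#' @export
scan_species_set <- function(upstream, species = NULL, gene_label = NULL,
                             mode = "sigE", spacer_range = NULL,
                             pentamer = NULL) {
  if (is.null(species) || is.null(gene_label)) {
    parts <- strsplit(names(upstream), "|", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("sequence names must be of the form 'species|gene_label'")
    }
    species <- vapply(parts, `[[`, "", 1L)
    gene_label <- vapply(parts, `[[`, "", 2L)
  }
  n_hits <- vapply(upstream, function(s) {
    nrow(scan_upstream(s, mode = mode, spacer_range = spacer_range,
                       pentamer = pentamer))
  }, integer(1L))
  data.frame(species = species, gene_label = gene_label,
             sequence_length = nchar(upstream), n_hits = unname(n_hits),
             present = unname(n_hits) > 0L, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Summarize stress-promoter presence across species
#'
#' @param records Data.frame from [scan_species_set()] (columns
#'   `species`, `gene_label`, `present`).
#' @return A list with `counts` (named integer vector: species with a
#'   hit per gene label) and `presence` (species x gene logical matrix).
#' @export
summarize_presence <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no scan records supplied")
  }
  key <- paste(records$species, records$gene_label)
  if (anyDuplicated(key)) {
    stop("duplicate (species, gene) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  presence <- with(records, tapply(present, list(species, gene_label),
                                   isTRUE))
  presence[is.na(presence)] <- FALSE
  counts <- colSums(presence)
  list(counts = stats::setNames(as.integer(counts), colnames(presence)),
       presence = presence)
}
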