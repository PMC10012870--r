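# All internal coordinates are 1-based inclusive. bedGraph and BED use
# 0-based half-open intervals at the file boundary; conversion happens here
# and nowhere else. In promoter-local numbering the TSS is +1, the base
# immediately 5' of it is -1, and there is no position 0.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, upper case.
#' @export
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Parse a promoter motif in HEXAMER-Nk-TAIL notation
#'
#' Stress-promoter motifs are printed as e.g. `"GGAACT-N16-CGTT"`: a -35
#' hexamer, a run of k unspecified spacer bases, and a -10 tail that is
#' either the GTT trimer itself or one known base followed by GTT (e.g.
#' `CGTT`). En dashes, em dashes and subscript underscores are normalized
#' before parsing.
#'
#' @param text Motif string such as `"GGAACT-N16-CGTT"`.
#' @param gene_id,distance,source Optional metadata carried on the record.
#' @return A list with fields `gene_id`, `hexamer`, `n_count`, `tail`,
#'   `distance`, `source`.
#' @examples
#' parse_motif_notation("GGAACT-N16-CGTT", gene_id = "cg1272", distance = 65)
#' @export
parse_motif_notation <- function(text, gene_id = NA_character_,
                                 distance = NA_integer_,
                                 source = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  norm <- gsub("[–—−]", "-", text)
  norm <- gsub("[_[:space:]]", "", norm)
  norm <- toupper(norm)
  parts <- strsplit(norm, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop("malformed motif notation '", text,
         "': expected HEXAMER-Nk-TAIL with two '-' separators")
  }
  hexamer <- parts[1L]
  if (!grepl("^[ACGT]{6}$", hexamer)) {
    stop("malformed motif notation '", text, "': token '", parts[1L],
         "' is not a 6-letter DNA hexamer")
  }
  if (!grepl("^N[0-9]+$", parts[2L])) {
    stop("malformed motif notation '", text, "': token '", parts[2L],
         "' is not a spacer of the form N<k>")
  }
  n_count <- as.integer(sub("^N", "", parts[2L]))
  tail <- parts[3L]
  if (!grepl("^[ACGT]{3,4}$", tail)) {
    stop("malformed motif notation '", text, "': token '", parts[3L],
         "' is not a 3- or 4-letter DNA tail")
  }
  if (substr(tail, nchar(tail) - 2L, nchar(tail)) != "GTT") {
    stop("invalid motif '", text, "': tail '", tail,
         "' does not end in the GTT trimer")
  }
  list(gene_id = as.character(gene_id), hexamer = hexamer,
       n_count = n_count, tail = tail,
       distance = if (is.na(distance)) NA_integer_ else as.integer(distance),
       source = as.character(source))
}

#' Render a motif record back to HEXAMER-Nk-TAIL notation
#'
#' @param record A list as returned by [parse_motif_notation()].
#' @return Single motif string, the inverse of [parse_motif_notation()].
#' @export
render_motif_notation <- function(record) {
  paste0(record$hexamer, "-N", record$n_count, "-", record$tail)
}

#' Read a motif table (TSV) in the printed notation
#'
#' Expected columns: `gene_id`, `motif`, `distance`, `source`; an optional
#' `name` column carries gene names. Each `motif` entry is parsed with
#' [parse_motif_notation()].
#'
#' @param path Path to a tab-separated motif table.
#' @return A data.frame with columns `gene_id`, `name`, `motif`, `hexamer`,
#'   `n_count`, `tail`, `distance`, `source`.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "motif", "distance", "source")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("motif table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parsed <- lapply(seq_len(nrow(tab)), function(i) {
    parse_motif_notation(tab$motif[i], gene_id = tab$gene_id[i],
                         distance = tab$distance[i], source = tab$source[i])
  })
  data.frame(
    gene_id = tab$gene_id,
    name = if ("name" %in% names(tab)) tab$name else NA_character_,
    motif = tab$motif,
    hexamer = vapply(parsed, `[[`, "", "hexamer"),
    n_count = vapply(parsed, `[[`, 0L, "n_count"),
    tail = vapply(parsed, `[[`, "", "tail"),
    distance = tab$distance,
    source = tab$source,
    stringsAsFactors = FALSE
  )
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are folded to upper case and U is converted to T. Letters
#' outside A/C/G/T/N are rejected; duplicate record names are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record (name = first
#'   whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA letters in FASTA record(s): ",
         paste(nm[bad], collapse = ", "))
  }
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read gene records from a GFF3 annotation
#'
#' GFF3 coordinates are 1-based inclusive, matching the internal
#' convention. The start-codon coordinate is the `start` field on the plus
#' strand and the `end` field on the minus strand.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type(s) to keep (default `"gene"`; use
#'   `"CDS"` for annotations without gene features).
#' @return A data.frame of gene records: `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `start_codon_pos`, `name`, `product`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  gff <- gff[gff$type %in% feature_type, , drop = FALSE]
  if (nrow(gff) == 0L) {
    stop("no '", paste(feature_type, collapse = "/"),
         "' features found in ", path)
  }
  pick <- function(col) {
    if (col %in% names(gff)) as.character(gff[[col]]) else
      rep(NA_character_, nrow(gff))
  }
  gene_id <- pick("ID")
  for (alt in c("locus_tag", "gene_id", "Name")) {
    fallback <- pick(alt)
    gene_id <- ifelse(is.na(gene_id), fallback, gene_id)
  }
  if (anyNA(gene_id)) stop("GFF3 feature(s) without an identifier in ", path)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  strand <- as.character(gff$strand)
  if (!all(strand %in% c("+", "-"))) {
    stop("unstranded feature(s) in ", path)
  }
  data.frame(
    gene_id = gene_id,
    contig = as.character(gff$seqid),
    strand = strand,
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    start_codon_pos = ifelse(strand == "+", as.integer(gff$start),
                             as.integer(gff$end)),
    name = pick("Name"),
    product = pick("product"),
    stringsAsFactors = FALSE
  )
}

write_gff3_genes <- function(genes, path) {
  # generator output only; full GFF3 round-trip writing is out of scope
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(is.na(genes$name) | genes$name == "", "",
                         paste0(";Name=", genes$name)))
  lines <- paste(genes$contig, "sigregulon", "gene", genes$start, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct an empty stranded read-start profile
#'
#' A stranded profile stores per-position counts of 5' read starts on each
#' strand of one contig, as dense integer vectors indexed by 1-based
#' position.
#'
#' @param contig Contig name.
#' @param length Contig length (positive integer).
#' @param fwd,rev Optional integer count vectors of length `length`.
#' @return An object of class `stranded_profile`.
#' @export
stranded_profile <- function(contig, length, fwd = NULL, rev = NULL) {
  stopifnot(is.character(contig), length >= 1L)
  length <- as.integer(length)
  if (is.null(fwd)) fwd <- integer(length)
  if (is.null(rev)) rev <- integer(length)
  stopifnot(base::length(fwd) == length, base::length(rev) == length,
            all(fwd >= 0L), all(rev >= 0L))
  structure(list(contig = contig, length = length,
                 fwd = as.integer(fwd), rev = as.integer(rev)),
            class = "stranded_profile")
}

parse_bedgraph_counts <- function(path, contig_lengths) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("contig", "start", "end", "count"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"),
                           comment.char = "#")
  tab <- tab[tab$count != 0, , drop = FALSE]
  out <- lapply(names(contig_lengths), function(ctg) integer(contig_lengths[[ctg]]))
  names(out) <- names(contig_lengths)
  for (i in seq_len(nrow(tab))) {
    ctg <- tab$contig[i]
    if (!ctg %in% names(contig_lengths)) {
      stop("bedGraph ", path, " references unknown contig '", ctg, "'")
    }
    # 0-based half-open [start, end) -> 1-based inclusive [start+1, end]
    from <- tab$start[i] + 1L
    to <- tab$end[i]
    if (from < 1L || to > contig_lengths[[ctg]]) {
      stop("bedGraph ", path, " interval ", tab$start[i], "-", tab$end[i],
           " outside contig '", ctg, "' (length ", contig_lengths[[ctg]], ")")
    }
    out[[ctg]][from:to] <- out[[ctg]][from:to] + as.integer(tab$count[i])
  }
  out
}

#' Read a pair of stranded bedGraph read-start files
#'
#' bedGraph intervals are 0-based half-open; a line `c1 99 100 50` sets the
#' internal 1-based position 100 to count 50.
#'
#' @param path_fwd,path_rev bedGraph files for the forward and reverse
#'   strand.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return Named list of [stranded_profile()] objects, one per contig.
#' @export
read_bedgraph_pair <- function(path_fwd, path_rev, contig_lengths) {
  fwd <- parse_bedgraph_counts(path_fwd, contig_lengths)
  rev <- parse_bedgraph_counts(path_rev, contig_lengths)
  profiles <- lapply(names(contig_lengths), function(ctg) {
    stranded_profile(ctg, contig_lengths[[ctg]], fwd = fwd[[ctg]],
                     rev = rev[[ctg]])
  })
  names(profiles) <- names(contig_lengths)
  profiles
}

write_bedgraph_strand <- function(counts_by_contig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(counts_by_contig)) {
    v <- counts_by_contig[[ctg]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (any(keep)) {
      writeLines(paste(ctg, starts[keep] - 1L, ends[keep], r$values[keep]),
                 con)
    }
  }
  invisible(path)
}

#' Write a list of stranded profiles as a bedGraph pair
#'
#' @param profiles Named list of [stranded_profile()] objects.
#' @param path_fwd,path_rev Output paths for the two strands.
#' @return Invisibly, `c(path_fwd, path_rev)`.
#' @export
write_bedgraph_pair <- function(profiles, path_fwd, path_rev) {
  if (inherits(profiles, "stranded_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$contig)
  }
  write_bedgraph_strand(lapply(profiles, `[[`, "fwd"), path_fwd)
  write_bedgraph_strand(lapply(profiles, `[[`, "rev"), path_rev)
  invisible(c(path_fwd, path_rev))
}

#' Write TSS calls as BED6
#'
#' Each call becomes one BED6 line with the score set to the read-start
#' count at +1; BED intervals are 0-based half-open, so an internal
#' position 100 is written as `99 100`.
#'
#' @param calls Data.frame of TSS calls (see [call_tss()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_tss <- function(calls, path) {
  name <- if ("gene_id" %in% names(calls)) {
    ifelse(is.na(calls$gene_id), ".", calls$gene_id)
  } else rep(".", nrow(calls))
  lines <- paste(calls$contig, calls$pos - 1L, calls$pos, name,
                 calls$starts_plus1, calls$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a tab-separated report
#'
#' @param rows Data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-level count matrix (TSV)
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with gene IDs as row names.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1L]]
  m
}

#' Read a sample-to-condition map (TSV with columns sample, condition)
#'
#' @param path Path to the TSV file.
#' @return Data.frame with columns `sample` and `condition`.
#' @export
read_conditions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(tab)))
  tab
}
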