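# File formats: FASTA targets, BED exon annotations, TSV tables; coordinate
# conventions. Reports use 1-based inclusive coordinates; BED I/O is 0-based
# half-open, as the format requires.

#' Read a (possibly RNA-alphabet) FASTA file of target sequences
#'
#' Accepts wrapped or unwrapped records, case-insensitive; U is normalized to
#' T. Record identifiers are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase T-alphabet sequences.
#' @export
read_targets_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- gsub("U", "T", toupper(as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA record(s) with invalid characters: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_targets_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file (0-based half-open intervals)
#'
#' @param path BED3/BED6 file (tab-separated, no header).
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`. `start`/`end` stay 0-based half-open.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (ncol(df) < 3 || ncol(df) > 6) {
    stop("BED file must have 3-6 columns, found ", ncol(df), call. = FALSE)
  }
  names(df) <- cols[seq_len(ncol(df))]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) {
    stop("BED intervals must satisfy start < end", call. = FALSE)
  }
  df
}

#' Write a BED data.frame (byte-identical round trip with [read_bed()])
#' @param df data.frame as returned by [read_bed()].
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert between BED (0-based half-open) and report (1-based inclusive)
#' coordinates
#'
#' @param start,end Interval bounds in the source convention.
#' @return Two-column data.frame in the other convention.
#' @export
bed_to_report_coords <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' @rdname bed_to_report_coords
#' @export
report_to_bed_coords <- function(start, end) {
  data.frame(start = start - 1L, end = end)
}

#' Exonic/intronic context of a candidate site
#'
#' A site is `EXONIC` when its full span lies within one exon, `INTRONIC` when
#' it does not touch any exon, and `EXON_BOUNDARY` otherwise. Exon intervals
#' are 0-based half-open (BED convention); the site span is 1-based inclusive
#' (report convention).
#'
#' @param site_start,site_end Site span, 1-based inclusive.
#' @param exons data.frame with 0-based half-open `start`, `end` columns (as
#'   from [read_bed()]), intervals sorted and non-overlapping.
#' @param target_length Optional sequence length for bounds checking.
#' @return `"EXONIC"`, `"INTRONIC"` or `"EXON_BOUNDARY"`.
#' @export
annotate_site_context <- function(site_start, site_end, exons,
                                  target_length = NULL) {
  if (site_start < 1 || site_end < site_start) {
    stop("invalid site span [", site_start, ", ", site_end, "]",
         call. = FALSE)
  }
  if (!is.null(target_length) && site_end > target_length) {
    stop("site [", site_start, ", ", site_end,
         "] extends beyond the target (length ", target_length, ")",
         call. = FALSE)
  }
  if (nrow(exons) == 0) return("INTRONIC")
  exon_ranges <- IRanges::IRanges(start = exons$start + 1L, end = exons$end)
  site <- IRanges::IRanges(start = site_start, end = site_end)
  within <- IRanges::countOverlaps(site, exon_ranges, type = "within") > 0
  if (within) return("EXONIC")
  touches <- IRanges::countOverlaps(site, exon_ranges) > 0
  if (touches) "EXON_BOUNDARY" else "INTRONIC"
}

# Expand a compact chemistry spec ("MOE", "MOEx18", "OMEx6,MOEx12", or a
# comma list of per-position tags) to one tag per residue.
.parse_chemistry <- function(spec, len) {
  spec <- gsub("\\s", "", spec)
  parts <- strsplit(spec, ",")[[1]]
  tags <- unlist(lapply(parts, function(p) {
    if (grepl("x", p, ignore.case = TRUE)) {
      bits <- strsplit(p, "[xX]")[[1]]
      rep(toupper(bits[1]), as.integer(bits[2]))
    } else {
      toupper(p)
    }
  }))
  if (length(tags) == 1) tags <- rep(tags, len)
  if (length(tags) != len) {
    stop("chemistry spec '", spec, "' expands to ", length(tags),
         " tags for a ", len, "-mer", call. = FALSE)
  }
  tags
}

#' Read an ASO definition table
#'
#' TSV with header columns `name`, `sequence`, `chemistry`, `backbone`.
#' The chemistry column accepts a single tag (`MOE`), a run-length form
#' (`OMEx6,MOEx12`) or a full comma-separated per-position list.
#'
#' @param path TSV file.
#' @return Named list of `aso` objects.
#' @export
read_aso_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("name", "sequence", "chemistry", "backbone")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("ASO table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    tokens <- tokenize_sequence(df$sequence[i])
    aso_definition(df$name[i], df$sequence[i],
                   .parse_chemistry(df$chemistry[i], length(tokens)),
                   df$backbone[i])
  })
  names(out) <- df$name
  out
}

#' Read a long-format splicing event table
#' @param path TSV with header `event_id`, `gene`, `group`, `sample`, `ijc`,
#'   `sjc` and optional `len_inc`, `len_skip`.
#' @return data.frame.
#' @export
read_event_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a scan hits table as TSV
#' @param hits List of `duplex_alignment`s or a [hits_table()] data.frame.
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- if (is.data.frame(hits)) hits else hits_table(hits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
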