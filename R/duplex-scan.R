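# Windowed scanning of an ASO across a target sequence, and a fast gapless
# mismatch-only mode for large screens.

# Coerce x into list(id =, seq =). Accepts a plain string, a named character
# vector of length 1, or a list with id/seq.
.as_target <- function(x, default_id = "target") {
  if (is.list(x) && !is.null(x$seq)) {
    return(list(id = x$id %||% default_id, seq = as.character(x$seq)))
  }
  if (is.character(x) && length(x) == 1) {
    id <- if (!is.null(names(x))) names(x) else default_id
    return(list(id = id, seq = unname(x)))
  }
  stop("target must be a sequence string (optionally named) or list(id, seq)",
       call. = FALSE)
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Do two 1-based inclusive spans overlap by >= 50% of the shorter span?
.spans_overlap <- function(a, b) {
  ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  if (ov <= 0) return(FALSE)
  shorter <- min(a[2] - a[1] + 1, b[2] - b[1] + 1)
  ov >= 0.5 * shorter
}

#' Scan a target sequence for candidate annealing sites of an ASO
#'
#' Slides windows across the target, aligns the ASO in each window with
#' [align_duplex()], merges overlapping hits (two hits overlap when their
#' target spans share at least half of the shorter span; the better-scoring one
#' is kept) and returns hits with `score >= min_score` sorted by score
#' descending. By default only the supplied (sense pre-mRNA) strand is
#' scanned; `both_strands = TRUE` also scans the reverse complement and
#' reports such hits with `strand = "-"` and spans in supplied-strand
#' coordinates.
#'
#' @param aso An `aso` object.
#' @param target Sequence record: a string, a named character vector of length
#'   one, or `list(id =, seq =)`.
#' @param params A `scan_params` object.
#' @param both_strands Also scan the reverse complement.
#' @return List of `duplex_alignment` objects sorted by score descending.
#'   Convert with [hits_table()] for a tabular view.
#' @export
scan_sequence <- function(aso, target, params = scan_params(),
                          both_strands = FALSE) {
  stopifnot(inherits(aso, "aso"))
  tgt <- .as_target(target)
  if (nchar(tgt$seq) == 0) stop("empty target sequence", call. = FALSE)

  scan_one_strand <- function(seq, strand) {
    L <- nchar(seq)
    la <- aso_length(aso)
    B <- params$max_bulged_nt
    w <- la + B
    if (L < la - B) return(list())
    if (L <= w) {
      offsets <- 1L
      w <- L
    } else {
      offsets <- seq.int(1L, L - w + 1L, by = params$window_step)
      if (offsets[length(offsets)] != L - w + 1L) {
        offsets <- c(offsets, L - w + 1L)
      }
    }
    hits <- list()
    for (off in offsets) {
      win <- substr(seq, off, off + w - 1L)
      al <- align_duplex(aso, win, params, target_id = tgt$id)
      al$columns$target_pos <- al$columns$target_pos + off - 1L
      al$target_span <- al$target_span + off - 1L
      al$strand <- strand
      attr(al, "target_chars") <- strsplit(gsub("U", "T", toupper(seq)),
                                           "")[[1]]
      feats <- feature_summary(al)
      if (al$score >= params$min_score &&
          feats$n_mismatch <= params$max_mismatches) {
        hits[[length(hits) + 1]] <- al
      }
    }
    hits
  }

  hits <- scan_one_strand(tgt$seq, "+")
  if (both_strands) {
    rc <- .revcomp_chr(gsub("U", "T", toupper(tgt$seq)))
    L <- nchar(rc)
    minus <- scan_one_strand(rc, "-")
    # report minus-strand spans in supplied-strand coordinates
    minus <- lapply(minus, function(al) {
      sp <- al$target_span
      al$target_span <- c(start = L - sp[[2]] + 1L, end = L - sp[[1]] + 1L)
      al
    })
    hits <- c(hits, minus)
  }
  if (length(hits) == 0) return(list())

  # order by alignment quality, then merge overlapping hits keeping the best
  feats <- lapply(hits, feature_summary)
  ord <- order(
    -vapply(hits, function(h) h$score, numeric(1)),
    -vapply(feats, function(f) f$n_canonical, numeric(1)),
    vapply(feats, function(f) f$n_bulge, numeric(1)),
    vapply(hits, function(h) h$target_span[[1]], numeric(1))
  )
  kept <- list()
  for (k in ord) {
    h <- hits[[k]]
    clash <- any(vapply(kept, function(g) {
      g$strand == h$strand && .spans_overlap(g$target_span, h$target_span)
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1]] <- h
  }
  kept
}

#' Tabulate scan hits
#'
#' @param hits List of `duplex_alignment` objects (from [scan_sequence()]).
#' @return data.frame with one row per hit: target_id, start, end, strand,
#'   score, pair-class counts, run lengths and the flattened duplex midline.
#' @export
hits_table <- function(hits) {
  if (length(hits) == 0) {
    return(data.frame(target_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), n_canonical = integer(0),
                      n_wobble = integer(0), n_mismatch = integer(0),
                      n_bulge = integer(0), max_noncanonical_run = integer(0),
                      max_canonical_run = integer(0),
                      duplex_string = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(hits, function(h) {
    f <- feature_summary(h)
    data.frame(target_id = h$target_id, start = h$target_span[[1]],
               end = h$target_span[[2]], strand = h$strand, score = h$score,
               n_canonical = f$n_canonical, n_wobble = f$n_wobble,
               n_mismatch = f$n_mismatch, n_bulge = f$n_bulge,
               max_noncanonical_run = f$max_noncanonical_run,
               max_canonical_run = f$max_canonical_run,
               duplex_string = duplex_string(h), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fast gapless mismatch-only scan
#'
#' Screens the target for loci whose Hamming distance to the ASO's perfect
#' annealing site (the reverse complement of the ASO) is at most
#' `max_mismatches`. Wobble pairs count as mismatches under this strict mode;
#' no bulges are considered. This is the screening mode under which allowing
#' more than two mismatches floods a transcriptome-scale search with
#' candidates.
#'
#' @param aso An `aso` object.
#' @param target Sequence record (see [scan_sequence()]).
#' @param max_mismatches Maximum Hamming mismatches (>= 0).
#' @return data.frame with columns `target_id`, `start`, `end` (1-based
#'   inclusive) and `n_mismatch`, ordered by position.
#' @export
scan_mismatch_only <- function(aso, target, max_mismatches = 2) {
  stopifnot(inherits(aso, "aso"), max_mismatches >= 0)
  tgt <- .as_target(target)
  # the perfect annealing site is the reverse complement of the ASO
  site <- antisense_of(paste(aso$pairing, collapse = ""))
  subject <- Biostrings::DNAString(gsub("U", "T", toupper(tgt$seq)))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site), subject,
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE)
  if (length(hits) == 0) {
    return(data.frame(target_id = character(0), start = integer(0),
                      end = integer(0), n_mismatch = integer(0),
                      stringsAsFactors = FALSE))
  }
  nmm <- vapply(seq_along(hits), function(k) {
    sum(strsplit(as.character(hits[[k]]), "")[[1]] !=
          strsplit(site, "")[[1]])
  }, numeric(1))
  data.frame(target_id = tgt$id,
             start = Biostrings::start(hits), end = Biostrings::end(hits),
             n_mismatch = as.integer(nmm), stringsAsFactors = FALSE)
}
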