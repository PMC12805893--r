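# ASO representation: sequence tokens, per-position sugar chemistry, backbone.
# Alphabet: A, C, G, T, U, mC (5-methylcytosine). Internally everything pairs in
# a T-alphabet: U is read as T and mC pairs exactly as C; display keeps the
# original tokens.

SUGAR_MODS <- c("MOE", "OME", "PMO", "DNA")
BACKBONES  <- c("PS", "PMO_NEUTRAL")
PAIR_CLASSES <- c("CANONICAL", "WOBBLE", "MISMATCH", "ASO_BULGE", "TARGET_BULGE")

#' Tokenize a nucleotide sequence that may contain mC
#'
#' Splits a sequence string into single-residue tokens. `mC` (5-methylcytosine,
#' written as the two characters "mC") is kept as one token; all other residues
#' are single characters. Case-insensitive except the `m` marker.
#'
#' @param x A sequence string or an already tokenized character vector.
#' @return Character vector of tokens from \{A, C, G, T, U, mC\}.
#' @keywords internal
tokenize_sequence <- function(x) {
  if (length(x) > 1) {
    tokens <- as.character(x)
  } else {
    chars <- strsplit(x, "")[[1]]
    tokens <- character(0)
    i <- 1
    while (i <= length(chars)) {
      if (chars[i] %in% c("m", "M") && i < length(chars) &&
          toupper(chars[i + 1]) == "C") {
        tokens <- c(tokens, "mC")
        i <- i + 2
      } else {
        tokens <- c(tokens, toupper(chars[i]))
        i <- i + 1
      }
    }
  }
  tokens <- sub("^MC$", "mC", toupper(tokens))
  bad <- setdiff(unique(tokens), c("A", "C", "G", "T", "U", "mC"))
  if (length(bad) > 0) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tokens
}

# Collapse display tokens to the internal T-alphabet pairing base.
.pairing_base <- function(tokens) {
  out <- toupper(tokens)
  out[out == "MC"] <- "C"
  out[out == "U"] <- "T"
  out
}

#' Define an antisense oligonucleotide
#'
#' Creates an ASO object holding the sequence (written 5' to 3'), the sugar
#' modification of every position, and the backbone type. The shortest ASO used
#' in practice is a 10-mer; a floor of 8 residues is enforced to accommodate
#' synthetic test oligos.
#'
#' @param name Identifier.
#' @param sequence Sequence string 5' to 3' over \{A, C, G, T, U, mC\}.
#' @param sugar_mods Per-position sugar chemistry: either a single tag from
#'   `MOE`, `OME`, `PMO`, `DNA` (recycled across all positions) or a vector
#'   with one tag per residue.
#' @param backbone `"PS"` (phosphorothioate) or `"PMO_NEUTRAL"` (morpholino).
#' @return An object of class `aso` with elements `name`, `sequence` (display
#'   tokens), `sugar_mods`, `backbone` and `pairing` (normalized T-alphabet
#'   bases used for duplex formation).
#' @examples
#' nusinersen_like <- aso_definition("F18MOE", "TCACTTTCATAATGCTGG", "MOE", "PS")
#' aso_length(nusinersen_like)
#' @export
aso_definition <- function(name, sequence, sugar_mods = "MOE", backbone = "PS") {
  stopifnot(is.character(name), length(name) == 1)
  tokens <- tokenize_sequence(sequence)
  n <- length(tokens)
  if (n < 8) {
    stop("ASO '", name, "' has ", n, " residues; minimum length is 8",
         call. = FALSE)
  }
  if (length(sugar_mods) == 1) sugar_mods <- rep(sugar_mods, n)
  sugar_mods <- toupper(sugar_mods)
  sugar_mods[sugar_mods == "OMe"] <- "OME"
  if (length(sugar_mods) != n) {
    stop("length(sugar_mods) must equal sequence length (", n, ")",
         call. = FALSE)
  }
  bad <- setdiff(unique(sugar_mods), SUGAR_MODS)
  if (length(bad) > 0) {
    stop("unknown sugar modification tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  backbone <- match.arg(backbone, BACKBONES)
  structure(
    list(name = name, sequence = tokens, sugar_mods = sugar_mods,
         backbone = backbone, pairing = .pairing_base(tokens)),
    class = "aso"
  )
}

#' @export
print.aso <- function(x, ...) {
  mods <- rle(x$sugar_mods)
  mod_str <- paste(sprintf("%sx%d", mods$values, mods$lengths), collapse = ",")
  cat(sprintf("<aso> %s  5'-%s-3'  [%s; %s backbone; %d nt]\n",
              x$name, paste(x$sequence, collapse = ""), mod_str, x$backbone,
              length(x$sequence)))
  invisible(x)
}

#' Number of residues in an ASO
#' @param aso An `aso` object.
#' @return Integer length.
#' @export
aso_length <- function(aso) {
  stopifnot(inherits(aso, "aso"))
  length(aso$sequence)
}

#' Classify one base pair of an ASO:target duplex
#'
#' Watson-Crick complements are `CANONICAL`; G paired with T (or U) on either
#' strand is a `WOBBLE` pair; anything else is a `MISMATCH`. T and U are
#' equivalent and mC pairs exactly as C. Bulge classes are assigned by the
#' aligner, not here.
#'
#' @param aso_base,target_base Single bases (vectorized) from
#'   \{A, C, G, T, U, mC\}.
#' @return Character vector over `CANONICAL`, `WOBBLE`, `MISMATCH`.
#' @examples
#' pair_class("T", "A")  # CANONICAL
#' pair_class("G", "T")  # WOBBLE
#' pair_class("A", "C")  # MISMATCH
#' @export
pair_class <- function(aso_base, target_base) {
  a <- .pairing_base(tokenize_sequence(aso_base))
  t <- .pairing_base(tokenize_sequence(target_base))
  if (length(a) != length(t)) {
    stop("aso_base and target_base must have equal length", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("MISMATCH", length(a))
  out[comp[a] == t] <- "CANONICAL"
  out[(a == "G" & t == "T") | (a == "T" & t == "G")] <- "WOBBLE"
  out
}

#' Reverse complement (the perfect antisense) of a target segment
#'
#' Returns the sequence of the oligonucleotide that pairs every position of
#' `target_segment` canonically, written 5' to 3' (pairing is antiparallel).
#' U and mC are normalized to the T-alphabet; N is preserved.
#'
#' @param target_segment Nucleotide string.
#' @return Character string, the reverse complement in the T-alphabet.
#' @examples
#' antisense_of("CCAGCATTATGAAAGTGA")
#' @export
antisense_of <- function(target_segment) {
  stopifnot(is.character(target_segment), length(target_segment) == 1)
  s <- gsub("U", "T", toupper(gsub("mC", "C", target_segment, fixed = TRUE)))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Derive a truncated ASO covering part of the parent's target footprint
#'
#' The parent ASO's target footprint is the stretch of target residues it
#' sequesters, numbered 1..n from the footprint's 5' end. `anchor = "FIRST"`
#' returns the k-mer covering the first k target residues (which are paired by
#' the 3'-most k residues of the ASO), `"LAST"` the last k, and `"MIDDLE"` a
#' centered window. Sugar chemistry tags are sliced together with the sequence.
#'
#' @param aso Parent `aso`.
#' @param k Length of the derived ASO, `8 <= k <= length(aso)`.
#' @param anchor `"FIRST"`, `"MIDDLE"` or `"LAST"` (which part of the target
#'   footprint the short ASO covers).
#' @param name Name for the derived ASO; default is built from the parent name.
#' @return An `aso` of length `k`. The attribute `footprint_offset` gives the
#'   0-based offset of the derived footprint within the parent's footprint.
#' @examples
#' f18 <- aso_definition("F18MOE", "TCACTTTCATAATGCTGG", "MOE", "PS")
#' derive_short_series(f18, 14, "FIRST")   # pairs target footprint residues 1-14
#' @export
derive_short_series <- function(aso, k, anchor = c("FIRST", "MIDDLE", "LAST"),
                                name = NULL) {
  stopifnot(inherits(aso, "aso"))
  anchor <- match.arg(anchor)
  n <- aso_length(aso)
  if (k < 8 || k > n) {
    stop("k must satisfy 8 <= k <= ", n, " (got ", k, ")", call. = FALSE)
  }
  # target footprint residue i is paired by ASO 5'-position n - i + 1
  offset <- switch(anchor,
    FIRST = 0L,
    MIDDLE = as.integer(floor((n - k) / 2)),
    LAST = as.integer(n - k)
  )
  # footprint residues (offset+1)..(offset+k)  ->  ASO 5'-positions
  aso_idx <- (n - offset - k + 1):(n - offset)
  if (is.null(name)) {
    name <- sprintf("%s_%s%d", aso$name, substr(anchor, 1, 1), k)
  }
  out <- aso_definition(name, aso$sequence[aso_idx], aso$sugar_mods[aso_idx],
                        aso$backbone)
  attr(out, "footprint_offset") <- offset
  out
}
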