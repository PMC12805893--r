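# Semi-global ASO:target duplex alignment tolerating mismatches, G-T/G-U
# wobble pairs and short bulges. The whole ASO is aligned (every ASO residue
# occupies a column); target ends are free. Bulges are interior: the duplex
# proper begins and ends with a base pair, matching the physical picture of a
# bulged helix with free dangling target ends.
#
# Ties between equal-score alignments are broken by (1) more canonical pairs,
# (2) fewer bulged nucleotides, (3) leftmost target start.

#' Scanning and alignment parameters
#'
#' Scores are per column; bulge penalties apply per bulged nucleotide with an
#' opening cost for the first nucleotide of a bulge run and an extension cost
#' for each further contiguous nucleotide on the same strand. `min_score` is
#' anchored at twice the canonical-pair count of the weakest splice-switching
#' site observed to act in cells (13 canonical pairs for an 18-mer duplex).
#'
#' @param score_canonical,score_wobble,score_mismatch Column scores; must
#'   satisfy `score_canonical > score_wobble > score_mismatch`.
#' @param bulge_open,bulge_extend Non-positive bulge penalties.
#' @param max_bulged_nt Total bulged nucleotides allowed (both strands).
#' @param max_mismatches Maximum mismatch columns a reported hit may carry
#'   (`Inf` = unlimited); applied when scanning, not during alignment.
#' @param min_score Minimum alignment score for a scan hit to be reported.
#' @param window_step Step (nt) between scan windows.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(score_canonical = 2, score_wobble = 1,
                        score_mismatch = -1, bulge_open = -3,
                        bulge_extend = -1, max_bulged_nt = 2,
                        max_mismatches = Inf, min_score = 26,
                        window_step = 1) {
  if (!(score_canonical > score_wobble && score_wobble > score_mismatch)) {
    stop("scores must satisfy canonical > wobble > mismatch", call. = FALSE)
  }
  if (bulge_open > 0 || bulge_extend > 0) {
    stop("bulge penalties must be <= 0", call. = FALSE)
  }
  if (max_bulged_nt < 0) stop("max_bulged_nt must be >= 0", call. = FALSE)
  structure(list(score_canonical = score_canonical,
                 score_wobble = score_wobble,
                 score_mismatch = score_mismatch,
                 bulge_open = bulge_open, bulge_extend = bulge_extend,
                 max_bulged_nt = as.integer(max_bulged_nt),
                 max_mismatches = max_mismatches,
                 min_score = min_score,
                 window_step = as.integer(window_step)),
            class = "scan_params")
}

# Normalize a target string to an uppercase T-alphabet character vector;
# degenerate symbols (N etc.) are kept and score as mismatches against
# everything.
.target_chars <- function(window) {
  s <- gsub("U", "T", toupper(window))
  strsplit(s, "")[[1]]
}

# Column score of aso pairing base `a` against target char `t`.
.pair_class_fast <- function(a, t) {
  if (!t %in% c("A", "C", "G", "T")) return("MISMATCH")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (comp[[a]] == t) return("CANONICAL")
  if ((a == "G" && t == "T") || (a == "T" && t == "G")) return("WOBBLE")
  "MISMATCH"
}

.class_score <- function(cls, params) {
  switch(cls,
         CANONICAL = params$score_canonical,
         WOBBLE = params$score_wobble,
         MISMATCH = params$score_mismatch)
}

# Lexicographic "is candidate better than incumbent": higher score, then more
# canonical pairs, then fewer bulged nt, then smaller target start.
.tuple_better <- function(s1, c1, b1, p1, s2, c2, b2, p2) {
  if (s1 != s2) return(s1 > s2)
  if (c1 != c2) return(c1 > c2)
  if (b1 != b2) return(b1 < b2)
  p1 < p2
}

.new_duplex_alignment <- function(aso_name, target_id, columns, score,
                                  strand = "+") {
  span <- range(columns$target_pos, na.rm = TRUE)
  structure(list(aso_name = aso_name, target_id = target_id,
                 target_span = c(start = span[1], end = span[2]),
                 strand = strand, columns = columns, score = score),
            class = "duplex_alignment")
}

#' Best semi-global alignment of an ASO against a target window
#'
#' Computes the maximum-score alignment of the whole ASO (antiparallel) against
#' the supplied window under `params`, allowing mismatches, wobble pairs and up
#' to `max_bulged_nt` interior bulged nucleotides on either strand. Coordinates
#' in the result are 1-based positions within `window`.
#'
#' @param aso An `aso` object.
#' @param window Target sequence string (sense strand, 5' to 3').
#' @param params A `scan_params` object.
#' @return A `duplex_alignment`: `aso_name`, `target_id`, `target_span`
#'   (1-based inclusive), `columns` (data.frame `aso_pos`, `target_pos`,
#'   `class`, ordered along the target; ASO positions decrease because pairing
#'   is antiparallel), and `score`.
#' @examples
#' f18 <- aso_definition("F18MOE", "TCACTTTCATAATGCTGG", "MOE", "PS")
#' align_duplex(f18, "CCAGCATTATGAAAGTGA")
#' @export
align_duplex <- function(aso, window, params = scan_params(),
                         target_id = "window") {
  stopifnot(inherits(aso, "aso"))
  a <- rev(aso$pairing)            # a[i] pairs leftward along the target
  n <- length(a)
  t <- .target_chars(window)
  m <- length(t)
  B <- params$max_bulged_nt
  if (m < n - B) {
    stop("window (", m, " nt) shorter than length(aso) - max_bulged_nt (",
         n - B, " nt)", call. = FALSE)
  }

  NEG <- -Inf
  # state 1 = M (pair), 2 = IA (ASO bulge), 3 = IT (target bulge)
  dims <- c(n, m, B + 1, 3)
  S <- array(NEG, dims)   # score
  CC <- array(0, dims)    # canonical pairs
  GG <- array(0, dims)    # bulged nucleotides
  PP <- array(0, dims)    # target start position
  BK <- array(0L, dims)   # backpointer: previous state (0 = origin)

  cls_cache <- matrix("", n, m)
  sc_cache <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cls <- .pair_class_fast(a[i], t[j])
      cls_cache[i, j] <- cls
      sc_cache[i, j] <- .class_score(cls, params)
    }
  }

  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      for (b in 0:B) {
        bi <- b + 1
        # --- M: pair a[i] with t[j] ---
        if (i == 1) {
          if (b == 0) {
            S[i, j, bi, 1] <- sc_cache[i, j]
            CC[i, j, bi, 1] <- as.numeric(cls_cache[i, j] == "CANONICAL")
            GG[i, j, bi, 1] <- 0
            PP[i, j, bi, 1] <- j
            BK[i, j, bi, 1] <- 0L
          }
        } else if (j >= 2) {
          best_s <- NEG; best <- 0L
          for (ps in 1:3) {
            sv <- S[i - 1, j - 1, bi, ps]
            if (sv == NEG) next
            if (best == 0L ||
                .tuple_better(sv, CC[i - 1, j - 1, bi, ps],
                              GG[i - 1, j - 1, bi, ps],
                              PP[i - 1, j - 1, bi, ps],
                              best_s, CC[i - 1, j - 1, bi, best],
                              GG[i - 1, j - 1, bi, best],
                              PP[i - 1, j - 1, bi, best])) {
              best <- ps; best_s <- sv
            }
          }
          if (best > 0L) {
            S[i, j, bi, 1] <- best_s + sc_cache[i, j]
            CC[i, j, bi, 1] <- CC[i - 1, j - 1, bi, best] +
              as.numeric(cls_cache[i, j] == "CANONICAL")
            GG[i, j, bi, 1] <- GG[i - 1, j - 1, bi, best]
            PP[i, j, bi, 1] <- PP[i - 1, j - 1, bi, best]
            BK[i, j, bi, 1] <- best
          }
        }
        # --- IA: a[i] bulged (interior: 1 < i < n) ---
        if (b >= 1 && i > 1 && i < n) {
          best <- 0L; best_s <- NEG
          for (ps in 1:3) {
            pen <- if (ps == 2) params$bulge_extend else params$bulge_open
            sv <- S[i - 1, j, b, ps]
            if (sv == NEG) next
            cand <- sv + pen
            if (best == 0L ||
                .tuple_better(cand, CC[i - 1, j, b, ps],
                              GG[i - 1, j, b, ps] + 1, PP[i - 1, j, b, ps],
                              best_s, CC[i - 1, j, b, best],
                              GG[i - 1, j, b, best] + 1,
                              PP[i - 1, j, b, best])) {
              best <- ps; best_s <- cand
            }
          }
          if (best > 0L) {
            S[i, j, bi, 2] <- best_s
            CC[i, j, bi, 2] <- CC[i - 1, j, b, best]
            GG[i, j, bi, 2] <- GG[i - 1, j, b, best] + 1
            PP[i, j, bi, 2] <- PP[i - 1, j, b, best]
            BK[i, j, bi, 2] <- best
          }
        }
        # --- IT: t[j] bulged (interior: more ASO must follow, i < n) ---
        if (b >= 1 && j > 1 && i >= 1 && i < n) {
          best <- 0L; best_s <- NEG
          for (ps in 1:3) {
            pen <- if (ps == 3) params$bulge_extend else params$bulge_open
            sv <- S[i, j - 1, b, ps]
            if (sv == NEG) next
            cand <- sv + pen
            if (best == 0L ||
                .tuple_better(cand, CC[i, j - 1, b, ps],
                              GG[i, j - 1, b, ps] + 1, PP[i, j - 1, b, ps],
                              best_s, CC[i, j - 1, b, best],
                              GG[i, j - 1, b, best] + 1,
                              PP[i, j - 1, b, best])) {
              best <- ps; best_s <- cand
            }
          }
          if (best > 0L) {
            S[i, j, bi, 3] <- best_s
            CC[i, j, bi, 3] <- CC[i, j - 1, b, best]
            GG[i, j, bi, 3] <- GG[i, j - 1, b, best] + 1
            PP[i, j, bi, 3] <- PP[i, j - 1, b, best]
            BK[i, j, bi, 3] <- best
          }
        }
      }
    }
  }

  # answer: last column is a pair -> state M at i = n
  bj <- 0L; bb <- 0L; bs <- NEG
  for (j in seq_len(m)) {
    for (b in 0:B) {
      sv <- S[n, j, b + 1, 1]
      if (sv == NEG) next
      if (bj == 0L ||
          .tuple_better(sv, CC[n, j, b + 1, 1], GG[n, j, b + 1, 1],
                        PP[n, j, b + 1, 1],
                        bs, CC[n, bj, bb + 1, 1], GG[n, bj, bb + 1, 1],
                        PP[n, bj, bb + 1, 1])) {
        bj <- j; bb <- b; bs <- sv
      }
    }
  }
  if (bj == 0L) stop("no admissible alignment found", call. = FALSE)

  # traceback
  cols <- list()
  i <- n; j <- bj; b <- bb; st <- 1L
  repeat {
    if (st == 1L) {
      cols[[length(cols) + 1]] <- list(aso_pos = n - i + 1, target_pos = j,
                                       class = cls_cache[i, j])
      prev <- BK[i, j, b + 1, 1]
      if (prev == 0L) break
      i <- i - 1; j <- j - 1; st <- prev
    } else if (st == 2L) {
      cols[[length(cols) + 1]] <- list(aso_pos = n - i + 1, target_pos = NA,
                                       class = "ASO_BULGE")
      prev <- BK[i, j, b + 1, 2]
      i <- i - 1; b <- b - 1; st <- prev
    } else {
      cols[[length(cols) + 1]] <- list(aso_pos = NA, target_pos = j,
                                       class = "TARGET_BULGE")
      prev <- BK[i, j, b + 1, 3]
      j <- j - 1; b <- b - 1; st <- prev
    }
  }
  cols <- rev(cols)
  columns <- data.frame(
    aso_pos = vapply(cols, function(x) as.numeric(x$aso_pos), numeric(1)),
    target_pos = vapply(cols, function(x) as.numeric(x$target_pos), numeric(1)),
    class = vapply(cols, function(x) x$class, character(1)),
    stringsAsFactors = FALSE
  )
  out <- .new_duplex_alignment(aso$name, target_id, columns, bs)
  attr(out, "target_chars") <- t
  attr(out, "aso_tokens") <- aso$sequence
  out
}

#' Summarize the pairing features of a duplex alignment
#'
#' Counts each pair class and the longest runs of canonical and non-canonical
#' columns. The longest canonical run is the best available seed for duplex
#' nucleation; a long non-canonical run is a barrier to zippering.
#'
#' @param alignment A `duplex_alignment`.
#' @return List of class `duplex_features`: `n_canonical`, `n_wobble`,
#'   `n_mismatch`, `n_bulge` (bulged nucleotides on both strands),
#'   `n_noncanonical` (wobble + mismatch + bulge), `max_noncanonical_run`,
#'   `max_canonical_run`, and `aso_length` (ASO residues in the alignment).
#' @export
feature_summary <- function(alignment) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  cls <- alignment$columns$class
  is_can <- cls == "CANONICAL"
  runs <- rle(is_can)
  max_run <- function(val) {
    if (any(runs$values == val)) max(runs$lengths[runs$values == val]) else 0L
  }
  structure(list(
    n_canonical = sum(cls == "CANONICAL"),
    n_wobble = sum(cls == "WOBBLE"),
    n_mismatch = sum(cls == "MISMATCH"),
    n_bulge = sum(cls %in% c("ASO_BULGE", "TARGET_BULGE")),
    n_noncanonical = sum(!is_can),
    max_noncanonical_run = max_run(FALSE),
    max_canonical_run = max_run(TRUE),
    aso_length = sum(!is.na(alignment$columns$aso_pos))
  ), class = "duplex_features")
}

#' @export
print.duplex_features <- function(x, ...) {
  cat(sprintf(paste0("<duplex_features> canonical %d, wobble %d, mismatch %d, ",
                     "bulged nt %d | longest canonical run %d, ",
                     "longest non-canonical run %d\n"),
              x$n_canonical, x$n_wobble, x$n_mismatch, x$n_bulge,
              x$max_canonical_run, x$max_noncanonical_run))
  invisible(x)
}

#' Flattened duplex diagram midline
#'
#' One character per alignment column: `|` canonical, `o` wobble, space
#' mismatch, `-` bulge.
#'
#' @param alignment A `duplex_alignment`.
#' @return A single string.
#' @export
duplex_string <- function(alignment) {
  sym <- c(CANONICAL = "|", WOBBLE = "o", MISMATCH = " ",
           ASO_BULGE = "-", TARGET_BULGE = "-")
  paste(sym[alignment$columns$class], collapse = "")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cols <- x$columns
  cat(sprintf("<duplex_alignment> %s vs %s [%d-%d]%s score %.1f\n",
              x$aso_name, x$target_id, x$target_span[1], x$target_span[2],
              if (x$strand == "-") " (-)" else "", x$score))
  tchars <- attr(x, "target_chars")
  atokens <- attr(x, "aso_tokens")
  if (!is.null(tchars) && !is.null(atokens)) {
    tline <- ifelse(is.na(cols$target_pos), "-",
                    tchars[pmax(1, cols$target_pos)])
    aline <- ifelse(is.na(cols$aso_pos), "-", atokens[pmax(1, cols$aso_pos)])
    cat("  target 5'-", paste(tline, collapse = ""), "-3'\n", sep = "")
    cat("            ", duplex_string(x), "\n", sep = "")
    cat("  ASO    3'-", paste(aline, collapse = ""), "-5'\n", sep = "")
  } else {
    cat("  ", duplex_string(x), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive-enumeration alignment oracle
#'
#' Enumerates every monotone antiparallel alignment of the whole ASO against
#' the window within the bulge budget (bulges interior, first and last columns
#' paired) and returns the argmax under the same scoring and tie-break rules as
#' [align_duplex()]. Intended as an independent correctness check; guarded to
#' small instances.
#'
#' @inheritParams align_duplex
#' @return A `duplex_alignment`.
#' @export
oracle_align <- function(aso, window, params = scan_params(),
                         target_id = "window") {
  stopifnot(inherits(aso, "aso"))
  a <- rev(aso$pairing)
  n <- length(a)
  t <- .target_chars(window)
  m <- length(t)
  if (n > 12 || m > 18) {
    stop("oracle_align is limited to length(aso) <= 12 and window <= 18",
         call. = FALSE)
  }
  B <- params$max_bulged_nt
  if (m < n - B) stop("window too short", call. = FALSE)

  best <- NULL

  score_cols <- function(cols) {
    sc <- 0; canon <- 0; bulged <- 0
    prev_class <- ""
    for (col in cols) {
      cl <- col$class
      if (cl %in% c("ASO_BULGE", "TARGET_BULGE")) {
        sc <- sc + if (cl == prev_class) params$bulge_extend else
          params$bulge_open
        bulged <- bulged + 1
      } else {
        sc <- sc + .class_score(cl, params)
        if (cl == "CANONICAL") canon <- canon + 1
      }
      prev_class <- cl
    }
    list(score = sc, canon = canon, bulged = bulged)
  }

  consider <- function(cols, start) {
    st <- score_cols(cols)
    if (is.null(best) ||
        .tuple_better(st$score, st$canon, st$bulged, start,
                      best$score, best$canon, best$bulged, best$start)) {
      best <<- c(st, list(start = start, cols = cols))
    }
  }

  recurse <- function(i, j, bleft, cols, start) {
    if (i > n) {
      # complete; last column is guaranteed to be a pair by construction
      consider(cols, start)
      return(invisible())
    }
    # pair a[i] with t[j]
    if (j <= m) {
      cl <- .pair_class_fast(a[i], t[j])
      recurse(i + 1, j + 1, bleft,
              c(cols, list(list(aso_pos = n - i + 1, target_pos = j,
                                class = cl))), start)
    }
    if (length(cols) > 0 && bleft > 0) {
      # ASO bulge: interior only
      if (i < n) {
        recurse(i + 1, j, bleft - 1,
                c(cols, list(list(aso_pos = n - i + 1, target_pos = NA,
                                  class = "ASO_BULGE"))), start)
      }
      # target bulge: interior only
      if (j <= m && i <= n) {
        recurse(i, j + 1, bleft - 1,
                c(cols, list(list(aso_pos = NA, target_pos = j,
                                  class = "TARGET_BULGE"))), start)
      }
    }
  }

  for (j0 in seq_len(m)) {
    if (m - j0 + 1 < n - B) break
    recurse(1, j0, B, list(), j0)
  }
  if (is.null(best)) stop("no admissible alignment found", call. = FALSE)
  columns <- data.frame(
    aso_pos = vapply(best$cols, function(x) as.numeric(x$aso_pos), numeric(1)),
    target_pos = vapply(best$cols, function(x) as.numeric(x$target_pos),
                        numeric(1)),
    class = vapply(best$cols, function(x) x$class, character(1)),
    stringsAsFactors = FALSE
  )
  out <- .new_duplex_alignment(aso$name, target_id, columns, best$score)
  attr(out, "target_chars") <- t
  attr(out, "aso_tokens") <- aso$sequence
  out
}
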