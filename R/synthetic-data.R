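# Synthetic inputs with known ground truth: transcripts with planted ASO
# target sites, junction-count event tables with planted delta-PSI effects,
# and qPCR Ct tables with planted fold changes. Every generator takes an
# explicit seed; backgrounds are i.i.d. nucleotides at a configurable GC
# fraction.

.sample_background <- function(n, gc = 0.5) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Base that pairs as weakly as possible (mismatch if attainable, else wobble)
# with every base in `aso_bases`; used to guard the footprint edges so random
# flank sequence cannot extend the planted duplex.
.weak_pairing_base <- function(aso_bases) {
  cand <- c("A", "C", "G", "T")
  penalty <- vapply(cand, function(b) {
    cls <- pair_class(aso_bases, rep(b, length(aso_bases)))
    2 * sum(cls == "CANONICAL") + sum(cls == "WOBBLE")
  }, numeric(1))
  cand[which.min(penalty)]
}

#' Plant an (optionally edited) ASO target site in random sequence
#'
#' The base footprint is the ASO's perfect annealing site (its reverse
#' complement). Edits are applied at footprint positions (1-based, footprint
#' 5' to 3'): `MISMATCH` substitutes a base that neither pairs canonically nor
#' forms a wobble with the facing ASO residue; `WOBBLE_SWAP` substitutes the
#' base turning a canonical pair into a G-T wobble (only possible facing a G
#' or T of the ASO); `INSERT` adds a random base after the position (a target
#' bulge); `DELETE` removes the base (an ASO bulge). The edited footprint is
#' embedded between random flanks and the true interval and expected feature
#' counts are recorded.
#'
#' @param aso An `aso` object.
#' @param edits data.frame with columns `position`, `kind`, or NULL for a
#'   perfect site.
#' @param flank Lengths of the left and right random flanks (recycled).
#' @param gc Background GC fraction.
#' @param seed Integer seed (mandatory: every generator is reproducible).
#' @param id Identifier of the resulting sequence record.
#' @return List: `id`, `seq`, `site_start`, `site_end` (1-based inclusive),
#'   `truth` (expected `n_mismatch`, `n_wobble`, `n_bulge`) and the applied
#'   `edits`.
#' @export
plant_target_site <- function(aso, edits = NULL, flank = c(200, 200),
                              gc = 0.5, seed, id = "synthetic_target") {
  stopifnot(inherits(aso, "aso"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  flank <- rep(flank, length.out = 2)
  footprint <- strsplit(antisense_of(paste(aso$pairing, collapse = "")),
                        "")[[1]]
  n <- length(footprint)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_mm <- 0L; n_wob <- 0L; n_bulge <- 0L

  if (!is.null(edits) && nrow(edits) > 0) {
    if (any(edits$position < 1 | edits$position > n)) {
      stop("edit positions must lie within the footprint (1..", n, ")",
           call. = FALSE)
    }
    if (anyDuplicated(edits$position)) {
      stop("duplicate edit positions", call. = FALSE)
    }
    # apply right-to-left so positions keep referring to the original footprint
    edits <- edits[order(edits$position, decreasing = TRUE), , drop = FALSE]
    for (r in seq_len(nrow(edits))) {
      pos <- edits$position[r]
      kind <- toupper(edits$kind[r])
      aso_base <- aso$pairing[n - pos + 1]   # facing ASO residue
      if (kind == "MISMATCH") {
        forbidden <- comp[[aso_base]]
        if (aso_base == "G") forbidden <- c(forbidden, "T")
        if (aso_base == "T") forbidden <- c(forbidden, "G")
        choices <- setdiff(c("A", "C", "G", "T"), forbidden)
        # among admissible mismatch bases, prefer one that also pairs weakly
        # with the neighboring ASO residues, so a shifted (bulged) register
        # cannot outscore the planted alignment and hide the mismatch
        ctx <- aso$pairing[pmax(1, n - pos - 1):pmin(n, n - pos + 3)]
        penalty <- vapply(choices, function(b) {
          cls <- pair_class(ctx, rep(b, length(ctx)))
          2 * sum(cls == "CANONICAL") + sum(cls == "WOBBLE")
        }, numeric(1))
        footprint[pos] <- choices[which.min(penalty)]
        n_mm <- n_mm + 1L
      } else if (kind == "WOBBLE_SWAP") {
        if (aso_base == "G") {
          footprint[pos] <- "T"
        } else if (aso_base == "T") {
          footprint[pos] <- "G"
        } else {
          stop("no wobble pairing possible at footprint position ", pos,
               " (ASO base ", aso_base, ")", call. = FALSE)
        }
        n_wob <- n_wob + 1L
      } else if (kind == "INSERT") {
        footprint <- append(footprint, sample(c("A", "C", "G", "T"), 1),
                            after = pos)
        n_bulge <- n_bulge + 1L
      } else if (kind == "DELETE") {
        footprint <- footprint[-pos]
        n_bulge <- n_bulge + 1L
      } else {
        stop("unknown edit kind: ", kind, call. = FALSE)
      }
    }
  }

  left <- .sample_background(flank[1], gc)
  right <- .sample_background(flank[2], gc)
  # guard bases: the flank positions bordering the footprint must not pair
  # with the ASO ends, or a bulged extension could outscore the planted
  # register and the recorded truth would not be recoverable
  n_guard <- 4
  aso_3p <- aso$pairing[seq.int(length(aso$pairing),
                                max(1, length(aso$pairing) - 2))]
  aso_5p <- aso$pairing[seq_len(min(3, length(aso$pairing)))]
  if (length(left) > 0) {
    idx <- seq.int(length(left), by = -1,
                   length.out = min(n_guard, length(left)))
    left[idx] <- .weak_pairing_base(aso_3p)
  }
  if (length(right) > 0) {
    idx <- seq_len(min(n_guard, length(right)))
    right[idx] <- .weak_pairing_base(aso_5p)
  }
  seq <- paste(c(left, footprint, right), collapse = "")
  list(id = id, seq = seq,
       site_start = flank[1] + 1L,
       site_end = flank[1] + length(footprint),
       truth = list(n_mismatch = n_mm, n_wobble = n_wob, n_bulge = n_bulge),
       edits = edits)
}

# Beta-binomial draw (rho = 0 degenerates to binomial).
.rcounts <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}

#' Simulate a junction-count event table with planted splicing effects
#'
#' Null events share one inclusion level between groups; true events differ by
#' `delta_psi_true` (direction randomized). Per-sample total junction reads
#' are Poisson around `depth`; inclusion counts are binomial (optionally
#' beta-binomial with overdispersion `rho`) at the sample's PSI. Effective
#' lengths are fixed at 1.
#'
#' @param n_events Total events.
#' @param n_true Events with a planted effect (`n_true <= n_events`).
#' @param delta_psi_true Planted PSI difference, in (0, 1].
#' @param depth Expected junction reads per sample per event.
#' @param n_per_group Samples per group.
#' @param rho Beta-binomial overdispersion in [0, 1); 0 = pure binomial.
#' @param seed Integer seed (mandatory).
#' @return List with `events` (long-format data.frame: `event_id`, `gene`,
#'   `group` in control/treated, `sample`, `ijc`, `sjc`, `len_inc`,
#'   `len_skip`) and `truth` (`event_id`, `is_true`, `psi_control`,
#'   `psi_treated`).
#' @export
simulate_event_table <- function(n_events = 200, n_true = 20,
                                 delta_psi_true = 0.4, depth = 100,
                                 n_per_group = 3, rho = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_true > n_events) stop("n_true must be <= n_events", call. = FALSE)
  if (delta_psi_true <= 0 || delta_psi_true > 1) {
    stop("delta_psi_true must lie in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  ids <- sprintf("ev%04d", seq_len(n_events))
  is_true <- c(rep(TRUE, n_true), rep(FALSE, n_events - n_true))

  psi_control <- numeric(n_events)
  psi_treated <- numeric(n_events)
  for (k in seq_len(n_events)) {
    if (is_true[k]) {
      lo <- stats::runif(1, 0.05, 0.95 - delta_psi_true)
      if (stats::runif(1) < 0.5) {
        psi_control[k] <- lo; psi_treated[k] <- lo + delta_psi_true
      } else {
        psi_control[k] <- lo + delta_psi_true; psi_treated[k] <- lo
      }
    } else {
      psi_control[k] <- psi_treated[k] <- stats::runif(1, 0.2, 0.8)
    }
  }

  groups <- c(rep("control", n_per_group), rep("treated", n_per_group))
  samples <- c(sprintf("c%d", seq_len(n_per_group)),
               sprintf("t%d", seq_len(n_per_group)))
  rows <- vector("list", n_events)
  for (k in seq_len(n_events)) {
    psi <- ifelse(groups == "control", psi_control[k], psi_treated[k])
    tot <- pmax(1L, stats::rpois(length(groups), depth))
    ijc <- mapply(function(sz, p) .rcounts(1, sz, p, rho), tot, psi)
    rows[[k]] <- data.frame(event_id = ids[k],
                            gene = sprintf("gene%04d", k),
                            group = groups, sample = samples,
                            ijc = as.integer(ijc),
                            sjc = as.integer(tot - ijc),
                            len_inc = 1L, len_skip = 1L,
                            stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, rows),
       truth = data.frame(event_id = ids, is_true = is_true,
                          psi_control = psi_control,
                          psi_treated = psi_treated,
                          stringsAsFactors = FALSE))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Target Ct values shift by minus the planted log2 fold change relative to
#' the control condition (one PCR cycle per 2-fold change); the normalizer
#' assay is unaffected. Gaussian technical noise is added to every Ct.
#'
#' @param log2fc Named numeric vector: planted log2 fold change per non-control
#'   condition.
#' @param n_reps Replicates per condition.
#' @param control Name of the control condition.
#' @param base_target_ct,base_normalizer_ct Baseline Ct values.
#' @param sd Gaussian noise standard deviation (cycles).
#' @param seed Integer seed (mandatory).
#' @return data.frame: `sample`, `condition`, `target_ct`, `normalizer_ct`.
#' @export
simulate_qpcr_table <- function(log2fc = c(treated = -1), n_reps = 3,
                                control = "control", base_target_ct = 24,
                                base_normalizer_ct = 18, sd = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  conditions <- c(control, names(log2fc))
  shifts <- c(0, unname(log2fc))
  rows <- mapply(function(cond, f) {
    data.frame(sample = sprintf("%s_r%d", cond, seq_len(n_reps)),
               condition = cond,
               target_ct = base_target_ct - f +
                 stats::rnorm(n_reps, 0, sd),
               normalizer_ct = base_normalizer_ct +
                 stats::rnorm(n_reps, 0, sd),
               stringsAsFactors = FALSE)
  }, conditions, shifts, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a differential-expression results table with planted truth
#'
#' Null genes get uniform p-values and small fold changes; planted significant
#' genes get tiny p-values and log2 fold changes drawn beyond the supplied
#' magnitude. Adjusted p-values are computed with [bh_adjust()].
#'
#' @param n_genes Total genes.
#' @param n_sig Planted differentially expressed genes.
#' @param lfc_magnitude Minimum |log2FC| of planted genes.
#' @param seed Integer seed (mandatory).
#' @return List with `table` (`gene`, `base_mean`, `log2fc`, `padj`) and
#'   `truth` (`gene`, `is_sig`, `direction`).
#' @export
simulate_de_table <- function(n_genes = 1000, n_sig = 100,
                              lfc_magnitude = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  gene <- sprintf("g%05d", seq_len(n_genes))
  is_sig <- c(rep(TRUE, n_sig), rep(FALSE, n_genes - n_sig))
  p <- ifelse(is_sig, stats::runif(n_genes, 0, 1e-8),
              stats::runif(n_genes, 0.05, 1))
  direction <- sample(c(-1, 1), n_genes, replace = TRUE)
  lfc <- ifelse(is_sig,
                direction * (lfc_magnitude + stats::rexp(n_genes, 2)),
                direction * stats::runif(n_genes, 0, 0.3))
  list(table = data.frame(gene = gene,
                          base_mean = stats::rlnorm(n_genes, 5, 1.5),
                          log2fc = lfc, padj = bh_adjust(p),
                          stringsAsFactors = FALSE),
       truth = data.frame(gene = gene, is_sig = is_sig,
                          direction = ifelse(direction > 0, "up", "down"),
                          stringsAsFactors = FALSE))
}
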