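# Downstream quantification: PSI from junction counts, event filtering,
# gel densitometry percent inclusion, delta-delta-Ct relative expression, and
# differential-expression table summaries.

#' Percent spliced in from junction counts
#'
#' Length-normalized PSI: `(ijc/len_inc) / (ijc/len_inc + sjc/len_skip)`.
#' Returns `NA` where an event has no supporting reads at all. Effective
#' lengths default to 1 (plain count PSI).
#'
#' @param ijc,sjc Inclusion / skipping junction counts (non-negative,
#'   vectorized).
#' @param len_inc,len_skip Positive effective lengths.
#' @return Numeric vector of PSI values in `[0, 1]` (NA where undefined).
#' @examples
#' psi_from_junctions(30, 10, 2, 1)  # 0.6
#' @export
psi_from_junctions <- function(ijc, sjc, len_inc = 1, len_skip = 1) {
  if (any(ijc < 0, na.rm = TRUE) || any(sjc < 0, na.rm = TRUE)) {
    stop("junction counts must be non-negative", call. = FALSE)
  }
  if (any(len_inc <= 0) || any(len_skip <= 0)) {
    stop("effective lengths must be positive", call. = FALSE)
  }
  ni <- ijc / len_inc
  ns <- sjc / len_skip
  out <- ni / (ni + ns)
  out[ijc + sjc == 0] <- NA_real_
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (a validated wrapper over
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group test for a difference in inclusion proportion
#'
#' Likelihood-ratio test comparing two binomials against a pooled binomial on
#' the length-normalized inclusion/skipping counts of one event. This is a
#' deliberate, documented stand-in for the paired likelihood model of
#' junction-count software: the downstream filters are faithful, the p-value
#' engine is generic.
#'
#' @param ijc,sjc Per-sample junction counts.
#' @param group Per-sample group labels (exactly two groups, at least two
#'   samples each).
#' @param len_inc,len_skip Effective lengths.
#' @return Two-sided p-value (`NA` when a group has zero total counts).
#' @export
delta_psi_test <- function(ijc, sjc, group, len_inc = 1, len_skip = 1) {
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("at least two samples per group required", call. = FALSE)
  }
  ni <- ijc / len_inc
  ns <- sjc / len_skip
  ll <- function(x, y) {
    tot <- x + y
    if (tot == 0) return(NA_real_)
    p <- x / tot
    term <- function(k, q) if (k == 0) 0 else k * log(q)
    term(x, p) + term(y, 1 - p)
  }
  xi <- vapply(levs, function(g) sum(ni[group == g]), numeric(1))
  xs <- vapply(levs, function(g) sum(ns[group == g]), numeric(1))
  if (any(xi + xs == 0)) return(NA_real_)
  ll_alt <- ll(xi[1], xs[1]) + ll(xi[2], xs[2])
  p0 <- sum(xi) / sum(xi + xs)
  ll0 <- function(x, y) {
    term <- function(k, q) if (k == 0) 0 else k * log(q)
    term(x, p0) + term(y, 1 - p0)
  }
  ll_null <- ll0(xi[1], xs[1]) + ll0(xi[2], xs[2])
  lr <- max(0, 2 * (ll_alt - ll_null))
  stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Event filter thresholds
#'
#' The three post-filters applied to candidate differential-splicing events:
#' FDR below 0.05, at least 10 average junction reads supporting each isoform
#' in at least one sample group, and an absolute PSI change of at least 0.1.
#'
#' @param fdr_max,min_avg_junction_reads,min_abs_delta_psi Thresholds.
#' @return List of class `event_filter_thresholds`.
#' @export
event_filter_thresholds <- function(fdr_max = 0.05,
                                    min_avg_junction_reads = 10,
                                    min_abs_delta_psi = 0.1) {
  if (fdr_max <= 0 || min_avg_junction_reads <= 0 || min_abs_delta_psi <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(list(fdr_max = fdr_max,
                 min_avg_junction_reads = min_avg_junction_reads,
                 min_abs_delta_psi = min_abs_delta_psi),
            class = "event_filter_thresholds")
}

#' Analyze a long-format splicing event table
#'
#' Computes per-sample PSI, per-group mean PSI, delta-PSI
#' (treated minus control), a per-event p-value ([delta_psi_test()]), BH FDR
#' across events, and the best single-group junction support (for each group
#' the smaller of the two isoforms' mean counts, maximized over groups).
#'
#' @param events data.frame with columns `event_id`, `gene`, `group`,
#'   `sample`, `ijc`, `sjc` and optionally `len_inc`, `len_skip` (default 1).
#' @param control Label of the control group.
#' @return data.frame of class `splice_event_table`, one row per event, with
#'   the per-sample table retained in attribute `"samples"`.
#' @export
analyze_splice_events <- function(events, control = "control") {
  req <- c("event_id", "gene", "group", "sample", "ijc", "sjc")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"len_inc" %in% names(events)) events$len_inc <- 1
  if (!"len_skip" %in% names(events)) events$len_skip <- 1
  groups <- unique(as.character(events$group))
  if (length(groups) != 2 || !control %in% groups) {
    stop("event table must contain exactly two groups including '", control,
         "'", call. = FALSE)
  }
  treated <- setdiff(groups, control)
  events$psi <- psi_from_junctions(events$ijc, events$sjc, events$len_inc,
                                   events$len_skip)
  per_event <- lapply(split(events, events$event_id), function(d) {
    mean_psi <- function(g) mean(d$psi[d$group == g])
    support <- vapply(groups, function(g) {
      min(mean(d$ijc[d$group == g]), mean(d$sjc[d$group == g]))
    }, numeric(1))
    p <- delta_psi_test(d$ijc, d$sjc, d$group, d$len_inc, d$len_skip)
    data.frame(event_id = d$event_id[1], gene = d$gene[1],
               psi_control = mean_psi(control), psi_treated = mean_psi(treated),
               delta_psi = mean_psi(treated) - mean_psi(control),
               p_value = p, best_support = max(support),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_event)
  out <- out[order(out$event_id), ]
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p_value)
  attr(out, "samples") <- events
  class(out) <- c("splice_event_table", "data.frame")
  out
}

#' Apply the event post-filters
#'
#' Keeps events with `fdr < fdr_max`, `|delta_psi| >= min_abs_delta_psi` and,
#' for each isoform, mean junction reads of at least `min_avg_junction_reads`
#' within a single group (both isoforms in the same group). Events with an
#' undefined PSI in either group are dropped with a logged reason. Survivors
#' are classified into increased inclusion (`delta_psi > 0`) versus increased
#' skipping.
#'
#' @param analyzed Output of [analyze_splice_events()].
#' @param thresholds An `event_filter_thresholds` object.
#' @return Subset of `analyzed` with a `verdict` column; dropped-event reasons
#'   are in attribute `"dropped"`.
#' @export
filter_events <- function(analyzed, thresholds = event_filter_thresholds()) {
  stopifnot(inherits(analyzed, "splice_event_table"))
  undefined <- is.na(analyzed$psi_control) | is.na(analyzed$psi_treated) |
    is.na(analyzed$p_value)
  dropped <- data.frame(event_id = analyzed$event_id[undefined],
                        reason = rep("undefined-psi", sum(undefined)),
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " event(s) dropped: undefined PSI or p-value")
  }
  keep <- !undefined &
    analyzed$fdr < thresholds$fdr_max &
    abs(analyzed$delta_psi) >= thresholds$min_abs_delta_psi &
    analyzed$best_support >= thresholds$min_avg_junction_reads
  out <- analyzed[keep, , drop = FALSE]
  out$verdict <- ifelse(out$delta_psi > 0, "increased_inclusion",
                        "increased_skipping")
  rownames(out) <- NULL
  attr(out, "samples") <- attr(analyzed, "samples")
  attr(out, "dropped") <- dropped
  class(out) <- c("splice_event_table", "data.frame")
  out
}

#' Percent of lane signal per isoform (gel densitometry)
#'
#' Each isoform's band intensity divided by the total signal in the lane,
#' times 100.
#'
#' @param intensities Named non-negative numeric vector of band intensities
#'   for one lane.
#' @return Named percentages summing to 100.
#' @export
gel_percent_inclusion <- function(intensities) {
  if (any(intensities < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  total <- sum(intensities)
  if (total <= 0) {
    stop("total lane signal must be positive for quantification",
         call. = FALSE)
  }
  100 * intensities / total
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_normalizer`; per condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and `RQ = 2^(-ddCt)`
#' (so the control condition has RQ exactly 1). Samples without a normalizer
#' Ct are excluded with a logged reason.
#'
#' @param records data.frame with columns `sample`, `condition`, `target_ct`,
#'   `normalizer_ct`.
#' @param control_condition Label of the reference condition.
#' @return data.frame per condition: `n`, `mean_dct`, `se_dct`, `ddct`, `rq`,
#'   `log2_rq`, `se_log2_rq` (standard error of the log2 RQ combining both
#'   conditions' dCt standard errors).
#' @export
ddct_relative_expression <- function(records, control_condition = "control") {
  req <- c("sample", "condition", "target_ct", "normalizer_ct")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("qPCR table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- is.na(records$normalizer_ct) | is.na(records$target_ct)
  if (any(bad)) {
    message(sum(bad), " sample(s) excluded: missing Ct value")
    records <- records[!bad, , drop = FALSE]
  }
  if (!control_condition %in% records$condition) {
    stop("control condition '", control_condition, "' not present",
         call. = FALSE)
  }
  records$dct <- records$target_ct - records$normalizer_ct
  agg <- lapply(split(records, records$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_dct = mean(d$dct),
               se_dct = stats::sd(d$dct) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  ctrl <- out[out$condition == control_condition, ]
  out$ddct <- out$mean_dct - ctrl$mean_dct
  out$rq <- 2^(-out$ddct)
  out$log2_rq <- -out$ddct
  out$se_log2_rq <- sqrt(out$se_dct^2 + ctrl$se_dct^2)
  out$se_log2_rq[out$condition == control_condition] <- 0
  rownames(out) <- NULL
  out
}

#' Summarize a differential-expression table at standard thresholds
#'
#' `significant` counts genes with adjusted p below 0.05; `fc_gt2` those that
#' are significant with more than a 2-fold change (`|log2FC| > 1`); `up` and
#' `down` split the significant genes by the sign of the fold change.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `padj` (a
#'   `base_mean` column is allowed and ignored).
#' @param padj_max,min_abs_log2fc Thresholds.
#' @return Named integer vector: `significant`, `fc_gt2`, `up`, `down`.
#' @export
summarize_de_table <- function(records, padj_max = 0.05,
                               min_abs_log2fc = 1) {
  if (nrow(records) == 0) {
    return(c(significant = 0L, fc_gt2 = 0L, up = 0L, down = 0L))
  }
  if (any(records$padj < 0 | records$padj > 1, na.rm = TRUE)) {
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  sig <- !is.na(records$padj) & records$padj < padj_max
  c(significant = sum(sig),
    fc_gt2 = sum(sig & abs(records$log2fc) > min_abs_log2fc),
    up = sum(sig & records$log2fc > 0),
    down = sum(sig & records$log2fc < 0))
}
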