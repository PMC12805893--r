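# End-to-end driver: scan targets with each ASO, classify hit competence,
# annotate exonic context, optionally run the splicing event filter, and
# assemble a machine-readable report.

#' Run the scan/classify/filter pipeline
#'
#' Config fields (a list, or a path to a JSON file with the same fields):
#' \describe{
#'   \item{targets}{FASTA path or named character vector of sequences.}
#'   \item{asos}{ASO TSV path (see [read_aso_table()]), a named list of `aso`
#'     objects, or `"fixtures"` for the packaged catalogue.}
#'   \item{policy}{`site_policy()` list or JSON path; default policy if
#'     absent.}
#'   \item{params}{Named overrides for [scan_params()].}
#'   \item{exons}{Optional BED path or data.frame of exon intervals per
#'     target (chrom = target id), for exonic/intronic context.}
#'   \item{events}{Optional event-table TSV path or data.frame; when present
#'     the event filter runs with `control_group` (default "control").}
#'   \item{both_strands}{Scan the reverse complement too (default FALSE).}
#'   \item{out_dir}{Optional output directory for hits TSV, surviving-events
#'     TSV and a JSON report.}
#' }
#'
#' @param config List or JSON path.
#' @param verbose Emit progress messages.
#' @return Report list (invisibly): `hits` data.frame (scan features, grade,
#'   reasons, context), `events` (filtered event table or NULL), and `counts`
#'   (per-stage record counts). Output ordering is deterministic: by ASO,
#'   target, then coordinate.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  say <- function(...) if (verbose) message(...)

  targets <- config$targets
  if (is.character(targets) && length(targets) == 1 && file.exists(targets)) {
    targets <- read_targets_fasta(targets)
  }
  if (is.null(names(targets))) {
    names(targets) <- sprintf("target%d", seq_along(targets))
  }

  asos <- config$asos
  if (identical(asos, "fixtures")) {
    asos <- fixture_catalogue()$asos
  } else if (is.character(asos) && length(asos) == 1 && file.exists(asos)) {
    asos <- read_aso_table(asos)
  }

  policy <- config$policy
  if (is.null(policy)) {
    policy <- site_policy()
  } else if (is.character(policy)) {
    policy <- read_site_policy(policy)
  } else if (!inherits(policy, "site_policy")) {
    policy <- do.call(site_policy, policy)
  }
  params <- do.call(scan_params, as.list(config$params))

  exons <- config$exons
  if (is.character(exons) && length(exons) == 1) exons <- read_bed(exons)
  both_strands <- isTRUE(config$both_strands)

  say("scanning ", length(asos), " ASO(s) against ", length(targets),
      " target(s)")
  hit_rows <- list()
  for (aso in asos) {
    for (tid in names(targets)) {
      hits <- scan_sequence(aso, c(stats::setNames(targets[[tid]], tid)),
                            params, both_strands = both_strands)
      for (h in hits) {
        f <- feature_summary(h)
        v <- classify_competence(aso, h, policy)
        ctx <- NA_character_
        if (!is.null(exons)) {
          ex <- exons[exons$chrom == tid, , drop = FALSE]
          ctx <- annotate_site_context(h$target_span[[1]], h$target_span[[2]],
                                       ex, nchar(targets[[tid]]))
        }
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          aso = aso$name, target_id = tid,
          start = h$target_span[[1]], end = h$target_span[[2]],
          strand = h$strand, score = h$score,
          n_canonical = f$n_canonical, n_wobble = f$n_wobble,
          n_mismatch = f$n_mismatch, n_bulge = f$n_bulge,
          max_noncanonical_run = f$max_noncanonical_run,
          max_canonical_run = f$max_canonical_run,
          grade = as.character(v$grade),
          reasons = paste(v$reasons, collapse = ";"),
          context = ctx, duplex_string = duplex_string(h),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits_df <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else
    data.frame(aso = character(0), target_id = character(0),
               start = integer(0), end = integer(0), grade = character(0),
               stringsAsFactors = FALSE)
  if (nrow(hits_df) > 0) {
    hits_df <- hits_df[order(hits_df$aso, hits_df$target_id, hits_df$start), ]
    rownames(hits_df) <- NULL
  } else {
    say("scan produced no hits (empty output)")
  }

  events_out <- NULL
  if (!is.null(config$events)) {
    ev <- config$events
    if (is.character(ev) && length(ev) == 1) ev <- read_event_table(ev)
    control <- config$control_group %||% "control"
    analyzed <- analyze_splice_events(ev, control = control)
    events_out <- filter_events(analyzed)
    say(nrow(events_out), " of ", nrow(analyzed), " events pass the filter")
  }

  report <- list(
    hits = hits_df,
    events = events_out,
    counts = list(
      n_targets = length(targets), n_asos = length(asos),
      n_hits = nrow(hits_df),
      n_strong = sum(hits_df$grade == "STRONG"),
      n_weak = sum(hits_df$grade == "WEAK"),
      n_events_surviving = if (is.null(events_out)) NA_integer_ else
        nrow(events_out)
    )
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_tsv(hits_df, file.path(config$out_dir, "hits.tsv"))
    if (!is.null(events_out)) {
      utils::write.table(as.data.frame(events_out),
                         file.path(config$out_dir, "events_filtered.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report$counts,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
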