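# Chemistry-specific off-target competence rules.
#
# Whether an imperfect duplex can still perturb splicing depends on the sugar
# chemistry of the ASO: fully MOE-modified ASOs tolerate several mismatches and
# wobbles, OMe-modified ASOs essentially none, and morpholinos behave like OMe.
# A site must also offer a contiguous canonical seed and must not contain a
# long non-canonical block, which would be an unsurmountable barrier for
# zippering.

#' Longest contiguous block of one sugar modification
#'
#' @param aso An `aso` object.
#' @param mod Sugar tag (`"MOE"`, `"OME"`, `"PMO"`, `"DNA"`).
#' @return Integer run length (0 if the tag is absent).
#' @export
longest_modification_run <- function(aso, mod = "MOE") {
  stopifnot(inherits(aso, "aso"))
  mod <- toupper(mod)
  r <- rle(aso$sugar_mods == mod)
  if (!any(r$values)) return(0L)
  as.integer(max(r$lengths[r$values]))
}

#' Site competence policy
#'
#' Thresholds controlling when a candidate annealing site is judged competent
#' to act on splicing. Defaults are calibrated on 18-mer duplexes
#' (`ref_length = 18`): the weakest site observed to act carries 13 canonical
#' pairs, hence `min_canonical = 13` and a non-canonical budget of 5 for fully
#' MOE-modified ASOs. For shorter ASOs the canonical-pair floor is scaled
#' proportionally (`ceiling(min_canonical * length / ref_length)`). The seed
#' requirement reflects duplex nucleation by 3-7 contiguous pairs; the default
#' of 5 sits inside that range and is configurable.
#'
#' @param min_canonical Minimum canonical pairs (at `ref_length`).
#' @param max_contig_noncanonical Longest tolerated run of consecutive
#'   non-canonical columns.
#' @param min_seed Minimum contiguous canonical run (valid range 3-7).
#' @param max_noncanonical_strong Named per-chemistry budgets of non-canonical
#'   columns compatible with a strong effect.
#' @param max_noncanonical_weak Per-chemistry budgets for a weak effect; must
#'   be >= the strong budgets.
#' @param min_moe_run Minimum uninterrupted MOE block required for the
#'   MOE-specific mismatch tolerance.
#' @param ref_length ASO length the thresholds were calibrated on.
#' @return List of class `site_policy`.
#' @export
site_policy <- function(min_canonical = 13, max_contig_noncanonical = 3,
                        min_seed = 5,
                        max_noncanonical_strong = c(MOE = 5, OME = 0, PMO = 0,
                                                    DNA = 0),
                        max_noncanonical_weak = c(MOE = 6, OME = 2, PMO = 2,
                                                  DNA = 2),
                        min_moe_run = 6, ref_length = 18) {
  if (min_seed < 3 || min_seed > 7) {
    stop("min_seed must lie in 3..7", call. = FALSE)
  }
  for (chem in names(max_noncanonical_strong)) {
    w <- max_noncanonical_weak[[chem]] %||% 0
    if (w < max_noncanonical_strong[[chem]]) {
      stop("weak budget must be >= strong budget for ", chem, call. = FALSE)
    }
  }
  if (min_canonical < 0 || max_contig_noncanonical < 0 ||
      any(max_noncanonical_strong < 0) || any(max_noncanonical_weak < 0)) {
    stop("all thresholds must be >= 0", call. = FALSE)
  }
  structure(list(min_canonical = min_canonical,
                 max_contig_noncanonical = max_contig_noncanonical,
                 min_seed = min_seed,
                 max_noncanonical_strong = max_noncanonical_strong,
                 max_noncanonical_weak = max_noncanonical_weak,
                 min_moe_run = min_moe_run,
                 ref_length = ref_length),
            class = "site_policy")
}

#' Read a site policy from a JSON file
#' @param path JSON file with `site_policy` fields (missing fields keep their
#'   defaults).
#' @return A `site_policy`.
#' @export
read_site_policy <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- site_policy()
  for (f in c("max_noncanonical_strong", "max_noncanonical_weak")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  args <- utils::modifyList(unclass(defaults), vals[names(vals) %in%
                                                      names(defaults)])
  do.call(site_policy, args)
}

# Canonical-pair floor scaled to the ASO length.
.effective_min_canonical <- function(policy, aso_length) {
  if (aso_length >= policy$ref_length) return(policy$min_canonical)
  ceiling(policy$min_canonical * aso_length / policy$ref_length)
}

#' Hard constraints on a candidate site
#'
#' A site fails outright when its longest non-canonical run exceeds the
#' zippering barrier, when no canonical seed of sufficient length exists, or
#' when it offers fewer canonical pairs than the (length-scaled) floor.
#'
#' @param features A `duplex_features` object.
#' @param policy A `site_policy`.
#' @return List with `pass` (logical) and `reasons` (identifiers of failed
#'   rules: `"contiguous-noncanonical"`, `"min-seed"`, `"min-canonical"`).
#' @export
hard_constraints <- function(features, policy = site_policy()) {
  stopifnot(inherits(features, "duplex_features"))
  reasons <- character(0)
  if (features$max_noncanonical_run > policy$max_contig_noncanonical) {
    reasons <- c(reasons, "contiguous-noncanonical")
  }
  if (features$max_canonical_run < policy$min_seed) {
    reasons <- c(reasons, "min-seed")
  }
  if (features$n_canonical <
      .effective_min_canonical(policy, features$aso_length)) {
    reasons <- c(reasons, "min-canonical")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Sugar chemistry charged for each non-canonical column: the modification of
# the ASO base in that column; for a target bulge (no ASO base) the nearest
# ASO base in the column order.
.noncanonical_chemistries <- function(aso, alignment) {
  cols <- alignment$columns
  nc <- which(cols$class != "CANONICAL")
  with_aso <- which(!is.na(cols$aso_pos))
  vapply(nc, function(k) {
    pos <- cols$aso_pos[k]
    if (is.na(pos)) {
      nearest <- with_aso[which.min(abs(with_aso - k))]
      pos <- cols$aso_pos[nearest]
    }
    aso$sugar_mods[pos]
  }, character(1))
}

#' Classify the off-target competence of a site under an ASO's chemistry
#'
#' A perfect all-canonical duplex is `STRONG` for every chemistry (full
#' complementarity rescues even chemistries with no mismatch tolerance). An
#' imperfect duplex must first pass [hard_constraints()]; it is then `STRONG`
#' only when every non-canonical column falls on an MOE-modified ASO residue,
#' the non-canonical count fits the MOE strong budget, and the ASO carries an
#' uninterrupted MOE block of at least `min_moe_run` residues. Otherwise it is
#' `WEAK` when the non-canonical count fits the weak budget of the dominant
#' chemistry at the non-canonical columns, else `NONE`.
#'
#' @param aso The `aso` the alignment was produced for.
#' @param alignment A `duplex_alignment` of that ASO.
#' @param policy A `site_policy`.
#' @return List of class `competence_verdict`: `grade` (ordered factor
#'   NONE < WEAK < STRONG) and `reasons` (rule identifiers that fired).
#' @export
classify_competence <- function(aso, alignment, policy = site_policy()) {
  stopifnot(inherits(aso, "aso"), inherits(alignment, "duplex_alignment"))
  if (!identical(aso$name, alignment$aso_name)) {
    stop("alignment was produced for ASO '", alignment$aso_name,
         "', not '", aso$name, "'", call. = FALSE)
  }
  n_aso_cols <- sum(!is.na(alignment$columns$aso_pos))
  if (n_aso_cols != aso_length(aso)) {
    stop("alignment covers ", n_aso_cols, " ASO residues but the ASO has ",
         aso_length(aso), call. = FALSE)
  }
  feats <- feature_summary(alignment)
  verdict <- function(grade, reasons) {
    structure(list(grade = factor(grade, levels = c("NONE", "WEAK", "STRONG"),
                                  ordered = TRUE),
                   reasons = reasons),
              class = "competence_verdict")
  }
  if (feats$n_noncanonical == 0) {
    return(verdict("STRONG", "perfect-duplex"))
  }
  hc <- hard_constraints(feats, policy)
  if (!hc$pass) return(verdict("NONE", hc$reasons))

  chems <- .noncanonical_chemistries(aso, alignment)
  if (all(chems == "MOE") &&
      feats$n_noncanonical <= policy$max_noncanonical_strong[["MOE"]] &&
      longest_modification_run(aso, "MOE") >= policy$min_moe_run) {
    return(verdict("STRONG", "moe-tolerance"))
  }
  tab <- table(chems)
  dominant <- names(tab)[tab == max(tab)]
  if (length(dominant) > 1) {
    # tie: charge against the most permissive chemistry involved
    budgets <- policy$max_noncanonical_weak[dominant]
    dominant <- dominant[which.max(budgets)]
  }
  weak_budget <- policy$max_noncanonical_weak[[dominant]] %||% 0
  if (feats$n_noncanonical <= weak_budget) {
    return(verdict("WEAK", paste0("weak-budget-", dominant)))
  }
  verdict("NONE", paste0("budget-exceeded-", dominant))
}

#' @export
print.competence_verdict <- function(x, ...) {
  cat(sprintf("<competence_verdict> %s (%s)\n", as.character(x$grade),
              paste(x$reasons, collapse = ", ")))
  invisible(x)
}

#' Competence of a series of ASO variants on one target site
#'
#' Aligns each variant against the site with [align_duplex()] and classifies
#' the result, reproducing truncation- and mixed-chemistry-series panels
#' qualitatively.
#'
#' @param aso_variants List of `aso` objects sharing a parent target footprint.
#' @param target_site Site sequence string.
#' @param policy A `site_policy`.
#' @param params A `scan_params` object.
#' @return data.frame with one row per variant: length, alignment score,
#'   feature counts and the competence grade.
#' @export
competence_series <- function(aso_variants, target_site,
                              policy = site_policy(),
                              params = scan_params()) {
  rows <- lapply(aso_variants, function(a) {
    al <- align_duplex(a, target_site, params)
    f <- feature_summary(al)
    v <- classify_competence(a, al, policy)
    data.frame(aso = a$name, length = aso_length(a), score = al$score,
               n_canonical = f$n_canonical, n_wobble = f$n_wobble,
               n_mismatch = f$n_mismatch, n_bulge = f$n_bulge,
               max_canonical_run = f$max_canonical_run,
               max_noncanonical_run = f$max_noncanonical_run,
               grade = as.character(v$grade),
               reasons = paste(v$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
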