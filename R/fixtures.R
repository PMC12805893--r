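# Packaged fixtures: the ISS-N1 region, the ASO series (full-length,
# truncated, mixed-chemistry, scrambled controls) and a set of SYNTHETIC
# stand-in target sites.
#
# The ISS-N1 sequences are real: the first 32 nt of SMN2 intron 7 and the
# 18-mer antisense drug sequence annealing to intron positions 10-27. The
# off-target site sequences (POLR2H exon 2 and the seven transplantable
# exonic enhancer sites) are synthetic reconstructions: each is built from
# the perfect 18-nt annealing site by introducing the reported number and
# layout of mismatches and wobbles, so that duplex feature counts match the
# published descriptions (14 canonical with two 3'-end mismatches and two
# mid-duplex wobbles for POLR2H; 13/14/15 canonical pairs for the enhancer
# panel) while the flanking genomic identity is not claimed.

# first 32 nt of SMN2 intron 7; ISS-N1 starts at intron position 10
ISSN1_REGION_32 <- "GTAAGTCTGCCAGCATTATGAAAGTGAATCTT"
# intron 7 positions 10-27: the 18-nt target of the full-length MOE ASO
ISSN1_TARGET_18 <- "CCAGCATTATGAAAGTGA"
# intron 7 positions 10-29: target of the 20-mer morpholino
ISSN1_TARGET_20 <- "CCAGCATTATGAAAGTGAAT"

F18_SEQUENCE_MOE <- "TmCAmCTTTmCATAATGmCTGG"  # MOE ASOs carry T and mC
F18_SEQUENCE_OME <- "UCACUUUCAUAAUGCUGG"       # OMe ASOs carry U and C
F20_SEQUENCE_PMO <- "ATTCACTTTCATAATGCTGG"

# SYNTHETIC stand-in target sites (18 nt, aligned columnwise against the
# 18-mer ASO; site position i faces ASO 3'-numbered position i).
# Substituted bases are chosen to avoid complementarity with nearby ASO
# residues, so the intended gapless register is the unique alignment optimum.
SYNTHETIC_SITES <- c(
  POLR2H_WT = "ACTGCATTGTGAGAGTGA",  # mm 1,3; wobble 9,13 -> 14 canonical
  POLR2H_M1 = "CCAGCATTGTGAGAGTGA",  # mismatches corrected -> 16 canonical
  POLR2H_M2 = "ACTGCATTATGAAAGTGA",  # wobbles corrected    -> 16 canonical
  POLR2H_M3 = "CCAGCATTATGAAAGTGA",  # perfect complement   -> 18 canonical
  PITHD1    = "CGAGCATTGTGAAACTGA",  # mm 2,15; wobble 9        -> 15 canonical
  SERPINB7  = "TGAGCATTGTGAACGTGG",  # wobble 1,9,18; mm 2,14   -> 13 canonical
  RTTN      = "CTAGCTTTATGAGAGTGC",  # wobble 2,13; mm 6,18     -> 14 canonical
  REV3L     = "CCAGTATTATCAAAGCGA",  # wobble 5; mm 11,16       -> 15 canonical
  PRKRA     = "CCTGCATTATGAGAGTCA",  # wobble 13; mm 3,17       -> 15 canonical
  GOLGA4    = "ACAGCGTTATGCAAGTGG",  # wobble 6,18; mm 1,12     -> 14 canonical
  PAK1      = "ACAGTATTATGGAAGTGC"   # wobble 5,12; mm 1,18     -> 14 canonical
)

# fixed permutation used for the scrambled-control stand-ins (deterministic,
# chosen once; the published scrambles are not machine-readable)
.SCRAMBLE_PERM_18 <- c(5L, 12L, 1L, 8L, 15L, 3L, 10L, 17L, 6L, 13L, 2L, 9L,
                       18L, 4L, 11L, 16L, 7L, 14L)
.SCRAMBLE_PERM_20 <- c(7L, 14L, 1L, 20L, 9L, 3L, 16L, 11L, 5L, 18L, 2L, 13L,
                       8L, 19L, 4L, 15L, 10L, 6L, 17L, 12L)

# Replace MOE with OME at the given positions COUNTED FROM THE ASO 3' END
# (the convention used for the mixed-chemistry series).
.ome_mask <- function(name, positions3p) {
  base <- aso_definition(name, F18_SEQUENCE_MOE, "MOE", "PS")
  idx5p <- aso_length(base) + 1 - positions3p
  mods <- base$sugar_mods
  mods[idx5p] <- "OME"
  aso_definition(name, base$sequence, mods, "PS")
}

#' Packaged ASO and target-site fixtures
#'
#' Returns the fixture set used throughout the package: the 32-nt start of
#' SMN2 intron 7 with its 18-nt ISS-N1 annealing target; the three full-length
#' splice-correcting ASOs (18-mer MOE, 18-mer OMe, 20-mer PMO) and
#' deterministic scrambled-control stand-ins; the truncated MOE series (14-
#' and 10-mers anchored at the first, middle and last residues of the target
#' footprint); the mixed MOE/OMe chemistry series (blocks numbered from the
#' ASO 3' end); and the synthetic stand-in off-target sites (POLR2H wild type
#' and its M1/M2/M3 complementarity-restoring mutants, plus the seven
#' transplantable exonic-enhancer sites).
#'
#' Site sequences in `$sites` are synthetic reconstructions matching the
#' reported duplex feature counts, not genomic sequence; `$site_truth` lists
#' the by-construction expectations.
#'
#' @return List with elements `asos` (named list of `aso` objects),
#'   `sites` (named character vector), `regions` (named character vector) and
#'   `site_truth` (data.frame of expected feature counts per site).
#' @export
fixture_catalogue <- function() {
  f18moe <- aso_definition("F18MOE", F18_SEQUENCE_MOE, "MOE", "PS")
  f18ome <- aso_definition("F18OMe", F18_SEQUENCE_OME, "OME", "PS")
  f20pmo <- aso_definition("F20PMO", F20_SEQUENCE_PMO, "PMO", "PMO_NEUTRAL")

  scr <- function(name, parent, perm, chem, backbone) {
    aso_definition(name, parent$sequence[perm], chem, backbone)
  }
  asos <- list(
    F18MOE = f18moe, F18OMe = f18ome, F20PMO = f20pmo,
    ScrMOE = scr("ScrMOE", f18moe, .SCRAMBLE_PERM_18, "MOE", "PS"),
    ScrOMe = scr("ScrOMe", f18ome, .SCRAMBLE_PERM_18, "OME", "PS"),
    ScrPMO = scr("ScrPMO", f20pmo, .SCRAMBLE_PERM_20, "PMO", "PMO_NEUTRAL"),
    F14MOE = derive_short_series(f18moe, 14, "FIRST", name = "F14MOE"),
    M14MOE = derive_short_series(f18moe, 14, "MIDDLE", name = "M14MOE"),
    L14MOE = derive_short_series(f18moe, 14, "LAST", name = "L14MOE"),
    F10MOE = derive_short_series(f18moe, 10, "FIRST", name = "F10MOE"),
    M10MOE = derive_short_series(f18moe, 10, "MIDDLE", name = "M10MOE"),
    L10MOE = derive_short_series(f18moe, 10, "LAST", name = "L10MOE"),
    `OMe1-6` = .ome_mask("OMe1-6", 1:6),
    `OMe4-9` = .ome_mask("OMe4-9", 4:9),
    `OMe7-13` = .ome_mask("OMe7-13", 7:13),
    `OMe10-15` = .ome_mask("OMe10-15", 10:15),
    `OMe13-18` = .ome_mask("OMe13-18", 13:18),
    `OMe1-9` = .ome_mask("OMe1-9", 1:9),
    `OMe1-12` = .ome_mask("OMe1-12", 1:12),
    `OMe1-12/16-18` = .ome_mask("OMe1-12/16-18", c(1:12, 16:18))
  )

  site_truth <- data.frame(
    site = c("POLR2H_WT", "POLR2H_M1", "POLR2H_M2", "POLR2H_M3", "PITHD1",
             "SERPINB7", "RTTN", "REV3L", "PRKRA", "GOLGA4", "PAK1"),
    n_canonical = c(14L, 16L, 16L, 18L, 15L, 13L, 14L, 15L, 15L, 14L, 14L),
    n_wobble = c(2L, 2L, 0L, 0L, 1L, 3L, 2L, 1L, 1L, 2L, 2L),
    n_mismatch = c(2L, 0L, 2L, 0L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )

  list(asos = asos,
       sites = SYNTHETIC_SITES,
       regions = c(ISSN1_region = ISSN1_REGION_32,
                   ISSN1_target18 = ISSN1_TARGET_18,
                   ISSN1_target20 = ISSN1_TARGET_20),
       site_truth = site_truth)
}
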