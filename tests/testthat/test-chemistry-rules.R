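test_that("longest_modification_run reads the chemistry layout", {
  expect_equal(longest_modification_run(F18MOE, "MOE"), 18)
  expect_equal(longest_modification_run(fx$asos[["OMe1-12"]], "MOE"), 6)
  expect_equal(longest_modification_run(fx$asos[["OMe1-12/16-18"]], "MOE"), 3)
  expect_equal(longest_modification_run(F18MOE, "OME"), 0)
})

test_that("hard constraints gate on runs, seed and canonical floor", {
  pol <- site_policy()
  wt <- feature_summary(align_duplex(F18MOE, fx$sites[["POLR2H_WT"]]))
  expect_true(hard_constraints(wt, pol)$pass)

  # a 4-column non-canonical block is an unsurmountable zippering barrier
  blocky <- feature_summary(fake_alignment(c(rep("CANONICAL", 7),
                                             rep("MISMATCH", 4),
                                             rep("CANONICAL", 7))))
  hc <- hard_constraints(blocky, pol)
  expect_false(hc$pass)
  expect_true("contiguous-noncanonical" %in% hc$reasons)

  # 12 canonical pairs in an 18-mer fall below the floor of 13
  sparse <- feature_summary(fake_alignment(rep(c("CANONICAL", "CANONICAL",
                                                 "MISMATCH"), 6)))
  hc2 <- hard_constraints(sparse, pol)
  expect_false(hc2$pass)
  expect_true("min-canonical" %in% hc2$reasons)

  # no contiguous canonical seed of >= 5
  seedless <- feature_summary(fake_alignment(rep(c(rep("CANONICAL", 4),
                                                   "WOBBLE"), 4)))
  expect_true("min-seed" %in% hard_constraints(seedless, pol)$reasons)
})

test_that("site_policy validates threshold invariants", {
  expect_error(site_policy(min_seed = 2), "3..7")
  expect_error(site_policy(max_noncanonical_weak = c(MOE = 1, OME = 0,
                                                     PMO = 0, DNA = 0)),
               "weak budget")
})

test_that("competence encodes MOE mismatch tolerance and OMe intolerance", {
  pol <- site_policy()
  grade_of <- function(aso, site) {
    al <- align_duplex(aso, site)
    as.character(classify_competence(aso, al, pol)$grade)
  }
  expect_equal(grade_of(F18MOE, fx$sites[["POLR2H_WT"]]), "STRONG")
  expect_equal(grade_of(F18OMe, fx$sites[["POLR2H_WT"]]), "NONE")
  # full complementarity rescues the OMe chemistry
  expect_equal(grade_of(F18OMe, fx$sites[["POLR2H_M3"]]), "STRONG")
  # three MOE residues are not enough for the MOE-specific tolerance
  expect_true(grade_of(fx$asos[["OMe1-12/16-18"]],
                       fx$sites[["POLR2H_WT"]]) != "STRONG")
})

test_that("every validated off-target site is STRONG for the 18-mer MOE ASO", {
  pol <- site_policy()
  for (s in EIGHT_SITES) {
    al <- align_duplex(F18MOE, fx$sites[[s]])
    v <- classify_competence(F18MOE, al, pol)
    expect_equal(as.character(v$grade), "STRONG", label = s)
  }
  # and none of them is competent for the OMe 18-mer
  for (s in EIGHT_SITES) {
    al <- align_duplex(F18OMe, fx$sites[[s]])
    v <- classify_competence(F18OMe, al, pol)
    expect_equal(as.character(v$grade), "NONE", label = s)
  }
})

test_that("truncation series loses off-target competence but keeps on-target", {
  ser_wt <- competence_series(fx$asos[c("F18MOE", "F14MOE", "F10MOE")],
                              fx$sites[["POLR2H_WT"]])
  expect_equal(ser_wt$grade, c("STRONG", "NONE", "NONE"))

  # the 14-mer regains (at least partial) competence once the mismatches are
  # corrected; the 18-mer stays at least as strong
  ser_m1 <- competence_series(fx$asos[c("F18MOE", "F14MOE")],
                              fx$sites[["POLR2H_M1"]])
  expect_equal(ser_m1$grade[1], "STRONG")
  expect_true(ser_m1$grade[2] %in% c("WEAK", "STRONG"))

  # any variant is STRONG on its own perfect antisense
  for (nm in c("F18MOE", "F14MOE", "L10MOE", "OMe10-15")) {
    a <- fx$asos[[nm]]
    site <- antisense_of(paste(a$pairing, collapse = ""))
    al <- align_duplex(a, site)
    expect_equal(as.character(classify_competence(a, al)$grade), "STRONG",
                 label = nm)
  }
})

test_that("verdicts are monotone in complementarity and chemistry", {
  pol <- site_policy()
  lv <- c(NONE = 1, WEAK = 2, STRONG = 3)
  grade_of <- function(aso, site) {
    lv[[as.character(classify_competence(aso, align_duplex(aso, site),
                                         pol)$grade)]]
  }
  # complementarity: WT -> M1 -> M3 and WT -> M2 -> M3 never lose grade
  for (aso in list(F18MOE, F18OMe)) {
    g <- vapply(c("POLR2H_WT", "POLR2H_M1", "POLR2H_M3"), function(s)
      grade_of(aso, fx$sites[[s]]), numeric(1))
    expect_true(all(diff(g) >= 0))
    g2 <- vapply(c("POLR2H_WT", "POLR2H_M2", "POLR2H_M3"), function(s)
      grade_of(aso, fx$sites[[s]]), numeric(1))
    expect_true(all(diff(g2) >= 0))
  }
  # chemistry: identical sequence and alignment, OMe grade <= MOE grade
  seqs <- paste(F18MOE$pairing, collapse = "")
  moe <- aso_definition("probe", seqs, "MOE", "PS")
  ome <- aso_definition("probe", seqs, "OME", "PS")
  for (s in names(fx$sites)) {
    expect_lte(grade_of(ome, fx$sites[[s]]), grade_of(moe, fx$sites[[s]]))
  }
})

test_that("every ISS-N1-targeting fixture ASO is STRONG on its own footprint", {
  target <- fx$regions[["ISSN1_target18"]]
  variants <- setdiff(names(fx$asos), c("ScrMOE", "ScrOMe", "ScrPMO",
                                        "F20PMO"))
  for (nm in variants) {
    a <- fx$asos[[nm]]
    off <- attr(a, "footprint_offset")
    if (is.null(off)) off <- 0
    site <- substr(target, off + 1, off + aso_length(a))
    al <- align_duplex(a, site)
    expect_equal(as.character(classify_competence(a, al)$grade), "STRONG",
                 label = nm)
  }
  # the 20-mer morpholino is STRONG on its 20-nt target
  al <- align_duplex(fx$asos$F20PMO, fx$regions[["ISSN1_target20"]])
  expect_equal(as.character(classify_competence(fx$asos$F20PMO, al)$grade),
               "STRONG")
})

test_that("classify_competence rejects mismatched ASO/alignment pairs", {
  al <- align_duplex(F18MOE, fx$sites[["POLR2H_WT"]])
  expect_error(classify_competence(F18OMe, al), "produced for ASO")
})
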