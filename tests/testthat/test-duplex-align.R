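test_that("a perfect 18-mer duplex is all-canonical with maximal score", {
  al <- align_duplex(F18MOE, fx$regions[["ISSN1_target18"]])
  f <- feature_summary(al)
  expect_equal(f$n_canonical, 18)
  expect_equal(f$n_noncanonical, 0)
  expect_equal(f$max_canonical_run, 18)
  expect_equal(al$score, 36)
})

test_that("the POLR2H-like site shows 14 canonical, 2 mismatches, 2 wobbles", {
  al <- align_duplex(F18MOE, fx$sites[["POLR2H_WT"]])
  f <- feature_summary(al)
  expect_equal(f$n_canonical, 14)
  expect_equal(f$n_mismatch, 2)
  expect_equal(f$n_wobble, 2)
  expect_equal(f$n_bulge, 0)
  expect_equal(f$n_noncanonical, 4)
  # mismatches sit toward the ASO 3' end, wobbles mid-duplex
  cols <- al$columns
  mm_aso <- cols$aso_pos[cols$class == "MISMATCH"]
  wob_aso <- cols$aso_pos[cols$class == "WOBBLE"]
  expect_true(all(mm_aso >= 16))          # 3'-terminal third of the 18-mer
  expect_true(all(wob_aso >= 5 & wob_aso <= 12))
})

test_that("feature_summary computes run lengths over the column sequence", {
  f <- feature_summary(fake_alignment(c("CANONICAL", "CANONICAL", "MISMATCH",
                                        "WOBBLE", "CANONICAL")))
  expect_equal(f$max_noncanonical_run, 2)
  expect_equal(f$max_canonical_run, 2)
  expect_equal(f$n_noncanonical, 2)
  f2 <- feature_summary(fake_alignment(rep("CANONICAL", 18)))
  expect_equal(f2$n_canonical, 18)
  expect_equal(f2$max_canonical_run, 18)
  # bulges count toward non-canonical runs and the bulged-nt tally
  f3 <- feature_summary(fake_alignment(c("CANONICAL", "ASO_BULGE",
                                         "TARGET_BULGE", "CANONICAL")))
  expect_equal(f3$n_bulge, 2)
  expect_equal(f3$max_noncanonical_run, 2)
})

test_that("align_duplex matches the exhaustive oracle on random instances", {
  set.seed(402)
  for (k in 1:200) {
    n <- sample(8:10, 1)
    m <- n + sample(0:4, 1)
    aso <- random_aso(n)
    win <- random_dna(m)
    a1 <- align_duplex(aso, win)
    a2 <- oracle_align(aso, win)
    f1 <- feature_summary(a1)
    f2 <- feature_summary(a2)
    expect_equal(a1$score, a2$score)
    expect_equal(f1$n_canonical, f2$n_canonical)
    expect_equal(f1$n_wobble, f2$n_wobble)
    expect_equal(f1$n_mismatch, f2$n_mismatch)
    expect_equal(f1$n_bulge, f2$n_bulge)
    expect_equal(a1$target_span[[1]], a2$target_span[[1]])
  }
})

test_that("zero bulge budget reduces to the best gapless offset", {
  params0 <- scan_params(max_bulged_nt = 0)
  set.seed(77)
  for (k in 1:30) {
    n <- sample(8:10, 1)
    m <- n + sample(0:5, 1)
    aso <- random_aso(n)
    win <- random_dna(m)
    # independent gapless enumeration
    wchars <- strsplit(gsub("U", "T", toupper(win)), "")[[1]]
    achars <- rev(aso$pairing)
    best <- -Inf
    for (off in 0:(m - n)) {
      cls <- pair_class(achars, wchars[off + seq_len(n)])
      sc <- sum(c(CANONICAL = 2, WOBBLE = 1, MISMATCH = -1)[cls])
      best <- max(best, sc)
    }
    expect_equal(align_duplex(aso, win, params0)$score, best)
  }
})

test_that("restoring complementarity is monotone (M-series and random edits)", {
  counts <- vapply(c("POLR2H_WT", "POLR2H_M1", "POLR2H_M2", "POLR2H_M3"),
                   function(s) {
                     feature_summary(align_duplex(F18MOE,
                                                  fx$sites[[s]]))$n_canonical
                   }, numeric(1))
  expect_equal(unname(counts), c(14, 16, 16, 18))
  scores <- vapply(c("POLR2H_WT", "POLR2H_M1", "POLR2H_M2", "POLR2H_M3"),
                   function(s) align_duplex(F18MOE, fx$sites[[s]])$score,
                   numeric(1))
  expect_true(all(diff(unname(scores)[c(1, 2, 4)]) >= 0))
  expect_true(all(diff(unname(scores)[c(1, 3, 4)]) >= 0))

  # converting any mismatch column's target base to the canonical complement
  # never decreases score or canonical count
  site <- fx$sites[["POLR2H_WT"]]
  al <- align_duplex(F18MOE, site)
  mm <- al$columns[al$columns$class == "MISMATCH", ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in seq_len(nrow(mm))) {
    fixed <- site
    aso_base <- F18MOE$pairing[mm$aso_pos[r]]
    substr(fixed, mm$target_pos[r], mm$target_pos[r]) <- comp[[aso_base]]
    al2 <- align_duplex(F18MOE, fixed)
    expect_gte(al2$score, al$score)
    expect_gte(feature_summary(al2)$n_canonical,
               feature_summary(al)$n_canonical)
  }
})

test_that("alignment respects the semi-global contract", {
  set.seed(9)
  for (k in 1:20) {
    n <- sample(8:12, 1)
    aso <- random_aso(n)
    win <- random_dna(n + sample(0:6, 1))
    al <- align_duplex(aso, win)
    cols <- al$columns
    # every ASO position exactly once
    expect_setequal(cols$aso_pos[!is.na(cols$aso_pos)], seq_len(n))
    # antiparallel: target positions increase, ASO positions decrease
    expect_true(all(diff(cols$target_pos[!is.na(cols$target_pos)]) > 0))
    expect_true(all(diff(cols$aso_pos[!is.na(cols$aso_pos)]) < 0))
    # no column pairs two gaps
    expect_false(any(is.na(cols$aso_pos) & is.na(cols$target_pos)))
    # feature conservation
    f <- feature_summary(al)
    aso_bulged <- sum(cols$class == "ASO_BULGE")
    expect_equal(f$n_canonical + f$n_wobble + f$n_mismatch, n - aso_bulged)
    expect_lte(f$max_canonical_run, f$n_canonical)
  }
})

test_that("too-short windows are rejected", {
  expect_error(align_duplex(F18MOE, "ACGTACGT"), "shorter")
  expect_error(oracle_align(random_aso(8), random_dna(19)), "limited")
  expect_error(oracle_align(random_aso(13), random_dna(14)), "limited")
})

test_that("the oracle applies the leftmost tie-break", {
  # an 8-mer against a window offering two equivalent registers: leftmost wins
  aso <- aso_definition("tie", "ACGTACGT", "MOE", "PS")
  win <- paste0(antisense_of("ACGTACGT"), antisense_of("ACGTACGT"))
  al <- align_duplex(aso, win)
  expect_equal(al$target_span[[1]], 1)
  or <- oracle_align(aso, substr(win, 1, 16))
  expect_equal(or$target_span[[1]], 1)
})
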