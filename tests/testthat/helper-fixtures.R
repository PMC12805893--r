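# Shared fixtures for the test suite.

fx <- fixture_catalogue()
F18MOE <- fx$asos$F18MOE
F18OMe <- fx$asos$F18OMe

# the eight validated off-target sites (synthetic stand-ins)
EIGHT_SITES <- c("POLR2H_WT", "PITHD1", "SERPINB7", "RTTN", "REV3L",
                 "PRKRA", "GOLGA4", "PAK1")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aso <- function(n, name = "rnd") {
  aso_definition(name, random_dna(n), "MOE", "PS")
}

# Build a duplex_alignment by hand from a vector of pair classes; used to
# unit-test feature/run arithmetic independently of the aligner.
fake_alignment <- function(classes, aso_name = "fake") {
  n_aso <- sum(classes != "TARGET_BULGE")
  aso_pos <- rep(NA_real_, length(classes))
  aso_pos[classes != "TARGET_BULGE"] <- seq(n_aso, 1)
  target_pos <- rep(NA_real_, length(classes))
  target_pos[classes != "ASO_BULGE"] <- seq_len(sum(classes != "ASO_BULGE"))
  structure(list(aso_name = aso_name, target_id = "fake",
                 target_span = c(start = 1, end = sum(classes != "ASO_BULGE")),
                 strand = "+",
                 columns = data.frame(aso_pos = aso_pos,
                                      target_pos = target_pos,
                                      class = classes,
                                      stringsAsFactors = FALSE),
                 score = NA_real_),
            class = "duplex_alignment")
}
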