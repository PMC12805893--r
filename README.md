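# asoscreen

Off-target annealing and splice-switching analysis for antisense
oligonucleotides (ASOs).

Splice-switching ASOs act by base-pairing to a pre-mRNA element and blocking
it sterically. An ASO with high affinity chemistry — such as the fully
2'-O-methoxyethyl (MOE) modified, phosphorothioate 18-mer that targets the
ISS-N1 silencer in *SMN2* intron 7 — tolerates mismatches, G-T/G-U wobble
pairs and small bulges, and can therefore also anneal to ISS-N1-like
sequences inside other exons. When those sequences act as exonic splicing
enhancers, sequestering them causes off-target exon skipping. `asoscreen` is
for researchers designing or evaluating such ASOs: it predicts candidate
annealing sites, judges whether each site is competent to act under a given
sugar chemistry, and quantifies the downstream splicing and expression
readouts.

## What it implements

* **Duplex scanning** — a semi-global aligner (whole ASO, free target ends,
  antiparallel) scoring canonical pairs +2, wobbles +1, mismatches −1, with
  affine penalties for up to 2 interior bulged nucleotides
  (`align_duplex()`, `scan_sequence()`), plus a strict gapless Hamming mode
  for large screens (`scan_mismatch_only()`) and an exhaustive enumeration
  oracle used by the test suite (`oracle_align()`).
* **Chemistry competence rules** — a site passes hard constraints (≥ 13 of 18
  canonical pairs, length-scaled for shorter ASOs; no non-canonical run
  longer than 3; a contiguous canonical seed of ≥ 5) and is then graded
  NONE/WEAK/STRONG from per-chemistry non-canonical budgets (MOE tolerates up
  to 5; OMe and PMO essentially none unless complementarity is perfect) and
  a minimum uninterrupted MOE block of 6 (`site_policy()`,
  `classify_competence()`, `competence_series()`).
* **Splicing/expression quantification** — length-normalized PSI from
  inclusion/skipping junction counts, a two-binomial likelihood-ratio test
  per event, Benjamini–Hochberg FDR, and the three event post-filters
  (FDR < 0.05, |ΔPSI| ≥ 0.1, ≥ 10 average junction reads per isoform in one
  group); gel-densitometry percent inclusion; ΔΔCt relative expression;
  differential-expression table summaries (`analyze_splice_events()`,
  `filter_events()`, `gel_percent_inclusion()`,
  `ddct_relative_expression()`, `summarize_de_table()`).
* **Synthetic data with known truth** — planted target sites with controlled
  mismatches/wobbles/bulges, junction-count tables with planted ΔPSI
  effects, qPCR tables with planted fold changes
  (`plant_target_site()`, `simulate_event_table()`,
  `simulate_qpcr_table()`), and a packaged fixture catalogue
  (`fixture_catalogue()`). Off-target site fixtures are *synthetic*
  reconstructions matching published duplex feature counts, and are labeled
  as such.

## Worked example

```r
library(asoscreen)
fx <- fixture_catalogue()

# align the 18-mer MOE ASO against the synthetic POLR2H-exon-2-like site
al <- align_duplex(fx$asos$F18MOE, fx$sites[["POLR2H_WT"]])
feature_summary(al)
#> <duplex_features> canonical 14, wobble 2, mismatch 2, bulged nt 0 |
#>   longest canonical run 5, longest non-canonical run 1

classify_competence(fx$asos$F18MOE, al)
#> <competence_verdict> STRONG (moe-tolerance)

# the same sequence with OMe sugars is not competent on the imperfect site
al2 <- align_duplex(fx$asos$F18OMe, fx$sites[["POLR2H_WT"]])
classify_competence(fx$asos$F18OMe, al2)
#> <competence_verdict> NONE (budget-exceeded-OME)
```

The duplex keeps 14 of 18 canonical pairs, with the two mismatches facing
the ASO 3' end and the two wobbles mid-duplex; that pattern fits the MOE
non-canonical budget (grade STRONG) but exceeds the OMe budget (grade NONE),
reproducing the chemistry-specific behavior seen experimentally. A full
scan → classify → filter run over FASTA/BED/TSV inputs is available through
`run_pipeline()`.

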