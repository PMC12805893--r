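---
title: "Methods: duplex scanning, chemistry rules and splicing quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex scanning, chemistry rules and splicing quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asoscreen)
```

## The problem

Splice-switching antisense oligonucleotides (ASOs) act by annealing to a
pre-mRNA element and sterically blocking it. The therapeutically important
example modeled throughout this package is the 18-mer, fully
2'-O-methoxyethyl (MOE) modified, phosphorothioate ASO that sequesters the
intronic splicing silencer ISS-N1 in *SMN2* intron 7 and thereby restores
exon 7 inclusion in spinal muscular atrophy. The same tolerance for imperfect
base pairing that makes an MOE ASO potent on its intended target lets it
anneal to ISS-N1-like sequences inside other exons, where those sequences act
as exonic splicing enhancers; sequestering them causes off-target exon
skipping. `asoscreen` implements the computational side of that analysis:

1. a mismatch-, wobble- and bulge-tolerant duplex aligner and scanner
   (`align_duplex()`, `scan_sequence()`, `scan_mismatch_only()`);
2. chemistry-specific competence rules deciding whether an imperfect site can
   act (`classify_competence()`, `site_policy()`);
3. the downstream quantification stages: percent-spliced-in (PSI) event
   filtering, gel densitometry, delta-delta-Ct, and differential-expression
   table summaries;
4. a synthetic-data generator with planted, recoverable ground truth.

## Duplex model

An ASO of length $n$ is aligned semi-globally against a target window: every
ASO residue occupies exactly one alignment column, the target ends are free,
and pairing is antiparallel. Each column is classified as

* `CANONICAL` — Watson–Crick complement (T and U equivalent; 5-methyl-C pairs
  as C),
* `WOBBLE` — G paired with T/U on either strand,
* `MISMATCH` — anything else (degenerate bases such as N mismatch
  everything),
* `ASO_BULGE` / `TARGET_BULGE` — an unpaired residue on one strand.

Default column scores are +2 canonical, +1 wobble, −1 mismatch, with bulges
costing −3 to open and −1 to extend, at most 2 bulged nucleotides in total,
and a reporting floor of `min_score = 26`. Wobble sits between canonical and
mismatch because wobble pairs, although nearly isosteric with canonical
pairs, are observed to be less well tolerated in ASO annealing than their
thermodynamic stability suggests. The floor of 26 is twice 13, the canonical
pair count of the weakest imperfect site validated to act in cells, so every
validated duplex clears it while near-random windows do not. These numbers
are conventions, not measurements — the published annealing diagrams were
drawn by inspection — and all of them are configurable through
`scan_params()`.

Bulges are *interior*: the duplex proper begins and ends with a base pair,
and a terminal unpaired residue is treated as a dangling end rather than an
alignment column. Ties between equal-scoring alignments are broken by (1)
more canonical pairs, (2) fewer bulged nucleotides, (3) leftmost target
start. The dynamic program in `align_duplex()` optimizes exactly this
lexicographic objective, and `oracle_align()` — a brute-force enumeration of
every admissible alignment, used only in tests — implements the identical
rules so the two can be compared on hundreds of random instances.

`scan_mismatch_only()` is a separate, deliberately strict screening mode:
gapless, with wobbles counted as mismatches. It reproduces the
genome-screening observation that allowing more than two mismatches floods
the search with candidates; it is a Hamming scan against the ASO's reverse
complement and is suitable for large sequences.

## Chemistry competence rules

Experimental observations the rules encode:

* the fully MOE-modified 18-mer skips exons at sites carrying up to five
  non-canonical pairs (the weakest validated site keeps 13 of 18 canonical
  pairs);
* the same sequence with 2'-O-methyl (OMe) sugars has essentially no
  mismatch tolerance, and a morpholino (PMO) behaves like OMe;
* full complementarity rescues every chemistry;
* no validated site contains a non-canonical run longer than three columns —
  consistent with duplex nucleation by a 3–7 nt seed followed by zippering,
  which a long imperfect block interrupts;
* at least six uninterrupted MOE residues are required for the MOE-specific
  tolerance: a mixed-chemistry ASO with only a three-residue MOE block loses
  its off-target activity.

`site_policy()` turns these into thresholds: `min_canonical = 13`,
`max_contig_noncanonical = 3`, `min_seed = 5` (chosen inside the stated 3–7
range and exposed as a parameter because only the range is known),
per-chemistry non-canonical budgets (strong: MOE 5, OMe/PMO 0; weak: MOE 6,
OMe/PMO 2) and `min_moe_run = 6`. `classify_competence()` then grades a site
`NONE`, `WEAK` or `STRONG`. Each non-canonical column is charged against the
chemistry of the ASO residue in that column (nearest residue for a target
bulge). This per-column attribution is a modeling choice that generalizes the
positional findings of the mixed-chemistry series; the data show
exon-dependent position effects that a single rule cannot fully capture, so
the rule is documented as an approximation and every threshold is
configurable. The PMO budgets mirror OMe: the PMO was only shown to act on a
perfect or near-perfect site, and its wobble tolerance was not measured, so
the mirror is an assumption.

Two design points deserve emphasis:

* **Length scaling.** The canonical-pair floor was calibrated on 18-mers. A
  14-mer with two wobbles can carry at most 12 canonical pairs, yet such an
  ASO demonstrably regains activity when its mismatches are corrected. The
  policy therefore carries a `ref_length` (18) and scales the floor for
  shorter ASOs as `ceiling(min_canonical * length / ref_length)` — 11 for a
  14-mer, 8 for a 10-mer. This reproduces the truncation-series observations
  that short ASOs lose off-target activity on the imperfect site but stay
  active on their perfect target.
* **Known over-calls, kept.** The rule set predicts activity for a few
  site/ASO pairs that were experimentally quiet: the site keeping 14
  canonical pairs through two wobbles when targeted by the 3'-anchored
  14-mer, the 5'-anchored 10-mer on the mismatch-corrected site, both
  middle/3' 10-mers on the fully corrected site, and the GOLGA4-derived site
  (14 canonical pairs but only 40% skipping). These divergences are recorded
  rather than tuned away; fitting them would require position- and
  exon-specific terms the data do not constrain.

## Splicing and expression quantification

Per sample, PSI is the length-normalized inclusion fraction
$\psi = (I/l_I) / (I/l_I + S/l_S)$ from inclusion ($I$) and skipping ($S$)
junction counts; effective lengths default to 1. Candidate events pass three
post-filters: FDR (Benjamini–Hochberg, `bh_adjust()`) below 0.05, absolute
PSI change of at least 0.1, and at least 10 average junction reads supporting
*each* isoform in at least one sample group. The support rule is read
same-group (one group must support both isoforms); the alternative
each-isoform-in-any-group reading is noted as an ambiguity of the verbal
rule. The per-event p-value comes from a pooled-binomial likelihood-ratio
test (`delta_psi_test()`); this is an explicit stand-in for the paired
likelihood model of dedicated junction-count software, so survivor identity
may differ at the margin while the three filters are applied exactly.

Gel densitometry divides each isoform's band intensity by the lane total
(`gel_percent_inclusion()`). Relative expression uses the delta-delta-Ct
method with a reference transcript as normalizer: condition-mean
$\Delta Ct$, not per-replicate RQ averaging, and $RQ = 2^{-\Delta\Delta Ct}$
(`ddct_relative_expression()`). Differential-expression tables are
summarized at adjusted $p < 0.05$ and $|log_2 FC| > 1$
(`summarize_de_table()`).

## Synthetic data and what it does (not) show

`plant_target_site()` embeds an edited copy of an ASO's perfect annealing
site in i.i.d. background sequence (configurable GC, default 0.5). Edits are
mismatches (substituting a base that pairs with neither the facing ASO
residue nor, where avoidable, its neighbors), wobble swaps (canonical →
G-T), insertions and deletions. The flank positions bordering the footprint
are set to bases that pair as weakly as possible with the ASO ends —
otherwise random flanks occasionally extend the duplex through a bulge and
the recorded truth would not be the scan optimum. `simulate_event_table()`
draws per-sample junction totals as Poisson around a target depth and
inclusion counts as binomial (optionally beta-binomial) at the group PSI;
planted events differ by a fixed PSI offset with randomized direction.
`simulate_qpcr_table()` shifts target Ct by minus the planted log2 fold
change with Gaussian cycle noise.

These generators emulate controlled, idealized versions of the real inputs:
no transcript structure or RNA secondary structure in the backgrounds, no
overdispersion beyond the optional beta-binomial, no library-size or mapping
artifacts in the counts. Passing tests therefore demonstrate that the
algorithms recover planted truth under their own model assumptions — not
that the biological study's numbers are reproduced, since its wet-lab
percentages are measurements, not computable quantities.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in every report and 0-based half-open in
  BED I/O; `bed_to_report_coords()` / `report_to_bed_coords()` convert.
* Sequences are normalized internally to an uppercase T-alphabet (U → T,
  mC → C); display keeps original tokens. N scores as a mismatch against
  everything.
* Events with no reads in a group give an undefined PSI/p-value and are
  dropped by the filter with a logged reason; lanes with zero total signal
  and qPCR records without a normalizer Ct are rejected or excluded
  likewise.
* `delta_psi_test()` returns exactly 1 when both groups have identical
  pooled proportions (the LR statistic is 0).
* Mixed-chemistry block positions are numbered from the ASO 3' end, matching
  the naming convention of that series (`OMe1-6` = the six 3'-terminal
  residues); 5'-based slices are what `aso_definition()` stores internally.

## Problem sizes

The test-suite and acceptance computations run at desk scale by design:
oracle-equivalence checks use 8–10-mer ASOs against windows of up to 14 nt
(200 random instances), planted-site scans use a few hundred nucleotides of
background, event-table simulations use 200–300 events at 3 + 3 samples and
around 100 reads of depth, and the null-calibration study uses 2000
simulated events. These sizes give the properties under test binomial error
bars far tighter than the thresholds being checked.

## Worked example

```{r example}
fx <- fixture_catalogue()
al <- align_duplex(fx$asos$F18MOE, fx$sites[["POLR2H_WT"]])
feature_summary(al)
classify_competence(fx$asos$F18MOE, al)
classify_competence(fx$asos$F18OMe,
                    align_duplex(fx$asos$F18OMe, fx$sites[["POLR2H_WT"]]))
```

## Limitations

* No thermodynamics: the scorer counts pair classes; it does not estimate
  binding free energy or melting temperature, and target-site structural
  accessibility is out of scope.
* The competence rules are qualitative (NONE/WEAK/STRONG), not dose–response
  predictions.
* The event-level p-value is a generic two-binomial LR test, not a clone of
  any specific junction-count model.
* Fixture target sites other than the ISS-N1 region are synthetic stand-ins
  constructed to match published duplex feature counts; they are labeled as
  such wherever they appear and must not be mistaken for genomic sequence.
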