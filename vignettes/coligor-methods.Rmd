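---
title: "Methods: barcode design, contamination tracing, and spike-in normalization in coligor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode design, contamination tracing, and spike-in normalization in coligor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coligor)
```

coligor is laboratory informatics for highly multiplexed amplicon sequencing
on microtiter plates. It covers four connected problems: (i) designing
variable-length dual-index barcodes (MIDs) and error-correcting well tracers
(coligos), (ii) demultiplexing paired reads that carry those barcodes inline,
(iii) quantifying well-to-well cross-contamination from tracer counts, and
(iv) rescaling compositional count tables with an internal standard (ISD) so
that within-taxon comparisons across samples become abundance-proportional.
A read-level simulator closes the loop: every analysis in the package can be
tested against generated data with known truth. This vignette explains the
models and the design decisions behind each part.

## Read structure and dual indexing

Each library molecule has the layout

```
R1:  [forward MID, 8-10 nt][forward primer][template ...]
R2:  [reverse MID, 8-10 nt][reverse primer][template, reverse strand ...]
```

Sample identity is the ordered pair of forward and reverse MIDs, so n MIDs
per side index `n^2` replicates (`dual_index_capacity(96, 96)` = 9,216).
Because the MIDs are sequenced inline rather than in separate index reads,
assignments are immune to index hopping on patterned flow cells, and the
mixture of MID lengths injects base diversity into the first sequencing
cycles, which reduces the amount of PhiX needed.

## MID design rules

`generate_mid_set()` builds MID sets by seeded rejection sampling under
explicit constraints, and `validate_mid_set()` re-checks any set against the
same constraints. The defaults are:

* **Same-length Levenshtein distance >= 2.** Two MIDs of equal length
  within one edit of each other could be silently confused by a single
  sequencing error; at distance 2, one error is either corrected uniquely or
  surfaces as a tie and the read is dropped as ambiguous.
* **Cross-length Levenshtein distance >= 3.** This constraint is easy to
  miss and is stronger than forbidding prefix relations. Consider an 8-mer
  MID `s` read with one inserted base at its end. The read now begins with
  nine bases. If any legal 9-mer MID sits within one edit of `s` plus that
  base — which a prefix ban alone does not prevent — the matcher sees a
  valid 9-mer with an *exact* primer right after it, and the read migrates
  to the wrong sample. Requiring distance >= 3 between MIDs of different
  lengths makes every single-edit read window at least 2 edits from any
  wrong MID, so a wrong candidate can never be accepted at tolerance 1.
  The package's test suite proves the property by exhaustively applying
  every possible substitution, insertion and deletion to every MID of a
  96+96 set and checking that no read is ever assigned to a different
  sample (it is either corrected or dropped).
* **Homopolymers capped at 3 and GC between 30 and 70%**, standard
  synthesis- and sequencing-friendliness heuristics.

Generation is deterministic given a seed and raises an error (naming the
budget and the partial count achieved) if the candidate budget is exhausted,
so infeasible requests fail loudly rather than loop forever.

## Coligos: one tracer per well

A coligo is a synthetic oligonucleotide added (ideally before DNA
extraction) to each well: a unique 13-nt identifier bookended by sequence
complementary to the locus primers, so it is amplified and sequenced along
with real amplicons at whatever depth its spike concentration dictates.
After demultiplexing, the 13 bases following the forward primer identify the
tracer; forward reads alone are used because the short insert "staggers"
read merging.

Identifiers are generated at **pairwise Levenshtein distance >= 3**, the
minimum at which every single substitution, insertion or deletion is both
detectable and uniquely correctable. `extract_coligo_id()` therefore accepts
an exact 13-mer prefix or the unique identifier within one edit of a
12-14 nt window (the flex absorbs single indels); everything else is
unmatched. An exact-only mode (`max_edits = 0`) is available for
conservative counting.

Contamination analytics operate on the wells x coligos count matrix:

* `contamination_report()` gives per-well expected/foreign read counts, the
  proportion of coligo reads that are the expected tracer, the number of
  distinct foreign tracers, and plate-level summaries (fraction of wells
  with any or multiple foreign tracers, the median foreign proportion, the
  overall fraction of out-of-place coligo reads). Wells with zero coligo
  reads have no defined proportion; they are excluded from medians and
  tallied separately rather than imputed, because dividing by zero coligo
  reads is undefined and such wells usually just have low depth.
  The evidence threshold `min_foreign_reads` defaults to 1 (any foreign
  read counts), but is exposed because a single read may itself be a
  sequencing artifact.
* `contamination_distance_profile()` turns every (recipient well, foreign
  coligo) pair into an event at the Euclidean distance between the tracer's
  home well and the recipient, in well-pitch units with row and column
  pitch treated as equal, rounded half away from zero. Multiple foreign
  tracers in one well contribute multiple events.
* `detect_plate_rotation()` compares the fraction of coligo reads matching
  expectation under the as-given layout and under the 180-degree rotation
  (the only physically possible misorientation of a rectangular plate).
  The score is read-weighted rather than well-weighted so that deep wells
  dominate, which is robust to uneven depth; an exact tie keeps the
  as-given orientation and records a warning.
* `estimate_event_fractions()` estimates each event's migrated pool
  fraction as the ratio of the foreign tracer's read fraction in the
  recipient to the same tracer's read fraction in its home well; read-depth
  differences cancel. The estimate carries a mild attenuation of
  `m/(1+m)` for a true migrated fraction `m`, because migration inflates
  the recipient's pool; for the percent-level events of interest this is
  within a few percent of unity.

## The k-of-n mixture alternative

An earlier tracer scheme combines k oligos from a panel of n into per-well
mixtures (`enumerate_mixtures(12, 3)` yields the classic 220).
`mixture_detectability()` quantifies its key weakness by exhaustive
enumeration: an event is only unambiguously attributable when exactly one
candidate donor (set) reproduces the observed foreign oligos. For the
unrestricted 220-mixture scheme and single donors the package's enumeration
equals the closed form C(9,3)/219 (about 38%): only donors fully disjoint
from the recipient's mixture are identifiable. Detectability depends
strongly on which mixtures share oligos with which, hence on the plate
arrangement; `assign_mixtures_to_plate()` implements the greedy
max-min-symmetric-difference placement, but the package deliberately does
not tune placement toward any particular detectability figure. One coligo
per well makes every single-donor event attributable, which is why the
13-nt identifier design is the primary scheme here.

## Demultiplexing policy

The matcher is primer-anchored and longest-length-first. For each candidate
MID length L (descending), the leading L bases are scored against all MIDs
of that length (edit distance, tolerance `max_mid_edits = 1` by default,
which must stay below the set's minimum same-length distance) and the
primer against the bases that follow (IUPAC-aware, substitutions only,
tolerance `max_primer_mismatches = 2`). The first length with an acceptable
candidate wins, and within it the unique minimizer of (MID edits, primer
mismatches); ties are reported as `ambiguous_mid`, not guessed. Primer
indels are not modelled by default — the primer is an anchor, not a target
of correction — which keeps matching fast and makes the safety argument
above airtight for primers without strong self-shift similarity (true of
the standard 16S/ITS primers). Both mates must agree on the locus
(`locus_conflict` otherwise), and the (forward, reverse) MID pair must
exist on the sample sheet (`unknown_pairing` otherwise). Reads are trimmed
of MID+primer on both mates, qualities identically; read-count conservation
(assigned plus every unassigned reason equals input) is asserted on every
run.

## ISD normalization

Sequencers emit compositions: per-sample counts are constrained by a
sequencing-depth total, so a change in one taxon's relative abundance
confounds changes in the taxon with changes in everything else. Spiking the
same known quantity of a reference molecule (the ISD) into every replicate
restores a usable scale: for taxon i in a sample, `y_i = x_i / x_ISD` is
invariant to the sample's total count (counts and proportions give the same
ratio), and `y_i` times the known spike amount estimates absolute
abundance in the spike's unit. The package deliberately supports only
within-taxon, across-sample comparisons: between-taxon comparisons remain
confounded by ribosomal copy-number and amplification-efficiency
differences, and no API is offered for them.

Denoising typically shatters a spike-in into several sequence variants, so
`match_isd_esvs()` identifies all features whose global (Needleman-Wunsch)
alignment to the ISD reference reaches 95% identity and 90% length coverage
(both exposed as arguments; the thresholds are conventional, not derived),
and `collapse_isd()` sums them into a single ISD feature, conserving
per-sample totals. Samples with zero ISD counts are flagged `no_isd` and
left undefined by default; an optional pseudocount (added to the ISD count
only) exists but is off, because inventing an ISD observation silently
biases every ratio in the sample. Coligo features are excluded from
normalized output: their replicate-to-replicate count variation makes them
tracers, not standards.

`isd_dilution_check()` verifies quantitative spike-in behaviour across a
dilution series by regressing `log10(p / (1 - p))` — the read-count odds of
the ISD — on `log10(amount)`. Odds, unlike proportions, stay proportional
to the spiked amount over the whole range (proportions saturate as the
spike dominates), so the expected slope is exactly 1 across many orders of
magnitude. Levels with zero ISD reads are excluded and reported.

## The simulator

`sim_config()` / `simulate_plate()` / `simulate_reads()` generate a plate
with known truth:

* per-well communities: log-normal taxon abundances (defaults meanlog 0,
  sdlog 1 over 30 taxa) over fixed random reference amplicons;
* spikes as expected molecule fractions — coligo 1e-4 and ISD 1e-3 by
  default, so realized read fractions land in the small-percentage band
  typical of low-level spiking. Spikes are parameterized as molecule
  fractions rather than mass concentrations; mass-to-molarity conversion
  is out of scope;
* contamination: each event moves a Beta-distributed fraction (default
  Beta(1, 499), i.e. ~0.2% of a pool) of a donor's pre-contamination pool
  into a recipient. The donor is drawn with probability proportional to
  `(1 - eps) * exp(-d / lambda) + eps * uniform`: an exponential decay with
  distance capturing the dominance of near-neighbour transfer, plus a
  uniform floor for the long-range events that do occur. This kernel is a
  modelling stand-in chosen for testability — real contamination processes
  are observational and no quantitative generative model is established;
* reads: negative-binomial depth per well (default mean 2000,
  dispersion 10), multinomial molecule sampling, constant qualities,
  per-base substitution (default 0.1%) and indel (default 0.01%) errors
  applied after read construction. Templates shorter than the read
  (coligos) are padded 3' with an adapter stub and random bases to model
  read-through. Identical configurations produce byte-identical FASTQ.

What the simulator does *not* emulate: chimeras, cycle-dependent quality
profiles, instrument-specific error spectra, PCR amplification bias (a
per-template efficiency hook exists but defaults to 1), or extraction
biases. Passing closed-loop tests therefore demonstrates the correctness of
the package's algorithms under the stated read structure, not robustness to
every artifact of real libraries.

`simulate_coligo_counts()` samples the well-by-coligo count matrix directly
from the pools — the identical depth and multinomial model as
`simulate_reads()`, skipping FASTQ serialization — and is used for the
larger contamination-recovery experiments; read-level pipeline closure is
separately exercised end to end. `dilution_series()` generates the ISD
dilution design: a fixed mock-community background with the ISD's molecule
mass proportional to the spike amount across levels (defaults: 6 levels,
depth ~66,000 reads per level).

## Verification problem sizes

The shipped test suite runs the whole battery in well under a minute of CPU:
closed-loop demultiplexing on a 96-well plate at about 10^5 read pairs (zero
error: 100% correct wells; 0.5% substitutions: zero misassignments among
assigned reads), 200 injected contamination events across 20 simulated
plates (all events leaving at least one sampled read are detected at
threshold 1; estimated versus true migrated fractions regress with slope
within [0.9, 1.1]), 50-table exact checks of scale invariance and
subcompositional coherence of the ISD ratio, a 6-level dilution spanning 5
orders of magnitude (log-odds slope within [0.9, 1.1], strictly monotone),
1,000 random-pair equivalence checks of the edit distance against an
independent dynamic-programming oracle, and exhaustive distance audits of
generated 96+96 MID and 96-coligo sets. `scripts/acceptance.R` recomputes
the same quantities from scratch at a caller-supplied seed.

## Numerical and degenerate-input conventions

Rounding of distances is half-away-from-zero. Demultiplexing ties are
dropped, never guessed. Wells without coligo reads propagate `NA`
proportions, never zeros. Rotation ties keep the as-given orientation with
a warning. Zero-ISD samples stay undefined unless a pseudocount is
explicitly requested. Empty FASTQ inputs yield empty, zero-count results.
All tabular output is tab-separated UTF-8 with '.' decimals; all
randomness flows from explicit integer seeds.
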