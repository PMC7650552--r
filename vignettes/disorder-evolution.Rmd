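---
title: "Comparative analysis of intrinsic disorder: methods and design notes"
author: "disevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of intrinsic disorder: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disevo)
```

## Scope and model

Intrinsically disordered regions (IDRs) are stretches of a protein that
lack a stable globular fold.  Per-residue disorder predictors emit a
score in [0, 1] per residue; `disevo` consumes those score tracks (it
does not implement a predictor) and builds a comparative analysis on top
of them:

1. **IDR calling.**  A residue is disordered when its score meets the
   cutoff (default 0.5, compared with `>=`; predictors of this family
   treat 0.5 as the decision boundary, and the comparison direction is
   exposed as `strict` for users whose predictor documents `>`).  An IDR
   is a maximal run of at least `min_len = 30` consecutive disordered
   residues; shorter runs are ignored entirely.  A protein with at least
   one IDR is an intrinsically disordered protein (IDP).
2. **Proteome summaries.**  Two proteome-level measures: the *IDP
   fraction* (IDPs / proteins) and the *IDR fraction* (disordered
   residues / residues).  Because every downstream analysis operates on
   IDRs of 30+ residues, the default residue accounting
   (`residue_counting = "idr"`) counts residues inside called IDRs;
   counting all above-cutoff residues is available as
   `residue_counting = "flag"` and the choice is recorded in every
   summary row.  Proteomes with fewer than 300 proteins are dropped by
   `filter_proteomes()` before cross-species comparison, since very
   small proteomes make the fractions statistically unstable.
3. **Disorder conservation.**  Within an ortholog group (one protein
   per species, one-to-one), per-residue disorder flags are projected
   through the group's multiple sequence alignment, labelling each
   alignment column disordered / ordered / gap per row.  Conservation
   between the reference species (human by default) and an ortholog is
   the Jaccard index over columns: columns disordered in both divided
   by columns disordered in at least one.  A disordered residue aligned
   to a gap therefore counts against conservation (union only).  As a
   confounding check, `build_conservation_matrix()` also reports the
   per-species correlation between conservation and pairwise sequence
   identity (identical residues over mutually ungapped columns).
4. **Conservation clustering.**  Group-by-species conservation profiles
   are clustered with complete-linkage hierarchical clustering on
   Euclidean distances (`stats::dist` + `stats::hclust`), and the
   dendrogram is cut at `k` clusters or height `h`.
5. **PPI enrichment.**  For each cluster, the observed number of
   protein-protein interactions among its reference-species members is
   compared with the counts in equally sized node sets drawn uniformly
   without replacement from a background list (default 10000 draws).
   The z-score standardises the observation against the null mean and
   (n-1)-denominator standard deviation; a one-sided upper-tail normal
   p-value and an empirical p-value `(1 + #{sample >= obs}) / (1 + n)`
   are both reported.
6. **Compositionally biased regions (CBRs).**  For each of the 20
   amino-acid types, every residue is scored against a homopolymer of
   that type under BLOSUM62 (no gaps) and the maximal-scoring segment is
   computed.  Segments scoring at least the threshold (default 40,
   compared with `>=`) are accepted iteratively: after acceptance the
   occurrences of the bias type inside the segment are masked to the
   neutral token `X` (which scores 0 against everything) and the search
   repeats.  Types are independent, so CBRs of different types may
   overlap.
7. **Conservation patterns of CBRs.**  Per ortholog group and bias
   type, presence/absence across the species panel is encoded as a bit
   string in a fixed species order (e.g. `11000` = present in the two
   species closest to the reference only), irrespective of CBR position
   or count.  Pattern tables exclude all-zero rows by default since they
   record CBR occurrences.

## Parameters that matter

| parameter | default | unit / meaning |
|---|---|---|
| `cutoff` | 0.5 | disorder score threshold, `>=` |
| `min_idr_length` | 30 | residues; minimum IDR length |
| `min_proteins` | 300 | proteins; proteome-size filter |
| `cast_threshold` | 40 | BLOSUM62 segment score for CBR acceptance |
| `n_clusters` | 7 | dendrogram cut for conservation profiles |
| `ppi_samples` | 10000 | Monte-Carlo draws per enrichment test |

The species panel defaults to human (reference), mouse, zebrafish,
fruit fly and baker's yeast, in that order; binary patterns are written
in panel order and every output header repeats the order to prevent
silent bit-position drift.

## Numerical and design choices

* **Interval convention.**  All intervals (IDRs, CBRs) are 1-based
  closed integers, the native R and file-format convention; readers and
  writers therefore perform no coordinate shifts.
* **Tie-breaking in maximal segments.**  Among equal-scoring segments
  the leftmost start wins, then the shortest length; when every
  position scores negative the best segment is the leftmost maximum
  single position.  This makes CBR output deterministic and testable
  against an exhaustive enumerator.
* **Termination of CBR iteration.**  Masking removes the bias type's
  own (positive-diagonal) contributions, so the attainable score
  strictly decreases and iteration terminates.  In the rare case where
  an accepted segment contains *no* residue of the target type (its
  score produced entirely by similar residues, e.g. a long E-run
  scoring against Q), masking would not reduce the score; the segment
  is recorded and the iteration for that type stops.
* **Jaccard 0/0.**  When neither ortholog has a disordered column the
  index is undefined; `jaccard_disorder()` returns 1 (identical, empty
  disorder).  In reference-vs-IDP analyses the case cannot arise
  because the reference protein always has at least one IDR.
* **Degenerate nulls.**  A Monte-Carlo null with zero standard
  deviation (empty background network, or set size equal to the
  background) is flagged and yields `NA` z-scores rather than an
  error mid-pipeline.
* **Cluster determinism.**  Rows are sorted lexicographically by id
  before clustering, so the partition and its labels do not depend on
  input order.
* **Unknown residues.**  `X` is accepted everywhere, is scored like any
  residue for disorder masks (masks come from the score track, not the
  sequence), and is never a bias target type; it scores 0 against all
  types, which also makes it the natural masking token.
* **Cut choice.**  The number of conservation clusters is genuinely
  subjective (one wants homogeneous clusters that are not tiny);
  `cluster_rows()` exposes both `k` and `h` and defaults to `k = 7`,
  which suits a four-species comparison panel where profiles mix
  high/low conservation per species.

## The synthetic-data generator

Real inputs at the scale of full proteome databases (reference
proteomes, curated ortholog databases, interaction databases) cannot be
bundled or downloaded by a test suite, so every pipeline stage is
validated against generated data with planted ground truth:

* `simulate_proteome()` plants IDRs: a protein becomes an IDP with the
  configured probability and receives one contiguous high-score block
  (baseline U(0.68, 0.97)) on a low baseline (U(0.03, 0.32)), plus
  clipped Gaussian noise (sd 0.03 by default, keeping boundary
  crossings beyond five sigma so the planted truth is exact).
* `simulate_ortholog_set()` plants conservation archetypes.  The
  reference protein carries one IDR of length `D` (default 120); each
  ortholog's IDR is the same-length block shifted by
  `s = round(D (1 - t) / (1 + t))`, which makes the column Jaccard
  index exactly `(D - s) / (D + s) ~ t` for a target `t` drawn from the
  group's archetype with Gaussian noise (sd 0.05).  Ortholog sequences
  are the reference with per-species point substitutions, so sequence
  identity is controlled independently of disorder conservation -- by
  construction the two are uncorrelated, mirroring the confounding
  check.  Optional insertions (realised as gap columns in the other
  rows) are placed in the tail region past all disorder blocks, so they
  exercise gap handling without moving the planted scores.
* `plant_cbrs()` plants biased segments by replacing a window (length
  12, 80% target residue minimum, enough target residues that the
  segment scores at least threshold + 2 by construction) -- replacement
  rather than insertion keeps companion alignments valid.  Presence is
  drawn independently per species, or from a single gain event on the
  ladder lineage implied by the species order; single-gain evolution
  can never produce a pattern with an absence flanked by presences
  (no substring `101`).
* `simulate_ppi()` draws an Erdős–Rényi background (default 984 nodes,
  edge probability 0.005, matching a realistically sparse curated
  interactome restricted to an ortholog background) with one planted
  dense module (default 20 nodes at internal probability 0.5).

What the generator does **not** emulate: realistic amino-acid
substitution processes (substitutions are uniform), predictor noise
structure (real disorder scores are autocorrelated and concentrated
near the boundary), alignment errors, in-paralogs, weighted or
confidence-filtered interaction networks, and compositional skews of
unusual clades.  Passing tests therefore demonstrate algorithmic
correctness against the stated definitions, not robustness to every
artefact of real data.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen to make
sampling error negligible relative to the tested tolerances while
keeping a laptop run comfortable: 1000 random masks for the IDR-caller
oracle, 1000 mask pairs for the Jaccard oracle, 200 sequences (length
<= 120) for the CBR oracle, 200 ortholog groups (4 archetypes x 50) for
cluster recovery, 20 replicates of 10000 draws for planted-module
detection plus 400 random sets for null calibration, and 3100 groups
for the pattern-frequency check (expected count ~97 per pattern, 3-sigma
band ~+-29).

## Known limitations

* The CBR detector is a faithful *maximal-scoring-segment* formulation
  of compositional-bias detection ("CAST-style"); it does not claim
  bit-compatibility with any particular binary's iteration order.
* Groups missing a species are flagged by the reader and excluded from
  conservation and pattern analyses rather than imputed.
* `pairwise_identity()` is one of several possible identity
  definitions (identical columns over mutually ungapped columns); the
  definition is stated in output headers because published identity
  values rarely specify theirs.
* The one-sided normal p-value assumes the null edge-count distribution
  is approximately normal; for very sparse backgrounds or tiny sets the
  empirical p-value is the safer of the two reported values.
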