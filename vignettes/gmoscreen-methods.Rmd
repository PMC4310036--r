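---
title: "Simulating qPCR-based GMO screening from sequence: models and design choices"
author: "gmoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating qPCR-based GMO screening from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmoscreen)
```

## What the package models

A real-time PCR assay detects a GM event when (i) both primers anneal to the
template in convergent orientation close enough to amplify, and (ii) for
TaqMan assays, the probe hybridises within the amplified fragment. The
package models all three steps at the sequence level with bounded edit
counts, not thermodynamics: annealing tolerance is expressed as *at most 2
mismatches and at most 2 gap bases per primer site*, and candidate amplicons
must span 20–500 bp end to end (primer footprints included). These
tolerances are the established defaults of reverse electronic PCR screening
and are deliberately permissive: a perfect-score prediction (both primers
exact, probe exact) is a confident positive, a score of 1 (some admissible
amplicon exists, but with mismatches or gaps in a primer or the probe)
flags a case whose real-world outcome is unreliable — laboratory experience
shows such assays may fire efficiently, weakly, or not at all — and 0 means
no admissible amplicon at all. The matrix therefore carries three values,
not two, and downstream interpretation (the event finder) treats 1 as
ambiguous by default.

"Gap bases" counts inserted plus deleted bases, not gap openings: a
two-base deletion consumes the whole gap budget. Budgets apply per primer
site; an amplicon whose two sites each carry 2 mismatches is still
admissible (4 total edits).

## The canonical alignment

The annealing question — *does this primer bind this window within budget?* —
is only well-posed relative to a fixed alignment: a 3-substitution window
must not be smuggled under budget by re-coding one substitution as an
insertion plus a deletion. The package therefore fixes a **canonical
semi-global alignment** per template window: the whole primer is aligned
against the window under match +1, mismatch −1, gap base −2, score ties
resolved towards fewer gap bases, and the budget test applied to that single
alignment. With the window length fixed, the insertion/deletion split is
forced by the lengths, so score and gap count pin the mismatch count
exactly; this is what makes the exhaustive reference search (below)
well-defined.

Two boundary rules matter:

* **No terminal insertions.** The alignment may not start or end with an
  unaligned template base: a dangling template base belongs to the flank,
  not the annealed footprint (the same physical situation is simply a
  different window). Terminal *deletions* — a primer end left unbound —
  remain allowed and cost the usual 2 per base.
* **Local-optimum reduction.** Budget-passing windows are redundant around
  any good site: an exact 20-mer footprint always spawns passing windows one
  and two bases wider or narrower (e.g. one mismatch plus one gap base, one
  base to the left). A site is therefore dropped when a strictly
  better-scoring site on the same strand overlaps it. The rule is symmetric
  under reverse complement, which the strand-symmetry tests rely on.

Degenerate IUPAC codes, common in validated primers, anneal to any base of
their set at zero mismatch cost; `N` in a template intersects everything.
Matching is set intersection of the codes' base sets (`iupacMatch`).

The production scan (`findBindingSites`) shares one dynamic-programming
matrix across all window lengths at a given start; the reference search
(`bruteForceBindingSites`) re-aligns every window from scratch with an
independently written per-window program. Their exact agreement on random
instances is a standing test, and the reference also guards the synthetic
data generator (below).

## Probe binding

A hydrolysis probe can bind either strand of the amplified fragment, so the
probe is aligned twice — against the amplicon and against its reverse
complement — and the better canonical alignment kept. Classification:
*perfect* (full-length annealing, zero mismatches and gaps), *imperfect*
(full coverage within the 2/2 budgets), *none* otherwise. Amplicons whose
probe classifies *none* are discarded before scoring: a TaqMan signal
requires probe hydrolysis. Two numerical choices make the classification
invariant under amplicon orientation: orientation and placement ties are
broken on alignment quality (score, then gap bases, then mismatches) before
position, and the window search spans probe length ±4 bases — an alignment
needing more than 4 gap bases scores at least 8 below an ungapped
competitor and could never classify as binding, so the band is exhaustive
in practice.

The choice to require *full* probe coverage (rather than accepting a strong
partial local alignment) is deliberate: partial coverage has no meaningful
mismatch budget, and a probe whose ends do not hybridise does not report
fluorescence reliably.

## Scoring and the matrix

For each method × event pair, amplicons are enumerated on every sequence of
the event (an event may carry several templates — e.g. a retransformation of
an earlier event — and the best sequence decides), pooled over the three
primer pairings, probe-filtered, and reduced to the best retained hit.
Quality 2 requires both primer sites exact and the probe (if any) perfect;
everything else retained is quality 1; nothing retained is 0. A perfect
primer pair with an imperfect probe scores 1, since the reliability problem
lies in the probe's hybridisation just as it would in a primer's. Best-hit
ties are broken deterministically (quality, fewer total primer edits, lower
sequence index, leftmost amplicon) so reruns are identical.

Self-pairing amplicons (one primer with a convergent copy of itself) count
toward the score but set a warning flag that the matrix renders as `!`:
such amplification falls outside the assay's design intent, and the
original screening matrices highlight rather than suppress these cases.

Scores are persisted in a single-file, self-describing tabular store keyed
by (event, method), with the simulation thresholds recorded in its header;
a store computed under different thresholds refuses to be silently mixed
with new requests. Matrices are built from the store in request order and
export to RFC-4180 CSV (and a static HTML rendering) byte-stably.

## The event finder

Observed screening results form a pattern: some methods positive, some
negative. A combination of events *fits* when every positive method detects
at least one member and no negative method detects any member. Score-1
cells are ambiguous, and their reading is a policy: `wildcard` (default)
counts them as detected when satisfying positives and undetected when
checking negatives — the most permissive consistent reading, appropriate
because imperfect assays can fire either way; `as_positive` / `as_negative`
force one reading for both checks. Detection calls are held as per-method
bit vectors over the event universe; positives are checked by
OR-accumulation, and events hit by any negative method are excluded before
enumeration. Only **minimal** fitting combinations (no fitting proper
subset) of up to 3 distinct events are reported — without minimality every
fitting singleton would drag in its quadratically many supersets — sorted
by size then lexicographically, together with the matrix excerpt restricted
to the involved events. Equality with brute-force subset enumeration,
including the minimality filter, is a standing test at the 20-event scale
(1,350 subsets).

## The synthetic panel generator

Real event sequence collections are confidential, so the generator builds
panels whose ground truth is *planted*: a score-2 cell receives an exact
`primer1 + spacer + rc(primer2)` cassette (with an exact probe copy in the
spacer for probe-bearing methods), a score-1 cell the same cassette with
exactly one substitution in a primer footprint (or in the probe site, per
`score1Mode`), a score-0 cell nothing. Designated score-2 cells additionally
receive a `primer1 + spacer + rc(primer1)` cassette to plant a self-pair
warning; for probed methods that cassette also embeds the probe, otherwise
the self-pair hit would be probe-filtered away and the planted flag
unobservable. Self-pair cells are restricted to score-2 cells because a
perfect self-pair amplicon would otherwise raise the cell above its planted
score.

Defaults emulate realistic assay geometry: 20-nt primers, 24-nt probes,
spacers of 30–160 bases (planted amplicons of 70–200 bp, the typical band
of validated TaqMan screening assays), backbones of at least 2 kb assembled
from 50–150-base random fillers between cassettes. Backbones are
**rejection-sampled against the reference search**: a candidate sequence is
accepted only when, for every primer and probe of every method, the
observed binding-site set equals exactly the planted footprints. This makes
the planted grid exact ground truth by verification rather than by
probabilistic argument — accidental near-sites (most commonly a flank base
extending a planted footprint) trigger a resample. All output is a pure
function of the spec's seed, so generated FASTA/table/CSV files are
byte-identical across runs.

What the generator does not emulate: real screening-element sequence
families (planted primers are uniform random), stacked-event genetics
beyond distributing cassettes over multiple sequences, vector backbones,
repeats, and sequencing error. Passing the planted-panel tests therefore
demonstrates that the pipeline computes its model faithfully on clean
ground truth — not that the model's predictions match wet-lab results on
real events, which requires the confidential collections.

## Problem sizes and numerical notes

The standing verification uses a 48 × 6 panel (288 cells, 3 self-pair
cells, one two-sequence event) for end-to-end recovery and the symmetry
laws, 200 random primer/template instances (primers 15–25 nt, templates up
to 300 nt, planted edited copies) for scan/reference equality, and 50
random patterns × 3 policies on a 20-event panel for the finder; the
acceptance script recomputes all of these from a user-supplied seed.
Degenerate inputs are hard errors rather than guesses: empty amplicons,
non-IUPAC characters (named with their position), negative budgets,
duplicate identifiers, malformed FASTA headers, missing store pairs, and a
method listed as both positive and negative in a pattern. Coordinates are
1-based inclusive at every user-facing surface, 0-based half-open inside
the C++ kernels.

## Known limitations

* Annealing is edit-count-based; no melting temperature, GC content, or
  3'-terminal stability model. Two assays with equal edit counts can behave
  very differently at the bench.
* The search is exhaustive over windows, whereas seed-based screening tools
  may miss marginal sites; predictions here are the conservative superset.
* The local-optimum reduction keeps only the best of overlapping candidate
  sites per strand; a genuinely bistable locus (two overlapping near-equal
  footprints) is reported once unless the scores tie.
* Scores are qualitative; no copy-number or efficiency quantification.
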