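# gmoscreen

In silico PCR simulation and screening matrices for GMO detection.

## The problem

Control laboratories test food and feed for genetically modified organisms
(GMOs) with a *screening* strategy: a first pass of element- and
construct-specific real-time PCR assays (targeting shared genetic elements
such as the CaMV 35S promoter or the nopaline synthase terminator) narrows
the candidate GM events, which are then confirmed with event-specific
methods. Planning and interpreting that screening requires knowing, for
every combination of GM event and validated detection method, whether the
assay is expected to fire. Annotation-based tables are unreliable — elements
with the same name differ at the DNA level between constructs — so the
expectation has to come from the sequences themselves. Because many event
sequences are confidential, the sequence-level simulation is pre-computed
once and only its qualitative outcome is published as a matrix.

`gmoscreen` implements that computational core for R:

* **Primer binding-site search** under re-PCR-style edit budgets. Every
  template window is judged by the canonical semi-global alignment of the
  full primer (match +1, mismatch −1, gap base −2; ties resolved towards
  fewer gap bases), and a window is a site when that alignment has ≤ 2
  mismatches and ≤ 2 gap bases. Degenerate IUPAC codes in validated primers
  anneal at zero mismatch cost. Both strands are searched; overlapping
  reports are reduced to local optima.
* **Amplicon enumeration** over all three primer pairings — the intended
  primer1/primer2 pair plus the two self pairings (primer1/primer1,
  primer2/primer2) — keeping convergent site pairs whose end-to-end length
  lies in [20, 500] bp. Self-pairing amplicons fall outside the assay's
  intent and carry a warning flag.
* **TaqMan probe classification**: the probe is aligned against each
  candidate amplicon and its reverse complement (a probe may bind either
  strand), and the better alignment is classified *perfect* / *imperfect* /
  *none* with the same edit budgets.
* **Scoring**: each event × method pair is reduced to the best retained hit —
  **2** for perfect primers and probe, **1** for a potential amplicon with
  imperfect primer or probe binding (empirically, such assays may or may not
  fire), **0** for no admissible amplicon.
* **Screening matrices** (events × methods grids with warning flags, CSV and
  HTML export) and the **event finder**, which inverts an observed pattern of
  positive/negative screening results into the minimal single events or
  mixes of up to 3 events that explain it.
* A **synthetic panel generator** that plants cassettes with known scores
  into rejection-sampled backbones, standing in for the confidential
  reference sequence collections so the whole pipeline is testable.

## Worked example

```r
library(gmoscreen)

# a deterministic 6-event x 4-method synthetic panel with planted scores
spec  <- panelSpec(nEvents = 6, nMethods = 4, seed = 101)
panel <- generatePanel(spec)
panel$methods
#> DetectionMethodSet with 4 method(s)
#>   SYN-MTH-001 [element_specific] synthElem01 (probe)
#>   SYN-MTH-002 [construct_specific] synthElem02 (-)
#>   SYN-MTH-003 [element_specific] synthElem03 (probe)
#>   SYN-MTH-004 [construct_specific] synthElem04 (-)

# simulate every pair and lay the scores out as a screening matrix
store <- scorePanel(panel$methods, panel$events)
store
#> ScoreStore: 24 pair(s), 6 event(s) x 4 method(s)
#>   thresholds: mm<=2, gaps<=2, amplicon 20-500 bp
scoreMatrix(buildMatrix(store))
#>            SYN-MTH-001 SYN-MTH-002 SYN-MTH-003 SYN-MTH-004
#> SYN-EV-001           0           2           2           0
#> SYN-EV-002           0           0           1           0
#> SYN-EV-003           2           2           0           2
#> SYN-EV-004           2           2           2           1
#> SYN-EV-005           0           1           2           0
#> SYN-EV-006           0           2           0           2

# which events explain: methods 1 and 2 positive, method 3 negative?
pat <- screeningPattern(positive = c("SYN-MTH-001", "SYN-MTH-002"),
                        negative = "SYN-MTH-003")
findEvents(pat, store)
#> FinderResult: 1 fitting combination(s) [policy: wildcard]
#>   SYN-EV-003
```

Reading the matrix: `SYN-EV-003` is the only event detected by methods 1
and 2 but not by method 3, so the finder reports it as the unique minimal
explanation of that laboratory pattern. Cells with value 1 are ambiguous
(*imperfect* binding); by default the finder treats them as possibly
positive when satisfying a positive result and possibly negative when
checking a negative one (`policy = "wildcard"`).

The same pipeline is available from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gmoscreen.R", package = "gmoscreen"))')
Rscript "$CLI" simulate-panel --out panel --n-events 6 --n-methods 4 --seed 101
Rscript "$CLI" build-db --events panel/events.fasta --methods panel/methods.tsv --store panel/scores.tsv
Rscript "$CLI" matrix   --store panel/scores.tsv --out panel/matrix.csv
Rscript "$CLI" find     --store panel/scores.tsv --positive SYN-MTH-001 --negative SYN-MTH-003
```

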