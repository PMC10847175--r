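---
title: "Methods: intragenic T-DNA analysis from border discovery to segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intragenic T-DNA analysis from border discovery to segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intragenic)
```

## The problem this package models

Intragenic plant transformation builds an *Agrobacterium* binary vector
whose entire transferred region — T-DNA borders, promoter, selectable
marker, terminator — derives from the host species' own gene pool, so a
transformation event introduces no foreign DNA and is formally equivalent
to a micro-translocation: a few host fragments relocated to a new
chromosomal site. Validating such an event end to end requires a chain of
computational steps, each of which this package implements as a tested,
deterministic function:

1. **Border discovery** — find host sequences that can supply the two
   halves of the 24-bp T-DNA border consensus
   `GRCAGGATATATNNNNNKGTMAWS`.
2. **Construct modelling** — assemble the vector in silico
   (restriction-ligation), keep per-base provenance, predict screening PCR
   products, and report the micro-translocation as a table.
3. **Insertion-site calling** — locate the integration locus from
   paired-end reads in which one mate maps to the vector, and screen for
   vector-backbone co-integration.
4. **Junction characterization** — at base resolution, how much of the
   right border transferred, where transfer truncated relative to the left
   border, and how much of the target site was deleted.
5. **Segregation testing** — chi-square goodness of fit of progeny
   resistance counts against single-locus Mendelian ratios.
6. **Simulation** — a generator for every input above, with ground truth,
   so the entire chain is testable without any external data.

## Border discovery

The border consensus is degenerate: two conserved flanks,
`GRCAGGATATAT` (degeneracy 2) and `KGTMAWS` (degeneracy 16), around a
five-nucleotide free spacer; the full 24-mer admits $2 \times 4^5 \times
16 = 32768$ concrete sequences. `scan_motif()` matches windows position by
position against the IUPAC code sets; all overlapping hits on both strands
are reported with forward-strand, 0-based half-open coordinates. One
deliberate rule: a subject `N` (masked base) matches only a pattern
position that is itself `N`, so repeat-masked regions cannot produce
spurious hits.

`assemble_border_candidates()` enumerates every way to cut the consensus
at an internal offset (1–23) and realize the 5' part from one host
sequence and the 3' part from another. A consequence worth stating
plainly: left and right borders share one consensus, so *any* sequence
hosting a 5'-part window pairs with *any* sequence hosting a 3'-part
window. A four-EST collection with two 5' hosts and two 3' hosts
therefore yields four two-source candidates, not two; "left" and "right"
are design decisions, not sequence properties, which is why
`border_side` is reported as `unassigned`. The free spacer also means a
candidate set collapses to single junction offsets only when the motif
halves sit at the very ends of their host sequences — which is how the
synthetic EST library is built.

## Construct model

`digest_and_ligate()` implements the one cloning step the workflow needs:
an insert flanked by exactly two SalI sites (`GTCGAC`, cut `G^TCGAC`)
ligated into a circular backbone opened at its single site. Only the
regenerated-site accounting is contract level — product length is always
`backbone + core + 6` — and re-digesting the product returns the original
site-to-site fragments, orientation-insensitively. Both insert
orientations are produced; callers select one.

The default synthetic vector mirrors a realistic intragenic design: a
3733-bp insert core assembled from five donor fragments
(140 + 81 + 3386 + 56 + 70 bp), ligated into a 7998-bp single-site
backbone, giving an 11737-bp circular construct. The adjoined fragments
reconstitute a full consensus match at each border (sources meeting at
consensus position 15). The transferred region of the canonical event —
from 7 bp interior of the left border to 3 bp into the right border —
spans 3495 bp and intersects exactly three provenance fragments: 65 bp of
the left-border EST, the 3386-bp marker cassette, and 44 bp of the
right-border EST. `translocation_table()` computes that intersection for
any transferred interval, and conservation (record lengths sum to the
interval span) is a tested invariant.

`in_silico_pcr()` uses an exact-match primer dialect (degenerate codes
rejected): screening primers are designed against a known construct, so
mismatch tolerance would only add failure modes. Product lengths are
counted inclusive of both primers, and circular templates are scanned
across the origin by internal doubling with deduplication modulo length.
The synthetic vector carries two designed screening pairs — a T-DNA pair
spanning the left-border-EST/promoter boundary (422-bp product) and a
backbone pair (210-bp product) — mirroring the two standard checks on a
putative event: T-DNA present, backbone absent.

## Read mapping

`map_to_reference()` is a seeded gapless local aligner: exact 21-mer
seeds (about every 40 bp along the query, both strands) propose
placements, and each placement is verified by a maximum-scoring-segment
extension (match +1, mismatch −3), thresholded at 0.9 identity within the
segment and 50% of the query aligned. Two properties motivated writing
this rather than wrapping a general-purpose mapper:

* the package's read model is substitution-only, under which gapless
  local alignment *is* the optimal local alignment, and
* the contract requires a deterministic result with an explicit
  tie-break (first reference, then leftmost, then plus strand) and an
  `n_best` count so callers can drop ambiguous placements — guarantees a
  black-box mapper does not make.

With 1% per-base error, the chance that a 150-bp read has no error-free
seed is about 0.1%; those reads go unmapped, which the calling layer
tolerates (support counts, not per-read decisions). The seed length and
thresholds are arguments, not constants.

## Insertion calling

`anchor_filter()` keeps exactly the pairs with one vector-mapped mate
(neither- and both-mapped pairs are discarded) and classifies the anchor
as `tdna` or `backbone` by the midpoint of its vector alignment.
`call_insertions()` maps the informative mates to the host genome, drops
mates with multiple equally best placements, clusters placements per
chromosome by single linkage with a 700-bp gap (about twice the 350-bp
library insert), and emits clusters with at least 3 supporting mates,
support partitioned by orientation — a genuine insertion shows support
from both flanks, hence both orientations. Both parameters are arguments;
the defaults are this package's own choices for a 350-bp/150-bp library.
`backbone_screen()` is deliberately independent of the anchor filter: it
counts every pair with any backbone-placed mate, since co-integrated
backbone also produces pairs entirely within backbone sequence.

## Junction characterization

Each junction sequence is modelled as a single genome↔vector switch.
After placing the junction on both references (gapless, both strands),
`call_breakpoint()` scores every split position by total matches — the
exhaustive scorer itself, not an approximation — and reports the
maximizing split. Shared bases at the switch make the exact breakpoint
ambiguous by their length; ties are resolved by assigning shared bases to
the genome side, and the maximal both-reference run adjacent to the
switch is reported as `microhomology_len`. Bases between the two matched
segments that match neither reference are reported as `filler`;
microhomology and filler are mutually exclusive in one call. Junctions
that place on only one reference raise a distinguishable
`no junction found` condition rather than a low-quality guess. Chimeric
multi-switch reads are out of scope.

`summarize_integration()` converts two junction calls into event
geometry. Border distances are measured from each border's
T-DNA-interior-proximal edge, which makes the summary invariant to how
the construct happens to be written (a tested reverse-complement
symmetry). The conventions:

* `rb_transferred` — right-border bases retained (0–24). The canonical
  event retains 3, matching nick-initiated T-strand synthesis between
  border nucleotides 3 and 4.
* `lb_truncation` — bp by which the integrated sequence stops short of
  the left border's proximal edge; the left border itself never
  transfers under this convention, so a complete transfer has truncation
  0.
* `deletion_len` — reference bases present in wild type and absent
  between the retained flanks: (first retained downstream base) −
  (last retained upstream base) − 1.

One practical caveat the tests encode: in random sequence, the base
adjacent to a junction matches *both* references with probability about
1/4, so even a simulated "zero-microhomology" event can be genuinely
ambiguous by a base or two. The caller then shifts coordinates by the
reported homology length (genome-side convention), and truth recovery is
exact only up to that window — summaries reporting zero homology are
exact. This is a property of the data, not of the implementation.

## Segregation statistics

`chisq_gof()` applies Pearson's goodness of fit on 1 df, no continuity
correction, via `stats::chisq.test()` with the expected ratio as `p`;
expected counts below 1 are rejected rather than silently approximated.
Published segregation tables print statistics truncated — not rounded —
to two decimals (a computed 1.8491 prints as 1.84), so the table output
carries `chisq_2dp`/`p_2dp` columns using truncation; full-precision
values are always retained alongside. `assess_single_locus()` classifies
each testable cross as consistent when `p >= alpha` (default 0.05, the
conventional level) and reports an overall verdict; control crosses with
no expected ratio pass through untested. The eleven tobacco crosses of
the two intragenic lines ship as `tobacco_crosses()` and reproduce their
published statistics exactly under the truncation convention.

## What the simulator emulates, and what it does not

The generators are pure functions of (parameters, seed); every default is
a study-scale condition:

* **Genome** — i.i.d. bases at 40% GC. Tests and acceptance use a single
  100-kb chromosome for event studies (smaller for geometry sweeps):
  large enough for unambiguous mapping and realistic fragment sampling,
  small enough that a full simulate–map–call cycle runs in seconds.
* **Donor library** — four EST-like sequences carrying the border
  half-motifs and an "unplaced scaffold" carrying the 3386-bp marker
  cassette. Donors are deliberately *not* part of the reference
  chromosomes: ESTs are transcript-derived, and the marker's native
  locus sits on a scaffold absent from the mapping assembly. This is
  what makes wild-type read sets vector-free, as in the real screening
  situation, and it is why wild-type specificity is testable at all.
* **Event** — defaults 3 right-border bases transferred, 7-bp left-border
  truncation, 20-bp target-site deletion (a typical size; reported
  medians for T-DNA integration deletions are about 19 bp), inserted
  right-border end first. Microhomology can be planted; backbone
  co-integration can be switched on.
* **Reads** — 150-bp pairs, 350 ± 35 bp inserts (truncated below at
  250 bp), 20× coverage, 1% substitution error. Substitution-only is a
  deliberate simplification: indel errors would conflate mapper and
  caller behaviour in tests. Pair count is exactly
  `round(coverage × genome / (2 × read_len))`.
* **Progeny** — binomial draws at 3/4 (selfing a hemizygote) or 1/2
  (backcross). A calibration test over 1000 simulated families of 100
  progeny checks the chi-square test rejects a true 3:1 at close to the
  nominal 5%.

What passing these tests does **not** show about real data: no indels or
structural noise around the junction, no quality-score structure, no PCR
duplicates, no repetitive genome content (i.i.d. bases understate
multi-mapping), and single-copy events only — tandem or multi-locus
insertions are out of scope throughout.

## Numerical and design choices

* Coordinates: 0-based half-open inside the package (motif hits,
  construct features, vector breakpoints); 1-based closed at format
  boundaries (GFF3, provenance source intervals, genome breakpoints),
  each documented on the field that carries it.
* Restriction overhangs are not modelled beyond regenerated-site
  accounting; the cut geometry of SalI is internal detail.
* Degenerate primers are rejected rather than expanded: an exact dialect
  keeps product prediction bijective with the designed primers.
* The k-mer seed length (21 for reads, 15 for junction amplicons) trades
  sensitivity at 1% error against chance collisions; both are exposed as
  arguments.
* Tie-breaks everywhere are explicit (reference order, leftmost
  placement, genome-side homology assignment) so identical inputs give
  identical outputs on any platform.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs the full chain from a single seed: the
published segregation table through `chisq_gof()`, consensus
combinatorics, the synthetic vector's screening PCR products (422/210
bp), the 3495-bp micro-translocation table (65 + 3386 + 44), canonical
junction recovery (3, 7, 20), insertion-site recovery over 20 simulated
studies, wild-type specificity, and the backbone screen on clean versus
co-integrated events. See the README for how to run it.
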