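# intragenic

Tools for analysing **intragenic plant transformation** — *Agrobacterium*
gene transfer in which the entire T-DNA (borders, promoter, selectable
marker, terminator) is assembled from the host species' own gene pool, so
the resulting event is equivalent to a micro-translocation and contains no
foreign DNA. The package is aimed at researchers designing intragenic
vectors and validating transformation events from sequence data, and covers
the full chain:

* **Border discovery.** Host collections (e.g. ESTs) are scanned for the
  degenerate 24-bp T-DNA border consensus

  `5'-GRCAGGATATATNNNNNKGTMAWS-3'`

  (R = A/G, K = G/T, M = A/C, W = A/T, S = C/G, N = any), whose two
  conserved flanks `GRCAGGATATAT` and `KGTMAWS` admit 2 and 16 concrete
  configurations (2¹⁵ = 32768 for the full 24-mer). Full border candidates
  are assembled by adjoining parts of two host sequences
  (`scan_motif()`, `assemble_border_candidates()`, `find_border_pairs()`).
* **Construct modelling.** In-silico SalI restriction-ligation assembly
  with per-base source provenance, exact-match in-silico PCR, and a
  micro-translocation table that clips provenance fragments to the
  transferred interval (`digest_and_ligate()`, `in_silico_pcr()`,
  `translocation_table()`).
* **Insertion-site calling.** Paired-end reads with exactly one
  vector-mapped mate are retained; the informative mates are mapped to the
  host genome and clustered into insertion calls with strand-partitioned
  support; a backbone screen certifies events free of vector backbone
  (`anchor_filter()`, `call_insertions()`, `backbone_screen()`).
* **Junction characterization.** Each junction sequence is split at the
  position maximizing matches against genome and vector over *all* splits;
  the event summary reports right-border bases transferred, left-border
  truncation, target-site deletion and microhomology
  (`call_breakpoint()`, `summarize_integration()`).
* **Segregation testing.** Pearson χ² goodness of fit (1 df, no continuity
  correction) of progeny resistance counts against 3:1 / 1:1 single-locus
  ratios: for observed counts $(o_r, o_s)$ and expected ratio $r\!:\!s$,

  $\chi^2 = \sum_i (o_i - e_i)^2 / e_i$, $e_r = n\,r/(r+s)$.

  (`chisq_gof()`, `assess_single_locus()`, `tobacco_crosses()`).
* **Simulation with truth.** Deterministic generators for genomes, donor
  libraries, constructs, integration events (defaults: 3 right-border
  bases transferred, 7-bp left-border truncation, 20-bp target-site
  deletion), 150-bp paired reads (350-bp inserts, 1% substitution error)
  and progeny counts (`simulate_event()`, `simulate_reads()`,
  `simulate_progeny()`).

Everything is tibble-in/tibble-out and pipe-friendly; constructs are a
small S3 class with `tidy()`/`glance()` methods; `plot_segregation()`,
`plot_insertion_calls()` and `plot_construct()` give quick ggplot2 views.

## Worked example

Simulate a complete single-insertion study and analyse it:

```r
library(intragenic)

sim   <- simulate_event(seed = 7)          # genome + donors + vector + event
reads <- simulate_reads(sim$event$transformed, coverage = 20, seed = 71)

anchored <- anchor_filter(reads$pairs, sim$construct)
call_insertions(anchored, sim$genome)
#> # A tibble: 1 × 6
#>   dest_ref start   end support_fwd support_rev n_support
#>   <chr>    <int> <int>       <int>       <int>     <int>
#> 1 chr1     49719 50328          13          12        25
```

One locus, spanning the true site (50000), supported by informative mates
from both flanks (13 forward, 12 reverse) — the signature of a single
integration. `backbone_screen(reads$pairs, sim$construct)` returns `0`:
no read pair touches the vector backbone, so the event is backbone-free at
this coverage. Junction sequences then give base resolution:

```r
j <- extract_junctions(sim$event)
summarize_integration(
  call_breakpoint(j[["left"]],  sim$genome, sim$construct, side = "left"),
  call_breakpoint(j[["right"]], sim$genome, sim$construct, side = "right"),
  sim$construct
)
#> # A tibble: 1 × 7
#>   genome_ref rb_transferred lb_truncation deletion_len transferred_length
#>   <chr>               <int>         <int>        <int>              <int>
#> 1 chr1                    3             7           20               3495
#> # ℹ 2 more variables: microhomology_left <int>, microhomology_right <int>
```

Only the first 3 bases of the right border integrated, transfer truncated
7 bp before the left border, and 20 bp of the target site were deleted —
3495 bp of host-derived construct relocated to a new chromosome, i.e. a
micro-translocation. Finally, inheritance of the resistance marker:

```r
chisq_gof(tobacco_crosses()) |>
  dplyr::select(ovule_parent, pollen_parent, ratio, chisq_2dp, p_2dp) |>
  head(3)
#> # A tibble: 3 × 5
#>   ovule_parent pollen_parent ratio chisq_2dp p_2dp
#>   <chr>        <chr>         <chr>     <dbl> <dbl>
#> 1 021401-1     021401-1      3:1        0.39  0.53
#> 2 021401-4     021401-4      3:1        0.66  0.41
#> 3 021401-4     021401-4      3:1        0.08  0.76
```

All nine testable crosses are consistent with a single dominant locus
(`assess_single_locus(tobacco_crosses())$overall` is `"consistent"`).
Statistics are shown truncated to two decimals (`chisq_2dp`), the
convention of published segregation tables; full precision is in `chisq`.

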