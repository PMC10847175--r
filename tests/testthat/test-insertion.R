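# Shared simulated study for the calling tests: one 100-kb chromosome,
# default event geometry, 20x coverage, 1% substitution error.
sim_study <- function() {
  cached("study", {
    sim <- fixture_sim()
    reads <- simulate_reads(sim$event$transformed, coverage = 20, seed = 71)
    anchored <- anchor_filter(reads$pairs, sim$construct)
    list(sim = sim, reads = reads, anchored = anchored)
  })
}

test_that("pairs with neither or both mates on the vector are discarded", {
  sim <- fixture_sim()
  cm <- sim$construct
  td <- intragenic:::feature_interval(cm, "tdna_region")
  inside <- function(off) substring(cm$sequence, td[1] + off, td[1] + off + 149)
  genome_read <- substr(sim$genome[[1]], 2001, 2150)
  pairs <- tibble::tibble(
    pair_id = c("both_tdna", "neither", "anchored"),
    read1 = c(inside(300), genome_read, inside(700)),
    qual1 = strrep("I", 150),
    read2 = c(intragenic:::revcomp(inside(600)),
              intragenic:::revcomp(substr(sim$genome[[1]], 2201, 2350)),
              intragenic:::revcomp(substr(sim$genome[[1]], 5001, 5150))),
    qual2 = strrep("I", 150)
  )
  out <- anchor_filter(pairs, cm)
  expect_identical(out$pair_id, "anchored")
  expect_identical(out$anchored_mate, 1L)
  expect_identical(out$vector_segment, "tdna")
  expect_identical(out$informative_sequence, pairs$read2[3])
  expect_identical(nrow(anchor_filter(pairs[0, ], cm)), 0L)
})

test_that("anchored mates from a simulated event straddle the junctions", {
  st <- sim_study()
  truth <- st$sim$event$truth
  expect_gt(nrow(st$anchored), 0)
  expect_true(all(st$anchored$vector_segment %in% c("tdna", "other")))
  # every retained pair's true fragment straddles a vector/genome junction
  frag <- st$reads$truth[match(st$anchored$pair_id, st$reads$truth$pair_id), ]
  ins_lo <- truth$site
  ins_hi <- truth$site + truth$transferred_length + 1L
  straddles <- (frag$frag_start <= ins_lo & frag$frag_end > ins_lo) |
    (frag$frag_start <= ins_hi & frag$frag_end >= ins_hi)
  inside_tdna <- frag$frag_start > ins_lo & frag$frag_end < ins_hi
  # every retained pair touches the insertion; the rare non-straddler is a
  # fully-interior pair whose second mate missed the vector at 1% read error
  expect_true(all(straddles | inside_tdna))
  expect_gte(mean(straddles), 0.9)
})

test_that("a single integration is called at the true site with both orientations", {
  st <- sim_study()
  truth <- st$sim$event$truth
  calls <- call_insertions(st$anchored, st$sim$genome)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$dest_ref, truth$chrom)
  expect_true(calls$start <= truth$site && truth$site <= calls$end)
  expect_gte(calls$support_fwd, 1L)
  expect_gte(calls$support_rev, 1L)
  # cluster span stays within twice the library insert of the site
  expect_lte(calls$end - calls$start, 2L * 700L)
})

test_that("wild-type read sets yield zero calls and empty input is empty", {
  sim <- fixture_sim()
  wt <- simulate_reads(sim$genome, coverage = 10, seed = 72)
  anchored <- anchor_filter(wt$pairs, sim$construct)
  expect_identical(nrow(anchored), 0L)
  expect_identical(nrow(call_insertions(anchored, sim$genome)), 0L)
  expect_identical(nrow(call_insertions(anchored[0, ], sim$genome)), 0L)
})

test_that("adding reads never removes a true call", {
  st <- sim_study()
  truth <- st$sim$event$truth
  full <- call_insertions(st$anchored, st$sim$genome)
  half <- call_insertions(st$anchored[seq_len(floor(nrow(st$anchored) / 2)), ],
                          st$sim$genome)
  if (nrow(half)) {
    expect_true(all(half$n_support <= full$n_support))
    expect_true(full$start <= truth$site && truth$site <= full$end)
  }
  expect_gte(full$n_support, nrow(st$anchored[st$anchored$vector_segment ==
                                                "tdna", ]) - 5L)
})

test_that("backbone screen is zero for clean events and positive with co-integration", {
  genome <- make_genome(c(chr1 = 30000L), seed = 73)
  donors <- fixture_donors()
  cm <- fixture_construct()
  clean <- integrate_tdna(genome, cm, site = 15000L)
  rd_clean <- simulate_reads(clean$transformed, coverage = 15, seed = 74)
  expect_identical(backbone_screen(rd_clean$pairs, cm), 0L)

  dirty <- integrate_tdna(genome, cm, site = 15000L, include_backbone = TRUE)
  rd_dirty <- simulate_reads(dirty$transformed, coverage = 15, seed = 75)
  expect_gt(backbone_screen(rd_dirty$pairs, cm), 0L)
  expect_identical(backbone_screen(rd_clean$pairs[0, ], cm), 0L)
})

test_that("insertion calls round-trip through GFF3", {
  st <- sim_study()
  calls <- call_insertions(st$anchored, st$sim$genome)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_insertion_gff(calls, path)
  back <- read_insertion_gff(path)
  expect_identical(tibble::as_tibble(back), tibble::as_tibble(calls))
  # and a second write of the re-read calls is identical on disk
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_insertion_gff(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
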