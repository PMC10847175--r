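test_that("genome generation is deterministic with controlled composition", {
  g1 <- make_genome(c(chr1 = 100000L), gc = 0.5, seed = 7)
  g2 <- make_genome(c(chr1 = 100000L), gc = 0.5, seed = 7)
  expect_identical(g1, g2)
  gc_obs <- sum(strsplit(g1[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gt(gc_obs, 0.48)
  expect_lt(gc_obs, 0.52)
  expect_error(make_genome(c(chr1 = 0L)), "at least 1 kb")
  g3 <- make_genome(c(a = 2000L, b = 3000L), seed = 1)
  expect_identical(nchar(g3), c(a = 2000L, b = 3000L))
})

test_that("the donor library plants exactly the designed half-motifs", {
  d <- fixture_donors()
  m5 <- tdna_consensus("motif_5p")
  m3 <- tdna_consensus("motif_3p")
  counts5 <- vapply(d$donors[1:4], function(s)
    nrow(scan_motif(c(x = s), m5, both_strands = FALSE)), integer(1))
  counts3 <- vapply(d$donors[1:4], function(s)
    nrow(scan_motif(c(x = s), m3, both_strands = FALSE)), integer(1))
  expect_identical(unname(counts5), c(1L, 0L, 1L, 0L))
  expect_identical(unname(counts3), c(0L, 1L, 0L, 1L))
  expect_false(any(grepl("GTCGAC", d$donors)))
  expect_identical(d$donors, make_donor_library(seed = 5)$donors)
})

test_that("integration length bookkeeping matches the closed form", {
  sim <- fixture_sim()
  truth <- sim$event$truth
  expect_identical(truth$transferred_length, 3495L)
  expect_identical(nchar(sim$event$transformed[[truth$chrom]]),
                   100000L - 20L + 3495L)
  # deletion_len 0 and full-length transfer keeps the interior verbatim
  ss <- fixture_small_sim()
  ev <- integrate_tdna(ss$genome, ss$construct, site = 9000L,
                       rb_transferred = 24L, lb_truncation = 0L,
                       deletion_len = 0L, rb_leading = FALSE)
  td <- intragenic:::feature_interval(ss$construct, "tdna_region")
  interior <- substring(ss$construct$sequence, td[1] + 24L + 1L, td[2])
  expect_true(grepl(interior, ev$transformed[[1]], fixed = TRUE))
  expect_error(integrate_tdna(ss$genome, ss$construct, site = 5L),
               "out of bounds")
})

test_that("microhomology planting edits the reference at the site", {
  ss <- fixture_small_sim()
  ev <- integrate_tdna(ss$genome, ss$construct, site = 8000L,
                       microhomology_len = 6L)
  expect_identical(ev$truth$microhomology_len, 6L)
  ins_start <- substr(ev$transformed[[1]], 8001, 8006)
  ref_tail <- substr(ev$reference[[1]], 7995, 8000)
  expect_identical(ins_start, ref_tail)
})

test_that("read simulation honours the pair-count formula and error model", {
  genome <- make_genome(c(chr1 = 50000L), seed = 11)
  sim <- simulate_reads(genome, coverage = 6, error_rate = 0, seed = 12)
  expect_identical(nrow(sim$pairs), as.integer(round(6 * 50000 / (2 * 150))))
  expect_true(all(nchar(sim$pairs$read1) == 150L))
  # error-free reads are exact substrings of the genome or its complement
  rc <- intragenic:::revcomp(genome[[1]])
  idx <- seq(1, nrow(sim$pairs), by = 37)
  expect_true(all(vapply(idx, function(i)
    grepl(sim$pairs$read1[i], genome[[1]], fixed = TRUE), logical(1))))
  expect_true(all(vapply(idx, function(i)
    grepl(sim$pairs$read2[i], rc, fixed = TRUE), logical(1))))
  # byte-identical regeneration, different under another seed
  again <- simulate_reads(genome, coverage = 6, error_rate = 0, seed = 12)
  expect_identical(sim$pairs, again$pairs)
  other <- simulate_reads(genome, coverage = 6, error_rate = 0, seed = 13)
  expect_false(identical(sim$pairs$read1[1], other$pairs$read1[1]))
  expect_error(simulate_reads(genome, coverage = 0), "positive")
})

test_that("the substitution error rate is realized at the requested level", {
  genome <- make_genome(c(chr1 = 20000L), seed = 14)
  clean <- simulate_reads(genome, coverage = 5, error_rate = 0, seed = 15)
  noisy <- simulate_reads(genome, coverage = 5, error_rate = 0.01, seed = 15)
  diffs <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                  clean$pairs$read1, noisy$pairs$read1)
  rate <- sum(diffs) / (length(diffs) * 150)
  expect_gt(rate, 0.007)
  expect_lt(rate, 0.013)
})

test_that("FASTQ pairs round-trip byte-identically", {
  genome <- make_genome(c(chr1 = 5000L), seed = 16)
  sim <- simulate_reads(genome, coverage = 2, seed = 17)
  p1 <- withr::local_tempfile(fileext = ".fq")
  p2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_pairs(sim$pairs, p1, p2)
  back <- read_fastq_pairs(p1, p2)
  expect_identical(back$read1, sim$pairs$read1)
  expect_identical(back$read2, sim$pairs$read2)
  expect_identical(back$pair_id, sim$pairs$pair_id)
})

test_that("progeny simulation matches its binomial design", {
  ctrl <- simulate_progeny("control", n = 188, seed = 1)
  expect_identical(c(ctrl$n_resistant, ctrl$n_susceptible), c(0L, 188L))
  expect_identical(ctrl$ratio, "-")
  big <- simulate_progeny("self_het", n = 10000, seed = 2)
  frac <- big$n_resistant / 10000
  expect_gt(frac, 0.73)
  expect_lt(frac, 0.77)
  bc <- simulate_progeny("backcross", n = 10000, seed = 3)
  expect_gt(bc$n_resistant / 10000, 0.48)
  expect_lt(bc$n_resistant / 10000, 0.52)
  expect_error(simulate_progeny("self_het", n = 0), "at least 1")
  expect_identical(simulate_progeny("backcross", 50, seed = 4),
                   simulate_progeny("backcross", 50, seed = 4))
})

test_that("the goodness-of-fit test holds its nominal level on simulated selfings", {
  # 1000 simulated selfed families of 100 progeny: the chi-square test should
  # reject a true 3:1 at close to alpha = 0.05
  rejections <- sum(vapply(1:1000, function(s) {
    rec <- simulate_progeny("self_het", n = 100, seed = s)
    chisq_gof(rec)$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 30)
  expect_lte(rejections, 70)
})
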