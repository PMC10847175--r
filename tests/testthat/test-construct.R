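test_that("restriction-ligation length bookkeeping holds on toy sequences", {
  core <- random_dna(50, gc = 0.5, seed = 301)
  insert <- paste0("GTCGAC", core, "GTCGAC")
  backbone <- paste0("GTCGAC", random_dna(194, gc = 0.5, seed = 302))
  expect_length(intragenic:::find_site(backbone, "GTCGAC"), 1)
  cm <- digest_and_ligate(insert, backbone, orientation = "both")
  expect_identical(cm$forward$length, 200L + 50L + 6L)
  expect_identical(cm$reverse$length, 256L)
  # the insert core is present in one orientation each
  expect_true(grepl(core, cm$forward$sequence, fixed = TRUE))
  expect_true(grepl(intragenic:::revcomp(core), cm$reverse$sequence, fixed = TRUE))
})

test_that("assembly is rejected when the site count is wrong", {
  backbone <- paste0("GTCGAC", random_dna(100, gc = 0.5, seed = 303))
  expect_error(digest_and_ligate(random_dna(60, 0.5, seed = 304), backbone),
               "exactly two")
  bad_insert <- paste0("GTCGAC", "AAAA", "GTCGAC", "CCCC", "GTCGAC")
  expect_error(digest_and_ligate(bad_insert, backbone), "found 3")
  expect_error(
    digest_and_ligate(paste0("GTCGAC", "AAAA", "GTCGAC"),
                      random_dna(100, 0.5, seed = 305)),
    "linearizable"
  )
})

test_that("ligation then re-digestion returns the original fragment set", {
  core <- random_dna(80, gc = 0.45, seed = 306)
  insert <- paste0("GTCGAC", core, "GTCGAC")
  backbone <- paste0("GTCGAC", random_dna(300, gc = 0.45, seed = 307))
  cm <- digest_and_ligate(insert, backbone, orientation = "forward")
  frags <- redigest(cm)
  expect_length(frags, 2)
  # compare orientation-insensitively as site-to-site fragments (the full
  # recognition site flanks both ends of each fragment)
  insert_frag <- insert
  backbone_frag <- paste0(backbone, "GTCGAC")  # circular, one site
  canon <- function(s) min(s, intragenic:::revcomp(s))
  expect_setequal(unname(vapply(frags, canon, character(1))),
                  unname(vapply(c(insert_frag, backbone_frag), canon,
                                character(1))))
})

test_that("construct invariants are enforced", {
  expect_error(
    construct_map("ACGT", features = tibble::tibble(
      name = "f", start = 2L, end = 8L, strand = "+", role = "gene")),
    "out of bounds"
  )
  expect_error(
    construct_map("ACGTACGT", provenance = tibble::tibble(
      label = c("a", "b"), source_ref = "x", source_start = c(1L, 1L),
      source_end = c(4L, 3L), construct_start = c(0L, 5L),
      construct_end = c(4L, 8L), role = "other")),
    "tile"
  )
})

test_that("the built vector matches the designed layout", {
  cm <- fixture_construct()
  expect_identical(cm$length, 3733L + 7998L + 6L)
  expect_true(cm$is_circular)
  td <- intragenic:::feature_interval(cm, "tdna_region")
  lb <- intragenic:::feature_interval(cm, "left_border")
  rb <- intragenic:::feature_interval(cm, "right_border")
  expect_identical(lb[2] - lb[1], 24L)
  expect_identical(rb[2] - rb[1], 24L)
  expect_identical(td, c(lb[1], rb[2]))
  # both borders re-scan as full consensus hits at their annotated positions
  hits <- scan_motif(c(v = cm$sequence), tdna_consensus(), both_strands = FALSE)
  expect_true(all(c(lb[1], rb[1]) %in% hits$start))
  # provenance tiles by construction (validated) and glance sees it
  g <- glance(cm)
  expect_identical(g$tdna_length, td[2] - td[1])
  expect_identical(tidy(cm)$length, cm$features$end - cm$features$start)
})

test_that("constructs are reproducible and FASTA+GFF3 round-trips", {
  d <- fixture_donors()
  cm1 <- build_construct(d, seed = 5)
  cm2 <- build_construct(d, seed = 5)
  expect_identical(cm1$sequence, cm2$sequence)

  cm <- fixture_construct()
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_construct(cm, fa, gff, tsv)
  back <- read_construct(fa, gff, tsv)
  expect_identical(back$sequence, cm$sequence)
  expect_identical(back$is_circular, TRUE)
  expect_setequal(paste(back$features$name, back$features$start,
                        back$features$end, back$features$role),
                  paste(cm$features$name, cm$features$start,
                        cm$features$end, cm$features$role))
  expect_identical(nrow(back$provenance), nrow(cm$provenance))
})
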