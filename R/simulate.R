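# Deterministic simulators for every input the pipeline consumes: host
# genome, donor sequence library (EST-like fragments and an unplaced
# scaffold carrying the marker cassette), the assembled intragenic vector,
# the integration event, paired-end reads and progeny counts. Every
# generator is a pure function of (parameters, seed).

#' Generate a synthetic multi-chromosome host genome
#'
#' Chromosomes are i.i.d. base draws at a target GC content. Lengths below
#' 1 kb are rejected (shorter references make insert placement and mapping
#' degenerate).
#'
#' @param lengths Named or unnamed vector of chromosome lengths (bp); names
#'   default to `chr1..chrN`.
#' @param gc Target GC fraction.
#' @param seed Integer seed; the output is fully determined by
#'   `(lengths, gc, seed)`.
#' @return Named character vector of chromosome sequences.
#' @examples
#' g <- make_genome(c(chr1 = 2000), seed = 1)
#' @export
make_genome <- function(lengths, gc = 0.4, seed = 1) {
  if (any(lengths < 1000)) abort("chromosome lengths must be at least 1 kb")
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  withr::with_seed(seed, {
    vapply(lengths, function(L) random_dna(L, gc = gc), character(1))
  })
}

# draw until `ok(x)` holds; deterministic given seed
resample_until <- function(make, ok, seed, what, max_iter = 200L) {
  for (i in seq_len(max_iter)) {
    x <- withr::with_seed(child_seed(seed, i), make())
    if (ok(x)) return(x)
  }
  abort(sprintf("could not generate %s within %d attempts", what, max_iter))
}

n_fwd_hits <- function(seq, m) nrow(scan_motif(c(x = seq), m, both_strands = FALSE))

#' Generate the donor sequence library
#'
#' Emulates the host-derived sources of an intragenic T-DNA: four EST-like
#' sequences that each carry one half of a 24-bp border consensus match
#' (`est_a`/`est_b` adjoin into a left border, `est_c`/`est_d` into a right
#' border, meeting at consensus position 15), and an unplaced-scaffold donor
#' carrying the 3386-bp selectable-marker cassette. Donors are deliberately
#' distinct from the reference chromosomes: ESTs are transcript-derived and
#' the marker's source scaffold is absent from the mapping assembly, which
#' is what keeps wild-type read sets free of vector-matching sequence.
#'
#' Each EST hosts exactly its planted half-motif and no stray sub-motif
#' occurrence on the forward strand, and no donor contains the SalI site
#' used for cloning, so downstream fixtures are exactly enumerable.
#'
#' @param seed Integer seed.
#' @param gc GC content of the random parts.
#' @return A list with `donors` (named character vector: `est_a..est_d`,
#'   `scaffold_u`), `lb`/`rb` (the concrete 24-mers), and `fragments`
#'   (tibble of the five construct fragments with 1-based source
#'   intervals).
#' @export
make_donor_library <- function(seed = 1, gc = 0.42) {
  m5 <- tdna_consensus("motif_5p")
  m3 <- tdna_consensus("motif_3p")
  full <- tdna_consensus()
  lb <- realize_motif(full, seed = child_seed(seed, 901))
  rb <- realize_motif(full, seed = child_seed(seed, 902))

  clean <- function(s) !grepl("GTCGAC", s, fixed = TRUE)
  est_prefix_host <- function(border24, sd) resample_until(
    make = function() paste0(random_dna(300, gc), random_dna(125, gc),
                             substr(border24, 1, 15)),
    ok = function(s) clean(s) && n_fwd_hits(s, m5) == 1 && n_fwd_hits(s, m3) == 0,
    seed = sd, what = "border 5'-part EST"
  )
  est_suffix_host <- function(border24, lead, sd) resample_until(
    make = function() paste0(substr(border24, 16, 24), random_dna(lead, gc),
                             random_dna(330, gc)),
    ok = function(s) clean(s) && n_fwd_hits(s, m5) == 0 && n_fwd_hits(s, m3) == 1,
    seed = sd, what = "border 3'-part EST"
  )
  est_a <- est_prefix_host(lb, child_seed(seed, 11))
  est_b <- est_suffix_host(lb, 72, child_seed(seed, 12))
  est_c <- resample_until(
    make = function() paste0(random_dna(300, gc), random_dna(41, gc),
                             substr(rb, 1, 15)),
    ok = function(s) clean(s) && n_fwd_hits(s, m5) == 1 && n_fwd_hits(s, m3) == 0,
    seed = child_seed(seed, 13), what = "border 5'-part EST"
  )
  est_d <- est_suffix_host(rb, 61, child_seed(seed, 14))
  scaffold_u <- resample_until(
    make = function() paste0(random_dna(500, gc), random_dna(3386, gc),
                             random_dna(500, gc)),
    ok = clean, seed = child_seed(seed, 15), what = "marker scaffold"
  )
  fragments <- tibble::tribble(
    ~label, ~source_ref, ~source_start, ~source_end, ~role,
    "frag1_lb_5p", "est_a", 301L, 440L, "left_border_part",
    "frag2_lb_3p", "est_b", 1L, 81L, "left_border_part",
    "marker_cassette", "scaffold_u", 501L, 3886L, "gene",
    "frag3_rb_5p", "est_c", 301L, 356L, "right_border_part",
    "frag4_rb_3p", "est_d", 1L, 70L, "right_border_part"
  )
  list(
    donors = c(est_a = est_a, est_b = est_b, est_c = est_c, est_d = est_d,
               scaffold_u = scaffold_u),
    lb = lb, rb = rb, fragments = fragments
  )
}

#' Assemble the intragenic vector from the donor library
#'
#' Concatenates the five donor fragments into a 3733-bp insert core
#' (140 + 81 + 3386 + 56 + 70 bp), flanks it with SalI sites, and ligates it
#' into a freshly generated 7998-bp single-SalI-site backbone with
#' [digest_and_ligate()]. The adjoined EST parts reconstitute a full 24-bp
#' consensus match at each border (the two sources meet at consensus
#' position 15). Features (borders, T-DNA region, promoter / gene /
#' terminator, backbone), full per-base provenance and two screening primer
#' pairs are annotated: a T-DNA pair spanning the left-border-EST/promoter
#' boundary with a 422-bp product and a backbone pair with a 210-bp
#' product.
#'
#' @param donors Output of [make_donor_library()].
#' @param seed Seed for the backbone sequence.
#' @param gc GC content of the backbone.
#' @return A `construct_map` (circular, 11737 bp) whose `primers` tibble
#'   holds the two screening pairs.
#' @export
build_construct <- function(donors, seed = 1, gc = 0.42) {
  fr <- donors$fragments
  dseq <- donors$donors
  piece <- function(i) substring(dseq[[fr$source_ref[i]]], fr$source_start[i],
                                 fr$source_end[i])
  core <- paste0(piece(1), piece(2), piece(3), piece(4), piece(5))
  stopifnot(seq_len_bp(core) == 3733L)
  insert <- paste0("GTCGAC", core, "GTCGAC")
  backbone <- resample_until(
    make = function() paste0("GTCGAC", random_dna(7992, gc)),
    ok = function(s) length(find_site(s, "GTCGAC")) == 1,
    seed = child_seed(seed, 31), what = "vector backbone"
  )
  cm <- digest_and_ligate(insert, backbone, orientation = "forward")

  # fragment offsets within the construct: core starts after the first
  # regenerated site
  off <- c(0L, cumsum(fr$source_end - fr$source_start + 1L)) + 6L
  features <- tibble::tibble(
    name = c("left_border", "tdna_region", "promoter", "marker_gene",
             "terminator", "right_border", "backbone"),
    start = c(off[2] - 15L, off[2] - 15L, off[3], off[3] + 1000L,
              off[4] - 300L, off[5] - 15L, off[6] + 6L),
    end = c(off[2] + 9L, off[5] + 9L, off[3] + 1000L, off[4] - 300L,
            off[4], off[5] + 9L, cm$length),
    strand = "+",
    role = c("left_border", "tdna_region", "promoter", "gene", "terminator",
             "right_border", "backbone")
  )
  provenance <- tibble::tibble(
    label = c("site_5p", fr$label, "site_3p", "backbone"),
    source_ref = c("ligation", fr$source_ref, "ligation", "backbone"),
    source_start = c(1L, fr$source_start, 1L, 7L),
    source_end = c(6L, fr$source_end, 6L, 7998L),
    construct_start = c(0L, off[1:5], off[6], off[6] + 6L),
    construct_end = c(6L, off[2:6], off[6] + 6L, cm$length),
    role = c("other", fr$role, "other", "backbone")
  )
  primers <- tibble::tibble(
    name = c("tdna_f", "tdna_r", "backbone_f", "backbone_r"),
    seq = c(
      substring(cm$sequence, 151, 170),
      revcomp(substring(cm$sequence, 553, 572)),
      substring(cm$sequence, 5001, 5020),
      revcomp(substring(cm$sequence, 5191, 5210))
    )
  )
  out <- construct_map(cm$sequence, is_circular = TRUE, features = features,
                       provenance = provenance, primers = primers)
  # designed amplicons must be unique on the construct
  stopifnot(
    nrow(in_silico_pcr(out, primers$seq[1], primers$seq[2])) == 1,
    nrow(in_silico_pcr(out, primers$seq[3], primers$seq[4])) == 1
  )
  out
}

#' Integrate the T-DNA into a host chromosome
#'
#' Writes a single integration event into the reference: `deletion_len`
#' bases are removed after `site`, and the transferred construct segment is
#' inserted, right-border end leading (T-strand synthesis initiates at the
#' nick after the third right-border nucleotide, so transfer begins at the
#' right border). The transferred segment runs from `lb_truncation` bases
#' interior of the left border's proximal edge to `rb_transferred` bases
#' into the right border; the left border itself never transfers.
#'
#' With `microhomology_len > 0` the reference bases immediately upstream of
#' the site are overwritten with the first bases of the inserted segment, so
#' the junction carries genuine shared sequence (the returned `reference`
#' reflects this edit). With `include_backbone = TRUE` transfer reads
#' through past the left-border end around the circular vector into the
#' backbone, emulating vector-backbone co-integration.
#'
#' @param genome Named character vector of reference chromosomes.
#' @param construct A `construct_map` from [build_construct()].
#' @param chrom Chromosome receiving the insertion.
#' @param site 1-based position of the last retained base before the
#'   insertion; must be at least `deletion_len` from the ends.
#' @param rb_transferred,lb_truncation,deletion_len,microhomology_len Event
#'   geometry in bp (defaults 3 / 7 / 20 / 0).
#' @param rb_leading Insert the segment right-border-first (default); set
#'   `FALSE` for the opposite genomic orientation.
#' @param include_backbone Simulate backbone co-integration.
#' @param backbone_carry Bp of backbone carried along when
#'   `include_backbone = TRUE`.
#' @return A list: `transformed` (genome with the transformed chromosome),
#'   `reference` (the wild-type genome, microhomology-edited if requested)
#'   and `truth` (one-row tibble of the event parameters, including
#'   `transferred_length` and `first_retained_down`).
#' @export
integrate_tdna <- function(genome, construct, chrom = names(genome)[1],
                           site = NULL, rb_transferred = 3L,
                           lb_truncation = 7L, deletion_len = 20L,
                           microhomology_len = 0L, rb_leading = TRUE,
                           include_backbone = FALSE, backbone_carry = 2000L) {
  stopifnot(inherits(construct, "construct_map"), chrom %in% names(genome))
  L <- seq_len_bp(genome[[chrom]])
  site <- site %||% as.integer(round(L / 2))
  if (site < max(1L, deletion_len) || site + deletion_len > L - 1L) {
    abort("integration site out of bounds for the requested deletion")
  }
  lb <- feature_interval(construct, "left_border")
  rb <- feature_interval(construct, "right_border")
  seg_start <- lb[2] + lb_truncation
  seg_end <- rb[1] + rb_transferred
  if (seg_end <= seg_start) abort("empty transferred segment")
  if (include_backbone) {
    bb <- feature_interval(construct, "backbone")
    carry_start <- max(bb[1], bb[2] - backbone_carry)
    segment <- paste0(construct_subseq(construct, carry_start, construct$length),
                      construct_subseq(construct, 0L, seg_end))
  } else {
    segment <- construct_subseq(construct, seg_start, seg_end)
  }
  ins <- if (rb_leading) revcomp(segment) else segment
  reference <- genome
  if (microhomology_len > 0) {
    stopifnot(microhomology_len < site)
    planted <- substring(ins, 1L, microhomology_len)
    pre <- substring(reference[[chrom]], 1L, site - microhomology_len)
    post <- substring(reference[[chrom]], site + 1L, L)
    reference[[chrom]] <- paste0(pre, planted, post)
  }
  transformed <- reference
  transformed[[chrom]] <- paste0(
    substring(reference[[chrom]], 1L, site),
    ins,
    substring(reference[[chrom]], site + deletion_len + 1L, L)
  )
  truth <- tibble::tibble(
    chrom = chrom, site = as.integer(site),
    first_retained_down = as.integer(site + deletion_len + 1L),
    rb_transferred = as.integer(rb_transferred),
    lb_truncation = as.integer(lb_truncation),
    deletion_len = as.integer(deletion_len),
    microhomology_len = as.integer(microhomology_len),
    transferred_length = seq_len_bp(ins),
    rb_leading = rb_leading,
    backbone_cointegrated = include_backbone,
    seg_start = as.integer(seg_start), seg_end = as.integer(seg_end)
  )
  list(transformed = transformed, reference = reference, truth = truth)
}

#' Extract junction sequences around an integration event
#'
#' Returns the two junction sequences of a simulated event, each centred on
#' its breakpoint with `flank` bases of genome and of insertion. With the
#' default right-border-leading orientation the upstream junction is the
#' right-border side and the downstream junction the left-border side.
#'
#' @param event Result of [integrate_tdna()].
#' @param flank Bases on each side of the breakpoint (default 300).
#' @return Named character vector with elements `right` and `left`.
#' @export
extract_junctions <- function(event, flank = 300L) {
  tr <- event$truth
  chrom <- event$transformed[[tr$chrom]]
  ins_len <- tr$transferred_length
  stopifnot(flank <= ins_len, tr$site > flank)
  up <- substring(chrom, tr$site - flank + 1L, tr$site + flank)
  down <- substring(chrom, tr$site + ins_len - flank + 1L,
                    tr$site + ins_len + flank)
  if (tr$rb_leading) c(right = up, left = down) else c(left = up, right = down)
}

#' Simulate a paired-end short-read library
#'
#' Draws `round(coverage * genome_length / (2 * read_len))` read pairs:
#' fragment lengths from a normal truncated below at
#' `max(read_len, 2 * read_len - 50)`, fragment starts uniform per
#' chromosome (chromosomes weighted by length), mate 1 the fragment's 5'
#' end, mate 2 the reverse complement of its 3' end, and independent
#' per-base substitution errors at `error_rate`. Output is byte-identical
#' for identical `(parameters, seed)`.
#'
#' @param genome Named character vector of chromosomes.
#' @param coverage Mean depth (must be > 0).
#' @param read_len Read length (default 150).
#' @param insert_mean,insert_sd Fragment-size distribution (defaults 350 and
#'   35; a mean below `2 * read_len` is allowed but flagged, mates then
#'   overlap).
#' @param error_rate Per-base substitution probability (default 0.01; no
#'   indels — the substitution-only model keeps mapper and caller behaviour
#'   separable).
#' @param seed Integer seed.
#' @return A list with `pairs` (tibble: `pair_id`, `read1`, `qual1`,
#'   `read2`, `qual2`) and `truth` (tibble of fragment placements).
#' @export
simulate_reads <- function(genome, coverage, read_len = 150L,
                           insert_mean = 350L, insert_sd = 35L,
                           error_rate = 0.01, seed = 1) {
  if (coverage <= 0) abort("coverage must be positive")
  genome <- as_seq_vector(genome)
  lens <- vapply(genome, seq_len_bp, integer(1))
  if (insert_mean < 2L * read_len) {
    warn("insert_mean below twice the read length: mates will overlap")
  }
  min_insert <- max(read_len, 2L * read_len - 50L)
  n_pairs <- as.integer(round(coverage * sum(lens) / (2 * read_len)))
  withr::with_seed(seed, {
    chrom <- sample(names(genome), n_pairs, replace = TRUE,
                    prob = lens / sum(lens))
    frag <- pmin(pmax(as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                                    insert_sd))),
                      min_insert), lens[chrom])
    start <- as.integer(floor(stats::runif(n_pairs) * (lens[chrom] - frag + 1))) + 1L
    frags <- unname(substring(genome[chrom], start, start + frag - 1L))
    read1 <- substring(frags, 1L, read_len)
    read2 <- revcomp(substring(frags, frag - read_len + 1L, frag))
    if (error_rate > 0) {
      read1 <- add_errors(read1, error_rate)
      read2 <- add_errors(read2, error_rate)
    }
    qual <- strrep("I", read_len)
    list(
      pairs = tibble::tibble(
        pair_id = sprintf("pair%06d", seq_len(n_pairs)),
        read1 = read1, qual1 = qual, read2 = read2, qual2 = qual
      ),
      truth = tibble::tibble(
        pair_id = sprintf("pair%06d", seq_len(n_pairs)),
        chrom = chrom, frag_start = start,
        frag_end = start + frag - 1L
      )
    )
  })
}

# independent per-base substitutions; each error picks one of the three
# other bases uniformly
add_errors <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(bases, b), 1), character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate progeny resistance counts for one cross
#'
#' Resistant counts are binomial: probability 3/4 for the selfing of a
#' hemizygous single-locus line (`self_het`, expected 3:1), 1/2 for a
#' backcross to wild type (`backcross`, 1:1), and 0 for a wild-type control
#' cross.
#'
#' @param cross One of `"self_het"`, `"backcross"`, `"control"`.
#' @param n Number of progeny scored (>= 1).
#' @param seed Integer seed.
#' @return A one-row segregation tibble compatible with [chisq_gof()].
#' @export
simulate_progeny <- function(cross = c("self_het", "backcross", "control"),
                             n, seed = 1) {
  cross <- match.arg(cross)
  if (n < 1) abort("n must be at least 1")
  p <- switch(cross, self_het = 0.75, backcross = 0.5, control = 0)
  r <- if (p > 0) withr::with_seed(seed, stats::rbinom(1L, n, p)) else 0L
  tibble::tibble(
    ovule_parent = switch(cross, self_het = "intragenic",
                          backcross = "wild_type", control = "wild_type"),
    pollen_parent = switch(cross, self_het = "intragenic",
                           backcross = "intragenic", control = "wild_type"),
    n_resistant = as.integer(r), n_susceptible = as.integer(n - r),
    ratio = switch(cross, self_het = "3:1", backcross = "1:1", control = "-")
  )
}

#' Simulate a complete single-insertion study
#'
#' Convenience wrapper: genome, donors, construct, one integration event
#' with the canonical geometry (3 right-border bases transferred, 7-bp
#' left-border truncation, 20-bp target-site deletion), and the derived
#' seeds for read simulation.
#'
#' @param seed Master seed; all stages derive their own seeds from it.
#' @param genome_lengths Chromosome lengths (default one 100-kb
#'   chromosome).
#' @param site Insertion site (default mid-chromosome).
#' @param ... Passed to [integrate_tdna()].
#' @return A list: `genome` (reference), `donors`, `construct`, `event`
#'   (see [integrate_tdna()]).
#' @export
simulate_event <- function(seed = 1, genome_lengths = c(chr1 = 100000L),
                           site = NULL, ...) {
  genome <- make_genome(genome_lengths, seed = child_seed(seed, 1))
  donors <- make_donor_library(seed = child_seed(seed, 2))
  construct <- build_construct(donors, seed = child_seed(seed, 3))
  event <- integrate_tdna(genome, construct, site = site, ...)
  list(genome = event$reference, donors = donors, construct = construct,
       event = event)
}
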