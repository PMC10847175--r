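# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_donors <- function() cached("donors", make_donor_library(seed = 5))

fixture_construct <- function() {
  cached("construct", build_construct(fixture_donors(), seed = 5))
}

# one canonical simulated study: 100-kb chromosome, default event geometry
fixture_sim <- function() {
  cached("sim", simulate_event(seed = 7))
}

# a small genome + construct for junction-geometry sweeps
fixture_small_sim <- function() {
  cached("small_sim", {
    genome <- make_genome(c(chr1 = 20000L), seed = 41)
    donors <- fixture_donors()
    construct <- fixture_construct()
    list(genome = genome, donors = donors, construct = construct)
  })
}

# Truth-recovery check allowing for chance microhomology at a simulated
# junction: shared bases adjacent to the switch make the exact breakpoint
# ambiguous by that many bases, and the caller assigns them to the genome
# side. The reported geometry must equal the truth up to that window; it is
# exact when no homology was reported.
check_truth_window <- function(s, rb, lbt, del) {
  hr <- s$microhomology_right
  hl <- s$microhomology_left
  ok <- s$rb_transferred <= rb && rb <= s$rb_transferred + hr &&
    lbt <= s$lb_truncation && s$lb_truncation <= lbt + hl &&
    s$deletion_len <= del && del <= s$deletion_len + hr + hl
  exact <- s$rb_transferred == rb && s$lb_truncation == lbt &&
    s$deletion_len == del
  list(ok = ok, exact = exact)
}

# random junction fixture with known placements; optionally with planted
# microhomology or filler (mutually exclusive)
make_junction_fixture <- function(seed, glen = 120L, vlen = 120L,
                                  mh = 0L, filler_len = 0L,
                                  genome_first = TRUE) {
  withr::with_seed(seed, {
    genome <- random_dna(2000, gc = 0.45)
    vec <- random_dna(2000, gc = 0.45)
    a <- sample(200:800, 1)   # genome segment start (1-based)
    b <- sample(600:1400, 1)  # vector segment start
    g_seg <- substr(genome, a, a + glen - 1L)
    if (mh > 0 && genome_first) {
      # the vector also carries the last mh genome bases just before its
      # segment, so both references explain the bases at the switch
      shared <- substr(g_seg, glen - mh + 1L, glen)
      vec <- paste0(substr(vec, 1, b - mh - 1L), shared,
                    substr(vec, b, nchar(vec)))
    }
    v_seg <- substr(vec, b, b + vlen - 1L)
    if (mh > 0 && !genome_first) {
      # vector leads: the genome carries the last mh vector bases just
      # before its segment
      shared <- substr(v_seg, vlen - mh + 1L, vlen)
      genome <- paste0(substr(genome, 1, a - mh - 1L), shared,
                       substr(genome, a, nchar(genome)))
    }
    fill <- if (filler_len > 0) {
      # filler bases chosen to clash with both adjacent reference bases
      vapply(seq_len(filler_len), function(i) {
        avoid <- c(substr(genome, a + glen - 1L + i, a + glen - 1L + i),
                   substr(vec, b - filler_len + i - 1L, b - filler_len + i - 1L))
        sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
      }, character(1)) |> paste(collapse = "")
    } else ""
    junction <- if (genome_first) paste0(g_seg, fill, v_seg)
                else paste0(v_seg, fill, g_seg)
    list(
      junction = junction, genome = c(chrJ = genome), vector = vec,
      a = a, b = b, glen = glen, vlen = vlen, mh = mh,
      filler = fill, genome_first = genome_first
    )
  })
}
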