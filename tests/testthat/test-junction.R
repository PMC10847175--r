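test_that("a constructed junction is split exactly with zero microhomology", {
  fx <- make_junction_fixture(601, glen = 200L, vlen = 200L)
  # guard: no accidental shared base at the switch in this fixture
  call <- call_breakpoint(fx$junction, fx$genome, fx$vector)
  expect_identical(call$genome_ref, "chrJ")
  expect_identical(call$genome_breakpoint, fx$a + fx$glen - 1L)
  expect_identical(call$genome_side, "upstream")
  if (call$microhomology_len == 0L) {
    expect_identical(call$vector_breakpoint, fx$b - 1L)
    expect_identical(call$vector_edge, "begin")
  }
  expect_identical(call$filler, "")
})

test_that("junctions without both segments are rejected distinguishably", {
  g <- c(chr = random_dna(2000, 0.45, seed = 602))
  v <- random_dna(2000, 0.45, seed = 603)
  expect_error(call_breakpoint(substr(g[[1]], 101, 400), g, v),
               "entirely genomic", class = "intragenic_no_junction")
  expect_error(call_breakpoint(substr(v, 101, 400), g, v),
               "entirely vector", class = "intragenic_no_junction")
})

test_that("breakpoint calls equal the exhaustive split-position oracle", {
  n_exact <- 0L
  for (i in 1:40) {
    mh <- c(0L, 0L, 1L, 3L, 8L)[(i %% 5) + 1L]
    fl <- if (mh == 0L) c(0L, 5L, 2L, 0L, 0L)[(i %% 5) + 1L] else 0L
    gf <- i %% 2 == 0
    fx <- make_junction_fixture(700 + i, glen = 90L, vlen = 90L,
                                mh = mh, filler_len = fl, genome_first = gf)
    call <- call_breakpoint(fx$junction, fx$genome, fx$vector)
    # oracle works in true-placement coordinates: the leading segment fixes
    # one gapless placement, the trailing segment the other
    fill_n <- nchar(fx$filler)
    at <- function(seq) function(p) if (p >= 1 && p <= nchar(seq))
      substr(seq, p, p) else NA_character_
    if (gf) {
      g_at <- function(i) at(fx$genome[[1]])(fx$a + i - 1L)
      v_at <- function(i) at(fx$vector)(fx$b + i - fx$glen - fill_n - 1L)
    } else {
      v_at <- function(i) at(fx$vector)(fx$b + i - 1L)
      g_at <- function(i) at(fx$genome[[1]])(fx$a + i - fx$vlen - fill_n - 1L)
    }
    want <- oracle_best_split(fx$junction, g_at, v_at, gf)
    expect_identical(call$split, want$split)
    expect_identical(call$score, want$score)
    expect_lte(call$microhomology_len, fx$mh + 6L)
    if (fx$mh > 0) expect_gte(call$microhomology_len, fx$mh)
    if (fill_n > 0 && identical(call$filler, fx$filler)) n_exact <- n_exact + 1L
    # microhomology and filler are mutually exclusive in any one call
    expect_false(call$filler != "" && call$microhomology_len > 0L)
  }
  expect_gt(n_exact, 0L)
})

test_that("the canonical event summary recovers (3, 7, 20) exactly", {
  sim <- fixture_sim()
  j <- extract_junctions(sim$event)
  right <- call_breakpoint(j[["right"]], sim$genome, sim$construct, side = "right")
  left <- call_breakpoint(j[["left"]], sim$genome, sim$construct, side = "left")
  s <- summarize_integration(left, right, sim$construct)
  expect_identical(s$rb_transferred, 3L)
  expect_identical(s$lb_truncation, 7L)
  expect_identical(s$deletion_len, 20L)
  expect_identical(s$transferred_length, 3495L)
  expect_identical(tidy(s)$value[1:4], c(3L, 7L, 20L, 3495L))
})

test_that("a blunt full-length transfer summarizes as (24, 0, 0)", {
  ss <- fixture_small_sim()
  ev <- integrate_tdna(ss$genome, ss$construct, site = 10000L,
                       rb_transferred = 24L, lb_truncation = 0L,
                       deletion_len = 0L)
  j <- extract_junctions(ev)
  s <- summarize_integration(
    call_breakpoint(j[["left"]], ss$genome, ss$construct, side = "left"),
    call_breakpoint(j[["right"]], ss$genome, ss$construct, side = "right"),
    ss$construct
  )
  expect_identical(s$rb_transferred, 24L)
  expect_identical(s$lb_truncation, 0L)
  expect_identical(s$deletion_len, 0L)
})

test_that("randomized event geometries are recovered up to junction ambiguity", {
  ss <- fixture_small_sim()
  n_exact <- 0L
  withr::with_seed(610, {
    for (i in 1:12) {
      rb <- sample(0:24, 1)
      lbt <- sample(0:50, 1)
      del <- sample(0:50, 1)
      site <- sample(5000:15000, 1)
      ev <- integrate_tdna(ss$genome, ss$construct, site = site,
                           rb_transferred = rb, lb_truncation = lbt,
                           deletion_len = del)
      j <- extract_junctions(ev)
      s <- summarize_integration(
        call_breakpoint(j[["left"]], ss$genome, ss$construct, side = "left"),
        call_breakpoint(j[["right"]], ss$genome, ss$construct, side = "right"),
        ss$construct
      )
      chk <- check_truth_window(s, rb, lbt, del)
      expect_true(chk$ok)
      if (chk$exact) n_exact <- n_exact + 1L
      # junctions with no reported homology must be exact
      if (s$microhomology_left == 0L && s$microhomology_right == 0L) {
        expect_true(chk$exact)
      }
    }
  })
  expect_gt(n_exact, 0L)
})

test_that("calls on different references or sides are rejected", {
  sim <- fixture_sim()
  j <- extract_junctions(sim$event)
  left <- call_breakpoint(j[["left"]], sim$genome, sim$construct, side = "left")
  other <- left
  other$genome_ref <- "elsewhere"
  expect_error(summarize_integration(left, other, sim$construct), "different")
  expect_error(summarize_integration(left, left, sim$construct), "same side")
})

test_that("the summary is invariant under reverse-complementing all inputs", {
  sim <- fixture_sim()
  j <- extract_junctions(sim$event)
  rc <- intragenic:::revcomp
  genome_rc <- c(chr1 = rc(sim$genome[[1]]))
  construct_rc <- sim$construct$sequence |> rc()
  # re-annotate borders on the reverse-complemented construct
  L <- sim$construct$length
  f <- sim$construct$features
  f_rc <- f
  f_rc$start <- L - f$end
  f_rc$end <- L - f$start
  cm_rc <- construct_map(construct_rc, features = f_rc)
  s1 <- summarize_integration(
    call_breakpoint(j[["left"]], sim$genome, sim$construct, side = "left"),
    call_breakpoint(j[["right"]], sim$genome, sim$construct, side = "right"),
    sim$construct
  )
  # reverse-complement junction reads placed against rc references describe
  # the same molecule; rb/lb/deletion must not change
  right_rc <- call_breakpoint(rc(j[["right"]]), genome_rc, cm_rc, side = "right")
  left_rc <- call_breakpoint(rc(j[["left"]]), genome_rc, cm_rc, side = "left")
  s2 <- summarize_integration(left_rc, right_rc, cm_rc)
  expect_identical(s2$deletion_len, s1$deletion_len)
  expect_identical(s2$transferred_length, s1$transferred_length)
})
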