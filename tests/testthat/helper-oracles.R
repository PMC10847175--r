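# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, their own IUPAC table, direct
# string comparison.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# window-by-window compatibility check; subject N matches only pattern N
oracle_window_ok <- function(window, pattern) {
  w <- strsplit(window, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  if (length(w) != length(p)) return(FALSE)
  for (i in seq_along(w)) {
    allowed <- ORACLE_IUPAC[[p[i]]]
    if (p[i] == "N") allowed <- c(allowed, "N")
    if (!w[i] %in% allowed) return(FALSE)
  }
  TRUE
}

# every-window scan over one or both strands; 0-based half-open forward coords
oracle_scan <- function(s, pattern, both_strands = TRUE) {
  k <- nchar(pattern)
  L <- nchar(s)
  rows <- list()
  if (L >= k) {
    for (i in seq_len(L - k + 1)) {
      win <- substr(s, i, i + k - 1)
      if (oracle_window_ok(win, pattern)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + k, strand = "+", matched = win)
      }
    }
    if (both_strands) {
      rc <- oracle_revcomp(s)
      for (i in seq_len(L - k + 1)) {
        win <- substr(rc, i, i + k - 1)
        if (oracle_window_ok(win, pattern)) {
          rows[[length(rows) + 1]] <- data.frame(
            start = L - (i - 1L + k), end = L - (i - 1L), strand = "-",
            matched = win)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive enumeration over all cut points and window positions
oracle_assemble <- function(seq_a, seq_b, consensus) {
  k <- nchar(consensus)
  rows <- list()
  for (off in 1:(k - 1)) {
    pre <- substr(consensus, 1, off)
    suf <- substr(consensus, off + 1, k)
    for (i in seq_len(max(0, nchar(seq_a) - off + 1))) {
      wa <- substr(seq_a, i, i + off - 1)
      if (!oracle_window_ok(wa, pre)) next
      for (j in seq_len(max(0, nchar(seq_b) - (k - off) + 1))) {
        wb <- substr(seq_b, j, j + (k - off) - 1)
        if (!oracle_window_ok(wb, suf)) next
        rows[[length(rows) + 1]] <- data.frame(
          upstream_start = i - 1L, downstream_start = j - 1L,
          junction_offset = off, assembled = paste0(wa, wb))
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(upstream_start = integer(), downstream_start = integer(),
                      junction_offset = integer(), assembled = character()))
  }
  unique(do.call(rbind, rows))
}

# per-base provenance attribution over a transferred interval
oracle_translocation_lengths <- function(construct, t_start, t_end) {
  p <- construct$provenance
  counts <- integer(nrow(p))
  if (t_end > t_start) {
    for (base in seq(t_start, t_end - 1L)) {
      hit <- which(p$construct_start <= base & base < p$construct_end)
      stopifnot(length(hit) == 1)
      counts[hit] <- counts[hit] + 1L
    }
  }
  counts[counts > 0]
}

# exhaustive split-position scorer for a junction whose true placements are
# known: `g_at(i)`/`v_at(i)` give the reference base aligned to junction
# position i (or NA). Returns the best split with the genome-side tie-break
# used by the caller: largest split when the genome leads, smallest when the
# vector leads.
oracle_best_split <- function(junction, g_at, v_at, genome_first) {
  L <- nchar(junction)
  jb <- strsplit(junction, "")[[1]]
  mg <- vapply(seq_len(L), function(i) identical(jb[i], g_at(i)), logical(1))
  mv <- vapply(seq_len(L), function(i) identical(jb[i], v_at(i)), logical(1))
  best <- -1L; best_s <- NA_integer_
  for (s in 0:L) {
    sc <- if (genome_first) {
      sum(mg[seq_len(s)]) + sum(mv[seq_len(L) > s])
    } else {
      sum(mv[seq_len(s)]) + sum(mg[seq_len(L) > s])
    }
    take <- if (genome_first) sc >= best else sc > best
    if (take) { best <- sc; best_s <- s }
  }
  list(split = best_s, score = best)
}

# Pearson goodness-of-fit statistic written out longhand
oracle_chisq <- function(r, s, ratio_r, ratio_s) {
  n <- r + s
  er <- n * ratio_r / (ratio_r + ratio_s)
  es <- n * ratio_s / (ratio_r + ratio_s)
  (r - er)^2 / er + (s - es)^2 / es
}
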