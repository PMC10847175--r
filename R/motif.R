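# Degenerate (IUPAC) nucleotide motifs and the T-DNA border consensus.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Create a degenerate nucleotide motif
#'
#' A motif is an IUPAC-coded pattern plus a display name. Every character must
#' be one of the 15 IUPAC nucleotide codes (A, C, G, T, R, Y, S, W, K, M, B,
#' D, H, V, N).
#'
#' @param pattern IUPAC nucleotide string.
#' @param name Label carried into hit tables.
#' @return An object of class `degenerate_motif`.
#' @examples
#' motif("KGTMAWS", "border_3p")
#' @export
motif <- function(pattern, name = "motif") {
  stopifnot(is.character(pattern), length(pattern) == 1)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) abort("motif pattern must be non-empty")
  chars <- strsplit(pattern, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC code '%s' at position %d of pattern '%s'",
                  chars[bad[1]], bad[1], pattern))
  }
  structure(list(name = name, pattern = pattern), class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("<degenerate_motif> %s: %s (%d nt, degeneracy %s)\n",
              x$name, x$pattern, nchar(x$pattern),
              format(motif_degeneracy(x), big.mark = ",")))
  invisible(x)
}

as_motif <- function(x, name = "motif") {
  if (inherits(x, "degenerate_motif")) x else motif(x, name)
}

#' The 24-bp T-DNA border consensus and its two flanking sub-motifs
#'
#' The border consensus `GRCAGGATATATNNNNNKGTMAWS` is a 24-bp degenerate
#' direct repeat recognized by the VirD2 nickase. Its two conserved parts,
#' `GRCAGGATATAT` (5') and `KGTMAWS` (3'), flank a five-nucleotide variable
#' region and are the units used to mine host sequence collections for
#' border-like sequences.
#'
#' @param part One of `"full"`, `"motif_5p"`, `"motif_3p"`.
#' @return A [motif()] object.
#' @examples
#' tdna_consensus()
#' motif_degeneracy(tdna_consensus("motif_3p"))
#' @export
tdna_consensus <- function(part = c("full", "motif_5p", "motif_3p")) {
  part <- match.arg(part)
  switch(part,
    full     = motif("GRCAGGATATATNNNNNKGTMAWS", "tdna_border_consensus"),
    motif_5p = motif("GRCAGGATATAT", "border_motif_5p"),
    motif_3p = motif("KGTMAWS", "border_motif_3p")
  )
}

#' Degeneracy of a motif
#'
#' The number of distinct concrete sequences compatible with the pattern:
#' the product over positions of each code's base-set size.
#'
#' @param m A [motif()] or IUPAC string.
#' @return A double (degeneracies overflow integers quickly).
#' @export
motif_degeneracy <- function(m) {
  m <- as_motif(m)
  prod(lengths(IUPAC_SETS[strsplit(m$pattern, "")[[1]]]))
}

#' Expand a degenerate motif into all compatible concrete sequences
#'
#' Enumerates every concrete nucleotide string matching the pattern. The
#' result has exactly `motif_degeneracy(m)` distinct elements.
#'
#' @inheritParams motif_degeneracy
#' @param max_size Guard against runaway expansion; raise it deliberately for
#'   patterns with many N positions.
#' @return Character vector of concrete sequences.
#' @examples
#' expand_motif("GRCAGGATATAT")
#' @export
expand_motif <- function(m, max_size = 1e6) {
  m <- as_motif(m)
  d <- motif_degeneracy(m)
  if (d > max_size) {
    abort(sprintf("degeneracy %.0f exceeds max_size %.0f", d, max_size))
  }
  sets <- IUPAC_SETS[strsplit(m$pattern, "")[[1]]]
  out <- ""
  for (s in sets) {
    out <- as.vector(vapply(s, function(b) paste0(out, b),
                            character(length(out))))
  }
  out
}

#' Realize one concrete instance of a degenerate motif
#'
#' Draws a uniform random member of the motif's expansion; used by the
#' simulator to plant border-like sequences.
#'
#' @inheritParams motif_degeneracy
#' @param seed Optional integer seed.
#' @return A single concrete sequence.
#' @export
realize_motif <- function(m, seed = NULL) {
  m <- as_motif(m)
  sets <- IUPAC_SETS[strsplit(m$pattern, "")[[1]]]
  draw <- function() paste(vapply(sets, function(s) sample(s, 1), character(1)),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Per-position allowed-character sets under the scanning rule: a subject N is
# masked sequence and matches only a pattern N.
scan_sets <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  lapply(seq_along(sets), function(i) {
    if (names(sets)[i] == "N") c(sets[[i]], "N") else sets[[i]]
  })
}

# TRUE iff `window` (concrete, possibly with N) is compatible with `pattern`.
motif_compatible <- function(window, pattern) {
  if (nchar(window) != nchar(pattern)) return(FALSE)
  w <- strsplit(window, "")[[1]]
  sets <- scan_sets(pattern)
  all(vapply(seq_along(w), function(i) w[i] %in% sets[[i]], logical(1)))
}

#' Scan sequences for a degenerate motif
#'
#' Reports every window compatible with the motif, position by position. All
#' overlapping occurrences are reported. Coordinates are 0-based half-open on
#' the forward strand of the subject, regardless of the strand of the hit;
#' `matched` is the hit read in motif orientation (i.e. reverse-complemented
#' for minus-strand hits). A subject `N` (masked base) matches only a pattern
#' position that is itself `N`.
#'
#' @param seqs Named character vector of subject sequences (or a
#'   `DNAStringSet`).
#' @param m A [motif()] or IUPAC string.
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`,
#'   `matched`, `motif`, sorted by `(seq_id, start, strand)`.
#' @examples
#' scan_motif(c(x = "GGCAGGATATAT"), tdna_consensus("motif_5p"))
#' @export
scan_motif <- function(seqs, m, both_strands = TRUE) {
  m <- as_motif(m)
  seqs <- as_seq_vector(seqs)
  assert_dna(unname(seqs), "subject")
  hits <- purrr::imap(seqs, function(s, id) {
    fwd <- scan_one(s, m$pattern)
    res <- if (nrow(fwd)) tibble::add_column(fwd, strand = "+") else NULL
    if (both_strands) {
      L <- seq_len_bp(s)
      rev <- scan_one(revcomp(s), m$pattern)
      if (nrow(rev)) {
        rev <- tibble::tibble(start = L - rev$end, end = L - rev$start,
                              matched = rev$matched, strand = "-")
        res <- dplyr::bind_rows(res, rev)
      }
    }
    if (is.null(res)) return(NULL)
    tibble::add_column(res, seq_id = id, .before = 1)
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          matched = character(), motif = character()))
  }
  out |>
    dplyr::mutate(motif = m$name) |>
    dplyr::select("seq_id", "start", "end", "strand", "matched", "motif") |>
    dplyr::arrange(.data$seq_id, .data$start, .data$strand)
}

# Vectorized forward-strand scan of one subject; 0-based half-open output.
scan_one <- function(s, pattern) {
  L <- seq_len_bp(s)
  k <- nchar(pattern)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          matched = character())
  if (L < k) return(empty)
  chars <- strsplit(s, "")[[1]]
  sets <- scan_sets(pattern)
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    ok <- ok & chars[seq_len(n_win) + j - 1L] %in% sets[[j]]
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  tibble::tibble(
    start = starts - 1L,
    end = starts - 1L + k,
    matched = substring(s, starts, starts + k - 1L)
  )
}
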