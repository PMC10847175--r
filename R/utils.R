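# Internal low-level sequence helpers. Sequences are plain upper-case character
# scalars throughout; Biostrings objects appear only at I/O boundaries.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn
NULL

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (!is.character(x)) abort(sprintf("%s must be a character vector", what))
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s} (first offender: element %d)",
      what, if (allow_n) ",N" else "", which(bad)[1]
    ))
  }
  invisible(x)
}

# IUPAC complement covers the full degenerate alphabet.
revcomp <- function(x) {
  from <- "ACGTRYSWKMBDHVNacgtryswkmbdhvn"
  to   <- "TGCAYRSWMKVHDBNtgcayrswmkvhdbn"
  comp <- chartr(from, to, x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

seq_len_bp <- function(x) nchar(x, type = "bytes")

#' Generate a random DNA sequence
#'
#' Draws i.i.d. bases with a specified GC content. Used by the simulators;
#' exported because fixtures in scripts and examples need it too.
#'
#' @param n Length in bp.
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed (local RNG scope; the global RNG state is
#'   untouched).
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5, seed = NULL) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  draw <- function() {
    if (n == 0) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Positionwise match indicator of two equal-length strings.
match_vector <- function(a, b) {
  va <- utf8ToInt(a)
  vb <- utf8ToInt(b)
  stopifnot(length(va) == length(vb))
  va == vb
}

# Maximum-scoring contiguous segment of a logical match vector
# (match = +1, mismatch = mismatch_penalty). Returns list(start, end, matches)
# with 1-based inclusive coordinates into `m`, or NULL when all mismatch.
best_segment <- function(m, mismatch_penalty = -3) {
  vals <- ifelse(m, 1, mismatch_penalty)
  best <- 0; best_i <- 0L; best_j <- -1L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(vals)) {
    if (cur <= 0) { cur <- 0; cur_i <- j }
    cur <- cur + vals[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  if (best_j < best_i) return(NULL)
  list(start = best_i, end = best_j, matches = sum(m[best_i:best_j]))
}

# Published segregation tables print statistics truncated (not rounded) to
# 2 decimals; reproduce that display convention.
trunc2 <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

# Deterministic child seeds below 2^31 derived from a user seed.
child_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + 97 * as.numeric(k)) %% 2147480000)
}
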