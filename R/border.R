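# Assembly of full-length T-DNA border candidates by adjoining parts of two
# host sequences, the in-silico analogue of ligating EST-derived fragments.

#' Assemble border candidates from two host sequences
#'
#' Enumerates every way to cut the 24-bp border consensus at an internal
#' offset and realize the 5' part from a window of `seq_a` and the 3' part
#' from a window of `seq_b`, so that the 24-nt concatenation matches the full
#' consensus. Windows are taken on the forward strand of each source sequence
#' at every position; candidates are deduplicated on
#' `(assembled, junction_offset, sources)`.
#'
#' @param seq_a,seq_b Host sequences (single strings) supplying the 5' and 3'
#'   parts respectively.
#' @param consensus Border consensus [motif()]; defaults to the 24-bp T-DNA
#'   consensus.
#' @param id_a,id_b Identifiers recorded in the output.
#' @return A tibble of border candidates with 0-based half-open source
#'   intervals (`upstream_*` from `seq_a`, `downstream_*` from `seq_b`),
#'   `junction_offset` (1..23, position in the 24-mer where the sources
#'   meet), `assembled` (the concrete 24-mer) and `border_side`
#'   (`"unassigned"`; sidedness is a downstream design choice, not a sequence
#'   property).
#' @examples
#' a <- paste0("TTTTT", "GGCAGGATATATACG")      # consensus positions 1-15
#' b <- paste0("TATGTCATG", "AAAAA")            # positions 16-24
#' assemble_border_candidates(a, b)
#' @export
assemble_border_candidates <- function(seq_a, seq_b,
                                       consensus = tdna_consensus(),
                                       id_a = "seqA", id_b = "seqB") {
  consensus <- as_motif(consensus)
  k <- nchar(consensus$pattern)
  if (k != 24) abort("border consensus must be 24 bp")
  assert_dna(c(seq_a, seq_b), "source sequence")
  out <- purrr::map(seq_len(k - 1L), function(off) {
    pre <- substr(consensus$pattern, 1L, off)
    suf <- substr(consensus$pattern, off + 1L, k)
    ha <- scan_one(seq_a, pre)
    if (!nrow(ha)) return(NULL)
    hb <- scan_one(seq_b, suf)
    if (!nrow(hb)) return(NULL)
    grid <- tidyr::expand_grid(ia = seq_len(nrow(ha)), ib = seq_len(nrow(hb)))
    tibble::tibble(
      upstream_id = id_a,
      upstream_start = ha$start[grid$ia],
      upstream_end = ha$end[grid$ia],
      downstream_id = id_b,
      downstream_start = hb$start[grid$ib],
      downstream_end = hb$end[grid$ib],
      junction_offset = off,
      assembled = paste0(ha$matched[grid$ia], hb$matched[grid$ib]),
      border_side = "unassigned"
    )
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty_border_candidates())
  dplyr::distinct(out) |>
    dplyr::arrange(.data$junction_offset, .data$upstream_start,
                   .data$downstream_start)
}

empty_border_candidates <- function() {
  tibble::tibble(
    upstream_id = character(), upstream_start = integer(),
    upstream_end = integer(), downstream_id = character(),
    downstream_start = integer(), downstream_end = integer(),
    junction_offset = integer(), assembled = character(),
    border_side = character()
  )
}

#' Find border candidates across a sequence collection
#'
#' Batch driver over all ordered pairs of distinct sequences in a collection
#' (e.g. an EST set), plus single-sequence hits where one sequence alone
#' contains a full consensus match (reported with `junction_offset = NA` and
#' the hit interval in the `upstream_*` columns).
#'
#' Note that because left and right T-DNA borders share one consensus, every
#' sequence hosting a 5'-part window can pair with every sequence hosting a
#' 3'-part window; candidate sets grow as the product of the two host sets.
#'
#' @param seqs Named character vector (or `DNAStringSet`) with at least two
#'   sequences for pair enumeration; fewer are allowed and yield only
#'   single-sequence hits.
#' @inheritParams assemble_border_candidates
#' @return A tibble as in [assemble_border_candidates()].
#' @export
find_border_pairs <- function(seqs, consensus = tdna_consensus()) {
  consensus <- as_motif(consensus)
  seqs <- as_seq_vector(seqs)
  if (!length(seqs)) return(empty_border_candidates())
  ids <- names(seqs)
  pairs <- NULL
  if (length(seqs) >= 2) {
    grid <- tidyr::expand_grid(a = ids, b = ids) |>
      dplyr::filter(.data$a != .data$b)
    pairs <- purrr::pmap(grid, function(a, b) {
      assemble_border_candidates(seqs[[a]], seqs[[b]], consensus,
                                 id_a = a, id_b = b)
    }) |> dplyr::bind_rows()
  }
  singles <- scan_motif(seqs, consensus, both_strands = FALSE)
  if (nrow(singles)) {
    singles <- tibble::tibble(
      upstream_id = singles$seq_id, upstream_start = singles$start,
      upstream_end = singles$end, downstream_id = NA_character_,
      downstream_start = NA_integer_, downstream_end = NA_integer_,
      junction_offset = NA_integer_, assembled = singles$matched,
      border_side = "unassigned"
    )
  } else {
    singles <- NULL
  }
  out <- dplyr::bind_rows(pairs, singles)
  if (!nrow(out)) return(empty_border_candidates())
  out
}
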