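# Vector-anchored paired-end insertion-site calling: keep read pairs with
# exactly one mate on the vector, map the other (informative) mate to the
# host genome, and cluster.

#' Filter read pairs to vector-anchored mates
#'
#' Retains exactly the pairs in which one mate maps to the vector and the
#' other does not; pairs where neither or both ends map to the vector are
#' discarded. The anchored mate is classified as `tdna`, `backbone` or
#' `other` by the midpoint of its vector alignment against the construct's
#' annotated features.
#'
#' @param pairs Read-pair tibble (`pair_id`, `read1`, `read2`, ...).
#' @param vector A `construct_map` with `tdna_region` and `backbone`
#'   features.
#' @param min_identity,min_aligned_frac Mapping thresholds passed to
#'   [map_to_reference()].
#' @return A tibble of anchored mates: `pair_id`, `anchored_mate` (1 or 2),
#'   `vector_start`, `vector_end` (0-based half-open on the construct),
#'   `anchor_strand`, `vector_segment`, `informative_sequence`.
#' @export
anchor_filter <- function(pairs, vector, min_identity = 0.9,
                          min_aligned_frac = 0.5) {
  stopifnot(inherits(vector, "construct_map"))
  empty <- tibble::tibble(
    pair_id = character(), anchored_mate = integer(),
    vector_start = integer(), vector_end = integer(),
    anchor_strand = character(), vector_segment = character(),
    informative_sequence = character()
  )
  if (!nrow(pairs)) return(empty)
  reads <- c(
    stats::setNames(pairs$read1, paste0(pairs$pair_id, "/1")),
    stats::setNames(pairs$read2, paste0(pairs$pair_id, "/2"))
  )
  aln <- map_to_reference(reads, c(vector = vector$sequence),
                          min_identity = min_identity,
                          min_aligned_frac = min_aligned_frac)
  mapped <- tibble::tibble(
    pair_id = sub("/[12]$", "", aln$query_id),
    mate = as.integer(sub("^.*/", "", aln$query_id)),
    vstart = aln$ref_start, vend = aln$ref_end, strand = aln$strand
  )
  n_mapped <- mapped |> dplyr::count(.data$pair_id)
  keep <- n_mapped$pair_id[n_mapped$n == 1L]
  mapped <- mapped[mapped$pair_id %in% keep, , drop = FALSE]
  if (!nrow(mapped)) return(empty)
  mid <- (mapped$vstart - 1L + mapped$vend) / 2   # 0-based midpoint
  other <- ifelse(mapped$mate == 1L, 2L, 1L)
  prow <- match(mapped$pair_id, pairs$pair_id)
  tibble::tibble(
    pair_id = mapped$pair_id,
    anchored_mate = mapped$mate,
    vector_start = mapped$vstart - 1L,
    vector_end = mapped$vend,
    anchor_strand = mapped$strand,
    vector_segment = classify_vector_position(vector, mid),
    informative_sequence = ifelse(other == 1L, pairs$read1[prow],
                                  pairs$read2[prow])
  )
}

classify_vector_position <- function(vector, pos0) {
  td <- feature_interval(vector, "tdna_region", required = FALSE)
  bb <- vector$features[vector$features$role == "backbone", , drop = FALSE]
  out <- rep("other", length(pos0))
  if (!is.null(td)) out[pos0 >= td[1] & pos0 < td[2]] <- "tdna"
  for (i in seq_len(nrow(bb))) {
    out[pos0 >= bb$start[i] & pos0 < bb$end[i]] <- "backbone"
  }
  out
}

#' Call insertion loci from anchored mates
#'
#' Maps the informative (non-vector) mate of each T-DNA-anchored pair to the
#' host genome, drops mates with multiple equally good placements, and
#' clusters the remaining placements per chromosome by single linkage with a
#' maximum gap. Clusters reaching `min_support` are emitted as insertion
#' calls with support partitioned by informative-mate orientation.
#'
#' @param anchored Output of [anchor_filter()].
#' @param genome Named character vector of host chromosomes.
#' @param cluster_gap Maximum gap (bp) joining placements into one cluster;
#'   default 700, about twice the 350-bp library insert.
#' @param min_support Minimum mates per emitted call (default 3).
#' @inheritParams anchor_filter
#' @return A tibble of class `insertion_calls`: `dest_ref`, `start`, `end`
#'   (1-based closed cluster span), `support_fwd`, `support_rev`,
#'   `n_support`, sorted by `(dest_ref, start)`.
#' @export
call_insertions <- function(anchored, genome, cluster_gap = 700L,
                            min_support = 3L, min_identity = 0.9,
                            min_aligned_frac = 0.5) {
  empty <- tibble::new_tibble(list(
    dest_ref = character(), start = integer(), end = integer(),
    support_fwd = integer(), support_rev = integer(), n_support = integer()
  ), class = "insertion_calls")
  anchored <- anchored[anchored$vector_segment == "tdna", , drop = FALSE]
  if (!nrow(anchored)) return(empty)
  reads <- stats::setNames(anchored$informative_sequence, anchored$pair_id)
  aln <- map_to_reference(reads, genome, min_identity = min_identity,
                          min_aligned_frac = min_aligned_frac)
  n_ambig <- sum(aln$n_best > 1L)
  if (n_ambig > 0) {
    rlang::inform(sprintf("dropping %d ambiguously placed informative mate(s)",
                          n_ambig))
  }
  aln <- aln[aln$n_best == 1L, , drop = FALSE]
  if (!nrow(aln)) return(empty)
  calls <- aln |>
    dplyr::group_by(.data$ref_id) |>
    dplyr::arrange(.data$ref_start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      c(TRUE, .data$ref_start[-1] - cummax(.data$ref_end)[-dplyr::n()] >
          cluster_gap))) |>
    dplyr::group_by(.data$ref_id, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$ref_start), end = max(.data$ref_end),
      support_fwd = sum(.data$strand == "+"),
      support_rev = sum(.data$strand == "-"),
      n_support = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_support >= min_support) |>
    dplyr::transmute(dest_ref = .data$ref_id, start = .data$start,
                     end = .data$end, support_fwd = .data$support_fwd,
                     support_rev = .data$support_rev,
                     n_support = .data$n_support) |>
    dplyr::arrange(.data$dest_ref, .data$start)
  tibble::new_tibble(calls, class = "insertion_calls")
}

#' Screen read pairs for vector-backbone integration
#'
#' Maps every mate of every pair to the vector and counts the pairs in which
#' at least one mate's best alignment lies in the annotated backbone. A count
#' of zero certifies the event backbone-free at the sampled coverage.
#'
#' @inheritParams anchor_filter
#' @return Integer count of backbone-evidencing pairs.
#' @export
backbone_screen <- function(pairs, vector, min_identity = 0.9,
                            min_aligned_frac = 0.5) {
  stopifnot(inherits(vector, "construct_map"))
  if (!nrow(pairs)) return(0L)
  reads <- c(
    stats::setNames(pairs$read1, paste0(pairs$pair_id, "/1")),
    stats::setNames(pairs$read2, paste0(pairs$pair_id, "/2"))
  )
  aln <- map_to_reference(reads, c(vector = vector$sequence),
                          min_identity = min_identity,
                          min_aligned_frac = min_aligned_frac)
  if (!nrow(aln)) return(0L)
  mid <- (aln$ref_start - 1L + aln$ref_end) / 2
  seg <- classify_vector_position(vector, mid)
  length(unique(sub("/[12]$", "", aln$query_id[seg == "backbone"])))
}

#' Write and read insertion calls as GFF3
#'
#' One `insertion_site` feature per call, with support counts in the
#' attribute column; the GFF3 round-trips losslessly through
#' [read_insertion_gff()].
#'
#' @param calls An `insertion_calls` tibble.
#' @param path Output path.
#' @return The path (write) or an `insertion_calls` tibble (read).
#' @export
write_insertion_gff <- function(calls, path) {
  gr <- GRanges(
    seqnames = if (nrow(calls)) calls$dest_ref else character(),
    ranges = IRanges(start = calls$start, end = calls$end)
  )
  S4Vectors::mcols(gr)$type <- rep("insertion_site", nrow(calls))
  S4Vectors::mcols(gr)$support_fwd <- calls$support_fwd
  S4Vectors::mcols(gr)$support_rev <- calls$support_rev
  S4Vectors::mcols(gr)$n_support <- calls$n_support
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_insertion_gff
#' @export
read_insertion_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::new_tibble(list(
    dest_ref = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    support_fwd = as.integer(S4Vectors::mcols(gr)$support_fwd),
    support_rev = as.integer(S4Vectors::mcols(gr)$support_rev),
    n_support = as.integer(S4Vectors::mcols(gr)$n_support)
  ), class = "insertion_calls")
}
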