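# The micro-translocation report: which source fragments, and how much of
# each, end up at the genomic destination when a sub-interval of the
# construct is transferred.

#' Tabulate a transferred interval by source provenance
#'
#' Intersects a transferred construct interval with the construct's
#' provenance fragments and reports one record per intersecting fragment,
#' with lengths clipped to the intersection. The destination position of each
#' record is laid out left to right in transfer order, so the records
#' describe exactly where each source fragment lands. Transferred lengths
#' always sum to the span of the transferred interval.
#'
#' @param construct A `construct_map` with provenance.
#' @param transferred_start,transferred_end Transferred interval on the
#'   construct, 0-based half-open. Must lie within the construct (use
#'   coordinates within the annotated T-DNA region for a biological
#'   transfer).
#' @param dest_ref Destination reference name (e.g. a chromosome).
#' @param dest_position 1-based destination position of the first transferred
#'   base.
#' @return A tibble with columns `source_ref`, `source_start`, `source_end`
#'   (1-based closed on the source), `dest_ref`, `dest_pos`,
#'   `transferred_length`.
#' @export
translocation_table <- function(construct, transferred_start, transferred_end,
                                dest_ref = "chr", dest_position = 1L) {
  stopifnot(inherits(construct, "construct_map"))
  if (transferred_start < 0 || transferred_end > construct$length ||
      transferred_start > transferred_end) {
    abort("transferred interval outside the construct")
  }
  empty <- tibble::tibble(
    source_ref = character(), source_start = integer(),
    source_end = integer(), dest_ref = character(), dest_pos = integer(),
    transferred_length = integer()
  )
  if (transferred_end == transferred_start) return(empty)
  p <- dplyr::arrange(construct$provenance, .data$construct_start)
  if (!nrow(p)) abort("construct has no provenance to tabulate")
  lo <- pmax(p$construct_start, transferred_start)
  hi <- pmin(p$construct_end, transferred_end)
  keep <- hi > lo
  p <- p[keep, , drop = FALSE]
  lo <- lo[keep]; hi <- hi[keep]
  tibble::tibble(
    source_ref = p$source_ref,
    source_start = p$source_start + (lo - p$construct_start),
    source_end = p$source_start + (hi - p$construct_start) - 1L,
    dest_ref = dest_ref,
    dest_pos = as.integer(dest_position + (lo - transferred_start)),
    transferred_length = as.integer(hi - lo)
  )
}
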