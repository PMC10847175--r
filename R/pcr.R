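# Exact-match in-silico PCR. Primer sites are located by exact string match
# (the screening primers in this workflow are designed against a known
# construct, so no mismatch tolerance is modelled); degenerate primer codes
# are rejected.

#' Predict PCR products on a template
#'
#' Finds every amplicon defined by an exact match of the forward primer on
#' the plus strand and an exact match of the reverse complement of the
#' reverse primer downstream of it, within `max_len`. Product length is
#' counted inclusive of both primers — the convention under which a product
#' spanning both primer binding sites is reported. Circular templates are
#' scanned across the origin and products are deduplicated modulo the
#' template length.
#'
#' @param template A `construct_map` or a single sequence string.
#' @param fwd_primer,rev_primer Primer sequences (>= 15 nt, concrete bases
#'   only; the reverse primer is given 5'->3' on the opposite strand as
#'   usual).
#' @param max_len Maximum product length considered (default 5000).
#' @param circular Treat a plain-sequence template as circular? Ignored when
#'   `template` is a `construct_map` (its own flag is used).
#' @return A tibble with one row per product: `start` (0-based on the
#'   template, position of the first forward-primer base), `end` (half-open;
#'   may exceed the template length when the amplicon wraps the origin) and
#'   `product_length`.
#' @examples
#' tmpl <- random_dna(100, seed = 1)
#' in_silico_pcr(tmpl, substr(tmpl, 1, 20), revcomp(substr(tmpl, 81, 100)),
#'               circular = FALSE)
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer, max_len = 5000,
                          circular = NULL) {
  if (inherits(template, "construct_map")) {
    seq <- template$sequence
    circular <- template$is_circular
  } else {
    seq <- toupper(template)
    circular <- circular %||% FALSE
  }
  assert_dna(seq, "template")
  for (p in c(fwd = fwd_primer, rev = rev_primer)) {
    if (nchar(p) < 15) abort("primers must be at least 15 nt")
    if (!grepl("^[ACGT]+$", toupper(p))) {
      abort("degenerate primer codes are not supported (exact-match dialect)")
    }
  }
  fwd <- toupper(fwd_primer)
  rev_site <- revcomp(toupper(rev_primer))
  L <- seq_len_bp(seq)
  scan_seq <- if (circular) paste0(seq, seq) else seq
  f_pos <- find_site(scan_seq, fwd)    # 0-based starts
  r_pos <- find_site(scan_seq, rev_site)
  if (circular) f_pos <- f_pos[f_pos < L]  # one origin copy per forward site
  out <- purrr::map(f_pos, function(s) {
    ends <- r_pos[r_pos >= s] + nchar(rev_site)  # half-open amplicon ends
    ends <- ends[ends - s <= max_len & ends - s >= nchar(fwd)]
    if (!length(ends)) return(NULL)
    tibble::tibble(start = s, end = ends, product_length = ends - s)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          product_length = integer()))
  }
  if (circular) out <- out[out$product_length <= L, , drop = FALSE]
  dplyr::distinct(out) |> dplyr::arrange(.data$start, .data$end)
}
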