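# The annotated vector construct: sequence + features + per-fragment
# provenance. Internal coordinates are 0-based half-open on the construct;
# provenance source intervals are 1-based closed on the source sequence
# (coordinates in exported GFF3 are 1-based closed, the format's convention).

FEATURE_ROLES <- c("left_border", "right_border", "gene", "promoter",
                   "terminator", "backbone", "tdna_region", "other")

#' Construct maps
#'
#' A `construct_map` holds a (possibly circular) vector sequence together
#' with its annotated features and an ordered per-fragment provenance that
#' tiles the construct without gaps or overlap — each base of the construct
#' is attributed to exactly one source fragment.
#'
#' @param sequence Construct sequence (single string over A,C,G,T,N).
#' @param is_circular Is the molecule circular?
#' @param features Tibble with columns `name`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `role` (one of left_border,
#'   right_border, gene, promoter, terminator, backbone, tdna_region, other).
#' @param provenance Tibble with columns `label`, `source_ref`,
#'   `source_start`, `source_end` (1-based closed on the source),
#'   `construct_start`, `construct_end` (0-based half-open on the construct),
#'   `role`.
#' @param primers Optional tibble of designed primers (`name`, `seq`).
#' @return An object of class `construct_map`.
#' @export
construct_map <- function(sequence, is_circular = TRUE,
                          features = NULL, provenance = NULL,
                          primers = NULL) {
  assert_dna(sequence, "construct sequence")
  L <- seq_len_bp(sequence)
  features <- features %||% tibble::tibble(
    name = character(), start = integer(), end = integer(),
    strand = character(), role = character()
  )
  provenance <- provenance %||% tibble::tibble(
    label = character(), source_ref = character(), source_start = integer(),
    source_end = integer(), construct_start = integer(),
    construct_end = integer(), role = character()
  )
  x <- structure(
    list(sequence = sequence, length = L, is_circular = is_circular,
         features = features, provenance = provenance, primers = primers),
    class = "construct_map"
  )
  validate_construct_map(x)
}

validate_construct_map <- function(x) {
  f <- x$features
  if (nrow(f)) {
    stopifnot(all(f$role %in% FEATURE_ROLES))
    if (any(f$start < 0 | f$end > x$length | f$start >= f$end)) {
      abort("construct features out of bounds")
    }
    if ("tdna_region" %in% f$role) {
      if (sum(f$role == "left_border") != 1 || sum(f$role == "right_border") != 1) {
        abort("an annotated tdna_region requires exactly one left and one right border")
      }
    }
  }
  p <- x$provenance
  if (nrow(p)) {
    p <- dplyr::arrange(p, .data$construct_start)
    if (p$construct_start[1] != 0 || p$construct_end[nrow(p)] != x$length ||
        (nrow(p) > 1 && any(p$construct_start[-1] != p$construct_end[-nrow(p)]))) {
      abort("provenance fragments must tile the construct without gaps or overlap")
    }
    span <- p$source_end - p$source_start + 1L
    if (any(span != p$construct_end - p$construct_start)) {
      abort("provenance source interval spans must equal construct interval spans")
    }
  }
  x
}

#' @export
print.construct_map <- function(x, ...) {
  cat(sprintf("<construct_map> %d bp, %s\n", x$length,
              if (x$is_circular) "circular" else "linear"))
  if (nrow(x$features)) {
    cat(sprintf("  features: %s\n",
                paste(sprintf("%s[%d,%d)", x$features$name, x$features$start,
                              x$features$end), collapse = ", ")))
  }
  if (nrow(x$provenance)) {
    cat(sprintf("  provenance: %d fragments from %d sources\n",
                nrow(x$provenance), dplyr::n_distinct(x$provenance$source_ref)))
  }
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy construct_map
#' @export
tidy.construct_map <- function(x, ...) {
  dplyr::mutate(x$features, length = .data$end - .data$start)
}

#' @method glance construct_map
#' @export
glance.construct_map <- function(x, ...) {
  td <- feature_interval(x, "tdna_region", required = FALSE)
  tibble::tibble(
    length = x$length,
    is_circular = x$is_circular,
    n_features = nrow(x$features),
    n_fragments = nrow(x$provenance),
    tdna_length = if (is.null(td)) NA_integer_ else td[2] - td[1]
  )
}

# c(start, end) 0-based half-open of the unique feature with a given role.
feature_interval <- function(x, role, required = TRUE) {
  f <- x$features[x$features$role == role, ]
  if (nrow(f) != 1) {
    if (required) abort(sprintf("construct has no unique '%s' feature", role))
    return(NULL)
  }
  c(f$start, f$end)
}

construct_subseq <- function(x, start, end) {
  # 0-based half-open, with wrap-around on circular constructs
  L <- x$length
  if (end <= L) return(substring(x$sequence, start + 1L, end))
  if (!x$is_circular) abort("interval beyond the end of a linear construct")
  paste0(substring(x$sequence, start + 1L, L), substring(x$sequence, 1L, end - L))
}

find_site <- function(seq, site) {
  # all 0-based starts of fixed `site` in `seq`
  out <- integer(0); from <- 1L
  repeat {
    p <- regexpr(site, substring(seq, from), fixed = TRUE)
    if (p < 0) break
    out <- c(out, from + p - 2L)
    from <- from + p
  }
  out
}

#' In-silico restriction-ligation assembly
#'
#' Digests an insert flanked by exactly two copies of a restriction site and a
#' circular backbone carrying exactly one copy, then ligates the released
#' insert fragment into the opened backbone. Both ligation junctions
#' regenerate the site, so the product length is
#' `length(backbone) + length(core) + length(site)` where `core` is the
#' sequence strictly between the two insert sites. Both insert orientations
#' are valid ligation products; the caller selects one (or keeps both).
#'
#' The returned construct is linearized to start at the first base of the
#' regenerated site preceding the insert, and carries provenance fragments
#' (`insert`, `backbone`, and the two regenerated sites).
#'
#' @param insert Insert sequence containing exactly two occurrences of
#'   `site` (one at each flank of the payload).
#' @param backbone Circular backbone sequence with exactly one occurrence of
#'   `site`.
#' @param site Recognition sequence; default SalI (`GTCGAC`).
#' @param orientation `"both"` (named list of two constructs), `"forward"`
#'   or `"reverse"`.
#' @return A `construct_map`, or a list of two when `orientation = "both"`.
#' @export
digest_and_ligate <- function(insert, backbone, site = "GTCGAC",
                              orientation = c("both", "forward", "reverse")) {
  orientation <- match.arg(orientation)
  assert_dna(c(insert, backbone), "input sequence")
  ins_sites <- find_site(insert, site)
  if (length(ins_sites) != 2) {
    abort(sprintf(
      "insert must contain exactly two '%s' sites; found %d", site,
      length(ins_sites)))
  }
  bb_sites <- find_site(backbone, site)
  # circular backbone: a site spanning the origin is not searched for; one
  # in-frame occurrence is required to linearize
  if (length(bb_sites) != 1) {
    abort(sprintf(
      "backbone must be linearizable at exactly one '%s' site; found %d",
      site, length(bb_sites)))
  }
  w <- nchar(site)
  core <- substring(insert, ins_sites[1] + w + 1L, ins_sites[2])
  # open the circular backbone at its site and drop the site (it is
  # regenerated at each ligation junction)
  bb_open <- paste0(
    substring(backbone, bb_sites[1] + w + 1L, seq_len_bp(backbone)),
    substring(backbone, 1L, bb_sites[1])
  )
  build <- function(core_seq, label) {
    Lc <- seq_len_bp(core_seq)
    prov <- tibble::tibble(
      label = c("site_5p", label, "site_3p", "backbone"),
      source_ref = c("ligation", "insert", "ligation", "backbone"),
      source_start = c(1L, 1L, 1L, 1L),
      source_end = c(w, Lc, w, seq_len_bp(bb_open)),
      construct_start = c(0L, w, w + Lc, 2L * w + Lc),
      construct_end = c(w, w + Lc, 2L * w + Lc, 2L * w + Lc + seq_len_bp(bb_open)),
      role = c("other", "other", "other", "backbone")
    )
    construct_map(paste0(site, core_seq, site, bb_open),
                  is_circular = TRUE, provenance = prov)
  }
  out <- switch(orientation,
    forward = build(core, "insert"),
    reverse = build(revcomp(core), "insert_rc"),
    both = list(forward = build(core, "insert"),
                reverse = build(revcomp(core), "insert_rc"))
  )
  out
}

#' Re-digest a construct at a restriction site
#'
#' Cuts a (circular) construct at every occurrence of the site and returns
#' the fragments with the full recognition sequence retained at each end of
#' the fragment it borders, matching the accounting in [digest_and_ligate()]
#' (fragments are compared as whole-site-to-whole-site sequences).
#'
#' @param x A `construct_map` or sequence string.
#' @inheritParams digest_and_ligate
#' @return Character vector of fragment sequences.
#' @export
redigest <- function(x, site = "GTCGAC") {
  seq <- if (inherits(x, "construct_map")) x$sequence else x
  circular <- if (inherits(x, "construct_map")) x$is_circular else TRUE
  sites <- find_site(seq, site)
  if (!length(sites)) return(seq)
  L <- seq_len_bp(seq)
  w <- nchar(site)
  if (!circular) abort("redigest currently handles circular molecules")
  n <- length(sites)
  vapply(seq_len(n), function(i) {
    a <- sites[i]
    b <- sites[if (i == n) 1L else i + 1L]
    if (b > a) substring(seq, a + 1L, b + w)
    else paste0(substring(seq, a + 1L, L), substring(seq, 1L, b + w))
  }, character(1))
}

#' Write and read a construct as FASTA + GFF3
#'
#' The sequence goes to FASTA; features go to GFF3 with 1-based closed
#' coordinates and the feature role in the `role` attribute. Provenance is
#' written as a plain TSV alongside when `provenance_path` is given.
#'
#' @param x A `construct_map`.
#' @param fasta_path,gff_path,provenance_path Output paths.
#' @param seq_id Sequence name used in both files.
#' @return `write_construct()` the paths, invisibly; `read_construct()` a
#'   `construct_map` (provenance is restored when the TSV is present).
#' @export
write_construct <- function(x, fasta_path, gff_path, provenance_path = NULL,
                            seq_id = "construct") {
  write_fasta(stats::setNames(x$sequence, seq_id), fasta_path)
  gr <- features_to_granges(x$features, seq_id)
  S4Vectors::mcols(gr)$circular <- x$is_circular
  rtracklayer::export(gr, gff_path, format = "gff3")
  if (!is.null(provenance_path)) {
    utils::write.table(x$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta_path, gff_path))
}

#' @rdname write_construct
#' @export
read_construct <- function(fasta_path, gff_path, provenance_path = NULL) {
  seqs <- read_fasta(fasta_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  feats <- granges_to_features(gr)
  circ <- S4Vectors::mcols(gr)$circular
  circ <- if (is.null(circ) || all(is.na(circ))) TRUE else isTRUE(as.logical(circ[1]))
  prov <- NULL
  if (!is.null(provenance_path) && file.exists(provenance_path)) {
    prov <- tibble::as_tibble(utils::read.table(provenance_path, sep = "\t",
                                                header = TRUE))
  }
  construct_map(unname(seqs[1]), is_circular = circ,
                features = feats, provenance = prov)
}
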