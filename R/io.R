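# Format boundaries: Biostrings handles FASTA/FASTQ, rtracklayer handles GFF3.
# Inside the package, sequences are named character vectors and tables are
# tibbles.

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom GenomicRanges GRanges mcols
#' @importFrom IRanges IRanges
NULL

# Accepts a named character vector, a DNAStringSet, or a tibble with columns
# (seq_id, sequence); returns a named character vector of upper-case DNA.
as_seq_vector <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("seq_id", "sequence") %in% names(x)))
    out <- stats::setNames(x$sequence, x$seq_id)
  } else if (is.character(x)) {
    out <- x
  } else {
    abort("expected a named character vector, DNAStringSet or (seq_id, sequence) data frame")
  }
  out <- toupper(out)
  if (length(out) && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

#' Read and write multi-FASTA files
#'
#' Thin wrappers around Biostrings that convert to and from the named
#' character vectors used throughout the package.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  as_seq_vector(readDNAStringSet(path))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- DNAStringSet(as_seq_vector(seqs))
  writeXStringSet(x, path)
  invisible(path)
}

#' Read and write paired FASTQ files
#'
#' Read pairs are kept in a tibble with one row per pair (`pair_id`, `read1`,
#' `qual1`, `read2`, `qual2`); mates are matched by record index across the
#' two files, the usual R1/R2 convention.
#'
#' @param pairs Tibble of read pairs as produced by [simulate_reads()].
#' @param path1,path2 Paths for the R1 and R2 files.
#' @return `read_fastq_pairs()` returns the pairs tibble;
#'   `write_fastq_pairs()` returns the two paths invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  stopifnot(all(c("pair_id", "read1", "qual1", "read2", "qual2") %in% names(pairs)))
  w <- function(seqs, quals, ids, path) {
    # Biostrings warns that the names metadata column is dropped on write;
    # mate identity lives in the record ids, so that drop is intended
    suppressWarnings({
      x <- Biostrings::QualityScaledDNAStringSet(
        DNAStringSet(stats::setNames(unname(seqs), ids)),
        Biostrings::PhredQuality(unname(quals))
      )
      Biostrings::writeQualityScaledXStringSet(x, path)
    })
  }
  w(pairs$read1, pairs$qual1, paste0(pairs$pair_id, "/1"), path1)
  w(pairs$read2, pairs$qual2, paste0(pairs$pair_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  stopifnot(length(r1) == length(r2))
  tibble::tibble(
    pair_id = sub("/1$", "", names(r1)),
    read1 = unname(as.character(r1)),
    qual1 = unname(as.character(r1@quality)),
    read2 = unname(as.character(r2)),
    qual2 = unname(as.character(r2@quality))
  )
}

# tibble(name, start, end, strand, role, [seqid]) with 0-based half-open
# coords -> GRanges (1-based) suitable for GFF3 export.
features_to_granges <- function(features, seqid, type = "region") {
  gr <- GRanges(
    seqnames = seqid,
    ranges = IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand %||% "*"
  )
  S4Vectors::mcols(gr)$Name <- features$name
  S4Vectors::mcols(gr)$role <- features$role
  S4Vectors::mcols(gr)$type <- type
  gr
}

granges_to_features <- function(gr) {
  tibble::tibble(
    name = as.character(S4Vectors::mcols(gr)$Name),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    role = as.character(S4Vectors::mcols(gr)$role)
  )
}
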