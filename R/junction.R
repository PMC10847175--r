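# Base-resolution characterization of integration junctions. Each junction
# sequence is modelled as a single switch between a genomic segment and a
# vector segment; the breakpoint is the split position maximizing total
# matches against the two references over every possible split.

#' Call the breakpoint in a junction sequence
#'
#' Places the junction on the host genome and on the vector (gapless, both
#' strands), then scores every split position `s` (genome-side bases on one
#' side of `s`, vector-side on the other) by total matches and returns the
#' maximizing split. When several splits tie — exactly what microhomology
#' produces — the tie is broken by assigning the shared bases to the genome
#' side, and the length of the maximal identical overlap at the switch is
#' reported as `microhomology_len`. Non-templated bases between the two
#' matched segments are reported as `filler`; microhomology and filler are
#' mutually exclusive.
#'
#' @param junction_seq A single junction sequence containing a genomic and a
#'   vector segment of at least ~20 nt each.
#' @param genome Named character vector of host chromosomes.
#' @param vector A `construct_map` or vector sequence.
#' @param side Label carried into the output (`"left"`, `"right"` or
#'   `"auto"`); the geometry itself is inferred from the placements.
#' @param k Seed length for placement (default 15; junction amplicons are
#'   high-quality consensus sequences).
#' @return A one-row tibble of class `junction_call`: `side`, `genome_ref`,
#'   `genome_breakpoint` (1-based; the retained reference base adjacent to
#'   the switch), `genome_side` (`"upstream"` if the genomic segment is the
#'   flank ending at the breakpoint, `"downstream"` if it begins there),
#'   `genome_strand`, `vector_breakpoint` (0-based construct coordinate
#'   where the integrated sequence begins or ends), `vector_edge`
#'   (`"begin"`/`"end"`), `vector_strand`, `microhomology_len`, `filler`,
#'   `score`, `split`.
#' @export
call_breakpoint <- function(junction_seq, genome, vector,
                            side = c("auto", "left", "right"), k = 15L) {
  side <- match.arg(side)
  vec_seq <- if (inherits(vector, "construct_map")) vector$sequence else vector
  genome <- as_seq_vector(genome)
  assert_dna(junction_seq, "junction sequence")
  L <- seq_len_bp(junction_seq)
  q <- c(junction = junction_seq)
  g_aln <- map_to_reference(q, genome, min_identity = 0.9,
                            min_aligned_frac = 0.01, k = k)
  v_aln <- map_to_reference(q, c(vector = vec_seq), min_identity = 0.9,
                            min_aligned_frac = 0.01, k = k)
  if (!nrow(g_aln) || !nrow(v_aln)) {
    abort(
      sprintf("no junction found: junction sequence is %s",
              if (nrow(g_aln)) "entirely genomic" else if (nrow(v_aln))
                "entirely vector" else "placeable on neither reference"),
      class = "intragenic_no_junction"
    )
  }
  mg <- placement_match_vector(junction_seq, genome[[g_aln$ref_id]], g_aln)
  mv <- placement_match_vector(junction_seq, vec_seq, v_aln)

  genome_first <- sum(mg$m[seq_len(min(20L, L))]) >=
    sum(mv$m[seq_len(min(20L, L))])
  cg <- c(0, cumsum(mg$m))
  cv <- c(0, cumsum(mv$m))
  if (genome_first) {
    sc <- cg + (cv[L + 1L] - cv)             # score over splits 0..L
    split <- max(which(sc == max(sc))) - 1L  # homology to the genome side
  } else {
    sc <- cv + (cg[L + 1L] - cg)
    split <- min(which(sc == max(sc))) - 1L
  }
  # microhomology: positions adjacent to the switch matching both references
  both <- mg$m & mv$m
  run_left <- function(i) { h <- 0L; while (i - h >= 1L && both[i - h]) h <- h + 1L; h }
  run_right <- function(i) { h <- 0L; while (i + h <= L && both[i + h]) h <- h + 1L; h }
  mh <- if (split >= 1L) run_left(split) else 0L
  mh <- mh + (if (split < L) run_right(split + 1L) else 0L)
  # filler: bases between the last match of the leading segment and the
  # first match of the trailing segment that match neither reference
  lead_m <- if (genome_first) mg$m else mv$m
  trail_m <- if (genome_first) mv$m else mg$m
  lead_idx <- which(lead_m)
  lead_idx <- lead_idx[lead_idx <= split]
  lead_last <- if (length(lead_idx)) max(lead_idx) else 0L
  trail_idx <- which(trail_m)
  trail_idx <- trail_idx[trail_idx > split]
  trail_first <- if (length(trail_idx)) min(trail_idx) else L + 1L
  filler <- ""
  if (trail_first - lead_last > 1L && lead_last >= 1L && trail_first <= L) {
    filler <- substring(junction_seq, lead_last + 1L, trail_first - 1L)
    mh <- 0L
  }

  g_edge_pos <- if (genome_first) split else split + 1L
  v_edge_pos <- if (genome_first) split + 1L else split
  g_bp <- mg$ref_pos(g_edge_pos)
  rv <- mv$ref_pos(v_edge_pos)
  vector_is_suffix <- genome_first
  v_begin <- (vector_is_suffix && v_aln$strand == "+") ||
    (!vector_is_suffix && v_aln$strand == "-")
  genome_upstream <- (genome_first && g_aln$strand == "+") ||
    (!genome_first && g_aln$strand == "-")

  tibble::new_tibble(list(
    side = side,
    genome_ref = g_aln$ref_id,
    genome_breakpoint = as.integer(g_bp),
    genome_side = if (genome_upstream) "upstream" else "downstream",
    genome_strand = g_aln$strand,
    vector_breakpoint = as.integer(if (v_begin) rv - 1L else rv),
    vector_edge = if (v_begin) "begin" else "end",
    vector_strand = v_aln$strand,
    microhomology_len = as.integer(mh),
    filler = filler,
    score = as.integer(max(sc)),
    split = as.integer(split)
  ), class = "junction_call")
}

# Extend a placement gaplessly across the full query; return the match
# vector in ORIGINAL query coordinates plus a coordinate map into the
# reference (1-based), NA outside the reference.
placement_match_vector <- function(query, ref_seq, aln) {
  L <- seq_len_bp(query)
  rL <- seq_len_bp(ref_seq)
  oseq <- if (aln$strand == "+") query else revcomp(query)
  offset <- aln$ref_start - aln$query_start   # ref = oriented pos + offset
  opos <- seq_len(L)
  rpos <- opos + offset
  ok <- rpos >= 1L & rpos <= rL
  m_or <- rep(FALSE, L)
  if (any(ok)) {
    i <- range(which(ok))
    m_or[i[1]:i[2]] <- match_vector(
      substring(oseq, i[1], i[2]),
      substring(ref_seq, rpos[i[1]], rpos[i[2]])
    )
  }
  if (aln$strand == "+") {
    list(m = m_or, ref_pos = function(i) i + offset)
  } else {
    list(m = rev(m_or), ref_pos = function(i) (L - i + 1L) + offset)
  }
}

#' Summarize an integration event from its two junction calls
#'
#' Combines the left-border-side and right-border-side junction calls with
#' the construct annotation into the event-level quantities: how many
#' right-border bases transferred, by how much the integrated sequence fell
#' short of the left border, the target-site deletion, and the total length
#' of construct integrated.
#'
#' Conventions: the transferred segment never includes the left border
#' itself (transfer terminates at or before the border-proximal edge), so
#' `lb_truncation` counts the interior bases lost beyond that edge;
#' `rb_transferred` counts right-border bases retained, at most the 24-bp
#' border length.
#'
#' @param left,right `junction_call` rows for the left-border and
#'   right-border junctions of one event, on the same genome reference.
#' @param construct The `construct_map` with annotated borders.
#' @return A one-row tibble of class `integration_summary`: `genome_ref`,
#'   `rb_transferred`, `lb_truncation`, `deletion_len`,
#'   `transferred_length`, `microhomology_left`, `microhomology_right`.
#' @export
summarize_integration <- function(left, right, construct) {
  stopifnot(inherits(construct, "construct_map"))
  if (left$genome_ref != right$genome_ref) {
    abort("junction calls are on different genome references")
  }
  if (left$genome_side == right$genome_side) {
    abort("junction calls describe the same side of the event")
  }
  lb <- feature_interval(construct, "left_border")
  rb <- feature_interval(construct, "right_border")
  # border distances are measured from each border's T-DNA-interior-proximal
  # edge, so they are independent of which way the construct is written
  if (lb[1] < rb[1]) {
    rb_transferred <- right$vector_breakpoint - rb[1]
    lb_truncation <- left$vector_breakpoint - lb[2]
  } else {
    rb_transferred <- rb[2] - right$vector_breakpoint
    lb_truncation <- lb[1] - left$vector_breakpoint
  }
  rb_transferred <- min(max(rb_transferred, 0L), rb[2] - rb[1])
  up <- if (left$genome_side == "upstream") left else right
  down <- if (left$genome_side == "upstream") right else left
  deletion_len <- down$genome_breakpoint - up$genome_breakpoint - 1L
  tibble::new_tibble(list(
    genome_ref = left$genome_ref,
    rb_transferred = as.integer(rb_transferred),
    lb_truncation = as.integer(lb_truncation),
    deletion_len = as.integer(deletion_len),
    transferred_length = as.integer(abs(right$vector_breakpoint -
                                          left$vector_breakpoint)),
    microhomology_left = left$microhomology_len,
    microhomology_right = right$microhomology_len
  ), class = "integration_summary")
}

#' @method tidy integration_summary
#' @export
tidy.integration_summary <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, -1], dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @method glance integration_summary
#' @export
glance.integration_summary <- function(x, ...) tibble::as_tibble(x)
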