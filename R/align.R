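#' Local (Smith-Waterman) alignment score and span
#'
#' Affine-gap local alignment with the fixed scoring scheme used for
#' germline assignment: match +1, mismatch -1, and a gap of length L
#' costing `gap_open + L * gap_extend` (defaults 2 and 1, the same
#' convention as `Biostrings::pairwiseAlignment`, which the test suite
#' uses as an independent oracle).
#'
#' @param query,ref nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score` and 1-based inclusive alignment spans
#'   `q_start`, `q_end`, `r_start`, `r_end` (NA when the best score is 0).
#' @export
sw_align <- function(query, ref, match = 1, mismatch = -1,
                     gap_open = 2, gap_extend = 1) {
  .sw_align_cpp(query, ref, match, mismatch, gap_open, gap_extend)
}

#' Assign germline V and J segments to a contig
#'
#' Aligns the contig against every V and every J segment of the reference
#' and keeps the top-scoring segment of each type; ties are broken by
#' reference order and flagged.  The CDR3 nucleotide span (junction) is
#' located from the V alignment: the last `v_cdr3_nt` reference
#' nucleotides of V (positions 89-96) plus everything up to the start of
#' the J alignment (the joint codon, position 97).  Substitution-only
#' divergence is assumed when mapping reference to contig coordinates.
#'
#' @param contig nucleotide string (>= 50 nt).
#' @param reference a [germline_reference()].
#' @param min_v_score,min_j_score minimum alignment scores for a
#'   productive call.
#' @return list of class `segment_call`: `v_gene`, `v_score`, `j_gene`,
#'   `j_score`, `junction` (0-based half-open span `c(start, end)` on the
#'   contig), `v_tie`, `j_tie`.
#' @export
assign_germline <- function(contig, reference, min_v_score = 50,
                            min_j_score = 15) {
  stopifnot(inherits(reference, "germline_reference"))
  if (is.na(contig) || nchar(contig) == 0)
    stop_ibcrep("empty contig sequence", "ibcrep_input_error")
  if (nchar(contig) < 50)
    stop_ibcrep("contig shorter than 50 nt", "ibcrep_input_error")
  pick <- function(refs, min_score, what) {
    hits <- lapply(refs, function(r) sw_align(contig, r))
    scores <- vapply(hits, `[[`, numeric(1), "score")
    best <- which.max(scores)  # first index on ties = reference order
    if (scores[best] < min_score)
      stop_ibcrep(sprintf("no %s segment above minimum score %g", what,
                          min_score),
                  "ibcrep_unproductive_error")
    list(gene = names(refs)[best], hit = hits[[best]],
         tie = sum(scores == scores[best]) > 1)
  }
  v <- pick(reference$V, min_v_score, "V")
  j <- pick(reference$J, min_j_score, "J")
  # map the reference CDR3 start (len(V) - v_cdr3_nt, 0-based) onto the
  # contig through the V alignment offset
  v_len <- nchar(reference$V[[v$gene]])
  offset <- v$hit$q_start - v$hit$r_start
  junction_start0 <- (v_len - reference$v_cdr3_nt) + offset
  junction_end0 <- j$hit$q_start - 1L
  structure(list(v_gene = v$gene, v_score = v$hit$score,
                 j_gene = j$gene, j_score = j$hit$score,
                 junction = c(junction_start0, junction_end0),
                 v_span = c(v$hit$q_start, v$hit$q_end),
                 j_span = c(j$hit$q_start, j$hit$q_end),
                 v_ref_span = c(v$hit$r_start, v$hit$r_end),
                 j_ref_span = c(j$hit$r_start, j$hit$r_end),
                 v_tie = v$tie, j_tie = j$tie),
            class = "segment_call")
}

#' Assign germline segments to many contigs
#'
#' Vectorized driver for [assign_germline()].  Identical sequences are
#' aligned once and the calls propagated (exact within-clonotype sequence
#' identity is the norm for an unmutated repertoire), which keeps the
#' full three-mouse fixture well under a second.
#'
#' @param sequences named character vector of contig sequences.
#' @param reference a [germline_reference()].
#' @param ... passed to [assign_germline()].
#' @return data.frame with one row per sequence: `contig_id`, `v_gene`,
#'   `v_score`, `j_gene`, `j_score`, `junction_start`, `junction_end`
#'   (0-based half-open), `tie`.
#' @export
call_germlines <- function(sequences, reference, ...) {
  uniq <- unique(sequences)
  calls <- lapply(uniq, assign_germline, reference = reference, ...)
  idx <- match(sequences, uniq)
  data.frame(contig_id = if (is.null(names(sequences)))
               as.character(seq_along(sequences)) else names(sequences),
             v_gene = vapply(calls, `[[`, character(1), "v_gene")[idx],
             v_score = vapply(calls, `[[`, numeric(1), "v_score")[idx],
             j_gene = vapply(calls, `[[`, character(1), "j_gene")[idx],
             j_score = vapply(calls, `[[`, numeric(1), "j_score")[idx],
             junction_start = vapply(calls, function(x) x$junction[1],
                                     numeric(1))[idx],
             junction_end = vapply(calls, function(x) x$junction[2],
                                   numeric(1))[idx],
             tie = vapply(calls, function(x) x$v_tie || x$j_tie,
                          logical(1))[idx],
             stringsAsFactors = FALSE)
}
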