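#' Centered log-ratio normalization of hashtag counts
#'
#' Within each cell, `log1p(count)` minus the cell's mean `log1p(count)`
#' across hashtags.  The pseudocount of 1 (via `log1p`) keeps all-zero
#' cells finite, and a cell with identical counts on every hashtag maps
#' to all-zero CLR values.
#'
#' @param counts non-negative cells x hashtags count matrix.
#' @return matrix of the same shape with CLR values.
#' @export
clr_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0)
    stop_ibcrep("empty hashtag matrix", "ibcrep_input_error")
  if (any(counts < 0))
    stop_ibcrep("hashtag counts must be non-negative",
                "ibcrep_input_error")
  l <- log1p(counts)
  l - rowMeans(l)
}

#' Demultiplex cells to donors from hashtag counts
#'
#' Counts are CLR-normalized per cell; a hashtag is "positive" in a cell
#' when its CLR exceeds a per-hashtag threshold (mean + `k` SD of that
#' hashtag's CLR over *background* cells, i.e. cells whose top hashtag is
#' a different one, floored at 0 -- a hashtag below the cell's own average
#' cannot be positive).  A cell whose top hashtag is positive and beats
#' the runner-up by at least `margin` CLR units is assigned to that
#' donor; otherwise two or more positive hashtags make a multiplet, and
#' anything else is left unassigned.
#'
#' @param counts cells x hashtags count matrix (>= 2 hashtags).
#' @param k threshold stringency in background SD units (default 2).
#' @param margin minimum CLR lead of the top hashtag over the runner-up
#'   (default 1); must be non-negative.
#' @return data.frame of class `donor_assignment`: `barcode`, `state`
#'   (hashtag index as character, `"unassigned"` or `"multiplet"`),
#'   `hashtag` (integer, NA unless assigned), `top_clr`, `margin`;
#'   the full CLR matrix is attached as attribute `clr`, the per-hashtag
#'   thresholds as attribute `thresholds`.
#' @export
demultiplex <- function(counts, k = 2, margin = 1) {
  if (margin < 0)
    stop_ibcrep("margin must be non-negative", "ibcrep_config_error")
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop_ibcrep("at least 2 hashtags are required", "ibcrep_input_error")
  clr <- clr_normalize(counts)
  top <- max.col(clr, ties.method = "first")
  thr <- vapply(seq_len(ncol(clr)), function(h) {
    bg <- clr[top != h, h]
    if (length(bg) < 2) return(0)
    max(mean(bg) + k * sd(bg), 0)
  }, numeric(1))
  above <- sweep(clr, 2, thr, ">")
  n_above <- rowSums(above)
  ord <- t(apply(clr, 1, sort, decreasing = TRUE))
  lead <- ord[, 1] - ord[, 2]
  top_above <- above[cbind(seq_len(nrow(clr)), top)]
  ok <- top_above & lead >= margin
  state <- rep("unassigned", nrow(clr))
  state[!ok & n_above >= 2] <- "multiplet"
  state[ok] <- as.character(top[ok])
  barcodes <- rownames(counts)
  if (is.null(barcodes)) barcodes <- sprintf("CELL%05d-1", seq_len(nrow(counts)))
  out <- data.frame(barcode = barcodes, state = state,
                    hashtag = ifelse(ok, top, NA_integer_),
                    top_clr = ord[, 1], margin = lead,
                    stringsAsFactors = FALSE)
  attr(out, "clr") <- clr
  attr(out, "thresholds") <- thr
  class(out) <- c("donor_assignment", "data.frame")
  out
}
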