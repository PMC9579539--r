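#' Hashtag-count generator configuration
#'
#' Negative-binomial model for hashtag-oligo UMI counts: a cell draws
#' NB(signal) on its own donor's hashtag and NB(background) on every
#' other hashtag.  Multiplets carry two signal hashtags.  The defaults
#' mimic a clean three-donor cell-hashing experiment; the multiplet
#' fraction defaults to 0 because the per-donor totals being emulated are
#' post-filter assigned counts (multiplet injection is opt-in).
#'
#' @param n_hashtags number of hashtag antibodies in the panel.
#' @param signal_mean,signal_dispersion NB mean / size of a cell's own
#'   hashtag counts.
#' @param background_mean,background_dispersion NB mean / size of
#'   off-target counts; `background_mean` must be below `signal_mean`.
#' @param multiplet_fraction fraction of labelled cells that receive a
#'   second signal hashtag.
#' @param unlabeled_fraction fraction of cells stripped of any signal
#'   hashtag when the donor truth does not already mark them as
#'   unlabelled.
#' @return a `hashtag_config` object.
#' @export
hashtag_config <- function(n_hashtags = 3L, signal_mean = 300,
                           signal_dispersion = 3, background_mean = 3,
                           background_dispersion = 1,
                           multiplet_fraction = 0,
                           unlabeled_fraction = 0) {
  if (background_mean >= signal_mean)
    stop_ibcrep("background_mean must be < signal_mean",
                "ibcrep_config_error")
  assert_fraction(multiplet_fraction, "multiplet_fraction")
  assert_fraction(unlabeled_fraction, "unlabeled_fraction")
  stopifnot(n_hashtags >= 1, signal_mean >= 0, background_mean >= 0,
            signal_dispersion > 0, background_dispersion > 0)
  structure(as.list(environment()), class = "hashtag_config")
}

#' Simulate a cells-by-hashtags UMI count matrix
#'
#' @param config a [hashtag_config()].
#' @param donor_truth integer vector (one entry per cell) giving each
#'   cell's hashtag index, `NA` for cells with no usable hashtag; names,
#'   if present, become matrix rownames (barcodes).
#' @param seed integer seed.
#' @return list with `counts` (cells x hashtags integer matrix, columns
#'   `Hash1..HashK`) and `truth` (data.frame `barcode`, `state`: hashtag
#'   index as character, `"multiplet"`, or `"unlabeled"`).
#' @export
simulate_hashtags <- function(config, donor_truth, seed) {
  stopifnot(inherits(config, "hashtag_config"))
  k <- config$n_hashtags
  if (any(donor_truth > k, na.rm = TRUE))
    stop_ibcrep("donor_truth index exceeds hashtag panel size",
                "ibcrep_config_error")
  set.seed(seed)
  n <- length(donor_truth)
  truth_idx <- donor_truth
  if (config$unlabeled_fraction > 0) {
    drop <- which(!is.na(truth_idx) &
                    runif(n) < config$unlabeled_fraction)
    truth_idx[drop] <- NA_integer_
  }
  labelled <- which(!is.na(truth_idx))
  second <- rep(NA_integer_, n)
  if (config$multiplet_fraction > 0 && k >= 2 && length(labelled) > 0) {
    is_mult <- labelled[runif(length(labelled)) < config$multiplet_fraction]
    second[is_mult] <- vapply(truth_idx[is_mult], function(h) {
      sample(setdiff(seq_len(k), h), 1)
    }, integer(1))
  }
  counts <- matrix(rnbinom(n * k, mu = config$background_mean,
                           size = config$background_dispersion),
                   nrow = n, ncol = k)
  sig <- function(m) rnbinom(m, mu = config$signal_mean,
                             size = config$signal_dispersion)
  own <- cbind(labelled, truth_idx[labelled])
  counts[own] <- sig(nrow(own))
  mult <- which(!is.na(second))
  if (length(mult) > 0) counts[cbind(mult, second[mult])] <- sig(length(mult))
  colnames(counts) <- paste0("Hash", seq_len(k))
  barcodes <- names(donor_truth)
  if (is.null(barcodes)) barcodes <- sprintf("CELL%05d-1", seq_len(n))
  rownames(counts) <- barcodes
  state <- ifelse(is.na(truth_idx), "unlabeled", as.character(truth_idx))
  state[!is.na(second)] <- "multiplet"
  list(counts = counts,
       truth = data.frame(barcode = barcodes, state = state,
                          stringsAsFactors = FALSE))
}
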