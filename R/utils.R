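#' @title Internal utilities
#' @name ibcrep-utils
#' @keywords internal
NULL

# Evaluate expr with a private RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_ibcrep <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ibcrep_error")))
}

assert_probabilities <- function(p, what = "probabilities", tol = 1e-9) {
  if (any(p < 0)) stop_ibcrep(sprintf("%s must be non-negative", what),
                              "ibcrep_config_error")
  if (abs(sum(p) - 1) > tol)
    stop_ibcrep(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)),
                "ibcrep_config_error")
  invisible(p)
}

assert_fraction <- function(x, what) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_ibcrep(sprintf("%s must be a single value in [0, 1]", what),
                "ibcrep_config_error")
  invisible(x)
}

#' Adjusted Rand index between two label vectors
#'
#' Permutation-invariant agreement between two partitions of the same
#' cells, used to score cluster recovery against planted ground truth.
#' 1 means identical partitions, 0 the chance level.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Mean silhouette width of a labelled point set (euclidean), computed on
# at most max_cells points (deterministic subsample) to bound memory/time.
mean_silhouette <- function(x, labels, max_cells = 1000L) {
  n <- nrow(x)
  if (length(unique(labels)) < 2) return(NA_real_)
  idx <- seq_len(n)
  if (n > max_cells) idx <- sort(sample.int(n, max_cells))
  x <- x[idx, , drop = FALSE]
  labels <- labels[idx]
  if (length(unique(labels)) < 2) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  sil <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) return(0)
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
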