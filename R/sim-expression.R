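#' Default marker-gene panel
#'
#' Signature genes used both by the expression generator (planted cluster
#' markers) and by the synthetic reference atlas.  Each atlas population
#' owns 18 systematically named genes (`MZ_g01` ... `T3_g18`); the default
#' expression panel plants 18 marginal-zone, 17 follicular and 17 memory
#' genes in clusters 1-3 (52 genes in all, matching the size of the
#' differentiating panel being emulated).
#'
#' @param population population label.
#' @param n number of signature genes.
#' @return character vector of gene names.
#' @export
population_signature_genes <- function(population, n = 18L) {
  sprintf("%s_g%02d", population, seq_len(n))
}

.ATLAS_POPULATIONS <- c("MZ", "FO", "MemB", "GC", "T1", "T2", "T3")

.default_marker_sets <- function() {
  list(population_signature_genes("MZ", 18),
       population_signature_genes("FO", 17),
       population_signature_genes("MemB", 17))
}

#' Expression-count generator configuration
#'
#' Negative-binomial UMI counts with planted cluster structure: every
#' gene has a baseline mean, and each cluster's marker genes are
#' up-shifted by `2^log2_fc` in that cluster.  The default emulates the
#' three transcriptional subpopulations observed among high-affinity
#' insulin-reactive B cells (2976 / 2295 / 875 cells).
#'
#' @param n_cells total number of cells.
#' @param cluster_proportions vector summing to 1.
#' @param marker_sets list (one element per cluster) of marker gene
#'   names; the default sets are pairwise disjoint and overlapping sets
#'   are rejected.
#' @param n_background number of non-marker genes.
#' @param baseline_mean NB mean of every gene outside its marker cluster.
#' @param dispersion NB size parameter.
#' @param log2_fc marker up-shift in log2 units (default 2, i.e. 4-fold).
#' @return an `expression_config` object.
#' @export
expression_config <- function(n_cells = 6146L,
                              cluster_proportions = c(2976, 2295, 875) / 6146,
                              marker_sets = .default_marker_sets(),
                              n_background = 148L,
                              baseline_mean = 2, dispersion = 2,
                              log2_fc = 2) {
  assert_probabilities(cluster_proportions, "cluster_proportions", 1e-6)
  if (length(marker_sets) != length(cluster_proportions))
    stop_ibcrep("one marker set per cluster is required",
                "ibcrep_config_error")
  all_markers <- unlist(marker_sets)
  if (anyDuplicated(all_markers))
    stop_ibcrep("marker sets overlap: conflicting effects",
                "ibcrep_config_error")
  stopifnot(n_cells >= 1, baseline_mean > 0, dispersion > 0, log2_fc >= 0)
  genes <- c(all_markers, sprintf("BG_g%03d", seq_len(n_background)))
  structure(list(n_cells = as.integer(n_cells),
                 cluster_proportions = cluster_proportions,
                 marker_sets = marker_sets, genes = genes,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 log2_fc = log2_fc),
            class = "expression_config")
}

#' Simulate an expression count matrix with planted clusters
#'
#' @param config an [expression_config()].
#' @param seed integer seed.
#' @return list with `counts` (cells x genes integer matrix) and `labels`
#'   (integer truth cluster per cell).
#' @export
simulate_expression <- function(config, seed) {
  stopifnot(inherits(config, "expression_config"))
  set.seed(seed)
  n <- config$n_cells
  k <- length(config$cluster_proportions)
  labels <- sample.int(k, n, replace = TRUE,
                       prob = config$cluster_proportions)
  genes <- config$genes
  mu <- matrix(config$baseline_mean, nrow = n, ncol = length(genes),
               dimnames = list(sprintf("CELL%05d-1", seq_len(n)), genes))
  shift <- 2^config$log2_fc
  for (cl in seq_len(k)) {
    cols <- match(config$marker_sets[[cl]], genes)
    mu[labels == cl, cols] <- config$baseline_mean * shift
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = config$dispersion),
                   nrow = n, dimnames = dimnames(mu))
  list(counts = counts, labels = labels)
}

#' Build a synthetic reference B-cell atlas
#'
#' Positive normalized expression values for a panel of splenic /
#' germinal-center B-cell populations (marginal zone, follicular, memory,
#' GC, transitional T1-T3), one row per population.  Each population's
#' signature genes are elevated 8-fold in their home population, so any
#' signature gene attains its maximum in its home row by construction.
#' A configurable number of panel genes is withheld to emulate
#' incomplete name-based mapping between datasets (default: `MZ_g18` and
#' `MemB_g17` are absent).
#'
#' @param populations unique population labels; must include marginal
#'   zone, follicular, memory and transitional entries.
#' @param genes gene universe; default the union of all population
#'   signature panels.
#' @param seed integer seed for the baseline values.
#' @param withhold_genes genes to omit from the atlas.
#' @return matrix populations x genes of positive values.
#' @export
make_reference_atlas <- function(populations = .ATLAS_POPULATIONS,
                                 genes = NULL, seed = 1L,
                                 withhold_genes = c("MZ_g18", "MemB_g17")) {
  if (anyDuplicated(populations))
    stop_ibcrep("duplicate population names", "ibcrep_config_error")
  if (is.null(genes))
    genes <- unlist(lapply(populations, population_signature_genes))
  genes <- setdiff(genes, withhold_genes)
  with_seed(seed, {
    atlas <- matrix(exp(rnorm(length(populations) * length(genes),
                              mean = 2, sd = 0.3)),
                    nrow = length(populations),
                    dimnames = list(populations, genes))
    for (p in populations) {
      home <- intersect(population_signature_genes(p), genes)
      atlas[p, home] <- atlas[p, home] * 8
    }
    atlas
  })
}

#' Write / read an atlas table as CSV
#'
#' @param atlas populations x genes matrix.
#' @param path CSV path (populations in the first column).
#' @return `path` invisibly; `read_atlas_csv` returns the matrix.
#' @export
write_atlas_csv <- function(atlas, path) {
  df <- data.frame(population = rownames(atlas), atlas,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_csv
#' @export
read_atlas_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
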