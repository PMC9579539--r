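#' Depth-normalize and log-transform a count matrix
#'
#' Per-cell library-size normalization to `scale_factor` total counts
#' followed by `log1p`.  All-zero cells cannot be normalized; they are
#' excluded with a message and recorded in the `excluded` attribute.
#'
#' @param counts cells x genes non-negative count matrix.
#' @param scale_factor target library size (default 10,000).
#' @return cells x genes matrix of `log1p` normalized values.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0))
    stop_ibcrep("counts must be non-negative", "ibcrep_input_error")
  depth <- rowSums(counts)
  zero <- depth == 0
  if (any(zero)) {
    message(sprintf("excluding %d all-zero cell(s)", sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
    depth <- depth[!zero]
  }
  out <- log1p(counts / depth * scale_factor)
  attr(out, "excluded") <- which(zero)
  out
}

#' Cluster cells by PCA + k-means with silhouette-selected k
#'
#' Cells are embedded in their top principal components and partitioned
#' with k-means for each candidate k; the k with the highest mean
#' silhouette width (computed on a deterministic subsample of at most
#' `max_sil_cells` cells) is kept.  When even the best mean silhouette
#' falls below `silhouette_floor`, the data are declared unstructured and
#' a single cluster is returned.  Cluster labels are contiguous from 1
#' and ordered by decreasing size.  Deterministic given `seed`.
#'
#' @param normalized cells x genes matrix from [normalize_counts()].
#' @param k_range candidate cluster numbers (values >= 2 are tried).
#' @param n_pcs number of principal components.
#' @param seed integer seed (k-means starts and silhouette subsample).
#' @param silhouette_floor minimum mean silhouette for multi-cluster
#'   structure (default 0.15).
#' @param max_sil_cells silhouette subsample cap.
#' @return list of class `cluster_result`: `labels`, `k`, `sizes`,
#'   `silhouette` (named by k), `pca` (the cell embedding).
#' @export
cluster_cells <- function(normalized, k_range = 1:6, n_pcs = 10,
                          seed = 1L, silhouette_floor = 0.15,
                          max_sil_cells = 1000L) {
  n <- nrow(normalized)
  if (n < 2)
    stop_ibcrep("at least 2 cells are required", "ibcrep_input_error")
  ks <- sort(unique(k_range[k_range >= 2]))
  if (length(ks) > 0 && max(ks) > n)
    stop_ibcrep("fewer cells than requested k", "ibcrep_input_error")
  n_pcs <- min(n_pcs, ncol(normalized), n - 1)
  pca <- prcomp(normalized, center = TRUE, scale. = FALSE,
                rank. = n_pcs)$x
  fits <- list()
  sil <- setNames(rep(NA_real_, length(ks)), ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    fits[[i]] <- with_seed(seed + k, kmeans(pca, centers = k,
                                            nstart = 5, iter.max = 200,
                                            algorithm = "Lloyd"))
    sil[i] <- with_seed(seed, mean_silhouette(pca, fits[[i]]$cluster,
                                              max_cells = max_sil_cells))
  }
  if (length(ks) == 0 || all(is.na(sil)) ||
      max(sil, na.rm = TRUE) < silhouette_floor) {
    labels <- rep(1L, n)
    k_best <- 1L
  } else {
    best <- which.max(sil)
    raw <- fits[[best]]$cluster
    # relabel by decreasing size for stable, contiguous labels
    ord <- order(-table(factor(raw, levels = seq_len(ks[best]))))
    labels <- match(raw, ord)
    k_best <- ks[best]
  }
  structure(list(labels = labels, k = k_best,
                 sizes = as.integer(table(labels)), silhouette = sil,
                 pca = pca),
            class = "cluster_result")
}

#' One-vs-rest rank-sum marker detection
#'
#' For every cluster with at least `min_cells` cells, each gene is tested
#' cluster-vs-rest with the Wilcoxon rank-sum test (normal
#' approximation).  Genes with raw p below `p_threshold` and absolute
#' log2 fold change of at least `lfc_floor` are reported as markers;
#' Benjamini-Hochberg adjusted p-values are reported alongside.
#'
#' @param normalized cells x genes matrix from [normalize_counts()].
#' @param labels cluster labels (one per cell, >= 2 clusters).
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @param lfc_floor minimum |log2 fold change| (default 0.25).
#' @param min_cells smallest testable cluster (default 3).
#' @return list of class `marker_set`: `all` (every test: `cluster`,
#'   `gene`, `statistic`, `p`, `p_adj`, `lfc`, `direction`) and
#'   `significant` (rows passing both cutoffs).
#' @export
find_markers <- function(normalized, labels, p_threshold = 0.05,
                         lfc_floor = 0.25, min_cells = 3L) {
  clusters <- sort(unique(labels))
  if (length(clusters) < 2)
    stop_ibcrep("at least 2 clusters are required", "ibcrep_input_error")
  # per-gene ranks and tie corrections are shared across the
  # one-vs-rest comparisons, so compute them once
  n <- nrow(normalized)
  ranks <- apply(normalized, 2, rank)
  tie_term <- apply(normalized, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  expd <- expm1(normalized)
  res <- list()
  for (cl in clusters) {
    inside <- labels == cl
    n1 <- sum(inside)
    if (n1 < min_cells) {
      warning(sprintf("cluster %s has fewer than %d cells; skipped",
                      cl, min_cells))
      next
    }
    n2 <- n - n1
    w <- colSums(ranks[inside, , drop = FALSE]) - n1 * (n1 + 1) / 2
    # normal approximation with tie and continuity corrections,
    # matching wilcox.test(exact = FALSE, correct = TRUE)
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    p <- pmin(p, 1)
    mean_in <- colMeans(expd[inside, , drop = FALSE])
    mean_out <- colMeans(expd[!inside, , drop = FALSE])
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    res[[length(res) + 1]] <- data.frame(
      cluster = cl, gene = colnames(normalized),
      statistic = unname(w), p = unname(p),
      p_adj = p.adjust(unname(p), method = "BH"),
      lfc = unname(lfc),
      direction = ifelse(lfc >= 0, "up", "down"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  all <- do.call(rbind, res)
  significant <- all[all$p < p_threshold & abs(all$lfc) >= lfc_floor, ,
                     drop = FALSE]
  structure(list(all = all, significant = significant,
                 p_threshold = p_threshold, lfc_floor = lfc_floor),
            class = "marker_set")
}

#' Map marker genes onto an atlas by name
#'
#' @param genes character vector of marker gene names (non-empty).
#' @param atlas populations x genes matrix.
#' @param ignore_case match names case-insensitively.
#' @return list with `mapped` (names as spelled in the atlas) and
#'   `unmapped` (input names with no atlas match); unmapped genes are
#'   reported, never silently dropped.
#' @export
map_genes <- function(genes, atlas, ignore_case = FALSE) {
  if (length(genes) == 0)
    stop_ibcrep("empty marker gene list", "ibcrep_input_error")
  atlas_genes <- colnames(atlas)
  if (ignore_case) {
    idx <- match(tolower(genes), tolower(atlas_genes))
  } else {
    idx <- match(genes, atlas_genes)
  }
  list(mapped = atlas_genes[idx[!is.na(idx)]],
       unmapped = genes[is.na(idx)])
}

#' Project marker genes onto a reference atlas by gene-wise z-scores
#'
#' For each gene, the median expression within each atlas population is
#' standardized by the mean and standard deviation of that gene across
#' *all* reference populations: \eqn{z_{gp} = (m_{gp} - \mu_g)/\sigma_g}.
#' Genes with zero across-population variance are flagged and set to
#' z = 0 with a warning.  When per-cluster up-regulated marker sets are
#' supplied, each cluster receives an enrichment score per population
#' (mean z over its mapped up-genes) and is assigned the population with
#' the maximal score.
#'
#' @param genes mapped gene names (present in the atlas).
#' @param atlas populations x genes matrix; replicate rows sharing a
#'   population name are summarized by their median.
#' @param cluster_markers optional named list: per cluster, its
#'   up-regulated genes.
#' @return list of class `signature_matrix`: `z` (genes x populations),
#'   `flagged` (zero-variance genes), and -- with `cluster_markers` --
#'   `enrichment` (clusters x populations) and `assignment` (named
#'   character: best population per cluster).
#' @export
project_to_atlas <- function(genes, atlas, cluster_markers = NULL) {
  missing <- setdiff(genes, colnames(atlas))
  if (length(missing) > 0)
    stop_ibcrep(paste("genes not in atlas (run map_genes first):",
                      paste(missing, collapse = ", ")),
                "ibcrep_input_error")
  pops <- unique(rownames(atlas))
  med <- t(vapply(pops, function(p) {
    apply(atlas[rownames(atlas) == p, genes, drop = FALSE], 2, median)
  }, numeric(length(genes))))
  rownames(med) <- pops
  mu <- colMeans(med)
  sigma <- apply(med, 2, sd)
  flagged <- colnames(med)[sigma == 0]
  if (length(flagged) > 0) {
    warning(paste("zero across-population variance; z set to 0 for:",
                  paste(flagged, collapse = ", ")))
    sigma[sigma == 0] <- Inf
  }
  z <- t((med - rep(mu, each = nrow(med))) /
           rep(sigma, each = nrow(med)))  # genes x populations
  out <- list(z = z, flagged = flagged)
  if (!is.null(cluster_markers)) {
    enrichment <- t(vapply(cluster_markers, function(gs) {
      gs <- intersect(gs, rownames(z))
      if (length(gs) == 0) return(rep(NA_real_, ncol(z)))
      colMeans(z[gs, , drop = FALSE])
    }, numeric(ncol(z))))
    colnames(enrichment) <- colnames(z)
    out$enrichment <- enrichment
    out$assignment <- setNames(colnames(z)[max.col(enrichment)],
                               rownames(enrichment))
  }
  structure(out, class = "signature_matrix")
}
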