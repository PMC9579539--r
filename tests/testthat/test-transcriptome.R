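test_that("normalization matches hand computation and its invariances", {
  m <- matrix(c(1, 2, 3,
                10, 0, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  norm <- normalize_counts(m)
  manual <- log1p(m / rowSums(m) * 1e4)
  expect_equal(unname(norm), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single expressed gene with count 10,000 -> log1p(10000)
  one <- matrix(c(10000, 0), nrow = 1,
                dimnames = list("c", c("g1", "g2")))
  expect_equal(normalize_counts(one)[1, 1], log1p(1e4))
  # depth invariance: doubling all counts of a cell changes nothing
  expect_equal(normalize_counts(2 * m), norm, ignore_attr = TRUE)
  # all-zero cells are excluded with a message
  z <- rbind(m, zero = c(0, 0, 0))
  expect_message(nz <- normalize_counts(z), "all-zero")
  expect_equal(nrow(nz), 2L)
})

test_that("planted three-cluster structure is recovered", {
  out <- simulate_expression(expression_config(n_cells = 600), seed = 41)
  norm <- normalize_counts(out$counts)
  clus <- cluster_cells(norm, seed = 42)
  expect_equal(clus$k, 3L)
  expect_gte(adjusted_rand_index(clus$labels, out$labels), 0.9)
  expect_equal(sum(clus$sizes), nrow(norm))
  expect_setequal(unique(clus$labels), 1:3)
  # determinism
  clus2 <- cluster_cells(norm, seed = 42)
  expect_identical(clus$labels, clus2$labels)
  expect_error(cluster_cells(norm[1, , drop = FALSE]),
               class = "ibcrep_input_error")
  expect_error(cluster_cells(norm[1:3, ], k_range = 1:10),
               class = "ibcrep_input_error")
})

test_that("markers separate a cleanly expressed gene", {
  set.seed(1)
  n <- 200
  labels <- rep(1:2, each = n / 2)
  counts <- matrix(rpois(n * 20, 3), nrow = n,
                   dimnames = list(NULL, sprintf("g%02d", 1:20)))
  counts[labels == 1, "g01"] <- rpois(n / 2, 40)
  counts[labels == 2, "g01"] <- 0
  norm <- normalize_counts(counts)
  mk <- find_markers(norm, labels)
  top1 <- mk$significant[mk$significant$cluster == 1 &
                           mk$significant$direction == "up", ]
  expect_identical(top1$gene[which.min(top1$p)], "g01")
  expect_lt(min(top1$p), 0.05)
  expect_error(find_markers(norm, rep(1, n)),
               class = "ibcrep_input_error")
  expect_warning(find_markers(norm, c(rep(1, n - 2), 2, 2)),
                 "fewer than")
})

test_that("vectorized rank-sum p-values match stats::wilcox.test", {
  set.seed(8)
  n <- 80
  labels <- rep(1:2, each = n / 2)
  counts <- matrix(rnbinom(n * 12, mu = 3, size = 2), nrow = n,
                   dimnames = list(NULL, sprintf("g%02d", 1:12)))
  norm <- normalize_counts(counts)
  mk <- find_markers(norm, labels, lfc_floor = 0)
  one <- mk$all[mk$all$cluster == 1, ]
  for (g in colnames(norm)) {
    ref <- suppressWarnings(
      wilcox.test(norm[labels == 1, g], norm[labels == 2, g],
                  exact = FALSE, correct = TRUE))
    row <- one[one$gene == g, ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("default threshold matches the 0.05 significance rule", {
  mk_args <- formals(find_markers)
  expect_equal(mk_args$p_threshold, 0.05)
  out <- simulate_expression(expression_config(n_cells = 500), seed = 2)
  norm <- normalize_counts(out$counts)
  mk <- find_markers(norm, out$labels)
  expect_true(all(mk$significant$p < 0.05))
})

test_that("gene mapping reports unmapped genes and handles case", {
  atlas <- make_reference_atlas(seed = 3)
  panel <- c(population_signature_genes("MZ", 18),
             population_signature_genes("FO", 17),
             population_signature_genes("MemB", 17))
  mp <- map_genes(panel, atlas)
  expect_length(mp$mapped, 50L)
  expect_setequal(mp$unmapped, c("MZ_g18", "MemB_g17"))
  # all present -> empty unmapped report
  mp2 <- map_genes(c("MZ_g01", "FO_g02"), atlas)
  expect_length(mp2$unmapped, 0L)
  # case-insensitive dialect handling
  expect_identical(map_genes("mz_G01", atlas,
                             ignore_case = TRUE)$mapped, "MZ_g01")
  expect_identical(map_genes("mz_G01", atlas)$unmapped, "mz_G01")
  expect_error(map_genes(character(0), atlas),
               class = "ibcrep_input_error")
})

test_that("z-score projection matches hand computation to 1e-12", {
  atlas <- matrix(c(1, 2, 3, 4,
                    2, 2, 2, 2,
                    5, 1, 3, 3), nrow = 4,
                  dimnames = list(c("P1", "P2", "P3", "P4"),
                                  c("gA", "gB", "gC")))
  expect_warning(proj <- project_to_atlas(c("gA", "gB", "gC"), atlas),
                 "zero across-population variance")
  manual <- apply(atlas, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(proj$z["gA", ], manual[, "gA"], tolerance = 1e-12)
  expect_equal(proj$z["gC", ], manual[, "gC"], tolerance = 1e-12)
  # constant gene flagged and zeroed
  expect_identical(proj$flagged, "gB")
  expect_equal(unname(proj$z["gB", ]), rep(0, 4))
  # row normalization invariant: mean 0, sd 1 for non-degenerate genes
  expect_lt(max(abs(rowMeans(proj$z[c("gA", "gC"), ]))), 1e-9)
  expect_lt(max(abs(apply(proj$z[c("gA", "gC"), ], 1, sd) - 1)), 1e-9)
})

test_that("planted clusters project onto their source atlas populations", {
  out <- simulate_expression(expression_config(n_cells = 600), seed = 13)
  norm <- normalize_counts(out$counts)
  mk <- find_markers(norm, out$labels)
  atlas <- make_reference_atlas(seed = 14)
  up <- split(mk$significant$gene[mk$significant$direction == "up"],
              mk$significant$cluster[mk$significant$direction == "up"])
  mapped <- map_genes(unique(mk$significant$gene), atlas)
  proj <- project_to_atlas(mapped$mapped, atlas,
                           cluster_markers = lapply(up, intersect,
                                                    y = mapped$mapped))
  expect_identical(unname(proj$assignment[c("1", "2", "3")]),
                   c("MZ", "FO", "MemB"))
})
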