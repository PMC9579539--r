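make_cells <- function(v, j, donor = 1L) {
  n <- length(v)
  id <- sprintf("c%03d_contig_1", seq_len(n))
  list(contigs = data.frame(barcode = sprintf("c%03d", seq_len(n)),
                            donor = donor, chain = "IGK", v_gene = v,
                            j_gene = j, cdr3_nt = "", cdr3_aa = "",
                            contig_id = id, stringsAsFactors = FALSE),
       calls = data.frame(contig_id = id, v_gene = v, v_score = 288,
                          j_gene = j, j_score = 30, junction_start = 264,
                          junction_end = 291, tie = FALSE,
                          stringsAsFactors = FALSE))
}

test_that("pair frequencies are plain cell-count arithmetic", {
  x <- make_cells(c("IGKV4-74", "IGKV4-74", "IGKV4-74", "IGKV4-57"),
                  c("IGKJ5", "IGKJ5", "IGKJ2", "IGKJ5"))
  tab <- build_clonotype_table(x$contigs, x$calls)
  expect_equal(unname(tab$pair_freq[, "mean"]),
               c(0.5, 0.25, 0.25))
  expect_setequal(rownames(tab$pair_freq),
                  c("IGKV4-74|IGKJ5", "IGKV4-74|IGKJ2",
                    "IGKV4-57|IGKJ5"))
})

test_that("rare rearrangements land in the others bin", {
  v <- c(rep("IGKV4-74", 999), "IGKV4-57")
  j <- c(rep("IGKJ5", 999), "IGKJ2")
  x <- make_cells(v, j)
  tab <- build_clonotype_table(x$contigs, x$calls)
  expect_false("IGKV4-57|IGKJ2" %in% rownames(tab$pair_freq))
  expect_equal(unname(tab$pair_freq["others", "mean"]), 0.001)
})

test_that("frequencies sum to 1 per mouse at every aggregation level", {
  sim <- simulate_repertoire(small_repertoire_config(), seed = 8)
  tab <- run_repertoire_stage(sim)
  for (fr in list(tab$v_freq, tab$j_freq, tab$pair_freq)) {
    sums <- colSums(fr[, setdiff(colnames(fr), "mean"), drop = FALSE])
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
  expect_equal(tab$kappa_fraction, 1.0)
  expect_equal(tab$n_excluded, sum(is.na(sim$truth$donor)))
})

test_that("cells without donor assignment are excluded with a count", {
  x <- make_cells(rep("IGKV4-74", 4), rep("IGKJ5", 4),
                  donor = c(1L, 1L, NA, 2L))
  expect_message(tab <- build_clonotype_table(x$contigs, x$calls),
                 "1 cell")
  expect_equal(tab$n_excluded, 1L)
  expect_equal(nrow(tab$cells), 3L)
})

test_that("pipeline frequencies converge to generator probabilities", {
  cfg <- repertoire_config(cells_per_mouse = c(4000L, 3000L, 3000L),
                           unassigned_fraction = 0)
  sim <- simulate_repertoire(cfg, seed = 31)
  tab <- run_repertoire_stage(sim)
  pooled <- table(paste(tab$cells$v_gene, tab$cells$j_gene, sep = "|"))
  pooled <- pooled / sum(pooled)
  probs <- aggregate(prob ~ v_gene + j_gene, cfg$clonotypes, sum)
  n <- nrow(tab$cells)
  for (i in seq_len(nrow(probs))) {
    p <- probs$prob[i]
    key <- paste(probs$v_gene[i], probs$j_gene[i], sep = "|")
    obs <- if (key %in% names(pooled)) as.numeric(pooled[key]) else 0
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("CDR3 extraction translates and numbers the junction", {
  ref <- germline_reference()
  contig <- paste0(ref$V[["IGKV4-74"]], "CTG", ref$J[["IGKJ5"]])
  call <- assign_germline(contig, ref)
  cdr3 <- extract_cdr3(contig, call)
  expect_identical(cdr3$flag, "productive")
  expect_equal(cdr3$positions, 89:97)
  expect_identical(unname(cdr3$residues["97"]), "L")
  # conserved anchors encoded in the synthetic germline
  expect_identical(unname(cdr3$residues[c("91", "92")]), c("Q", "Y"))
  # serine variant at the joint
  cdr3_s <- extract_cdr3(paste0(ref$V[["IGKV4-74"]], "AGC",
                                ref$J[["IGKJ5"]]), call)
  expect_identical(unname(cdr3_s$residues["97"]), "S")
})

test_that("frameshift and stop junctions are flagged, not translated", {
  fs <- extract_cdr3("ACGTACGTACGTACG", list(junction = c(0, 10)))
  expect_identical(fs$flag, "frameshift")
  expect_true(is.na(fs$aa))
  stop_case <- extract_cdr3("ATGTAACCC", list(junction = c(0, 9)))
  expect_identical(stop_case$flag, "stop")
})

test_that("position composition matches a direct truth-table tally", {
  sim <- simulate_repertoire(small_repertoire_config(), seed = 12)
  tab <- run_repertoire_stage(sim)
  comp <- position_composition(tab, "IGKV4-74", "IGKJ5", 97)
  expect_equal(sum(comp), 1)
  truth <- sim$truth[!is.na(sim$truth$donor) &
                       sim$truth$v_gene == "IGKV4-74" &
                       sim$truth$j_gene == "IGKJ5", ]
  oracle <- table(truth$junction_aa) / nrow(truth)
  expect_equal(unname(comp[names(oracle)]), unname(as.numeric(oracle)),
               tolerance = 1e-12)
  # degenerate: all cells carry one residue
  x <- make_cells(rep("IGKV4-74", 3), rep("IGKJ5", 3))
  x$contigs$cdr3_aa <- "QQQYDSSYL"
  tab1 <- build_clonotype_table(x$contigs, x$calls)
  expect_equal(position_composition(tab1, position = 97), c(L = 1))
  expect_error(position_composition(tab1, "IGKV1-110", NULL, 97),
               class = "ibcrep_input_error")
})

test_that("mutation counting is exact per region", {
  ref <- germline_reference()
  contig <- paste0(ref$V[["IGKV4-74"]], "CTG", ref$J[["IGKJ5"]])
  expect_equal(count_mutations(contig, ref),
               c(cdr1 = 0L, cdr2 = 0L, cdr3 = 0L, fwr = 0L))
  mutate_at <- function(s, i) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, i, i))[1]
    s
  }
  # nt 80 lies in CDR1 (codons 24-34); nt 10 in framework 1
  expect_equal(count_mutations(mutate_at(contig, 80), ref)[["cdr1"]], 1L)
  expect_equal(count_mutations(mutate_at(contig, 10), ref)[["fwr"]], 1L)
  # default fixture: zero CDR mutations everywhere
  sim <- simulate_repertoire(small_repertoire_config(), seed = 3)
  light <- sim$contigs[sim$contigs$chain == "IGK", ][1:25, ]
  for (id in light$contig_id) {
    m <- count_mutations(sim$sequences[[id]], sim$reference)
    expect_equal(sum(m[c("cdr1", "cdr2", "cdr3")]), 0L)
  }
})

test_that("charge classes follow standard chemistry", {
  expect_identical(charge_class(c("D", "E")), c("negative", "negative"))
  expect_identical(charge_class(c("H", "K", "R")),
                   rep("positive", 3))
  expect_identical(charge_class(c("S", "L", "Q", "Y")),
                   rep("neutral", 4))
  expect_error(charge_class("Z"), class = "ibcrep_input_error")
})

test_that("strain comparison flags charge-altering polymorphisms", {
  nod <- germline_reference("NOD")
  b6 <- germline_reference("B6")
  cdr3_of <- function(ref, v) {
    nt <- paste0(substr(ref$V[[v]], 265, 288), "CTG")
    as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  }
  rep74 <- compare_strains(cdr3_of(nod, "IGKV4-74"),
                           cdr3_of(b6, "IGKV4-74"),
                           clonotype = "IGKV4-74|IGKJ5")
  expect_false(rep74$length_mismatch)
  pos <- rep74$positions
  # D93 -> H93 and S94 -> R94 alter charge
  expect_true(all(pos$charge_altering[pos$position %in% c(93, 94)]))
  # Q91 / Y92 conserved and never charge-altering
  expect_true(all(pos$identical[pos$position %in% c(91, 92)]))
  expect_false(any(pos$charge_altering[pos$identical]))
  # identical sets -> zero flags
  same <- compare_strains(cdr3_of(nod, "IGKV4-74"),
                          cdr3_of(nod, "IGKV4-74"))
  expect_false(any(same$positions$charge_altering))
  # inconsistent lengths -> length-mismatch report
  mm <- compare_strains("QQYDSSYL", c("QQYDSSYLX", "QQYDSSYLX"))
  expect_true(mm$length_mismatch)
  expect_null(mm$positions)
  expect_error(compare_strains(character(0), "QQY"),
               class = "ibcrep_input_error")
})
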