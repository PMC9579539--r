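#' Default clonotype probability table
#'
#' The generator's stated world for the kappa repertoire of high-affinity
#' insulin-reactive B cells: five predominant light chains at the reported
#' frequencies -- Vk4-74/Jk5 with leucine at position 97 (35.3%),
#' Vk4-74/Jk5 with serine at 97 (28.8%), Vk4-74/Jk2 (22.1%), Vk4-57/Jk5
#' (7.4%) and Vk4-57/Jk2 (3.2%) -- with the remaining 3.2% spread over 20
#' rare V/J pairs at 0.16% each, i.e. below the 0.2% "others" binning
#' threshold.  Four of the rare pairs use Jk5 so the Jk5 marginal is
#' 72.14%; the Vk4-74 marginal is 86.52% (mouse kappa has only four
#' functional J genes, so rare pairs cannot raise it further without one
#' of them crossing the 0.2% threshold).
#'
#' @param serine_label one-letter label used for the serine junction
#'   variant (configurable because source material labels it
#'   inconsistently; biologically it is serine, `"S"`).
#' @return a data.frame with columns `v_gene`, `j_gene`, `junction_aa`,
#'   `prob` (summing to 1).
#' @export
default_clonotype_table <- function(serine_label = "S") {
  majors <- data.frame(
    v_gene = c("IGKV4-74", "IGKV4-74", "IGKV4-74", "IGKV4-57", "IGKV4-57"),
    j_gene = c("IGKJ5", "IGKJ5", "IGKJ2", "IGKJ5", "IGKJ2"),
    junction_aa = c("L", serine_label, "P", "T", "T"),
    prob = c(0.353, 0.288, 0.221, 0.074, 0.032),
    stringsAsFactors = FALSE)
  rare_pairs <- rbind(
    c("IGKV4-74", "IGKJ1"), c("IGKV4-74", "IGKJ4"),
    c("IGKV4-56", "IGKJ5"), c("IGKV4-91", "IGKJ5"),
    c("IGKV3-7",  "IGKJ5"), c("IGKV5-43", "IGKJ5"),
    c("IGKV4-56", "IGKJ2"), c("IGKV4-91", "IGKJ1"),
    c("IGKV1-110", "IGKJ2"), c("IGKV3-1", "IGKJ1"),
    c("IGKV14-111", "IGKJ2"), c("IGKV16-104", "IGKJ4"),
    c("IGKV17-127", "IGKJ1"), c("IGKV19-93", "IGKJ2"),
    c("IGKV9-120", "IGKJ4"), c("IGKV10-94", "IGKJ1"),
    c("IGKV15-103", "IGKJ2"), c("IGKV4-56", "IGKJ4"),
    c("IGKV4-91", "IGKJ2"), c("IGKV1-110", "IGKJ4"))
  others <- data.frame(v_gene = rare_pairs[, 1], j_gene = rare_pairs[, 2],
                       junction_aa = "A", prob = 0.0016,
                       stringsAsFactors = FALSE)
  rbind(majors, others)
}

#' Repertoire generator configuration
#'
#' @param cells_per_mouse integer vector of donor-assigned cell counts,
#'   default the study design `c(2081, 1947, 63)`.
#' @param clonotypes probability table as from [default_clonotype_table()]:
#'   columns `v_gene`, `j_gene`, `junction_aa`, `prob` (must sum to 1
#'   within 1e-9).
#' @param mutation_rate per-base substitution rate in `[0, 1]`; the
#'   default 0 reflects the unmutated germline repertoire.
#' @param unassigned_fraction fraction of cells carrying no usable donor
#'   hashtag; the default 0.0012 adds ~5 donor-unassigned cells to the
#'   4,091 assigned ones (total 4,096).
#' @param strain germline allele set, `"NOD"` (default) or `"B6"`.
#' @return a `repertoire_config` object.
#' @export
repertoire_config <- function(cells_per_mouse = c(2081L, 1947L, 63L),
                              clonotypes = default_clonotype_table(),
                              mutation_rate = 0,
                              unassigned_fraction = 0.0012,
                              strain = "NOD") {
  if (any(cells_per_mouse < 0))
    stop_ibcrep("cells_per_mouse must be >= 0", "ibcrep_config_error")
  stopifnot(all(c("v_gene", "j_gene", "junction_aa", "prob") %in%
                  names(clonotypes)))
  assert_probabilities(clonotypes$prob, "clonotype probabilities")
  assert_fraction(mutation_rate, "mutation_rate")
  assert_fraction(unassigned_fraction, "unassigned_fraction")
  ref <- germline_reference(strain)
  unknown <- setdiff(unique(clonotypes$v_gene), names(ref$V))
  unknown <- c(unknown, setdiff(unique(clonotypes$j_gene), names(ref$J)))
  if (length(unknown) > 0)
    stop_ibcrep(paste("unknown germline segment id:",
                      paste(unknown, collapse = ", ")),
                "ibcrep_reference_error")
  bad_aa <- setdiff(unique(clonotypes$junction_aa), names(.CODON))
  if (length(bad_aa) > 0)
    stop_ibcrep(paste("no codon for junction residue:",
                      paste(bad_aa, collapse = ", ")),
                "ibcrep_config_error")
  structure(list(cells_per_mouse = as.integer(cells_per_mouse),
                 clonotypes = clonotypes, mutation_rate = mutation_rate,
                 unassigned_fraction = unassigned_fraction,
                 strain = strain),
            class = "repertoire_config")
}

#' Simulate a kappa-restricted single-cell V(D)J repertoire
#'
#' Draws one productive kappa contig per cell from the configured
#' clonotype distribution (contig = germline V + one junction codon +
#' germline J, with optional random substitutions), plus the single fixed
#' heavy chain every cell carries.  Donor-unassigned cells (no usable
#' hashtag) are appended according to `config$unassigned_fraction`.
#'
#' @param config a [repertoire_config()].
#' @param seed integer seed; the output is fully determined by
#'   `(config, seed)`.
#' @return a list of class `ibc_repertoire_sim` with elements
#'   \describe{
#'     \item{contigs}{data.frame, two rows per cell (IGK + IGH): `barcode`,
#'       `donor` (1-based index, NA for unassigned), `chain`, `v_gene`,
#'       `j_gene`, `cdr3_nt`, `cdr3_aa`, `contig_id`.}
#'     \item{sequences}{named character vector of full contig nucleotide
#'       sequences (names = `contig_id`).}
#'     \item{truth}{per-cell ground truth: `barcode`, `donor`, `v_gene`,
#'       `j_gene`, `junction_aa`, `clonotype` ("V|J" pair label).}
#'     \item{reference}{the [germline_reference()] used.}
#'   }
#' @export
simulate_repertoire <- function(config, seed) {
  stopifnot(inherits(config, "repertoire_config"))
  set.seed(seed)
  ref <- germline_reference(config$strain)
  cl <- config$clonotypes
  n_assigned <- sum(config$cells_per_mouse)
  f <- config$unassigned_fraction
  n_unassigned <- round(f / (1 - f) * n_assigned)
  donors <- c(rep(seq_along(config$cells_per_mouse),
                  config$cells_per_mouse),
              rep(NA_integer_, n_unassigned))
  n <- length(donors)
  idx <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$prob)
  barcodes <- sprintf("CELL%05d-1", seq_len(n))

  joint_codons <- .CODON[cl$junction_aa[idx]]
  v_seq <- ref$V[cl$v_gene[idx]]
  j_seq <- ref$J[cl$j_gene[idx]]
  light <- paste0(v_seq, joint_codons, j_seq)
  if (config$mutation_rate > 0)
    light <- vapply(light, .mutate_seq, character(1),
                    rate = config$mutation_rate, USE.NAMES = FALSE)
  cdr3_nt <- substr(light, nchar(v_seq) - ref$v_cdr3_nt + 1,
                    nchar(v_seq) + 3)
  uniq_nt <- unique(cdr3_nt)
  cdr3_aa <- vapply(uniq_nt, .translate_cdr3, character(1),
                    USE.NAMES = FALSE)[match(cdr3_nt, uniq_nt)]
  light_ids <- paste0(barcodes, "_contig_1")
  heavy_ids <- paste0(barcodes, "_contig_2")
  contigs <- rbind(
    data.frame(barcode = barcodes, donor = donors, chain = "IGK",
               v_gene = cl$v_gene[idx], j_gene = cl$j_gene[idx],
               cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
               contig_id = light_ids, stringsAsFactors = FALSE),
    data.frame(barcode = barcodes, donor = donors, chain = "IGH",
               v_gene = names(ref$heavy), j_gene = "IGHJ-TG",
               cdr3_nt = "", cdr3_aa = "", contig_id = heavy_ids,
               stringsAsFactors = FALSE))
  sequences <- c(setNames(light, light_ids),
                 setNames(rep(unname(ref$heavy), n), heavy_ids))
  truth <- data.frame(barcode = barcodes, donor = donors,
                      v_gene = cl$v_gene[idx], j_gene = cl$j_gene[idx],
                      junction_aa = cl$junction_aa[idx],
                      clonotype = paste(cl$v_gene[idx], cl$j_gene[idx],
                                        sep = "|"),
                      stringsAsFactors = FALSE)
  structure(list(contigs = contigs, sequences = sequences, truth = truth,
                 reference = ref, config = config, seed = seed),
            class = "ibc_repertoire_sim")
}

.mutate_seq <- function(s, rate) {
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

.translate_cdr3 <- function(nt) {
  if (nchar(nt) %% 3 != 0) return(NA_character_)
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}
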