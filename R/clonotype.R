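#' Build per-mouse and pooled clonotype frequency tables
#'
#' Combines contig records, germline segment calls and donor assignments
#' into the clonotype table: per-mouse frequencies (summing to 1 within
#' each mouse) and their unweighted mean across mice (mice weighted
#' equally, matching a mean +/- SEM presentation) for V genes, J genes
#' and V/J pairs.  V/J pairs whose pooled frequency is below
#' `others_threshold` (default 0.2%) are collected into an `"others"`
#' bin.  Cells without a donor assignment are excluded and counted.
#'
#' @param contigs contig annotation data.frame (`barcode`, `chain`,
#'   `contig_id`, optionally `donor`, `cdr3_aa`).
#' @param calls data.frame from [call_germlines()] for the same contigs
#'   (matched by `contig_id`); light chains (`IGK`/`IGL`) are analysed.
#' @param assignments optional [demultiplex()] result; when given, donors
#'   come from its assigned states instead of the `donor` column.
#' @param sequences optional named contig sequences; when given,
#'   `cdr3_aa` is (re)derived from the calls via [extract_cdr3()].
#' @param others_threshold pooled-frequency threshold below which a V/J
#'   pair is binned as `"others"`.
#' @return list of class `clonotype_table`: `cells` (per-cell records),
#'   `v_freq`, `j_freq`, `pair_freq` (matrices: rows = category, columns
#'   = `mouse1..mouseM` plus `mean`), `kappa_fraction`, `n_excluded`.
#' @export
build_clonotype_table <- function(contigs, calls, assignments = NULL,
                                  sequences = NULL,
                                  others_threshold = 0.002) {
  light <- contigs[contigs$chain %in% c("IGK", "IGL"), , drop = FALSE]
  kappa_fraction <- mean(light$chain == "IGK")
  m <- merge(light, calls, by = "contig_id", suffixes = c("", ".call"))
  if ("v_gene.call" %in% names(m)) {
    m$v_gene <- m$v_gene.call
    m$j_gene <- m$j_gene.call
  }
  if (!is.null(sequences)) {
    # identical (sequence, junction) pairs translate identically;
    # dedupe before the per-contig CDR3 extraction
    key <- paste(sequences[m$contig_id], m$junction_start,
                 m$junction_end)
    first <- !duplicated(key)
    aa_uniq <- vapply(which(first), function(i) {
      cdr3 <- extract_cdr3(sequences[[m$contig_id[i]]],
                           list(junction = c(m$junction_start[i],
                                             m$junction_end[i])))
      if (cdr3$flag == "productive") cdr3$aa else NA_character_
    }, character(1))
    m$cdr3_aa <- aa_uniq[match(key, key[first])]
  }
  if (!"cdr3_aa" %in% names(m)) m$cdr3_aa <- NA_character_
  if (!is.null(assignments)) {
    st <- assignments$state[match(m$barcode, assignments$barcode)]
    m$donor <- suppressWarnings(as.integer(st))
  }
  if (!"donor" %in% names(m))
    stop_ibcrep("no donor information: supply assignments or a donor column",
                "ibcrep_input_error")
  n_excluded <- sum(is.na(m$donor))
  if (n_excluded > 0)
    message(sprintf("excluding %d cell(s) without donor assignment",
                    n_excluded))
  m <- m[!is.na(m$donor), , drop = FALSE]
  if (nrow(m) == 0)
    stop_ibcrep("no assignable cells", "ibcrep_input_error")
  donors <- sort(unique(m$donor))

  freq_matrix <- function(values) {
    tab <- table(factor(values), factor(m$donor, levels = donors))
    per_mouse <- prop.table(tab, margin = 2)
    out <- cbind(as.matrix(per_mouse), mean = rowMeans(per_mouse))
    colnames(out) <- c(paste0("mouse", donors), "mean")
    out[order(-out[, "mean"]), , drop = FALSE]
  }
  pair <- paste(m$v_gene, m$j_gene, sep = "|")
  pooled <- table(pair) / length(pair)
  rare <- names(pooled)[pooled < others_threshold]
  pair_binned <- ifelse(pair %in% rare, "others", pair)
  pair_freq <- freq_matrix(pair_binned)
  if ("others" %in% rownames(pair_freq)) {
    keep <- setdiff(rownames(pair_freq), "others")
    pair_freq <- pair_freq[c(keep, "others"), , drop = FALSE]
  }
  cells <- data.frame(barcode = m$barcode, donor = m$donor,
                      v_gene = m$v_gene, j_gene = m$j_gene,
                      cdr3_aa = m$cdr3_aa, stringsAsFactors = FALSE)
  structure(list(cells = cells, v_freq = freq_matrix(m$v_gene),
                 j_freq = freq_matrix(m$j_gene), pair_freq = pair_freq,
                 kappa_fraction = kappa_fraction, n_excluded = n_excluded,
                 others_threshold = others_threshold, cdr3_first = 89L),
            class = "clonotype_table")
}

#' Residue composition at a numbered CDR3 position
#'
#' Frequencies of the amino acids observed at one numbered CDR3 position
#' among cells matching a clonotype filter; frequencies sum to 1 over the
#' selected cells.
#'
#' @param table a [build_clonotype_table()] result.
#' @param v_gene,j_gene optional clonotype filter.
#' @param position numbered CDR3 position (e.g. 97, the V-J joint of the
#'   dominant nine-residue CDR3).
#' @return named numeric vector of residue frequencies.
#' @export
position_composition <- function(table, v_gene = NULL, j_gene = NULL,
                                 position) {
  cells <- table$cells
  if (!is.null(v_gene)) cells <- cells[cells$v_gene == v_gene, ]
  if (!is.null(j_gene)) cells <- cells[cells$j_gene == j_gene, ]
  idx <- position - table$cdr3_first + 1
  res <- substr(cells$cdr3_aa, idx, idx)
  res <- res[!is.na(res) & res != ""]
  if (length(res) == 0)
    stop_ibcrep("empty selection for position composition",
                "ibcrep_input_error")
  tab <- table(res)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Count somatic substitutions per region
#'
#' Compares a contig against its assigned germline V and J segments and
#' counts substitutions separately for CDR1, CDR2, the V-encoded part of
#' CDR3, and the frameworks (V frameworks plus J).  The junctional joint
#' codon (position 97) is not germline-encoded and is never counted.
#' Substitution-only divergence is assumed; an alignment with indels
#' raises an unalignable-contig error.
#'
#' @param contig contig nucleotide string.
#' @param reference a [germline_reference()].
#' @param call a `segment_call` from [assign_germline()]; computed if
#'   missing.
#' @return named integer vector `c(cdr1, cdr2, cdr3, fwr)`.
#' @export
count_mutations <- function(contig, reference, call = NULL) {
  if (is.null(call)) call <- assign_germline(contig, reference)
  regions <- reference$cdr_codons
  nt_span <- function(codons) c((min(codons) - 1) * 3 + 1, max(codons) * 3)
  out <- c(cdr1 = 0L, cdr2 = 0L, cdr3 = 0L, fwr = 0L)
  count_seg <- function(seg_seq, q_span, r_span, classify) {
    if (diff(q_span) != diff(r_span))
      stop_ibcrep("unalignable contig: indels in germline alignment",
                  "ibcrep_input_error")
    q <- strsplit(substr(contig, q_span[1], q_span[2]), "")[[1]]
    r <- strsplit(substr(seg_seq, r_span[1], r_span[2]), "")[[1]]
    mm <- which(q != r)
    if (length(mm) == 0) return(invisible(NULL))
    ref_pos <- r_span[1] + mm - 1
    for (p in ref_pos) {
      region <- classify(p)
      out[region] <<- out[region] + 1L
    }
  }
  v_seq <- reference$V[[call$v_gene]]
  spans <- lapply(regions, nt_span)
  classify_v <- function(p) {
    for (nm in names(spans))
      if (p >= spans[[nm]][1] && p <= spans[[nm]][2]) return(nm)
    "fwr"
  }
  count_seg(v_seq, call$v_span, call$v_ref_span, classify_v)
  count_seg(reference$J[[call$j_gene]], call$j_span, call$j_ref_span,
            function(p) "fwr")
  out
}
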