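#' Synthetic immunoglobulin kappa germline reference
#'
#' Builds the package's built-in kappa V/J germline segment reference.
#' The sequences are *synthetic*: framework codons are drawn once from a
#' fixed internal seed (so the reference is identical in every session),
#' while the CDR3-proximal codons of Vk4-74 and Vk4-57 are set by hand to
#' reproduce the residues relevant to the NOD vs C57BL/6-H2g7 strain
#' comparison: Q91/Y92 conserved in both strains; D93/S94 (NOD) exchanged
#' for H93/R94 (B6) in Vk4-74; H93/D95 (NOD) exchanged for S93/Y95 (B6) in
#' Vk4-57.  They are not IMGT sequences and must not be used to annotate
#' real data.
#'
#' Every V segment is 96 codons (288 nt); its last 8 codons encode CDR3
#' positions 89-96.  The V-J joint contributes the codon for position 97,
#' and J segments (10 codons) encode framework 4.  CDR spans (in codons of
#' the V segment): CDR1 24-34, CDR2 50-56, CDR3 89-96.
#'
#' @param strain `"NOD"` or `"B6"` (C57BL/6-H2g7) allele set.
#' @return an object of class `germline_reference`: a list with named
#'   character vectors `V` and `J` (nucleotide sequences), the fixed
#'   `heavy` chain sequence, `strain`, `v_cdr3_nt` (number of V nucleotides
#'   inside CDR3, 24) and `cdr_codons` (codon spans of CDR1/2/3 on V).
#' @export
germline_reference <- function(strain = c("NOD", "B6")) {
  strain <- match.arg(strain)
  ref <- .germline_base()
  if (strain == "B6") {
    ref$V["IGKV4-74"] <- .set_codons(ref$V["IGKV4-74"],
                                     c("90" = "H", "93" = "H", "94" = "R"))
    ref$V["IGKV4-57"] <- .set_codons(ref$V["IGKV4-57"],
                                     c("93" = "S", "95" = "Y"))
  }
  structure(list(V = ref$V, J = ref$J, heavy = ref$heavy, strain = strain,
                 v_cdr3_nt = 24L,
                 cdr_codons = list(cdr1 = 24:34, cdr2 = 50:56, cdr3 = 89:96)),
            class = "germline_reference")
}

# one codon per amino acid, used wherever a residue is prescribed
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
            S = "AGC", T = "ACA", V = "GTT", W = "TGG", Y = "TAC")

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.V_GENES <- c("IGKV4-74", "IGKV4-57", "IGKV4-56", "IGKV4-91", "IGKV3-7",
              "IGKV5-43", "IGKV1-110", "IGKV3-1", "IGKV14-111",
              "IGKV16-104", "IGKV17-127", "IGKV19-93", "IGKV9-120",
              "IGKV10-94", "IGKV15-103")
.J_GENES <- c("IGKJ1", "IGKJ2", "IGKJ4", "IGKJ5")

# replace codons of a V sequence; positions are CDR3 amino-acid numbers
# (89-96), codon i of the 96-codon segment is aa number i
.set_codons <- function(seq, aa_by_pos) {
  s <- unname(seq)
  for (pos in names(aa_by_pos)) {
    i <- as.integer(pos)
    substr(s, 3 * i - 2, 3 * i) <- .CODON[[aa_by_pos[[pos]]]]
  }
  s
}

.germline_base <- function() {
  with_seed(190973L, {
    v <- vapply(seq_along(.V_GENES), function(i) {
      paste(sample(.SENSE_CODONS, 96, replace = TRUE), collapse = "")
    }, character(1))
    names(v) <- .V_GENES
    # locus-conserved CDR3 anchors
    v <- vapply(v, .set_codons, character(1),
                aa_by_pos = c("91" = "Q", "92" = "Y"))
    v["IGKV4-74"] <- .set_codons(v["IGKV4-74"],
      c("89" = "Q", "90" = "Q", "93" = "D", "94" = "S", "95" = "S",
        "96" = "Y"))
    v["IGKV4-57"] <- .set_codons(v["IGKV4-57"],
      c("89" = "Q", "90" = "Q", "93" = "H", "94" = "S", "95" = "D",
        "96" = "P"))
    j <- vapply(seq_along(.J_GENES), function(i) {
      paste(sample(.SENSE_CODONS, 10, replace = TRUE), collapse = "")
    }, character(1))
    names(j) <- .J_GENES
    heavy <- paste(sample(.SENSE_CODONS, 120, replace = TRUE), collapse = "")
    names(heavy) <- "VH125"
    list(V = v, J = j, heavy = heavy)
  })
}

#' Write / read a germline reference as FASTA
#'
#' V, J and the fixed heavy-chain segment are stored in one FASTA file;
#' segment type is encoded in the sequence name (`IGKV*`, `IGKJ*`,
#' `VH125`).
#'
#' @param reference a [germline_reference()] object.
#' @param path output (input) FASTA path.
#' @return `write_germline_fasta` returns `path` invisibly;
#'   `read_germline_fasta` returns a `germline_reference` object (the
#'   strain is taken from the `strain=` tag in the heavy-chain header).
#' @export
write_germline_fasta <- function(reference, path) {
  seqs <- c(reference$V, reference$J, reference$heavy)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna)[length(dna)] <- paste0(names(reference$heavy),
                                    " strain=", reference$strain)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_germline_fasta
#' @export
read_germline_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*", "", names(dna))
  seqs <- setNames(as.character(dna), ids)
  strain <- sub(".*strain=(\\S+).*", "\\1",
                names(dna)[grepl("strain=", names(dna))][1])
  if (is.na(strain) || !strain %in% c("NOD", "B6")) strain <- "NOD"
  heavy <- seqs[!grepl("^IGK", ids)]
  structure(list(V = seqs[grepl("^IGKV", ids)],
                 J = seqs[grepl("^IGKJ", ids)],
                 heavy = heavy, strain = strain, v_cdr3_nt = 24L,
                 cdr_codons = list(cdr1 = 24:34, cdr2 = 50:56,
                                   cdr3 = 89:96)),
            class = "germline_reference")
}
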