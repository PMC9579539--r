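#' Extract and number the CDR3 amino-acid sequence
#'
#' Translates the junction span of a segment call with the standard
#' genetic code and numbers residues consecutively from `first_position`
#' (default 89, a Kabat-style kappa convention) so that the V-J joint
#' residue of the dominant nine-residue CDR3 falls at position 97.
#'
#' @param contig contig nucleotide string.
#' @param call a `segment_call` from [assign_germline()], or any list
#'   with a `junction` element (0-based half-open span).
#' @param first_position numbering of the first CDR3 residue.
#' @return list of class `cdr3`: `aa` (string or NA), `positions`
#'   (integer vector), `residues` (named character vector), `flag`
#'   (`"productive"`, `"frameshift"` or `"stop"`).
#' @export
extract_cdr3 <- function(contig, call, first_position = 89L) {
  span <- call$junction
  if (span[1] < 0 || span[2] > nchar(contig) || span[2] < span[1])
    stop_ibcrep("junction span outside contig bounds",
                "ibcrep_input_error")
  nt <- substr(contig, span[1] + 1, span[2])
  if (nchar(nt) %% 3 != 0)
    return(structure(list(aa = NA_character_, positions = integer(0),
                          residues = character(0), flag = "frameshift"),
                     class = "cdr3"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  flag <- if (grepl("*", aa, fixed = TRUE)) "stop" else "productive"
  residues <- strsplit(aa, "", fixed = TRUE)[[1]]
  positions <- seq(first_position, length.out = length(residues))
  names(residues) <- positions
  structure(list(aa = aa, positions = positions, residues = residues,
                 flag = flag),
            class = "cdr3")
}

#' Charge class of an amino-acid residue
#'
#' Aspartate and glutamate are negative; histidine, lysine and arginine
#' positive; everything else neutral.
#'
#' @param residue character vector of one-letter amino-acid codes.
#' @return character vector: `"negative"`, `"neutral"` or `"positive"`.
#' @export
charge_class <- function(residue) {
  valid <- names(.CODON)
  if (any(!residue %in% valid))
    stop_ibcrep(paste("invalid amino-acid letter:",
                      paste(setdiff(residue, valid), collapse = ", ")),
                "ibcrep_input_error")
  out <- rep("neutral", length(residue))
  out[residue %in% c("D", "E")] <- "negative"
  out[residue %in% c("H", "K", "R")] <- "positive"
  out
}

#' Compare CDR3 consensus sequences of two strains
#'
#' Builds the per-position consensus residue of each CDR3 set (e.g. the
#' NOD and B6 cells of one clonotype) and reports, per numbered position,
#' whether the residues are identical, their charge classes, and whether
#' the substitution alters charge.  Identical positions are never
#' charge-altering.
#'
#' @param cdr3_a,cdr3_b non-empty character vectors of CDR3 amino-acid
#'   strings (one per cell/sequence).
#' @param clonotype optional label stored in the report.
#' @param first_position numbering of the first CDR3 residue.
#' @return list of class `polymorphism_report`: `clonotype`,
#'   `length_mismatch` (logical), and -- when lengths agree -- `positions`,
#'   a data.frame with columns `position`, `residue_a`, `residue_b`,
#'   `identical`, `charge_a`, `charge_b`, `charge_altering`.
#' @export
compare_strains <- function(cdr3_a, cdr3_b, clonotype = NA_character_,
                            first_position = 89L) {
  if (length(cdr3_a) == 0 || length(cdr3_b) == 0)
    stop_ibcrep("both CDR3 sets must be non-empty", "ibcrep_input_error")
  consensus <- function(set) {
    lens <- nchar(set)
    if (length(unique(lens)) > 1) return(NULL)
    chars <- do.call(rbind, strsplit(set, "", fixed = TRUE))
    apply(chars, 2, function(col) names(sort(table(col),
                                             decreasing = TRUE))[1])
  }
  ca <- consensus(cdr3_a)
  cb <- consensus(cdr3_b)
  if (is.null(ca) || is.null(cb) || length(ca) != length(cb))
    return(structure(list(clonotype = clonotype, length_mismatch = TRUE,
                          positions = NULL),
                     class = "polymorphism_report"))
  pos <- seq(first_position, length.out = length(ca))
  same <- ca == cb
  charge_a <- charge_class(ca)
  charge_b <- charge_class(cb)
  positions <- data.frame(position = pos, residue_a = ca, residue_b = cb,
                          identical = same, charge_a = charge_a,
                          charge_b = charge_b,
                          charge_altering = !same & charge_a != charge_b,
                          stringsAsFactors = FALSE)
  structure(list(clonotype = clonotype, length_mismatch = FALSE,
                 positions = positions),
            class = "polymorphism_report")
}
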