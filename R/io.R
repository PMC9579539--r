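#' Contig annotation CSV I/O
#'
#' The annotation dialect is a 10x-style CSV with required columns
#' `barcode`, `chain`, `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa` (plus any
#' extras such as `donor` and `contig_id`, which round-trip).  Column
#' order is irrelevant.  Rows whose `chain` is not one of IGH/IGK/IGL are
#' rejected with their line numbers; a missing required column is a
#' schema error.
#'
#' @param contigs contig annotation data.frame.
#' @param path CSV path.
#' @return `write_contig_annotations` returns `path` invisibly;
#'   `read_contig_annotations` returns the validated data.frame with
#'   rejected line numbers in attribute `rejected_lines`.
#' @export
write_contig_annotations <- function(contigs, path) {
  write.csv(contigs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_contig_annotations
#' @export
read_contig_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                "cdr3_aa")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_ibcrep(paste("missing required column(s):",
                      paste(missing, collapse = ", ")),
                "ibcrep_schema_error")
  bad <- which(!df$chain %in% c("IGH", "IGK", "IGL"))
  if (length(bad) > 0) {
    message(sprintf("rejecting %d row(s) with unknown chain (lines: %s)",
                    length(bad),
                    paste(bad + 1, collapse = ", ")))  # +1: header line
    df <- df[-bad, , drop = FALSE]
  }
  df$cdr3_nt[is.na(df$cdr3_nt)] <- ""
  df$cdr3_aa[is.na(df$cdr3_aa)] <- ""
  rownames(df) <- NULL
  attr(df, "rejected_lines") <- bad + 1
  df
}

#' Contig FASTA I/O
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param path FASTA path.
#' @return `path` invisibly; `read_contig_fasta` returns the named
#'   character vector.
#' @export
write_contig_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_contig_fasta
#' @export
read_contig_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), sub(" .*", "", names(dna)))
}

#' Count matrix I/O (MatrixMarket or dense CSV)
#'
#' Matrices are cells x features.  The MTX dialect stores the sparse
#' matrix at `<stem>.mtx` with rownames in `<stem>.barcodes.tsv` and
#' colnames in `<stem>.features.tsv`; the CSV dialect is dense with
#' barcodes in the first column.  Both dialects parse to the identical
#' in-memory representation.
#'
#' @param m matrix with dimnames.
#' @param path output path ending in `.mtx` or `.csv`.
#' @param barcodes,features optional name-file paths overriding the
#'   `<stem>.barcodes.tsv` / `<stem>.features.tsv` convention.
#' @return `path` invisibly; `read_matrix` returns a base dense matrix
#'   with dimnames.
#' @export
write_matrix <- function(m, path, barcodes = NULL, features = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_ibcrep("matrix must carry dimnames", "ibcrep_input_error")
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(barcodes)) barcodes <- paste0(stem, ".barcodes.tsv")
    if (is.null(features)) features <- paste0(stem, ".features.tsv")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), barcodes)
    writeLines(colnames(m), features)
  } else {
    write.csv(data.frame(barcode = rownames(m), m, check.names = FALSE),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, barcodes = NULL, features = NULL) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(barcodes)) barcodes <- paste0(stem, ".barcodes.tsv")
    if (is.null(features)) features <- paste0(stem, ".features.tsv")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(barcodes)
    cn <- readLines(features)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_ibcrep("dimension mismatch between matrix and name files",
                  "ibcrep_schema_error")
    dimnames(m) <- list(rn, cn)
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (length(m) == 0)
    stop_ibcrep("empty matrix", "ibcrep_input_error")
  storage.mode(m) <- "double"
  m
}

#' Sensorgram CSV I/O
#'
#' Columns `time_s`, `ru`, `conc_M`, `phase` (one of baseline / assoc /
#' dissoc).  On reading, the association duration attribute is
#' reconstructed from the phase labels.
#'
#' @param set a `sensorgram_set` data.frame.
#' @param path CSV path.
#' @return `path` invisibly; `read_sensorgram_csv` returns a
#'   `sensorgram_set`.
#' @export
write_sensorgram_csv <- function(set, path) {
  write.csv(as.data.frame(set), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgram_csv
#' @export
read_sensorgram_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "ru", "conc_M", "phase") %in% names(df)))
  a <- df$time_s[df$phase == "assoc"]
  if (length(a) > 0) attr(df, "t_assoc") <- max(a) - min(a)
  class(df) <- c("sensorgram_set", "data.frame")
  df
}

#' ELISA titration CSV I/O
#'
#' @param curve data.frame with `dilution`, `od450`, `group`.
#' @param path CSV path.
#' @return `path` invisibly; the reader returns the data.frame.
#' @export
write_elisa_csv <- function(curve, path) {
  write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_elisa_csv
#' @export
read_elisa_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dilution", "od450") %in% names(df)))
  df
}
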