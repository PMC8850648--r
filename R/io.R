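#' Expression matrix container
#'
#' A thin wrapper around a genes x samples numeric matrix that records the
#' unit of its values, so downstream operations can enforce their
#' preconditions (e.g. the expressed-gene filter requires FPKM).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param unit One of `"counts"`, `"FPKM"`, `"CPM"`, `"log2"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, unit = c("counts", "FPKM", "CPM", "log2")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids in expression matrix")
  if (anyNA(values)) stop("expression matrix contains NA/NaN values")
  if (any(values < 0)) stop("expression matrix contains negative values")
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %d genes x %d samples, unit %s>\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or MatrixMarket
#'
#' TSV layout: genes in rows, first column gene ids, header row of sample
#' ids. MTX layout: a MatrixMarket triplet file plus sidecar text files with
#' one gene id (rows) and one sample id (columns) per line.
#'
#' @param path Path to a `.tsv` or `.mtx` file.
#' @param unit Unit of the stored values (see [expr_matrix()]).
#' @param row_names,col_names For MTX input, paths to the sidecar row/column
#'   name files; default `<path>.rownames` / `<path>.colnames`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, unit = "counts",
                                   row_names = paste0(path, ".rownames"),
                                   col_names = paste0(path, ".colnames")) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) stop("duplicate gene ids in expression matrix")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  expr_matrix(m, unit = unit)
}

#' Write an expression matrix
#'
#' Writes TSV (default) or MatrixMarket with sidecar name files, the same
#' layouts [read_expression_matrix()] accepts.
#'
#' @param x An [expr_matrix()].
#' @param path Output path (`.tsv` or `.mtx`).
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(rownames(x$values), paste0(path, ".rownames"))
    writeLines(colnames(x$values), paste0(path, ".colnames"))
  } else {
    df <- data.frame(gene_id = rownames(x$values), x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

ASE_REQUIRED_COLS <- c("contig", "position", "refAllele", "altAllele",
                       "refCount", "altCount", "totalCount")

#' Read per-SNP allele counts (ASEReadCounter dialect)
#'
#' Reads a GATK-ASEReadCounter-style TSV of read counts per allele at
#' heterozygous SNPs. Positions stay 1-based (VCF convention). Records with
#' a non-ACGT allele are excluded with a warning; a row whose
#' `refCount + altCount` exceeds `totalCount` is a validation error.
#' Optional columns `gene_id`, `intronic`, `multi_gene`, `is_xist` are kept
#' when present (they drive the site filters in the ASE module).
#'
#' @param path Path to the TSV.
#' @param sample_id Sample id to attach to every record.
#' @return A `data.frame` of class `allele_counts` with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`, `total_count`
#'   plus any optional columns found.
#' @export
read_allele_counts <- function(path, sample_id = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(ASE_REQUIRED_COLS, names(df))
  if (length(missing))
    stop("allele-count table missing column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(sample_id = if ("sample_id" %in% names(df)) df$sample_id else sample_id,
                    chrom = normalize_chrom(df$contig),
                    pos = as.integer(df$position),
                    ref = toupper(df$refAllele), alt = toupper(df$altAllele),
                    ref_count = as.integer(df$refCount),
                    alt_count = as.integer(df$altCount),
                    total_count = as.integer(df$totalCount),
                    stringsAsFactors = FALSE)
  for (opt in c("gene_id", "intronic", "multi_gene", "is_xist"))
    if (opt %in% names(df)) out[[opt]] <- df[[opt]]
  allele_counts(out)
}

#' Validate and class an allele-count table
#'
#' @param df A `data.frame` with the columns produced by
#'   [read_allele_counts()].
#' @return The validated table, classed `allele_counts`.
#' @export
allele_counts <- function(df) {
  bad_sum <- df$ref_count + df$alt_count > df$total_count
  if (any(bad_sum))
    stop(sprintf("%d record(s) with refCount + altCount > totalCount", sum(bad_sum)))
  if (any(df$ref_count < 0 | df$alt_count < 0 | df$total_count < 0))
    stop("negative allele counts")
  ok_allele <- df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T")
  if (!all(ok_allele)) {
    warning(sprintf("excluding %d record(s) with non-ACGT alleles", sum(!ok_allele)))
    df <- df[ok_allele, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("allele_counts", "data.frame")
  df
}

#' Write allele counts in the ASEReadCounter dialect
#'
#' @param x An `allele_counts` table.
#' @param path Output TSV path.
#' @export
write_allele_counts <- function(x, path) {
  df <- data.frame(contig = x$chrom, position = x$pos, variantID = ".",
                   refAllele = x$ref, altAllele = x$alt,
                   refCount = x$ref_count, altCount = x$alt_count,
                   totalCount = x$total_count, stringsAsFactors = FALSE)
  for (opt in c("sample_id", "gene_id", "intronic", "multi_gene", "is_xist"))
    if (opt %in% names(x)) df[[opt]] <- x[[opt]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
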