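#' Sex-chromosome karyotype specification
#'
#' Encodes a karyotype by its sex-chromosome copy numbers. All dosage laws in
#' the package are driven by `n_x` (number of X chromosomes) and `n_y`
#' (number of Y chromosomes); the number of inactivated X copies expected in
#' a euploid-autosome cell follows the n-1 rule, `n_x - 1`.
#'
#' @param n_x Integer number of X chromosomes (>= 1).
#' @param n_y Integer number of Y chromosomes (>= 0).
#' @param label Optional display label such as `"47,XXY"`. When supplied, the
#'   total chromosome number it implies must equal `44 + n_x + n_y`.
#' @return An object of class `karyotype_spec`: a list with elements `n_x`,
#'   `n_y`, `label` and `n_xi` (expected inactivated X count).
#' @examples
#' karyotype_spec(2, 1)          # 47,XXY
#' karyotype_spec(4, 1)$n_xi     # 3 inactive X in 49,XXXXY
#' @export
karyotype_spec <- function(n_x, n_y, label = NULL) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (is.na(n_x) || n_x < 1L) stop("n_x must be an integer >= 1")
  if (is.na(n_y) || n_y < 0L) stop("n_y must be an integer >= 0")
  total <- 44L + n_x + n_y
  auto_label <- paste0(total, ",", strrep("X", n_x), strrep("Y", n_y))
  if (is.null(label)) {
    label <- auto_label
  } else {
    implied <- suppressWarnings(as.integer(sub(",.*$", "", label)))
    if (!is.na(implied) && implied != total) {
      stop(sprintf("label '%s' implies %d chromosomes but n_x=%d, n_y=%d imply %d",
                   label, implied, n_x, n_y, total))
    }
  }
  structure(list(n_x = n_x, n_y = n_y, label = label, n_xi = n_x - 1L),
            class = "karyotype_spec")
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat(sprintf("<karyotype %s: n_x=%d, n_y=%d, expected Xi=%d>\n",
              x$label, x$n_x, x$n_y, x$n_xi))
  invisible(x)
}

#' Parse a karyotype label into a karyotype_spec
#'
#' Accepts labels of the form `"46,XY"`, `"47,XXY"`, ..., counting the X and
#' Y letters in the sex-chromosome part.
#'
#' @param label Character karyotype label.
#' @return A [karyotype_spec()].
#' @export
parse_karyotype <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  sex <- sub("^[0-9]+,", "", label)
  if (!grepl("^X+Y*$", sex)) stop(sprintf("cannot parse karyotype label '%s'", label))
  n_x <- nchar(gsub("[^X]", "", sex))
  n_y <- nchar(gsub("[^Y]", "", sex))
  karyotype_spec(n_x, n_y, label = label)
}

#' Pseudoautosomal region boundaries
#'
#' PAR1 and PAR2 sit at the termini of Xp and Xq and are shared with the Y
#' chromosome; genes inside them are present on, and expressed from, every
#' sex chromosome. Defaults are the commonly cited spans of roughly 2.6 Mb
#' (PAR1) and 320 kb (PAR2).
#'
#' @param par1_span_bp Length of PAR1 measured from the Xp terminus.
#' @param par2_span_bp Length of PAR2 measured from the Xq terminus.
#' @param x_length_bp Total length of the X chromosome model.
#' @return An object of class `par_boundaries`.
#' @export
par_boundaries <- function(par1_span_bp = 2.6e6, par2_span_bp = 3.2e5,
                           x_length_bp = 156040895) {
  if (par1_span_bp <= 0 || par2_span_bp <= 0) stop("PAR spans must be positive")
  if (par1_span_bp + par2_span_bp >= x_length_bp)
    stop("PAR spans must sum to less than the X chromosome length")
  structure(list(par1_span_bp = par1_span_bp, par2_span_bp = par2_span_bp,
                 x_length_bp = x_length_bp),
            class = "par_boundaries")
}

REGION_CLASSES <- c("PAR1", "PAR2", "X_NONPAR", "Y_LINKED", "AUTOSOME")

# "chrX" and "X" refer to the same chromosome in the wild; strip the prefix.
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Assign a genomic region class to gene coordinates
#'
#' Classifies genes into `PAR1`, `PAR2`, `X_NONPAR`, `Y_LINKED` or
#' `AUTOSOME`. The classification is a pure function of (chromosome, start,
#' end, boundaries); a gene straddling a PAR boundary is classified by its
#' start position so that every gene receives exactly one class.
#'
#' @param chrom Character vector of chromosome names (`"X"`/`"chrX"` etc.).
#' @param start,end Numeric vectors of 0-based half-open gene coordinates.
#' @param boundaries A [par_boundaries()] object.
#' @return Character vector of region classes.
#' @export
assign_region_class <- function(chrom, start, end, boundaries = par_boundaries()) {
  stopifnot(inherits(boundaries, "par_boundaries"))
  chrom <- normalize_chrom(chrom)
  if (any(start >= end)) stop("gene coordinates must satisfy start < end")
  is_x <- chrom %in% c("X", "x")
  is_y <- chrom %in% c("Y", "y")
  if (any(is_x & end > boundaries$x_length_bp))
    stop("X gene end beyond the declared chromosome length")
  par2_start <- boundaries$x_length_bp - boundaries$par2_span_bp
  out <- rep("AUTOSOME", length(chrom))
  out[is_y] <- "Y_LINKED"
  out[is_x] <- ifelse(start[is_x] < boundaries$par1_span_bp, "PAR1",
               ifelse(start[is_x] >= par2_start, "PAR2", "X_NONPAR"))
  out
}

#' Build a gene annotation table
#'
#' Constructs the internal gene-record table used throughout the package:
#' one row per gene with 0-based half-open coordinates, strand, region class
#' and (optionally) a literature X-inactivation status.
#'
#' @param gene_id Character gene identifiers (unique).
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` per gene.
#' @param xci_status Optional literature XCI annotation per gene, one of
#'   `"escape"`, `"inactive"`, `"variable"`, `"unknown"`.
#' @param boundaries A [par_boundaries()] used to assign region classes.
#' @return A `data.frame` of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `region_class`, `xci_status`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand = "+",
                            xci_status = "unknown",
                            boundaries = par_boundaries()) {
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  n <- length(gene_id)
  strand <- rep_len(strand, n)
  xci_status <- rep_len(xci_status, n)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ann <- data.frame(gene_id = as.character(gene_id),
                    chrom = normalize_chrom(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    strand = strand,
                    region_class = assign_region_class(chrom, start, end, boundaries),
                    xci_status = xci_status,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  attr(ann, "boundaries") <- boundaries
  ann
}

#' Read gene annotation from GTF or BED
#'
#' Reads gene spans from an Ensembl-dialect GTF (1-based closed coordinates,
#' converted to the internal 0-based half-open convention) or a BED6 file
#' (already 0-based half-open). Region classes are assigned on read. Records
#' on chromosomes that cannot be resolved to an autosome, X or Y are skipped
#' with a warning.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @param boundaries A [par_boundaries()] object.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return A [gene_annotation()] table.
#' @export
read_gene_annotation <- function(path, boundaries = par_boundaries(),
                                 format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  .check_annotation_lines(path, format)
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gtf") {
    if ("type" %in% names(df) && any(df$type == "gene")) df <- df[df$type == "gene", ]
    gene_id <- if ("gene_id" %in% names(df)) df$gene_id else as.character(seq_len(nrow(df)))
    xci <- if ("xci_status" %in% names(df)) df$xci_status else "unknown"
  } else {
    gene_id <- if ("name" %in% names(df)) df$name else as.character(seq_len(nrow(df)))
    xci <- "unknown"
  }
  xci[is.na(xci)] <- "unknown"
  chrom <- normalize_chrom(df$seqnames)
  known <- grepl("^([0-9]+|X|Y)$", chrom)
  if (!all(known)) {
    warning(sprintf("skipping %d record(s) on unresolvable chromosome(s): %s",
                    sum(!known), paste(unique(chrom[!known]), collapse = ", ")))
    df <- df[known, ]; gene_id <- gene_id[known]
    xci <- if (length(xci) > 1L) xci[known] else xci
    chrom <- chrom[known]
  }
  strand <- as.character(df$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  # rtracklayer yields 1-based closed starts for both dialects; end stays.
  gene_annotation(gene_id, chrom, start = df$start - 1, end = df$end,
                  strand = strand, xci_status = xci, boundaries = boundaries)
}

# Pre-scan so that a malformed line is reported with its line number, which
# rtracklayer's parser does not do.
.check_annotation_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  min_fields <- if (format == "gtf") 9L else 4L
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    coords <- if (format == "gtf") f[4:5] else f[2:3]
    if (length(f) < min_fields || anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed %s line %d in %s", toupper(format), i, path))
  }
  invisible(TRUE)
}

#' Write gene annotation as GTF
#'
#' Serializes the internal table back to Ensembl-dialect GTF (1-based closed
#' coordinates), carrying `xci_status` as an attribute so a read round-trips.
#'
#' @param ann A [gene_annotation()] table.
#' @param path Output file path.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  attrs <- sprintf('gene_id "%s"; xci_status "%s";', ann$gene_id, ann$xci_status)
  lines <- sprintf("%s\txdosage\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, as.integer(ann$start) + 1L, as.integer(ann$end),
                   ann$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata from YAML
#'
#' The metadata file maps each sample id to a karyotype label and an optional
#' cohort role / clone id, e.g.
#' `samples: {S1: {karyotype: "47,XXY", role: case}}`.
#'
#' @param path Path to a YAML file with a top-level `samples` mapping.
#' @return A `data.frame` with columns `sample_id`, `karyotype`, `n_x`,
#'   `n_y`, `cohort_role`, `clone_id`.
#' @export
read_sample_meta <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- if (!is.null(y$samples)) y$samples else y
  if (anyDuplicated(names(samples))) stop("sample ids must be unique")
  rows <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    if (is.character(s)) s <- list(karyotype = s)
    ks <- parse_karyotype(s$karyotype)
    data.frame(sample_id = id, karyotype = ks$label, n_x = ks$n_x, n_y = ks$n_y,
               cohort_role = if (!is.null(s$role)) s$role else "case",
               clone_id = if (!is.null(s$clone)) s$clone else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write sample metadata as YAML
#'
#' @param meta A sample-metadata `data.frame` as returned by
#'   [read_sample_meta()].
#' @param path Output YAML path.
#' @export
write_sample_meta <- function(meta, path) {
  samples <- stats::setNames(lapply(seq_len(nrow(meta)), function(i) {
    s <- list(karyotype = meta$karyotype[i], role = meta$cohort_role[i])
    if (!is.na(meta$clone_id[i])) s$clone <- meta$clone_id[i]
    s
  }), meta$sample_id)
  yaml::write_yaml(list(samples = samples), path)
  invisible(path)
}
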