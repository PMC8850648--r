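#' Build a variant whitelist from filtered variant calls
#'
#' Only variants confirmed in DNA (e.g. by whole-exome sequencing) are used
#' for allele-specific expression, which controls for RNA-editing artifacts.
#' A call enters the whitelist iff its FILTER is `PASS` and its total read
#' depth exceeds 10 (strict). Records without a depth field are excluded
#' with a warning.
#'
#' @param vcf Path to a VCF file, or a data.frame with columns `chrom`,
#'   `pos`, `filter`, `dp`.
#' @param min_total_reads Minimum depth, exclusive bound is
#'   `min_total_reads - 1` (default 11, i.e. depth > 10).
#' @param require_pass Keep only `FILTER == "PASS"` records.
#' @return Data frame `chrom`, `pos` of whitelisted positions (1-based).
#' @export
filter_variant_whitelist <- function(vcf, min_total_reads = 11L, require_pass = TRUE) {
  if (is.character(vcf)) {
    v <- vcfR::read.vcfR(vcf, verbose = FALSE)
    dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
    df <- data.frame(chrom = normalize_chrom(vcfR::getCHROM(v)),
                     pos = as.integer(vcfR::getPOS(v)),
                     filter = vcfR::getFILTER(v), dp = dp,
                     stringsAsFactors = FALSE)
  } else {
    df <- vcf
    df$chrom <- normalize_chrom(df$chrom)
  }
  no_dp <- is.na(df$dp)
  if (any(no_dp)) {
    warning(sprintf("excluding %d variant(s) without a depth field", sum(no_dp)))
    df <- df[!no_dp, , drop = FALSE]
  }
  keep <- df$dp >= min_total_reads
  if (require_pass) keep <- keep & df$filter == "PASS"
  unique(df[keep, c("chrom", "pos"), drop = FALSE])
}

#' Apply the per-site ASE filters
#'
#' Keeps allele-count records that (1) sit at a whitelisted variant
#' position, (2) have total depth strictly greater than `min_depth - 1`
#' (default: depth > 6), (3) are not intronic, and (4) map uniquely to one
#' gene. XIST is exempt from the intronic and unique-mapping filters (its
#' unspliced nuclear transcript would otherwise be discarded). Each filtered
#' record carries exactly one primary reason, assessed in the order
#' whitelist, depth, intronic, multi-gene.
#'
#' @param records An `allele_counts` table; optional logical columns
#'   `intronic`, `multi_gene`, `is_xist` default to
#'   FALSE/FALSE/`gene_id == "XIST"`.
#' @param whitelist Data frame `chrom`, `pos` from
#'   [filter_variant_whitelist()].
#' @param min_depth Minimum total depth (kept iff `total_count >= min_depth`;
#'   default 7, the "greater than six" rule).
#' @param xist_exempt_intronic Whether XIST records bypass the intronic
#'   filter as well as the multi-gene filter.
#' @return List with `kept` (records) and `filtered` (records plus a
#'   `reason` column in `whitelist`, `depth`, `intronic`, `multi_gene`).
#' @export
filter_sites <- function(records, whitelist, min_depth = 7L,
                         xist_exempt_intronic = TRUE) {
  n <- nrow(records)
  intronic <- if ("intronic" %in% names(records)) isTRUE_vec(records$intronic) else rep(FALSE, n)
  multi <- if ("multi_gene" %in% names(records)) isTRUE_vec(records$multi_gene) else rep(FALSE, n)
  is_xist <- if ("is_xist" %in% names(records)) isTRUE_vec(records$is_xist)
             else if ("gene_id" %in% names(records)) records$gene_id == "XIST"
             else rep(FALSE, n)
  if (nrow(whitelist) == 0) warning("empty variant whitelist: all records filtered")
  in_wl <- paste(normalize_chrom(records$chrom), records$pos) %in%
    paste(normalize_chrom(whitelist$chrom), whitelist$pos)
  reason <- rep(NA_character_, n)
  reason[!in_wl] <- "whitelist"
  low <- is.na(reason) & records$total_count < min_depth
  reason[low] <- "depth"
  intr <- is.na(reason) & intronic & !(xist_exempt_intronic & is_xist)
  reason[intr] <- "intronic"
  mg <- is.na(reason) & multi & !is_xist
  reason[mg] <- "multi_gene"
  kept <- records[is.na(reason), , drop = FALSE]
  filtered <- records[!is.na(reason), , drop = FALSE]
  filtered$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(filtered) <- NULL
  list(kept = kept, filtered = filtered)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Classify SNPs as biallelic or monoallelic
#'
#' The reference-allele fraction is `ref_count / total_count`. A SNP is
#' biallelic when the fraction lies within \[`lower`, `upper`\] (default
#' 0.1-0.9, boundaries inclusive) and monoallelic when it falls below or
#' above that range. Records with `total_count == 0` are marked `filtered`,
#' never classified.
#'
#' @param records Allele-count records that passed [filter_sites()].
#' @param lower,upper Biallelic fraction gate (inclusive).
#' @return The records with added columns `ref_fraction` and `status`
#'   (`biallelic` / `monoallelic` / `filtered`).
#' @export
classify_snp <- function(records, lower = 0.1, upper = 0.9) {
  frac <- ifelse(records$total_count > 0,
                 records$ref_count / records$total_count, NA_real_)
  status <- ifelse(is.na(frac), "filtered",
            ifelse(frac >= lower & frac <= upper, "biallelic", "monoallelic"))
  records$ref_fraction <- frac
  records$status <- status
  records
}

#' Aggregate SNP calls into per-gene ASE calls
#'
#' A gene is biallelic in a sample if one or more of its informative SNPs is
#' biallelic; monoallelic if it has informative SNPs and none is biallelic;
#' uninformative if every one of its SNPs was filtered (a gene with no SNP
#' rows at all does not appear in the output).
#'
#' @param snp_calls Output of [classify_snp()] with a `gene_id` column.
#' @return Data frame with one row per (sample, gene): `sample_id`,
#'   `gene_id`, `n_informative`, `n_biallelic`, `status`.
#' @export
call_genes <- function(snp_calls) {
  if (!"gene_id" %in% names(snp_calls)) stop("snp calls need a gene_id column")
  if (nrow(snp_calls) == 0)
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      n_informative = integer(0), n_biallelic = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    cbind(n_informative = as.integer(snp_calls$status != "filtered"),
          n_biallelic = as.integer(snp_calls$status == "biallelic")),
    by = list(sample_id = snp_calls$sample_id, gene_id = snp_calls$gene_id),
    FUN = sum)
  agg$status <- ifelse(agg$n_biallelic >= 1, "biallelic",
                ifelse(agg$n_informative >= 1, "monoallelic", "uninformative"))
  out <- agg[order(agg$sample_id, agg$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize per-gene ASE calls by sample and region class
#'
#' Counts biallelic and monoallelic genes per sample within each genomic
#' region class, and reports the per-gene biallelic detection frequency
#' across samples (replicates): 100 x biallelic / informative.
#'
#' @param gene_calls Output of [call_genes()].
#' @param annotation A [gene_annotation()]; genes missing from it are
#'   counted under region class `unknown` with a warning.
#' @return List of class `ase_summary` with `by_sample` (sample x
#'   region_class x status counts, long format), `gene_frequency` (per-gene
#'   percentage) and `nonpar_biallelic` (per-sample biallelic non-PAR X gene
#'   count, the erosion readout).
#' @export
summarize_ase <- function(gene_calls, annotation) {
  rc <- annotation$region_class[match(gene_calls$gene_id, annotation$gene_id)]
  if (anyNA(rc)) {
    warning(sprintf("%d gene(s) absent from annotation counted as region 'unknown'",
                    length(unique(gene_calls$gene_id[is.na(rc)]))))
    rc[is.na(rc)] <- "unknown"
  }
  gene_calls$region_class <- rc
  by_sample <- as.data.frame(table(sample_id = gene_calls$sample_id,
                                   region_class = gene_calls$region_class,
                                   status = gene_calls$status),
                             stringsAsFactors = FALSE)
  names(by_sample)[names(by_sample) == "Freq"] <- "n_genes"
  n_inf <- tapply(gene_calls$status != "uninformative", gene_calls$gene_id, sum)
  n_bi <- tapply(gene_calls$status == "biallelic", gene_calls$gene_id, sum)
  gene_frequency <- data.frame(gene_id = names(n_inf),
                               n_informative_samples = as.integer(n_inf),
                               n_biallelic_samples = as.integer(n_bi),
                               biallelic_pct = 100 * as.integer(n_bi) / as.integer(n_inf),
                               stringsAsFactors = FALSE)
  rownames(gene_frequency) <- NULL
  np <- gene_calls$region_class == "X_NONPAR" & gene_calls$status == "biallelic"
  samples <- unique(gene_calls$sample_id)
  nonpar <- vapply(samples, function(s) sum(np & gene_calls$sample_id == s), integer(1))
  structure(list(by_sample = by_sample, gene_frequency = gene_frequency,
                 nonpar_biallelic = data.frame(sample_id = samples,
                                               n_biallelic_nonpar = nonpar,
                                               stringsAsFactors = FALSE)),
            class = "ase_summary")
}

#' @export
print.ase_summary <- function(x, ...) {
  cat("<ase_summary>\nbiallelic non-PAR X genes per sample:\n")
  print(x$nonpar_biallelic, row.names = FALSE)
  invisible(x)
}

#' Flag X-eroded samples
#'
#' X erosion in cultured pluripotent cells manifests as an excess of
#' biallelically expressed non-PAR X genes. A sample is flagged iff its
#' biallelic non-PAR X gene count is at least `multiplier_threshold` times
#' the median count of the other samples AND at least `min_biallelic`.
#'
#' @param summary An [summarize_ase()] result, or a data.frame with columns
#'   `sample_id` and `n_biallelic_nonpar`.
#' @param multiplier_threshold Fold-excess over the cohort median of the
#'   remaining samples (default 2).
#' @param min_biallelic Absolute floor on the biallelic count (default 30).
#' @return Data frame `sample_id`, `n_biallelic_nonpar`, `median_others`,
#'   `eroded`.
#' @export
flag_erosion <- function(summary, multiplier_threshold = 2.0, min_biallelic = 30L) {
  df <- if (inherits(summary, "ase_summary")) summary$nonpar_biallelic else summary
  if (nrow(df) < 3) stop("erosion flagging needs at least 3 samples for a reference distribution")
  med_others <- vapply(seq_len(nrow(df)), function(i)
    stats::median(df$n_biallelic_nonpar[-i]), numeric(1))
  df$median_others <- med_others
  df$eroded <- df$n_biallelic_nonpar >= multiplier_threshold * med_others &
    df$n_biallelic_nonpar >= min_biallelic
  df
}

#' Check the allelic status of XIST
#'
#' Monoallelic XIST expression argues against mosaic X inactivation (two
#' cell populations inactivating different X copies would show both
#' alleles). Applies the standard SNP and gene rules to XIST records only; a
#' biallelic verdict emits a mosaic-XCI warning.
#'
#' @param snp_calls Output of [classify_snp()]; rows are restricted to
#'   XIST via the `is_xist` flag or `gene_id == "XIST"`.
#' @return Per-sample data frame `sample_id`, `status` (`monoallelic` /
#'   `biallelic` / `uninformative`).
#' @export
xist_allelic_check <- function(snp_calls) {
  sel <- if ("is_xist" %in% names(snp_calls)) isTRUE_vec(snp_calls$is_xist)
         else snp_calls$gene_id == "XIST"
  samples <- unique(snp_calls$sample_id)
  xist <- snp_calls[sel & snp_calls$status != "filtered", , drop = FALSE]
  status <- vapply(samples, function(s) {
    st <- xist$status[xist$sample_id == s]
    if (!length(st)) "uninformative"
    else if (any(st == "biallelic")) "biallelic" else "monoallelic"
  }, character(1))
  if (any(status == "biallelic"))
    warning("biallelic XIST detected: possible mosaic X inactivation")
  data.frame(sample_id = samples, status = status, stringsAsFactors = FALSE)
}

#' Compare biallelic fractions between region classes
#'
#' Convenience report: two-sided Wilcoxon rank-sum (Mann-Whitney) test of
#' per-gene reference-allele fractions between two region classes (e.g. PAR1
#' vs non-PAR X) within each sample.
#'
#' @param snp_calls Output of [classify_snp()] with `gene_id`.
#' @param annotation A [gene_annotation()].
#' @param class_a,class_b Region classes to compare.
#' @return Data frame `sample_id`, `n_a`, `n_b`, `p_value`.
#' @export
ase_region_test <- function(snp_calls, annotation,
                            class_a = "PAR1", class_b = "X_NONPAR") {
  rc <- annotation$region_class[match(snp_calls$gene_id, annotation$gene_id)]
  # fold to distance-from-balance so direction of the reference allele is irrelevant
  bal <- abs(snp_calls$ref_fraction - 0.5)
  out <- lapply(unique(snp_calls$sample_id), function(s) {
    i <- snp_calls$sample_id == s
    a <- bal[i & rc %in% class_a]; b <- bal[i & rc %in% class_b]
    p <- if (length(a) >= 2 && length(b) >= 2)
      stats::wilcox.test(a, b, exact = FALSE)$p.value else NA_real_
    data.frame(sample_id = s, n_a = length(a), n_b = length(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
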