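#' Restrict an FPKM matrix to expressed genes
#'
#' Genes with expression below 0.5 FPKM are considered not expressed and
#' excluded. The cut is applied to the per-gene aggregate over samples
#' (mean by default); genes at exactly the cutoff are kept.
#'
#' @param x An [expr_matrix()] with unit FPKM.
#' @param cutoff Minimum aggregate FPKM (default 0.5).
#' @param aggregate Function collapsing a gene's values across samples
#'   (default `mean`).
#' @return The filtered [expr_matrix()].
#' @export
filter_expressed <- function(x, cutoff = 0.5, aggregate = mean) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "FPKM") stop("expressed-gene filter requires FPKM values, got ", x$unit)
  keep <- apply(x$values, 1, aggregate) >= cutoff
  expr_matrix(x$values[keep, , drop = FALSE], unit = x$unit)
}

#' X:autosome expression ratio
#'
#' Dosage-compensation readout per sample. The mean FPKM (MF) of a
#' chromosome is the sum of its genes' FPKM divided by its gene count; the
#' ratio is the X chromosome's MF over the unweighted average of the
#' per-autosome MFs. The ratio is invariant under global rescaling of the
#' matrix.
#'
#' @param x An expressed-gene-filtered FPKM [expr_matrix()].
#' @param annotation A [gene_annotation()] covering the matrix genes.
#' @return Data frame `sample_id`, `mf_x`, `mf_autosome_mean`, `ratio`.
#' @export
x_a_ratio <- function(x, annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  chrom <- annotation$chrom[match(rownames(x$values), annotation$gene_id)]
  if (anyNA(chrom)) stop("matrix contains genes absent from the annotation")
  on_x <- chrom == "X"
  on_auto <- grepl("^[0-9]+$", chrom)
  if (!any(on_x)) stop("no expressed X-linked genes in the matrix")
  if (!any(on_auto)) stop("no expressed autosomal genes in the matrix")
  mf_x <- colMeans(x$values[on_x, , drop = FALSE])
  auto_chr <- unique(chrom[on_auto])
  per_auto <- matrix(vapply(auto_chr, function(a)
    colMeans(x$values[chrom == a, , drop = FALSE]), numeric(ncol(x$values))),
    nrow = ncol(x$values))
  mf_auto <- rowMeans(per_auto)
  data.frame(sample_id = colnames(x$values), mf_x = mf_x,
             mf_autosome_mean = mf_auto, ratio = mf_x / mf_auto,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene fold change over the male-median reference
#'
#' The male median (MM) of a gene is its median FPKM over healthy 46,XY
#' reference samples after removing non-expressed genes; each sample's fold
#' change (FC) is its FPKM divided by MM. Genes with MM = 0 are dropped
#' (message emitted).
#'
#' @param x An FPKM [expr_matrix()] (expressed-gene filter recommended
#'   first).
#' @param reference_samples Sample ids of the 46,XY references (>= 2).
#' @return List of class `fc_track`: `fc` (genes x samples matrix of fold
#'   changes), `male_median` (named vector), `reference_samples`.
#' @export
male_median_fc <- function(x, reference_samples) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(reference_samples) < 2) stop("need at least 2 reference XY samples")
  if (!all(reference_samples %in% colnames(x$values)))
    stop("reference sample(s) missing from the matrix")
  mm <- apply(x$values[, reference_samples, drop = FALSE], 1, stats::median)
  zero <- mm == 0
  if (any(zero))
    message(sprintf("dropping %d gene(s) with male median 0", sum(zero)))
  fc <- sweep(x$values[!zero, , drop = FALSE], 1, mm[!zero], `/`)
  structure(list(fc = fc, male_median = mm[!zero],
                 reference_samples = reference_samples),
            class = "fc_track")
}

#' Loess moving average of fold change along the X chromosome
#'
#' Smooths each sample's log2 fold change as a function of gene start
#' position on X with a loess fit (span 0.45 by default; the span is the
#' fraction of genes in each sliding window), evaluated at the gene
#' positions. Uses locally weighted quadratic regression with tricube
#' weights and no robustness iterations.
#'
#' @param track A [male_median_fc()] result.
#' @param annotation A [gene_annotation()] giving gene positions; only
#'   X-linked genes are used.
#' @param span Loess span (default 0.45).
#' @param degree Local polynomial degree (default 2).
#' @param log2_scale Smooth log2(FC) (default) rather than raw FC.
#' @param pseudo Value added to FC before log2 to guard zeros.
#' @return List of class `ma_curve`: `position` (sorted gene starts),
#'   `smoothed` (positions x samples matrix), `span`, `gene_id`.
#' @export
moving_average_x <- function(track, annotation, span = 0.45, degree = 2,
                             log2_scale = TRUE, pseudo = 1e-8) {
  stopifnot(inherits(track, "fc_track"))
  idx <- match(rownames(track$fc), annotation$gene_id)
  on_x <- !is.na(idx) & annotation$chrom[idx] == "X"
  if (sum(on_x) < 10)
    stop("need at least 10 X-linked genes with positions; supply a larger matrix")
  pos <- annotation$start[idx[on_x]]
  fc <- track$fc[on_x, , drop = FALSE]
  ord <- order(pos)
  pos <- pos[ord]; fc <- fc[ord, , drop = FALSE]
  y_all <- if (log2_scale) log2(fc + pseudo) else fc
  smoothed <- apply(y_all, 2, function(y) {
    fit <- stats::loess(y ~ pos, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, data.frame(pos = pos))
  })
  structure(list(position = pos, smoothed = smoothed, span = span,
                 gene_id = rownames(fc)),
            class = "ma_curve")
}

#' Call differentially expressed genes from summary statistics
#'
#' Applies the thresholds FDR < 0.05 with log2 fold change > 0.25 (up) or
#' < -0.25 (down); anything else is `ns`. Accepts externally computed
#' statistics (e.g. an edgeR table) unchanged.
#'
#' @param stats_df Data frame with columns `gene_id`, `log2_fc`, `fdr`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.25,
#'   strict).
#' @return The input with a `direction` column (`up`/`down`/`ns`).
#' @export
call_degs <- function(stats_df, fdr_cut = 0.05, lfc_cut = 0.25) {
  stopifnot(all(c("gene_id", "log2_fc", "fdr") %in% names(stats_df)))
  if (any(stats_df$fdr < 0 | stats_df$fdr > 1, na.rm = TRUE))
    stop("fdr values must lie in [0, 1]")
  stats_df$direction <- ifelse(stats_df$fdr < fdr_cut & stats_df$log2_fc > lfc_cut, "up",
                        ifelse(stats_df$fdr < fdr_cut & stats_df$log2_fc < -lfc_cut, "down",
                               "ns"))
  stats_df
}

#' Differential-expression statistics on log2(CPM + 1)
#'
#' Simple two-group engine: counts are scaled to counts per million,
#' log2(CPM + 1)-transformed, compared by Welch's t-test per gene, and
#' corrected by Benjamini-Hochberg. The log2 fold change is the difference
#' of group means on the transformed scale. Intended as the in-package
#' engine behind [call_degs()]; externally computed tables (e.g. edgeR) can
#' be fed to [call_degs()] directly instead.
#'
#' @param x A counts [expr_matrix()].
#' @param group_a,group_b Sample ids of the two groups (`a` vs `b`; positive
#'   log2 FC means higher in `a`).
#' @return Data frame `gene_id`, `log2_fc`, `p_value`, `fdr`.
#' @export
deg_stats <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (x$unit == "counts" || x$unit == "FPKM") {
    cpm <- sweep(m, 2, colSums(m), `/`) * 1e6
    m <- log2(cpm + 1)
  }
  a <- m[, group_a, drop = FALSE]; b <- m[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(m)), function(i) {
    if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0)
      return(if (mean(a[i, ]) == mean(b[i, ])) 1 else 0)
    tryCatch(stats::t.test(a[i, ], b[i, ])$p.value, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(gene_id = rownames(m), log2_fc = rowMeans(a) - rowMeans(b),
             p_value = p, fdr = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect two DEG calls with concordant direction
#'
#' @param calls_a,calls_b Outputs of [call_degs()].
#' @return Data frame of genes called (non-`ns`) in both comparisons with
#'   the same direction.
#' @export
deg_intersection <- function(calls_a, calls_b) {
  a <- calls_a[calls_a$direction != "ns", c("gene_id", "direction")]
  b <- calls_b[calls_b$direction != "ns", c("gene_id", "direction")]
  merge(a, b, by = c("gene_id", "direction"))
}

#' Classify per-gene dosage trends across karyotypes
#'
#' Fits ordinary least squares of log2(FPKM + pseudocount) on a
#' sex-chromosome covariate: the total sex-chromosome count `n_x + n_y` for
#' PAR genes (present on every sex chromosome) and the X count `n_x`
#' otherwise. Genes are classified `proportional` (positive slope,
#' BH-adjusted p < alpha), `inverse` (negative slope, adjusted p < alpha)
#' or `flat`.
#'
#' @param x An FPKM [expr_matrix()].
#' @param meta Sample metadata with `sample_id`, `n_x`, `n_y` (>= 3
#'   distinct karyotype groups required).
#' @param annotation A [gene_annotation()] for the region-class-driven
#'   covariate choice.
#' @param alpha Significance level on the BH-adjusted slope p-value.
#' @param pseudo Pseudocount before log2 (default 0.1). Kept below the
#'   0.5-FPKM detection floor: a pseudocount of 1 attenuates the log-scale
#'   slope of moderately expressed genes by several percent, biasing trend
#'   recovery.
#' @param covariate `"auto"` (region-class-driven), `"n_x"` or
#'   `"n_x_plus_n_y"` for all genes.
#' @return Data frame `gene_id`, `covariate`, `slope`, `p_value`, `fdr`,
#'   `trend`.
#' @export
classify_dosage_trend <- function(x, meta, annotation, alpha = 0.05, pseudo = 0.1,
                                  covariate = c("auto", "n_x", "n_x_plus_n_y")) {
  stopifnot(inherits(x, "expr_matrix"))
  covariate <- match.arg(covariate)
  meta <- meta[match(colnames(x$values), meta$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  if (length(unique(paste(meta$n_x, meta$n_y))) < 3)
    stop("dosage-trend classification needs at least 3 distinct karyotype groups")
  rc <- annotation$region_class[match(rownames(x$values), annotation$gene_id)]
  use_total <- switch(covariate,
                      auto = !is.na(rc) & rc %in% c("PAR1", "PAR2"),
                      n_x = rep(FALSE, nrow(x$values)),
                      n_x_plus_n_y = rep(TRUE, nrow(x$values)))
  y_all <- log2(x$values + pseudo)
  nx <- meta$n_x; total <- meta$n_x + meta$n_y
  res <- t(vapply(seq_len(nrow(y_all)), function(i) {
    cv <- if (use_total[i]) total else nx
    fit <- stats::lm(y_all[i, ] ~ cv)
    co <- suppressWarnings(summary(fit)$coefficients)
    if (nrow(co) < 2) return(c(0, 1))
    out <- co[2, c(1, 4)]
    if (is.na(out[2])) out[2] <- 1  # zero-residual (constant) genes
    out
  }, numeric(2)))
  fdr <- stats::p.adjust(res[, 2], "BH")
  trend <- ifelse(fdr < alpha & res[, 1] > 0, "proportional",
           ifelse(fdr < alpha & res[, 1] < 0, "inverse", "flat"))
  data.frame(gene_id = rownames(y_all),
             covariate = ifelse(use_total, "n_x_plus_n_y", "n_x"),
             slope = res[, 1], p_value = res[, 2], fdr = fdr, trend = trend,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Categorize X-linked DEGs by region and XCI status
#'
#' Each X-linked gene receives exactly one category: PAR1 membership
#' overrides the literature XCI status; otherwise the status maps escape /
#' inactive / variable directly and genes without a described status are
#' `novel`.
#'
#' @param deg_genes Character vector of DEG gene ids.
#' @param annotation A [gene_annotation()] with `xci_status`.
#' @return Data frame `gene_id`, `category` for the X-linked subset
#'   (PAR2 genes are categorized `PAR2`).
#' @export
categorize_x_degs <- function(deg_genes, annotation) {
  i <- match(deg_genes, annotation$gene_id)
  if (anyNA(i)) stop("DEG gene(s) absent from annotation")
  ann <- annotation[i, ]
  on_x <- ann$region_class %in% c("PAR1", "PAR2", "X_NONPAR")
  ann <- ann[on_x, ]
  category <- ifelse(ann$region_class == "PAR1", "PAR1",
              ifelse(ann$region_class == "PAR2", "PAR2",
              ifelse(ann$xci_status == "escape", "escape",
              ifelse(ann$xci_status == "inactive", "inactive",
              ifelse(ann$xci_status == "variable", "variable", "novel")))))
  data.frame(gene_id = ann$gene_id, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}
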