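#' Library-size normalize single-cell counts
#'
#' Scales each cell's counts to the median library size across cells, then
#' log2(x + 1)-transforms. Cells with zero total counts are dropped with a
#' warning.
#'
#' @param counts Genes x cells matrix of non-negative counts.
#' @return List: `values` (normalized matrix), `dropped` (ids of removed
#'   cells).
#' @export
normalize_cells <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    warning(sprintf("dropping %d cell(s) with zero library size", sum(zero)))
    counts <- counts[, !zero, drop = FALSE]
    lib <- lib[!zero]
  }
  target <- stats::median(lib)
  scaled <- sweep(counts, 2, target / lib, `*`)
  list(values = log2(scaled + 1), dropped = names(zero)[zero])
}

#' XIST expression by karyotype with Kruskal-Wallis test
#'
#' XIST is expressed from every inactive X, so its per-cell level is
#' expected to scale with `n_x - 1`. Reports per-karyotype medians and the
#' rank-based Kruskal-Wallis test across karyotype groups.
#'
#' @param values Genes x cells matrix (normalized).
#' @param cells Cell metadata with `cell_id`, `karyotype` (and `n_x` for
#'   ordering, optional).
#' @param xist_gene Row name of XIST (default `"XIST"`).
#' @return List: `medians` (data frame karyotype, n_cells, median),
#'   `statistic` (Kruskal-Wallis H), `p_value`.
#' @export
xist_by_karyotype <- function(values, cells, xist_gene = "XIST") {
  if (!xist_gene %in% rownames(values)) stop("XIST row not found in matrix")
  cells <- cells[match(colnames(values), cells$cell_id), ]
  groups <- split(values[xist_gene, ], cells$karyotype)
  if (length(groups) < 2) stop("need at least 2 karyotype groups")
  small <- vapply(groups, length, integer(1)) < 3
  if (any(small))
    warning("karyotype group(s) with fewer than 3 cells: ",
            paste(names(groups)[small], collapse = ", "))
  kw <- stats::kruskal.test(groups)
  med <- data.frame(karyotype = names(groups),
                    n_cells = vapply(groups, length, integer(1)),
                    median = vapply(groups, stats::median, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if ("n_x" %in% names(cells)) {
    nx <- vapply(med$karyotype, function(k) cells$n_x[match(k, cells$karyotype)],
                 numeric(1))
    med <- med[order(nx), ]; rownames(med) <- NULL
  }
  list(medians = med, statistic = unname(kw$statistic), p_value = kw$p.value)
}

#' Per-karyotype Pearson correlation of genes with XIST
#'
#' Tests, within each karyotype group separately, whether a gene's per-cell
#' expression tracks the cell's realized XIST level. Correlations are never
#' pooled across karyotypes: pooling would induce spurious correlation
#' through the shared dosage. A gene is declared `independent` when the
#' two-sided p-value exceeds `alpha`, `correlated` otherwise; zero-variance
#' genes (or a zero-variance XIST group) are flagged `undefined`.
#'
#' @param values Genes x cells matrix (normalized).
#' @param cells Cell metadata with `cell_id`, `karyotype`.
#' @param genes Gene ids to test.
#' @param xist_gene Row name of XIST.
#' @param alpha Significance level (default 0.05).
#' @param min_cells Minimum cells per karyotype group (default 10).
#' @return Data frame `gene_id`, `karyotype`, `r`, `p_value`, `n_cells`,
#'   `verdict`.
#' @export
correlate_with_xist <- function(values, cells, genes, xist_gene = "XIST",
                                alpha = 0.05, min_cells = 10L) {
  cells <- cells[match(colnames(values), cells$cell_id), ]
  out <- list()
  for (k in unique(cells$karyotype)) {
    idx <- which(cells$karyotype == k)
    if (length(idx) < min_cells) next
    xist <- values[xist_gene, idx]
    xist_const <- stats::sd(xist) == 0
    for (g in genes) {
      y <- values[g, idx]
      if (xist_const || stats::sd(y) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, karyotype = k, r = NA_real_, p_value = NA_real_,
          n_cells = length(idx), verdict = "undefined", stringsAsFactors = FALSE)
        next
      }
      ct <- stats::cor.test(xist, y, method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, karyotype = k, r = unname(ct$estimate),
        p_value = ct$p.value, n_cells = length(idx),
        verdict = if (ct$p.value > alpha) "independent" else "correlated",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Test gene expression against cell-cycle phase
#'
#' Kruskal-Wallis test of each gene's per-cell expression across the G1, S
#' and G2M phases; a gene is declared phase-independent when p > alpha.
#' Phases with fewer than 3 cells trigger a warning and the test is
#' skipped.
#'
#' @param values Genes x cells matrix (normalized).
#' @param cells Cell metadata with `cell_id`, `phase`.
#' @param genes Gene ids to test.
#' @param alpha Significance level (default 0.05).
#' @return Data frame `gene_id`, `statistic`, `p_value`, `independent`.
#' @export
phase_independence <- function(values, cells, genes, alpha = 0.05) {
  cells <- cells[match(colnames(values), cells$cell_id), ]
  phases <- cells$phase[cells$phase %in% c("G1", "S", "G2M")]
  tab <- table(phases)
  if (any(tab < 3) || length(tab) < 2) {
    warning("cell-cycle phase(s) with fewer than 3 cells; test skipped")
    return(data.frame(gene_id = genes, statistic = NA_real_,
                      p_value = NA_real_, independent = NA,
                      stringsAsFactors = FALSE))
  }
  keep <- cells$phase %in% c("G1", "S", "G2M")
  ph <- factor(cells$phase[keep])
  out <- lapply(genes, function(g) {
    y <- values[g, keep]
    if (stats::sd(y) == 0)
      return(data.frame(gene_id = g, statistic = 0, p_value = 1,
                        independent = TRUE, stringsAsFactors = FALSE))
    kw <- stats::kruskal.test(y, ph)
    data.frame(gene_id = g, statistic = unname(kw$statistic),
               p_value = kw$p.value, independent = kw$p.value > alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
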