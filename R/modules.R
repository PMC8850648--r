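#' Filter counts by CPM detectability
#'
#' Keeps genes with at least one count per million reads in at least
#' `min_samples` samples.
#'
#' @param x A counts [expr_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Number of samples that must reach it (default 4).
#' @return The filtered counts [expr_matrix()].
#' @export
filter_cpm <- function(x, min_cpm = 1, min_samples = 4L) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit != "counts") stop("CPM filter requires counts, got ", x$unit)
  if (ncol(x$values) < min_samples)
    stop(sprintf("CPM filter needs at least %d samples", min_samples))
  cpm <- sweep(x$values, 2, colSums(x$values), `/`) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  expr_matrix(x$values[keep, , drop = FALSE], unit = "counts")
}

#' log2(CPM + 1) transform
#'
#' Monotone variance-stabilizing transform used before network
#' construction.
#'
#' @param x A counts [expr_matrix()].
#' @return A matrix of log2(CPM + 1) values.
#' @export
log_cpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  log2(sweep(x$values, 2, colSums(x$values), `/`) * 1e6 + 1)
}

#' Network configuration for module detection
#'
#' @param soft_power Soft-thresholding exponent of the signed adjacency
#'   (default 20).
#' @param min_module_size Smallest gene count a module may have (default
#'   30); smaller clusters are folded into `"grey"`.
#' @param cut_quantile Quantile of the dendrogram merge heights at which
#'   the static tree cut is made (default 0.99).
#' @param cor_gate Minimum mean within-module correlation for a candidate
#'   cluster to be accepted as a module (default 0.3); incoherent clusters
#'   are folded into `"grey"`.
#' @param merge_dissimilarity Eigengene dissimilarity below which
#'   same-trend modules merge into a supermodule (default 0.25).
#' @param anova_alpha Significance level of the per-module ANOVA filter.
#' @return List of class `network_config`.
#' @export
network_config <- function(soft_power = 20, min_module_size = 30L,
                           cut_quantile = 0.99, cor_gate = 0.3,
                           merge_dissimilarity = 0.25, anova_alpha = 0.05) {
  stopifnot(soft_power >= 1, min_module_size >= 3)
  structure(as.list(environment()), class = "network_config")
}

#' Detect co-expression modules on a signed network
#'
#' Builds the signed adjacency `a_ij = ((1 + cor_ij) / 2)^soft_power`,
#' converts it to a signed topological-overlap dissimilarity, clusters by
#' average-linkage hierarchical clustering, and cuts the tree at a static
#' height (the `cut_quantile` of the merge heights). Candidate clusters
#' smaller than `min_module_size`, or whose mean within-cluster correlation
#' falls below `cor_gate`, are assigned to `"grey"`. Constant gene rows are
#' dropped with a warning before the correlation step.
#'
#' @param values Genes x samples numeric matrix on a normalized scale (e.g.
#'   [log_cpm()]), or an [expr_matrix()] of counts (transformed
#'   internally).
#' @param config A [network_config()].
#' @return List of class `module_set`: `labels` (named character vector,
#'   module ids `"M1"`, ... or `"grey"`), `n_modules`, `config`.
#' @export
build_modules <- function(values, config = network_config()) {
  if (inherits(values, "expr_matrix")) values <- log_cpm(values)
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene row(s)", sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
  }
  if (nrow(values) < 3 * config$min_module_size)
    stop("too few genes for module detection")
  if (ncol(values) < 8) stop("module detection needs at least 8 samples")
  cormat <- stats::cor(t(values))
  adj <- ((1 + cormat) / 2)^config$soft_power
  diss <- 1 - .tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cut_h <- stats::quantile(hc$height, config$cut_quantile)
  raw <- stats::cutree(hc, h = cut_h)
  labels <- rep("grey", nrow(values))
  names(labels) <- rownames(values)
  next_id <- 1L
  for (cl in unique(raw)) {
    g <- which(raw == cl)
    if (length(g) < config$min_module_size) next
    mean_cor <- mean(cormat[g, g][upper.tri(matrix(0, length(g), length(g)))])
    if (mean_cor < config$cor_gate) next
    labels[g] <- sprintf("M%d", next_id)
    next_id <- next_id + 1L
  }
  structure(list(labels = labels, n_modules = next_id - 1L, config = config),
            class = "module_set")
}

# Signed topological overlap: shared-neighbor weighting of the adjacency.
.tom_similarity <- function(adj) {
  diag(adj) <- 0
  k <- colSums(adj)
  shared <- adj %*% adj
  kmin <- outer(k, k, pmin)
  tom <- (shared + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set: %d modules, %d/%d genes assigned>\n",
              x$n_modules, sum(x$labels != "grey"), length(x$labels)))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix,
#' sign-oriented to correlate positively with the module's mean expression
#' profile, reported per sample together with the variance it explains.
#' A rank-deficient submatrix falls back to the mean profile with a
#' warning.
#'
#' @param values Genes x samples matrix.
#' @param module_genes Gene ids of one module (>= 3).
#' @return List: `eigengene` (named per-sample vector), `var_explained`.
#' @export
module_eigengene <- function(values, module_genes) {
  if (length(module_genes) < 3) stop("module must have at least 3 genes")
  sub <- values[module_genes, , drop = FALSE]
  std <- t(scale(t(sub)))
  if (anyNA(std)) {
    warning("rank-deficient module submatrix; using the mean profile")
    eg <- colMeans(sub)
    return(list(eigengene = scale(eg)[, 1], var_explained = NA_real_))
  }
  sv <- svd(std)
  eg <- sv$v[, 1]
  if (stats::cor(eg, colMeans(std)) < 0) eg <- -eg
  names(eg) <- colnames(values)
  list(eigengene = eg, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' ANOVA filter of module eigengenes across karyotypes
#'
#' One-way ANOVA of each module's eigengene on the karyotype factor; a
#' module passes iff p < alpha. Modules with degenerate group structure are
#' skipped.
#'
#' @param modules A [build_modules()] result.
#' @param values Genes x samples matrix used to build the modules.
#' @param meta Sample metadata with `sample_id` and `karyotype`.
#' @param alpha Significance level (default from the config).
#' @return Data frame `module`, `f_statistic`, `p_value`, `pass`, with the
#'   eigengene matrix in attribute `"eigengenes"` (modules x samples).
#' @export
anova_filter <- function(modules, values, meta, alpha = modules$config$anova_alpha) {
  meta <- meta[match(colnames(values), meta$sample_id), ]
  grp <- factor(meta$karyotype)
  if (length(levels(grp)) < 2 || any(table(grp) < 2))
    stop("ANOVA filter needs >= 2 karyotype groups with >= 2 samples each")
  mods <- setdiff(unique(modules$labels), "grey")
  egs <- matrix(NA_real_, length(mods), ncol(values),
                dimnames = list(mods, colnames(values)))
  out <- lapply(mods, function(m) {
    eg <- module_eigengene(values, names(modules$labels)[modules$labels == m])$eigengene
    egs[m, ] <<- eg
    fit <- stats::aov(eg ~ grp)
    s <- summary(fit)[[1]]
    data.frame(module = m, f_statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$pass <- res$p_value < alpha
  attr(res, "eigengenes") <- egs
  res
}

#' Select dosage-trend supermodules
#'
#' Among ANOVA-passing modules, keeps those whose eigengene shows a
#' significant linear trend on the X count with monotone per-karyotype
#' group means, and merges same-trend modules whose eigengenes correlate
#' above `1 - merge_dissimilarity` into supermodules.
#'
#' @param anova_res An [anova_filter()] result (its `"eigengenes"`
#'   attribute is used).
#' @param meta Sample metadata with `sample_id`, `n_x`.
#' @param alpha Significance level of the eigengene-on-`n_x` regression.
#' @param merge_dissimilarity Eigengene dissimilarity merge threshold
#'   (default 0.25, i.e. correlation > 0.75).
#' @return Data frame `module`, `slope`, `p_value`, `trend`
#'   (`up`/`down`/`flat`), `supermodule` (NA for flat/non-monotone
#'   modules).
#' @export
select_dosage_supermodules <- function(anova_res, meta, alpha = 0.05,
                                       merge_dissimilarity = 0.25) {
  egs <- attr(anova_res, "eigengenes")
  if (is.null(egs)) stop("anova_res lacks the eigengene attribute")
  pass <- anova_res$module[anova_res$pass]
  if (!length(pass)) stop("no ANOVA-passing modules to select from")
  meta <- meta[match(colnames(egs), meta$sample_id), ]
  nx <- meta$n_x
  res <- lapply(pass, function(m) {
    eg <- egs[m, ]
    fit <- summary(stats::lm(eg ~ nx))$coefficients
    slope <- fit[2, 1]; p <- fit[2, 4]
    means <- tapply(eg, sprintf("%03d", nx), mean)  # sorted by n_x
    monotone <- all(diff(means) > 0) || all(diff(means) < 0)
    trend <- if (p < alpha && monotone && slope > 0) "up"
             else if (p < alpha && monotone && slope < 0) "down" else "flat"
    data.frame(module = m, slope = slope, p_value = p, trend = trend,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$supermodule <- NA_character_
  for (tr in c("up", "down")) {
    mods <- res$module[res$trend == tr]
    if (!length(mods)) next
    if (length(mods) == 1) { res$supermodule[res$module == mods] <- paste0("S_", tr, "1"); next }
    cors <- stats::cor(t(egs[mods, , drop = FALSE]))
    comp <- .connected_components(cors > 1 - merge_dissimilarity)
    res$supermodule[match(mods, res$module)] <- sprintf("S_%s%d", tr, comp)
  }
  res
}

.connected_components <- function(adjacency) {
  n <- nrow(adjacency)
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adjacency[v, ] & comp == 0L))
    }
  }
  comp
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test (`P[X >= k]`) of the overlap between a
#' query gene set and each term set within a universe, with Bonferroni
#' adjustment across terms.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param term_sets Named list of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @return Data frame `term`, `k` (overlap), `n` (query size), `K` (term
#'   size), `N` (universe size), `p_value`, `p_adjusted`.
#' @export
hypergeom_enrich <- function(query, term_sets, universe) {
  if (!length(query)) stop("empty query set")
  if (!all(query %in% universe)) stop("query genes must be in the universe")
  N <- length(universe); n <- length(unique(query))
  res <- lapply(names(term_sets), function(tm) {
    term <- intersect(term_sets[[tm]], universe)
    K <- length(term); k <- length(intersect(query, term))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, res$p_value * nrow(res))
  res
}

#' Overlap of two gene sets with enrichment p-value
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe All eligible genes.
#' @return List: `overlap` (count), `pct_of_a` (percentage of `set_a`
#'   shared), `genes`, `p_value` (upper-tail hypergeometric).
#' @export
gene_set_overlap <- function(set_a, set_b, universe) {
  if (!length(set_a) || !length(set_b)) stop("empty gene set")
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  shared <- intersect(set_a, set_b)
  k <- length(shared)
  p <- stats::phyper(k - 1, length(set_b), length(universe) - length(set_b),
                     length(set_a), lower.tail = FALSE)
  list(overlap = k, pct_of_a = 100 * k / length(set_a), genes = shared,
       p_value = p)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  sets
}
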