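#' Simulation configuration
#'
#' Collects every parameter of the synthetic-cohort generator. The defaults
#' encode the dosage laws the analysis assumes: PAR genes expressed in
#' proportion to the total sex-chromosome count, non-PAR escape genes in
#' proportion to the X count, inactive X genes flat (one active X), XIST in
#' proportion to `n_x - 1`, autosomes flat apart from a configurable subset
#' with a log2-linear response to the X count (used for trend-recovery
#' checks), and an optional "eroded" sample carrying 2-3x the baseline
#' number of biallelically expressed non-PAR X genes.
#'
#' The gene model uses a scaled-down chromosome (default 156 kb X with 26 kb
#' and 3.2 kb pseudoautosomal spans, 1:1000 of the human proportions) so a
#' matching genome sequence can be generated in memory.
#'
#' @param seed Integer master seed; every generator derives its own
#'   substream from it.
#' @param n_genes_autosome,n_genes_x_nonpar,n_genes_par1,n_genes_par2 Gene
#'   counts per region class.
#' @param fraction_escape_nonpar Proportion of non-PAR X genes that escape
#'   inactivation.
#' @param karyotype_panel List of `list(karyotype =, n =)` entries giving
#'   the cohort composition.
#' @param base_meanlog,base_sdlog Log-normal law for per-gene baseline
#'   expression (FPKM scale).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   replicate noise.
#' @param x_base_scale Baseline expression of X-linked genes relative to
#'   autosomal genes (default 0.6). X-linked genes are expressed below the
#'   autosomal average, which keeps the simulated X:autosome ratio inside
#'   the 0.5-1 band observed across karyotypes.
#' @param n_autosome_up,n_autosome_down Autosomal genes given a positive /
#'   negative log2-linear response to `n_x`.
#' @param trend_log2_slope Magnitude of that response (log2 units per X).
#' @param snp_per_gene_mean Poisson mean of heterozygous SNPs per gene.
#' @param depth_mean,depth_dispersion Negative-binomial law (mean, size) for
#'   per-SNP total read counts.
#' @param monoallelic_leak Probability that a read from a monoallelically
#'   expressed gene reports the silenced allele (leakage + sequencing
#'   error).
#' @param biallelic_beta Two shape parameters of the Beta law for the
#'   reference-allele proportion of truly biallelic sites (centred on 0.5).
#' @param eroded_samples Character vector of sample ids to simulate as
#'   X-eroded.
#' @param erosion_multiplier Factor by which eroded samples multiply the
#'   baseline count of biallelic non-PAR X genes.
#' @param sc_base_scale Scaling from bulk FPKM baseline to single-cell mean
#'   counts.
#' @param sc_dispersion Negative-binomial size for single-cell counts.
#' @param n_phase_dependent Autosomal genes given a cell-cycle-phase effect
#'   in the single-cell generator (for power checks).
#' @param boundaries [par_boundaries()] of the scaled-down gene model.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_autosome = 300L, n_genes_x_nonpar = 100L,
                       n_genes_par1 = 15L, n_genes_par2 = 5L,
                       fraction_escape_nonpar = 0.2,
                       karyotype_panel = default_karyotype_panel(),
                       base_meanlog = 3, base_sdlog = 1,
                       noise_cv = 0.1, x_base_scale = 0.6,
                       n_autosome_up = 20L, n_autosome_down = 20L,
                       trend_log2_slope = 0.5,
                       snp_per_gene_mean = 3,
                       depth_mean = 30, depth_dispersion = 5,
                       monoallelic_leak = 0.01,
                       biallelic_beta = c(20, 20),
                       eroded_samples = character(0),
                       erosion_multiplier = 2.5,
                       sc_base_scale = 0.5, sc_dispersion = 2,
                       n_phase_dependent = 0L,
                       boundaries = par_boundaries(par1_span_bp = 26000,
                                                   par2_span_bp = 3200,
                                                   x_length_bp = 156000)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes_autosome > 0, cfg$n_genes_x_nonpar > 0,
            cfg$n_genes_par1 > 0, cfg$n_genes_par2 > 0)
  if (fraction_escape_nonpar < 0 || fraction_escape_nonpar > 1)
    stop("fraction_escape_nonpar must lie in [0, 1]")
  if (monoallelic_leak < 0 || monoallelic_leak > 1)
    stop("monoallelic_leak must lie in [0, 1]")
  for (entry in karyotype_panel) {
    if (!inherits(entry$karyotype, "karyotype_spec"))
      stop("karyotype_panel entries need a karyotype_spec")
    if (entry$karyotype$n_x < 1) stop("karyotypes with n_x = 0 are not supported")
  }
  structure(cfg, class = "sim_config")
}

#' Default karyotype panel: 46,XY / 47,XXY / 48,XXXY / 49,XXXXY, 4 each
#' @return List of panel entries for [sim_config()].
#' @export
default_karyotype_panel <- function() {
  list(list(karyotype = karyotype_spec(1, 1), n = 4L),
       list(karyotype = karyotype_spec(2, 1), n = 4L),
       list(karyotype = karyotype_spec(3, 1), n = 4L),
       list(karyotype = karyotype_spec(4, 1), n = 4L))
}

# One substream per generator, derived from the master seed and kept within
# 32-bit integer range.
.sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a gene annotation
#'
#' Places genes on the scaled-down genome model: autosomal genes across
#' chr1-chr22, PAR1/PAR2 genes inside the pseudoautosomal spans, non-PAR X
#' genes across the chromosome body (including XIST), each with a literature
#' XCI status (`escape` per `fraction_escape_nonpar`; the remainder mostly
#' `inactive` with small `variable` and `unknown` fractions).
#'
#' @param config A [sim_config()].
#' @return A [gene_annotation()] table; XIST is always present with
#'   `gene_id == "XIST"`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$boundaries
  .with_seed(.sub_seed(config$seed, 1L), {
    gene_len <- 200
    n_auto <- config$n_genes_autosome
    auto_chr <- as.character(sort(sample(1:22, n_auto, replace = TRUE)))
    auto_start <- round(stats::runif(n_auto, 0, 20000))
    # non-PAR X body, sorted so a positional moving average is meaningful
    n_xb <- config$n_genes_x_nonpar
    body_lo <- b$par1_span_bp + 1000
    body_hi <- b$x_length_bp - b$par2_span_bp - 1000 - gene_len
    x_start <- sort(round(stats::runif(n_xb, body_lo, body_hi)))
    p1_start <- sort(round(stats::runif(config$n_genes_par1, 0, b$par1_span_bp - gene_len - 1)))
    p2_lo <- b$x_length_bp - b$par2_span_bp
    p2_start <- sort(round(stats::runif(config$n_genes_par2, p2_lo, b$x_length_bp - gene_len - 1)))

    n_escape <- round(config$fraction_escape_nonpar * (n_xb - 1L))
    status <- rep("inactive", n_xb - 1L)
    pick <- sample(n_xb - 1L)
    status[pick[seq_len(n_escape)]] <- "escape"
    rest <- pick[-seq_len(n_escape)]
    n_var <- min(length(rest), max(1L, round(0.05 * n_xb)))
    status[rest[seq_len(n_var)]] <- "variable"
    rest <- rest[-seq_len(n_var)]
    n_unk <- min(length(rest), max(1L, round(0.05 * n_xb)))
    if (n_unk > 0) status[rest[seq_len(n_unk)]] <- "unknown"

    ids <- c(sprintf("AUTO%04d", seq_len(n_auto)),
             c(sprintf("XNP%04d", seq_len(n_xb - 1L)), "XIST"),
             sprintf("PAR1G%03d", seq_len(config$n_genes_par1)),
             sprintf("PAR2G%03d", seq_len(config$n_genes_par2)))
    chrom <- c(auto_chr, rep("X", n_xb + config$n_genes_par1 + config$n_genes_par2))
    start <- c(auto_start, x_start, p1_start, p2_start)
    xci <- c(rep("unknown", n_auto), status, "inactive",
             rep("escape", config$n_genes_par1 + config$n_genes_par2))
    strand <- sample(c("+", "-"), length(ids), replace = TRUE)
    gene_annotation(ids, chrom, start, start + gene_len, strand = strand,
                    xci_status = xci, boundaries = b)
  })
}

# Expected-expression multiplier for one gene in one karyotype; the heart of
# every dosage law the generator encodes.
.dosage_factor <- function(ann, kar, n_auto_up, n_auto_down, slope) {
  n_x <- kar$n_x; n_y <- kar$n_y
  f <- rep(1, nrow(ann))
  par <- ann$region_class %in% c("PAR1", "PAR2")
  f[par] <- (n_x + n_y) / 2
  nonpar <- ann$region_class == "X_NONPAR"
  f[nonpar & ann$xci_status == "escape"] <- n_x
  f[ann$gene_id == "XIST"] <- n_x - 1
  f[ann$region_class == "Y_LINKED"] <- n_y
  auto <- which(ann$region_class == "AUTOSOME")
  if (n_auto_up > 0) f[auto[seq_len(n_auto_up)]] <- 2^(slope * (n_x - 2))
  if (n_auto_down > 0)
    f[auto[n_auto_up + seq_len(n_auto_down)]] <- 2^(-slope * (n_x - 2))
  f
}

.panel_meta <- function(panel) {
  rows <- list()
  for (entry in panel) {
    kar <- entry$karyotype
    short <- gsub("^[0-9]+,", "", kar$label)
    role <- if (kar$n_x == 1 && kar$n_y == 1) "control_male"
            else if (kar$n_x == 2 && kar$n_y == 0) "control_female" else "case"
    for (r in seq_len(entry$n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", short, r), karyotype = kar$label,
        n_x = kar$n_x, n_y = kar$n_y, cohort_role = role,
        clone_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a bulk expression cohort
#'
#' Draws per-gene baseline FPKM from a log-normal law, applies the
#' karyotype-specific dosage multiplier of each gene's class, and adds
#' multiplicative log-normal replicate noise with coefficient of variation
#' `noise_cv` (mean-preserving). With `noise_cv = 0` the values equal the
#' dosage laws exactly.
#'
#' @param config A [sim_config()].
#' @param annotation Optional [gene_annotation()]; defaults to
#'   [simulate_annotation()] under the same config.
#' @return List with elements `expr` (an FPKM [expr_matrix()]), `meta`
#'   (sample metadata), `truth` (per-gene law, covariate and true log2
#'   slope where defined) and `annotation`.
#' @export
simulate_bulk_cohort <- function(config, annotation = simulate_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  meta <- .panel_meta(config$karyotype_panel)
  .with_seed(.sub_seed(config$seed, 2L), {
    base <- stats::rlnorm(nrow(annotation), config$base_meanlog, config$base_sdlog)
    base[annotation$chrom == "X"] <- base[annotation$chrom == "X"] * config$x_base_scale
    m <- matrix(0, nrow(annotation), nrow(meta),
                dimnames = list(annotation$gene_id, meta$sample_id))
    sigma <- sqrt(log(1 + config$noise_cv^2))
    for (j in seq_len(nrow(meta))) {
      kar <- karyotype_spec(meta$n_x[j], meta$n_y[j])
      mu <- base * .dosage_factor(annotation, kar, config$n_autosome_up,
                                  config$n_autosome_down, config$trend_log2_slope)
      noise <- if (sigma > 0)
        exp(stats::rnorm(length(mu), -sigma^2 / 2, sigma)) else 1
      m[, j] <- mu * noise
    }
    truth <- .law_table(annotation, config)
    truth$base <- base
    list(expr = expr_matrix(m, unit = "FPKM"), meta = meta,
         truth = truth, annotation = annotation)
  })
}

.law_table <- function(ann, config) {
  law <- rep("autosome_flat", nrow(ann))
  law[ann$region_class %in% c("PAR1", "PAR2")] <- "par"
  nonpar <- ann$region_class == "X_NONPAR"
  law[nonpar & ann$xci_status == "escape"] <- "escape"
  law[nonpar & ann$xci_status != "escape"] <- "x_inactive"
  law[ann$gene_id == "XIST"] <- "xist"
  auto <- which(ann$region_class == "AUTOSOME")
  if (config$n_autosome_up > 0)
    law[auto[seq_len(config$n_autosome_up)]] <- "autosome_up"
  if (config$n_autosome_down > 0)
    law[auto[config$n_autosome_up + seq_len(config$n_autosome_down)]] <- "autosome_down"
  slope <- ifelse(law == "autosome_up", config$trend_log2_slope,
           ifelse(law == "autosome_down", -config$trend_log2_slope,
           ifelse(law == "autosome_flat", 0, NA_real_)))
  data.frame(gene_id = ann$gene_id, law = law, region_class = ann$region_class,
             true_log2_slope = slope, stringsAsFactors = FALSE)
}

#' Simulate per-SNP allele counts with gene-level truth
#'
#' For every sample and gene, draws a Poisson number of heterozygous SNPs,
#' a negative-binomial total depth per SNP, and binomial reference counts
#' with success probability centred on 0.5 (Beta law) for truly biallelic
#' genes or equal to the leakage rate for monoallelic genes. Non-PAR X genes
#' are hemizygous (no heterozygous sites) when `n_x = 1`; eroded samples
#' flip enough inactive genes to biallelic to reach
#' `erosion_multiplier` times the baseline escape-gene count. A matching
#' whitelist variant table (PASS, depth > 10) is returned alongside, with a
#' few failing decoy records for filter exercising.
#'
#' @param config A [sim_config()].
#' @param annotation A [gene_annotation()].
#' @param meta Sample metadata (from [simulate_bulk_cohort()]).
#' @return List with `counts` (an `allele_counts` table over all samples),
#'   `truth` (sample x gene true status: `biallelic`, `monoallelic` or
#'   `none`), and `variants` (whitelist data.frame: chrom, pos, ref, alt,
#'   filter, dp).
#' @export
simulate_allele_counts <- function(config, annotation, meta) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.sub_seed(config$seed, 3L), {
    ann <- annotation
    n_escape <- sum(ann$region_class == "X_NONPAR" & ann$xci_status == "escape")
    inactive_ids <- ann$gene_id[ann$region_class == "X_NONPAR" &
                                ann$xci_status != "escape" & ann$gene_id != "XIST"]
    rows <- list(); truth_rows <- list()
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(nrow(meta))) {
      sid <- meta$sample_id[j]
      n_x <- meta$n_x[j]; n_y <- meta$n_y[j]
      flipped <- character(0)
      if (sid %in% config$eroded_samples && length(inactive_ids)) {
        n_flip <- min(length(inactive_ids),
                      round((config$erosion_multiplier - 1) * n_escape))
        flipped <- sample(inactive_ids, n_flip)
      }
      rc <- ann$region_class
      status <- rep("biallelic", nrow(ann))
      status[rc %in% c("PAR1", "PAR2") & (n_x + n_y) < 2] <- "none"
      status[rc == "Y_LINKED"] <- "none"
      nonpar <- rc == "X_NONPAR"
      status[nonpar] <- if (n_x < 2) "none" else "monoallelic"
      if (n_x >= 2) {
        status[nonpar & (ann$xci_status == "escape" |
                         ann$gene_id %in% flipped)] <- "biallelic"
        status[ann$gene_id == "XIST"] <- "monoallelic"
      }
      truth_rows[[j]] <- data.frame(sample_id = sid, gene_id = ann$gene_id,
                                    region_class = rc, true_status = status,
                                    stringsAsFactors = FALSE)
      het <- which(status != "none")
      n_snp <- stats::rpois(length(het), config$snp_per_gene_mean)
      keep <- n_snp > 0
      het <- het[keep]; n_snp <- n_snp[keep]
      if (!length(het)) next
      gi <- rep(het, n_snp)            # annotation row per SNP
      tot <- length(gi)
      off <- 1L + floor(stats::runif(tot) * (ann$end[gi] - ann$start[gi]))
      depth <- pmax(1L, stats::rnbinom(tot, mu = config$depth_mean,
                                       size = config$depth_dispersion))
      bi <- rep(status[het] == "biallelic", n_snp)
      p <- numeric(tot)
      p[bi] <- stats::rbeta(sum(bi), config$biallelic_beta[1],
                            config$biallelic_beta[2])
      p[!bi] <- ifelse(stats::runif(sum(!bi)) < 0.5, config$monoallelic_leak,
                       1 - config$monoallelic_leak)
      ref_n <- stats::rbinom(tot, depth, p)
      ref_b <- sample(bases, tot, replace = TRUE)
      alt_b <- bases[(match(ref_b, bases) + sample(1:3, tot, replace = TRUE) - 1L) %% 4L + 1L]
      rows[[j]] <- data.frame(
        sample_id = sid, chrom = ann$chrom[gi],
        pos = as.integer(ann$start[gi] + off),  # 0-based start + offset -> 1-based
        ref = ref_b, alt = alt_b,
        ref_count = ref_n, alt_count = depth - ref_n, total_count = depth,
        gene_id = ann$gene_id[gi], intronic = FALSE, multi_gene = FALSE,
        is_xist = ann$gene_id[gi] == "XIST", stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    # decoys: a few intronic copies so site filters have work to do
    n_dec <- min(20L, nrow(counts))
    dec <- counts[sample.int(nrow(counts), n_dec), ]
    dec$pos <- dec$pos + 7L
    dec$intronic <- TRUE
    counts <- rbind(counts, dec)
    keypos <- !duplicated(counts[c("chrom", "pos")])
    variants <- data.frame(chrom = counts$chrom[keypos], pos = counts$pos[keypos],
                           ref = counts$ref[keypos], alt = counts$alt[keypos],
                           filter = "PASS",
                           dp = pmax(11L, counts$total_count[keypos]),
                           stringsAsFactors = FALSE)
    # failing decoy variants at unused positions
    bad <- variants[seq_len(min(10L, nrow(variants))), ]
    bad$pos <- bad$pos + 1000000L
    bad$filter <- rep_len(c("germline", "PASS"), nrow(bad))
    bad$dp <- rep_len(c(50L, 8L), nrow(bad))
    list(counts = allele_counts(counts),
         truth = do.call(rbind, truth_rows),
         variants = rbind(variants, bad))
  })
}

#' Write a minimal VCF for a whitelist variant table
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter`, `dp` (as produced by [simulate_allele_counts()]).
#' @param path Output VCF path (plain text).
#' @export
write_simple_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FILTER=<ID=germline,Description=\"Germline risk\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$filter, variants$dp)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a single-cell count matrix
#'
#' Per-cell counts are independent negative-binomial draws around the same
#' karyotype dosage laws as the bulk generator, so that within a karyotype
#' the expression of escape genes is conditionally independent of the cell's
#' realized XIST count by construction. Cell-cycle phases are assigned
#' independently of everything else; optionally the first
#' `n_phase_dependent` autosomal genes receive a phase effect (means scaled
#' 1 / 1.5 / 2 in G1 / S / G2M) for power checks.
#'
#' @param config A [sim_config()].
#' @param annotation A [gene_annotation()].
#' @param meta Sample metadata.
#' @param n_cells_per_sample Cells per sample (>= 50 recommended for test
#'   stability).
#' @return List with `counts` (genes x cells integer matrix), `cells`
#'   (cell metadata: cell_id, sample_id, karyotype, n_x, n_y, phase) and
#'   `truth` (the per-gene law table).
#' @export
simulate_single_cell <- function(config, annotation, meta, n_cells_per_sample = 100L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.sub_seed(config$seed, 4L), {
    ann <- annotation
    cells <- do.call(rbind, lapply(seq_len(nrow(meta)), function(j) {
      data.frame(cell_id = sprintf("%s_c%03d", meta$sample_id[j],
                                   seq_len(n_cells_per_sample)),
                 sample_id = meta$sample_id[j], karyotype = meta$karyotype[j],
                 n_x = meta$n_x[j], n_y = meta$n_y[j], stringsAsFactors = FALSE)
    }))
    cells$phase <- sample(c("G1", "S", "G2M"), nrow(cells), replace = TRUE,
                          prob = c(0.5, 0.3, 0.2))
    base <- stats::rlnorm(nrow(ann), config$base_meanlog, config$base_sdlog) *
      config$sc_base_scale
    base[ann$chrom == "X"] <- base[ann$chrom == "X"] * config$x_base_scale
    m <- matrix(0L, nrow(ann), nrow(cells),
                dimnames = list(ann$gene_id, cells$cell_id))
    phase_mult <- c(G1 = 1, S = 1.5, G2M = 2)
    auto <- which(ann$region_class == "AUTOSOME")
    phase_genes <- auto[seq_len(min(config$n_phase_dependent, length(auto)))]
    for (j in seq_len(nrow(meta))) {
      kar <- karyotype_spec(meta$n_x[j], meta$n_y[j])
      mu <- base * .dosage_factor(ann, kar, config$n_autosome_up,
                                  config$n_autosome_down, config$trend_log2_slope)
      idx <- which(cells$sample_id == meta$sample_id[j])
      for (ci in idx) {
        mu_c <- mu
        if (length(phase_genes))
          mu_c[phase_genes] <- mu[phase_genes] * phase_mult[[cells$phase[ci]]]
        m[, ci] <- stats::rnbinom(length(mu_c), mu = mu_c, size = config$sc_dispersion)
      }
    }
    list(counts = m, cells = cells, truth = .law_table(ann, config))
  })
}

#' Simulate block-correlated module structure
#'
#' Builds a genes x samples matrix of `n_modules` correlated blocks. Each
#' module has a latent per-sample score; `up`/`down` modules tie the score
#' linearly to the sample's X count, `flat` modules draw it independently.
#' Per-gene noise is calibrated so that the within-module correlation is
#' about 0.8 by construction. Two modules assigned the same trend share the
#' dosage response and are therefore intrinsically correlated; the default
#' assignment gives at most one module per trend direction so that the
#' planted blocks are mutually identifiable.
#'
#' @param n_modules Number of modules.
#' @param genes_per_module Genes in each module.
#' @param n_samples Number of samples; karyotypes cycle through the panel.
#' @param trend_assignment Character vector of length `n_modules`, each
#'   `"up"`, `"down"` or `"flat"`.
#' @param seed Integer seed.
#' @param panel Karyotype panel (as in [sim_config()]); samples are assigned
#'   karyotypes round-robin.
#' @param trend_effect Latent-score shift per X chromosome for trending
#'   modules.
#' @return List with `values` (matrix on a normalized log-like scale),
#'   `meta` (sample metadata with `n_x`) and `truth_modules` (gene ->
#'   module id and module -> trend map).
#' @export
simulate_module_structure <- function(n_modules = 5L, genes_per_module = 100L,
                                      n_samples = 20L,
                                      trend_assignment = c("up", "down",
                                                           rep("flat", max(0, n_modules - 2)))[seq_len(n_modules)],
                                      seed = 1L,
                                      panel = default_karyotype_panel(),
                                      trend_effect = 0.8) {
  stopifnot(length(trend_assignment) == n_modules,
            all(trend_assignment %in% c("up", "down", "flat")))
  .with_seed(.sub_seed(seed, 5L), {
    kars <- do.call(rbind, lapply(panel, function(e)
      data.frame(n_x = e$karyotype$n_x, n_y = e$karyotype$n_y,
                 karyotype = e$karyotype$label)))
    idx <- rep_len(seq_len(nrow(kars)), n_samples)
    meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                       karyotype = kars$karyotype[idx],
                       n_x = kars$n_x[idx], n_y = kars$n_y[idx],
                       stringsAsFactors = FALSE)
    n_genes <- n_modules * genes_per_module
    m <- matrix(0, n_genes, n_samples,
                dimnames = list(sprintf("G%04d", seq_len(n_genes)), meta$sample_id))
    labels <- rep(seq_len(n_modules), each = genes_per_module)
    centered_nx <- meta$n_x - mean(meta$n_x)
    for (mod in seq_len(n_modules)) {
      dir <- switch(trend_assignment[mod], up = 1, down = -1, flat = 0)
      score <- if (dir == 0) stats::rnorm(n_samples, 0, 1)
               else dir * trend_effect * centered_nx + stats::rnorm(n_samples, 0, 0.6)
      g <- which(labels == mod)
      m[g, ] <- matrix(rep(score, each = length(g)), length(g)) +
        matrix(stats::rnorm(length(g) * n_samples, 0, 0.5), length(g))
    }
    list(values = m, meta = meta,
         truth_modules = data.frame(gene_id = rownames(m), module = labels,
                                    trend = trend_assignment[labels],
                                    stringsAsFactors = FALSE))
  })
}

#' Generate a random genome matching an annotation
#'
#' Returns one random DNA sequence per chromosome present in the
#' annotation, long enough to cover every gene plus promoter flanks. Used to
#' exercise promoter extraction and motif scanning on the scaled-down gene
#' model; optionally plants a motif consensus at fixed offsets upstream of
#' selected genes' TSS.
#'
#' @param annotation A [gene_annotation()].
#' @param seed Integer seed.
#' @param plant_motif Optional DNA string to insert 200 bp upstream of the
#'   TSS of `plant_genes` (on the gene's strand).
#' @param plant_genes Gene ids receiving the planted motif.
#' @param flank Extra sequence beyond the outermost gene ends.
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(annotation, seed = 1L, plant_motif = NULL,
                            plant_genes = character(0), flank = 5000L) {
  .with_seed(.sub_seed(seed, 6L), {
    chroms <- unique(annotation$chrom)
    seqs <- lapply(chroms, function(ch) {
      len <- max(annotation$end[annotation$chrom == ch]) + flank
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- chroms
    if (!is.null(plant_motif)) {
      for (g in plant_genes) {
        i <- match(g, annotation$gene_id)
        if (is.na(i)) next
        ch <- annotation$chrom[i]
        if (annotation$strand[i] == "+") {
          at <- annotation$start[i] - 200  # 0-based insertion point
          seqpart <- plant_motif
        } else {
          at <- annotation$end[i] + 200 - nchar(plant_motif)
          seqpart <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(plant_motif)))
        }
        if (at < 0) next
        s <- as.character(genome[[ch]])
        substr(s, at + 1, at + nchar(seqpart)) <- seqpart
        genome[[ch]] <- Biostrings::DNAString(s)
      }
    }
    genome
  })
}
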