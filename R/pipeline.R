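.pipeline_schema <- list(
  seed = "integer", outdir = "character",
  simulate = list(noise_cv = "number", eroded_samples = "character",
                  erosion_multiplier = "number", n_cells_per_sample = "integer",
                  fraction_escape_nonpar = "number"),
  ase = list(min_depth = "integer", lower = "number", upper = "number"),
  dosage = list(span = "span", fdr_cut = "prob", lfc_cut = "number",
                alpha = "prob"),
  modules = list(soft_power = "number", min_module_size = "integer",
                 merge_dissimilarity = "prob", anova_alpha = "prob"),
  motifs = list(deficit = "prob", upstream = "integer", downstream = "integer"))

#' Validate a pipeline configuration
#'
#' Checks a YAML configuration (or an equivalent list) against the pipeline
#' schema, reporting every problem at once: unknown keys are rejected by
#' name, and values are range-checked (e.g. the loess span must lie in
#' (0, 1]).
#'
#' @param config Path to a YAML file, or a list.
#' @return Invisibly, the validated config list; raises a single error
#'   listing all violations otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(0)
  check_value <- function(key, val, type) {
    switch(type,
      integer = if (!is.numeric(val) || val != round(val))
        errors <<- c(errors, sprintf("%s must be an integer", key)),
      number = if (!is.numeric(val))
        errors <<- c(errors, sprintf("%s must be numeric", key)),
      character = if (!is.character(val))
        errors <<- c(errors, sprintf("%s must be character", key)),
      prob = if (!is.numeric(val) || val < 0 || val > 1)
        errors <<- c(errors, sprintf("%s must lie in [0, 1]", key)),
      span = if (!is.numeric(val) || val <= 0 || val > 1)
        errors <<- c(errors, sprintf("%s must be in (0,1]", key)))
  }
  for (key in names(config)) {
    sch <- .pipeline_schema[[key]]
    if (is.null(sch)) { errors <- c(errors, sprintf("unknown key '%s'", key)); next }
    if (is.list(sch)) {
      blk <- config[[key]]
      for (sub in names(blk)) {
        if (is.null(sch[[sub]]))
          errors <- c(errors, sprintf("unknown key '%s.%s'", key, sub))
        else check_value(paste(key, sub, sep = "."), blk[[sub]], sch[[sub]])
      }
    } else check_value(key, config[[key]], sch)
  }
  if (length(errors))
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

.stage_log <- function(stage, t0, note = "") {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")), note))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic cohort, writes its raw inputs in the standard
#' formats (GTF, TSV, VCF, MTX, YAML), reads them back, and runs every
#' analysis stage: allele-specific expression calling with erosion
#' flagging, bulk dosage statistics (X:A ratio, male-median fold change,
#' loess moving average, dosage trends, DEGs), module detection with
#' supermodule selection, single-cell XIST tests, and promoter motif
#' enrichment with a planted-motif query. All stage outputs plus a
#' deterministic run manifest (parameters, input checksums) are written
#' under `outdir`; given a fixed seed the outputs are byte-identical across
#' runs.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#'   Recognized keys: `seed`, `outdir`, and per-stage blocks `simulate`,
#'   `ase`, `dosage`, `modules`, `motifs`.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_config(config)
  seed <- if (!is.null(config$seed)) config$seed else 1L
  outdir <- if (!is.null(config$outdir)) config$outdir else tempfile("xdosage_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }
  t0 <- Sys.time()
  res <- list()

  # -- simulate -------------------------------------------------------------
  eroded <- g("simulate", "eroded_samples", "XXY_r4")
  cfg <- sim_config(seed = seed,
                    noise_cv = g("simulate", "noise_cv", 0.1),
                    fraction_escape_nonpar = g("simulate", "fraction_escape_nonpar", 0.2),
                    eroded_samples = eroded,
                    erosion_multiplier = g("simulate", "erosion_multiplier", 2.5))
  bulk <- simulate_bulk_cohort(cfg)
  ase_sim <- simulate_allele_counts(cfg, bulk$annotation, bulk$meta)
  sc_sim <- simulate_single_cell(cfg, bulk$annotation, bulk$meta,
                                 n_cells_per_sample = g("simulate", "n_cells_per_sample", 60L))
  paths <- list(annotation = file.path(outdir, "annotation.gtf"),
                meta = file.path(outdir, "samples.yaml"),
                fpkm = file.path(outdir, "bulk_fpkm.tsv"),
                counts = file.path(outdir, "allele_counts.tsv"),
                vcf = file.path(outdir, "variants.vcf"),
                sc = file.path(outdir, "sc_counts.mtx"))
  write_gene_annotation(bulk$annotation, paths$annotation)
  write_sample_meta(bulk$meta, paths$meta)
  write_expression_matrix(bulk$expr, paths$fpkm)
  write_allele_counts(ase_sim$counts, paths$counts)
  write_simple_vcf(ase_sim$variants, paths$vcf)
  write_expression_matrix(expr_matrix(sc_sim$counts, "counts"), paths$sc)
  .stage_log("simulate", t0, sprintf("%d genes, %d samples", nrow(bulk$annotation),
                                     nrow(bulk$meta)))

  # -- read back through the standard-format readers ------------------------
  ann <- read_gene_annotation(paths$annotation, boundaries = cfg$boundaries)
  meta <- read_sample_meta(paths$meta)
  fpkm <- read_expression_matrix(paths$fpkm, unit = "FPKM")
  counts <- read_allele_counts(paths$counts)

  # -- ase ------------------------------------------------------------------
  wl <- filter_variant_whitelist(paths$vcf)
  sites <- filter_sites(counts, wl, min_depth = g("ase", "min_depth", 7L))
  snp_calls <- classify_snp(sites$kept, lower = g("ase", "lower", 0.1),
                            upper = g("ase", "upper", 0.9))
  gene_calls <- call_genes(snp_calls)
  ase_sum <- summarize_ase(gene_calls, ann)
  erosion <- flag_erosion(ase_sum)
  xist_status <- xist_allelic_check(snp_calls)
  utils::write.table(snp_calls, file.path(outdir, "snp_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gene_calls, file.path(outdir, "gene_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ase_sum$by_sample, file.path(outdir, "ase_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(erosion = erosion, xist = xist_status),
                       file.path(outdir, "erosion_report.json"), digits = NA)
  res$ase <- list(summary = ase_sum, erosion = erosion, xist = xist_status)
  .stage_log("ase", t0, sprintf("%d kept / %d filtered SNPs", nrow(sites$kept),
                                nrow(sites$filtered)))

  # -- dosage ---------------------------------------------------------------
  expressed <- filter_expressed(fpkm)
  xa <- x_a_ratio(expressed, ann)
  ref <- meta$sample_id[meta$n_x == 1 & meta$n_y == 1]
  track <- male_median_fc(expressed, ref)
  curve <- moving_average_x(track, ann, span = g("dosage", "span", 0.45))
  trends <- classify_dosage_trend(fpkm, meta, ann,
                                  alpha = g("dosage", "alpha", 0.05))
  case49 <- meta$sample_id[meta$n_x == 4]
  degs <- call_degs(deg_stats(fpkm, case49, ref),
                    fdr_cut = g("dosage", "fdr_cut", 0.05),
                    lfc_cut = g("dosage", "lfc_cut", 0.25))
  xcat <- categorize_x_degs(degs$gene_id[degs$direction != "ns"], ann)
  utils::write.table(xa, file.path(outdir, "xa_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(position = curve$position, curve$smoothed),
                     file.path(outdir, "moving_average.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trends, file.path(outdir, "dosage_trends.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(degs, file.path(outdir, "degs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(xcat, file.path(outdir, "x_deg_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$dosage <- list(xa = xa, curve = curve, trends = trends, degs = degs)
  .stage_log("dosage", t0, sprintf("mean X:A %.2f", mean(xa$ratio)))

  # -- modules --------------------------------------------------------------
  modsim <- simulate_module_structure(seed = seed)
  ncfg <- network_config(soft_power = g("modules", "soft_power", 20),
                         min_module_size = g("modules", "min_module_size", 30L),
                         merge_dissimilarity = g("modules", "merge_dissimilarity", 0.25),
                         anova_alpha = g("modules", "anova_alpha", 0.05))
  mods <- build_modules(modsim$values, ncfg)
  anv <- anova_filter(mods, modsim$values, modsim$meta)
  super <- select_dosage_supermodules(anv, modsim$meta,
                                      merge_dissimilarity = ncfg$merge_dissimilarity)
  utils::write.table(data.frame(gene_id = names(mods$labels), module = mods$labels),
                     file.path(outdir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(super, file.path(outdir, "supermodules.json"), digits = NA)
  res$modules <- list(modules = mods, anova = anv, supermodules = super)
  .stage_log("modules", t0, sprintf("%d modules, %d supermodule-assigned",
                                    mods$n_modules, sum(!is.na(super$supermodule))))

  # -- single cell ----------------------------------------------------------
  norm <- normalize_cells(sc_sim$counts)
  xist_kw <- xist_by_karyotype(norm$values, sc_sim$cells)
  esc <- bulk$annotation$gene_id[bulk$annotation$region_class == "X_NONPAR" &
                                 bulk$annotation$xci_status == "escape"]
  xcor <- correlate_with_xist(norm$values, sc_sim$cells, esc)
  phase <- phase_independence(norm$values, sc_sim$cells, esc)
  utils::write.table(xcor, file.path(outdir, "xist_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(phase, file.path(outdir, "phase_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(xist_kw, file.path(outdir, "xist_kruskal.json"), digits = NA)
  res$single_cell <- list(kw = xist_kw, correlations = xcor, phase = phase)
  .stage_log("single_cell", t0,
             sprintf("KW p = %.3g over %d cells", xist_kw$p_value, ncol(norm$values)))

  # -- motifs ---------------------------------------------------------------
  motif_seq <- "TGACGTCATCGA"
  query <- c(bulk$annotation$gene_id[bulk$annotation$region_class == "PAR1"], esc)
  flat_auto <- bulk$truth$gene_id[bulk$truth$law == "autosome_flat"]
  background <- utils::head(flat_auto, 60)
  genome <- simulate_genome(bulk$annotation, seed = seed,
                            plant_motif = motif_seq, plant_genes = query)
  promoters <- extract_promoters(bulk$annotation, genome,
                                 upstream = g("motifs", "upstream", 1500L),
                                 downstream = g("motifs", "downstream", 500L))
  counts_mat <- diag(4)[match(strsplit(motif_seq, "")[[1]], c("A", "C", "G", "T")), ]
  pwms <- list(PLANTED = pwm(t(counts_mat) * 20, name = "PLANTED"))
  bound <- scan_promoters(promoters, pwms,
                          deficit = g("motifs", "deficit", 0.15))
  enr <- coverage_fisher(bound, intersect(query, rownames(bound)),
                         intersect(background, rownames(bound)))
  utils::write.table(enr, file.path(outdir, "motif_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$motifs <- enr
  .stage_log("motifs", t0, sprintf("planted motif p = %.3g", enr$p_value[1]))

  # -- manifest -------------------------------------------------------------
  manifest <- list(package = "xdosage",
                   version = as.character(utils::packageVersion("xdosage")),
                   seed = seed,
                   parameters = config[setdiff(names(config), "outdir")],
                   input_checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$input_checksums) <- basename(names(manifest$input_checksums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$outdir <- outdir
  invisible(res)
}
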