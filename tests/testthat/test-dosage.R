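small_ann <- function() {
  b <- par_boundaries(par1_span_bp = 26000, par2_span_bp = 3200,
                      x_length_bp = 156000)
  gene_annotation(c("x1", "x2", "a1", "a2", "b1"),
                  c("X", "X", "1", "1", "2"),
                  start = c(5e4, 6e4, 100, 300, 100),
                  end = c(5.1e4, 6.1e4, 200, 400, 200),
                  boundaries = b)
}

test_that("expressed-gene filter cuts below 0.5 FPKM with an inclusive boundary", {
  m <- matrix(c(0.4, 0.4, 0.5, 0.5, 2, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("lo", "edge", "hi"), c("s1", "s2")))
  x <- expr_matrix(m, "FPKM")
  f <- filter_expressed(x)
  expect_equal(rownames(f$values), c("edge", "hi"))
  all_hi <- expr_matrix(m[3, , drop = FALSE], "FPKM")
  expect_equal(filter_expressed(all_hi)$values, all_hi$values)
  expect_error(filter_expressed(expr_matrix(m, "counts")), "FPKM")
})

test_that("X:A ratio follows the per-chromosome mean-FPKM definition", {
  ann <- small_ann()
  ones <- expr_matrix(matrix(1, 5, 2, dimnames = list(ann$gene_id, c("s1", "s2"))),
                      "FPKM")
  expect_equal(x_a_ratio(ones, ann)$ratio, c(1, 1))
  m <- matrix(1, 5, 1, dimnames = list(ann$gene_id, "s1"))
  m[c("x1", "x2"), ] <- 2
  expect_equal(x_a_ratio(expr_matrix(m, "FPKM"), ann)$ratio, 2)
  # unweighted average over per-autosome MFs, not pooled autosomal genes
  m2 <- m; m2["a1", ] <- 3; m2["a2", ] <- 1; m2["b1", ] <- 1
  # chr1 MF = 2, chr2 MF = 1 -> autosome term 1.5
  expect_equal(x_a_ratio(expr_matrix(m2, "FPKM"), ann)$ratio, 2 / 1.5)
  auto_only <- expr_matrix(m[3:5, , drop = FALSE], "FPKM")
  expect_error(x_a_ratio(auto_only, ann), "X-linked")
})

test_that("X:A ratio equals brute-force recomputation and is scale-invariant", {
  set.seed(13)
  cfg <- sim_config(seed = 13)
  bulk <- simulate_bulk_cohort(cfg)
  x <- filter_expressed(bulk$expr)
  res <- x_a_ratio(x, bulk$annotation)
  # brute force straight from the two formulas
  chrom <- bulk$annotation$chrom[match(rownames(x$values), bulk$annotation$gene_id)]
  for (j in seq_len(ncol(x$values))) {
    mf_x <- sum(x$values[chrom == "X", j]) / sum(chrom == "X")
    autos <- setdiff(unique(chrom), c("X", "Y"))
    mfs <- vapply(autos, function(a)
      sum(x$values[chrom == a, j]) / sum(chrom == a), numeric(1))
    expect_equal(res$ratio[j], mf_x / mean(mfs), tolerance = 1e-12)
  }
  scaled <- expr_matrix(x$values * 37.5, "FPKM")
  expect_equal(x_a_ratio(scaled, bulk$annotation)$ratio, res$ratio,
               tolerance = 1e-12)
})

test_that("male-median fold change is 1 on the median profile and ratios otherwise", {
  m <- matrix(c(2, 2, 2,   4, 2, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "var"), c("r1", "r2", "r3")))
  tr <- male_median_fc(expr_matrix(m, "FPKM"), c("r1", "r2", "r3"))
  expect_equal(unname(tr$male_median), c(2, 4))
  expect_true(all(tr$fc["flat", ] == 1))
  expect_equal(unname(tr$fc["var", ]), c(1, 0.5, 2))
  # odd reference count: each gene's FC hits 1 in at least one reference
  expect_true(all(apply(tr$fc, 1, function(f) any(f == 1))))
  expect_error(male_median_fc(expr_matrix(m, "FPKM"), "r1"), "at least 2")
  # genes with zero male median are dropped
  m0 <- rbind(m, zero = c(0, 0, 0))
  expect_message(tr0 <- male_median_fc(expr_matrix(m0, "FPKM"), c("r1", "r2", "r3")),
                 "male median 0")
  expect_false("zero" %in% rownames(tr0$fc))
})

test_that("PAR1 fold change under zero noise follows the sex-chromosome count", {
  cfg <- sim_config(seed = 2, noise_cv = 0)
  bulk <- simulate_bulk_cohort(cfg)
  ref <- bulk$meta$sample_id[bulk$meta$n_x == 1]
  tr <- male_median_fc(bulk$expr, ref)
  p1 <- bulk$annotation$gene_id[bulk$annotation$region_class == "PAR1"][1]
  for (k in 2:4) {
    s <- bulk$meta$sample_id[bulk$meta$n_x == k][1]
    expect_equal(unname(tr$fc[p1, s]), (k + 1) / 2)  # 1.5, 2.0, 2.5
  }
})

test_that("moving average is flat for constant fold change", {
  cfg <- sim_config(seed = 4, noise_cv = 0)
  bulk <- simulate_bulk_cohort(cfg)
  ref <- bulk$meta$sample_id[bulk$meta$n_x == 1]
  tr <- male_median_fc(bulk$expr, ref)
  # restrict to the reference sample itself: FC identically 1
  tr$fc <- tr$fc[, ref[1], drop = FALSE]
  curve <- moving_average_x(tr, bulk$annotation, pseudo = 0)
  expect_lt(max(abs(curve$smoothed)), 1e-9)
})

test_that("loess moving average matches the local-regression oracle", {
  set.seed(55)
  n <- 200
  pos <- sort(runif(n, 0, 1.5e8))
  fc <- 2^(rnorm(n, 0.3, 0.4))
  ann <- gene_annotation(sprintf("g%03d", 1:n), rep("X", n),
                         start = pos, end = pos + 100)
  track <- structure(list(fc = matrix(fc, n, 1,
                                      dimnames = list(ann$gene_id, "s1")),
                          male_median = rep(1, n), reference_samples = "ref"),
                     class = "fc_track")
  curve <- moving_average_x(track, ann, span = 0.45)
  oracle <- oracle_local_regression(curve$position, log2(fc[order(pos)] + 1e-8),
                                    curve$position, span = 0.45, degree = 2)
  expect_lt(max(abs(curve$smoothed[, 1] - oracle)), 1e-6)
  expect_error(moving_average_x(track, ann[1:5, ]), "at least 10")
})

test_that("DEG thresholds are strict and the call is threshold-monotone", {
  stats_df <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                         log2_fc = c(0.3, 0.25, -0.3, -0.2, 1),
                         fdr = c(0.01, 0.01, 0.049, 0.01, 0.2))
  calls <- call_degs(stats_df)
  expect_equal(calls$direction, c("up", "ns", "down", "ns", "ns"))
  # lowering the FDR cut never adds calls
  loose <- sum(call_degs(stats_df, fdr_cut = 0.05)$direction != "ns")
  tight <- sum(call_degs(stats_df, fdr_cut = 0.01)$direction != "ns")
  expect_lte(tight, loose)
  # idempotent on its own output
  expect_identical(call_degs(calls), calls)
  expect_error(call_degs(transform(stats_df, fdr = fdr + 1)), "fdr")
})

test_that("two-comparison intersection keeps concordant directions only", {
  a <- data.frame(gene_id = c("a", "b", "c", "x"),
                  direction = c("up", "up", "up", "down"))
  b <- data.frame(gene_id = c("b", "c", "d", "x"),
                  direction = c("up", "up", "up", "up"))
  shared <- deg_intersection(a, b)
  expect_setequal(shared$gene_id, c("b", "c"))
})

test_that("dosage-trend classification recovers generator laws", {
  cfg <- sim_config(seed = 17, noise_cv = 0.1)
  bulk <- simulate_bulk_cohort(cfg)
  trends <- classify_dosage_trend(bulk$expr, bulk$meta, bulk$annotation)
  tr <- merge(trends, bulk$truth, by = "gene_id")
  par1 <- tr[tr$region_class == "PAR1", ]
  expect_gte(mean(par1$trend == "proportional"), 0.95)
  expect_true(all(par1$covariate == "n_x_plus_n_y"))
  dn <- tr[tr$law == "autosome_down", ]
  expect_gte(mean(dn$trend == "inverse"), 0.95)
  flat <- tr[tr$law == "autosome_flat", ]
  expect_lte(mean(flat$trend != "flat"), 0.05)
  # slope recovery on the log2-linear trend genes: bias under 5% of truth
  up <- tr[tr$law == "autosome_up", ]
  expect_lt(abs(mean(up$slope) - cfg$trend_log2_slope),
            0.05 * cfg$trend_log2_slope)
  # identical values across karyotypes -> slope 0, flat
  const <- expr_matrix(matrix(5, 12, nrow(bulk$meta),
                              dimnames = list(bulk$annotation$gene_id[1:12],
                                              bulk$meta$sample_id)), "FPKM")
  ct <- classify_dosage_trend(const, bulk$meta, bulk$annotation)
  expect_true(all(ct$slope == 0))
  expect_true(all(ct$trend == "flat"))
  one_kar <- bulk$meta[bulk$meta$n_x == 2, ]
  sub <- expr_matrix(bulk$expr$values[, one_kar$sample_id], "FPKM")
  expect_error(classify_dosage_trend(sub, one_kar, bulk$annotation),
               "3 distinct karyotype")
})

test_that("X-linked DEGs are categorized with PAR1 precedence", {
  b <- par_boundaries(par1_span_bp = 26000, par2_span_bp = 3200,
                      x_length_bp = 156000)
  ann <- gene_annotation(c("p", "e", "i", "v", "n", "a"),
                         c("X", "X", "X", "X", "X", "5"),
                         start = c(100, 5e4, 6e4, 7e4, 8e4, 100),
                         end = c(200, 5.01e4, 6.01e4, 7.01e4, 8.01e4, 200),
                         xci_status = c("escape", "escape", "inactive",
                                        "variable", "unknown", "unknown"),
                         boundaries = b)
  cat <- categorize_x_degs(c("p", "e", "i", "v", "n", "a"), ann)
  expect_equal(cat$category[match(c("p", "e", "i", "v", "n"), cat$gene_id)],
               c("PAR1", "escape", "inactive", "variable", "novel"))
  expect_false("a" %in% cat$gene_id)  # autosomal DEGs are outside the X table
})
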