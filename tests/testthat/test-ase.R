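mk_records <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(sample_id = "s1", chrom = "X", ref = "A", alt = "G")
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df
}

test_that("variant whitelist keeps only PASS calls with depth over 10", {
  v <- data.frame(chrom = "X", pos = 1:4,
                  filter = c("PASS", "PASS", "germline", "PASS"),
                  dp = c(11L, 10L, 100L, NA))
  expect_warning(wl <- filter_variant_whitelist(v), "depth field")
  expect_equal(wl$pos, 1L)
  # the same rules hold reading from an actual VCF
  path <- tempfile(fileext = ".vcf")
  write_simple_vcf(data.frame(chrom = "X", pos = 1:3, ref = "A", alt = "G",
                              filter = c("PASS", "PASS", "germline"),
                              dp = c(11L, 10L, 100L)), path)
  expect_equal(filter_variant_whitelist(path)$pos, 1L)
})

test_that("site filters apply depth, whitelist, intronic and mapping rules", {
  rec <- mk_records(pos = 1:5,
                    ref_count = c(3L, 4L, 5L, 5L, 5L),
                    alt_count = c(3L, 3L, 5L, 5L, 5L),
                    total_count = c(6L, 7L, 10L, 10L, 10L),
                    gene_id = c("g1", "g1", "g2", "XIST", "g3"),
                    intronic = c(FALSE, FALSE, TRUE, TRUE, FALSE),
                    multi_gene = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                    is_xist = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  wl <- data.frame(chrom = "X", pos = 1:4)
  out <- filter_sites(rec, wl)
  # depth 6 fails the strictly-greater-than-six rule; depth 7 passes
  expect_equal(out$filtered$reason[out$filtered$pos == 1], "depth")
  expect_true(2 %in% out$kept$pos)
  # intronic non-XIST record removed; intronic + multi-gene XIST retained
  expect_equal(out$filtered$reason[out$filtered$pos == 3], "intronic")
  expect_true(4 %in% out$kept$pos)
  # position 5 off the whitelist, and whitelist reason takes precedence
  expect_equal(out$filtered$reason[out$filtered$pos == 5], "whitelist")
  expect_equal(nrow(out$kept) + nrow(out$filtered), nrow(rec))
  # XIST exemption from the intronic filter is configurable
  out2 <- filter_sites(rec, wl, xist_exempt_intronic = FALSE)
  expect_equal(out2$filtered$reason[out2$filtered$pos == 4], "intronic")
  expect_warning(filter_sites(rec, wl[0, ]), "empty")
})

test_that("raising min_depth never increases the kept-record count", {
  set.seed(42)
  rec <- mk_records(pos = 1:200, ref_count = 0L, alt_count = 0L,
                    total_count = sample(1:40, 200, replace = TRUE))
  rec$ref_count <- rbinom(200, rec$total_count, 0.5)
  rec$alt_count <- rec$total_count - rec$ref_count
  wl <- data.frame(chrom = "X", pos = 1:200)
  kept <- vapply(1:30, function(d) nrow(filter_sites(rec, wl, min_depth = d)$kept),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("SNP classification follows the 0.1-0.9 fraction gate, inclusive", {
  rec <- mk_records(pos = 1:5,
                    ref_count = c(5L, 19L, 1L, 18L, 0L),
                    alt_count = c(5L, 1L, 9L, 2L, 0L),
                    total_count = c(10L, 20L, 10L, 20L, 0L))
  calls <- classify_snp(rec)
  expect_equal(calls$status,
               c("biallelic",    # 0.5
                 "monoallelic",  # 0.95, over 0.9
                 "biallelic",    # exactly 0.10, inclusive boundary
                 "biallelic",    # exactly 0.90, inclusive boundary
                 "filtered"))    # zero depth is never classified
  expect_equal(calls$ref_fraction[1:4], c(0.5, 0.95, 0.1, 0.9))
})

test_that("classification is symmetric under allele swap", {
  set.seed(7)
  total <- sample(1:60, 300, replace = TRUE)
  ref <- vapply(total, function(t) sample(0:t, 1), integer(1))
  a <- classify_snp(mk_records(pos = seq_along(total), ref_count = ref,
                               alt_count = total - ref, total_count = total))
  b <- classify_snp(mk_records(pos = seq_along(total), ref_count = total - ref,
                               alt_count = ref, total_count = total))
  expect_identical(a$status, b$status)
})

test_that("gene calls need just one biallelic SNP; all-filtered genes are uninformative", {
  calls <- data.frame(sample_id = "s1",
                      gene_id = c("g1", "g1", "g2", "g2", "g3"),
                      status = c("monoallelic", "biallelic", "monoallelic",
                                 "monoallelic", "filtered"),
                      stringsAsFactors = FALSE)
  gc <- call_genes(calls)
  expect_equal(gc$status[gc$gene_id == "g1"], "biallelic")
  expect_equal(gc$status[gc$gene_id == "g2"], "monoallelic")
  expect_equal(gc$status[gc$gene_id == "g3"], "uninformative")
  expect_equal(gc$n_informative[gc$gene_id == "g3"], 0L)
})

test_that("SNP and gene rules match the brute-force oracle on random records", {
  set.seed(101)
  n <- 10000
  total <- sample(1:80, n, replace = TRUE)
  ref <- vapply(total, function(t) sample(0:t, 1), integer(1))
  gene <- sprintf("g%04d", sample(1:800, n, replace = TRUE))
  rec <- mk_records(pos = seq_len(n), ref_count = ref,
                    alt_count = total - ref, total_count = total,
                    gene_id = gene)
  calls <- classify_snp(rec)
  expect_identical(calls$status, oracle_snp_status(ref, total))
  gc <- call_genes(calls)
  for (g in unique(gene)[1:200]) {
    expect_identical(gc$status[gc$gene_id == g],
                     oracle_gene_status(calls$status[gene == g]))
  }
  # full-set check without the loop cap
  oracle_by_gene <- vapply(split(calls$status, gene), oracle_gene_status,
                           character(1))
  expect_identical(gc$status[match(names(oracle_by_gene), gc$gene_id)],
                   unname(oracle_by_gene))
})

test_that("summaries count by region class and compute biallelic frequency", {
  ann <- gene_annotation(c("p1", "x1", "x2"), c("X", "X", "X"),
                         start = c(100, 5e7, 6e7), end = c(1100, 5.0001e7, 6.0001e7))
  gc <- data.frame(sample_id = rep(c("a", "b", "c", "d"), each = 2),
                   gene_id = rep(c("p1", "x1"), 4),
                   status = c("biallelic", "biallelic",
                              "biallelic", "biallelic",
                              "biallelic", "biallelic",
                              "biallelic", "monoallelic"),
                   stringsAsFactors = FALSE)
  s <- summarize_ase(gc, ann)
  # x1 biallelic in 3 of 4 informative replicates -> 75%
  expect_equal(s$gene_frequency$biallelic_pct[s$gene_frequency$gene_id == "x1"], 75)
  expect_equal(s$nonpar_biallelic$n_biallelic_nonpar,
               c(1L, 1L, 1L, 0L))
  bs <- s$by_sample
  expect_equal(bs$n_genes[bs$sample_id == "a" & bs$region_class == "PAR1" &
                          bs$status == "biallelic"], 1L)
  expect_warning(summarize_ase(data.frame(sample_id = "a", gene_id = "nope",
                                          status = "biallelic"), ann),
                 "unknown")
})

test_that("erosion flag marks the sample with a 2-3x biallelic excess", {
  counts <- data.frame(sample_id = c("a", "b", "c", "d"),
                       n_biallelic_nonpar = c(20L, 22L, 19L, 57L))
  fl <- flag_erosion(counts)
  expect_identical(fl$eroded, c(FALSE, FALSE, FALSE, TRUE))
  none <- flag_erosion(data.frame(sample_id = c("a", "b", "c"),
                                  n_biallelic_nonpar = c(20L, 21L, 19L)))
  expect_false(any(none$eroded))
  expect_error(flag_erosion(counts[1:2, ]), "3 samples")
  # the absolute floor prevents flagging tiny coh: 10 vs 4 median
  low <- flag_erosion(data.frame(sample_id = c("a", "b", "c", "d"),
                                 n_biallelic_nonpar = c(4L, 5L, 4L, 10L)))
  expect_false(any(low$eroded))
})

test_that("XIST allelic check reports monoallelic expression and warns on mosaics", {
  calls <- data.frame(sample_id = c("a", "a", "b", "c"),
                      gene_id = c("XIST", "XIST", "XIST", "other"),
                      is_xist = c(TRUE, TRUE, TRUE, FALSE),
                      status = c("monoallelic", "monoallelic", "biallelic",
                                 "biallelic"),
                      ref_fraction = c(0.98, 0.02, 0.5, 0.5),
                      stringsAsFactors = FALSE)
  expect_warning(st <- xist_allelic_check(calls), "mosaic")
  expect_equal(st$status[st$sample_id == "a"], "monoallelic")
  expect_equal(st$status[st$sample_id == "b"], "biallelic")
  expect_equal(st$status[st$sample_id == "c"], "uninformative")
})

test_that("gene-level recovery on synthetic data is near-perfect at low leakage", {
  cfg <- sim_config(seed = 31, monoallelic_leak = 0.01, depth_mean = 50)
  ann <- simulate_annotation(cfg)
  meta <- simulate_bulk_cohort(cfg)$meta
  sim <- simulate_allele_counts(cfg, ann, meta)
  rec <- sim$counts[!sim$counts$intronic, ]
  gc <- call_genes(classify_snp(rec))
  truth <- sim$truth[sim$truth$true_status != "none", ]
  key <- paste(gc$sample_id, gc$gene_id)
  tkey <- paste(truth$sample_id, truth$gene_id)
  matched <- truth$true_status[match(key, tkey)]
  acc <- mean(gc$status == matched, na.rm = TRUE)
  expect_gte(acc, 0.98)
})
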