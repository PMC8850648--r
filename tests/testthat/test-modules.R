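test_that("CPM filter keeps genes detectable in at least four samples", {
  counts <- matrix(1000, 6, 6,
                   dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:6)))
  # library size 1e6 per sample once totals are set: make each column sum 1e6
  counts[1, ] <- c(1, 1, 1, 1, 0, 0)       # CPM >= 1 in exactly 4 samples
  counts[2, ] <- c(1, 1, 1, 0, 0, 0)       # only 3
  counts[3, ] <- 0
  for (j in 1:6) counts[6, j] <- 1e6 - sum(counts[1:5, j])
  x <- expr_matrix(counts, "counts")
  kept <- filter_cpm(x)
  expect_true("g1" %in% rownames(kept$values))
  expect_false("g2" %in% rownames(kept$values))
  expect_false("g3" %in% rownames(kept$values))
  expect_error(filter_cpm(expr_matrix(counts[, 1:3], "counts")), "4 samples")
  expect_error(filter_cpm(expr_matrix(counts, "FPKM")), "counts")
})

test_that("module detection recovers planted blocks and is order-invariant", {
  sim <- simulate_module_structure(seed = 41)
  mods <- build_modules(sim$values)
  ari <- oracle_ari(mods$labels[sim$truth_modules$gene_id],
                    sim$truth_modules$module)
  expect_gte(ari, 0.9)
  # permuting gene order yields the same partition up to renaming
  perm <- sample(nrow(sim$values))
  mods_p <- build_modules(sim$values[perm, ])
  expect_gte(oracle_ari(mods$labels[rownames(sim$values)[perm]],
                        mods_p$labels[rownames(sim$values)[perm]]), 0.999)
})

test_that("anticorrelated genes land in different modules on a signed network", {
  set.seed(3)
  base <- matrix(rnorm(90 * 20), 90, 20)
  s <- rnorm(20)
  up <- matrix(rep(s, each = 45), 45) + matrix(rnorm(45 * 20, 0, 0.3), 45)
  dn <- matrix(rep(-s, each = 45), 45) + matrix(rnorm(45 * 20, 0, 0.3), 45)
  m <- rbind(up, dn)
  rownames(m) <- sprintf("g%02d", 1:90)
  colnames(m) <- sprintf("s%02d", 1:20)
  mods <- build_modules(m, network_config(min_module_size = 20))
  expect_false(any(mods$labels[1:45] %in% mods$labels[46:90] &
                   mods$labels[1:45] != "grey"))
})

test_that("a structureless matrix stays almost entirely grey", {
  set.seed(8)
  m <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:20)))
  mods <- build_modules(m)
  expect_gte(mean(mods$labels == "grey"), 0.9)
})

test_that("eigengene matches direct SVD and keeps its sign orientation", {
  sim <- simulate_module_structure(seed = 43)
  g <- sim$truth_modules$gene_id[sim$truth_modules$module == 1]
  eg <- module_eigengene(sim$values, g)
  std <- t(scale(t(sim$values[g, ])))
  ev <- eigen(crossprod(std))$values
  expect_equal(eg$var_explained, ev[1] / sum(ev), tolerance = 1e-9)
  expect_gt(cor(eg$eigengene, colMeans(sim$values[g, ])), 0)
  # flipped input preserves orientation relative to the module mean
  eg_f <- module_eigengene(-sim$values, g)
  expect_gt(cor(eg_f$eigengene, colMeans(-sim$values[g, ])), 0)
  # identical genes -> eigengene proportional to that profile
  ident <- matrix(rep(sim$values[g[1], ], each = 5), 5,
                  dimnames = list(sprintf("i%d", 1:5), colnames(sim$values)))
  eg_i <- module_eigengene(ident, rownames(ident))
  expect_equal(abs(cor(eg_i$eigengene, sim$values[g[1], ])), 1, tolerance = 1e-9)
  # constant gene rows force the mean-profile fallback
  const <- rbind(ident[1:2, ], flatrow = rep(1, ncol(ident)))
  expect_warning(module_eigengene(const, rownames(const)), "rank-deficient")
  expect_error(module_eigengene(sim$values, g[1:2]), "at least 3")
})

test_that("ANOVA filter reproduces the hand-computed F statistic", {
  eg <- c(1.0, 1.2, 0.8,  2.0, 2.1, 1.9,  3.2, 2.8, 3.0)
  grp <- rep(c("A", "B", "C"), each = 3)
  # brute-force sums of squares
  gm <- mean(eg)
  ssb <- sum(tapply(eg, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(eg, grp, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / 6)
  labels <- c(rep("M1", 3), rep("grey", 2))
  names(labels) <- sprintf("g%d", 1:5)
  vals <- matrix(rnorm(45), 5, 9, dimnames = list(names(labels), sprintf("s%d", 1:9)))
  vals[1, ] <- eg; vals[2, ] <- eg + rnorm(9, 0, 0.01); vals[3, ] <- eg + rnorm(9, 0, 0.01)
  mods <- structure(list(labels = labels, n_modules = 1L,
                         config = network_config()), class = "module_set")
  meta <- data.frame(sample_id = sprintf("s%d", 1:9), karyotype = grp)
  res <- anova_filter(mods, vals, meta)
  # eigengene is standardized; F is scale-invariant, so compare to the hand F
  expect_equal(res$f_statistic, f_hand, tolerance = 0.05)
  expect_true(res$pass)
  # constant eigengene fails
  flat_eg <- anova_filter(mods, matrix(rep(seq(1, 2, length.out = 9), each = 5), 5, 9,
                                       dimnames = dimnames(vals)), meta)
  expect_false(is.na(flat_eg$p_value) && flat_eg$p_value < 0.05)
})

test_that("supermodule selection needs significance plus monotone means", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:16),
                     karyotype = rep(c("46,XY", "47,XXY", "48,XXXY", "49,XXXXY"),
                                     each = 4),
                     n_x = rep(1:4, each = 4))
  nx <- meta$n_x
  egs <- rbind(up1 = nx + rnorm(16, 0, 0.1),
               up2 = nx + rnorm(16, 0, 0.1),
               down = -nx + rnorm(16, 0, 0.1),
               bump = c(1, 1, 1, 1, 3, 3, 3, 3, 3.1, 3.1, 3.1, 3.1, 1, 1, 1, 1))
  colnames(egs) <- meta$sample_id
  anv <- data.frame(module = rownames(egs), f_statistic = 10, p_value = 1e-4,
                    pass = TRUE)
  attr(anv, "eigengenes") <- egs
  res <- select_dosage_supermodules(anv, meta)
  expect_equal(res$trend[res$module == "up1"], "up")
  expect_equal(res$trend[res$module == "down"], "down")
  expect_equal(res$trend[res$module == "bump"], "flat")  # non-monotone
  expect_true(is.na(res$supermodule[res$module == "bump"]))
  # two up modules correlated > 0.75 merge into one supermodule
  expect_equal(res$supermodule[res$module == "up1"],
               res$supermodule[res$module == "up2"])
})

test_that("hypergeometric p equals exact enumeration, including the toy example", {
  # N=10, K=5, n=4, k=3: (C(5,3) C(5,1) + C(5,4) C(5,0)) / C(10,4)
  p_toy <- (choose(5, 3) * choose(5, 1) + choose(5, 4) * choose(5, 0)) / choose(10, 4)
  res <- hypergeom_enrich(letters[1:4], list(t = letters[c(1, 2, 3, 6)]),
                          letters[1:10])
  # overlap k = 3 of query 4, term size 4... construct the exact (10,5,4,3) case
  uni <- letters[1:10]
  res2 <- hypergeom_enrich(uni[1:4], list(t = uni[c(1:3, 9, 10)]), uni)
  expect_equal(res2$p_value, p_toy, tolerance = 1e-12)
  # sweep all instances with N <= 30 against the oracle
  set.seed(6)
  for (rep in 1:200) {
    N <- sample(3:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- sprintf("u%02d", 1:N)
    term <- sample(uni, K); query <- sample(uni, n)
    k <- length(intersect(term, query))
    p <- hypergeom_enrich(query, list(t = term), uni)$p_value
    expect_equal(p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
  # k = 0 -> upper tail from zero is certain
  expect_equal(hypergeom_enrich("a", list(t = "b"), letters[1:10])$p_value, 1)
  # K = n = N -> certain overlap, p = 1
  expect_equal(hypergeom_enrich(letters[1:5], list(t = letters[1:5]),
                                letters[1:5])$p_value, 1)
  expect_error(hypergeom_enrich(character(0), list(t = "a"), "a"), "empty")
})

test_that("gene-set overlap reports count, percentage and enrichment p", {
  uni <- letters[1:20]
  ov <- gene_set_overlap(c("a", "b", "c", "d"), c("c", "d", "e"), uni)
  expect_equal(ov$overlap, 2)
  expect_equal(ov$pct_of_a, 50)
  expect_equal(ov$p_value, oracle_hyper_upper(2, 3, 20, 4), tolerance = 1e-12)
  expect_equal(gene_set_overlap(c("a", "b"), c("c", "d"), uni)$overlap, 0)
  expect_error(gene_set_overlap(character(0), "a", uni), "empty")
})

test_that("GMT reader returns named gene sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g2")
})
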