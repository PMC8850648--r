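# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive re-statements of the definitions, written
# without reference to the package internals.

# SNP rule: biallelic iff ref/total in [0.1, 0.9]; gene rule: biallelic iff
# any SNP biallelic, monoallelic iff informative and none biallelic.
oracle_snp_status <- function(ref, total, lower = 0.1, upper = 0.9) {
  out <- character(length(ref))
  for (i in seq_along(ref)) {
    if (total[i] == 0) { out[i] <- "filtered"; next }
    f <- ref[i] / total[i]
    out[i] <- if (f >= lower && f <= upper) "biallelic" else "monoallelic"
  }
  out
}

oracle_gene_status <- function(snp_statuses) {
  inf <- snp_statuses[snp_statuses != "filtered"]
  if (length(inf) == 0) return("uninformative")
  if (any(inf == "biallelic")) "biallelic" else "monoallelic"
}

# Local weighted polynomial regression with tricube weights: the classical
# loess definition, evaluated point by point.
oracle_local_regression <- function(x, y, x0s, span, degree = 2) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x0s, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    u <- pmin(1, d / h)
    w <- (1 - u^3)^3
    X <- outer(x - x0, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y, w)
    unname(fit$coefficients[1])
  }, numeric(1))
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Upper-tail hypergeometric probability by direct pmf summation.
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# Two-sided Fisher p for a 2x2 table by enumerating all tables with the
# observed margins and summing probabilities not exceeding the observed one
# (with the customary relative tolerance for ties).
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  pmf <- choose(r1, ks) * choose(N - r1, c1 - ks) / choose(N, c1)
  p_obs <- pmf[ks == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# Exhaustive PWM window scoring on both strands.
oracle_pwm_hits <- function(seq_chr, score_mat, threshold) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- ncol(score_mat)
  score_window <- function(win) {
    b <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(b)) return(-Inf)
    sum(score_mat[cbind(b, seq_len(L))])
  }
  n <- nchar(seq_chr)
  hits <- data.frame(position = integer(0), strand = character(0))
  if (n < L) return(hits)
  for (w in 1:(n - L + 1)) {
    win <- substr(seq_chr, w, w + L - 1)
    if (score_window(win) >= threshold)
      hits <- rbind(hits, data.frame(position = w, strand = "+"))
    if (score_window(revcomp(win)) >= threshold)
      hits <- rbind(hits, data.frame(position = w, strand = "-"))
  }
  hits
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
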