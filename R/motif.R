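#' Build a position weight matrix from base counts or frequencies
#'
#' Adds a pseudocount, normalizes columns to probabilities, and derives the
#' log2-odds score matrix against the background base frequencies together
#' with the maximum and minimum achievable window scores.
#'
#' @param counts 4 x L numeric matrix, rows A, C, G, T.
#' @param name Motif identifier.
#' @param pseudocount Added to every cell before normalization (default
#'   0.01).
#' @param background Named base frequencies (default uniform).
#' @return List of class `pwm`: `name`, `prob` (4 x L), `score` (log2-odds,
#'   4 x L), `length`, `s_max`, `s_min`, `consensus`.
#' @export
pwm <- function(counts, name = "motif", pseudocount = 0.01,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  rownames(counts) <- c("A", "C", "G", "T")
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), `/`)
  if (any(abs(colSums(prob) - 1) > 1e-9)) stop("PWM columns failed to normalize")
  score <- log2(prob / background[rownames(prob)])
  structure(list(name = name, prob = prob, score = score,
                 length = ncol(prob),
                 s_max = sum(apply(score, 2, max)),
                 s_min = sum(apply(score, 2, min)),
                 consensus = paste(rownames(score)[apply(score, 2, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: length %d, consensus %s, score range [%.2f, %.2f]>\n",
              x$name, x$length, x$consensus, x$s_min, x$s_max))
  invisible(x)
}

#' Read JASPAR-format position frequency matrices
#'
#' Supports the JASPAR dialect (`>ID name` header, then `A [ ... ]` rows)
#' and the raw dialect (header line, then four bare number rows in A, C,
#' G, T order).
#'
#' @param path Path to the PFM file (may contain several matrices).
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    name <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    counts <- do.call(rbind, rows)
    out[[name]] <- pwm(counts, name = name, pseudocount = pseudocount,
                       background = background)
  }
  out
}

#' Extract promoter windows around transcription start sites
#'
#' The promoter spans -`upstream` to +`downstream` bases relative to the
#' TSS (gene start on the plus strand, gene end on the minus strand), in
#' transcription direction: minus-strand windows are reverse-complemented.
#' Windows running off a contig edge are truncated and flagged. Genes on
#' contigs missing from the genome are skipped with a warning.
#'
#' @param annotation A [gene_annotation()].
#' @param genome Named [Biostrings::DNAStringSet] (one sequence per
#'   chromosome) or a FASTA path.
#' @param upstream,downstream Bases before/after the TSS (defaults 1500 and
#'   500, giving 2 kb windows).
#' @return Data frame `gene_id`, `sequence`, `truncated`.
#' @export
extract_promoters <- function(annotation, genome, upstream = 1500L,
                              downstream = 500L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- normalize_chrom(sub("\\s.*$", "", names(genome)))
  missing <- !annotation$chrom %in% names(genome)
  if (any(missing)) {
    warning(sprintf("skipping %d gene(s) on contig(s) absent from the genome",
                    sum(missing)))
    annotation <- annotation[!missing, ]
  }
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    chrom_seq <- genome[[annotation$chrom[i]]]
    len <- length(chrom_seq)
    if (annotation$strand[i] == "+") {
      tss <- annotation$start[i]                 # 0-based
      from <- tss - upstream; to <- tss + downstream   # [from, to)
    } else {
      tss <- annotation$end[i] - 1
      from <- tss - downstream + 1; to <- tss + upstream + 1
    }
    truncated <- from < 0 || to > len
    from_c <- max(0, from); to_c <- min(len, to)
    s <- Biostrings::subseq(chrom_seq, from_c + 1, to_c)
    if (annotation$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    data.frame(gene_id = annotation$gene_id[i], sequence = as.character(s),
               truncated = truncated, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scan a sequence with a PWM at a deficit threshold
#'
#' Scores every window on both strands with the log-odds matrix and reports
#' the positions whose score reaches `s_max - deficit * (s_max - s_min)`:
#' deficit 0 admits only the consensus-score windows, deficit 1 admits
#' every window. Windows containing a non-ACGT base are skipped.
#'
#' @param sequence Character DNA string (or anything coercible).
#' @param motif A [pwm()].
#' @param deficit Allowed shortfall from the maximum score, as a fraction
#'   of the score range (default 0.15).
#' @return Data frame `position` (1-based window start on the given
#'   sequence), `strand`, `score`.
#' @export
scan_pwm <- function(sequence, motif, deficit = 0.15) {
  stopifnot(inherits(motif, "pwm"), deficit >= 0, deficit <= 1)
  thr <- motif$s_max - deficit * (motif$s_max - motif$s_min)
  fwd <- .pwm_window_scores(as.character(sequence), motif$score)
  rev_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(as.character(sequence))))
  rev <- .pwm_window_scores(rev_seq, motif$score)
  n <- nchar(as.character(sequence))
  L <- motif$length
  wf <- which(fwd >= thr); wr <- which(rev >= thr)
  hits <- rbind(
    if (length(wf)) data.frame(position = wf, strand = "+", score = fwd[wf]),
    if (length(wr))
      # map a window on the reverse strand back to forward coordinates
      data.frame(position = n - L + 2L - wr, strand = "-", score = rev[wr]))
  if (is.null(hits) || !nrow(hits))
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  hits <- hits[order(hits$position, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

.pwm_window_scores <- function(seq_chr, score_mat) {
  L <- ncol(score_mat)
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  n <- length(chars)
  if (n < L) return(numeric(0))
  idx <- match(chars, c("A", "C", "G", "T"))
  n_win <- n - L + 1L
  s <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    b <- idx[j:(j + n_win - 1L)]
    valid <- valid & !is.na(b)
    contrib <- score_mat[cbind(ifelse(is.na(b), 1L, b), j)]
    s <- s + contrib
  }
  s[!valid] <- -Inf   # windows containing N are skipped
  s
}

#' Scan a promoter set with several PWMs
#'
#' @param promoters Output of [extract_promoters()].
#' @param pwms Named list of [pwm()] objects.
#' @param deficit Deficit threshold passed to [scan_pwm()].
#' @return Logical genes x motifs matrix: TRUE iff the gene's promoter has
#'   at least one hit ("bound").
#' @export
scan_promoters <- function(promoters, pwms, deficit = 0.15) {
  bound <- matrix(FALSE, nrow(promoters), length(pwms),
                  dimnames = list(promoters$gene_id, names(pwms)))
  for (tf in names(pwms)) {
    bound[, tf] <- vapply(promoters$sequence, function(s)
      nrow(scan_pwm(s, pwms[[tf]], deficit)) > 0, logical(1), USE.NAMES = FALSE)
  }
  bound
}

#' Fisher's exact gene-coverage enrichment of TF binding sites
#'
#' A gene is "bound" by a TF iff its promoter holds at least one PWM hit.
#' For each TF, the 2x2 table (bound/unbound x query/background) is tested
#' with a two-sided Fisher's exact test; the enrichment is the log2 ratio
#' of bound proportions (query over background).
#'
#' @param bound Logical genes x motifs matrix from [scan_promoters()].
#' @param query,background Gene id vectors (rows of `bound`).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param allow_overlap Permit overlapping query and background sets.
#' @return Data frame `tf`, `query_bound`, `query_total`, `bg_bound`,
#'   `bg_total`, `enrichment`, `p_value`, `significant`.
#' @export
coverage_fisher <- function(bound, query, background, alpha = 0.05,
                            allow_overlap = FALSE) {
  if (!length(background)) stop("empty background gene set")
  if (!allow_overlap && length(intersect(query, background)))
    stop("query and background overlap; set allow_overlap = TRUE to permit")
  q <- bound[query, , drop = FALSE]; b <- bound[background, , drop = FALSE]
  out <- lapply(colnames(bound), function(tf) {
    qb <- sum(q[, tf]); bb <- sum(b[, tf])
    tab <- matrix(c(qb, nrow(q) - qb, bb, nrow(b) - bb), 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    enr <- log2((qb / nrow(q)) / (bb / nrow(b)))
    data.frame(tf = tf, query_bound = qb, query_total = nrow(q),
               bg_bound = bb, bg_total = nrow(b), enrichment = enr,
               p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transcription factors recurrently enriched across supermodules
#'
#' Reports TFs significantly over-represented (p < alpha and positive
#' enrichment) in at least `min_supermodules` of the supplied supermodule
#' enrichment tables.
#'
#' @param enrichments Named list of [coverage_fisher()] results, one per
#'   supermodule.
#' @param min_supermodules Minimum number of supermodules (default 7).
#' @param alpha Significance level (default 0.05).
#' @return Data frame `tf`, `n_supermodules`, sorted descending.
#' @export
recurrent_tfs <- function(enrichments, min_supermodules = 7L, alpha = 0.05) {
  if (!length(enrichments)) stop("no supermodule enrichments supplied")
  hits <- lapply(enrichments, function(e)
    e$tf[e$p_value < alpha & e$enrichment > 0])
  counts <- table(unlist(hits))
  keep <- counts[counts >= min_supermodules]
  if (!length(keep))
    return(data.frame(tf = character(0), n_supermodules = integer(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(tf = names(keep), n_supermodules = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$n_supermodules, out$tf), , drop = FALSE]
}
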