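# Independent oracles and fixture builders. Each oracle recomputes its
# quantity by direct enumeration or a brute-force double loop over the
# definition, never through the code path it checks.

# exact two-sided rank-sum p by enumeration of all C(n, n_x) rank
# assignments (tie-free data only)
oracle_wilcox_p <- function(x, y) {
  stopifnot(anyDuplicated(c(x, y)) == 0)
  n_x <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n_x)])
  idx <- utils::combn(length(r), n_x)
  w_all <- colSums(matrix(r[idx], nrow = n_x))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# upper-tail hypergeometric p by direct combinatorial summation
oracle_hyper_p <- function(N, K, n, k) {
  j <- k:min(n, K)
  if (k > min(n, K)) return(0)
  min(1, sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n))
}

# 2x2 chi-squared from the closed formula N(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force double loop over the wt-C-T definition
oracle_wtct <- function(peaks, genes, degs, window, mode) {
  w_fun <- function(d) switch(mode,
                              unweighted = rep(1, length(d)),
                              weighted = exp(-(0.5 + 4 * d / window)),
                              binary = ifelse(d <= 10000, 1, 0.5))
  mid <- floor((peaks$start + peaks$end) / 2)
  degs <- degs[degs$gene_id %in% genes$gene_id, , drop = FALSE]
  score <- numeric(nrow(degs))
  for (i in seq_len(nrow(degs))) {
    g <- genes[genes$gene_id == degs$gene_id[i], ]
    d <- abs(mid - g$tss)
    sel <- peaks$chrom == g$chrom & d <= window
    s <- if (any(sel)) sum(w_fun(d[sel]) * peaks$neglog_padj[sel]) else 0
    score[i] <- s * abs(degs$log_fc[i])
  }
  data.frame(gene_id = degs$gene_id, score = score,
             stringsAsFactors = FALSE)
}

# draw one element of a vector (safe for length-1 vectors, unlike sample())
pick1 <- function(v) v[sample.int(length(v), 1)]

# quick builders ------------------------------------------------------------

test_peaks <- function(intervals, chrom = "chr1", neglog = NULL,
                       prefix = "pk") {
  n <- length(intervals)
  data.frame(chrom = rep(chrom, length.out = n),
             start = vapply(intervals, `[`, numeric(1), 1),
             end = vapply(intervals, `[`, numeric(1), 2),
             name = sprintf("%s%d", prefix, seq_len(n)),
             neglog_padj = if (is.null(neglog)) rep(1, n) else neglog,
             source = NA_character_, stringsAsFactors = FALSE)
}

test_genes <- function(tss, chrom = "chr1", strand = "+") {
  n <- length(tss)
  data.frame(gene_id = sprintf("G%d", seq_len(n)),
             chrom = rep(chrom, length.out = n),
             start = tss, end = tss + 1000,
             strand = rep(strand, length.out = n),
             tss = tss, stringsAsFactors = FALSE)
}

test_degs <- function(gene_id, log_fc, log_pv = 2, padj = 0.01) {
  data.frame(gene_id = gene_id, log_fc = log_fc,
             log_pv = rep(log_pv, length.out = length(gene_id)),
             padj = rep(padj, length.out = length(gene_id)),
             stringsAsFactors = FALSE)
}

# a random scoring instance (peaks, genes, degs on a small genome)
random_instance <- function(n_genes, n_peaks, n_chrom = 2, len = 2e6) {
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  g_chrom <- sample(chroms, n_genes, replace = TRUE)
  tss <- sample.int(len - 2000, n_genes)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      chrom = g_chrom,
                      start = ifelse(strand == "+", tss, tss - 999),
                      end = ifelse(strand == "+", tss + 1000, tss + 1),
                      strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
  starts <- sample.int(len - 3000, n_peaks)
  peaks <- data.frame(chrom = sample(chroms, n_peaks, replace = TRUE),
                      start = starts,
                      end = starts + sample(100:2000, n_peaks, TRUE),
                      name = sprintf("pk%04d", seq_len(n_peaks)),
                      neglog_padj = stats::runif(n_peaks, 0.1, 6),
                      source = "t", stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = genes$gene_id,
                     log_fc = stats::rnorm(n_genes),
                     log_pv = stats::runif(n_genes, 0, 4),
                     padj = stats::runif(n_genes),
                     stringsAsFactors = FALSE)
  list(peaks = peaks, genes = genes, degs = degs)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
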