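test_that("distance weights evaluate their closed forms", {
  expect_equal(peak_weight(0, "weighted", 1e5), exp(-0.5))
  expect_equal(peak_weight(1e5, "weighted", 1e5), exp(-4.5))
  expect_equal(peak_weight(70000, "unweighted", 1e5), 1)
  expect_equal(peak_weight(c(5000, 50000), "binary", 1e5), c(1, 0.5))
  expect_error(peak_weight(1e5 + 1, "weighted", 1e5), "exceeds window")
  expect_error(peak_weight(-1, "weighted", 1e5), "negative")
  w <- peak_weight(seq(0, 1e5, by = 1e4), "weighted", 1e5)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) < 0))  # strictly decaying
})

test_that("single-gene score is the weighted significance sum times |logFC|", {
  peaks <- test_peaks(list(c(900, 1100), c(4900, 5100)),
                      neglog = c(2, 3))
  links <- annotate_peaks_to_genes(peaks, test_genes(1000))
  deg <- test_degs("G1", 0.5)
  s <- wtct_gene_score(links, peaks, deg, "unweighted")
  expect_equal(s$score, (2 + 3) * 0.5)
  expect_equal(wtct_gene_score(links[0, ], peaks, deg, "unweighted")$score,
               0)
  expect_equal(wtct_gene_score(links, peaks, test_degs("G1", 0),
                               "unweighted")$score, 0)
  bad <- links; bad$peak_name[1] <- "ghost"
  expect_error(wtct_gene_score(bad, peaks, deg, "unweighted"),
               "missing peak")
})

test_that("score table matches the brute-force oracle on random instances", {
  set.seed(10)
  for (rep in 1:15) {
    inst <- random_instance(sample(10:80, 1), sample(10:120, 1))
    for (mode in c("unweighted", "weighted", "binary")) {
      got <- suppressMessages(
        wtct_table(inst$peaks, inst$genes, inst$degs, mode = mode))
      want <- oracle_wtct(inst$peaks, inst$genes, inst$degs, 1e5, mode)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$score, want$score,
                   tolerance = if (mode == "unweighted") 0 else 1e-12)
    }
  }
})

test_that("scores are linear in peak significance and monotone in peaks", {
  set.seed(11)
  inst <- random_instance(30, 40)
  base <- suppressMessages(wtct_table(inst$peaks, inst$genes, inst$degs))
  doubled <- inst$peaks; doubled$neglog_padj <- 2 * doubled$neglog_padj
  expect_equal(suppressMessages(
    wtct_table(doubled, inst$genes, inst$degs))$score, 2 * base$score)
  # adding an in-window peak never decreases a score
  g <- inst$genes[1, ]
  extra <- rbind(inst$peaks,
                 data.frame(chrom = g$chrom, start = g$tss + 100,
                            end = g$tss + 400, name = "extra",
                            neglog_padj = 2, source = "t"))
  with_extra <- suppressMessages(
    wtct_table(extra, inst$genes, inst$degs))
  expect_true(all(with_extra$score >= base$score - 1e-12))
  # a peak beyond the window changes nothing
  far <- rbind(inst$peaks,
               data.frame(chrom = "chrZ", start = 0, end = 100,
                          name = "far", neglog_padj = 50, source = "t"))
  expect_equal(suppressMessages(
    wtct_table(far, inst$genes, inst$degs))$score, base$score)
  # weighted scores never exceed unweighted
  uw <- suppressMessages(
    wtct_table(inst$peaks, inst$genes, inst$degs, mode = "unweighted"))
  expect_true(all(base$score <= uw$score + 1e-12))
})

test_that("state filtering restricts the cistrome before scoring", {
  peaks <- test_peaks(list(c(900, 1100)), neglog = 4)
  genes <- test_genes(1000)
  seg <- data.frame(chrom = "chr1", start = 50000L, end = 60000L,
                    state = "Promoter", stringsAsFactors = FALSE)
  sc <- wtct_table(peaks, genes, test_degs("G1", 1), state = "Promoter",
                   segments = seg)
  expect_equal(sc$score, 0)  # no peak in that state
  expect_error(wtct_table(peaks, genes, test_degs("G1", 1),
                          state = "Promoter"), "segmentation")
  expect_error(wtct_table(peaks, genes, test_degs("G1", 1)[0, ]), "empty")
})

test_that("Wilcoxon comparison is exact at small tie-free sizes", {
  cmp <- compare_wtct(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$p, 0.1)
  expect_true(cmp$exact)
  expect_equal(cmp$direction, -1)
  # enumeration agreement over random tie-free groups up to 6 each
  set.seed(12)
  for (rep in 1:20) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    v <- sample(1000, na + nb) / 7
    p_pkg <- compare_wtct(v[1:na], v[(na + 1):(na + nb)])$p
    expect_equal(p_pkg, oracle_wilcox_p(v[1:na], v[(na + 1):(na + nb)]))
  }
  # identical multisets -> p = 1, label swap negates direction only
  expect_equal(compare_wtct(c(1, 1, 2), c(1, 1, 2))$p, 1)
  a <- c(0.3, 1.2, 5); b <- c(0.1, 0.2, 9, 4)
  expect_equal(compare_wtct(a, b)$p, compare_wtct(b, a)$p)
  expect_equal(compare_wtct(a, b)$direction, -compare_wtct(b, a)$direction)
  expect_error(compare_wtct(numeric(0), 1:3), "size 0")
})

test_that("normal approximation tracks enumeration at sizes 10-12", {
  set.seed(13)
  for (sizes in list(c(10, 10), c(10, 12), c(11, 11))) {
    for (rep in 1:3) {
      v <- sample(5000, sum(sizes)) / 11
      x <- v[seq_len(sizes[1])]
      y <- v[(sizes[1] + 1):sum(sizes)]
      cmp <- compare_wtct(x, y)
      expect_false(cmp$exact)
      expect_lt(abs(cmp$p - oracle_wilcox_p(x, y)), 0.01)
    }
  }
})

test_that("BH adjustment is monotone, capped and matches hand values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(14)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_true(all(diff(q[order(p)]) > -1e-12))
})
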