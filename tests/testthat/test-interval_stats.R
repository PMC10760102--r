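test_that("1-bp overlap rule follows half-open coordinates", {
  expect_true(intervals_overlap("chr1", 0, 10, "chr1", 9, 20))
  expect_false(intervals_overlap("chr1", 0, 10, "chr1", 10, 20))
  expect_false(intervals_overlap("chr1", 5, 6, "chr2", 0, 100))
  # symmetry over random pairs
  set.seed(1)
  for (i in 1:50) {
    a <- sort(sample.int(1000, 2)); b <- sort(sample.int(1000, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    if (b[1] == b[2]) b[2] <- b[2] + 1
    ch <- sample(c("chr1", "chr2"), 2, replace = TRUE)
    expect_identical(
      intervals_overlap(ch[1], a[1], a[2], ch[2], b[1], b[2]),
      intervals_overlap(ch[2], b[1], b[2], ch[1], a[1], a[2]))
  }
})

test_that("shared/unique peak counts match a brute-force pair scan", {
  a <- test_peaks(list(c(0, 10), c(100, 110)))
  b <- test_peaks(list(c(5, 15)), prefix = "qk")
  xs <- intersect_peak_sets(a, b)
  expect_equal(xs$shared_a, 1L)
  expect_equal(xs$unique_a, 1L)
  expect_equal(xs$shared_b, 1L)
  expect_equal(xs$pairs$name_a, "pk1")

  ident <- intersect_peak_sets(a, a)
  expect_equal(ident$shared_a, nrow(a))
  expect_equal(ident$unique_a, 0L)

  disj <- intersect_peak_sets(test_peaks(list(c(0, 10))),
                              test_peaks(list(c(50, 60)), prefix = "qk"))
  expect_equal(disj$shared_a + disj$shared_b, 0L)

  set.seed(2)
  for (rep in 1:10) {
    a <- random_instance(1, 40)$peaks
    b <- random_instance(1, 40)$peaks
    b$name <- paste0("b_", b$name)
    xs <- intersect_peak_sets(a, b)
    brute <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
                   function(i, j) intervals_overlap(
                     a$chrom[i], a$start[i], a$end[i],
                     b$chrom[j], b$start[j], b$end[j]))
    expect_equal(xs$shared_a, sum(rowSums(brute) > 0))
    expect_equal(xs$shared_b, sum(colSums(brute) > 0))
    expect_equal(nrow(xs$pairs), sum(brute))
    # pair list is the transpose of the swapped call
    sw <- intersect_peak_sets(b, a)
    expect_setequal(paste(xs$pairs$name_a, xs$pairs$name_b),
                    paste(sw$pairs$name_b, sw$pairs$name_a))
  }
})

test_that("binned chi-squared matches the 2x2 closed formula", {
  sizes <- c(chr1 = 100000)
  a <- test_peaks(list(c(0, 20000)))                      # bins 1-20
  b <- test_peaks(list(c(0, 10000), c(20000, 30000)),
                  prefix = "qk")                          # bins 1-10, 21-30
  ov <- suppressWarnings(overlap_chi2(a, b, sizes, 1000))
  expect_equal(c(ov$both, ov$a_only, ov$b_only, ov$neither),
               c(10, 10, 10, 70))
  expect_equal(ov$chi2, oracle_chi2_2x2(10, 10, 10, 70))
  expect_equal(ov$chi2, 14.0625)
  expect_equal(ov$both + ov$a_only + ov$b_only + ov$neither, ov$n_bins)
  # swap invariance
  sw <- suppressWarnings(overlap_chi2(b, a, sizes, 1000))
  expect_equal(sw$chi2, ov$chi2)
  expect_equal(sw$p, ov$p)
  # maximal association
  self <- suppressWarnings(overlap_chi2(a, a, sizes, 1000))
  expect_lt(self$p, 1e-4)
  # degenerate margin
  expect_warning(z <- overlap_chi2(empty <- a[0, ], b, sizes, 1000),
                 "zero margin")
  expect_equal(z$p, 1)
})

test_that("peak-to-gene links respect the inclusive 100 kb window", {
  genes <- test_genes(50000)
  hit <- annotate_peaks_to_genes(test_peaks(list(c(115000, 125000))),
                                 genes)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 70000)
  none <- annotate_peaks_to_genes(test_peaks(list(c(150000, 152000))),
                                  genes)  # midpoint 151000
  expect_equal(nrow(none), 0L)
  edge <- annotate_peaks_to_genes(test_peaks(list(c(149999, 150001))),
                                  genes)  # midpoint exactly 100000 away
  expect_equal(edge$distance, 100000)
  over <- annotate_peaks_to_genes(test_peaks(list(c(150000, 150003))),
                                  genes)  # midpoint 150001
  expect_equal(nrow(over), 0L)
  # one peak between two TSSs -> two links
  two <- annotate_peaks_to_genes(test_peaks(list(c(99000, 101000))),
                                 test_genes(c(50000, 150000)))
  expect_equal(sort(two$gene_id), c("G1", "G2"))
})

test_that("annotation agrees with a brute-force double loop", {
  set.seed(3)
  for (rep in 1:10) {
    inst <- random_instance(60, 80, len = 1e6)
    links <- annotate_peaks_to_genes(inst$peaks, inst$genes, 100000)
    mid <- floor((inst$peaks$start + inst$peaks$end) / 2)
    brute <- 0L
    for (i in seq_len(nrow(inst$genes))) {
      d <- abs(mid - inst$genes$tss[i])
      sel <- inst$peaks$chrom == inst$genes$chrom[i] & d <= 100000
      brute <- brute + sum(sel)
      got <- links[links$gene_id == inst$genes$gene_id[i], ]
      expect_setequal(got$peak_name, inst$peaks$name[sel])
      expect_equal(sort(got$distance), sort(d[sel]))
    }
    expect_equal(nrow(links), brute)
  }
})

test_that("state stratification follows the 1-bp rule", {
  seg <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                    end = c(10000L, 20000L),
                    state = c("Active Enhancer", "Promoter"),
                    stringsAsFactors = FALSE)
  inside <- stratify_by_states(test_peaks(list(c(100, 600))), seg)
  expect_named(inside, "Active Enhancer")
  spanning <- stratify_by_states(test_peaks(list(c(9900, 10100))), seg)
  expect_setequal(names(spanning), c("Active Enhancer", "Promoter"))
  outside <- stratify_by_states(test_peaks(list(c(50000, 50100))), seg)
  expect_named(outside, "unassigned")
  allun <- stratify_by_states(test_peaks(list(c(1, 5))), seg[0, ])
  expect_named(allun, "unassigned")
  bad <- seg; bad$start[2] <- 5000L
  expect_error(stratify_by_states(test_peaks(list(c(1, 5))), bad),
               "overlapping")
})

test_that("region FDR filter is strict at the cutoff", {
  pk <- test_peaks(list(c(0, 10), c(20, 30), c(40, 50)),
                   neglog = c(1.0001, 1, 3))  # padj just <0.1, =0.1, 0.001
  kept <- filter_peaks_fdr(pk, 0.1)
  expect_setequal(kept$name, c("pk1", "pk3"))
})
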