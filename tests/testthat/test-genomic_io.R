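test_that("peak tables parse, convert significance and report bad lines", {
  f <- write_tmp(c("chr1\t100\t200\tpk1\t0.01",
                   "chr2\t0\t50\tpk2\t0.5"))
  p <- read_peaks(f, "tsv", padj_column = 5)
  expect_equal(p$neglog_padj, c(2, -log10(0.5)))
  expect_equal(p$start, c(100L, 0L))
  expect_equal(p$name, c("pk1", "pk2"))

  expect_error(read_peaks(write_tmp("chr1\t200\t100\tx\t0.1"), "tsv"),
               "end <= start")
  expect_error(read_peaks(write_tmp("chr1\t-5\t100\tx\t0.1"), "tsv"),
               "negative start")
  expect_error(read_peaks(write_tmp("chr1\t1\t100\tx\tfoo"), "tsv"),
               "non-numeric")
  expect_error(read_peaks(write_tmp("chr1\t1\t100\tx\t1.5"), "tsv"),
               "outside")
  err <- tryCatch(read_peaks(write_tmp(c("chr1\t1\t2\ta\t0.1",
                                         "chr1\t9\t3\tb\t0.1")), "tsv"),
                  error = conditionMessage)
  expect_match(err, "line 2")
  expect_warning(read_peaks(write_tmp("chr1\t1\t100\tx\t0"), "tsv"),
                 "clamped")
})

test_that("narrowPeak q-values are taken as -log10 directly", {
  line <- "chr1\t100\t300\tnp1\t0\t.\t5.5\t4.2\t3.25\t100"
  p <- read_peaks(write_tmp(line), "narrowpeak")
  expect_equal(p$neglog_padj, 3.25)
  expect_equal(p$name, "np1")
})

test_that("peak write/read round-trips field-for-field", {
  peaks <- test_peaks(list(c(0, 10), c(100, 2000)),
                      neglog = c(1.234567, 0.5))
  peaks$source <- "condA"
  f <- tempfile()
  write_peaks(peaks, f)
  back <- read_peaks(f, "tsv", padj_column = 5, padj_scale = "neglog10",
                     source_column = 6, header = TRUE)
  expect_equal(back, peaks)
})

test_that("gene TSS follows strand under half-open coordinates", {
  f <- write_tmp(c("chrX\t1000\t5000\tGENE1\t0\t+",
                   "chrX\t1000\t5000\tGENE2\t0\t-"))
  g <- read_genes(f, "bed6")
  expect_equal(g$tss, c(1000L, 4999L))
  expect_warning(read_genes(write_tmp("chr1\t0\t10\tG\t0\t."), "bed6"),
                 "unknown strand")
  expect_error(read_genes(write_tmp("chr1\t0\t10\tG"), "bed6"),
               "missing strand")
  expect_error(read_genes(write_tmp(c("chr1\t0\t10\tG\t0\t+",
                                      "chr1\t50\t60\tG\t0\t+")), "bed6"),
               "duplicate gene_id")
})

test_that("minimal GTF input is converted from 1-based inclusive", {
  f <- write_tmp(c(
    paste0("chr1\tsrc\tgene\t1001\t5000\t.\t+\t.\tgene_id \"GA\";"),
    paste0("chr1\tsrc\tgene\t2001\t6000\t.\t-\t.\tgene_id \"GB\";")),
    ext = ".gtf")
  g <- read_genes(f, "gtf_min")
  expect_equal(g$start, c(1000L, 2000L))
  expect_equal(g$end, c(5000L, 6000L))
  expect_equal(g$tss, c(1000L, 5999L))
})

test_that("DE tables validate ranges and drop incomplete rows", {
  f <- write_tmp(c("gene_id\tlog_fc\tlog_pv\tpadj",
                   "G1\t0.5\t2.0\t0.01",
                   "G2\tNA\t1.0\t0.5",
                   "G3\t-1\t3\t0.2"))
  expect_message(d <- read_de_table(f), "dropped 1")
  expect_equal(d$gene_id, c("G1", "G3"))
  expect_equal(d$log_fc[1], 0.5)
  expect_error(read_de_table(write_tmp(c("gene_id\tlog_fc\tlog_pv\tpadj",
                                         "G1\t1\t1\t1.5"))),
               "padj outside")
  expect_error(read_de_table(write_tmp(c("gene_id\tlfc", "G1\t1"))),
               "missing mapped column")
  expect_warning(read_de_table(write_tmp("gene_id\tlog_fc\tlog_pv\tpadj")),
                 "empty")
})

test_that("GMT, ranked lists and segmentations round-trip", {
  sets <- list(SetA = c("P1", "P2", "P3"), SetB = c("P2", "P9"))
  f <- tempfile()
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)

  ids <- sprintf("G%02d", sample(20))
  f2 <- tempfile()
  write_ranked_list(ids, f2)
  expect_equal(read_ranked_list(f2), ids)

  seg <- data.frame(chrom = "chr1", start = c(0L, 5000L),
                    end = c(5000L, 9000L),
                    state = c("Promoter", "Quiescent"),
                    stringsAsFactors = FALSE)
  f3 <- tempfile()
  write_state_segments(seg, f3)
  expect_equal(read_state_segments(f3), seg)
  bad <- seg; bad$start[2] <- 4000L
  f4 <- tempfile(); write_state_segments(bad, f4)
  expect_error(read_state_segments(f4), "overlapping")
})

test_that("expression matrices and NES tables read back", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(sprintf("S%d", 1:4), c("A", "B", "C")))
  f <- tempfile()
  write_expression_matrix(m, f)
  expect_equal(read_expression_matrix(f), m)

  f2 <- write_tmp(c("term\tNES\tbackground", "HALLMARK_X\t2.1\tmock",
                    "HALLMARK_Y\t-1.3\tmock"))
  nes <- read_nes_table(f2)
  expect_equal(nes$nes, c(2.1, -1.3))
  f3 <- write_tmp(c("term\tNES\tbackground", "T1\t1\tm", "T1\t2\tm"))
  expect_error(read_nes_table(f3), "duplicate")
})
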