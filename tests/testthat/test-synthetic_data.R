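test_that("configs validate their fields", {
  expect_s3_class(sim_config(), "ct_sim_config")
  expect_error(sim_config(coupling = 1.2), "in \\[0,1\\]")
  expect_error(sim_config(frac_antagonistic = -0.1), "in \\[0,1\\]")
  expect_error(sim_config(chrom_len = 150000, window = 100000),
               "twice the annotation window")
  expect_error(sim_config(n_samples = 2), "positive")
})

test_that("generators are pure functions of the config", {
  cfg <- sim_config(seed = 9)
  expect_identical(make_genome_and_genes(cfg), make_genome_and_genes(cfg))
  gg <- make_genome_and_genes(cfg)
  expect_identical(make_coupled_peaks_and_de(gg$genes, cfg),
                   make_coupled_peaks_and_de(gg$genes, cfg))
  expect_identical(make_paired_contrasts(gg$genes, cfg),
                   make_paired_contrasts(gg$genes, cfg))
  expect_identical(make_expression_matrix(cfg),
                   make_expression_matrix(cfg))
  expect_identical(make_ranked_lists(cfg), make_ranked_lists(cfg))
  expect_identical(make_state_segments(cfg), make_state_segments(cfg))
  # a different seed changes the draw
  expect_false(identical(make_genome_and_genes(sim_config(seed = 10)),
                         gg))
})

test_that("gene catalogs respect placement bounds and distinct TSSs", {
  cfg <- sim_config(seed = 9, n_genes = 200, n_chrom = 3)
  gg <- make_genome_and_genes(cfg)
  g <- gg$genes
  expect_equal(nrow(g), 200L)
  expect_true(all(g$tss >= 0 & g$tss < cfg$chrom_len))
  expect_true(all(g$end <= cfg$chrom_len))
  expect_false(anyDuplicated(g[, c("chrom", "tss")]) > 0)
  expect_true(all(g$tss >= g$start & g$tss < g$end))
  expect_equal(nrow(make_genome_and_genes(
    sim_config(seed = 1, n_genes = 0))$genes), 0L)
})

test_that("coupled peaks land near boosted targets and all pass FDR", {
  cfg <- sim_config(seed = 9)
  gg <- make_genome_and_genes(cfg)
  cp <- make_coupled_peaks_and_de(gg$genes, cfg)
  expect_equal(nrow(cp$peaks), cfg$n_peaks)
  expect_true(all(10^(-cp$peaks$neglog_padj) < 0.1))
  expect_equal(nrow(filter_peaks_fdr(cp$peaks, 0.1)), cfg$n_peaks)
  # every coupled gene has at least one peak within the window
  links <- annotate_peaks_to_genes(cp$peaks, gg$genes, cfg$window)
  coupled <- cp$truth$gene_id[cp$truth$is_coupled]
  expect_true(all(coupled %in% links$gene_id))
  expect_true(all(coupled %in% cp$truth$gene_id[cp$truth$is_target]))
  # coupled genes are up-regulated with the planted bonus
  degs <- cp$degs
  expect_true(all(degs$log_fc[degs$gene_id %in% coupled] >=
                    cfg$effect_fc))
  # coupling = 0 plants nothing
  cp0 <- make_coupled_peaks_and_de(gg$genes,
                                   sim_config(seed = 9, coupling = 0))
  expect_equal(sum(cp0$truth$is_coupled), 0L)
})

test_that("paired contrasts plant the antagonism labels as a partition", {
  cfg <- sim_config(seed = 9)
  gg <- make_genome_and_genes(cfg)
  pc <- make_paired_contrasts(gg$genes, cfg, n_shared = 150)
  expect_equal(sum(pc$truth$shared), 150L)
  expect_equal(sum(pc$truth$antagonistic), round(0.3 * 150))
  expect_true(all(pc$truth$shared[pc$truth$antagonistic]))
  thr <- de_thresholds("rna")
  sig_a <- filter_de(pc$contrast_a, thr[1], thr[2])$gene_id
  sig_b <- filter_de(pc$contrast_b, thr[1], thr[2])$gene_id
  expect_setequal(intersect(sig_a, sig_b),
                  pc$truth$gene_id[pc$truth$shared])
})

test_that("latent-factor matrices carry their analytic correlations", {
  cfg <- sim_config(seed = 9, n_samples = 50)
  em <- make_expression_matrix(cfg)
  expect_equal(dim(em$expr), c(50L, 2L + cfg$n_expr_targets))
  expect_equal(colnames(em$expr)[1:2], c("REG", "COREG"))
  an <- em$analytic
  expect_equal(an$delta, an$r_marginal - an$r_partial)
  # lambda = 0 decouples the coregulator exactly
  expect_equal(make_expression_matrix(
    sim_config(seed = 9, confounder_loading = 0))$analytic$delta, 0)
})

test_that("ranked lists plant an exact top-k overlap", {
  for (ov in c(0, 0.5, 1)) {
    rl <- make_ranked_lists(sim_config(seed = 9, top_k_overlap = ov))
    k <- rl$truth$k
    inter <- length(intersect(rl$list_a[1:k], rl$list_b[1:k]))
    expect_equal(inter, round(ov * k))
    expect_setequal(rl$list_a, rl$list_b)  # same universe, reordered
  }
  expect_error(make_ranked_lists(sim_config(seed = 1, n_genes = 120)),
               "too small")
})

test_that("fixture directories are readable by the package's own readers", {
  cfg <- sim_config(seed = 11)
  dir <- file.path(tempdir(), "fixture-test")
  man <- simulate_fixture(cfg, dir)
  expect_true(all(file.exists(unlist(man))))
  gg <- make_genome_and_genes(cfg)
  expect_equal(read_genes(man$genes, "bed6"), gg$genes)
  cp <- make_coupled_peaks_and_de(gg$genes, cfg)
  back <- read_peaks(man$peaks, "tsv", padj_column = 5,
                     padj_scale = "neglog10", source_column = 6,
                     header = TRUE)
  expect_equal(back, cp$peaks)
  expect_equal(read_de_table(man$de), cp$degs)
  seg <- read_state_segments(man$segments)
  expect_gt(nrow(seg), 0)
  truth <- jsonlite::read_json(man$truth)
  expect_equal(unlist(truth$ranked$expected_jaccard), 1 / 3)
})
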