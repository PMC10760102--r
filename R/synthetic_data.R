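# Seeded synthetic-data generators. Each generator plants a known effect
# (peak-to-gene coupling, antagonism fraction, latent confounder, top-k
# rank overlap) and emits truth labels alongside the data, so downstream
# stages are validated by parameter recovery rather than by distributional
# realism. Every generator is a pure function of the config: one global
# seed, with a fixed per-generator offset defining its substream.

SEED_OFFSETS <- c(genome = 101L, coupled = 202L, contrasts = 303L,
                  expression = 404L, ranked = 505L, segments = 606L)

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults are the package's reference study conditions: 300 genes and
#' 600 peaks on two 10 Mb chromosomes, 90% of peaks coupled to target
#' genes with a +1.0 mean |log2 FC| bonus, a 0.3 antagonism fraction over
#' a 200-gene shared set, latent-factor loadings of 0.5, 293 expression
#' samples, and a 50% planted overlap of two top-100 ranked lists.
#'
#' @param seed integer RNG seed; per-generator substreams are derived from
#'   it deterministically.
#' @param n_chrom,chrom_len chromosome count and length (bases);
#'   `chrom_len` must exceed twice the annotation `window`.
#' @param n_genes,n_peaks catalog sizes.
#' @param coupling fraction of peaks placed within `window` of target-gene
#'   TSSs.
#' @param effect_fc mean |log2 fold change| bonus for coupled genes.
#' @param frac_targets fraction of genes designated as targets.
#' @param frac_antagonistic fraction of shared significant genes given
#'   opposite-sign regulation across the two paired contrasts.
#' @param confounder_loading loading of the latent factor on the
#'   coregulator column of the expression model.
#' @param loading_regulator,loading_target_reg,loading_target_conf the
#'   `a`, `b`, `c` loadings of the latent-factor model (see
#'   [make_expression_matrix()]).
#' @param n_samples expression-matrix sample count.
#' @param n_expr_targets number of target-gene columns in the expression
#'   matrix.
#' @param top_k_overlap planted overlap fraction of the two ranked lists'
#'   top-`k_top` sets.
#' @param k_top rank cutoff of the planted overlap.
#' @param peak_width simulated peak width (bases).
#' @param window annotation window (bases), default 100 kb.
#' @return validated list of class `ct_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 1e7,
                       n_genes = 300L, n_peaks = 600L,
                       coupling = 0.9, effect_fc = 1.0,
                       frac_targets = 0.5, frac_antagonistic = 0.3,
                       confounder_loading = 0.5,
                       loading_regulator = 0.5,
                       loading_target_reg = 0.5,
                       loading_target_conf = 0.5,
                       n_samples = 293L, n_expr_targets = 20L,
                       top_k_overlap = 0.5, k_top = 100L,
                       peak_width = 500L, window = 100000L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = chrom_len, n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks), coupling = coupling,
              effect_fc = effect_fc, frac_targets = frac_targets,
              frac_antagonistic = frac_antagonistic,
              confounder_loading = confounder_loading,
              loading_regulator = loading_regulator,
              loading_target_reg = loading_target_reg,
              loading_target_conf = loading_target_conf,
              n_samples = as.integer(n_samples),
              n_expr_targets = as.integer(n_expr_targets),
              top_k_overlap = top_k_overlap, k_top = as.integer(k_top),
              peak_width = as.integer(peak_width), window = window)
  fracs <- c(coupling = coupling, frac_targets = frac_targets,
             frac_antagonistic = frac_antagonistic,
             top_k_overlap = top_k_overlap)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) ct_stop(names(fracs)[bad][1], " must be in [0,1]")
  if (n_chrom < 1 || n_peaks < 0 || n_genes < 0 || n_samples < 3 ||
      n_expr_targets < 1 || k_top < 1 || peak_width < 1)
    ct_stop("counts must be positive")
  if (chrom_len <= 2 * window)
    ct_stop("chrom_len must exceed twice the annotation window")
  if (effect_fc < 0) ct_stop("effect_fc must be >= 0")
  structure(cfg, class = "ct_sim_config")
}

sub_seed <- function(cfg, stream) {
  set.seed(cfg$seed + SEED_OFFSETS[[stream]])
}

#' Simulate a genome and gene catalog
#'
#' Gene starts are uniform (without replacement, so TSSs are distinct) on
#' each chromosome, lengths uniform on 1-10 kb, strands random.
#' Deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (gene data.frame as from [read_genes()]) and
#'   `chrom_sizes` (named vector).
#' @export
make_genome_and_genes <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  sub_seed(cfg, "genome")
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms)
  if (cfg$n_genes == 0)
    return(list(genes = data.frame(gene_id = character(),
                                   chrom = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   tss = integer(),
                                   stringsAsFactors = FALSE),
                chrom_sizes = chrom_sizes))
  len_max <- 10000L
  gene_chrom <- chroms[1L + (seq_len(cfg$n_genes) - 1L) %% cfg$n_chrom]
  per_chrom <- table(gene_chrom)
  capacity <- floor(cfg$chrom_len - len_max - 1)
  if (any(per_chrom > capacity))
    ct_stop("n_genes exceeds placeable capacity")
  starts <- integer(cfg$n_genes)
  for (ch in chroms) {
    i <- which(gene_chrom == ch)
    starts[i] <- sample.int(capacity, length(i))  # distinct per chrom
  }
  lens <- sample(1000:len_max, cfg$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                      chrom = gene_chrom, start = starts,
                      end = starts + lens, strand = strand,
                      tss = as.integer(ifelse(strand == "+", starts,
                                              starts + lens - 1L)),
                      stringsAsFactors = FALSE)
  # minus-strand TSSs could coincide with another gene's; nudge duplicates
  while (anyDuplicated(genes[, c("chrom", "tss")])) {
    d <- which(duplicated(genes[, c("chrom", "tss")]))
    genes$start[d] <- genes$start[d] + 1L
    genes$end[d] <- genes$end[d] + 1L
    genes$tss[d] <- genes$tss[d] + 1L
  }
  stopifnot(all(genes$tss >= 0 & genes$tss < cfg$chrom_len))
  list(genes = genes, chrom_sizes = chrom_sizes)
}

#' Simulate peaks coupled to up-regulated genes, with matching DE table
#'
#' A fraction `coupling` of the peaks is placed within the annotation
#' window of the TSS of a randomly chosen designated target gene; the
#' remaining peaks are uniform on the genome. Target genes that receive at
#' least one coupled peak ("coupled genes") are up-regulated: their
#' `log_fc` is `|N(0, 0.5)| + effect_fc`; all other genes get
#' `N(0, 0.5)`. `log_pv` is a deterministic function of `|log_fc|` (a
#' two-sided Gaussian tail on the same noise scale), so under
#' `coupling = 0` targets and non-targets are exchangeable. Peak
#' significance is drawn as `neglog_padj = 1 + Exp(1)`, so every simulated
#' region passes FDR < 0.1.
#'
#' @param genes gene data.frame from [make_genome_and_genes()].
#' @param cfg a [sim_config()].
#' @return list with `peaks`, `degs` and `truth` (data.frame `gene_id`,
#'   `is_target`, `is_coupled`).
#' @export
make_coupled_peaks_and_de <- function(genes, cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  if (!nrow(genes)) ct_stop("genes must be non-empty")
  sub_seed(cfg, "coupled")
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  half <- floor(cfg$peak_width / 2)
  n_coupled <- round(cfg$coupling * cfg$n_peaks)
  n_targets <- max(1L, round(cfg$frac_targets * nrow(genes)))
  target_ids <- sort(sample(genes$gene_id, n_targets))
  clamp_mid <- function(mid) pmin(pmax(mid, half),
                                  cfg$chrom_len - (cfg$peak_width - half))
  peak_chrom <- character(cfg$n_peaks)
  mid <- numeric(cfg$n_peaks)
  if (n_coupled > 0) {
    anchor <- sample(target_ids, n_coupled, replace = TRUE)
    gi <- match(anchor, genes$gene_id)
    peak_chrom[seq_len(n_coupled)] <- genes$chrom[gi]
    offs <- round(stats::runif(n_coupled, -cfg$window, cfg$window))
    mid[seq_len(n_coupled)] <- clamp_mid(genes$tss[gi] + offs)
  }
  if (n_coupled < cfg$n_peaks) {
    i <- (n_coupled + 1):cfg$n_peaks
    peak_chrom[i] <- sample(chroms, length(i), replace = TRUE)
    mid[i] <- clamp_mid(round(stats::runif(length(i), 0, cfg$chrom_len)))
  }
  peaks <- data.frame(chrom = peak_chrom,
                      start = as.integer(mid - half),
                      end = as.integer(mid - half + cfg$peak_width),
                      name = sprintf("peak_%04d", seq_len(cfg$n_peaks)),
                      neglog_padj = 1 + stats::rexp(cfg$n_peaks, rate = 1),
                      source = "sim",
                      stringsAsFactors = FALSE)
  validate_peaks(peaks)
  coupled_ids <- if (n_coupled > 0) sort(unique(anchor)) else character(0)
  base_fc <- stats::rnorm(nrow(genes), 0, 0.5)
  is_coupled <- genes$gene_id %in% coupled_ids
  log_fc <- ifelse(is_coupled, abs(base_fc) + cfg$effect_fc, base_fc)
  log_pv <- -log10(pmax(2 * stats::pnorm(-abs(log_fc) / 0.5),
                        .Machine$double.xmin))
  degs <- data.frame(gene_id = genes$gene_id, log_fc = log_fc,
                     log_pv = log_pv,
                     padj = pmin(1, 10^(-log_pv)),
                     stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes$gene_id,
                      is_target = genes$gene_id %in% target_ids,
                      is_coupled = is_coupled,
                      stringsAsFactors = FALSE)
  list(peaks = peaks, degs = degs, truth = truth)
}

#' Simulate two paired DE contrasts with a planted antagonism fraction
#'
#' A shared set of `n_shared` genes is made significant in both contrasts;
#' exactly `round(frac_antagonistic * n_shared)` of them get opposite
#' fold-change signs in contrast B, the rest the same sign. Non-shared
#' genes are left non-significant in at least one contrast, so the
#' concordance stage must recover the planted counts exactly.
#'
#' @param genes gene data.frame.
#' @param cfg a [sim_config()].
#' @param n_shared size of the both-significant gene set; defaults to
#'   two thirds of the catalog (200 genes under the default config).
#' @return list with `contrast_a`, `contrast_b` (DEG data.frames) and
#'   `truth` (data.frame `gene_id`, `shared`, `antagonistic`).
#' @export
make_paired_contrasts <- function(genes, cfg,
                                  n_shared = round(2 / 3 * nrow(genes))) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  n <- nrow(genes)
  if (!n) ct_stop("genes must be non-empty")
  if (n_shared > n) ct_stop("n_shared exceeds the catalog")
  sub_seed(cfg, "contrasts")
  ids <- genes$gene_id
  shared <- sort(sample(ids, n_shared))
  n_ant <- round(cfg$frac_antagonistic * n_shared)
  antag <- if (n_ant > 0) sort(sample(shared, n_ant)) else character(0)
  sig_fc <- function(m) sample(c(-1, 1), m, TRUE) * stats::runif(m, 0.5, 2)
  sig_pv <- function(m) stats::runif(m, 1.5, 4)
  dull_fc <- function(m) stats::runif(m, -0.2, 0.2)
  dull_pv <- function(m) stats::runif(m, 0, 0.8)
  is_shared <- ids %in% shared
  fc_a <- ifelse(is_shared, 0, dull_fc(n))
  fc_a[is_shared] <- sig_fc(sum(is_shared))
  pv_a <- ifelse(is_shared, sig_pv(n), dull_pv(n))
  fc_b <- numeric(n)
  mag_b <- stats::runif(n, 0.5, 2)
  flip <- ids %in% antag
  fc_b[is_shared] <- sign(fc_a[is_shared]) * mag_b[is_shared] *
    ifelse(flip[is_shared], -1, 1)
  fc_b[!is_shared] <- dull_fc(sum(!is_shared))
  pv_b <- ifelse(is_shared, sig_pv(n), dull_pv(n))
  mk <- function(fc, pv) data.frame(gene_id = ids, log_fc = fc,
                                    log_pv = pv,
                                    padj = pmin(1, 10^(-pv)),
                                    stringsAsFactors = FALSE)
  list(contrast_a = mk(fc_a, pv_a), contrast_b = mk(fc_b, pv_b),
       truth = data.frame(gene_id = ids, shared = is_shared,
                          antagonistic = flip,
                          stringsAsFactors = FALSE))
}

#' Analytic correlations of the latent-factor expression model
#'
#' Closed-form population correlations of the model used by
#' [make_expression_matrix()]: with latent factor `F ~ N(0,1)` and unit
#' noises, `coregulator = lambda F + e`, `regulator = a F + e`,
#' `target = b regulator + c F + e`. Returns the regulator-target marginal
#' correlation, the first-order partial correlation given the coregulator,
#' and their difference (the population delta.corr).
#'
#' @param a,b,c,lambda loadings.
#' @return list `r_marginal`, `r_partial`, `delta`.
#' @export
latent_factor_correlations <- function(a, b, c, lambda) {
  v_reg <- a^2 + 1
  load_t <- a * b + c
  v_tgt <- load_t^2 + b^2 + 1
  v_cor <- lambda^2 + 1
  r_rt <- (a * load_t + b) / sqrt(v_reg * v_tgt)
  r_rc <- (a * lambda) / sqrt(v_reg * v_cor)
  r_tc <- (load_t * lambda) / sqrt(v_tgt * v_cor)
  r_part <- partial_cor_from_r(r_rt, r_rc, r_tc)
  list(r_marginal = r_rt, r_partial = r_part, delta = r_rt - r_part)
}

#' Simulate an expression matrix with a planted confounder
#'
#' Latent-factor model (see [latent_factor_correlations()] for the
#' analytic covariance): one regulator column (`REG`), one coregulator
#' column (`COREG`) loading on the same latent factor with loading
#' `confounder_loading`, and `n_expr_targets` target columns driven by the
#' regulator and the factor. All noises are standard Gaussian.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (samples x genes matrix), `regulator`,
#'   `coregulator`, `targets` (column names) and `analytic` (the
#'   population `r_marginal`, `r_partial`, `delta`).
#' @export
make_expression_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  sub_seed(cfg, "expression")
  n <- cfg$n_samples
  a <- cfg$loading_regulator
  b <- cfg$loading_target_reg
  cc <- cfg$loading_target_conf
  lambda <- cfg$confounder_loading
  f <- stats::rnorm(n)
  coreg <- lambda * f + stats::rnorm(n)
  reg <- a * f + stats::rnorm(n)
  tgt <- vapply(seq_len(cfg$n_expr_targets), function(j)
    b * reg + cc * f + stats::rnorm(n), numeric(n))
  targets <- sprintf("T%03d", seq_len(cfg$n_expr_targets))
  expr <- cbind(REG = reg, COREG = coreg, tgt)
  colnames(expr) <- c("REG", "COREG", targets)
  rownames(expr) <- sprintf("S%04d", seq_len(n))
  list(expr = expr, regulator = "REG", coregulator = "COREG",
       targets = targets,
       analytic = latent_factor_correlations(a, b, cc, lambda))
}

#' Simulate two ranked gene lists with a planted top-k overlap
#'
#' The top-`k_top` of list B contains exactly
#' `round(top_k_overlap * k_top)` members of the top-`k_top` of list A;
#' the remainder of each list is shuffled. The planted top-k Jaccard is
#' therefore `m / (2k - m)` with `m` the planted overlap count.
#'
#' @param cfg a [sim_config()]; requires
#'   `n_genes >= 2 k_top - round(top_k_overlap * k_top)`.
#' @return list with `list_a`, `list_b` and `truth` (`k`, `n_overlap`,
#'   `expected_jaccard`).
#' @export
make_ranked_lists <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  sub_seed(cfg, "ranked")
  k <- cfg$k_top
  m <- round(cfg$top_k_overlap * k)
  n <- cfg$n_genes
  if (n < 2 * k - m)
    ct_stop("n_genes too small for the requested top-k overlap")
  ids <- sprintf("G%04d", seq_len(n))
  list_a <- sample(ids)
  top_a <- list_a[seq_len(k)]
  keep <- if (m > 0) sample(top_a, m) else character(0)
  fill <- if (k - m > 0) sample(setdiff(ids, top_a), k - m)
          else character(0)
  top_b <- sample(c(keep, fill))
  list_b <- c(top_b, sample(setdiff(ids, top_b)))
  list(list_a = list_a, list_b = list_b,
       truth = list(k = k, n_overlap = m,
                    expected_jaccard = m / (2 * k - m)))
}

#' Simulate a chromatin-state segmentation
#'
#' Tiles each chromosome with non-overlapping segments of 5-50 kb labelled
#' with generic regulatory states; roughly a tenth of the genome is left
#' unsegmented so the `"unassigned"` stratum is exercised.
#'
#' @param cfg a [sim_config()].
#' @return segment data.frame (`chrom`, `start`, `end`, `state`).
#' @export
make_state_segments <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  sub_seed(cfg, "segments")
  states <- c("Active Enhancer", "Promoter", "Transcribed", "Quiescent")
  out <- list()
  for (ch in sprintf("chr%d", seq_len(cfg$n_chrom))) {
    pos <- 0
    rows <- list()
    while (pos < cfg$chrom_len) {
      len <- sample(5000:50000, 1)
      end <- min(pos + len, cfg$chrom_len)
      if (stats::runif(1) > 0.1)  # leave occasional gaps unannotated
        rows[[length(rows) + 1]] <-
          data.frame(chrom = ch, start = as.integer(pos),
                     end = as.integer(end),
                     state = sample(states, 1),
                     stringsAsFactors = FALSE)
      pos <- end
    }
    out[[ch]] <- do.call(rbind, rows)
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  assert_nonoverlapping(seg)
  seg
}

#' Write a self-contained synthetic fixture directory
#'
#' Runs every generator under one config and writes the results in the
#' same formats the readers consume, plus a `truth.json` with the planted
#' parameters and labels and a `chrom_sizes.tsv`. The directory is a valid
#' input manifest for [run_pipeline()].
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest: a named list of the file paths.
#' @export
simulate_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gg <- make_genome_and_genes(cfg)
  cp <- make_coupled_peaks_and_de(gg$genes, cfg)
  pc <- make_paired_contrasts(gg$genes, cfg)
  em <- make_expression_matrix(cfg)
  rl <- make_ranked_lists(cfg)
  seg <- make_state_segments(cfg)
  p <- function(f) file.path(dir, f)
  write_genes(gg$genes, p("genes.bed"))
  write.table(data.frame(chrom = names(gg$chrom_sizes),
                         size = as.integer(gg$chrom_sizes)),
              p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_peaks(cp$peaks, p("peaks.tsv"))
  write_de_table(cp$degs, p("de.tsv"))
  write_de_table(pc$contrast_a, p("contrast_a.tsv"))
  write_de_table(pc$contrast_b, p("contrast_b.tsv"))
  write_expression_matrix(em$expr, p("expr.tsv"))
  write_ranked_list(rl$list_a, p("list_a.txt"))
  write_ranked_list(rl$list_b, p("list_b.txt"))
  write_state_segments(seg, p("segments.bed"))
  truth <- list(config = unclass(cfg),
                target_genes = cp$truth$gene_id[cp$truth$is_target],
                coupled_genes = cp$truth$gene_id[cp$truth$is_coupled],
                shared_genes = pc$truth$gene_id[pc$truth$shared],
                antagonistic_genes =
                  pc$truth$gene_id[pc$truth$antagonistic],
                expression = list(regulator = em$regulator,
                                  coregulator = em$coregulator,
                                  targets = em$targets,
                                  analytic = em$analytic),
                ranked = rl$truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(genes = p("genes.bed"),
                   chrom_sizes = p("chrom_sizes.tsv"),
                   peaks = p("peaks.tsv"), de = p("de.tsv"),
                   contrast_a = p("contrast_a.tsv"),
                   contrast_b = p("contrast_b.tsv"),
                   expr = p("expr.tsv"), list_a = p("list_a.txt"),
                   list_b = p("list_b.txt"), segments = p("segments.bed"),
                   truth = p("truth.json"))
  invisible(manifest)
}
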