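# Orchestration: a single validated config object carrying every printed
# constant of the analysis (100 kb window, DEG/DEP thresholds, region FDR
# cutoff, bin size, bootstrap replicates, seed), and a run_pipeline()
# driver that executes the stages in dependency order on a file manifest.

#' Analysis configuration
#'
#' @param window peak-to-gene annotation window in bases (default 100 kb).
#' @param wtct_mode wt-C-T weighting mode, see [peak_weight()].
#' @param de_preset DEG threshold preset, see [de_thresholds()]; ignored
#'   when both thresholds are given explicitly.
#' @param log_pv_min,abs_fc_min explicit DEG thresholds (override the
#'   preset).
#' @param region_fdr_max region significance cutoff on the adjusted-p
#'   scale (default 0.1).
#' @param bin_size chi-squared overlap bin size in bases.
#' @param n_boot bootstrap replicates for the ranked-list comparison.
#' @param k_top rank cutoff for the ranked-list comparison.
#' @param state optional chromatin-state label restricting the wt-C-T
#'   cistrome.
#' @param seed integer seed applied to every stochastic stage.
#' @return validated list of class `ct_config`.
#' @export
analysis_config <- function(window = 100000L,
                            wtct_mode = c("weighted", "unweighted",
                                          "binary"),
                            de_preset = c("rna", "proteomics"),
                            log_pv_min = NULL, abs_fc_min = NULL,
                            region_fdr_max = 0.1, bin_size = 1000L,
                            n_boot = 1000L, k_top = 100L, state = NULL,
                            seed = 1L) {
  wtct_mode <- match.arg(wtct_mode)
  de_preset <- match.arg(de_preset)
  thr <- de_thresholds(de_preset)
  cfg <- list(window = window, wtct_mode = wtct_mode,
              de_preset = de_preset,
              log_pv_min = log_pv_min %||% unname(thr["log_pv_min"]),
              abs_fc_min = abs_fc_min %||% unname(thr["abs_fc_min"]),
              region_fdr_max = region_fdr_max,
              bin_size = as.integer(bin_size),
              n_boot = as.integer(n_boot), k_top = as.integer(k_top),
              state = state, seed = as.integer(seed))
  if (cfg$window <= 0) ct_stop("window must be > 0")
  if (cfg$region_fdr_max <= 0 || cfg$region_fdr_max >= 1)
    ct_stop("region_fdr_max must be in (0,1)")
  if (cfg$bin_size <= 0 || cfg$n_boot < 1 || cfg$k_top < 1)
    ct_stop("bin_size, n_boot and k_top must be positive")
  if (cfg$log_pv_min < 0 || cfg$abs_fc_min < 0)
    ct_stop("thresholds must be >= 0")
  structure(cfg, class = "ct_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) ct_stop("unknown config key(s): ",
                               paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.ct_config <- function(x, ...) {
  cat("cistromeCT analysis configuration\n")
  cat("  window =", x$window, "bp, wt-C-T mode =", x$wtct_mode, "\n")
  cat("  DEG rule: logPV >", x$log_pv_min, "& |FC| >", x$abs_fc_min,
      "(preset", x$de_preset, ")\n")
  cat("  region FDR <", x$region_fdr_max, ", bin size =", x$bin_size,
      "bp\n")
  cat("  n_boot =", x$n_boot, ", k_top =", x$k_top, ", seed =", x$seed,
      "\n")
  invisible(x)
}

read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    ct_stop("stage '", name, "': ", conditionMessage(e)))
}

#' Run the integrative pipeline on a file manifest
#'
#' Executes every stage whose inputs are present in the manifest and
#' writes one headered TSV per stage plus a `run.log` recording the
#' thresholds actually applied and the config hash; re-running with the
#' same inputs and config is byte-identical.
#'
#' Stages and the manifest keys they require:
#' \describe{
#'   \item{wtct}{`peaks`, `genes`, `de` (optionally `peaks_b`, `de_b` for
#'     a second background, then the Wilcoxon comparison is also run;
#'     optionally `segments` with `config$state`): region FDR filter,
#'     annotation, scoring, comparison.}
#'   \item{overlap}{`peaks`, `peaks_b`, `chrom_sizes`: shared/unique
#'     counts and the binned chi-squared test.}
#'   \item{concord}{`contrast_a`, `contrast_b`: concordance calls and
#'     summary.}
#'   \item{enrich}{`members`, `gene_sets` (GMT), optional `universe`
#'     (defaults to the union of all set members and the member list).}
#'   \item{assoc}{`expr`, `regulator`, `targets_file`, `coregulator`:
#'     delta.corr per coregulator.}
#'   \item{jaccard}{`list_a`, `list_b`: bootstrap Jaccard at
#'     `config$k_top`.}
#' }
#'
#' @param inputs named list of file paths (and the scalar keys
#'   `regulator`, `coregulator`).
#' @param config a [analysis_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named list of the output paths.
#' @export
run_pipeline <- function(inputs, config = analysis_config(), out_dir) {
  stopifnot(inherits(config, "ct_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  outputs <- list()
  log_lines <- c("cistromeCT run",
           paste0("config: window=", config$window,
                  " mode=", config$wtct_mode,
                  " logPV>", config$log_pv_min,
                  " |FC|>", config$abs_fc_min,
                  " regionFDR<", config$region_fdr_max,
                  " bin=", config$bin_size,
                  " n_boot=", config$n_boot,
                  " k_top=", config$k_top,
                  " seed=", config$seed))
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_lines <- c(log_lines, paste0("config_hash: ",
                       unname(tools::md5sum(cfg_json))))
  need <- function(keys) all(keys %in% names(inputs))
  req_file <- function(key) {
    if (!key %in% names(inputs))
      ct_stop("missing input '", key, "'")
    if (!file.exists(inputs[[key]]))
      ct_stop("input file not found: ", inputs[[key]])
    inputs[[key]]
  }
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- path
    path
  }

  if (need("genes") || need("de")) {
    run_stage("wtct", {
      genes <- read_genes(req_file("genes"), "bed6")
      segments <- if (!is.null(config$state))
        read_state_segments(req_file("segments")) else NULL
      score_bg <- function(peak_key, de_key, label) {
        peaks <- filter_peaks_fdr(
          read_peaks(req_file(peak_key), "tsv", padj_column = 5,
                     padj_scale = "neglog10", source_column = 6,
                     header = TRUE),
          config$region_fdr_max)
        degs <- read_de_table(req_file(de_key))
        wtct_table(peaks, genes, degs, window = config$window,
                   mode = config$wtct_mode, background = label,
                   state = config$state, segments = segments)
      }
      scores_a <- score_bg("peaks", "de", "background_a")
      emit("wtct_scores_a", scores_a)
      log_lines <- c(log_lines, paste0("stage wtct: scored ", nrow(scores_a),
                            " genes (background_a)"))
      if (need(c("peaks_b", "de_b"))) {
        scores_b <- score_bg("peaks_b", "de_b", "background_b")
        emit("wtct_scores_b", scores_b)
        cmp <- compare_wtct(scores_a, scores_b)
        emit("wtct_comparison",
             data.frame(background_a = "background_a",
                        background_b = "background_b",
                        n_a = cmp$n_a, n_b = cmp$n_b,
                        statistic = cmp$statistic, p = cmp$p,
                        direction = cmp$direction))
        log_lines <- c(log_lines, sprintf("stage wtct: Wilcoxon p = %.6g", cmp$p))
      }
    })
  }

  if (need(c("peaks", "peaks_b", "chrom_sizes"))) {
    run_stage("overlap", {
      a <- read_peaks(req_file("peaks"), "tsv", padj_column = 5,
                      padj_scale = "neglog10", source_column = 6,
                      header = TRUE)
      b <- read_peaks(req_file("peaks_b"), "tsv", padj_column = 5,
                      padj_scale = "neglog10", source_column = 6,
                      header = TRUE)
      sizes <- read_chrom_sizes(req_file("chrom_sizes"))
      xs <- intersect_peak_sets(a, b)
      ov <- overlap_chi2(a, b, sizes, config$bin_size)
      emit("overlap",
           data.frame(shared_a = xs$shared_a, unique_a = xs$unique_a,
                      shared_b = xs$shared_b, unique_b = xs$unique_b,
                      both = ov$both, a_only = ov$a_only,
                      b_only = ov$b_only, neither = ov$neither,
                      chi2 = ov$chi2, p = ov$p))
      log_lines <- c(log_lines, sprintf("stage overlap: chi2 = %.6g, p = %.6g",
                             ov$chi2, ov$p))
    })
  }

  if (need("contrast_a") || need("contrast_b")) {
    run_stage("concord", {
      cs <- concordance_summary(read_de_table(req_file("contrast_a")),
                                read_de_table(req_file("contrast_b")),
                                config$log_pv_min, config$abs_fc_min)
      emit("concordance_calls", cs$calls)
      emit("concordance_summary",
           data.frame(cooperative = cs$counts[["cooperative"]],
                      antagonistic = cs$counts[["antagonistic"]],
                      unclassified = cs$counts[["unclassified"]],
                      n_union = cs$n_union,
                      antagonistic_fraction_union =
                        cs$antagonistic_fraction_union,
                      antagonistic_fraction_both_sig =
                        cs$antagonistic_fraction_both_sig))
      log_lines <- c(log_lines, paste0("stage concord: ",
                            cs$counts[["antagonistic"]],
                            " antagonistic of ", cs$n_union, " genes"))
    })
  }

  if (need("members") || need("gene_sets")) {
    run_stage("enrich", {
      members <- read_ranked_list(req_file("members"))
      sets <- read_gmt(req_file("gene_sets"))
      universe <- if (need("universe"))
        read_ranked_list(req_file("universe"))
      else unique(c(members, unlist(sets)))
      emit("enrichment", hypergeom_enrichment(members, sets, universe))
      log_lines <- c(log_lines, paste0("stage enrich: ", length(sets),
                            " sets against universe of ",
                            length(universe)))
    })
  }

  if (need("expr")) {
    run_stage("assoc", {
      for (key in c("regulator", "targets_file", "coregulator"))
        if (!key %in% names(inputs)) ct_stop("missing input '", key, "'")
      expr <- read_expression_matrix(req_file("expr"))
      targets <- read_ranked_list(req_file("targets_file"))
      dc <- delta_corr(expr, inputs$regulator, targets,
                       inputs$coregulator)
      emit("delta_corr",
           data.frame(coregulator = dc$coregulator, r_mean = dc$r_mean,
                      r_partial_mean = dc$r_partial_mean,
                      delta = dc$delta))
      emit("delta_corr_per_gene", dc$per_gene)
      log_lines <- c(log_lines, sprintf("stage assoc: delta.corr = %.6g", dc$delta))
    })
  }

  if (need("list_a") || need("list_b")) {
    run_stage("jaccard", {
      jb <- ranked_jaccard_boot(read_ranked_list(req_file("list_a")),
                                read_ranked_list(req_file("list_b")),
                                k = config$k_top,
                                n_boot = config$n_boot,
                                seed = config$seed)
      emit("jaccard",
           data.frame(k = jb$k, jaccard = jb$jaccard,
                      n_boot = jb$n_boot, p = jb$p))
      log_lines <- c(log_lines, sprintf("stage jaccard: J = %.6g, p = %.6g",
                             jb$jaccard, jb$p))
    })
  }

  if (!length(outputs))
    ct_stop("manifest enables no stage (check input keys)")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  outputs$run_log <- file.path(out_dir, "run.log")
  outputs$config <- cfg_json
  invisible(outputs)
}
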