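# The weighted cistrome-transcriptome (wt-C-T) score: for each gene, the
# summed significance (-log10 adjusted p) of peaks within a window of its
# TSS, optionally distance-weighted, multiplied by the gene's absolute
# log fold change. Score distributions from two cell backgrounds are then
# compared with a Wilcoxon rank-sum test.

#' Distance weight of a peak relative to a gene TSS
#'
#' Three weighting modes for the proximal-versus-distal peak distribution:
#' \describe{
#'   \item{`unweighted`}{every in-window peak weighs 1.}
#'   \item{`weighted`}{regulatory-potential exponential decay
#'     `exp(-(0.5 + 4 d / window))`, so a peak at the TSS weighs
#'     `exp(-0.5) ~ 0.607` and one at the window edge `exp(-4.5) ~ 0.011`.}
#'   \item{`binary`}{proximal peaks (`d <= proximal`) weigh 1, distal
#'     peaks 0.5 — a coarse two-level reading of proximal-versus-distal.}
#' }
#'
#' @param distance midpoint-to-TSS distance(s) in bases, `0 <= d <= window`.
#' @param mode `"weighted"` (default), `"unweighted"` or `"binary"`.
#' @param window annotation window in bases.
#' @param proximal proximal cutoff for `binary` mode (default 10 kb).
#' @return numeric weights in (0, 1].
#' @export
peak_weight <- function(distance, mode = c("weighted", "unweighted",
                                           "binary"),
                        window = 100000L, proximal = 10000L) {
  mode <- match.arg(mode)
  if (any(distance < 0)) ct_stop("negative distance")
  if (any(distance > window)) ct_stop("distance exceeds window")
  switch(mode,
         unweighted = rep(1, length(distance)),
         weighted = exp(-(0.5 + 4 * distance / window)),
         binary = ifelse(distance <= proximal, 1, 0.5))
}

#' wt-C-T score of a single gene
#'
#' `score = (sum_i weight_i * neglog_padj_i) * |log_fc|` over the gene's
#' peak links. Exposed mainly for auditing; [wtct_table()] computes all
#' genes at once.
#'
#' @param links link data.frame for one gene (from
#'   [annotate_peaks_to_genes()]).
#' @param peaks peak data.frame the links refer to.
#' @param deg one-row DEG record for the gene.
#' @param mode weighting mode, see [peak_weight()].
#' @param window annotation window in bases.
#' @return one-row `WtCTScore` data.frame (`gene_id`, `score`,
#'   `background`, `mode`).
#' @export
wtct_gene_score <- function(links, peaks, deg,
                            mode = c("weighted", "unweighted", "binary"),
                            window = 100000L) {
  mode <- match.arg(mode)
  stopifnot(nrow(deg) == 1)
  if (nrow(links) && !all(links$gene_id == deg$gene_id))
    ct_stop("links refer to a different gene")
  s <- 0
  if (nrow(links)) {
    idx <- match(links$peak_name, peaks$name)
    if (anyNA(idx)) ct_stop("link refers to missing peak '",
                            links$peak_name[which(is.na(idx))[1]], "'")
    w <- peak_weight(links$distance, mode, window)
    s <- sum(w * peaks$neglog_padj[idx])
  }
  data.frame(gene_id = deg$gene_id, score = s * abs(deg$log_fc),
             background = NA_character_, mode = mode,
             stringsAsFactors = FALSE)
}

#' wt-C-T score table for one condition/background
#'
#' Scores every gene present in the differential-expression table: peaks
#' are linked to TSSs within `window`, each link weighted by
#' [peak_weight()], peak significances summed per gene and multiplied by
#' the gene's `|log_fc|`. Genes in `degs` with no in-window peak score 0;
#' genes in the catalog absent from `degs` are skipped (the score is
#' defined only for genes with a DE record), as are DE records without a
#' gene model — both with a message.
#'
#' @param peaks peak data.frame (pre-filter with [filter_peaks_fdr()] if
#'   the upstream table still contains non-significant regions).
#' @param genes gene data.frame.
#' @param degs DEG data.frame for the matching transcriptome contrast.
#' @param window annotation window in bases (default 100 kb).
#' @param mode weighting mode, see [peak_weight()].
#' @param background label stored in the result.
#' @param state optional chromatin-state label: restrict peaks to this
#'   state of `segments` (via [stratify_by_states()]) before scoring.
#' @param segments segmentation data.frame, required with `state`.
#' @return `WtCTScore` data.frame: `gene_id`, `score`, `background`,
#'   `mode`.
#' @export
wtct_table <- function(peaks, genes, degs, window = 100000L,
                       mode = c("weighted", "unweighted", "binary"),
                       background = NA_character_,
                       state = NULL, segments = NULL) {
  mode <- match.arg(mode)
  validate_peaks(peaks)
  if (is.null(degs) || !nrow(degs)) ct_stop("empty differential-expression table")
  validate_degs(degs)
  if (!is.null(state)) {
    if (is.null(segments)) ct_stop("state filter requires a segmentation")
    strata <- stratify_by_states(peaks, segments)
    peaks <- strata[[state]] %||% empty_peaks()
  }
  keep <- degs$gene_id %in% genes$gene_id
  if (any(!keep))
    message("wtct_table: ", sum(!keep),
            " DE record(s) without a gene model skipped")
  skipped_genes <- sum(!genes$gene_id %in% degs$gene_id)
  if (skipped_genes)
    message("wtct_table: ", skipped_genes,
            " gene(s) without a DE record skipped")
  degs <- degs[keep, , drop = FALSE]
  if (!nrow(degs)) ct_stop("no DE record matches the gene catalog")
  links <- annotate_peaks_to_genes(peaks, genes, window)
  contrib <- numeric(nrow(degs))
  if (nrow(links)) {
    links <- links[links$gene_id %in% degs$gene_id, , drop = FALSE]
    w <- peak_weight(links$distance, mode, window)
    sig <- peaks$neglog_padj[match(links$peak_name, peaks$name)]
    sums <- tapply(w * sig, links$gene_id, sum)
    hit <- match(names(sums), degs$gene_id)
    contrib[hit] <- as.numeric(sums)
  }
  data.frame(gene_id = degs$gene_id,
             score = contrib * abs(degs$log_fc),
             background = background, mode = mode,
             stringsAsFactors = FALSE)
}

score_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"score" %in% names(x)) ct_stop("score column missing")
    stats::setNames(x$score, x$gene_id)
  } else as.numeric(x)
}

#' Compare wt-C-T score distributions between two backgrounds
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the per-gene score
#' distributions of a modified cell background against its control. The
#' exact p-value is computed by enumeration when `n_a + n_b <= 12` and the
#' pooled scores are tie-free; otherwise the normal approximation with
#' mid-rank tie correction and continuity correction is used (ties are
#' expected: scores of 0 are common).
#'
#' @param scores_a,scores_b `WtCTScore` data.frames (or bare numeric
#'   vectors) for the two backgrounds.
#' @return object of class `ct_comparison`: background labels, group sizes,
#'   the Mann-Whitney statistic (`W` of a vs b), two-sided `p`, and
#'   `direction` = sign of `median(a) - median(b)`.
#' @export
compare_wtct <- function(scores_a, scores_b) {
  xa <- score_vector(scores_a)
  xb <- score_vector(scores_b)
  if (!length(xa) || !length(xb)) ct_stop("a group of size 0")
  ties <- anyDuplicated(c(xa, xb)) > 0L
  exact <- (length(xa) + length(xb) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(xa, xb, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  bg <- function(s) if (is.data.frame(s)) s$background[1] else NA_character_
  structure(list(background_a = bg(scores_a), background_b = bg(scores_b),
                 n_a = length(xa), n_b = length(xb),
                 statistic = unname(wt$statistic),
                 p = min(max(wt$p.value, .Machine$double.xmin), 1),
                 direction = sign(stats::median(xa) - stats::median(xb)),
                 exact = exact),
            class = "ct_comparison")
}

#' @export
print.ct_comparison <- function(x, ...) {
  cat("Wilcoxon rank-sum comparison of wt-C-T scores\n")
  cat("  ", x$background_a %||% "a", " (n=", x$n_a, ") vs ",
      x$background_b %||% "b", " (n=", x$n_b, ")\n", sep = "")
  cat(sprintf("  W = %g, p = %.4g (%s), direction = %+d\n",
              x$statistic, x$p, if (x$exact) "exact" else "approximate",
              x$direction))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector (capped at 1, monotone after
#' sorting). Thin validated wrapper used by the enrichment and scoring
#' stages.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) ct_stop("p outside [0,1]")
  stats::p.adjust(p, method = "BH")
}
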