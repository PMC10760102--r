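# DEG/DEP filtering at the study thresholds, hypergeometric enrichment of
# annotated classes (coactivator/corepressor/mixed/TF, ...) in complex
# membership lists, and delta-NES tables.

#' DEG/DEP significance threshold presets
#'
#' The two filter presets used throughout: `rna` (`logPV > 1`,
#' `|FC| > 0.37`) for transcriptomes and `proteomics` (`logPV > 1.3`,
#' `|FC| > 0.37`) for RIME/LFQ protein enrichment.
#'
#' @param preset `"rna"` or `"proteomics"`.
#' @return named numeric vector `c(log_pv_min=, abs_fc_min=)`.
#' @export
de_thresholds <- function(preset = c("rna", "proteomics")) {
  preset <- match.arg(preset)
  switch(preset,
         rna = c(log_pv_min = 1, abs_fc_min = 0.37),
         proteomics = c(log_pv_min = 1.3, abs_fc_min = 0.37))
}

#' Filter a differential table at significance thresholds
#'
#' Keeps records with `log_pv > log_pv_min` and `|log_fc| > abs_fc_min`,
#' both strict. Idempotent; the output is a subset of the input.
#'
#' @param degs DEG data.frame.
#' @param log_pv_min,abs_fc_min thresholds (>= 0); see [de_thresholds()]
#'   for the presets.
#' @export
filter_de <- function(degs, log_pv_min = 1, abs_fc_min = 0.37) {
  if (log_pv_min < 0 || abs_fc_min < 0) ct_stop("thresholds must be >= 0")
  validate_degs(degs)
  degs[sig_mask(degs, log_pv_min, abs_fc_min), , drop = FALSE]
}

#' Hypergeometric enrichment of annotated sets in a member list
#'
#' One-sided (enrichment-only) hypergeometric test: for each annotated set,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the annotated-set size within the universe, `n` the
#' member-list size and `k` the observed overlap. Elements outside the
#' universe are dropped with a warning. BH adjustment is applied across all
#' sets tested in the call.
#'
#' @param members character vector (e.g. proteins found in a complex).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all testable elements (e.g. every
#'   protein detected in the experiment).
#' @return data.frame: `set_name`, `k`, `n`, `K`, `N`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(members, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) ct_stop("empty universe")
  if (!is.list(sets)) sets <- list(set = sets)
  members <- unique(members)
  out_m <- setdiff(members, universe)
  if (length(out_m)) {
    warning(length(out_m), " member(s) outside the universe dropped",
            call. = FALSE)
    members <- intersect(members, universe)
  }
  n <- length(members)
  N <- length(universe)
  res <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    out_s <- setdiff(s, universe)
    if (length(out_s))
      warning(length(out_s), " element(s) of set '", nm,
              "' outside the universe dropped", call. = FALSE)
    s <- intersect(s, universe)
    K <- length(s)
    k <- length(intersect(members, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               p = min(max(p, .Machine$double.xmin), 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res
}

#' Per-term delta-NES between a variant background and its reference
#'
#' `delta_nes = nes_variant - nes_reference` for every term present in both
#' tables; terms present on only one side are reported separately, never
#' imputed.
#'
#' @param nes_variant,nes_reference NES data.frames (columns `term`, `nes`;
#'   see [read_nes_table()]). Duplicate terms within one table are an
#'   error.
#' @return list with `delta` (data.frame `term`, `nes_variant`,
#'   `nes_reference`, `delta_nes`), `variant_only` and `reference_only`
#'   term vectors.
#' @export
delta_nes <- function(nes_variant, nes_reference) {
  for (tab in list(nes_variant, nes_reference))
    if (anyDuplicated(tab$term))
      ct_stop("duplicate term '", tab$term[duplicated(tab$term)][1],
              "' within one NES table")
  shared <- intersect(nes_variant$term, nes_reference$term)
  iv <- match(shared, nes_variant$term)
  ir <- match(shared, nes_reference$term)
  list(delta = data.frame(term = shared,
                          nes_variant = nes_variant$nes[iv],
                          nes_reference = nes_reference$nes[ir],
                          delta_nes = nes_variant$nes[iv] -
                            nes_reference$nes[ir],
                          stringsAsFactors = FALSE),
       variant_only = setdiff(nes_variant$term, shared),
       reference_only = setdiff(nes_reference$term, shared))
}
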