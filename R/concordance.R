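# Cooperative vs antagonistic gene classification between two
# differential-expression contrasts: a gene significant in both contrasts
# is cooperative if its fold changes share a sign and antagonistic if they
# oppose; everything else is unclassified.

sig_mask <- function(degs, log_pv_min, abs_fc_min) {
  degs$log_pv > log_pv_min & abs(degs$log_fc) > abs_fc_min
}

#' Classify gene concordance between two contrasts
#'
#' For every gene present in either contrast, evaluates significance per
#' contrast under the DEG rule (strict `log_pv > log_pv_min` and
#' `|log_fc| > abs_fc_min`) and assigns:
#' \describe{
#'   \item{cooperative}{significant in both, same fold-change sign;}
#'   \item{antagonistic}{significant in both, opposite sign;}
#'   \item{unclassified}{everything else (absent or non-significant in at
#'     least one contrast, or a zero fold change in a significant record,
#'     which carries no direction).}
#' }
#'
#' @param de_a,de_b DEG data.frames for the two contrasts.
#' @param log_pv_min,abs_fc_min significance thresholds; defaults are the
#'   RNA-seq DEG rule (`logPV > 1`, `|FC| > 0.37`), see [de_thresholds()].
#' @return data.frame over the union of genes: `gene_id`, `sign_a`,
#'   `sign_b` (`"+"`, `"-"` or NA), `label`.
#' @export
classify_concordance <- function(de_a, de_b, log_pv_min = 1,
                                 abs_fc_min = 0.37) {
  if ((is.null(de_a) || !nrow(de_a)) && (is.null(de_b) || !nrow(de_b)))
    ct_stop("empty union of genes")
  validate_degs(de_a); validate_degs(de_b)
  union_ids <- union(de_a$gene_id, de_b$gene_id)
  ia <- match(union_ids, de_a$gene_id)
  ib <- match(union_ids, de_b$gene_id)
  sig_a <- !is.na(ia) & sig_mask(de_a, log_pv_min, abs_fc_min)[ia]
  sig_b <- !is.na(ib) & sig_mask(de_b, log_pv_min, abs_fc_min)[ib]
  fc_a <- de_a$log_fc[ia]
  fc_b <- de_b$log_fc[ib]
  zero_dir <- (sig_a & fc_a == 0) | (sig_b & fc_b == 0)
  zero_dir[is.na(zero_dir)] <- FALSE
  if (any(zero_dir))
    message("classify_concordance: ", sum(zero_dir),
            " significant gene(s) with log_fc = 0 left unclassified")
  sgn <- function(fc, sig) ifelse(sig & fc != 0,
                                  ifelse(fc > 0, "+", "-"), NA_character_)
  sign_a <- sgn(fc_a, sig_a)
  sign_b <- sgn(fc_b, sig_b)
  label <- rep("unclassified", length(union_ids))
  directed <- !is.na(sign_a) & !is.na(sign_b)
  label[directed & sign_a == sign_b] <- "cooperative"
  label[directed & sign_a != sign_b] <- "antagonistic"
  data.frame(gene_id = union_ids, sign_a = sign_a, sign_b = sign_b,
             label = label, stringsAsFactors = FALSE)
}

#' Summarise concordance between two contrasts
#'
#' Counts cooperative/antagonistic/unclassified calls over the union of
#' genes (the counts always sum to the union size) and reports the
#' antagonistic fraction both over the union and restricted to genes
#' significant in both contrasts (the regulated-gene denominator).
#'
#' @inheritParams classify_concordance
#' @return object of class `ct_concordance` with `calls` (per-gene table),
#'   `counts`, `n_union`, `n_both_significant`,
#'   `antagonistic_fraction_union`, `antagonistic_fraction_both_sig`.
#' @export
concordance_summary <- function(de_a, de_b, log_pv_min = 1,
                                abs_fc_min = 0.37) {
  calls <- classify_concordance(de_a, de_b, log_pv_min, abs_fc_min)
  counts <- c(cooperative = sum(calls$label == "cooperative"),
              antagonistic = sum(calls$label == "antagonistic"),
              unclassified = sum(calls$label == "unclassified"))
  n_both <- unname(counts["cooperative"] + counts["antagonistic"])
  structure(list(calls = calls, counts = counts, n_union = nrow(calls),
                 n_both_significant = n_both,
                 antagonistic_fraction_union =
                   unname(counts["antagonistic"]) / nrow(calls),
                 antagonistic_fraction_both_sig =
                   if (n_both > 0) unname(counts["antagonistic"]) / n_both
                   else NA_real_,
                 thresholds = c(log_pv_min = log_pv_min,
                                abs_fc_min = abs_fc_min)),
            class = "ct_concordance")
}

#' @export
print.ct_concordance <- function(x, ...) {
  cat("Concordance over", x$n_union, "genes (thresholds: logPV >",
      x$thresholds[["log_pv_min"]], ", |FC| >",
      x$thresholds[["abs_fc_min"]], ")\n")
  print(x$counts)
  cat(sprintf("  antagonistic fraction: %.4g (union), %.4g (both-significant)\n",
              x$antagonistic_fraction_union,
              x$antagonistic_fraction_both_sig))
  invisible(x)
}

#' Compare antagonistic fractions between two backgrounds
#'
#' Two-proportion chi-squared test (no continuity correction) of the
#' antagonistic fraction, computed over both-significant genes, between two
#' concordance summaries (e.g. two cell backgrounds against the same
#' reference contrast).
#'
#' @param x,y `ct_concordance` objects.
#' @return list with the two fractions, `chi2` and `p`.
#' @export
compare_antagonism <- function(x, y) {
  stopifnot(inherits(x, "ct_concordance"), inherits(y, "ct_concordance"))
  k <- c(x$counts[["antagonistic"]], y$counts[["antagonistic"]])
  n <- c(x$n_both_significant, y$n_both_significant)
  if (any(n == 0)) ct_stop("no both-significant genes in one summary")
  pt <- suppressWarnings(stats::prop.test(k, n, correct = FALSE))
  list(fraction_x = k[1] / n[1], fraction_y = k[2] / n[2],
       chi2 = unname(pt$statistic), p = pt$p.value)
}
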