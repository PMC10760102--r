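# Coregulator-influence statistics: delta.corr, the drop in the Pearson
# correlation between a regulator and its target genes when a coregulator
# is partialled out, and bootstrap Jaccard similarity of ranked gene lists.

#' Pearson correlation with degeneracy checks
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) ct_stop("vectors of unequal length")
  if (length(x) < 3) ct_stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    ct_stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ct_stop("degenerate vector (zero variance)")
  stats::cor(x, y)
}

#' First-order partial correlation from three marginal correlations
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz marginal Pearson correlations.
#' @return partial correlation of x and y given z.
#' @export
partial_cor_from_r <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1)) ct_stop("correlation outside [-1,1]")
  if (any(abs(c(r_xz, r_yz)) == 1))
    ct_stop("collinear with conditioning variable")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' First-order partial correlation of two vectors given a third
#'
#' @param x,y,z numeric vectors (same requirements as [pearson_cor()]).
#' @return `r_xy.z`.
#' @export
partial_cor <- function(x, y, z) {
  partial_cor_from_r(pearson_cor(x, y), pearson_cor(x, z),
                     pearson_cor(y, z))
}

#' delta.corr: coregulator influence on regulator-target correlations
#'
#' For each target gene, computes the Pearson correlation between the
#' regulator and the gene and the first-order partial correlation given the
#' coregulator; `delta = mean(r) - mean(r_partial)` (unweighted means over
#' the target set). A positive delta means the coregulator accounts for
#' part of the regulator-target association. Per-gene values are returned
#' alongside the aggregate.
#'
#' @param expr samples-by-genes numeric matrix with column names.
#' @param regulator column name of the regulator (e.g. the receptor).
#' @param targets character vector of target-gene column names.
#' @param coregulator column name of the coregulator conditioned on.
#' @return object of class `ct_delta_corr`: `coregulator`, `r_mean`,
#'   `r_partial_mean`, `delta`, and `per_gene` data.frame.
#' @export
delta_corr <- function(expr, regulator, targets, coregulator) {
  if (!length(targets)) ct_stop("empty target_set")
  ids <- c(regulator, coregulator, targets)
  miss <- setdiff(ids, colnames(expr))
  if (length(miss)) ct_stop("column(s) absent from matrix: ",
                            paste(head(miss, 3), collapse = ", "))
  if (nrow(expr) < 3) ct_stop("need at least 3 samples")
  x <- expr[, regulator]
  z <- expr[, coregulator]
  r <- vapply(targets, function(g) pearson_cor(x, expr[, g]), numeric(1))
  rp <- vapply(targets, function(g) partial_cor(x, expr[, g], z),
               numeric(1))
  structure(list(coregulator = coregulator,
                 r_mean = mean(r), r_partial_mean = mean(rp),
                 delta = mean(r) - mean(rp),
                 per_gene = data.frame(gene_id = targets, r = r,
                                       r_partial = rp, delta = r - rp,
                                       row.names = NULL,
                                       stringsAsFactors = FALSE)),
            class = "ct_delta_corr")
}

#' @export
print.ct_delta_corr <- function(x, ...) {
  cat("delta.corr for coregulator", x$coregulator, "over",
      nrow(x$per_gene), "target genes\n")
  cat(sprintf("  mean r = %.4f, mean partial r = %.4f, delta = %.4f\n",
              x$r_mean, x$r_partial_mean, x$delta))
  invisible(x)
}

#' Jaccard index of two sets
#' @param a,b vectors treated as sets.
#' @return `|intersect| / |union|` (0 for two empty sets).
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard similarity of two ranked lists
#'
#' Computes the Jaccard index of the top-`k` sets of two ranked lists and
#' its significance against a permutation null: the order of `list_b` is
#' randomly permuted `n_boot` times, the top-`k` Jaccard recomputed each
#' time, and `p = (1 + #\{J_null >= J_obs\}) / (n_boot + 1)` (the add-one
#' estimator, which never returns 0).
#'
#' @param list_a,list_b ranked identifier vectors (best rank first, unique
#'   within each list).
#' @param k rank cutoff, `1 <= k <= min(lengths)`.
#' @param n_boot permutation replicates (default 1000).
#' @param seed optional integer seed for the permutations.
#' @return object of class `ct_jaccard_boot`: `k`, `jaccard`, `n_boot`,
#'   `p`, and the null values `j_null`.
#' @export
ranked_jaccard_boot <- function(list_a, list_b, k, n_boot = 1000L,
                                seed = NULL) {
  if (k < 1) ct_stop("k must be >= 1")
  if (k > min(length(list_a), length(list_b)))
    ct_stop("k exceeds a list length")
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    ct_stop("ids must be unique within each list")
  if (n_boot < 1) ct_stop("n_boot must be >= 1")
  top_a <- list_a[seq_len(k)]
  in_top_a <- list_b %in% top_a          # by position of list_b
  j_of <- function(n_shared) n_shared / (2 * k - n_shared)
  j_obs <- j_of(sum(in_top_a[seq_len(k)]))
  if (!is.null(seed)) set.seed(seed)
  nb <- length(list_b)
  j_null <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nb)
    j_of(sum(in_top_a[idx[seq_len(k)]]))
  }, numeric(1))
  structure(list(k = as.integer(k), jaccard = j_obs,
                 n_boot = as.integer(n_boot),
                 p = (1 + sum(j_null >= j_obs)) / (n_boot + 1),
                 j_null = j_null),
            class = "ct_jaccard_boot")
}

#' @export
print.ct_jaccard_boot <- function(x, ...) {
  cat(sprintf(
    "Top-%d Jaccard = %.4f, permutation p = %.4g (%d replicates)\n",
    x$k, x$jaccard, x$p, x$n_boot))
  invisible(x)
}
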