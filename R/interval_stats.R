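# Interval primitives. All public tables are 0-based half-open; GRanges
# objects (1-based inclusive) exist only transiently inside these helpers.

as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end))
}

assert_nonoverlapping <- function(segments, what = "segmentation") {
  if (!nrow(segments)) return(invisible(TRUE))
  gr <- as_granges0(segments)
  n_self <- GenomicRanges::countOverlaps(gr, gr, minoverlap = 1L)
  if (any(n_self > 1L))
    ct_stop(what, " contains overlapping segments")
  invisible(TRUE)
}

#' Do two genomic intervals share at least 1 bp?
#'
#' The shared-binding rule used throughout: two intervals overlap iff they
#' lie on the same chromosome and share a minimum of 1 bp under 0-based
#' half-open coordinates, i.e. `max(starts) < min(ends)`. Strand is
#' ignored. Vectorised with recycling.
#'
#' @param chrom_a,start_a,end_a first interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @examples
#' intervals_overlap("chr1", 0, 10, "chr1", 9, 20)   # TRUE, 1 bp shared
#' intervals_overlap("chr1", 0, 10, "chr1", 10, 20)  # FALSE, abutting
#' @export
intervals_overlap <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  stopifnot(all(end_a > start_a), all(end_b > start_b),
            all(start_a >= 0), all(start_b >= 0))
  chrom_a == chrom_b & pmax(start_a, start_b) < pmin(end_a, end_b)
}

#' Shared and unique peaks between two peak sets
#'
#' A peak counts as shared if it overlaps (>= 1 bp) at least one peak of
#' the other set, so `shared_a` need not equal `shared_b` (one peak can
#' absorb several partners). The full pair list is returned for auditing.
#'
#' @param a,b peak data.frames.
#' @return list with `shared_a`, `unique_a`, `shared_b`, `unique_b` counts
#'   and a `pairs` data.frame of overlapping `(name_a, name_b)`.
#' @export
intersect_peak_sets <- function(a, b) {
  validate_peaks(a); validate_peaks(b)
  if (!nrow(a) || !nrow(b)) {
    return(list(shared_a = 0L, unique_a = nrow(a),
                shared_b = 0L, unique_b = nrow(b),
                pairs = data.frame(name_a = character(),
                                   name_b = character(),
                                   stringsAsFactors = FALSE)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  list(shared_a = length(unique(qh)),
       unique_a = nrow(a) - length(unique(qh)),
       shared_b = length(unique(sh)),
       unique_b = nrow(b) - length(unique(sh)),
       pairs = data.frame(name_a = a$name[qh], name_b = b$name[sh],
                          stringsAsFactors = FALSE))
}

#' Chi-squared test of cistrome co-occurrence on genome bins
#'
#' Tiles the genome into fixed-width bins, labels each bin as covered
#' (>= 1 bp) or not by each peak set, and tests independence of the two
#' labels with a 1-df chi-squared test without continuity correction. The
#' bin construction gives the 2x2 table well-defined margins; 1 kb is the
#' default resolution.
#'
#' @param a,b peak data.frames.
#' @param chrom_sizes named numeric vector of chromosome lengths (bases).
#' @param bin_size bin width in bases (> 0).
#' @return object of class `ct_overlap_test`: bin counts `both`, `a_only`,
#'   `b_only`, `neither`, the `chi2` statistic and upper-tail `p`. If a row
#'   or column margin of the table is zero the test is degenerate: `p` is
#'   reported as 1 with a warning.
#' @export
overlap_chi2 <- function(a, b, chrom_sizes, bin_size = 1000L) {
  validate_peaks(a); validate_peaks(b)
  if (bin_size <= 0) ct_stop("bin_size must be > 0")
  if (is.null(names(chrom_sizes)) || !length(chrom_sizes))
    ct_stop("chrom_sizes must be a named vector")
  for (df in list(a, b)) {
    if (nrow(df) && !all(df$chrom %in% names(chrom_sizes)))
      ct_stop("peak chromosome absent from chrom_sizes universe")
    if (nrow(df) && any(df$end > chrom_sizes[df$chrom]))
      ct_stop("peak extends beyond its chromosome size")
  }
  lens <- as.integer(chrom_sizes)
  names(lens) <- names(chrom_sizes)
  bins <- GenomicRanges::tileGenome(lens, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  in_a <- if (nrow(a)) IRanges::overlapsAny(bins, as_granges0(a),
                                            minoverlap = 1L)
          else rep(FALSE, length(bins))
  in_b <- if (nrow(b)) IRanges::overlapsAny(bins, as_granges0(b),
                                            minoverlap = 1L)
          else rep(FALSE, length(bins))
  both <- sum(in_a & in_b)
  a_only <- sum(in_a & !in_b)
  b_only <- sum(!in_a & in_b)
  neither <- sum(!in_a & !in_b)
  tab <- matrix(c(both, a_only, b_only, neither), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p reported as 1",
            call. = FALSE)
    chi2 <- 0
    p <- 1
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    chi2 <- unname(ct$statistic)
    p <- max(ct$p.value, .Machine$double.xmin)
  }
  structure(list(both = both, a_only = a_only, b_only = b_only,
                 neither = neither, n_bins = length(bins),
                 bin_size = as.integer(bin_size), chi2 = chi2, p = p),
            class = "ct_overlap_test")
}

#' @export
print.ct_overlap_test <- function(x, ...) {
  cat("Binned cistrome overlap test (", x$n_bins, " bins of ",
      x$bin_size, " bp)\n", sep = "")
  cat("  both=", x$both, " a_only=", x$a_only, " b_only=", x$b_only,
      " neither=", x$neither, "\n", sep = "")
  cat(sprintf("  chi-squared = %.6g (1 df), p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' Link peaks to genes within a TSS window
#'
#' A link is created for every (gene, peak) pair on the same chromosome
#' whose peak midpoint lies within `window` bases of the gene TSS,
#' boundary inclusive (`|midpoint - tss| <= window`). A peak may link to
#' several genes. The midpoint is `floor((start + end) / 2)`.
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame (needs `gene_id`, `chrom`, `tss`).
#' @param window distance cutoff in bases; default 100000 (the 100 kb
#'   annotation window).
#' @return data.frame of links: `gene_id`, `peak_name`, `distance`,
#'   `weight` (initialised to 1; set by the scoring stage).
#' @export
annotate_peaks_to_genes <- function(peaks, genes, window = 100000L) {
  validate_peaks(peaks)
  if (window <= 0) ct_stop("window must be > 0")
  empty <- data.frame(gene_id = character(), peak_name = character(),
                      distance = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) return(empty)
  mid <- floor((peaks$start + peaks$end) / 2)
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(start = mid + 1L,
                                               width = 1L))
  s <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(
                                start = genes$tss - as.integer(window) + 1L,
                                end = genes$tss + as.integer(window) + 1L))
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene_id = genes$gene_id[sh],
                    peak_name = peaks$name[qh],
                    distance = abs(mid[qh] - genes$tss[sh]),
                    weight = rep(1, length(qh)),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$distance <= window))
  out
}

#' Stratify peaks by chromatin state
#'
#' Assigns each peak to every state whose segments it overlaps by >= 1 bp;
#' a peak spanning a state boundary appears under both states. Peaks
#' overlapping no segment are collected under `"unassigned"`.
#'
#' @param peaks peak data.frame.
#' @param segments chromatin-state segmentation (columns `chrom`, `start`,
#'   `end`, `state`); segments must be non-overlapping, otherwise an error.
#' @return named list of peak data.frames, one per state present.
#' @export
stratify_by_states <- function(peaks, segments) {
  validate_peaks(peaks)
  assert_nonoverlapping(segments, "state segmentation")
  if (!nrow(peaks)) return(stats::setNames(list(), character()))
  if (!nrow(segments)) return(list(unassigned = peaks))
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks),
                                      as_granges0(segments),
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  states <- segments$state[S4Vectors::subjectHits(hits)]
  out <- lapply(split(qh, states), function(i)
    peaks[sort(unique(i)), , drop = FALSE])
  un <- setdiff(seq_len(nrow(peaks)), unique(qh))
  if (length(un)) out$unassigned <- peaks[un, , drop = FALSE]
  out
}

#' Keep peaks passing a region FDR cutoff
#'
#' Regions enter the downstream scoring only if their differential
#' enrichment passed FDR < `fdr_max` upstream (strict inequality on the
#' adjusted-p scale, i.e. `neglog_padj > -log10(fdr_max)`).
#'
#' @param peaks peak data.frame.
#' @param fdr_max adjusted-p cutoff, default 0.1.
#' @export
filter_peaks_fdr <- function(peaks, fdr_max = 0.1) {
  validate_peaks(peaks)
  if (fdr_max <= 0 || fdr_max >= 1) ct_stop("fdr_max must be in (0,1)")
  peaks[peaks$neglog_padj > -log10(fdr_max), , drop = FALSE]
}
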