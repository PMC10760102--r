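#' @importFrom utils read.table write.table head
NULL

# Coordinate convention used throughout the package: 0-based half-open
# [start, end), BED-style. The single conversion point for 1-based inclusive
# input is the GTF branch of read_genes().

`%||%` <- function(a, b) if (is.null(a)) b else a

ct_stop <- function(...) stop(..., call. = FALSE)

# Read a tab-separated text file into a character matrix, tolerating CRLF
# line endings and a trailing newline. Keeps original line numbers so
# format errors can point at the offending line.
read_tsv_raw <- function(path, skip = 0L) {
  if (!file.exists(path)) ct_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- which(nzchar(lines))
  if (skip > 0L) keep <- keep[keep > skip]
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  list(fields = fields, line_no = keep)
}

field_col <- function(raw, j) {
  vapply(raw$fields, function(f) if (length(f) >= j) f[[j]] else NA_character_,
         character(1))
}

as_num_col <- function(x, raw, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    ct_stop("line ", raw$line_no[bad[1]], ": non-numeric ", what,
            " ('", x[bad[1]], "')")
  miss <- which(is.na(x))
  if (length(miss))
    ct_stop("line ", raw$line_no[miss[1]], ": malformed line (missing ",
            what, ")")
  out
}

check_interval_cols <- function(chrom, start, end, raw) {
  bad <- which(is.na(chrom) | !nzchar(chrom) | grepl("[[:space:]]", chrom))
  if (length(bad))
    ct_stop("line ", raw$line_no[bad[1]], ": malformed chromosome name")
  bad <- which(start < 0)
  if (length(bad))
    ct_stop("line ", raw$line_no[bad[1]], ": negative start")
  bad <- which(end <= start)
  if (length(bad))
    ct_stop("line ", raw$line_no[bad[1]], ": end <= start")
  invisible(TRUE)
}

# Convert adjusted p on (0,1] to -log10. Exact zeros are clamped to the
# smallest representable positive double (with a warning) rather than
# producing Inf; negative or > 1 values are format errors.
neglog10_from_p <- function(p, raw) {
  bad <- which(p < 0 | p > 1)
  if (length(bad))
    ct_stop("line ", raw$line_no[bad[1]], ": p-value outside (0,1] (",
            p[bad[1]], ")")
  zero <- which(p == 0)
  if (length(zero)) {
    warning(length(zero), " adjusted p-value(s) of exactly 0 clamped to ",
            ".Machine$double.xmin", call. = FALSE)
    p[zero] <- .Machine$double.xmin
  }
  -log10(p)
}

#' Read a peak table
#'
#' Reads differential-enrichment peaks from BED-like or tab-separated files
#' into the package's peak table: a data.frame with columns `chrom`,
#' `start`, `end` (0-based half-open), `name`, `neglog_padj` (-log10 of the
#' adjusted p-value) and `source`.
#'
#' Formats:
#' \describe{
#'   \item{`tsv` / `bed`}{columns 1-3 are chrom/start/end, column 4 (when
#'     present) the peak name; `padj_column` names the ordinal column
#'     holding the significance value.}
#'   \item{`narrowpeak`}{ENCODE 10-column dialect; the q-value in column 9
#'     is already -log10-scaled and is used directly.}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"bed"`, `"narrowpeak"`.
#' @param padj_column ordinal of the significance column (ignored for
#'   narrowPeak). Default 5.
#' @param padj_scale `"linear"` if the column holds adjusted p in (0,1]
#'   (converted to -log10 on read), `"neglog10"` if it is already
#'   -log10-scaled. Whether the upstream caller stored raw or adjusted p in
#'   that column is the caller's choice; adjusted p is the convention
#'   assumed by the defaults.
#' @param source label recorded in the `source` column (cistrome/condition).
#' @param source_column optional ordinal of a column holding per-row source
#'   labels (overrides `source`).
#' @param header logical; skip a header line first.
#' @return a validated peak data.frame, input order preserved.
#' @seealso [write_peaks()], [validate_peaks()]
#' @export
read_peaks <- function(path, format = c("tsv", "bed", "narrowpeak"),
                       padj_column = 5L,
                       padj_scale = c("linear", "neglog10"),
                       source = NA_character_, source_column = NULL,
                       header = FALSE) {
  format <- match.arg(format)
  padj_scale <- match.arg(padj_scale)
  raw <- read_tsv_raw(path, skip = if (header) 1L else 0L)
  if (!length(raw$fields)) {
    warning("empty peak file: ", path, call. = FALSE)
    return(empty_peaks())
  }
  ncol_min <- if (format == "narrowpeak") 10L else max(3L, padj_column)
  short <- which(lengths(raw$fields) < ncol_min)
  if (length(short))
    ct_stop("line ", raw$line_no[short[1]], ": malformed line (expected >= ",
            ncol_min, " columns for format '", format, "')")
  chrom <- field_col(raw, 1L)
  start <- as_num_col(field_col(raw, 2L), raw, "start")
  end <- as_num_col(field_col(raw, 3L), raw, "end")
  check_interval_cols(chrom, start, end, raw)
  has_name <- all(lengths(raw$fields) >= 4L) &&
    (format == "narrowpeak" || padj_column != 4L)
  name <- if (has_name) field_col(raw, 4L) else
    sprintf("peak_%d", seq_along(chrom))
  if (format == "narrowpeak") {
    neglog <- as_num_col(field_col(raw, 9L), raw, "qValue")
    if (any(neglog < 0))
      ct_stop("line ", raw$line_no[which(neglog < 0)[1]],
              ": negative -log10 q-value")
  } else if (padj_scale == "linear") {
    p <- as_num_col(field_col(raw, padj_column), raw, "p-value")
    neglog <- neglog10_from_p(p, raw)
  } else {
    neglog <- as_num_col(field_col(raw, padj_column), raw, "-log10 p")
    bad <- which(neglog < 0 | !is.finite(neglog))
    if (length(bad))
      ct_stop("line ", raw$line_no[bad[1]], ": -log10 p must be finite, >= 0")
  }
  src <- if (!is.null(source_column)) field_col(raw, source_column)
         else rep(source, length(chrom))
  dup <- which(duplicated(name))
  if (length(dup))
    ct_stop("line ", raw$line_no[dup[1]], ": duplicate peak name '",
            name[dup[1]], "'")
  peaks <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), name = name,
                      neglog_padj = neglog, source = src,
                      stringsAsFactors = FALSE)
  validate_peaks(peaks)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), neglog_padj = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

#' Validate a peak table
#'
#' Checks the peak-table invariants (0-based half-open coordinates with
#' `end > start >= 0`, finite non-negative `neglog_padj`, unique names) on a
#' programmatically built data.frame. Returns the table invisibly unchanged.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `neglog_padj` and optionally `source`.
#' @export
validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "name", "neglog_padj")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) ct_stop("peak table missing column(s): ",
                            paste(miss, collapse = ", "))
  if (!"source" %in% names(peaks)) peaks$source <- NA_character_
  if (nrow(peaks)) {
    if (any(peaks$start < 0)) ct_stop("negative start in peak table")
    if (any(peaks$end <= peaks$start)) ct_stop("end <= start in peak table")
    if (any(!is.finite(peaks$neglog_padj) | peaks$neglog_padj < 0))
      ct_stop("neglog_padj must be finite and >= 0")
    if (anyDuplicated(peaks$name))
      ct_stop("duplicate peak name '",
              peaks$name[duplicated(peaks$name)][1], "'")
  }
  invisible(peaks)
}

#' Write a peak table
#'
#' Writes the package's peak representation as a headered TSV carrying the
#' `-log10` significance column verbatim, so that
#' `read_peaks(path, "tsv", padj_column = 5, padj_scale = "neglog10",
#' source_column = 6, header = TRUE)` round-trips the table field-for-field.
#'
#' @param peaks validated peak data.frame.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  write.table(peaks[, c("chrom", "start", "end", "name", "neglog_padj",
                        "source")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Reads gene annotations and derives the TSS anchor used by the 100 kb
#' peak-to-gene window: plus-strand TSS = `start`, minus-strand TSS =
#' `end - 1` (half-open convention). Unknown strand (`"."` or `"*"`) is
#' treated as plus with a warning.
#'
#' @param path file path.
#' @param format `"bed6"` (0-based half-open, name column = gene id) or
#'   `"gtf_min"` (minimal GTF; 1-based inclusive coordinates are converted
#'   here, the package's single conversion point; rows with feature type
#'   `gene` are used when present).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (all coordinates 0-based half-open).
#' @export
read_genes <- function(path, format = c("bed6", "gtf_min")) {
  format <- match.arg(format)
  if (format == "bed6") {
    raw <- read_tsv_raw(path)
    if (!length(raw$fields))
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), tss = integer(),
                        stringsAsFactors = FALSE))
    short <- which(lengths(raw$fields) < 6L)
    if (length(short))
      ct_stop("line ", raw$line_no[short[1]],
              ": missing strand (bed6 requires 6 columns)")
    chrom <- field_col(raw, 1L)
    start <- as_num_col(field_col(raw, 2L), raw, "start")
    end <- as_num_col(field_col(raw, 3L), raw, "end")
    check_interval_cols(chrom, start, end, raw)
    gene_id <- field_col(raw, 4L)
    strand <- field_col(raw, 6L)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
      ct_stop("gtf_min input lacks a gene_id attribute")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    # 1-based inclusive -> 0-based half-open
    start <- GenomicRanges::start(gr) - 1L
    end <- GenomicRanges::end(gr)
    gene_id <- S4Vectors::mcols(gr)$gene_id
    strand <- as.character(GenomicRanges::strand(gr))
  }
  unk <- strand %in% c(".", "*")
  if (any(unk)) {
    warning(sum(unk), " gene(s) with unknown strand treated as '+'",
            call. = FALSE)
    strand[unk] <- "+"
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) ct_stop("invalid strand '", strand[bad[1]], "' for gene ",
                           gene_id[bad[1]])
  dup <- which(duplicated(gene_id))
  if (length(dup)) ct_stop("duplicate gene_id '", gene_id[dup[1]], "'")
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = as.integer(start), end = as.integer(end),
                      strand = strand,
                      tss = as.integer(ifelse(strand == "+", start, end - 1)),
                      stringsAsFactors = FALSE)
  stopifnot(all(genes$tss >= genes$start & genes$tss < genes$end))
  genes
}

#' Write gene models as BED6
#'
#' @param genes gene data.frame from [read_genes()] or
#'   [make_genome_and_genes()].
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Reads a headered TSV of per-gene differential-expression results (the
#' output of an upstream edgeR/limma-style fit) into the package's DEG
#' table: `gene_id`, `log_fc` (signed log2 fold change), `log_pv`
#' (-log10 p), `padj`.
#'
#' @param path file path.
#' @param columns named character vector mapping the internal names
#'   `gene`, `log_fc`, `log_pv`, `padj` to header names in the file.
#' @return DEG data.frame; rows with missing values are dropped with a
#'   message stating the count.
#' @export
read_de_table <- function(path,
                          columns = c(gene = "gene_id", log_fc = "log_fc",
                                      log_pv = "log_pv", padj = "padj")) {
  need <- c("gene", "log_fc", "log_pv", "padj")
  miss <- setdiff(need, names(columns))
  if (length(miss)) ct_stop("columns mapping missing: ",
                            paste(miss, collapse = ", "))
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  absent <- setdiff(unname(columns[need]), names(tab))
  if (length(absent)) ct_stop("missing mapped column(s) in ", path, ": ",
                              paste(absent, collapse = ", "))
  degs <- data.frame(gene_id = as.character(tab[[columns[["gene"]]]]),
                     log_fc = as.numeric(tab[[columns[["log_fc"]]]]),
                     log_pv = as.numeric(tab[[columns[["log_pv"]]]]),
                     padj = as.numeric(tab[[columns[["padj"]]]]),
                     stringsAsFactors = FALSE)
  incomplete <- !stats::complete.cases(degs)
  if (any(incomplete)) {
    message("read_de_table: dropped ", sum(incomplete),
            " row(s) with missing values")
    degs <- degs[!incomplete, , drop = FALSE]
  }
  if (!nrow(degs)) {
    warning("empty differential-expression table: ", path, call. = FALSE)
    return(degs)
  }
  validate_degs(degs)
  degs
}

validate_degs <- function(degs) {
  if (any(degs$padj < 0 | degs$padj > 1))
    ct_stop("padj outside [0,1]")
  if (any(degs$log_pv < 0))
    ct_stop("log_pv must be >= 0")
  if (anyDuplicated(degs$gene_id))
    ct_stop("duplicate gene_id '",
            degs$gene_id[duplicated(degs$gene_id)][1],
            "' (one record per gene per contrast)")
  invisible(degs)
}

#' Write a differential-expression table
#' @param degs DEG data.frame.
#' @param path output path.
#' @export
write_de_table <- function(degs, path) {
  write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chromatin-state segments
#'
#' BED4: chrom, start, end, state label. Segments of one segmentation must
#' be non-overlapping per chromosome (checked here and again by
#' [stratify_by_states()]).
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `state`.
#' @export
read_state_segments <- function(path) {
  raw <- read_tsv_raw(path)
  if (!length(raw$fields))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), state = character(),
                      stringsAsFactors = FALSE))
  short <- which(lengths(raw$fields) < 4L)
  if (length(short))
    ct_stop("line ", raw$line_no[short[1]], ": segment lacks a state label")
  chrom <- field_col(raw, 1L)
  start <- as_num_col(field_col(raw, 2L), raw, "start")
  end <- as_num_col(field_col(raw, 3L), raw, "end")
  check_interval_cols(chrom, start, end, raw)
  seg <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), state = field_col(raw, 4L),
                    stringsAsFactors = FALSE)
  assert_nonoverlapping(seg, "state segmentation")
  seg
}

#' Write chromatin-state segments as BED4
#' @param segments segment data.frame.
#' @param path output path.
#' @export
write_state_segments <- function(segments, path) {
  write.table(segments[, c("chrom", "start", "end", "state")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then members.
#'
#' @param path file path.
#' @return named list of character vectors of members.
#' @export
read_gmt <- function(path) {
  raw <- read_tsv_raw(path)
  short <- which(lengths(raw$fields) < 3L)
  if (length(short))
    ct_stop("line ", raw$line_no[short[1]],
            ": GMT line needs name, description and >= 1 member")
  sets <- lapply(raw$fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(raw$fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) ct_stop("duplicate set name in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalized-enrichment-score (NES) table
#'
#' Headered TSV of per-term GSEA normalized enrichment scores for one or
#' more cell backgrounds; the input to [delta_nes()].
#'
#' @param path file path.
#' @param columns named character vector mapping `term`, `nes` and
#'   (optionally) `background` to header names.
#' @return data.frame with columns `term`, `nes`, `background`.
#' @export
read_nes_table <- function(path, columns = c(term = "term", nes = "NES",
                                             background = "background")) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (nm in c("term", "nes"))
    if (!columns[[nm]] %in% names(tab))
      ct_stop("missing mapped column '", columns[[nm]], "'")
  bg <- if ("background" %in% names(columns) &&
            columns[["background"]] %in% names(tab))
    as.character(tab[[columns[["background"]]]]) else NA_character_
  nes <- data.frame(term = as.character(tab[[columns[["term"]]]]),
                    nes = as.numeric(tab[[columns[["nes"]]]]),
                    background = bg, stringsAsFactors = FALSE)
  if (anyDuplicated(nes[, c("term", "background")]))
    ct_stop("duplicate (term, background) record in NES table")
  nes
}

#' Read an expression matrix (samples x genes)
#'
#' Headered TSV whose first column holds sample identifiers and remaining
#' header names are gene/protein identifiers.
#'
#' @param path file path.
#' @return numeric matrix, samples in rows.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix (samples x genes)
#' @param expr numeric matrix with sample rownames and gene colnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  tab <- data.frame(sample = rownames(expr) %||%
                      sprintf("S%03d", seq_len(nrow(expr))),
                    expr, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked identifier list (one id per line, best rank first)
#' @param path file path.
#' @return character vector.
#' @export
read_ranked_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- sub("\r$", "", ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) ct_stop("duplicate id in ranked list")
  ids
}

#' Write a ranked identifier list
#' @param ids character vector, best rank first.
#' @param path output path.
#' @export
write_ranked_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
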