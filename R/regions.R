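## Interval arithmetic and retroviral-element selection around differentially
## expressed cancer predisposition genes (CPGs).
##
## All intervals handled here are 0-based, half-open [start, end) -- BED
## native. VCF positions are converted at I/O boundaries.

validate_intervals <- function(df, what = "interval table") {
  check_columns(df, c("chrom", "start", "end"), what)
  bad <- which(!(df$start >= 0 & df$start < df$end) | is.na(df$chrom) |
                 df$chrom == "")
  if (length(bad)) {
    stop(sprintf("%s: malformed interval(s) at row(s) %s (need 0 <= start < end, non-empty chrom)",
                 what, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Filter a gene table for differentially expressed cancer predisposition genes
#'
#' Keeps genes with `|log2fc| > lfc` and `padj < alpha` (both strict, so a
#' gene sitting exactly on either boundary is dropped). Duplicated gene
#' symbols are collapsed to their first occurrence; input order is preserved.
#'
#' @param cpg_table data.frame with at least columns `gene`, `log2fc`, `padj`.
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return the filtered data.frame, one row per gene symbol.
#' @export
filter_de_cpgs <- function(cpg_table, lfc = 1, alpha = 0.05) {
  check_columns(cpg_table, c("gene", "log2fc", "padj"), "CPG table")
  if (any(cpg_table$padj < 0 | cpg_table$padj > 1, na.rm = TRUE)) {
    stop("CPG table: adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  keep <- abs(cpg_table$log2fc) > lfc & cpg_table$padj < alpha
  keep[is.na(keep)] <- FALSE
  out <- cpg_table[keep, , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Gap between [a,b) and [c,d) on the same chromosome: 0 when they share a
## base, otherwise the number of bases separating them. Bookended intervals
## have gap 0 under the closed formula max(0, c - b, a - d).
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, b_start - a_end, a_start - b_end)
}

#' Select retroviral elements within a radius of genes
#'
#' An element is selected when its gap distance to a gene body is at most
#' `radius_bp`; the gap is zero for any overlap, and bookended intervals
#' (gap 0 under half-open coordinates) are within any radius. An element near
#' two genes yields one row per gene; the row with minimal gap carries
#' `nearest = TRUE` (ties broken by lexicographically smallest gene symbol).
#'
#' @param elements data.frame of elements: `chrom`, `start`, `end`, `strand`,
#'   plus any annotation columns (e.g. `name`, `family`, `element_type`).
#' @param genes data.frame of gene bodies: `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param exons optional data.frame (`gene`, `start`, `end`) used to classify
#'   each pair's positional relation; without it, relations overlapping the
#'   gene body are labelled `intronic`.
#' @param radius_bp selection radius in bp (default 20000).
#' @return data.frame with one row per (element, gene) pair within radius:
#'   element columns, `gene`, `distance`, `relation`, `nearest`.
#' @export
select_near <- function(elements, genes, exons = NULL, radius_bp = 20000) {
  if (radius_bp < 0) stop("radius_bp must be >= 0", call. = FALSE)
  validate_intervals(elements, "element table")
  validate_intervals(genes, "gene table")
  check_columns(genes, "gene", "gene table")

  rows <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, , drop = FALSE]
    cand <- genes[genes$chrom == el$chrom, , drop = FALSE]
    if (!nrow(cand)) next
    gaps <- interval_gap(el$start, el$end, cand$start, cand$end)
    sel <- which(gaps <= radius_bp)
    if (!length(sel)) next
    cand <- cand[sel, , drop = FALSE]
    gaps <- gaps[sel]
    ord <- order(gaps, cand$gene)   # min gap first, then lexicographic symbol
    rel <- character(length(sel))
    for (j in seq_along(sel)) {
      rel[j] <- classify_relation(el, cand[j, , drop = FALSE],
                                  exons = exons, radius_bp = radius_bp)$relation
    }
    out <- cbind(el[rep(1L, length(sel)), , drop = FALSE],
                 data.frame(gene = cand$gene, distance = gaps,
                            relation = rel,
                            nearest = seq_along(sel) == ord[1L],
                            stringsAsFactors = FALSE))
    rows[[i]] <- out
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) {
    res <- cbind(elements[0, , drop = FALSE],
                 data.frame(gene = character(0), distance = integer(0),
                            relation = character(0), nearest = logical(0)))
  }
  rownames(res) <- NULL
  res
}

#' Merge overlapping intervals into non-overlapping regions
#'
#' Intervals are merged iff they share at least one base; bookended
#' half-open intervals (e.g. `[0,10)` and `[10,20)`) are kept separate. Output
#' is sorted by (chrom, start) and pairwise disjoint, and covers exactly the
#' union of input base positions. Idempotent.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame `chrom`, `start`, `end` of merged regions.
#' @export
merge_regions <- function(intervals) {
  validate_intervals(intervals)
  if (!nrow(intervals)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  ## min.gapwidth = 0: merge only on shared bases, never across a bookend
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- GenomicRanges::sort(red)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

#' Classify an element's positional relation to a gene
#'
#' Precedence: `exonic` (overlaps any exon by >= 1 base) > `intronic`
#' (overlaps the gene body) > flank. Flanks are strand-aware: the 5' side of
#' the gene is `upstream`, so an element past the end of a minus-strand gene
#' is upstream of it.
#'
#' @param element one-row data.frame or list with `chrom`, `start`, `end`.
#' @param gene one-row data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param exons optional data.frame (`gene`, `start`, `end`).
#' @param radius_bp contract radius; the element must lie within it.
#' @return list with `relation` (one of exonic/intronic/upstream/downstream)
#'   and `distance` (gap to the gene body, 0 for exonic/intronic).
#' @export
classify_relation <- function(element, gene, exons = NULL, radius_bp = Inf) {
  gap <- interval_gap(element$start, element$end, gene$start, gene$end)
  if (gap > radius_bp) {
    stop("classify_relation: element lies outside the selection radius for this gene",
         call. = FALSE)
  }
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  if (!is.null(exons)) {
    ex <- exons[exons$gene == gene$gene, , drop = FALSE]
    if (nrow(ex) && any(overlaps(element$start, element$end, ex$start, ex$end))) {
      return(list(relation = "exonic", distance = 0L))
    }
  }
  if (overlaps(element$start, element$end, gene$start, gene$end)) {
    return(list(relation = "intronic", distance = 0L))
  }
  before <- element$end <= gene$start  # element on the lower-coordinate side
  minus <- identical(as.character(gene$strand), "-")
  rel <- if (xor(before, minus)) "upstream" else "downstream"
  list(relation = rel, distance = as.integer(gap))
}

#' Summarize element relations
#'
#' Counts selected elements by positional relation and element type,
#' mirroring the region-annotation bookkeeping of the pipeline report.
#'
#' @param annotation output of [select_near()], rows with `nearest = TRUE`
#'   are counted once per element.
#' @return list with `by_relation` and `by_type` count tables.
#' @export
summarize_relations <- function(annotation) {
  ann <- annotation[annotation$nearest, , drop = FALSE]
  out <- list(by_relation = table(ann$relation))
  if ("element_type" %in% names(ann)) out$by_type <- table(ann$element_type)
  out
}
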