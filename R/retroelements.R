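## Alu substructure localization and poly(A)-tail run-length arithmetic.
##
## An Alu element is dimeric: left monomer, A-rich linker, right monomer,
## and a 3' poly(A)-tail. Human Alu tails average 21-26 bp; single-base
## substitutions in a short spacer next to the tail can merge adjacent A
## runs, extending the tail well beyond that range and potentially restoring
## retrotransposition competence.

#' Locate a variant within Alu substructure
#'
#' Containment against the element's annotated sub-intervals, which are
#' 0-based half-open genomic coordinates ordered 5' to 3' on the element's
#' strand.
#'
#' @param variant_pos 1-based genomic position of the variant.
#' @param alu list or one-row data.frame with 0-based half-open interval
#'   columns `start`, `end` (whole element) and
#'   `left_monomer_start`/`_end`, `linker_start`/`_end`,
#'   `right_monomer_start`/`_end`, `tail_start`/`_end`.
#' @return one of `"left_monomer"`, `"linker"`, `"right_monomer"`, `"tail"`,
#'   `"outside"`.
#' @export
locate_in_alu <- function(variant_pos, alu) {
  p0 <- variant_pos - 1L  # 0-based position
  inside <- function(s, e) !is.na(s) && !is.na(e) && p0 >= s && p0 < e
  parts <- list(tail = c(alu$tail_start, alu$tail_end),
                linker = c(alu$linker_start, alu$linker_end),
                left_monomer = c(alu$left_monomer_start, alu$left_monomer_end),
                right_monomer = c(alu$right_monomer_start, alu$right_monomer_end))
  for (nm in names(parts)) {
    iv <- parts[[nm]]
    if (!is.na(iv[1]) && (iv[1] < alu$start || iv[2] > alu$end)) {
      stop("locate_in_alu: substructure interval outside the element interval",
           call. = FALSE)
    }
  }
  for (nm in names(parts)) {
    iv <- parts[[nm]]
    if (inside(iv[1], iv[2])) return(nm)
  }
  if (inside(alu$start, alu$end)) return("body")
  "outside"
}

## Maximal homopolymer run of `base` containing 1-based position `anchor`.
## Returns 0 when the anchor base itself differs from `base`.
run_length_at <- function(chars, anchor, base) {
  if (anchor < 1L || anchor > length(chars)) return(0L)
  if (chars[anchor] != base) return(0L)
  lo <- anchor
  while (lo > 1L && chars[lo - 1L] == base) lo <- lo - 1L
  hi <- anchor
  while (hi < length(chars) && chars[hi + 1L] == base) hi <- hi + 1L
  hi - lo + 1L
}

#' Poly(A)-tail run length before and after applying a variant
#'
#' Measures the maximal uninterrupted homopolymer run of the tail base
#' containing the annotated tail anchor, applies a single-nucleotide
#' substitution to the sequence, and measures again. The tail base is `A` on
#' a plus-strand element and `T` on a minus-strand element (the sequence is
#' taken as the reference plus strand). Runs are strict homopolymers:
#' a spacer-merging substitution extends the run by
#' `left_run + right_run + 1 - before`.
#'
#' @param sequence character string (or `Biostrings::DNAString`) covering the
#'   element and flanks.
#' @param anchor 1-based position of the annotated tail anchor within
#'   `sequence`.
#' @param pos 1-based position of the variant within `sequence`.
#' @param ref,alt single-base reference and alternate alleles, on the plus
#'   strand of `sequence`.
#' @param strand element strand, `"+"` (tail base A) or `"-"` (tail base T).
#' @return list: `before`, `after`, `extension = after - before`, and
#'   `region` = `"tail"` if the variant sits inside the pre-variant run,
#'   `"adjacent"` otherwise.
#' @export
polyA_extension <- function(sequence, anchor, pos, ref, alt, strand = "+") {
  seq_chr <- toupper(as.character(sequence))
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("polyA_extension: only single-nucleotide substitutions are supported",
         call. = FALSE)
  }
  chars <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  if (pos < 1L || pos > length(chars)) {
    stop("polyA_extension: variant position outside the provided sequence",
         call. = FALSE)
  }
  if (chars[pos] != toupper(ref)) {
    stop(sprintf("polyA_extension: reference mismatch at position %d (sequence has %s, variant says %s)",
                 pos, chars[pos], ref), call. = FALSE)
  }
  base <- if (identical(strand, "-")) "T" else "A"
  before <- run_length_at(chars, anchor, base)
  edited <- chars
  edited[pos] <- toupper(alt)
  after <- run_length_at(edited, anchor, base)
  in_run <- before > 0L && chars[pos] == base && {
    lo <- anchor; while (lo > 1L && chars[lo - 1L] == base) lo <- lo - 1L
    pos >= lo && pos < lo + before
  }
  list(before = before, after = after, extension = after - before,
       region = if (in_run) "tail" else "adjacent")
}

#' Tabulate poly(A) effects for a set of variants
#'
#' Applies [locate_in_alu()] and [polyA_extension()] to every variant that
#' falls inside an annotated element. Sequences are per-element, with
#' substructure coordinates giving each element's offset.
#'
#' @param sequences named character vector (or `DNAStringSet`) of element
#'   sequences.
#' @param alu_table data.frame, one row per element: `name`, `strand`,
#'   `seq_offset` (0-based genomic start of the sequence), substructure
#'   columns as in [locate_in_alu()], and `tail_anchor_pos` (1-based genomic).
#' @param variants data.frame: `chrom`, `pos` (1-based genomic), `ref`,
#'   `alt`, `element` (matching `alu_table$name`).
#' @return data.frame: variant key, element, region label, `before`,
#'   `after`, `extension`.
#' @export
polya_table <- function(sequences, alu_table, variants) {
  nm <- names(sequences)
  sequences <- as.character(sequences)
  names(sequences) <- nm
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    a <- alu_table[alu_table$name == v$element, , drop = FALSE]
    if (!nrow(a)) next
    region <- locate_in_alu(v$pos, a)
    local_pos <- v$pos - a$seq_offset
    local_anchor <- a$tail_anchor_pos - a$seq_offset
    res <- polyA_extension(sequences[[a$name]], anchor = local_anchor,
                           pos = local_pos, ref = v$ref, alt = v$alt,
                           strand = a$strand)
    rows[[i]] <- data.frame(
      key = variant_key(v$chrom, v$pos, v$ref, v$alt),
      element = a$name, region = region,
      before = res$before, after = res$after, extension = res$extension,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(key = character(0), element = character(0),
                      region = character(0), before = integer(0),
                      after = integer(0), extension = integer(0))
  }
  out
}
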