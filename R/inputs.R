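## File-level plumbing: writing the full synthetic input bundle and reading
## each input format back (gene models as TSV, element annotations as BED6+,
## the AIM panel and metadata as TSV, cohort VCFs through vcfR).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", ...)
}

#' Write every pipeline input for a synthetic study
#'
#' Lays out gene models (with exon structure and differential-expression
#' statistics), HERV intervals placed intronic to, within radius of, and
#' beyond radius of the genes, study variants inside the in-radius elements
#' plus out-of-region decoys, the AIM reference panel, case blood / case
#' tumor / control VCFs, an external frequency reference, Alu sequences with
#' substructure, and ground-truth tables.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return invisible list with `paths` (named file paths) and `truth`.
#' @export
simulate_inputs <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  ## ---- annotations --------------------------------------------------------
  ng <- config$n_genes
  nde <- config$n_de_genes
  gstart <- 60000L + (seq_len(ng) - 1L) * 120000L
  genes <- data.frame(
    gene = sprintf("CPG%02d", seq_len(ng)),
    chrom = "chr1", start = gstart, end = gstart + 30000L,
    strand = rep_len(c("+", "-"), ng),
    exon_starts = paste(gstart, gstart + 12000L, gstart + 25000L, sep = ","),
    exon_ends = paste(gstart + 1000L, gstart + 13000L, gstart + 26000L, sep = ","),
    log2fc = c(rep_len(c(2.1, -1.8), nde), rep(0.2, ng - nde)),
    padj = c(rep(0.001, nde), rep(0.6, ng - nde)),
    stringsAsFactors = FALSE)

  herv_fams <- c("MSTA", "MLT1A", "LTR12C", "MLT1J", "LTR41B")
  hervs <- do.call(rbind, lapply(seq_len(ng), function(i) {
    s <- gstart[i]
    data.frame(
      chrom = "chr1",
      start = c(s + 14000L, s - 19000L, s - 45000L),
      end = c(s + 15200L, s - 17800L, s - 43800L),
      name = sprintf("herv_%02d_%s", i, c("intronic", "flank", "far")),
      score = 0L,
      strand = c("+", "-", "+"),
      family = herv_fams[(i + 0:2) %% length(herv_fams) + 1L],
      element_type = c("soloLTR", "soloLTR", "complete"),
      stringsAsFactors = FALSE)
  }))

  ## ---- variant placement --------------------------------------------------
  de <- filter_de_cpgs(genes)
  de_idx <- match(de$gene, genes$gene)
  in_region_iv <- hervs[hervs$name %in%
                          sprintf("herv_%02d_%s", rep(de_idx, each = 2),
                                  c("intronic", "flank")), , drop = FALSE]
  out_region_iv <- hervs[grepl("_far$", hervs$name), , drop = FALSE]

  place <- function(iv, n) {
    per <- ceiling(n / nrow(iv))
    pos <- integer(0)
    chs <- character(0)
    for (i in seq_len(nrow(iv))) {
      k <- min(per, n - length(pos))
      if (k <= 0) break
      pos <- c(pos, iv$start[i] + 10L + 9L * seq_len(k))
      chs <- c(chs, rep(iv$chrom[i], k))
    }
    data.frame(chrom = chs, pos = pos, stringsAsFactors = FALSE)
  }
  pin <- place(in_region_iv, config$n_variants)
  pout <- place(out_region_iv, config$n_decoy)
  positions <- rbind(pin, pout)
  nt <- nrow(positions)
  positions$ref <- rep_len(c("A", "C", "G", "T"), nt)
  positions$alt <- rep_len(c("G", "T", "A", "C"), nt)

  ## ---- cohort -------------------------------------------------------------
  panel <- simulate_panel(config)
  cohort <- simulate_cohort(panel, config, positions = positions)
  is_case_col <- cohort$samples$cohort == "case"

  write_tsv(panel, p("panel.tsv"))
  write_tsv(genes, p("genes.tsv"))
  utils::write.table(hervs, p("hervs.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(cohort$samples[, c("sample_id", "cohort", "sex")], p("samples.tsv"))

  keep <- cohort$control_site_keep
  write_vcf(p("case_blood.vcf"), cohort$sites[, c("chrom", "pos", "id", "ref", "alt")],
            cohort$gt_blood)
  write_vcf(p("case_tumor.vcf"), cohort$sites[, c("chrom", "pos", "id", "ref", "alt")],
            cohort$gt_tumor)
  write_vcf(p("controls.vcf"),
            cohort$sites[keep, c("chrom", "pos", "id", "ref", "alt")],
            cohort$gt_control)

  ## ---- external frequency reference --------------------------------------
  vt <- cohort$truth$variant_classes
  ctrl_dos <- cohort$dosage_blood[!is_case_col, , drop = FALSE]
  ctrl_af <- colMeans(ctrl_dos) / 2
  ext <- vapply(seq_len(nrow(vt)), function(i) {
    cls <- vt$class[i]
    if (cls %in% c("rare_enriched", "somatic", "linked")) 0.002
    else if (cls == "extracted_only") 0.03
    else if (cls == "db_discrepant") 0.0
    else if (cls == "decoy") NA_real_
    else round(ctrl_af[i], 4)
  }, numeric(1))
  ext_tab <- data.frame(key = vt$key, maf_external = ext,
                        stringsAsFactors = FALSE)
  ext_tab <- ext_tab[!is.na(ext_tab$maf_external), , drop = FALSE]
  write_tsv(ext_tab, p("external_maf.tsv"))

  ## ---- ground truth -------------------------------------------------------
  write_tsv(vt, p("truth_variants.tsv"))
  write_tsv(cohort$samples, p("truth_samples.tsv"))

  ## ---- retroelement sequences --------------------------------------------
  retro <- simulate_retro_sequences(config)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(retro$sequences),
                              p("alu_sequences.fasta"))
  write_tsv(retro$alu_table, p("alu_structure.tsv"))
  write_tsv(retro$variants[, c("chrom", "pos", "ref", "alt", "element")],
            p("alu_variants.tsv"))
  write_tsv(retro$variants, p("truth_alu.tsv"))

  paths <- c(panel = p("panel.tsv"), genes = p("genes.tsv"),
             hervs = p("hervs.bed"), samples = p("samples.tsv"),
             case_blood = p("case_blood.vcf"), case_tumor = p("case_tumor.vcf"),
             controls = p("controls.vcf"), external = p("external_maf.tsv"),
             alu_fasta = p("alu_sequences.fasta"),
             alu_structure = p("alu_structure.tsv"),
             alu_variants = p("alu_variants.tsv"),
             truth_variants = p("truth_variants.tsv"),
             truth_samples = p("truth_samples.tsv"),
             truth_alu = p("truth_alu.tsv"))
  invisible(list(paths = paths, truth = cohort$truth,
                 retro_truth = retro$variants))
}

#' Read a gene-model TSV
#'
#' Expects columns `gene`, `chrom`, `start`, `end`, `strand`,
#' `exon_starts`, `exon_ends` (comma-separated 0-based half-open), `log2fc`,
#' `padj`.
#'
#' @param path file path.
#' @return list with `genes` (one row per gene) and `exons`
#'   (`gene`, `start`, `end`).
#' @export
read_genes_tsv <- function(path) {
  g <- read_tsv(path)
  check_columns(g, c("gene", "chrom", "start", "end", "strand",
                     "exon_starts", "exon_ends", "log2fc", "padj"),
                "gene table")
  exons <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    s <- as.integer(strsplit(as.character(g$exon_starts[i]), ",")[[1]])
    e <- as.integer(strsplit(as.character(g$exon_ends[i]), ",")[[1]])
    data.frame(gene = g$gene[i], start = s, end = e, stringsAsFactors = FALSE)
  }))
  list(genes = g[, c("gene", "chrom", "start", "end", "strand",
                     "log2fc", "padj")],
       exons = exons)
}

#' Read a BED6+ element annotation file
#'
#' BED columns chrom/start/end/name/score/strand followed by `family` and
#' `element_type`.
#'
#' @param path file path.
#' @return data.frame of elements.
#' @export
read_herv_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(b)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (ncol(b) >= 8) names(b)[7:8] <- c("family", "element_type")
  b
}

#' Read an AIM reference panel TSV
#'
#' @param path file with `marker_id`, `chrom`, `pos`, `ref`, `alt`, and one
#'   `freq_<pop>` column per reference population.
#' @return data.frame as stored.
#' @export
read_panel_tsv <- function(path) {
  panel <- read_tsv(path)
  check_columns(panel, c("marker_id", "chrom", "pos", "ref", "alt"),
                "panel table")
  if (!length(grep("^freq_", names(panel)))) {
    stop_schema("panel table", "freq_<population>")
  }
  panel
}
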