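## End-to-end orchestration: from annotation + VCF inputs to the triage
## table, Manhattan data, rare-variant table, poly(A) table, and a hashed
## output manifest.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters. Input files are checked for
#' existence at validation time, before any stage runs.
#'
#' @param input_dir directory containing the input bundle (as written by
#'   [simulate_inputs()] or assembled by hand with the same file names).
#' @param output_dir directory for stage outputs (created).
#' @param radius_bp element selection radius (default 20000).
#' @param alpha family-wise alpha for the multiplicity threshold.
#' @param threshold_n optional explicit divisor for the threshold (default:
#'   the number of variants actually tested).
#' @param split_trials,seed stratified-split randomization settings.
#' @param missing_to_ref cohort-merge convention for unseen genotypes.
#' @param dagger_abs,dagger_rel training/validation consistency thresholds.
#' @param diamond_abs,diamond_fold cross-database discrepancy thresholds.
#' @param rare_case_maf,rare_control_maf,enrich_fold rare-screen thresholds.
#' @param somatic_delta minimum blood-to-tumor shift.
#' @param ld_r2 linkage cluster threshold.
#' @param run_polya toggle for the Alu poly(A) stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            radius_bp = 20000, alpha = 0.05,
                            threshold_n = NULL,
                            split_trials = 20, seed = 1,
                            missing_to_ref = TRUE,
                            dagger_abs = 0.10, dagger_rel = 2,
                            diamond_abs = 0.10, diamond_fold = 2,
                            rare_case_maf = 0.10, rare_control_maf = 0.01,
                            enrich_fold = 10, somatic_delta = 0.02,
                            ld_r2 = 0.8, run_polya = TRUE) {
  cfg <- as.list(environment())
  files <- c("genes.tsv", "hervs.bed", "panel.tsv", "samples.tsv",
             "case_blood.vcf", "case_tumor.vcf", "controls.vcf",
             "external_maf.tsv")
  if (cfg$run_polya) {
    files <- c(files, "alu_sequences.fasta", "alu_structure.tsv",
               "alu_variants.tsv")
  }
  missing <- files[!file.exists(file.path(input_dir, files))]
  if (length(missing)) {
    stop(sprintf("pipeline_config: missing input file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

in_merged_regions <- function(chrom, pos, regions) {
  ## pos is 1-based; regions are 0-based half-open
  vapply(seq_along(pos), function(i) {
    any(regions$chrom == chrom[i] & regions$start < pos[i] &
          pos[i] <= regions$end)
  }, logical(1))
}

#' Run the full triage pipeline
#'
#' Stages, in dependency order: differential-expression filter and element
#' selection; cohort VCF reading, multiallelic splitting and merge; AIM-based
#' admixture estimation; stratified 3:2 split; per-variant unadjusted and
#' adjusted logistic association for blood and tumor samples in training and
#' validation sets; the exclusion cascade, rare-variant screen, somatic flag
#' and linkage clustering; the Alu poly(A) stage; and a manifest of all
#' outputs with content hashes. Any stage error aborts with the failing
#' stage named.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with `manifest` (file, md5), `counts` (per-stage
#'   bookkeeping), `threshold`, and the main result tables (`triage`,
#'   `assoc`, `ancestry`, `polya`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ip <- function(f) file.path(config$input_dir, f)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## ---- stage: regions -----------------------------------------------------
  reg <- stage("regions", {
    gm <- read_genes_tsv(ip("genes.tsv"))
    hervs <- read_herv_bed(ip("hervs.bed"))
    de <- filter_de_cpgs(gm$genes)
    ann <- select_near(hervs, de, exons = gm$exons,
                       radius_bp = config$radius_bp)
    sel <- ann[ann$nearest, c("chrom", "start", "end")]
    regions <- merge_regions(sel)
    utils::write.table(regions, op("regions.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_tsv(ann, op("herv_annotation.tsv"))
    list(regions = regions, annotation = ann, de = de)
  })
  outputs <- c(outputs, "regions.bed", "herv_annotation.tsv")
  counts$n_de_genes <- nrow(reg$de)
  counts$n_elements_selected <- sum(reg$annotation$nearest)
  counts$n_regions <- nrow(reg$regions)

  ## ---- stage: cohort ------------------------------------------------------
  coh <- stage("cohort", {
    case_blood <- read_cohort_vcf(ip("case_blood.vcf"), "case", "blood")
    case_tumor <- read_cohort_vcf(ip("case_tumor.vcf"), "case", "tumor")
    controls <- read_cohort_vcf(ip("controls.vcf"), "control", "control")
    merged_blood <- merge_cohorts(case_blood, controls,
                                  missing_to_ref = config$missing_to_ref)
    merged_tumor <- merge_cohorts(case_tumor, controls,
                                  missing_to_ref = config$missing_to_ref)
    meta <- read_tsv(ip("samples.tsv"))
    list(blood = merged_blood, tumor = merged_tumor, meta = meta)
  })

  ## ---- stage: ancestry ----------------------------------------------------
  anc <- stage("ancestry", {
    panel <- read_panel_tsv(ip("panel.tsv"))
    pf <- panel_freq_matrix(panel)
    panel_keys <- variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)
    hit <- match(panel_keys, coh$blood$variants$key)
    if (all(is.na(hit))) stop("no AIM marker found in the merged cohort")
    usable <- !is.na(hit)
    aim_geno <- coh$blood$geno[, hit[usable], drop = FALSE]
    prof <- estimate_admixture_all(aim_geno, pf[usable, , drop = FALSE])
    write_tsv(prof, op("ancestry.tsv"))
    prof
  })
  outputs <- c(outputs, "ancestry.tsv")
  counts$n_samples_ancestry <- nrow(anc)

  ## ---- stage: split -------------------------------------------------------
  spl <- stage("split", {
    meta <- coh$meta
    lab <- anc$label[match(meta$sample_id, anc$sample_id)]
    is_case <- meta$cohort == "case"
    case_split <- stratified_split(meta$sample_id[is_case],
                                   paste(meta$sex[is_case]),
                                   n_trials = config$split_trials,
                                   seed = config$seed)
    ctrl_split <- stratified_split(meta$sample_id[!is_case],
                                   paste(meta$sex[!is_case], lab[!is_case]),
                                   n_trials = config$split_trials,
                                   seed = config$seed + 1L)
    assign_set <- function(ids) {
      ifelse(ids %in% c(case_split$training, ctrl_split$training),
             "training", "validation")
    }
    tab <- data.frame(sample_id = meta$sample_id,
                      cohort = meta$cohort,
                      set = assign_set(meta$sample_id),
                      stringsAsFactors = FALSE)
    write_tsv(tab, op("split.tsv"))
    tab
  })
  outputs <- c(outputs, "split.tsv")
  counts$n_training <- sum(spl$set == "training")
  counts$n_validation <- sum(spl$set == "validation")

  ## ---- stage: association -------------------------------------------------
  assoc <- stage("association", {
    in_reg <- function(gm) {
      v <- gm$variants
      v$key[in_merged_regions(v$chrom, v$pos, reg$regions)]
    }
    test_keys <- sort(unique(c(in_reg(coh$blood), in_reg(coh$tumor))))
    n_thr <- config$threshold_n %||% length(test_keys)
    thr <- significance_threshold(config$alpha, n_thr)

    qmat <- as.matrix(anc[, grep("^q_", names(anc)), drop = FALSE])
    rownames(qmat) <- anc$sample_id
    covs <- ancestry_covariates(qmat)

    run_block <- function(gm, type) {
      sm <- gm$samples
      sets <- spl$set[match(sm$sample_id, spl$sample_id)]
      sex <- coh$meta$sex[match(sm$sample_id, coh$meta$sample_id)]
      anc_cov <- covs[match(sm$sample_id, rownames(covs)), , drop = FALSE]
      pheno <- as.integer(sm$cohort == "case")
      rows <- list()
      for (set_name in c("training", "validation")) {
        use <- sets == set_name
        for (k in test_keys) {
          if (!k %in% gm$variants$key) next
          r <- test_variant(gm$geno[use, k], pheno[use], sex = sex[use],
                            ancestry = anc_cov[use, , drop = FALSE], key = k)
          r$set <- set_name
          r$sample_type <- type
          rows[[length(rows) + 1L]] <- r
        }
      }
      do.call(rbind, rows)
    }
    res <- rbind(run_block(coh$blood, "blood"), run_block(coh$tumor, "tumor"))
    write_tsv(res, op("association.tsv"))
    ## Manhattan-style table: adjusted training-set blood p-values by position
    vb <- coh$blood$variants
    tr <- res[res$set == "training" & res$sample_type == "blood", ]
    mh <- data.frame(chrom = vb$chrom[match(tr$key, vb$key)],
                     pos = vb$pos[match(tr$key, vb$key)],
                     neg_log10_p = -log10(tr$p_adj),
                     key = tr$key, stringsAsFactors = FALSE)
    mh <- mh[order(mh$chrom, mh$pos), ]
    write_tsv(mh, op("manhattan.tsv"))
    list(results = res, threshold = thr, test_keys = test_keys)
  })
  outputs <- c(outputs, "association.tsv", "manhattan.tsv")
  counts$n_variants_tested <- length(assoc$test_keys)
  conf_sum <- confounding_summary(
    assoc$results[assoc$results$set == "training" &
                    assoc$results$sample_type == "blood", ],
    threshold = assoc$threshold$threshold)
  counts$confounding <- conf_sum

  ## ---- stage: triage ------------------------------------------------------
  tri <- stage("triage", {
    ext <- read_tsv(ip("external_maf.tsv"))
    decisions <- triage_variants(
      assoc$results, blood = coh$blood, tumor = coh$tumor, split = spl,
      external = ext, threshold = assoc$threshold$threshold, config = config)
    write_triage_table(decisions, op("triage.tsv"))
    rare <- decisions[decisions$rare_class %in% c("rare", "rare_enriched"), ]
    write_tsv(rare, op("rare_variants.tsv"))
    decisions
  })
  outputs <- c(outputs, "triage.tsv", "rare_variants.tsv")
  counts$n_confirmed <- sum(tri$status == "confirmed")
  counts$n_excluded <- sum(tri$status == "excluded")
  counts$by_code <- list(dagger = sum(tri$dagger), ddagger = sum(tri$ddagger),
                         diamond = sum(tri$diamond))
  stopifnot(nrow(tri) == length(assoc$test_keys))

  ## ---- stage: polya -------------------------------------------------------
  polya <- NULL
  if (config$run_polya) {
    polya <- stage("polya", {
      seqs <- Biostrings::readDNAStringSet(ip("alu_sequences.fasta"))
      seqv <- stats::setNames(as.character(seqs),
                              sub("\\s.*$", "", names(seqs)))
      alu <- read_tsv(ip("alu_structure.tsv"))
      av <- read_tsv(ip("alu_variants.tsv"))
      tab <- polya_table(seqv, alu, av)
      write_tsv(tab, op("polya.tsv"))
      tab
    })
    outputs <- c(outputs, "polya.tsv")
  }

  ## ---- manifest -----------------------------------------------------------
  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(config$output_dir, outputs))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, op("manifest.tsv"))

  invisible(list(manifest = manifest, counts = counts,
                 threshold = assoc$threshold, triage = tri,
                 assoc = assoc$results, ancestry = anc, polya = polya,
                 regions = reg$regions))
}

## Per-variant triage decisions from association results and frequencies.
triage_variants <- function(results, blood, tumor, split, external,
                            threshold, config) {
  keys <- sort(unique(results$key))
  conf <- confirm_variants(results, threshold)

  maf_of <- function(gm, key, ids) {
    if (!key %in% gm$variants$key) return(NA_real_)
    codes <- gm$geno[rownames(gm$geno) %in% ids, key]
    if (all(is.na(codes))) return(NA_real_)
    allele_frequency(codes)
  }
  case_blood_ids <- blood$samples$sample_id[blood$samples$cohort == "case"]
  case_tumor_ids <- tumor$samples$sample_id[tumor$samples$cohort == "case"]
  ctrl_ids <- blood$samples$sample_id[blood$samples$cohort == "control"]
  train_ids <- split$sample_id[split$set == "training"]
  valid_ids <- split$sample_id[split$set == "validation"]

  sig <- function(key, set_name, type) {
    r <- results[results$key == key & results$set == set_name &
                   results$sample_type == type, ]
    nrow(r) > 0 && !is.na(r$p_adj[1]) && r$p_adj[1] < threshold
  }

  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    vrow <- blood$variants[blood$variants$key == k, , drop = FALSE]
    if (!nrow(vrow)) vrow <- tumor$variants[tumor$variants$key == k, , drop = FALSE]
    tri_allelic <- isTRUE(vrow$multiallelic_split[1])
    m_blood <- maf_of(blood, k, case_blood_ids)
    m_tumor <- maf_of(tumor, k, case_tumor_ids)
    m_ctrl <- maf_of(blood, k, ctrl_ids)
    m_ext <- external$maf_external[match(k, external$key)]
    m_bt <- maf_of(blood, k, intersect(case_blood_ids, train_ids))
    m_bv <- maf_of(blood, k, intersect(case_blood_ids, valid_ids))
    m_tt <- maf_of(tumor, k, intersect(case_tumor_ids, train_ids))
    m_tv <- maf_of(tumor, k, intersect(case_tumor_ids, valid_ids))

    dag <- isTRUE(suppressWarnings(
      dagger_screen(m_bt, m_bv, config$dagger_abs, config$dagger_rel))) ||
      isTRUE(suppressWarnings(
        dagger_screen(m_tt, m_tv, config$dagger_abs, config$dagger_rel)))
    ddag <- ddagger_screen(sig(k, "training", "blood"),
                           sig(k, "validation", "blood"),
                           sig(k, "training", "tumor"),
                           sig(k, "validation", "tumor"))
    dia <- diamond_screen(m_ctrl, if (length(m_ext)) m_ext else NA,
                          tri_allelic = tri_allelic,
                          t_abs = config$diamond_abs,
                          t_fold = config$diamond_fold)
    rare_cls <- rare_screen(m_blood, m_ctrl,
                            if (length(m_ext)) m_ext else NA,
                            case_min = config$rare_case_maf,
                            control_max = config$rare_control_maf,
                            enrich_fold = config$enrich_fold)
    som <- !is.na(m_blood) && !is.na(m_tumor) &&
      somatic_flag(m_blood, m_tumor, config$somatic_delta)

    ci <- match(k, conf$key)
    confirmed <- conf$confirmed[ci]
    ## the common-variant screens only apply to confirmed candidates; the
    ## rare screen and somatic flag run for everyone
    codes <- c(dagger = dag, ddagger = ddag, diamond = dia$exclude)
    excluded <- confirmed && any(codes) || ddag
    status <- if (excluded) "excluded"
      else if (confirmed) "confirmed"
      else if (rare_cls %in% c("rare", "rare_enriched")) "rare_candidate"
      else if (som) "somatic_candidate"
      else "not_significant"
    rows[[i]] <- data.frame(
      key = k, id = vrow$id[1] %||% ".",
      chrom = vrow$chrom[1], pos = vrow$pos[1], ref = vrow$ref[1],
      alt = vrow$alt[1],
      maf_case_blood = m_blood, maf_case_tumor = m_tumor,
      maf_control = m_ctrl,
      maf_external = if (length(m_ext)) m_ext else NA_real_,
      tri_allelic = tri_allelic,
      confirmed = confirmed, adjusted_only = conf$adjusted_only[ci],
      dagger = dag, ddagger = ddag, diamond = dia$exclude,
      diamond_inconclusive = dia$inconclusive,
      rare_class = rare_cls, somatic = som,
      status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)

  ## linkage clusters among rare/somatic candidates
  cand <- out$key[out$rare_class %in% c("rare", "rare_enriched") | out$somatic]
  out$ld_cluster <- NA_integer_
  if (length(cand) >= 2) {
    geno <- blood$geno[, intersect(cand, colnames(blood$geno)), drop = FALSE]
    cl <- ld_clusters(geno, r2_min = config$ld_r2)
    out$ld_cluster[match(names(cl$cluster), out$key)] <- cl$cluster
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$alt), ]
}

#' Write the triage table
#'
#' One row per variant with frequency columns, the exclusion-code column
#' using dagger/double-dagger/diamond marks, and rare/somatic flags, in
#' deterministic (chrom, pos, alt) order. Unicode marks get an ASCII alias
#' column for toolchain safety.
#'
#' @param decisions output of the triage stage.
#' @param path output TSV path.
#' @return invisible path.
#' @export
write_triage_table <- function(decisions, path) {
  code_uni <- function(d) {
    paste0(ifelse(d$dagger, "†", ""),
           ifelse(d$ddagger, "‡", ""),
           ifelse(d$diamond, "◊", ""))
  }
  code_ascii <- function(d) {
    x <- cbind(ifelse(d$dagger, "dagger", NA),
               ifelse(d$ddagger, "ddagger", NA),
               ifelse(d$diamond, "diamond", NA))
    apply(x, 1, function(r) paste(stats::na.omit(r), collapse = ","))
  }
  tab <- data.frame(
    name = decisions$id, key = decisions$key,
    maf_case_blood = decisions$maf_case_blood,
    maf_case_tumor = decisions$maf_case_tumor,
    maf_control = decisions$maf_control,
    maf_external = decisions$maf_external,
    codes = code_uni(decisions), codes_ascii = code_ascii(decisions),
    status = decisions$status, rare_class = decisions$rare_class,
    somatic = decisions$somatic, ld_cluster = decisions$ld_cluster,
    stringsAsFactors = FALSE)
  write_tsv(tab, path)
  invisible(path)
}
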