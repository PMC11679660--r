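## Synthetic-data module: generates every input the triage pipeline consumes
## -- reference AIM panel, annotations, admixed case/control genotypes with
## planted effects, and Alu sequences -- with known ground truth, written in
## standard formats (VCF v4.2, BED, TSV, FASTA).
##
## Defaults describe a desk-scale analogue of a targeted case-control study:
## four reference populations, 85 ancestry-informative markers, a few hundred
## cases against a larger control cohort, planted per-allele log-odds effects
## at a handful of common variants, ancestry-driven confounding, case-only
## rare variants with tumor-shifted somatic candidates and a linked pair.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data module with validated defaults.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_pop number of reference populations (K >= 2).
#' @param n_aims number of ancestry-informative markers.
#' @param divergence per-marker allele-frequency spread across populations
#'   in `[0, 1]` (Balding-Nichols F). The default emulates a panel of
#'   *selected* ancestry-informative markers, whose inter-population
#'   frequency differentials are far larger than those of random SNPs.
#' @param n_cases,n_controls cohort sizes.
#' @param n_variants number of in-region study variants (the planted classes
#'   below are carved out of this total).
#' @param n_effect number of planted common association hits.
#' @param effect_beta per-allele log-odds of each planted hit.
#' @param n_confounded planted ancestry-confounded variants (strongly
#'   population-divergent frequency, no direct effect).
#' @param n_rare_enriched,n_extracted_only,n_somatic,n_linked planted
#'   rare-variant classes (case-only; see the methods vignette).
#' @param n_db_discrepant planted common variants whose external reference
#'   frequency disagrees with the internal control cohort.
#' @param n_decoy out-of-region variants that region selection must drop.
#' @param rare_case_freq per-allele frequency of rare planted variants in
#'   cases.
#' @param somatic_shift per-allele probability that a reference allele of a
#'   somatic-candidate variant converts to the alternate in the tumor sample
#'   (expected tumor MAF gain is `somatic_shift * (1 - blood MAF)`).
#' @param missing_rate fraction of genotypes set to missing.
#' @param ancestry_effect,sex_effect,baseline phenotype-model coefficients on
#'   the logit scale (ancestry acts through the African admixture component).
#' @param sex_prob probability of sex = 1 (female).
#' @param variant_divergence Balding-Nichols F of ordinary study variants.
#' @param n_genes,n_de_genes,n_alus annotation sizes.
#' @param radius_bp element-selection radius used to lay out annotations.
#' @param fixed_admixture optional length-K vector: give every individual
#'   this admixture vector instead of drawing from the cohort mixture
#'   (useful for degenerate single-population simulations).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_pop = 4, n_aims = 85, divergence = 0.55,
                       n_cases = 200, n_controls = 800, n_variants = 120,
                       n_effect = 3, effect_beta = 1.2,
                       n_confounded = 4, n_rare_enriched = 3,
                       n_extracted_only = 2, n_somatic = 2, n_linked = 2,
                       n_db_discrepant = 2, n_decoy = 10,
                       rare_case_freq = 0.15, somatic_shift = 0.12,
                       missing_rate = 0.02,
                       ancestry_effect = 2.0, sex_effect = 0.5,
                       baseline = -1.4, sex_prob = 0.5,
                       variant_divergence = 0.05,
                       n_genes = 12, n_de_genes = 6, n_alus = 8,
                       radius_bp = 20000, fixed_admixture = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_pop < 2) stop("sim_config: need at least two populations (K >= 2)", call. = FALSE)
  if (cfg$divergence < 0 || cfg$divergence > 1) {
    stop("sim_config: divergence must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("sim_config: missing_rate must lie in [0, 1)", call. = FALSE)
  }
  n_planted <- cfg$n_effect + cfg$n_confounded + cfg$n_rare_enriched +
    cfg$n_extracted_only + cfg$n_somatic + cfg$n_linked + cfg$n_db_discrepant + 2
  if (cfg$n_variants < n_planted) {
    stop("sim_config: n_variants too small for the planted classes", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

## Balding-Nichols draw: ancestral frequency a perturbed per population with
## divergence F, clamped to [0.01, 0.99] to keep likelihoods non-degenerate.
bn_frequencies <- function(a, K, F) {
  M <- length(a)
  if (F == 0) {
    p <- matrix(rep(a, K), M, K)
  } else if (F >= 1) {
    p <- matrix(ifelse(stats::rbinom(M * K, 1, rep(a, K)) == 1, 0.99, 0.01),
                M, K)
  } else {
    shape <- (1 - F) / F
    p <- matrix(stats::rbeta(M * K, rep(a, K) * shape, (1 - rep(a, K)) * shape),
                M, K)
  }
  pmin(pmax(p, 0.01), 0.99)
}

#' Simulate a reference AIM panel
#'
#' Per-population alternate-allele frequencies for each ancestry-informative
#' marker, drawn by a Balding-Nichols construction: a common ancestral
#' frequency perturbed per population, with `divergence` controlling the
#' spread. Frequencies are clamped to `[0.01, 0.99]`.
#'
#' @param config a [sim_config()].
#' @return data.frame: `marker_id`, `chrom`, `pos`, `ref`, `alt`, one
#'   `freq_<pop>` column per population.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$n_aims
  K <- config$n_pop
  pops <- if (K == 4) DEFAULT_POPS else paste0("POP", seq_len(K))
  a <- stats::runif(M, 0.1, 0.9)
  p <- bn_frequencies(a, K, config$divergence)
  colnames(p) <- paste0("freq_", pops)
  data.frame(marker_id = sprintf("aim_%03d", seq_len(M)),
             chrom = "chr9", pos = 10000L * seq_len(M),
             ref = "A", alt = "G", p, stringsAsFactors = FALSE)
}

panel_freq_matrix <- function(panel) {
  cols <- grep("^freq_", names(panel), value = TRUE)
  m <- as.matrix(panel[, cols, drop = FALSE])
  colnames(m) <- sub("^freq_", "", cols)
  rownames(m) <- panel$marker_id
  m
}

## Admixture vectors for a cohort: a mixture of mostly-one-population
## individuals and broadly admixed ones, emulating an American study cohort.
draw_admixture <- function(n, K) {
  base_prob <- if (K == 4) c(0.55, 0.12, 0.12, 0.21) else rep(1 / K, K)
  comp <- sample.int(K + 1L, n, replace = TRUE,
                     prob = c(0.75 * base_prob, 0.25))
  q <- matrix(0, n, K)
  for (i in seq_len(n)) {
    alpha <- if (comp[i] <= K) {
      a <- rep(0.4, K); a[comp[i]] <- 20; a
    } else {
      c(3, rep(1.2, K - 1L))  # admixed, leaning on population 1
    }
    gam <- stats::rgamma(K, alpha)
    q[i, ] <- gam / sum(gam)
  }
  q
}

## Variant class layout inside the in-region variant set. The multiallelic
## site occupies two split records (classes multiallelic_1 / multiallelic_2).
variant_classes <- function(config) {
  with(config, c(rep("effect", n_effect),
                 rep("confounded", n_confounded),
                 c("multiallelic_1", "multiallelic_2"),
                 rep("rare_enriched", n_rare_enriched),
                 rep("extracted_only", n_extracted_only),
                 rep("somatic", n_somatic),
                 rep("linked", n_linked),
                 rep("db_discrepant", n_db_discrepant),
                 rep("common", n_variants - n_effect - n_confounded - 2 -
                       n_rare_enriched - n_extracted_only - n_somatic -
                       n_linked - n_db_discrepant)))
}

rare_classes <- c("rare_enriched", "extracted_only", "somatic", "linked")

#' Simulate an admixed case/control cohort with planted effects
#'
#' Individuals carry an admixture vector q (Dirichlet mixture), a sex
#' covariate, AIM genotypes `g ~ Binomial(2, sum_k q_k p_km)` from the panel,
#' and study-variant genotypes from per-population frequencies. The binary
#' phenotype follows
#' `logit(P) = baseline + sum(effects * dosage) + ancestry_effect * q_AFR +
#' sex_effect * sex`; sampling continues until the case and control quotas
#' fill. Case-only rare variants, tumor-shifted somatic candidates, a linked
#' pair with duplicated genotypes, and a two-alternate multiallelic site are
#' planted afterwards. Genotypes are set missing at `missing_rate`.
#'
#' @param panel output of [simulate_panel()].
#' @param config the same [sim_config()].
#' @param positions optional data.frame assigning `chrom`, `pos`, `ref`,
#'   `alt` to the in-region variants plus `n_decoy` out-of-region decoys
#'   (default: synthetic placeholder coordinates).
#' @return list with `samples` (sample table incl. true q and labels),
#'   `aim_geno`, `sites` (VCF-level site table), `gt_blood`, `gt_tumor`,
#'   `gt_control` (GT string matrices, sites x samples), and `truth`.
#' @export
simulate_cohort <- function(panel, config, positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  P_aim <- panel_freq_matrix(panel)
  K <- ncol(P_aim)
  if (K != config$n_pop) {
    stop("simulate_cohort: panel and config disagree on the number of populations",
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  classes <- variant_classes(config)
  V <- length(classes)
  n_decoy <- config$n_decoy

  if (is.null(positions)) {
    total <- V + n_decoy
    positions <- data.frame(chrom = "chr1",
                            pos = 1000000L + 500L * seq_len(total),
                            ref = rep_len(c("A", "C", "G", "T"), total),
                            alt = rep_len(c("G", "T", "A", "C"), total),
                            stringsAsFactors = FALSE)
  }
  if (nrow(positions) != V + n_decoy) {
    stop("simulate_cohort: positions table must cover every in-region variant and decoy",
         call. = FALSE)
  }
  classes <- c(classes, rep("decoy", n_decoy))
  Vtot <- length(classes)

  ## per-population frequencies for frequency-modelled variants
  freq <- matrix(0, Vtot, K)
  ord_cls <- classes %in% c("effect", "common", "decoy",
                            "multiallelic_1", "multiallelic_2")
  n_ord <- sum(ord_cls)
  anc <- stats::runif(n_ord, 0.08, 0.5)
  freq[ord_cls, ] <- bn_frequencies(anc, K, config$variant_divergence)
  conf_idx <- which(classes == "confounded")
  for (i in conf_idx) {
    f <- rep(0.08, K)
    f[2] <- 0.70   # concentrated in population 2 (AFR in the default panel)
    freq[i, ] <- pmin(pmax(f + stats::runif(K, -0.02, 0.02), 0.01), 0.99)
  }
  dbd_idx <- which(classes == "db_discrepant")
  anc_dbd <- stats::runif(length(dbd_idx), 0.3, 0.5)
  freq[dbd_idx, ] <- bn_frequencies(anc_dbd, K, config$variant_divergence)
  effect_idx <- which(classes == "effect")
  freq[effect_idx, ] <- bn_frequencies(rep(0.3, length(effect_idx)), K,
                                       config$variant_divergence)
  rare_idx <- which(classes %in% rare_classes)

  effects <- data.frame(index = effect_idx,
                        beta = rep(config$effect_beta, length(effect_idx)))
  if (length(effects$index) && any(effects$index > Vtot)) {
    stop("simulate_cohort: planted effect refers to a nonexistent variant index",
         call. = FALSE)
  }

  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  freq_model_idx <- which(!(classes %in% rare_classes))

  q_rows <- list(); sex_v <- integer(0); pheno_v <- integer(0)
  geno_rows <- list()
  got_case <- 0L; got_ctrl <- 0L
  guard <- 0L
  while ((got_case < n_case || got_ctrl < n_ctrl) && guard < 200L) {
    guard <- guard + 1L
    nb <- 2L * (n_case + n_ctrl - got_case - got_ctrl) + 50L
    q <- if (is.null(config$fixed_admixture)) {
      draw_admixture(nb, K)
    } else {
      stopifnot(length(config$fixed_admixture) == K,
                abs(sum(config$fixed_admixture) - 1) < 1e-8)
      matrix(config$fixed_admixture, nb, K, byrow = TRUE)
    }
    sex <- stats::rbinom(nb, 1, config$sex_prob)
    f <- q %*% t(freq)                       # nb x Vtot expected frequencies
    g <- matrix(stats::rbinom(nb * Vtot, 2, as.numeric(f)), nb, Vtot)
    g[, rare_idx] <- 0L
    eta <- config$baseline + config$ancestry_effect * q[, min(2, K)] +
      config$sex_effect * sex
    if (nrow(effects)) {
      eta <- eta + g[, effects$index, drop = FALSE] %*% effects$beta
    }
    y <- stats::rbinom(nb, 1, stats::plogis(as.numeric(eta)))
    for (i in seq_len(nb)) {
      if (y[i] == 1 && got_case < n_case) {
        got_case <- got_case + 1L
      } else if (y[i] == 0 && got_ctrl < n_ctrl) {
        got_ctrl <- got_ctrl + 1L
      } else next
      q_rows[[length(q_rows) + 1L]] <- q[i, ]
      sex_v <- c(sex_v, sex[i])
      pheno_v <- c(pheno_v, y[i])
      geno_rows[[length(geno_rows) + 1L]] <- g[i, ]
    }
  }
  if (got_case < n_case || got_ctrl < n_ctrl) {
    stop("simulate_cohort: could not fill cohort quotas; check the phenotype model",
         call. = FALSE)
  }
  Q <- do.call(rbind, q_rows)
  colnames(Q) <- colnames(P_aim)
  G <- do.call(rbind, geno_rows)
  n <- nrow(G)
  is_case <- pheno_v == 1

  ## case-only rare variants (absent from the control cohort's file)
  for (i in rare_idx) {
    G[is_case, i] <- stats::rbinom(sum(is_case), 2, config$rare_case_freq)
  }
  linked_idx <- which(classes == "linked")
  if (length(linked_idx) >= 2) {
    for (j in linked_idx[-1]) G[, j] <- G[, linked_idx[1]]
  }

  ## tumor genotypes: germline copy plus somatic gains -- each remaining
  ## reference allele converts to the alternate with probability
  ## somatic_shift, so the expected MAF gain is somatic_shift * (1 - AF)
  G_tumor <- G[is_case, , drop = FALSE]
  som_idx <- which(classes == "somatic")
  for (i in som_idx) {
    gains <- stats::rbinom(sum(is_case), 2L - G_tumor[, i],
                           config$somatic_shift)
    G_tumor[, i] <- G_tumor[, i] + gains
  }

  ## AIM genotypes for everyone
  f_aim <- Q %*% t(P_aim)
  G_aim <- matrix(stats::rbinom(n * nrow(P_aim), 2, as.numeric(f_aim)),
                  n, nrow(P_aim))
  colnames(G_aim) <- rownames(P_aim)

  ids <- character(n)
  ids[is_case] <- sprintf("case_%03d", seq_len(sum(is_case)))
  ids[!is_case] <- sprintf("ctrl_%04d", seq_len(sum(!is_case)))
  rownames(G_aim) <- ids
  labels <- if (all(DEFAULT_POPS %in% colnames(Q))) {
    apply(Q, 1, function(qq) classify_ancestry(stats::setNames(qq, colnames(Q))))
  } else {
    rep(NA_character_, n)   # categorical rules are defined for the 4-way panel
  }
  samples <- data.frame(sample_id = ids,
                        cohort = ifelse(is_case, "case", "control"),
                        sex = sex_v, label_true = labels,
                        stringsAsFactors = FALSE)
  qd <- as.data.frame(Q)
  names(qd) <- paste0("q_", colnames(Q))
  samples <- cbind(samples, qd)

  ## --- site-level tables and GT strings -----------------------------------
  ## the two multiallelic split records share one VCF site with ALT "X,Y"
  ma_idx <- which(classes %in% c("multiallelic_1", "multiallelic_2"))
  site_of_variant <- seq_len(Vtot)
  if (length(ma_idx) == 2) site_of_variant[ma_idx[2]] <- ma_idx[1]
  site_ids <- unique(site_of_variant)
  sites <- positions[site_ids, , drop = FALSE]
  sites$id <- sprintf("rs%07d", 100000L + site_ids)
  rownames(sites) <- NULL
  if (length(ma_idx) == 2) {
    k <- which(site_ids == ma_idx[1])
    a1 <- positions$alt[ma_idx[1]]
    ref <- positions$ref[ma_idx[1]]
    a2 <- setdiff(c("A", "C", "G", "T"), c(ref, a1))[1]
    sites$alt[k] <- paste(a1, a2, sep = ",")
  }

  gt_strings <- function(gmat) {
    out <- matrix("./.", nrow = length(site_ids), ncol = nrow(gmat),
                  dimnames = list(NULL, rownames(gmat)))
    for (s in seq_along(site_ids)) {
      vi <- site_ids[s]
      if (length(ma_idx) == 2 && vi == ma_idx[1]) {
        d1 <- gmat[, ma_idx[1]]
        d2 <- gmat[, ma_idx[2]]
        ## combine split dosages back into a two-alt genotype; planted so
        ## that d1 + d2 <= 2
        over <- d1 + d2 > 2
        d2[over] <- 2 - d1[over]
        gt <- character(nrow(gmat))
        for (i in seq_len(nrow(gmat))) {
          al <- c(rep("1", d1[i]), rep("2", d2[i]))
          al <- c(al, rep("0", 2 - length(al)))
          gt[i] <- paste(sort(al), collapse = "/")
        }
        out[s, ] <- gt
      } else {
        d <- gmat[, vi]
        out[s, ] <- c("0/0", "0/1", "1/1")[d + 1L]
      }
    }
    out
  }
  rownames(G) <- ids
  gt_blood_all <- gt_strings(G)
  gt_tumor <- gt_strings(G_tumor)
  ctrl_site_keep <- !(site_ids %in% rare_idx)

  ## AIM sites appended to every cohort file
  aim_sites <- data.frame(chrom = panel$chrom, pos = panel$pos,
                          id = panel$marker_id, ref = panel$ref,
                          alt = panel$alt, stringsAsFactors = FALSE)
  aim_gt <- function(gmat) {
    m <- matrix(c("0/0", "0/1", "1/1")[t(gmat) + 1L],
                nrow = ncol(gmat), ncol = nrow(gmat))
    colnames(m) <- rownames(gmat)
    m
  }

  add_missing <- function(m) {
    mask <- matrix(stats::runif(length(m)) < config$missing_rate,
                   nrow(m), ncol(m))
    m[mask] <- "./."
    m
  }

  gt_blood_full <- add_missing(rbind(gt_blood_all[, is_case, drop = FALSE],
                                     aim_gt(G_aim[is_case, , drop = FALSE])))
  gt_tumor_full <- add_missing(rbind(gt_tumor,
                                     aim_gt(G_aim[is_case, , drop = FALSE])))
  gt_ctrl_full <- add_missing(rbind(gt_blood_all[ctrl_site_keep, !is_case, drop = FALSE],
                                    aim_gt(G_aim[!is_case, , drop = FALSE])))

  keys <- variant_key(positions$chrom, positions$pos, positions$ref, positions$alt)
  if (length(ma_idx) == 2) {
    a2 <- strsplit(sites$alt[which(site_ids == ma_idx[1])], ",")[[1]][2]
    keys[ma_idx[2]] <- variant_key(positions$chrom[ma_idx[1]],
                                   positions$pos[ma_idx[1]],
                                   positions$ref[ma_idx[1]], a2)
  }
  colnames(G) <- keys
  variant_truth <- data.frame(key = keys, class = classes,
                              chrom = positions$chrom, pos = positions$pos,
                              stringsAsFactors = FALSE)
  variant_truth$beta <- 0
  variant_truth$beta[effects$index] <- effects$beta

  truth <- list(q = Q, labels = labels, effects = effects,
                variant_classes = variant_truth,
                rare_case_freq = config$rare_case_freq,
                somatic_shift = config$somatic_shift)

  list(samples = samples, aim_geno = G_aim,
       sites = rbind(cbind(sites, aim = FALSE),
                     cbind(aim_sites, aim = TRUE)),
       gt_blood = gt_blood_full, gt_tumor = gt_tumor_full,
       gt_control = gt_ctrl_full,
       control_site_keep = c(ctrl_site_keep, rep(TRUE, nrow(aim_sites))),
       dosage_blood = G, truth = truth)
}

#' Write a VCF v4.2 file
#'
#' Plain-text writer kept deliberately simple so that a fixed seed yields
#' byte-identical files (no timestamps, no compression).
#'
#' @param path output file.
#' @param sites data.frame: `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param gt character matrix of GT strings, sites x samples, with sample
#'   ids as column names.
#' @export
write_vcf <- function(path, sites, gt) {
  stopifnot(nrow(sites) == nrow(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hervtriage-simulator",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt)), collapse = "\t")),
             con)
  ord <- order(sites$chrom, sites$pos)
  body <- vapply(ord, function(i) {
    paste(c(sites$chrom[i], sites$pos[i], sites$id[i], sites$ref[i],
            sites$alt[i], ".", "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

## Random DNA with no long A runs (interior separator every 5 bases).
random_dna <- function(n, bases = c("C", "G", "T", "A")) {
  paste(sample(bases, n, replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15)),
        collapse = "")
}

#' Simulate Alu element sequences with annotated poly(A) tails
#'
#' Each element carries a left monomer, an A-rich linker, a right monomer,
#' and a 3' poly(A) tail whose true run length is drawn from 21-26 bp (the
#' genomic average range). A configurable subset of elements instead gets a
#' tail of the form `A^a <spacer> A^b` with a planted spacer substitution
#' (`<spacer> > A`) whose ground-truth extension is `a + 1 + b - a`.
#'
#' @param config a [sim_config()].
#' @param planted data.frame with columns `a`, `spacer`, `b` describing the
#'   spacer-split tails (default: one `A29 G A7` and one `A25 C A10`
#'   element).
#' @return list with `sequences` (named character vector), `alu_table`,
#'   `variants` (planted spacer variants incl. truth columns), `truth`.
#' @export
simulate_retro_sequences <- function(config,
                                     planted = data.frame(
                                       a = c(29L, 25L),
                                       spacer = c("G", "C"),
                                       b = c(7L, 10L))) {
  stopifnot(inherits(config, "sim_config"))
  if (any(planted$a < 1 | planted$b < 1)) {
    stop("simulate_retro_sequences: requested tail run lengths must be >= 1",
         call. = FALSE)
  }
  set.seed(config$seed + 2L)
  n <- max(config$n_alus, nrow(planted))
  fams <- sample(c("AluY", "AluSx", "AluJb"), n, replace = TRUE)
  seqs <- character(n)
  tab <- vector("list", n)
  vars <- list()
  truth <- list()
  for (i in seq_len(n)) {
    flank_l <- random_dna(30)
    mono_l <- paste0(random_dna(128), "C")
    linker <- paste0("C", paste(rep("A", 5), collapse = ""), "TAC",
                     paste(rep("A", 6), collapse = ""), "C")
    mono_r <- paste0(random_dna(118), "C")
    is_planted <- i <= nrow(planted)
    if (is_planted) {
      a <- planted$a[i]; b <- planted$b[i]; sp <- planted$spacer[i]
      tail <- paste0(strrep("A", a), sp, strrep("A", b))
      tail_true <- a
    } else {
      tail_true <- sample(21:26, 1)
      tail <- strrep("A", tail_true)
    }
    flank_r <- paste0("C", random_dna(29))
    seqs[i] <- paste0(flank_l, mono_l, linker, mono_r, tail, flank_r)
    name <- sprintf("alu_%02d", i)
    o <- 0L
    pos_flank_l <- c(0L, nchar(flank_l))
    s_ml <- pos_flank_l[2]; e_ml <- s_ml + nchar(mono_l)
    s_lk <- e_ml; e_lk <- s_lk + nchar(linker)
    s_mr <- e_lk; e_mr <- s_mr + nchar(mono_r)
    s_tl <- e_mr; e_tl <- s_tl + nchar(tail)
    tab[[i]] <- data.frame(
      name = name, chrom = name, start = s_ml, end = e_tl, strand = "+",
      family = fams[i], seq_offset = 0L,
      left_monomer_start = s_ml, left_monomer_end = e_ml,
      linker_start = s_lk, linker_end = e_lk,
      right_monomer_start = s_mr, right_monomer_end = e_mr,
      tail_start = s_tl, tail_end = e_tl,
      tail_anchor_pos = s_tl + 1L,   # 1-based first tail base
      stringsAsFactors = FALSE)
    if (is_planted) {
      a <- planted$a[i]; b <- planted$b[i]; sp <- planted$spacer[i]
      vpos <- s_tl + a + 1L           # 1-based spacer position
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = name, pos = vpos, ref = sp, alt = "A", element = name,
        truth_before = a, truth_after = a + 1L + b,
        stringsAsFactors = FALSE)
    }
    names(seqs)[i] <- name
  }
  alu_table <- do.call(rbind, tab)
  variants <- if (length(vars)) do.call(rbind, vars) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), element = character(0),
               truth_before = integer(0), truth_after = integer(0))
  list(sequences = seqs, alu_table = alu_table, variants = variants,
       truth = list(planted = planted))
}
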