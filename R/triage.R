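## The exclusion cascade applied to association results across sample types
## (blood/tumor), training/validation sets, and external frequency
## references, plus the rare-variant screen, the somatic-candidate flag, and
## genotype-r2 linkage.
##
## Exclusion codes mirror the reporting convention of the triage table:
##   dagger   - inconsistent case frequency between training and validation
##   ddagger  - significance only in a crossed (train x type) pattern
##   diamond  - discrepancy between the internal control reference and an
##              external database frequency
## The cascade is order-independent: codes are computed separately and
## unioned per variant.

#' Confirm variants across training and validation sets
#'
#' A variant is confirmed when its adjusted-model p-value falls below
#' `threshold` in both the training and the validation set for at least one
#' sample type, consistently (the same type in both sets). The
#' `adjusted_only` flag marks variants whose confirming cells are significant
#' in the adjusted model but not in the unadjusted one.
#'
#' @param results data.frame with columns `key`, `set`
#'   ("training"/"validation"), `sample_type`, `p_adj`, `p_unadj`.
#' @param threshold significance threshold (see [significance_threshold()]).
#' @return data.frame per variant: `key`, `confirmed`, `adjusted_only`,
#'   `confirming_types` (comma-separated, "" when none).
#' @export
confirm_variants <- function(results, threshold) {
  check_columns(results, c("key", "set", "sample_type", "p_adj", "p_unadj"),
                "association results")
  sets <- unique(results$set)
  if (!all(c("training", "validation") %in% sets)) {
    stop("confirm_variants: results must cover both the training and the validation set",
         call. = FALSE)
  }
  keys <- unique(results$key)
  out <- data.frame(key = keys, confirmed = FALSE, adjusted_only = FALSE,
                    confirming_types = "", stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    r <- results[results$key == keys[i], , drop = FALSE]
    types <- unique(r$sample_type)
    conf_types <- character(0)
    adj_only <- logical(0)
    for (ty in types) {
      tr <- r[r$set == "training" & r$sample_type == ty, , drop = FALSE]
      va <- r[r$set == "validation" & r$sample_type == ty, , drop = FALSE]
      if (!nrow(tr) || !nrow(va)) next
      sig_adj <- !is.na(tr$p_adj[1]) && tr$p_adj[1] < threshold &&
        !is.na(va$p_adj[1]) && va$p_adj[1] < threshold
      if (sig_adj) {
        conf_types <- c(conf_types, ty)
        sig_unadj <- !is.na(tr$p_unadj[1]) && tr$p_unadj[1] < threshold &&
          !is.na(va$p_unadj[1]) && va$p_unadj[1] < threshold
        adj_only <- c(adj_only, !sig_unadj)
      }
    }
    if (length(conf_types)) {
      out$confirmed[i] <- TRUE
      out$adjusted_only[i] <- all(adj_only)
      out$confirming_types[i] <- paste(sort(conf_types), collapse = ",")
    }
  }
  out
}

#' Training/validation case-frequency consistency screen (dagger)
#'
#' Excludes a variant whose case allele frequency is inconsistent between
#' the training and validation sets: absolute difference strictly above
#' `t_abs`, or (when both frequencies are positive) a fold-ratio outside
#' `[1/t_rel, t_rel]`. An absent frequency is not evaluable; the variant
#' passes with a warning.
#'
#' @param maf_train,maf_valid case allele frequencies.
#' @param t_abs absolute-difference threshold (default 0.10, strict).
#' @param t_rel fold-ratio threshold (default 2).
#' @return TRUE when the variant is excluded.
#' @export
dagger_screen <- function(maf_train, maf_valid, t_abs = 0.10, t_rel = 2) {
  if (is.na(maf_train) || is.na(maf_valid)) {
    warning("dagger_screen: frequency absent, screen not evaluable; variant passes",
            call. = FALSE)
    return(FALSE)
  }
  if (abs(maf_train - maf_valid) > t_abs) return(TRUE)
  if (maf_train > 0 && maf_valid > 0) {
    ratio <- maf_train / maf_valid
    if (ratio > t_rel || ratio < 1 / t_rel) return(TRUE)
  }
  FALSE
}

#' Crossed-significance-pattern screen (double dagger)
#'
#' Excludes a variant whose only significant cells form a crossed pattern
#' over \{blood, tumor\} x \{training, validation\}: one sample type
#' significant in training, the other in validation, with no same-type
#' confirmation in either direction.
#'
#' @param blood_train,blood_valid,tumor_train,tumor_valid logical
#'   significance indicators.
#' @return TRUE when the variant is excluded.
#' @export
ddagger_screen <- function(blood_train, blood_valid, tumor_train, tumor_valid) {
  cross1 <- tumor_train && blood_valid && !blood_train && !tumor_valid
  cross2 <- blood_train && tumor_valid && !tumor_train && !blood_valid
  isTRUE(cross1 || cross2)
}

#' Cross-database frequency-discrepancy screen (diamond)
#'
#' Excludes a variant whose internal control-cohort frequency disagrees with
#' an external reference frequency: both an absolute difference strictly
#' above `t_abs` and a fold-change above `t_fold` (an external frequency of
#' exactly zero counts as infinite fold-change). Variants that arose from a
#' multiallelic split are never excluded here -- their frequencies are
#' inconclusive -- only flagged. An absent external frequency retains the
#' variant.
#'
#' @param maf_internal internal control reference frequency.
#' @param maf_external external database frequency, or NA when unreported.
#' @param tri_allelic TRUE for variants deriving from a multiallelic site.
#' @param t_abs absolute-difference threshold (default 0.10).
#' @param t_fold fold-change threshold (default 2).
#' @return list with `exclude` and `inconclusive`.
#' @export
diamond_screen <- function(maf_internal, maf_external, tri_allelic = FALSE,
                           t_abs = 0.10, t_fold = 2) {
  if (is.na(maf_internal)) {
    stop("diamond_screen: internal control frequency must be defined",
         call. = FALSE)
  }
  if (is.na(maf_external)) {
    return(list(exclude = FALSE, inconclusive = FALSE))
  }
  big_abs <- abs(maf_internal - maf_external) > t_abs
  ratio <- if (maf_external == 0) {
    if (maf_internal == 0) 1 else Inf
  } else {
    maf_internal / maf_external
  }
  big_fold <- ratio > t_fold || ratio < 1 / t_fold
  hit <- big_abs && big_fold
  if (tri_allelic) {
    return(list(exclude = FALSE, inconclusive = hit))
  }
  list(exclude = hit, inconclusive = FALSE)
}

#' Rare-variant screen
#'
#' Classifies a variant by case and control frequencies: `not_extracted`
#' below the case-frequency floor; `extracted` at case MAF >= `case_min`;
#' `rare` when additionally every control frequency is at most `control_max`
#' (an absent external frequency counts as 0); `rare_enriched` when the case
#' frequency further reaches `enrich_fold` times the external frequency (or
#' the external frequency is absent/zero).
#'
#' @param maf_case case cohort allele frequency.
#' @param maf_control_internal internal control frequency.
#' @param maf_external external database frequency or NA.
#' @param case_min extraction floor (default 0.10).
#' @param control_max rare ceiling in controls (default 0.01).
#' @param enrich_fold enrichment fold (default 10).
#' @return one of `"not_extracted"`, `"extracted"`, `"rare"`,
#'   `"rare_enriched"`.
#' @export
rare_screen <- function(maf_case, maf_control_internal, maf_external = NA,
                        case_min = 0.10, control_max = 0.01,
                        enrich_fold = 10) {
  if (is.na(maf_case)) {
    stop("rare_screen: case frequency must be defined", call. = FALSE)
  }
  if (maf_case < case_min) return("not_extracted")
  ext <- if (is.na(maf_external)) 0 else maf_external
  ctrl <- c(maf_control_internal, ext)
  ctrl <- ctrl[!is.na(ctrl)]
  if (any(ctrl > control_max)) return("extracted")
  if (is.na(maf_external) || maf_external == 0 ||
      maf_case >= enrich_fold * maf_external) {
    return("rare_enriched")
  }
  "rare"
}

#' Somatic-candidate flag
#'
#' Flags a variant whose tumor-sample allele frequency exceeds its
#' blood-sample frequency by at least `min_delta`.
#'
#' @param maf_blood,maf_tumor allele frequencies in matched sample types.
#' @param min_delta minimum blood-to-tumor shift (default 0.02).
#' @return logical.
#' @export
somatic_flag <- function(maf_blood, maf_tumor, min_delta = 0.02) {
  stopifnot(!is.na(maf_blood), !is.na(maf_tumor))
  (maf_tumor - maf_blood) >= min_delta
}

#' Genotype-level linkage: squared dosage correlation
#'
#' r2 is the squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples, the genotype-level LD measure produced by
#' geno-r2 style tools. Undefined (flagged) when fewer than two complete
#' pairs remain or either vector is constant on the complete subset.
#'
#' @param dosage_a,dosage_b dosage vectors (NA missing).
#' @return list with `r2`, `n` (complete pairs), `defined`.
#' @export
geno_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[keep]
  b <- dosage_b[keep]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0) {
    return(list(r2 = NA_real_, n = length(a), defined = FALSE))
  }
  r <- stats::cor(a, b)
  list(r2 = r * r, n = length(a), defined = TRUE)
}

#' Cluster variants by pairwise genotype r2
#'
#' Single-linkage clusters over the graph connecting variant pairs with
#' `r2 >= r2_min`. Returns integer cluster ids (singletons get their own id).
#'
#' @param geno samples x variants dosage matrix.
#' @param r2_min linkage threshold (default 0.8).
#' @return list with `cluster` (named integer vector) and `pairs`
#'   (data.frame of evaluated pairs with `key_a`, `key_b`, `r2`, `n`).
#' @export
ld_clusters <- function(geno, r2_min = 0.8) {
  keys <- colnames(geno)
  m <- ncol(geno)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  pairs <- list()
  if (m >= 2) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        r <- geno_r2(geno[, i], geno[, j])
        pairs[[length(pairs) + 1L]] <- data.frame(
          key_a = keys[i], key_b = keys[j], r2 = r$r2, n = r$n,
          stringsAsFactors = FALSE)
        if (r$defined && r$r2 >= r2_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  cluster <- match(roots, unique(roots))
  names(cluster) <- keys
  list(cluster = cluster,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(key_a = character(0), key_b = character(0),
                    r2 = numeric(0), n = integer(0)))
}

#' Power to detect a proportion difference (normal approximation)
#'
#' Two-sided one-sample test of a proportion against zero, with the variance
#' evaluated at the alternative:
#' `power = pnorm(p_alt / sqrt(p_alt (1 - p_alt) / n) - z_{1 - alpha/2})`.
#'
#' @param n sample size.
#' @param p_alt detectable difference on the proportion scale.
#' @param alpha two-sided alpha (default 0.05).
#' @return power in (0, 1).
#' @export
power_detectable_difference <- function(n, p_alt, alpha = 0.05) {
  stopifnot(n >= 2, p_alt > 0, p_alt < 1)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(p_alt / sqrt(p_alt * (1 - p_alt) / n) - z)
}
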