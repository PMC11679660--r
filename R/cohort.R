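## Cohort genotype handling: VCF reading via vcfR, multiallelic splitting,
## case/control merging with missing-to-reference semantics, allele
## frequencies, and the stratified 3:2 train/validation split.
##
## A genotype matrix in this package is samples x variants, integer codes
## 0/1/2 with NA for missing, carried inside a `geno_matrix` list together
## with a variant table and a sample table.

new_geno_matrix <- function(geno, variants, samples) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(variants))
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$key
  structure(list(geno = geno, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

## Parse one vcfR GT string column into dosages of a given alt index.
## Half-calls (0/.) and any call touching '.' are treated as missing.
gt_to_dosage <- function(gt, alt_index = 1L) {
  gt <- sub(":.*$", "", gt)
  gt[is.na(gt)] <- "./."
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    sum(a == as.character(alt_index))
  }, integer(1))
}

#' Read a cohort VCF into a genotype matrix
#'
#' Reads a VCF v4.x file (plain or gzipped) with `vcfR`, splits multiallelic
#' records into biallelic ones (see [split_multiallelic()]) and returns a
#' `geno_matrix`. Symbolic alternate alleles (e.g. `<DEL>`) are skipped with
#' a warning.
#'
#' @param path VCF file path.
#' @param cohort label attached to every sample (e.g. "case", "control").
#' @param sample_type label attached to every sample (e.g. "blood", "tumor").
#' @return a `geno_matrix`.
#' @export
read_cohort_vcf <- function(path, cohort = NA_character_,
                            sample_type = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- v@gt
  sample_ids <- colnames(gt)[-1L]  # first column is FORMAT
  recs <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  recs$id[is.na(recs$id)] <- "."
  split_multiallelic(recs, gt[, -1L, drop = FALSE],
                     samples = data.frame(sample_id = sample_ids,
                                          cohort = cohort,
                                          sample_type = sample_type,
                                          stringsAsFactors = FALSE))
}

#' Split multiallelic variant records into biallelic ones
#'
#' Each (site, alternate allele) pair becomes one output variant; genotypes
#' are recoded per alternate (copies of that alternate counted, other
#' alternates counted as reference). Rows deriving from a site with more than
#' one alternate keep the site's rsID and are flagged `multiallelic_split`.
#' Symbolic alleles are dropped with a warning.
#'
#' @param records data.frame with `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (possibly comma-separated).
#' @param gt character matrix of GT strings, rows matching `records`.
#' @param samples data.frame describing the columns of `gt`
#'   (`sample_id`, `cohort`, `sample_type`).
#' @return a `geno_matrix` whose variant table carries `multiallelic_split`
#'   and `alt_index`.
#' @export
split_multiallelic <- function(records, gt, samples) {
  out_var <- list()
  out_geno <- list()
  for (i in seq_len(nrow(records))) {
    alts <- strsplit(records$alt[i], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    for (j in seq_along(alts)) {
      if (grepl("[<>*]", alts[j])) {
        warning(sprintf("skipping symbolic allele %s at %s:%d",
                        alts[j], records$chrom[i], records$pos[i]),
                call. = FALSE)
        next
      }
      if (alts[j] == records$ref[i]) {
        stop(sprintf("ref == alt at %s:%d", records$chrom[i], records$pos[i]),
             call. = FALSE)
      }
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = records$chrom[i], pos = records$pos[i],
        id = records$id[i], ref = records$ref[i], alt = alts[j],
        multiallelic_split = multi, alt_index = j,
        stringsAsFactors = FALSE)
      out_geno[[length(out_geno) + 1L]] <- gt_to_dosage(gt[i, ], j)
    }
  }
  variants <- do.call(rbind, out_var)
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           id = character(0), ref = character(0),
                           alt = character(0), multiallelic_split = logical(0),
                           alt_index = integer(0))
  }
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  geno <- if (length(out_geno)) do.call(cbind, out_geno) else
    matrix(integer(0), nrow = nrow(samples), ncol = 0)
  new_geno_matrix(geno, variants, samples)
}

#' Merge two cohort genotype matrices
#'
#' Variants are matched on (chrom, pos, ref, alt). The merged matrix carries
#' the union of variants over all samples. For a variant absent from one
#' cohort's file, that cohort's genotypes become homozygous reference (0)
#' when `missing_to_ref = TRUE`, and missing otherwise. Genotypes that were
#' explicitly missing (`./.`) stay missing in either mode.
#'
#' @param a,b `geno_matrix` objects on the same reference coordinates.
#' @param missing_to_ref logical (default TRUE), the merge convention for
#'   unseen genotypes.
#' @return a merged `geno_matrix`.
#' @export
merge_cohorts <- function(a, b, missing_to_ref = TRUE) {
  stopifnot(inherits(a, "geno_matrix"), inherits(b, "geno_matrix"))
  ## conflicting REF at a shared site is a coordinate-system error
  pos_a <- paste(a$variants$chrom, a$variants$pos)
  pos_b <- paste(b$variants$chrom, b$variants$pos)
  shared <- intersect(pos_a, pos_b)
  if (length(shared)) {
    ref_a <- a$variants$ref[match(shared, pos_a)]
    ref_b <- b$variants$ref[match(shared, pos_b)]
    bad <- which(ref_a != ref_b)
    if (length(bad)) {
      stop(sprintf("merge_cohorts: conflicting REF allele at %s (%s vs %s)",
                   shared[bad[1L]], ref_a[bad[1L]], ref_b[bad[1L]]),
           call. = FALSE)
    }
  }
  keys <- union(a$variants$key, b$variants$key)
  variants <- rbind(a$variants, b$variants)
  variants <- variants[match(keys, variants$key), , drop = FALSE]
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  fill <- if (missing_to_ref) 0L else NA_integer_
  expand <- function(g) {
    m <- matrix(fill, nrow = nrow(g$geno), ncol = nrow(variants),
                dimnames = list(rownames(g$geno), variants$key))
    hit <- intersect(variants$key, g$variants$key)
    m[, hit] <- g$geno[, hit, drop = FALSE]
    m
  }
  geno <- rbind(expand(a), expand(b))
  samples <- rbind(a$samples, b$samples)
  new_geno_matrix(geno, variants, samples)
}

#' Alternate-allele frequency of one variant
#'
#' Sum of dosage codes over twice the number of non-missing genotypes.
#' Reported unfolded (frequency of the alternate allele, which may exceed
#' 0.5). Missing genotypes contribute to neither numerator nor denominator.
#'
#' @param codes integer vector of dosages 0/1/2 with NA for missing.
#' @param mask optional logical/index vector restricting to a sample subset.
#' @return frequency in `[0, 1]`.
#' @export
allele_frequency <- function(codes, mask = NULL) {
  if (!is.null(mask)) codes <- codes[mask]
  n <- sum(!is.na(codes))
  if (n == 0L) {
    stop("allele_frequency: all genotypes missing in the requested subset",
         call. = FALSE)
  }
  sum(codes, na.rm = TRUE) / (2 * n)
}

#' Stratified train/validation split with multi-trial balancing
#'
#' Allocates `round(train_frac * n_s)` samples of each stratum to the
#' training set (round-half-up, so 138 samples at 3:2 give 83 training).
#' Among `n_trials` seeded shuffles, the trial minimizing the balance score
#' (maximum absolute deviation of the per-stratum training fraction from
#' `train_frac`) is returned; ties resolve to the earliest trial, so the
#' result is deterministic given the seed.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param strata vector (same length) assigning each sample to one stratum.
#' @param train_frac training fraction (default 0.6, the 3:2 split).
#' @param n_trials number of randomized trials compared (default 20).
#' @param seed RNG seed.
#' @return list with `training`, `validation`, `balance_score`,
#'   `chosen_trial`, `scores`, `seed`.
#' @export
stratified_split <- function(sample_ids, strata, train_frac = 0.6,
                             n_trials = 20, seed = 1) {
  stopifnot(length(sample_ids) == length(strata), n_trials >= 1)
  strata <- as.character(strata)
  levels <- unique(strata)
  sizes <- vapply(levels, function(s) sum(strata == s), integer(1))
  if (any(sizes == 0L)) {
    warning("stratified_split: skipping empty stratum", call. = FALSE)
    levels <- levels[sizes > 0L]
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  trials <- vector("list", n_trials)
  scores <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    train <- character(0)
    fracs <- numeric(length(levels))
    for (k in seq_along(levels)) {
      ids <- sample_ids[strata == levels[k]]
      n_s <- length(ids)
      n_train <- min(round_half_up(train_frac * n_s), n_s)
      train <- c(train, sample(ids, n_train))
      fracs[k] <- n_train / n_s
    }
    trials[[t]] <- train
    scores[t] <- max(abs(fracs - train_frac))
  }
  best <- which.min(scores)
  training <- sort(trials[[best]])
  list(training = training,
       validation = sort(setdiff(sample_ids, training)),
       balance_score = scores[best],
       chosen_trial = best,
       scores = scores,
       seed = seed)
}
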