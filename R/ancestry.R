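## Supervised admixture estimation from ancestry-informative markers (AIMs).
##
## Model: for individual genotype g_m at marker m (dosage of the alternate
## allele), g_m ~ Binomial(2, f_m) with f_m = sum_k q_k p_km, where p_km are
## fixed reference-population alternate-allele frequencies and q is the
## individual's admixture vector on the simplex. q is estimated by EM; the
## log-likelihood is non-decreasing across iterations.

DEFAULT_POPS <- c("EUR", "AFR", "EAS", "NAT")

#' Estimate one individual's admixture proportions by EM
#'
#' @param g integer vector of AIM dosages (0/1/2, NA for missing), aligned
#'   with the rows of `panel_freq`.
#' @param panel_freq numeric matrix markers x populations of reference
#'   alternate-allele frequencies, strictly inside (0, 1).
#' @param tol convergence tolerance on the max absolute change in q.
#' @param max_iter iteration cap; hitting it returns the current estimate
#'   with `converged = FALSE` and a warning.
#' @return list with `q` (named, sums to 1), `loglik`, `n_iter`,
#'   `converged`, and `flat` (TRUE when the panel is uninformative and the
#'   uniform vector is returned).
#' @export
estimate_admixture <- function(g, panel_freq, tol = 1e-6, max_iter = 2000) {
  stopifnot(is.matrix(panel_freq), ncol(panel_freq) >= 2)
  use <- which(!is.na(g))
  if (!length(use)) {
    stop("estimate_admixture: no usable (non-missing) AIM genotypes",
         call. = FALSE)
  }
  g <- as.numeric(g[use])
  p <- panel_freq[use, , drop = FALSE]
  if (any(p <= 0 | p >= 1)) {
    stop("estimate_admixture: panel frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  }
  K <- ncol(p)
  M <- length(g)
  flat <- all(apply(p, 1, function(r) max(r) - min(r)) < 1e-12)
  q <- rep(1 / K, K)
  loglik <- function(q) {
    f <- as.numeric(p %*% q)
    sum(g * log(f) + (2 - g) * log1p(-f))
  }
  if (flat) {
    warning("estimate_admixture: panel frequencies identical across populations; likelihood is flat in q, returning the uniform vector",
            call. = FALSE)
    names(q) <- colnames(p)
    return(list(q = q, loglik = loglik(q), n_iter = 0L,
                converged = TRUE, flat = TRUE))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    f <- as.numeric(p %*% q)
    ## E-step responsibilities folded into the M-step update: expected number
    ## of allele copies attributed to population k, over 2M gametes
    num_alt <- colSums((g / f) * sweep(p, 2, q, `*`))
    num_ref <- colSums(((2 - g) / (1 - f)) * sweep(1 - p, 2, q, `*`))
    q_new <- (num_alt + num_ref) / (2 * M)
    q_new <- q_new / sum(q_new)
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) {
      warning("estimate_admixture: EM did not converge within max_iter",
              call. = FALSE)
      converged <- FALSE
      break
    }
  }
  names(q) <- colnames(p)
  list(q = q, loglik = loglik(q), n_iter = it, converged = converged,
       flat = FALSE)
}

#' Estimate admixture for every sample of a genotype matrix
#'
#' @param aim_geno samples x markers dosage matrix (NA for missing).
#' @param panel_freq markers x populations frequency matrix matching the
#'   columns of `aim_geno`.
#' @param ... passed to [estimate_admixture()].
#' @return data.frame with one row per sample: `sample_id`, one `q_<pop>`
#'   column per population, `label`, `loglik`, `n_iter`.
#' @export
estimate_admixture_all <- function(aim_geno, panel_freq, ...) {
  stopifnot(ncol(aim_geno) == nrow(panel_freq))
  pops <- colnames(panel_freq)
  qs <- matrix(NA_real_, nrow(aim_geno), length(pops),
               dimnames = list(rownames(aim_geno), paste0("q_", pops)))
  ll <- numeric(nrow(aim_geno))
  ni <- integer(nrow(aim_geno))
  n_nonconv <- 0L
  for (i in seq_len(nrow(aim_geno))) {
    fit <- withCallingHandlers(
      estimate_admixture(aim_geno[i, ], panel_freq, ...),
      warning = function(w) {
        if (grepl("did not converge", conditionMessage(w))) {
          n_nonconv <<- n_nonconv + 1L
          invokeRestart("muffleWarning")
        }
      })
    qs[i, ] <- fit$q
    ll[i] <- fit$loglik
    ni[i] <- fit$n_iter
  }
  if (n_nonconv > 0L) {
    warning(sprintf("estimate_admixture_all: EM hit max_iter for %d of %d samples",
                    n_nonconv, nrow(aim_geno)), call. = FALSE)
  }
  out <- data.frame(sample_id = rownames(aim_geno) %||%
                      as.character(seq_len(nrow(aim_geno))),
                    qs, stringsAsFactors = FALSE)
  out$label <- apply(qs, 1, function(q) classify_ancestry(stats::setNames(q, pops)))
  out$loglik <- ll
  out$n_iter <- ni
  rownames(out) <- NULL
  out
}

#' Categorical ancestry label from an admixture vector
#'
#' Rules applied in order: EUR when `q_EUR > 0.90`; AFR when `q_AFR >= 0.70`;
#' EAS when `q_EAS >= 0.70`; HIS when the Native American component
#' `q_NAT >= 0.10` and exceeds both the African and East Asian components;
#' everything else is labelled AMR (admixed American).
#'
#' @param q named numeric vector on the simplex with components
#'   `EUR`, `AFR`, `EAS`, `NAT`.
#' @return one of `"EUR"`, `"AFR"`, `"EAS"`, `"HIS"`, `"AMR"`.
#' @export
classify_ancestry <- function(q) {
  if (abs(sum(q) - 1) > 1e-6 || any(q < -1e-9)) {
    stop("classify_ancestry: q must be a probability vector summing to 1",
         call. = FALSE)
  }
  stopifnot(all(DEFAULT_POPS %in% names(q)))
  if (q[["EUR"]] > 0.90) return("EUR")
  if (q[["AFR"]] >= 0.70) return("AFR")
  if (q[["EAS"]] >= 0.70) return("EAS")
  if (q[["NAT"]] >= 0.10 && q[["NAT"]] > q[["AFR"]] && q[["NAT"]] > q[["EAS"]]) {
    return("HIS")
  }
  "AMR"
}

#' Continuous ancestry covariates for regression
#'
#' Returns the admixture components used as regression covariates, dropping
#' one component (EUR by default) as the baseline so the design keeps full
#' rank next to an intercept.
#'
#' @param q named vector on the simplex, or a matrix/data.frame of `q_<pop>`
#'   columns (one row per sample).
#' @param drop population used as the baseline (default `"EUR"`).
#' @return numeric vector (or matrix) of the remaining components.
#' @export
ancestry_covariates <- function(q, drop = "EUR") {
  if (is.null(dim(q))) {
    stopifnot(drop %in% names(q))
    return(q[setdiff(names(q), drop)])
  }
  q <- as.matrix(q)
  cols <- colnames(q)
  cols <- sub("^q_", "", cols)
  colnames(q) <- cols
  stopifnot(drop %in% cols)
  q[, setdiff(cols, drop), drop = FALSE]
}

#' Concordance between two categorical label vectors
#'
#' Reporting helper for classification-consistency checks (e.g. agreement
#' between AIM-derived labels and an external superpopulation assignment).
#'
#' @param labels,reference equal-length character vectors.
#' @return list with `n_agree`, `n`, and `percent` (0-100).
#' @export
label_concordance <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  n <- length(labels)
  n_agree <- sum(labels == reference)
  list(n_agree = n_agree, n = n, percent = 100 * n_agree / n)
}
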