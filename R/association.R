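## Per-variant case-control logistic association.
##
## The fitter is iteratively reweighted least squares with Wald tests
## (2 * pnorm(-|beta/se|)), additive genotype coding 0/1/2, complete-case per
## variant. Odds ratios are exp(beta); the confounding-change statistic
## compares the adjusted and unadjusted per-allele OR.

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial GLM with the canonical logit link. Convergence is declared
#' when the score norm drops below `score_tol` or the parameter change below
#' `par_tol`. Complete or quasi-complete separation (diverging coefficients
#' with fitted probabilities piling on 0/1) is detected and flagged: the fit
#' is returned with `separated = TRUE` and Wald p-values set to NA.
#'
#' @param y binary response vector (0/1).
#' @param X design matrix including the intercept column.
#' @param max_iter IRLS iteration cap.
#' @param score_tol,par_tol convergence tolerances.
#' @return list with `beta`, `se`, `z`, `p`, `converged`, `separated`,
#'   `n`, `loglik`.
#' @export
fit_logistic <- function(y, X, max_iter = 100, score_tol = 1e-8,
                         par_tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (nrow(X) <= ncol(X)) {
    stop("fit_logistic: need more observations than parameters", call. = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf("fit_logistic: design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < score_tol) {
      converged <- TRUE
      break
    }
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      break
    }
    beta_new <- beta + step
    if (max(abs(beta_new - beta)) < par_tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (max(abs(beta)) > 30) {   # monotone likelihood, coefficients diverging
      separated <- TRUE
      break
    }
  }
  ## a score that vanishes only because fitted probabilities saturated at
  ## 0/1 is separation, not convergence
  if (max(abs(beta)) > 15) separated <- TRUE
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X, X * w)
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  if (separated) pval[] <- NA_real_
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  names(beta) <- names(se) <- names(z) <- names(pval) <- colnames(X)
  list(beta = beta, se = se, z = z, p = pval, converged = converged,
       separated = separated, n = length(y), loglik = loglik)
}

#' Unadjusted and covariate-adjusted association for one variant
#'
#' Fits two additive-dosage logistic models: `phenotype ~ dosage` and
#' `phenotype ~ dosage + sex + ancestry covariates`. Samples with a missing
#' genotype are dropped from both fits (complete-case per variant). A variant
#' monomorphic among the analyzed samples is returned flagged, with NA
#' effects.
#'
#' @param genotypes dosage vector 0/1/2 (NA missing).
#' @param phenotype binary vector, 1 = case.
#' @param sex optional numeric/binary covariate vector.
#' @param ancestry optional matrix of continuous ancestry covariates
#'   (see [ancestry_covariates()]).
#' @param key variant identifier carried into the result.
#' @return one-row data.frame: effects, standard errors, p-values and odds
#'   ratios for both models, `delta_or_fraction`, `confounded`, and flags.
#' @export
test_variant <- function(genotypes, phenotype, sex = NULL, ancestry = NULL,
                         key = NA_character_) {
  keep <- !is.na(genotypes) & !is.na(phenotype)
  if (!is.null(sex)) keep <- keep & !is.na(sex)
  if (!is.null(ancestry)) keep <- keep & stats::complete.cases(as.matrix(ancestry))
  g <- genotypes[keep]
  y <- phenotype[keep]
  res <- data.frame(key = key, n = length(g),
                    beta_unadj = NA_real_, se_unadj = NA_real_,
                    p_unadj = NA_real_, or_unadj = NA_real_,
                    beta_adj = NA_real_, se_adj = NA_real_,
                    p_adj = NA_real_, or_adj = NA_real_,
                    delta_or_fraction = NA_real_, confounded = NA,
                    monomorphic = FALSE, separated = FALSE,
                    stringsAsFactors = FALSE)
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("test_variant: need at least one case and one control with a non-missing genotype",
         call. = FALSE)
  }
  if (length(unique(g)) < 2L) {
    res$monomorphic <- TRUE
    return(res)
  }
  X0 <- cbind(intercept = 1, dosage = g)
  f0 <- fit_logistic(y, X0)
  res$beta_unadj <- f0$beta[["dosage"]]
  res$se_unadj <- f0$se[["dosage"]]
  res$p_unadj <- f0$p[["dosage"]]
  res$or_unadj <- exp(f0$beta[["dosage"]])
  X1 <- X0
  if (!is.null(sex)) X1 <- cbind(X1, sex = sex[keep])
  if (!is.null(ancestry)) {
    anc <- as.matrix(ancestry)[keep, , drop = FALSE]
    ## drop covariates that are constant in the analyzed subset
    anc <- anc[, apply(anc, 2, function(v) length(unique(v)) > 1L), drop = FALSE]
    if (ncol(anc)) X1 <- cbind(X1, anc)
  }
  f1 <- fit_logistic(y, X1)
  res$beta_adj <- f1$beta[["dosage"]]
  res$se_adj <- f1$se[["dosage"]]
  res$p_adj <- f1$p[["dosage"]]
  res$or_adj <- exp(f1$beta[["dosage"]])
  res$separated <- f0$separated || f1$separated
  if (!res$separated) {
    cc <- confounding_change(res$or_unadj, res$or_adj)
    res$delta_or_fraction <- cc$fraction
    res$confounded <- cc$confounded
  }
  res
}

#' Confounding-change statistic between unadjusted and adjusted odds ratios
#'
#' The fraction is `|OR_adj - OR_unadj| / OR_unadj`; a variant is flagged
#' confounded when the fraction strictly exceeds `threshold` (default 0.10,
#' i.e. a >10 percent change in the OR after covariate adjustment).
#'
#' @param or_unadj,or_adj positive odds ratios.
#' @param threshold flag threshold (strict).
#' @return list with `fraction` and `confounded`.
#' @export
confounding_change <- function(or_unadj, or_adj, threshold = 0.10) {
  if (any(or_unadj <= 0) || any(or_adj <= 0)) {
    stop("confounding_change: odds ratios must be positive", call. = FALSE)
  }
  fraction <- abs(or_adj - or_unadj) / or_unadj
  ## strict >, with a guard so that an exactly-10% change represented
  ## inexactly in floating point does not flag
  list(fraction = fraction, confounded = fraction > threshold + 1e-12)
}

#' Confounding summary over association results
#'
#' Restricts to variants significant in the unadjusted model, the adjusted
#' model, or both, and reports how many of those are flagged confounded.
#'
#' @param results data.frame with `p_unadj`, `p_adj`, `confounded`.
#' @param threshold significance threshold applied to both p-value columns.
#' @return list with `n_significant`, `n_confounded`, `percent_confounded`.
#' @export
confounding_summary <- function(results, threshold = 0.05) {
  sig <- (!is.na(results$p_unadj) & results$p_unadj < threshold) |
    (!is.na(results$p_adj) & results$p_adj < threshold)
  n_sig <- sum(sig)
  n_conf <- sum(sig & results$confounded %in% TRUE)
  list(n_significant = n_sig, n_confounded = n_conf,
       percent_confounded = if (n_sig) 100 * n_conf / n_sig else NA_real_)
}

#' Per-variant multiplicity threshold
#'
#' Bonferroni-style threshold `alpha / n_variants`, returned together with
#' its `-log10` for Manhattan-style plotting.
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param n_variants number of variants tested.
#' @return list with `threshold` and `neg_log10`.
#' @export
significance_threshold <- function(alpha = 0.05, n_variants = 1) {
  stopifnot(alpha > 0, alpha < 1, n_variants >= 1)
  thr <- alpha / n_variants
  list(threshold = thr, neg_log10 = -log10(thr))
}
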