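test_that("confirmation requires same-type significance in both sets", {
  mk <- function(key, set, type, p_adj, p_unadj = p_adj) {
    data.frame(key = key, set = set, sample_type = type,
               p_adj = p_adj, p_unadj = p_unadj, stringsAsFactors = FALSE)
  }
  thr <- 1e-5
  res <- rbind(
    mk("v1", "training", "blood", 1e-9), mk("v1", "validation", "blood", 1e-8),
    mk("v2", "training", "blood", 1e-9), mk("v2", "validation", "blood", 0.2),
    ## adjusted-only in both sets
    mk("v3", "training", "blood", 1e-9, p_unadj = 0.3),
    mk("v3", "validation", "blood", 1e-8, p_unadj = 0.5))
  out <- confirm_variants(res, thr)
  expect_true(out$confirmed[out$key == "v1"])
  expect_false(out$adjusted_only[out$key == "v1"])
  expect_false(out$confirmed[out$key == "v2"])
  expect_true(out$confirmed[out$key == "v3"])
  expect_true(out$adjusted_only[out$key == "v3"])
  expect_error(confirm_variants(res[res$set == "training", ], thr),
               "training and the validation")
})

test_that("training/validation frequency consistency screen (dagger)", {
  expect_false(dagger_screen(0.25, 0.26))
  expect_true(dagger_screen(0.30, 0.05))
  expect_false(dagger_screen(0.20, 0.30))     # boundary: strict > 0.10
  expect_true(dagger_screen(0.04, 0.09))      # within abs band, ratio > 2
  expect_warning(out <- dagger_screen(NA, 0.2), "not evaluable")
  expect_false(out)
})

test_that("crossed-significance screen (double dagger)", {
  ## arguments: blood_train, blood_valid, tumor_train, tumor_valid
  expect_true(ddagger_screen(FALSE, TRUE, TRUE, FALSE))   # tumor-train + blood-valid
  expect_true(ddagger_screen(TRUE, FALSE, FALSE, TRUE))
  expect_false(ddagger_screen(TRUE, TRUE, FALSE, FALSE))  # same-type confirmation
  expect_false(ddagger_screen(TRUE, TRUE, TRUE, TRUE))
  expect_false(ddagger_screen(FALSE, FALSE, FALSE, FALSE))
})

test_that("cross-database discrepancy screen (diamond) with tri-allelic exemption", {
  expect_true(diamond_screen(0.378, 0.000)$exclude)
  expect_false(diamond_screen(0.749, 0.415)$exclude)   # ratio 1.80 <= 2
  tri <- diamond_screen(0.730, 0.357, tri_allelic = TRUE)
  expect_false(tri$exclude)
  expect_true(tri$inconclusive)
  expect_false(diamond_screen(0.5, NA)$exclude)        # absent external retains
  expect_error(diamond_screen(NA, 0.2), "internal")
})

test_that("the default discrepancy screen reproduces the bundled 27-variant fixture", {
  fx <- read_common_fixture()
  expect_equal(nrow(fx), 27)
  got <- vapply(seq_len(nrow(fx)), function(i) {
    diamond_screen(fx$maf_control[i], fx$maf_external[i],
                   tri_allelic = fx$tri_allelic[i])$exclude
  }, logical(1))
  expect_equal(sum(got), 8)
  expect_equal(got, fx$expected_diamond)
  ## the tri-allelic rows are retained but flagged inconclusive
  tri <- which(fx$tri_allelic)
  inc <- vapply(tri, function(i) {
    diamond_screen(fx$maf_control[i], fx$maf_external[i],
                   tri_allelic = TRUE)$inconclusive
  }, logical(1))
  expect_true(all(inc))
})

test_that("rare-variant screen thresholds and monotonicity in case frequency", {
  expect_equal(rare_screen(0.12, 0.005, 0.002), "rare_enriched")
  expect_equal(rare_screen(0.08, 0.0, 0.0), "not_extracted")
  expect_equal(rare_screen(0.15, 0.0, 0.02), "extracted")  # external above 1%
  expect_equal(rare_screen(0.15, 0.0, NA), "rare_enriched")
  expect_error(rare_screen(NA, 0, 0), "case frequency")
  ## raising the case frequency never demotes the classification
  rank <- c(not_extracted = 1, extracted = 2, rare = 3, rare_enriched = 4)
  for (ctrl in c(0, 0.005, 0.02)) {
    for (ext in c(NA, 0, 0.004, 0.03)) {
      cls <- rank[vapply(seq(0.01, 0.9, by = 0.01), rare_screen,
                         character(1), maf_control_internal = ctrl,
                         maf_external = ext)]
      expect_true(all(diff(cls) >= 0))
    }
  }
})

test_that("somatic flag requires a tumor-ward shift of at least min_delta", {
  expect_true(somatic_flag(0.05, 0.09))
  expect_false(somatic_flag(0.09, 0.09))
  expect_false(somatic_flag(0.10, 0.05))
  expect_true(somatic_flag(0.05, 0.07, min_delta = 0.02))
})

test_that("genotype r2 equals the squared Pearson correlation on complete pairs", {
  expect_equal(geno_r2(c(0, 1, 2, 1), c(0, 1, 2, 1))$r2, 1)
  expect_equal(geno_r2(c(0, 0, 1, 1), c(1, 1, 0, 0))$r2, 1)  # sign squares away
  const <- geno_r2(c(1, 1, 1), c(0, 1, 2))
  expect_false(const$defined)

  set.seed(14)
  a <- sample(0:2, 300, replace = TRUE)
  b <- sample(0:2, 300, replace = TRUE)
  a[sample(300, 30)] <- NA
  b[sample(300, 30)] <- NA
  r <- geno_r2(a, b)
  keep <- !is.na(a) & !is.na(b)
  x <- a[keep]; y <- b[keep]
  ## hand-rolled Pearson oracle
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r2, (num / den)^2, tolerance = 1e-12)
  expect_equal(r$n, sum(keep))
  ## symmetry and affine invariance
  expect_equal(geno_r2(b, a)$r2, r$r2)
  expect_equal(geno_r2(2 - a, b)$r2, r$r2, tolerance = 1e-12)
})

test_that("linkage clustering joins pairs above the r2 threshold transitively", {
  set.seed(2)
  v1 <- rbinom(100, 2, 0.4)
  v2 <- v1; v2[1:3] <- 2 - v2[1:3]
  v3 <- rbinom(100, 2, 0.4)
  geno <- cbind(a = v1, b = v2, c = v3)
  cl <- ld_clusters(geno, r2_min = 0.8)
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])
  expect_false(cl$cluster[["a"]] == cl$cluster[["c"]])
})

test_that("normal-approximation power for a detectable proportion difference", {
  expect_equal(power_detectable_difference(74, 0.10), 0.818, tolerance = 1e-3)
  expect_lt(power_detectable_difference(74, 1e-6), 0.05)
  expect_gt(power_detectable_difference(1e6, 0.10), 0.999)
})
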