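# Null-model construction, per-variant QC, partitioning, weighting, and the
# burden / dispersion / ACAT battery.

make_null <- function(n = 500, seed = 20, family = "gaussian",
                      covariates = TRUE) {
  set.seed(seed)
  X <- if (covariates)
    data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5)) else NULL
  y <- stats::setNames(rnorm(n) + (if (covariates) 0.5 * X$age else 0),
                       sprintf("s%04d", seq_len(n)))
  list(null = fit_null_model(y, X, family = family), y = y, X = X, n = n)
}

test_that("variant QC applies the per-type hard filters with NA passing", {
  v <- data.frame(
    ref = c("A", "A", "AT", "A", "C"),
    alt = c("G", "G", "A", "G", "T"),
    QD = c(1.9, 10, 10, NA, 10),
    MQ = c(60, 60, NA, NA, 60),
    FS = c(1, 1, 150, NA, 1),
    SOR = c(1, 1, 1, NA, 1),
    MQRankSum = c(0, 0, NA, NA, -13),
    ReadPosRankSum = c(0, 0, -15, NA, 0))
  kept <- qc_filter(v)
  # SNV with QD = 1.9 removed; indel with FS = 150 retained (indel cut 200);
  # all-NA metrics retained; SNV MQRankSum -13 removed
  expect_identical(sort(rownames(kept)), sort(c("2", "3", "4")))
  removed <- attr(kept, "removed")
  expect_equal(nrow(kept) + nrow(removed), nrow(v))
  # idempotence
  again <- qc_filter(kept)
  expect_identical(again$QD, kept$QD)
  expect_equal(nrow(attr(again, "removed")), 0)
})

test_that("indel ReadPosRankSum uses the looser threshold", {
  v <- data.frame(ref = c("AT", "AT"), alt = c("A", "A"),
                  ReadPosRankSum = c(-15, -25))
  kept <- qc_filter(v)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$ReadPosRankSum, -15)
})

test_that("genotype blocks orient to the minor allele and impute after MAF/MAC", {
  dos <- cbind(v1 = c(2, 2, 2, 1, NA), v2 = c(0, 1, 0, 0, NA))
  rownames(dos) <- paste0("s", 1:5)
  b <- genotype_block("G1", dos)
  # v1 major-allele coded: flipped, MAF = 1 - 7/8
  expect_true(b$flipped["v1"])
  expect_equal(unname(b$maf["v1"]), 1 / 8)
  expect_equal(unname(b$mac["v1"]), 1L)
  expect_equal(unname(b$mac["v2"]), 1L)
  # imputation fills the NA with the observed mean and leaves MAC unchanged
  expect_equal(unname(b$dosages[5, "v2"]), 0.25)
  expect_false(anyNA(b$dosages))
})

test_that("variants partition by MAF and MAC with the stated boundaries", {
  n <- 600
  dos <- cbind(
    common = rbinom(n, 2, 0.2),
    rare = c(rep(1, 6), rep(0, n - 6)),     # MAC 6, MAF 0.005
    ultra = c(rep(1, 3), rep(0, n - 3)),    # MAC 3
    mono = rep(0, n))
  rownames(dos) <- sprintf("s%03d", 1:n)
  b <- genotype_block("G", dos)
  part <- partition_variants(b)
  expect_equal(colnames(b$dosages)[part$common], "common")
  expect_equal(colnames(b$dosages)[part$rare], "rare")
  expect_equal(colnames(b$dosages)[part$ultra_rare], "ultra")
  expect_false(4 %in% unlist(part))  # monomorphic excluded everywhere
  # the MAF = 0.01 boundary goes to the common/low-frequency partition
  dos2 <- cbind(bnd = c(rep(1, 12), rep(0, 588)))  # MAF = 12/1200 = 0.01
  b2 <- genotype_block("G2", dos2)
  expect_equal(unname(partition_variants(b2)$common), 1L)
})

test_that("beta weights follow the Beta(1,25) density and decrease in MAF", {
  expect_equal(beta_weight(0.01), 25 * 0.99^24, tolerance = 1e-12)
  expect_equal(beta_weight(0.01), dbeta(0.01, 1, 25), tolerance = 1e-12)
  expect_equal(beta_weight(1e-9), 25, tolerance = 1e-6)
  mafs <- seq(0.001, 0.5, length.out = 50)
  expect_true(all(diff(beta_weight(mafs)) < 0))
  expect_error(beta_weight(0), "positive")
})

test_that("the Gaussian null model centers residuals and flags degenerate covariates", {
  d <- make_null(covariates = FALSE)
  expect_equal(unname(d$null$residuals), unname(d$y - mean(d$y)),
               tolerance = 1e-10)
  expect_lt(abs(sum(d$null$residuals)), 1e-8)
  # covariate identical to the score: residuals vanish, tests return p near 1
  y <- d$y
  null2 <- fit_null_model(y, data.frame(same = as.numeric(y)),
                          family = "gaussian")
  expect_lt(max(abs(null2$residuals)), 1e-8)
  set.seed(30)
  g <- rbinom(length(y), 2, 0.1)
  expect_warning(p_degen <- burden_test(null2, cbind(g)), "residual variance")
  expect_equal(p_degen, 1)
})

test_that("the inverse-Gaussian null model recovers planted covariate effects", {
  set.seed(31)
  n <- 3000
  age <- rnorm(n)
  sexm <- rbinom(n, 1, 0.5)
  eta <- 1 + 0.3 * age + 0.2 * sexm
  y <- stats::setNames(
    statmod_rinvgauss(n, mean = exp(eta), shape = 50), sprintf("s%04d", 1:n))
  null <- fit_null_model(y, data.frame(age = age, sex = sexm),
                         family = "inverse-gaussian")
  expect_equal(null$family, "inverse-gaussian")
  cf <- null$coefficients
  se <- sqrt(diag(null$xtwx_inv) * null$phi)
  expect_lt(abs(cf["age"] - 0.3), 3 * se["age"])
  expect_lt(abs(cf["sex"] - 0.2), 3 * se["sex"])
})

test_that("burden, dispersion, and single-variant tests coincide for one variant", {
  d <- make_null()
  set.seed(32)
  g <- matrix(rbinom(d$n, 2, 0.05), ncol = 1,
              dimnames = list(names(d$y), "v1"))
  pb <- burden_test(d$null, g, weights = 3.7)   # weight cancels in the 1-df test
  pd <- dispersion_test(d$null, g, weights = 3.7)
  ps <- single_variant_tests(d$null, g)
  expect_equal(pb, unname(ps["v1"]), tolerance = 1e-10)
  expect_equal(pd, pb, tolerance = 1e-8)
  # a singleton's ultra-rare aggregate equals its single-variant test
  g1 <- matrix(c(1, rep(0, d$n - 1)), ncol = 1,
               dimnames = list(names(d$y), "u1"))
  expect_equal(ultra_rare_burden(d$null, g1),
               unname(single_variant_tests(d$null, g1)), tolerance = 1e-10)
})

test_that("ultra-rare aggregation is additive over disjoint carriers", {
  d <- make_null()
  g2 <- matrix(0, d$n, 2, dimnames = list(names(d$y), c("a", "b")))
  g2[1, "a"] <- 1
  g2[2, "b"] <- 1
  combined <- matrix(rowSums(g2), ncol = 1, dimnames = list(names(d$y), "ab"))
  expect_equal(ultra_rare_burden(d$null, g2),
               unname(single_variant_tests(d$null, combined)),
               tolerance = 1e-10)
})

test_that("degenerate partitions return p = 1 with a warning", {
  d <- make_null()
  g0 <- matrix(0, d$n, 2, dimnames = list(names(d$y), c("a", "b")))
  expect_warning(p1 <- burden_test(d$null, g0), "constant")
  expect_equal(p1, 1)
  expect_warning(p2 <- dispersion_test(d$null, g0), "variance")
  expect_equal(p2, 1)
  expect_warning(p3 <- ultra_rare_burden(d$null, g0), "carriers")
  expect_equal(p3, 1)
})

test_that("single-variant Gaussian score test matches the correlation t-test", {
  set.seed(33)
  n <- 5000
  y <- stats::setNames(rnorm(n), sprintf("s%04d", 1:n))
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(names(y), "v"))
  null <- fit_null_model(y, NULL, family = "gaussian")
  p_score <- unname(single_variant_tests(null, g))
  p_t <- stats::cor.test(as.numeric(y), g[, 1])$p.value
  expect_equal(p_score, p_t, tolerance = 1e-3)
})

test_that("dispersion beats burden when effects alternate in sign", {
  set.seed(34)
  n <- 2000
  m <- 10
  g <- matrix(rbinom(n * m, 2, 0.04), n, m,
              dimnames = list(sprintf("s%04d", 1:n), paste0("v", 1:m)))
  eff <- rep(c(0.4, -0.4), m / 2)
  ratio <- replicate(7, {
    y <- stats::setNames(rnorm(n) + drop(g %*% eff), rownames(g))
    null <- fit_null_model(y, NULL, family = "gaussian")
    c(b = burden_test(null, g), d = dispersion_test(null, g))
  })
  expect_lt(median(ratio["d", ]), median(ratio["b", ]) / 10)
})

test_that("Liu moment matching reproduces the exact single-chi-square tail", {
  qs <- c(0.1, 1, 4, 9)
  for (q in qs)
    expect_equal(qdrisk:::liu_pvalue(q, 1), pchisq(q, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  expect_equal(qdrisk:::liu_pvalue(7, c(2, 2)),
               pchisq(3.5, 2, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ACAT reproduces its closed-form identities and rejects bad input", {
  expect_equal(acat_combine(rep(0.137, 4)), 0.137, tolerance = 1e-12)
  expect_equal(acat_combine(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_error(acat_combine(numeric(0)), "no p-values")
  expect_error(acat_combine(c(0.5, 0)), "0, 1")
  # degenerate p = 1 components use the Bonferroni-style bound
  expect_equal(acat_combine(c(1, 1)), 1)
  expect_equal(acat_combine(c(0.001, 1, 1)), 0.003, tolerance = 1e-12)
})

test_that("the combined gene test mirrors partition availability", {
  d <- make_null(n = 800, seed = 35)
  set.seed(36)
  # rare-only gene: p.common is NA
  g_rare <- sapply(1:6, function(i) {
    x <- rep(0, d$n)
    x[sample(d$n, 6)] <- 1
    x
  })
  dimnames(g_rare) <- list(names(d$y), paste0("r", 1:6))
  b <- genotype_block("RAREONLY", g_rare)
  res <- gene_combined_test(d$null, b)
  expect_true(is.na(res$p_common))
  expect_false(is.na(res$p_rare))
  expect_false(is.na(res$p_all))
  expect_true(all(res$components > 0 & res$components <= 1))
})

test_that("a single runnable component passes through ACAT unchanged", {
  d <- make_null(n = 600, seed = 37)
  set.seed(38)
  g <- matrix(rbinom(d$n, 2, 0.15), ncol = 1,
              dimnames = list(names(d$y), "c1"))
  b <- genotype_block("ONEVAR", g)
  res <- gene_combined_test(d$null, b)
  # one common variant: burden = dispersion = single-variant = p.all
  expect_equal(unname(res$p_all), unname(res$components["burden.common"]),
               tolerance = 1e-8)
})

test_that("significance threshold reproduces the Bonferroni arithmetic", {
  expect_equal(significance_threshold(1, 1), 1)
  expect_equal(significance_threshold(0.02, 100), 2 * significance_threshold(0.01, 100))
})
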