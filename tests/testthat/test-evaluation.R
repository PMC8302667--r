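test_that("AUROC matches worked examples", {
  lab <- function(y) stats::setNames(ifelse(y == 1, "case", "control"),
                                     names(y))
  # perfectly separated
  s <- stats::setNames(c(5, 4, 3, 1, 0), paste0("s", 1:5))
  y <- stats::setNames(c(1, 1, 1, 0, 0), names(s))
  expect_equal(auroc(s, lab(y)), 1)
  # 3 cases {3,2,1}, 2 controls {2,0}: 4 wins, 1 tie, 1 loss of 6 pairs
  s2 <- stats::setNames(c(3, 2, 1, 2, 0), paste0("t", 1:5))
  y2 <- stats::setNames(c(1, 1, 1, 0, 0), names(s2))
  expect_equal(auroc(s2, lab(y2)), 4.5 / 6, tolerance = 1e-12)
  expect_equal(auroc(s2, lab(y2)),
               auroc_bruteforce(unname(s2), unname(y2)), tolerance = 1e-12)
  expect_error(auroc(s[y == 1], lab(y[y == 1])), "case and one control")
})

test_that("AUROC equals brute-force pair counting and is rank-invariant", {
  for (seed in 1:5) {
    d <- toy_scored_cohort(n = 150, seed = seed, ties = seed %% 2 == 0)
    expect_equal(auroc(d$scores, d$labels),
                 auroc_bruteforce(unname(d$scores), d$y), tolerance = 1e-12)
    # strictly increasing transform leaves AUROC unchanged
    expect_equal(auroc(exp(d$scores / 2), d$labels),
                 auroc(d$scores, d$labels), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  d <- toy_scored_cohort(n = 120, seed = 3)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(d$y, unname(d$scores),
                                             quiet = TRUE, direction = "<")))
  expect_equal(auroc(d$scores, d$labels), proc_auc, tolerance = 1e-10)
})

test_that("AUPRC is 1 under perfect separation and near prevalence under noise", {
  s <- stats::setNames(c(5, 4, 1, 0), paste0("s", 1:4))
  lab <- stats::setNames(c("case", "case", "control", "control"), names(s))
  expect_equal(auprc(s, lab), 1)
  set.seed(13)
  n <- 4000
  y <- rbinom(n, 1, 0.2)
  sc <- stats::setNames(rnorm(n), paste0("r", 1:n))
  labs <- stats::setNames(ifelse(y == 1, "case", "control"), names(sc))
  expect_equal(auprc(sc, labs), 0.2, tolerance = 0.04)
  expect_error(auprc(sc, stats::setNames(rep("control", n), names(sc))),
               "case")
})

test_that("AUPRC agrees with the exhaustive threshold sweep", {
  for (seed in 1:5) {
    d <- toy_scored_cohort(n = 80, seed = seed, ties = TRUE)
    expect_equal(auprc(d$scores, d$labels),
                 auprc_bruteforce(unname(d$scores), d$y), tolerance = 1e-12)
  }
})

test_that("Spearman staging correlation handles perfect and reversed orderings", {
  s <- stats::setNames(c(0.1, 0.5, 1.2, 3.0), paste0("s", 1:4))
  g <- stats::setNames(1:4, names(s))
  expect_equal(spearman_with_staging(s, g)$rho, 1)
  expect_equal(spearman_with_staging(s, rev(stats::setNames(1:4, names(s))))$rho,
               1)  # names align, values reversed but renamed
  g2 <- stats::setNames(4:1, names(s))
  expect_equal(spearman_with_staging(s, g2)$rho, -1)
  expect_error(spearman_with_staging(s, stats::setNames(rep(1, 4), names(s))),
               "constant")
})

test_that("Spearman rho and p match cor.test on a tie-heavy vector", {
  set.seed(14)
  s <- stats::setNames(sample(1:5, 60, replace = TRUE) + rnorm(60, 0, 0.01),
                       paste0("s", 1:60))
  g <- stats::setNames(sample(0:3, 60, replace = TRUE), names(s))
  ours <- spearman_with_staging(s, g)
  ref <- suppressWarnings(stats::cor.test(unname(s), unname(g),
                                          method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  # t approximation agrees with cor.test's tie-corrected p at moderate n
  expect_equal(ours$p.value, ref$p.value, tolerance = 0.02)
})

test_that("bin prevalence partitions the cohort and conserves case counts", {
  s <- stats::setNames(c(0, 0, 0, 1, 1, 1), paste0("s", 1:6))
  lab <- stats::setNames(ifelse(s == 1, "case", "control"), names(s))
  b <- bin_prevalence(s, lab, n_bins = 2)
  expect_equal(b$prevalence, c(0, 1))
  allc <- stats::setNames(rep("case", 6), names(s))
  expect_true(all(bin_prevalence(s, allc, n_bins = 2)$prevalence == 1))
  d <- toy_scored_cohort(n = 300, seed = 15)
  tb <- bin_prevalence(d$scores, d$labels, n_bins = 60)
  expect_equal(sum(tb$n_cases), sum(d$y))
  expect_equal(sum(tb$n), 300)
  expect_true(all(abs(tb$n - 5) <= 1))
  expect_error(bin_prevalence(s, lab, n_bins = 10), "fewer bins")
})

test_that("unknown subjects enter bins only as non-cases when flagged", {
  s <- stats::setNames(seq(0, 1, length.out = 100), sprintf("u%03d", 1:100))
  lab <- stats::setNames(rep(c("case", "control", "unknown"), length.out = 100),
                         names(s))
  excl <- bin_prevalence(s, lab, n_bins = 4)
  incl <- bin_prevalence(s, lab, n_bins = 4, include_unknown_as_control = TRUE)
  expect_equal(sum(excl$n), sum(lab != "unknown"))
  expect_equal(sum(incl$n), 100)
  expect_equal(sum(incl$n_cases), sum(lab == "case"))
})

test_that("per-bin prevalence under random scores stays near overall prevalence", {
  set.seed(16)
  n <- 6000
  y <- rbinom(n, 1, 0.3)
  s <- stats::setNames(runif(n), sprintf("q%04d", 1:n))
  lab <- stats::setNames(ifelse(y == 1, "case", "control"), names(s))
  b <- bin_prevalence(s, lab, n_bins = 10)
  se <- sqrt(0.3 * 0.7 / 600)
  expect_true(all(abs(b$prevalence - 0.3) < 4 * se))
})

test_that("weight enrichment test matches exact enumeration and is antisymmetric", {
  w <- c(r1 = 10, r2 = 9, n1 = 2, n2 = 1)
  # both relevant weights exceed both others: exact p = 1 / C(4,2)
  expect_equal(weight_enrichment_test(w, c("r1", "r2")), 1 / 6,
               tolerance = 1e-12)
  expect_equal(weight_enrichment_test(w, c("r1", "r2")),
               wilcox_exact_enumeration(w[1:2], w[3:4]), tolerance = 1e-12)
  for (seed in 1:4) {
    set.seed(seed)
    w2 <- stats::setNames(rnorm(12), paste0("f", 1:12))
    rel <- paste0("f", 1:5)
    expect_equal(weight_enrichment_test(w2, rel),
                 wilcox_exact_enumeration(w2[rel], w2[setdiff(names(w2), rel)]),
                 tolerance = 1e-12)
    # swapping groups: p_fwd + p_rev = 1 + P(W = w_obs) under the exact law
    p_fwd <- weight_enrichment_test(w2, rel)
    p_rev <- weight_enrichment_test(w2, setdiff(names(w2), rel))
    atom <- wilcox_exact_atom(w2[rel], w2[setdiff(names(w2), rel)])
    expect_lt(abs(p_fwd + p_rev - 1 - atom), 1e-12)
  }
  # identical weight multisets: symmetric, p near 0.5
  w3 <- stats::setNames(rep(c(1, 2, 3), 8), paste0("g", 1:24))
  expect_equal(weight_enrichment_test(w3, paste0("g", 1:12)), 0.5,
               tolerance = 1e-9)
  expect_error(weight_enrichment_test(w3, character(0)), "non-empty")
})
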