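# Independent brute-force oracles used to validate the fast implementations.

# AUROC by exhaustive case/control pair counting (ties count 1/2).
auroc_bruteforce <- function(scores, y) {
  cs <- scores[y == 1L]
  ct <- scores[y == 0L]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Average precision by an exhaustive sweep over unique thresholds.
auprc_bruteforce <- function(scores, y) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  npos <- sum(y)
  for (t in thr) {
    called <- scores >= t
    tp <- sum(y[called])
    precision <- tp / sum(called)
    recall <- tp / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Exact one-sided Wilcoxon rank-sum p-value by enumerating all group
# assignments (alternative: group x has greater values).
wilcox_exact_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(n, length(x))
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(w_all >= w_obs)
}

# Point mass of the permutation rank-sum distribution at the observed sum.
wilcox_exact_atom <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(w_all == w_obs)
}

# Inverse-Gaussian sampler (Michael-Schucany-Haas transformation), used to
# generate responses for the null-model recovery tests.
statmod_rinvgauss <- function(n, mean, shape) {
  nu <- rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

# Small labeled cohort for evaluation tests.
toy_scored_cohort <- function(n = 60, seed = 42, ties = FALSE) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  s <- rnorm(n) + y
  if (ties) s <- round(s)
  ids <- sprintf("id%03d", seq_len(n))
  list(scores = stats::setNames(s, ids),
       labels = stats::setNames(ifelse(y == 1, "case", "control"), ids),
       y = y)
}

# Tiny occurrence-record fixture (built in code, deterministic).
toy_records <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    phecode = c("585.3", "585.3", "250.2", "585.3", "250.2", "250.2"),
    age = c(50, 51, 50, 60, 60, 40),
    stringsAsFactors = FALSE)
}

# Small standardized matrix plus labels for LPC fits.
toy_lpc_data <- function(n = 400, j = 12, seed = 7) {
  set.seed(seed)
  f <- rnorm(n)
  p <- matrix(rbinom(n * j, 1, plogis(-1 + f %o% c(rep(1.5, 4), rep(0, j - 4)))),
              n, j, dimnames = list(sprintf("s%03d", 1:n), paste0("ph", 1:j)))
  labels <- stats::setNames(ifelse(f > quantile(f, 0.7), "case",
                                   ifelse(f < 0, "control", "unknown")),
                            rownames(p))
  list(presence = p, labels = labels, factor = f)
}
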