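# Score evaluation: discrimination, severity correlation, percentile-bin
# prevalence, and enrichment of weights on disease-relevant features.

# Coerce weak labels to a 0/1 case indicator aligned with scores, dropping
# unknown-status subjects.
align_case_indicator <- function(scores, labels) {
  stop_if_not_named(scores, "scores")
  stop_if_not_named(labels, "labels")
  common <- intersect(names(scores), names(labels))
  lab <- labels[common]
  keep <- lab %in% c("case", "control")
  list(scores = scores[common][keep], y = as.integer(lab[keep] == "case"))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, with ties counted 1/2; computed from midranks.
#'
#' @param scores named numeric score vector.
#' @param labels named weak labels (`case`/`control`/`unknown`; unknowns are
#'   excluded).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  d <- align_case_indicator(scores, labels)
  n1 <- sum(d$y == 1L)
  n0 <- sum(d$y == 0L)
  if (n1 == 0L || n0 == 0L) stop("need at least one case and one control")
  r <- rank(d$scores)
  (sum(r[d$y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision over unique score thresholds:
#' AP = sum_k (R_k - R_{k-1}) P_k, with subjects tied at a threshold entering
#' together.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  d <- align_case_indicator(scores, labels)
  if (sum(d$y) == 0L) stop("need at least one case")
  thr <- sort(unique(d$scores), decreasing = TRUE)
  idx <- order(d$scores, decreasing = TRUE)
  s <- d$scores[idx]
  y <- d$y[idx]
  grp <- match(s, thr)                      # threshold group per subject
  tp <- cumsum(y)
  pos <- seq_along(y)
  last <- which(diff(c(grp, Inf)) != 0)     # last index within each group
  precision <- tp[last] / pos[last]
  recall <- tp[last] / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Spearman correlation of scores with ordinal disease staging
#'
#' Spearman's rho on midranks with a large-sample t approximation for the
#' p-value.
#'
#' @param scores named numeric score vector.
#' @param staging named ordinal grade per subject (integer or ordered
#'   factor); subjects with NA staging are dropped.
#' @return list with `rho`, `p.value`, `n`.
#' @export
spearman_with_staging <- function(scores, staging) {
  stop_if_not_named(scores, "scores")
  stop_if_not_named(staging, "staging")
  common <- intersect(names(scores), names(staging))
  g <- as.numeric(staging[common])
  s <- scores[common]
  keep <- !is.na(g) & !is.na(s)
  g <- g[keep]; s <- s[keep]
  n <- length(g)
  if (n < 3L) stop("need at least 3 subjects with staging")
  if (length(unique(g)) < 2L) stop("staging is constant")
  rho <- stats::cor(rank(s), rank(g))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Case prevalence in score-percentile bins
#'
#' Subjects are ranked by score (ties broken by their stable input order) and
#' assigned to `n_bins` nearly equal bins; per-bin case prevalence is
#' reported.  Unknown-status subjects are either excluded (default) or
#' counted as non-cases.
#'
#' @inheritParams auroc
#' @param n_bins number of percentile bins (default 60).
#' @param include_unknown_as_control count unknown-status subjects as
#'   non-cases instead of excluding them.
#' @return data.frame with columns `bin`, `score_min`, `score_max`, `n`,
#'   `n_cases`, `prevalence`.
#' @export
bin_prevalence <- function(scores, labels, n_bins = 60L,
                           include_unknown_as_control = FALSE) {
  stop_if_not_named(scores, "scores")
  stop_if_not_named(labels, "labels")
  common <- intersect(names(scores), names(labels))
  lab <- labels[common]
  keep <- if (include_unknown_as_control) rep(TRUE, length(lab))
          else lab %in% c("case", "control")
  s <- scores[common][keep]
  y <- as.integer(lab[keep] == "case")
  n <- length(s)
  if (n < n_bins)
    stop("only ", n, " subjects for ", n_bins, " bins; use fewer bins")
  r <- rank(s, ties.method = "first")
  bin <- floor((r - 1) * n_bins / n) + 1L
  out <- data.frame(
    bin = seq_len(n_bins),
    score_min = as.numeric(tapply(s, bin, min)),
    score_max = as.numeric(tapply(s, bin, max)),
    n = as.integer(tabulate(bin, n_bins)),
    n_cases = as.integer(tapply(y, bin, sum)))
  out$prevalence <- out$n_cases / out$n
  out
}

#' One-sided weight-enrichment test for relevant features
#'
#' Wilcoxon rank-sum test that the weights of the `relevant` features are
#' greater than the weights of the remaining features.  The exact
#' distribution is used when both groups have at most 10 members and there
#' are no ties; otherwise the normal approximation with tie correction.
#'
#' @param weights named numeric per-feature weights.
#' @param relevant names (or logical/integer index) of the relevant features.
#' @return one-sided p-value.
#' @export
weight_enrichment_test <- function(weights, relevant) {
  if (is.character(relevant)) {
    missing <- setdiff(relevant, names(weights))
    if (length(missing) > 0L)
      stop("relevant features absent from weights: ",
           paste(missing, collapse = ", "))
    rel <- names(weights) %in% relevant
  } else if (is.logical(relevant)) {
    stopifnot(length(relevant) == length(weights))
    rel <- relevant
  } else {
    rel <- seq_along(weights) %in% relevant
  }
  x <- weights[rel]
  y <- weights[!rel]
  if (length(x) == 0L || length(y) == 0L)
    stop("both the relevant and the remaining group must be non-empty")
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = "greater",
                     exact = exact, correct = FALSE)$p.value
}
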