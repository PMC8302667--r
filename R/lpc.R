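# LPC: eigenvalue-weighted linear combination of principal components of the
# phecode correlation matrix, with the number of components chosen by the
# Tracy-Widom test and component signs fixed with weak case/control labels.

# Tracy-Widom (beta = 1) distribution via the Chiani (2014) shifted-gamma
# approximation, accurate to about 1e-4 in CDF over the support of interest.
TW1_K <- 46.44604884387
TW1_THETA <- 0.18605402228279
TW1_SHIFT <- 9.84801210848987

#' Tracy-Widom (TW1) distribution function
#' @param q quantile(s).
#' @return P(TW1 <= q).
#' @export
ptw1 <- function(q) stats::pgamma(q + TW1_SHIFT, shape = TW1_K, scale = TW1_THETA)

#' Tracy-Widom (TW1) quantile function
#' @param p probability in (0,1).
#' @return quantile of the TW1 law.
#' @export
qtw1 <- function(p) stats::qgamma(p, shape = TW1_K, scale = TW1_THETA) - TW1_SHIFT

#' Number of significant eigenvalues by sequential Tracy-Widom testing
#'
#' Eigenvalues of the feature correlation matrix are tested from the top
#' down.  At each step the leading remaining eigenvalue is normalized
#' Patterson-style against the remaining spectrum (L = p * lambda / sum,
#' effective sample size n - 1), centered and scaled with the
#' Johnstone constants, and compared to the TW1 critical value at `alpha`.
#' Testing stops at the first non-significant eigenvalue.
#'
#' @param eigenvalues non-increasing, non-negative eigenvalues.
#' @param n sample size used to estimate the correlation matrix.
#' @param alpha significance level (default 0.05).
#' @return integer K, the number of significant leading eigenvalues.
#' @export
tracy_widom_k <- function(eigenvalues, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(eigenvalues) == 0L) return(0L)
  if (any(eigenvalues < -1e-8)) stop("eigenvalues must be non-negative")
  ev <- pmax(eigenvalues, 0)
  if (is.unsorted(rev(ev))) stop("eigenvalues must be non-increasing")
  crit <- qtw1(1 - alpha)
  neff <- n - 1
  if (neff < 2) stop("sample size too small for the Tracy-Widom test")
  k <- 0L
  while (k < length(ev)) {
    rem <- ev[(k + 1L):length(ev)]
    p <- length(rem)
    if (p < 2L || sum(rem) <= 0) break
    L <- neff * rem[1L] * p / sum(rem)
    a <- sqrt(neff - 1)
    b <- sqrt(p)
    mu <- (a + b)^2
    sigma <- (a + b) * (1 / a + 1 / b)^(1 / 3)
    x <- (L - mu) / sigma
    if (x <= crit) break
    k <- k + 1L
  }
  k
}

#' Fit an LPC score model
#'
#' Computes the sample correlation matrix Q of the standardized training
#' features, its eigendecomposition Q = sum_j lambda_j u_j u_j', selects the
#' number of components K with [tracy_widom_k()], and fixes the arbitrary
#' sign of each retained component so that the mean PC value among weakly
#' labeled cases is at least that among controls (exact ties keep +1).
#'
#' @param x `std_features` training matrix (see [standardize()]).
#' @param labels named weak labels (`case`/`control`/`unknown`); only used
#'   for sign fixing.
#' @param alpha Tracy-Widom significance level (default 0.05).
#' @param K optional override of the number of components.
#' @return `lpc_model`: features, training centering/scaling statistics,
#'   loadings (J x K orthonormal columns), eigenvalues, signs, K.
#' @export
fit_lpc <- function(x, labels, alpha = 0.05, K = NULL) {
  stopifnot(inherits(x, "std_features"))
  stop_if_not_named(labels, "labels")
  subj <- x$subjects
  cases <- intersect(subj, names(labels)[labels == "case"])
  controls <- intersect(subj, names(labels)[labels == "control"])
  if (length(cases) == 0L || length(controls) == 0L)
    stop("need at least one labeled case and one labeled control for sign fixing")
  n <- nrow(x$values)
  Q <- stats::cor(x$values)
  eig <- eigen(Q, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (is.null(K)) K <- tracy_widom_k(lambda, n = n, alpha = alpha)
  if (K == 0L) {
    warning("Tracy-Widom test found no significant components; keeping K = 1")
    K <- 1L
  }
  U <- eig$vectors[, seq_len(K), drop = FALSE]
  rownames(U) <- x$features
  pc <- x$values %*% U
  rownames(pc) <- subj
  s <- ifelse(colMeans(pc[cases, , drop = FALSE]) >=
                colMeans(pc[controls, , drop = FALSE]), 1, -1)
  structure(list(features = x$features, col_means = x$col_means,
                 col_sds = x$col_sds, dropped_features = x$dropped_features,
                 loadings = U, eigenvalues = lambda[seq_len(K)],
                 signs = as.numeric(s), K = K, alpha = alpha),
            class = "lpc_model")
}

#' Score subjects with a fitted LPC model
#'
#' LPC_i = sum_{k=1..K} lambda_k s_k (x_i . u_k), where x_i is the subject's
#' feature row standardized with the model's training statistics.
#'
#' @param model `lpc_model`.
#' @param x `std_features` standardized with the model's training stats
#'   (see [standardize()] with `stats =` the model fields), or a presence
#'   matrix which will be standardized on the fly with those stats.
#' @return named numeric score vector.
#' @export
score_lpc <- function(model, x) {
  stopifnot(inherits(model, "lpc_model"))
  if (!inherits(x, "std_features"))
    x <- standardize(x, stats = model[c("features", "col_means", "col_sds")])
  if (!identical(x$features, model$features))
    stop("feature set mismatch between model and matrix")
  w <- model$loadings %*% (model$eigenvalues * model$signs)
  stats::setNames(drop(x$values %*% w), x$subjects)
}

#' Effective per-feature weights of an LPC model
#'
#' Collapses the component form into the weighted-linear-combination form:
#' w = sum_k lambda_k s_k u_k, so that the LPC score is exactly
#' sum_j w_j x_ij on standardized features.
#'
#' @param model `lpc_model`.
#' @return named numeric vector of per-feature weights.
#' @export
effective_feature_weights <- function(model) {
  stopifnot(inherits(model, "lpc_model"))
  stats::setNames(drop(model$loadings %*% (model$eigenvalues * model$signs)),
                  model$features)
}

#' @export
print.lpc_model <- function(x, ...) {
  cat("LPC model:", length(x$features), "features, K =", x$K,
      "components (TW alpha =", x$alpha, ")\n")
  cat("eigenvalue weights:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}
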