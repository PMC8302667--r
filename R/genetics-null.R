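# Null GLM for the quantitative risk score, and the shared score-test
# machinery used by the burden, dispersion, and single-variant tests.

#' Fit the null covariate model for gene-based score tests
#'
#' Regresses the quantitative disease risk score on the covariates (typically
#' age, sex, and genetic PCs).  Because the risk scores are right-skewed, the
#' default family is the inverse-Gaussian GLM with a log link; the response
#' is affinely shifted to positive support (s' = s - min(s) + 0.01 * IQR(s))
#' before fitting.  Non-convergence falls back to the Gaussian family with a
#' warning.
#'
#' @param scores named numeric score vector.
#' @param covariates data.frame of covariates with subject ids as rownames
#'   (or aligned by position when NULL rownames); NULL for an
#'   intercept-only model.
#' @param family `"inverse-gaussian"` (default) or `"gaussian"`.
#' @return `null_score_model` holding the fitted GLM, the design matrix, the
#'   score residuals, the IRLS weights, and the dispersion estimate.
#' @export
fit_null_model <- function(scores, covariates = NULL,
                           family = c("inverse-gaussian", "gaussian")) {
  family <- match.arg(family)
  stop_if_not_named(scores, "scores")
  y <- as.numeric(scores)
  n <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(names(scores), "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    if (!is.null(rownames(covariates)) &&
        all(names(scores) %in% rownames(covariates)))
      covariates <- covariates[names(scores), , drop = FALSE]
    stopifnot(nrow(covariates) == n)
    X <- stats::model.matrix(~ ., data = covariates)
    rownames(X) <- names(scores)
  }
  if (n <= ncol(X) + 1L) stop("need n greater than the number of covariates + 1")
  shift <- 0
  family_used <- family
  fit <- NULL
  if (family == "inverse-gaussian") {
    # shift to positive support only when needed; already-positive scores
    # are fitted on their own scale so covariate effects stay interpretable
    if (min(y) <= 0) {
      iqr <- stats::IQR(y)
      shift <- -min(y) + 0.01 * (if (iqr > 0) iqr else 1)
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(
        X, y + shift, family = stats::inverse.gaussian(link = "log"))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("inverse-Gaussian GLM did not converge; falling back to Gaussian")
      family_used <- "gaussian"
      shift <- 0
      fit <- NULL
    }
  }
  if (is.null(fit))
    fit <- stats::glm.fit(X, y, family = stats::gaussian())
  w <- fit$weights                       # IRLS working weights
  mu <- fit$fitted.values
  fam <- fit$family
  rdf <- n - fit$rank
  phi <- sum(w * fit$residuals^2) / rdf  # Pearson dispersion
  r <- w * fit$residuals                 # score residuals: (y-mu) dmu/deta / V(mu)
  Xw <- X * sqrt(w)
  xtwx <- crossprod(Xw)
  vy <- stats::var(y)
  degenerate <- !is.finite(phi) || phi <= max(1e-12 * vy, 1e-300)
  structure(list(fit = fit, X = X, family = family_used, shift = shift,
                 weights = w, phi = phi, degenerate = degenerate,
                 residuals = stats::setNames(r, names(scores)),
                 coefficients = fit$coefficients,
                 xtwx_inv = solve(xtwx), n = n),
            class = "null_score_model")
}

#' @export
print.null_score_model <- function(x, ...) {
  cat("Null score model (", x$family, " family), n = ", x$n, ", ",
      ncol(x$X) - 1L, " covariate column(s), dispersion = ",
      signif(x$phi, 4), "\n", sep = "")
  invisible(x)
}

# Score statistic pieces for a matrix of tested covariates Z (n x m):
# U = Z' r / phi and V = (Z' W Z - (X'WZ)' (X'WX)^-1 (X'WZ)) / phi,
# the covariance of U under the null, with W the IRLS weights.
score_test_parts <- function(null, Z) {
  stopifnot(inherits(null, "null_score_model"))
  Z <- as.matrix(Z)
  if (nrow(Z) != null$n) stop("tested covariates have the wrong length")
  U <- drop(crossprod(Z, null$residuals)) / null$phi
  WZ <- Z * null$weights
  XtWZ <- crossprod(null$X, WZ)
  V <- (crossprod(Z, WZ) - t(XtWZ) %*% null$xtwx_inv %*% XtWZ) / null$phi
  list(U = U, V = V)
}

# 1-df chi-square score test for a single tested covariate z.
score_test_1df <- function(null, z) {
  if (isTRUE(null$degenerate)) {
    warning("null model has (near-)zero residual variance; p = 1")
    return(1)
  }
  parts <- score_test_parts(null, matrix(z, ncol = 1))
  v <- as.numeric(parts$V)
  if (v <= 0) return(1)
  stats::pchisq(parts$U^2 / v, df = 1, lower.tail = FALSE)
}

# Liu-Tang-Zhang moment-matching tail probability for Q = sum lambda_k chi^2_1.
# Matches mean, variance, skewness and kurtosis to a (noncentral) chi-square.
liu_pvalue <- function(Q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    delta <- 0
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta
  sigma_x <- sqrt(2 * (l + 2 * delta))
  tstar <- (Q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}
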