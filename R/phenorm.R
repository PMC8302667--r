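# PheNorm: utilization-normalized count of case-defining phecodes, denoised
# by regressing the normalized count on a randomly corrupted copy of the
# feature matrix (dropout training).

#' Utilization-normalize a count of case-defining phecodes
#'
#' z = log(1 + x) - alpha * log(1 + u), where x is the per-subject count of
#' case-defining phecodes and u the healthcare utilization.
#'
#' @param counts non-negative numeric vector of case-defining code counts.
#' @param utl non-negative utilization vector, aligned with `counts`.
#' @param alpha normalization exponent.
#' @return numeric vector z.
#' @export
phenorm_normalize <- function(counts, utl, alpha) {
  stopifnot(length(counts) == length(utl), all(counts >= 0), all(utl >= 0))
  if (!is.null(names(counts)) && !is.null(names(utl))) {
    if (!setequal(names(counts), names(utl)))
      stop("counts and utilization cover different subjects")
    utl <- utl[names(counts)]
  }
  log1p(counts) - alpha * log1p(utl)
}

# Two-component equal-variance Gaussian mixture by EM with a deterministic
# quantile-based initialization (k-means style split at the two quartiles).
fit_mixture2 <- function(z, max_iter = 500L, tol = 1e-8) {
  n <- length(z)
  if (n < 4L || stats::sd(z) == 0) stop("degenerate sample for mixture fit")
  mu <- as.numeric(stats::quantile(z, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * stats::sd(z) / 2
  sigma <- stats::sd(z)
  pi1 <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(z, mu[1], sigma)
    d2 <- (1 - pi1) * stats::dnorm(z, mu[2], sigma)
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    n1 <- sum(g)
    if (n1 < 1e-8 || n - n1 < 1e-8) break  # component collapsed
    pi1 <- n1 / n
    mu[1] <- sum(g * z) / n1
    mu[2] <- sum((1 - g) * z) / (n - n1)
    sigma <- sqrt((sum(g * (z - mu[1])^2) + sum((1 - g) * (z - mu[2])^2)) / n)
    if (sigma < 1e-10) break
  }
  list(pi = c(pi1, 1 - pi1), mu = mu, sigma = sigma,
       loglik = ll_old, converged = converged)
}

mixture2_cdf <- function(q, fit) {
  fit$pi[1] * stats::pnorm(q, fit$mu[1], fit$sigma) +
    fit$pi[2] * stats::pnorm(q, fit$mu[2], fit$sigma)
}

# Kolmogorov-Smirnov distance between the empirical CDF of z and a fitted
# two-component mixture CDF.
ks_mixture_distance <- function(z, fit) {
  zs <- sort(z)
  n <- length(zs)
  Fz <- mixture2_cdf(zs, fit)
  max(abs(Fz - seq_len(n) / n), abs(Fz - (seq_len(n) - 1L) / n))
}

#' Select the PheNorm normalization exponent alpha
#'
#' For each alpha on the grid, the normalized counts z(alpha) are fitted
#' with a two-component equal-variance Gaussian mixture by EM, and the
#' Kolmogorov-Smirnov distance between the empirical distribution of z and
#' the fitted mixture is computed.  The alpha minimizing this distance is
#' returned; grid points where the EM fails are skipped with a warning.
#'
#' @param counts,utl as in [phenorm_normalize()].
#' @param grid candidate alpha values (default `seq(0, 2, by = 0.01)`).
#' @return the selected alpha (numeric scalar) with attribute `ks` holding
#'   the per-grid-point distances.
#' @export
select_alpha <- function(counts, utl, grid = seq(0, 2, by = 0.01)) {
  if (length(grid) == 0L) stop("alpha grid is empty")
  ks <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    z <- phenorm_normalize(counts, utl, grid[i])
    fit <- tryCatch(fit_mixture2(z), error = function(e) NULL)
    if (is.null(fit)) {
      warning("EM failed at alpha = ", grid[i], "; grid point skipped")
      next
    }
    ks[i] <- ks_mixture_distance(z, fit)
  }
  if (all(is.na(ks))) stop("mixture EM failed at every grid point")
  best <- which.min(ks)
  structure(grid[best], ks = stats::setNames(ks, grid))
}

#' Randomly corrupt a matrix by dropout to the column mean
#'
#' Each entry is independently kept with probability 1 - r and otherwise
#' replaced by its column mean (dropout rate r).
#'
#' @param Z numeric matrix.
#' @param r dropout rate in [0, 1).
#' @param seed optional integer for reproducibility.
#' @return corrupted matrix of the same shape.
#' @export
corrupt_matrix <- function(Z, r, seed = NULL) {
  Z <- as.matrix(Z)
  if (r < 0 || r >= 1) stop("dropout rate r must be in [0, 1)")
  if (r == 0) return(Z)
  with_seed(seed, {
    drop_it <- matrix(stats::runif(length(Z)) < r, nrow(Z), ncol(Z))
    cm <- colMeans(Z)
    Z[drop_it] <- cm[col(Z)[drop_it]]
    Z
  })
}

#' Fit a PheNorm model
#'
#' Selects alpha on the full training set, assembles the feature matrix
#' Z = [z_case, z_1, ..., z_p] (the normalized case-code count followed by
#' the standardized candidate features), draws a bootstrap of `B` rows with
#' replacement, corrupts the bootstrap copy by dropout, and regresses the
#' uncorrupted z_case on the corrupted matrix by ordinary least squares with
#' an intercept.  A singular cross-product falls back to a minimal ridge
#' (1e-8 on the diagonal) with a warning.
#'
#' @param x_candidates `std_features` of candidate features; must exclude the
#'   case-defining phecodes themselves (they enter only through `counts`).
#' @param counts per-subject count of case-defining phecodes (aligned with
#'   the rows of `x_candidates`).
#' @param utl per-subject utilization.
#' @param r dropout rate (default 0.3).
#' @param B bootstrap size (default 1e5).
#' @param alpha optional fixed alpha; selected with [select_alpha()] when
#'   NULL.
#' @param alpha_grid grid for [select_alpha()].
#' @param seed integer seed controlling the bootstrap and corruption.
#' @return `phenorm_model`: alpha, r, B, seed, coefficients `beta`
#'   (intercept, z_case, one per candidate feature), candidate `features`,
#'   and the in-sample `r_squared` of the denoising regression.
#' @export
fit_phenorm <- function(x_candidates, counts, utl, r = 0.3, B = 1e5,
                        alpha = NULL, alpha_grid = seq(0, 2, by = 0.01),
                        seed = 1L) {
  stopifnot(inherits(x_candidates, "std_features"))
  n <- nrow(x_candidates$values)
  stopifnot(length(counts) == n, length(utl) == n)
  if (is.null(alpha)) alpha <- as.numeric(select_alpha(counts, utl, alpha_grid))
  z <- phenorm_normalize(counts, utl, alpha)
  Z <- cbind(z_case = z, x_candidates$values)
  with_seed(seed, {
    idx <- sample.int(n, size = B, replace = TRUE)
    Zb <- Z[idx, , drop = FALSE]
    Zc <- corrupt_matrix(Zb, r)
    D <- cbind(`(Intercept)` = 1, Zc)
    y <- z[idx]
    xtx <- crossprod(D)
    xty <- crossprod(D, y)
    beta <- tryCatch(drop(solve(xtx, xty)), error = function(e) {
      warning("singular design after corruption; using minimal ridge (1e-8)")
      drop(solve(xtx + diag(1e-8, ncol(D)), xty))
    })
    fitted <- drop(D %*% beta)
    r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  })
  structure(list(alpha = alpha, r = r, B = as.integer(B), seed = seed,
                 beta = stats::setNames(beta, colnames(D)),
                 features = x_candidates$features,
                 col_means = x_candidates$col_means,
                 col_sds = x_candidates$col_sds,
                 r_squared = r2),
            class = "phenorm_model")
}

#' Score subjects with a fitted PheNorm model
#'
#' Applies the denoising regression coefficients to the UNcorrupted feature
#' vector [1, z_case, z_1, ..., z_p].
#'
#' @param model `phenorm_model`.
#' @param x_candidates `std_features` standardized with the model's training
#'   statistics.
#' @param counts,utl per-subject case-code counts and utilization.
#' @return named numeric score vector.
#' @export
score_phenorm <- function(model, x_candidates, counts, utl) {
  stopifnot(inherits(model, "phenorm_model"))
  if (!inherits(x_candidates, "std_features"))
    x_candidates <- standardize(
      x_candidates, stats = model[c("features", "col_means", "col_sds")])
  if (!identical(x_candidates$features, model$features))
    stop("feature set mismatch between model and matrix")
  n <- nrow(x_candidates$values)
  stopifnot(length(counts) == n, length(utl) == n)
  z <- phenorm_normalize(counts, utl, model$alpha)
  D <- cbind(1, z_case = z, x_candidates$values)
  stats::setNames(drop(D %*% model$beta), x_candidates$subjects)
}

#' @export
print.phenorm_model <- function(x, ...) {
  cat("PheNorm model: alpha =", signif(x$alpha, 4), ", dropout r =", x$r,
      ", bootstrap B =", x$B, "\n")
  cat(length(x$features), "candidate features; denoising R^2 =",
      signif(x$r_squared, 4), "\n")
  invisible(x)
}
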