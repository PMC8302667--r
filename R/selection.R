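# PRS computation from supplied weights, and PRS-driven pre-selection of
# disease-relevant phecodes by per-phecode logistic regression.

#' Compute a polygenic risk score from supplied variant weights
#'
#' PRS_i = sum_v dosage_iv * weight_v, with dosages oriented to the effect
#' allele and weights on the natural-log relative-risk scale.
#'
#' @param dosages subjects x variants numeric matrix with values in [0, 2]
#'   and variant ids as column names.
#' @param weights either a named numeric vector (variant id -> weight) or a
#'   data.frame with columns `variant_id`, `effect_allele`, `weight`.
#' @return named numeric PRS vector.
#' @export
compute_prs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (is.data.frame(weights)) {
    stopifnot(all(c("variant_id", "weight") %in% names(weights)))
    w <- stats::setNames(weights$weight, as.character(weights$variant_id))
  } else {
    stop_if_not_named(weights, "weights")
    w <- weights
  }
  if (!all(is.finite(w))) stop("weights must be finite")
  missing <- setdiff(names(w), colnames(dosages))
  if (length(missing) > 0L)
    stop("variants absent from dosage matrix: ",
         paste(missing, collapse = ", "))
  drop(dosages[, names(w), drop = FALSE] %*% w)
}

#' Pre-select disease-relevant phecodes by association with a PRS
#'
#' Regresses each phecode's presence indicator on the standardized PRS by
#' logistic regression and retains phecodes whose Wald p-value on the PRS
#' coefficient falls below `threshold`.  Phecodes with zero or full
#' prevalence in the analysis subjects are skipped with a warning
#' (separation).
#'
#' @param p presence matrix.
#' @param prs named PRS vector; subjects are intersected with the matrix
#'   rows.
#' @param threshold retention p-value threshold (default 1e-5).
#' @param min_overlap minimum number of subjects shared between `p` and
#'   `prs` (default 50).
#' @param covariates optional data.frame of additional adjustment covariates
#'   (rows aligned to the shared subjects by rowname).
#' @return data.frame with columns `phecode`, `beta`, `p_value`, `selected`,
#'   and attribute `threshold`.
#' @export
preselect_phecodes <- function(p, prs, threshold = 1e-5, min_overlap = 50L,
                               covariates = NULL) {
  p <- as.matrix(p)
  stop_if_not_named(prs, "prs")
  common <- intersect(rownames(p), names(prs))
  if (length(common) < min_overlap)
    stop("only ", length(common), " overlapping subjects (need >= ",
         min_overlap, ")")
  pm <- p[common, , drop = FALSE]
  z <- as.numeric(scale(prs[common]))
  cov_df <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!all(common %in% rownames(covariates)))
      stop("covariates missing for some overlapping subjects")
    cov_df <- covariates[common, , drop = FALSE]
  }
  J <- ncol(pm)
  beta <- p_value <- rep(NA_real_, J)
  degenerate <- logical(J)
  for (j in seq_len(J)) {
    y <- pm[, j]
    if (all(y == 0) || all(y == 1)) {
      degenerate[j] <- TRUE
      next
    }
    df <- data.frame(y = y, prs = z)
    if (!is.null(cov_df)) df <- cbind(df, cov_df)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    if ("prs" %in% rownames(cf)) {
      beta[j] <- cf["prs", "Estimate"]
      p_value[j] <- cf["prs", "Pr(>|z|)"]
    }
  }
  if (any(degenerate))
    warning(sum(degenerate),
            " phecode(s) with zero or full prevalence skipped")
  out <- data.frame(phecode = colnames(pm), beta = beta, p_value = p_value,
                    selected = !is.na(p_value) & p_value < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}
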