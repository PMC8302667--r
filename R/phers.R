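#' Fit a phenotype risk score (PheRS) model
#'
#' Weights each phecode by the log inverse prevalence of the phecode in a
#' reference cohort (typically the controls of the training set):
#' w_j = log(N / n_j), where N is the reference size and n_j the number of
#' reference subjects carrying feature j.  Features absent from the entire
#' reference (n_j = 0) are smoothed to n_j = 1 so test-set carriers still
#' receive a finite weight.
#'
#' @param p presence matrix (subjects x phecodes, 0/1).
#' @param reference_ids subject ids defining the reference prevalence cohort.
#' @return `phers_model`: list with `features`, `weights`, `n_ref`.
#' @export
fit_phers <- function(p, reference_ids) {
  p <- as.matrix(p)
  reference_ids <- as.character(reference_ids)
  if (length(reference_ids) == 0L) stop("reference cohort is empty")
  missing <- setdiff(reference_ids, rownames(p))
  if (length(missing) > 0L)
    stop("reference subjects absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  N <- length(reference_ids)
  n_j <- colSums(p[reference_ids, , drop = FALSE])
  w <- log(N / ifelse(n_j == 0, n_j + 1, n_j))
  structure(list(features = colnames(p),
                 weights = stats::setNames(w, colnames(p)),
                 n_ref = N),
            class = "phers_model")
}

#' Score subjects with a fitted PheRS model
#'
#' PheRS_i = sum_j w_j 1{subject i has feature j}.
#'
#' @param model `phers_model`.
#' @param p presence matrix containing all model features.
#' @return named numeric score vector.
#' @export
score_phers <- function(model, p) {
  stopifnot(inherits(model, "phers_model"))
  p <- as.matrix(p)
  missing <- setdiff(model$features, colnames(p))
  if (length(missing) > 0L)
    stop("matrix lacks model features: ", paste(missing, collapse = ", "))
  drop(p[, model$features, drop = FALSE] %*% model$weights)
}

#' @export
print.phers_model <- function(x, ...) {
  cat("PheRS model:", length(x$features), "features, reference N =",
      x$n_ref, "\n")
  invisible(x)
}
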