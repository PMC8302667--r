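# JSON serialization of fitted score models for exact re-scoring.

#' Write a fitted score model to JSON
#'
#' @param model `phers_model`, `lpc_model`, or `phenorm_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  type <- class(model)[1]
  stopifnot(type %in% c("phers_model", "lpc_model", "phenorm_model"))
  obj <- unclass(model)
  if (type == "lpc_model") {
    obj$loadings <- list(values = as.numeric(model$loadings),
                         nrow = nrow(model$loadings),
                         ncol = ncol(model$loadings))
  }
  obj$.type <- type
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted score model from JSON
#'
#' @param path path written by [write_model()].
#' @return the reconstructed model object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$.type
  obj$.type <- NULL
  num <- function(x) stats::setNames(as.numeric(x), names(x))
  if (type == "phers_model") {
    m <- list(features = obj$features, weights = num(obj$weights),
              n_ref = as.integer(obj$n_ref))
  } else if (type == "lpc_model") {
    U <- matrix(as.numeric(obj$loadings$values),
                nrow = as.integer(obj$loadings$nrow),
                ncol = as.integer(obj$loadings$ncol))
    rownames(U) <- obj$features
    m <- list(features = obj$features, col_means = num(obj$col_means),
              col_sds = num(obj$col_sds),
              dropped_features = as.character(obj$dropped_features %||% character(0)),
              loadings = U, eigenvalues = as.numeric(obj$eigenvalues),
              signs = as.numeric(obj$signs), K = as.integer(obj$K),
              alpha = obj$alpha)
  } else if (type == "phenorm_model") {
    m <- list(alpha = obj$alpha, r = obj$r, B = as.integer(obj$B),
              seed = obj$seed, beta = num(obj$beta),
              features = obj$features, col_means = num(obj$col_means),
              col_sds = num(obj$col_sds), r_squared = obj$r_squared)
  } else stop("unknown model type: ", type)
  structure(m, class = type)
}
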