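# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.  A NULL seed uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column standard deviations with the n-1 denominator.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to compute column SDs")
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu)^2) / (n - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_named <- function(x, what) {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop(what, " must be a fully named vector (names are subject ids)")
  invisible(x)
}
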