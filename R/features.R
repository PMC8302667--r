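#' Build a phecode presence matrix from code-occurrence records
#'
#' A phecode is marked present for a subject when it occurs at least
#' `min_occurrences` times in the subject's longitudinal record.  Occurrences
#' are counted per raw record; the same age may contribute more than once.
#'
#' @param records data.frame with columns `subject_id`, `phecode`,
#'   `age` (age at observation in years, non-negative).  Records with a
#'   negative age or an empty phecode are rejected with a warning.
#' @param min_occurrences minimum number of records required for presence
#'   (default 2).
#' @param roster optional character vector of subject ids to include as rows
#'   even when they have no qualifying records (all-zero rows).
#' @param features optional character vector fixing the column set.
#' @return integer matrix of 0/1 with subjects as rows and phecodes as
#'   columns, class `presence_matrix`.
#' @export
build_presence_matrix <- function(records, min_occurrences = 2L,
                                  roster = NULL, features = NULL) {
  stopifnot(min_occurrences >= 1L)
  records <- validate_records(records)
  if (nrow(records) == 0L && is.null(roster))
    stop("no usable records and no subject roster supplied")
  subjects <- sort(unique(c(as.character(records$subject_id), roster)))
  feats <- features %||% sort(unique(as.character(records$phecode)))
  if (length(feats) == 0L) stop("no features: empty records and no feature list")
  counts <- table(factor(as.character(records$subject_id), levels = subjects),
                  factor(as.character(records$phecode), levels = feats))
  m <- matrix(as.integer(counts >= min_occurrences),
              nrow = length(subjects), ncol = length(feats),
              dimnames = list(subjects, feats))
  structure(m, min_occurrences = as.integer(min_occurrences),
            class = c("presence_matrix", class(m)))
}

validate_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("subject_id", "phecode", "age")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad_age <- !is.na(records$age) & records$age < 0
  if (any(bad_age)) {
    warning(sum(bad_age), " record(s) with negative age rejected")
    records <- records[!bad_age, , drop = FALSE]
  }
  bad_code <- is.na(records$phecode) | as.character(records$phecode) == ""
  if (any(bad_code)) {
    warning(sum(bad_code), " record(s) with empty phecode rejected")
    records <- records[!bad_code, , drop = FALSE]
  }
  records
}

#' Map raw ICD codes to phecodes
#'
#' Replaces the `phecode` column of a record table using a two-column
#' code-to-phecode map; unmapped codes are dropped with a warning.
#'
#' @param records data.frame with columns `subject_id`, `phecode` (raw codes),
#'   `age`.
#' @param map data.frame with columns `code` and `phecode`.
#' @return records with `phecode` translated.
#' @export
apply_code_map <- function(records, map) {
  stopifnot(all(c("code", "phecode") %in% names(map)))
  idx <- match(as.character(records$phecode), as.character(map$code))
  if (anyNA(idx))
    warning(sum(is.na(idx)), " record(s) with unmapped codes dropped")
  out <- records[!is.na(idx), , drop = FALSE]
  out$phecode <- as.character(map$phecode)[idx[!is.na(idx)]]
  out
}

#' Center and scale a presence matrix
#'
#' Columns are centered and scaled by the sample standard deviation
#' (n-1 denominator).  In training mode (`stats = NULL`) the statistics are
#' computed from `p` itself and zero-variance columns are dropped and
#' recorded; in test mode the supplied training statistics are reused so new
#' subjects are expressed on the training scale.
#'
#' @param p presence matrix (or any numeric matrix with feature columns).
#' @param stats optional list with `col_means`, `col_sds`, `features` (and
#'   optionally `dropped_features`) as returned in a previous fit.
#' @return object of class `std_features`: list with `values` (n x J numeric
#'   matrix), `col_means`, `col_sds`, `features`, `subjects`,
#'   `dropped_features`.
#' @export
standardize <- function(p, stats = NULL) {
  p <- as.matrix(p)
  if (is.null(stats)) {
    mu <- colMeans(p)
    sd <- col_sds(p)
    keep <- sd > 0
    if (!any(keep)) stop("all columns have zero variance; nothing to standardize")
    dropped <- colnames(p)[!keep]
    mu <- mu[keep]; sd <- sd[keep]
    feats <- colnames(p)[keep]
  } else {
    feats <- stats$features
    if (!all(feats %in% colnames(p)))
      stop("matrix lacks features required by the supplied stats: ",
           paste(setdiff(feats, colnames(p)), collapse = ", "))
    mu <- stats$col_means; sd <- stats$col_sds
    dropped <- stats$dropped_features %||% character(0)
    if (any(sd <= 0)) stop("supplied col_sds must be positive")
  }
  vals <- sweep(sweep(p[, feats, drop = FALSE], 2L, mu), 2L, sd, "/")
  structure(list(values = vals, col_means = stats::setNames(mu, feats),
                 col_sds = stats::setNames(sd, feats), features = feats,
                 subjects = rownames(p),
                 dropped_features = dropped),
            class = "std_features")
}

#' @export
print.std_features <- function(x, ...) {
  cat("Standardized feature matrix:", nrow(x$values), "subjects x",
      length(x$features), "features (", length(x$dropped_features),
      "zero-variance dropped )\n")
  invisible(x)
}

#' Healthcare utilization: distinct ages at observation per subject
#'
#' @param records data.frame with columns `subject_id`, `phecode`, `age`.
#' @param roster optional subject ids to report with zero counts.
#' @return named non-negative integer vector.
#' @export
utilization <- function(records, roster = NULL) {
  records <- validate_records(records)
  subjects <- sort(unique(c(as.character(records$subject_id), roster)))
  out <- stats::setNames(integer(length(subjects)), subjects)
  if (nrow(records) > 0L) {
    cnt <- tapply(records$age, as.character(records$subject_id),
                  function(a) length(unique(a)))
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}

#' Stratified train/test split on weak labels
#'
#' Cases and controls are split separately at `case_fraction`;
#' unknown-status subjects always go to the test set.
#'
#' @param labels named character vector with values `case`, `control`,
#'   `unknown`.
#' @param case_fraction proportion of each labeled stratum assigned to
#'   training (default 0.5).
#' @param seed integer; the split is deterministic given the seed.
#' @return list with `train` and `test` character vectors of subject ids.
#' @export
split_cohort <- function(labels, case_fraction = 0.5, seed = 1L) {
  stop_if_not_named(labels, "labels")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0, 1)")
  cases <- names(labels)[labels == "case"]
  controls <- names(labels)[labels == "control"]
  if (length(cases) < 2L || length(controls) < 2L)
    stop("need at least 2 cases and 2 controls to split")
  n_case <- floor(case_fraction * length(cases))
  n_ctrl <- floor(case_fraction * length(controls))
  if (n_case < 1L || n_ctrl < 1L)
    stop("case_fraction too small: empty training stratum")
  train <- with_seed(seed, c(sample(cases, n_case), sample(controls, n_ctrl)))
  list(train = sort(train), test = sort(setdiff(names(labels), train)))
}

#' Read code-occurrence records from a delimited file
#'
#' Delimiter inferred from the extension (`.csv` comma, otherwise tab);
#' expects a header `subject_id,phecode,age`.
#'
#' @param file path.
#' @return data.frame of records.
#' @export
read_occurrences <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::read.table(file, header = TRUE, sep = sep,
                    colClasses = c("character", "character", "numeric"))
}

#' Write a standardized feature matrix with a JSON sidecar
#'
#' Emits a wide TSV of the standardized values and `<file>.json` holding the
#' column means/SDs and dropped features needed to re-standardize new data.
#'
#' @param x `std_features` object.
#' @param file output TSV path.
#' @return invisibly, the sidecar path.
#' @export
write_feature_matrix <- function(x, file) {
  stopifnot(inherits(x, "std_features"))
  df <- data.frame(subject_id = x$subjects, x$values, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(file, ".json")
  jsonlite::write_json(
    list(features = x$features, col_means = unname(x$col_means),
         col_sds = unname(x$col_sds), dropped_features = x$dropped_features),
    sidecar, auto_unbox = FALSE, digits = NA)
  invisible(sidecar)
}
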