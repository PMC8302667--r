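# Config-driven end-to-end pipeline: simulate -> build matrix -> fit ->
# score -> evaluate -> gene-based association, with a run manifest.

#' Default pipeline configuration
#'
#' @return named list of pipeline parameters (cohort spec arguments, method
#'   thresholds, genotype settings).  All thresholds default to the package's
#'   documented values (min_occurrences 2, dropout r 0.3, bootstrap B 1e5,
#'   60 bins, Beta(1,25), 0.05/18000).
#' @export
default_config <- function() {
  list(
    cohort = list(n = 2000L, j_relevant = 20L, j_noise = 100L,
                  n_case_codes = 2L, b_relevant = 1.5),
    min_occurrences = 2L,
    train_fraction = 0.5,
    tw_alpha = 0.05,
    phenorm = list(r = 0.3, B = 1e5,
                   alpha_grid = list(from = 0, to = 2, by = 0.01)),
    n_bins = 60L,
    preselect_threshold = 1e-5,
    genotypes = list(n_genes = 10L, variants_per_gene = 20L,
                     causal = list(GENE001 = 0.4)),
    family = "inverse-gaussian",
    significance = list(alpha = 0.05, n_genes = 18000L),
    seed = 1L)
}

read_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(base, config)
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, builds and standardizes the presence matrix, splits
#' train/test, fits PheRS, LPC, and PheNorm, scores the test set, evaluates
#' AUROC/AUPRC/staging correlation/bin prevalence, pre-selects phecodes
#' against the synthetic PRS, simulates genotypes with a causal gene, and
#' runs the combined gene-based tests on the LPC score.  All outputs are
#' written under `out_dir` along with a manifest recording seeds and file
#' checksums.
#'
#' @param config NULL (defaults), a YAML file path, or a named list merged
#'   over [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("qdrisk_run_"),
                         seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  cohort <- simulate_cohort(spec)
  utils::write.table(cohort$records, pth("occurrences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject_id = names(cohort$labels), label = cohort$labels,
               staging = cohort$staging[names(cohort$labels)]),
    pth("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  roster <- names(cohort$labels)
  pm_all <- build_presence_matrix(cohort$records, cfg$min_occurrences,
                                  roster = roster)
  feature_codes <- setdiff(colnames(pm_all), cohort$case_codes)
  pm <- pm_all[, feature_codes, drop = FALSE]
  utl <- utilization(cohort$records, roster = roster)[roster]
  case_counts <- case_code_counts(cohort$records, cohort$case_codes, roster)

  split <- split_cohort(cohort$labels, cfg$train_fraction, seed = cfg$seed)
  train <- split$train
  test <- split$test
  x_train <- standardize(pm[train, , drop = FALSE])
  stats_train <- x_train[c("features", "col_means", "col_sds",
                           "dropped_features")]
  x_test <- standardize(pm[test, , drop = FALSE], stats = stats_train)

  controls_train <- intersect(train, names(cohort$labels)[cohort$labels == "control"])
  phers <- fit_phers(pm[train, , drop = FALSE], controls_train)
  lpc <- fit_lpc(x_train, cohort$labels, alpha = cfg$tw_alpha)
  grid <- seq(cfg$phenorm$alpha_grid$from, cfg$phenorm$alpha_grid$to,
              by = cfg$phenorm$alpha_grid$by)
  phenorm <- fit_phenorm(x_train, case_counts[train], utl[train],
                         r = cfg$phenorm$r, B = cfg$phenorm$B,
                         alpha_grid = grid, seed = cfg$seed)
  write_model(phers, pth("model_phers.json"))
  write_model(lpc, pth("model_lpc.json"))
  write_model(phenorm, pth("model_phenorm.json"))

  scores <- data.frame(
    subject_id = test,
    phers = score_phers(phers, pm[test, , drop = FALSE]),
    lpc = score_lpc(lpc, x_test),
    phenorm = score_phenorm(phenorm, x_test, case_counts[test], utl[test]))
  utils::write.table(scores, pth("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  eval_one <- function(s) {
    sv <- stats::setNames(s, test)
    list(auroc = auroc(sv, cohort$labels),
         auprc = auprc(sv, cohort$labels),
         spearman_staging = spearman_with_staging(sv, cohort$staging)$rho)
  }
  evaluation <- lapply(scores[, c("phers", "lpc", "phenorm")], eval_one)
  lpc_scores <- stats::setNames(scores$lpc, test)
  bins <- bin_prevalence(lpc_scores, cohort$labels,
                         n_bins = min(cfg$n_bins, floor(length(test) / 2)))
  utils::write.table(bins, pth("bin_prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(evaluation, pth("evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  presel <- preselect_phecodes(pm[train, , drop = FALSE], cohort$prs[train],
                               threshold = cfg$preselect_threshold)
  utils::write.table(presel, pth("preselection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  geno <- do.call(simulate_genotypes, c(
    list(subjects = roster),
    cfg$genotypes[setdiff(names(cfg$genotypes), "causal")],
    list(causal = unlist(cfg$genotypes$causal) %||% numeric(0),
         seed = cfg$seed + 1L)))
  write_vcf(geno$dosages, geno$variants, pth("genotypes.vcf"))
  base_scores <- score_lpc(lpc, standardize(pm, stats = stats_train))
  # causal increment is on the standardized-burden scale; express it per SD
  # of the score so the configured effect size is scale-free
  assoc_scores <- stats::setNames(
    base_scores + stats::sd(base_scores) * geno$score_increment[roster],
    roster)
  covs <- data.frame(util = log1p(utl[roster]), row.names = roster)
  null <- fit_null_model(assoc_scores, covs, family = cfg$family)
  keep_var <- qc_filter(geno$variants)
  blocks <- make_genotype_blocks(geno$dosages[, keep_var$variant_id,
                                              drop = FALSE], keep_var)
  assoc <- do.call(rbind, lapply(blocks, function(b) {
    res <- gene_combined_test(null, b)
    data.frame(gene = res$gene, p_all = res$p_all, p_common = res$p_common,
               p_rare = res$p_rare, stringsAsFactors = FALSE)
  }))
  rownames(assoc) <- NULL
  utils::write.table(assoc, pth("assoc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  outputs <- c("occurrences.tsv", "labels.tsv", "scores.tsv",
               "evaluation.json", "bin_prevalence.tsv", "preselection.tsv",
               "genotypes.vcf", "assoc.tsv", "model_phers.json",
               "model_lpc.json", "model_phenorm.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("qdrisk")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    significance_threshold = significance_threshold(
      cfg$significance$alpha, cfg$significance$n_genes),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(out_dir = out_dir, config = cfg, cohort = cohort,
                 models = list(phers = phers, lpc = lpc, phenorm = phenorm),
                 scores = scores, evaluation = evaluation, bins = bins,
                 preselection = presel, assoc = assoc, manifest = manifest))
}

#' Count case-defining phecode occurrences per subject
#'
#' The PheNorm numerator: the number of occurrence records of the
#' case-defining phecodes in each subject's history.
#'
#' @param records occurrence records.
#' @param case_codes character vector of case-defining phecodes.
#' @param roster subject ids to report (zero counts when absent).
#' @return named non-negative integer vector.
#' @export
case_code_counts <- function(records, case_codes, roster) {
  out <- stats::setNames(integer(length(roster)), roster)
  rec <- records[records$phecode %in% case_codes, , drop = FALSE]
  if (nrow(rec) > 0L) {
    cnt <- table(factor(as.character(rec$subject_id), levels = roster))
    out[] <- as.integer(cnt)
  }
  out
}
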