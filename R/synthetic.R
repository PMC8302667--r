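# Synthetic EHR cohort and genotype generator.  Emulates the latent-liability
# structure the scoring methods assume: correlated disease-relevant phecodes
# driven by a standard-normal liability, independent noise phecodes, a
# negative-binomial utilization covariate that confounds code presence,
# ordinal disease staging from liability cutpoints, and Hardy-Weinberg
# genotypes with rare causal variants in designated genes.

#' Specify a synthetic EHR cohort
#'
#' @param n number of subjects.
#' @param j_relevant number of disease-relevant phecodes (presence driven by
#'   the latent liability).
#' @param j_noise number of noise phecodes independent of liability.
#' @param n_case_codes number of case-defining phecodes (strongly
#'   liability-driven; excluded from the PheRS/LPC feature set, counted for
#'   PheNorm).
#' @param b_relevant liability loading of the relevant phecodes (log-odds per
#'   liability SD; default 1.5).
#' @param b_case_codes liability loading of case-defining phecodes
#'   (default 2.5).
#' @param intercept_range log-odds intercept range for relevant phecodes
#'   (uniform; controls prevalence).
#' @param noise_intercept_range intercept range for noise phecodes.
#' @param util_size,util_mu negative-binomial parameters of the utilization
#'   (visit-count) distribution.
#' @param util_coef strength of the utilization confounding on code presence
#'   (log-odds per unit log(1 + u)).
#' @param case_quantile liability quantile above which a subject is a weak
#'   case (default 0.8).
#' @param control_quantile liability quantile below which a subject is a weak
#'   control (default 0.5); subjects in between have unknown status.
#' @param staging_cutpoints within-case liability quantiles splitting cases
#'   into ordinal severity stages (default quartiles -> 4 stages).
#' @param prs_cor correlation between the synthetic PRS proxy and the latent
#'   liability (default 0.5).
#' @param singleton_rate probability that an absent phecode still contributes
#'   a single (sub-threshold) occurrence record (default 0.02).
#' @param seed integer seed.
#' @return validated `cohort_spec` list.
#' @export
cohort_spec <- function(n = 4000L, j_relevant = 20L, j_noise = 200L,
                        n_case_codes = 2L, b_relevant = 1.5,
                        b_case_codes = 2.5,
                        intercept_range = c(-3, -1),
                        noise_intercept_range = c(-5, -1),
                        util_size = 2, util_mu = 8, util_coef = 0.3,
                        case_quantile = 0.8, control_quantile = 0.5,
                        staging_cutpoints = c(0.25, 0.5, 0.75),
                        prs_cor = 0.5, singleton_rate = 0.02, seed = 1L) {
  spec <- list(n = as.integer(n), j_relevant = as.integer(j_relevant),
               j_noise = as.integer(j_noise),
               n_case_codes = as.integer(n_case_codes),
               b_relevant = b_relevant, b_case_codes = b_case_codes,
               intercept_range = intercept_range,
               noise_intercept_range = noise_intercept_range,
               util_size = util_size, util_mu = util_mu,
               util_coef = util_coef, case_quantile = case_quantile,
               control_quantile = control_quantile,
               staging_cutpoints = staging_cutpoints, prs_cor = prs_cor,
               singleton_rate = singleton_rate, seed = as.integer(seed))
  with(spec, {
    stopifnot(n > 0, j_relevant >= 0, j_noise >= 0, n_case_codes >= 0,
              util_size > 0, util_mu > 0,
              case_quantile > control_quantile,
              case_quantile < 1, control_quantile > 0,
              !is.unsorted(staging_cutpoints, strictly = TRUE),
              all(staging_cutpoints > 0), all(staging_cutpoints < 1),
              prs_cor >= -1, prs_cor <= 1,
              singleton_rate >= 0, singleton_rate < 1)
  })
  structure(spec, class = "cohort_spec")
}

#' Simulate an EHR cohort from a specification
#'
#' Draws a latent liability L ~ N(0, 1) per subject; a relevant phecode j is
#' present with probability logistic(a_j + b_j L + c log(1 + u)); noise
#' phecodes are independent of L.  Present phecodes receive 2 + Poisson(1)
#' occurrence records (ages drawn from a per-subject pool of u distinct
#' visit ages), so they always satisfy the two-occurrence presence rule;
#' a small fraction of absent phecodes contribute a single sub-threshold
#' record.  Weak case/control/unknown labels come from liability quantile
#' thresholds and ordinal stages from within-case cutpoints.
#'
#' @param spec `cohort_spec`.
#' @return list with `records` (subject_id, phecode, age), `labels`,
#'   `staging` (integer stage, 0 = control, NA = unknown), `utilization`
#'   (true per-subject visit count), `prs` (synthetic PRS proxy),
#'   `liability`, the feature name sets `relevant_codes`, `noise_codes`,
#'   `case_codes`, and the drawn per-code `intercepts` and `loadings`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    subj <- sprintf("S%05d", seq_len(n))
    L <- stats::rnorm(n)
    u <- stats::rnbinom(n, size = spec$util_size, mu = spec$util_mu) + 1L
    lu <- log1p(u)
    rel_codes <- if (spec$j_relevant > 0)
      sprintf("rel.%03d", seq_len(spec$j_relevant)) else character(0)
    noise_codes <- if (spec$j_noise > 0)
      sprintf("noise.%03d", seq_len(spec$j_noise)) else character(0)
    case_codes <- if (spec$n_case_codes > 0)
      sprintf("dx.%d", seq_len(spec$n_case_codes)) else character(0)
    a_rel <- stats::runif(spec$j_relevant, spec$intercept_range[1],
                          spec$intercept_range[2])
    a_noise <- stats::runif(spec$j_noise, spec$noise_intercept_range[1],
                            spec$noise_intercept_range[2])
    a_case <- rep(-2, spec$n_case_codes)
    codes <- c(case_codes, rel_codes, noise_codes)
    a <- c(a_case, a_rel, a_noise)
    b <- c(rep(spec$b_case_codes, spec$n_case_codes),
           rep(spec$b_relevant, spec$j_relevant),
           rep(0, spec$j_noise))
    eta <- outer(L, b) + matrix(a, n, length(codes), byrow = TRUE) +
      spec$util_coef * lu
    present <- matrix(stats::runif(length(eta)) < stats::plogis(eta),
                      n, length(codes))
    # per-subject visit-age pools
    pools <- lapply(seq_len(n), function(i)
      round(stats::runif(u[i], 30, 80), 1))
    idx <- which(present, arr.ind = TRUE)
    n_occ <- 2L + stats::rpois(nrow(idx), 1)
    rec_subj <- rep(idx[, 1], n_occ)
    rec_code <- rep(idx[, 2], n_occ)
    # sub-threshold singletons among absent cells
    absent <- which(!present)
    single <- absent[stats::runif(length(absent)) < spec$singleton_rate]
    rec_subj <- c(rec_subj, (single - 1L) %% n + 1L)
    rec_code <- c(rec_code, (single - 1L) %/% n + 1L)
    ages <- vapply(rec_subj, function(i) {
      pool <- pools[[i]]
      pool[sample.int(length(pool), 1L)]
    }, numeric(1))
    records <- data.frame(subject_id = subj[rec_subj],
                          phecode = codes[rec_code],
                          age = ages, stringsAsFactors = FALSE)
    records <- records[order(records$subject_id, records$phecode,
                             records$age), , drop = FALSE]
    rownames(records) <- NULL
    q_case <- stats::quantile(L, spec$case_quantile)
    q_ctrl <- stats::quantile(L, spec$control_quantile)
    labels <- ifelse(L >= q_case, "case",
                     ifelse(L <= q_ctrl, "control", "unknown"))
    names(labels) <- subj
    staging <- rep(NA_integer_, n)
    staging[labels == "control"] <- 0L
    is_case <- labels == "case"
    if (any(is_case)) {
      cuts <- stats::quantile(L[is_case], spec$staging_cutpoints)
      staging[is_case] <- 1L + as.integer(
        findInterval(L[is_case], cuts))
    }
    names(staging) <- subj
    prs <- spec$prs_cor * L +
      sqrt(max(0, 1 - spec$prs_cor^2)) * stats::rnorm(n)
    names(prs) <- subj
    list(records = records, labels = labels, staging = staging,
         utilization = stats::setNames(u, subj),
         prs = prs, liability = stats::setNames(L, subj),
         relevant_codes = rel_codes, noise_codes = noise_codes,
         case_codes = case_codes,
         intercepts = stats::setNames(a, codes),
         loadings = stats::setNames(b, codes))
  })
}

#' Simulate per-gene genotypes with optional causal effects on a score
#'
#' Hardy-Weinberg dosages at MAFs drawn from a mixed spectrum (a configurable
#' share of common, rare, and ultra-rare variants).  In causal genes the
#' subject's score increment is effect * standardized Beta(1,25)-weighted
#' burden of the qualifying rare variants.  QC metric fields are drawn
#' passing by default; `qc_fail_fraction` of variants fail one randomly
#' chosen site filter.
#'
#' @param subjects character vector of subject ids.
#' @param n_genes number of genes (default 30).
#' @param variants_per_gene variants per gene (default 20).
#' @param causal named numeric vector: gene name -> effect size on the score
#'   (per SD of weighted burden); empty for a null genome.
#' @param maf_mix proportions of (common, rare, ultra-rare) variants
#'   (default c(0.2, 0.6, 0.2)).
#' @param qualifying_rate probability a rare variant is flagged deleterious
#'   (default 0.5).
#' @param qc_fail_fraction fraction of variants drawn to fail a site filter
#'   (default 0).
#' @param missing_rate per-call missing genotype rate (default 0).
#' @param seed integer seed.
#' @return list with `dosages` (subjects x all variants), `variants`
#'   (metadata incl. QC metrics, gene, qualifying flag, func_weight),
#'   `blocks` (per-gene [genotype_block()]s), and `score_increment`
#'   (named per-subject causal contribution to add to a simulated score).
#' @export
simulate_genotypes <- function(subjects, n_genes = 30L,
                               variants_per_gene = 20L,
                               causal = numeric(0),
                               maf_mix = c(0.2, 0.6, 0.2),
                               qualifying_rate = 0.5,
                               qc_fail_fraction = 0,
                               missing_rate = 0, seed = 1L) {
  n <- length(subjects)
  stopifnot(n > 0, n_genes > 0, variants_per_gene > 0,
            length(maf_mix) == 3L, all(maf_mix >= 0), sum(maf_mix) > 0,
            qc_fail_fraction >= 0, qc_fail_fraction <= 1)
  if (length(causal) > 0) stop_if_not_named(causal, "causal")
  maf_mix <- maf_mix / sum(maf_mix)
  with_seed(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    m_total <- n_genes * variants_per_gene
    cls <- sample(c("common", "rare", "ultra"), m_total, replace = TRUE,
                  prob = maf_mix)
    maf <- numeric(m_total)
    maf[cls == "common"] <- stats::runif(sum(cls == "common"), 0.02, 0.30)
    maf[cls == "rare"] <- stats::runif(sum(cls == "rare"), 0.002, 0.009)
    maf[cls == "ultra"] <- stats::runif(sum(cls == "ultra"),
                                        0.2 / (2 * n), 1.8 / (2 * n))
    dos <- matrix(stats::rbinom(n * m_total, 2L,
                                rep(maf, each = n)), n, m_total)
    if (missing_rate > 0)
      dos[stats::runif(length(dos)) < missing_rate] <- NA
    gene_of <- rep(genes, each = variants_per_gene)
    vid <- paste0(gene_of, ".v", rep(seq_len(variants_per_gene), n_genes))
    dimnames(dos) <- list(subjects, vid)
    qual <- cls == "rare" & stats::runif(m_total) < qualifying_rate
    fw <- ifelse(qual, stats::runif(m_total, 0.5, 1), 1)
    variants <- data.frame(
      variant_id = vid, chrom = "1",
      pos = 1000L * seq_len(m_total),
      ref = "A", alt = "G", type = "SNV",
      QD = stats::runif(m_total, 5, 30),
      MQ = stats::runif(m_total, 50, 60),
      FS = stats::runif(m_total, 0, 10),
      SOR = stats::runif(m_total, 0.5, 2),
      MQRankSum = stats::rnorm(m_total),
      ReadPosRankSum = stats::rnorm(m_total),
      gene = gene_of, qualifying = qual, func_weight = fw,
      stringsAsFactors = FALSE)
    if (qc_fail_fraction > 0) {
      bad <- which(stats::runif(m_total) < qc_fail_fraction)
      which_metric <- sample(c("QD", "MQ", "FS", "SOR"), length(bad),
                             replace = TRUE)
      fail_val <- c(QD = 1, MQ = 30, FS = 80, SOR = 5)
      for (k in seq_along(bad))
        variants[[which_metric[k]]][bad[k]] <- fail_val[[which_metric[k]]]
    }
    increment <- stats::setNames(rep(0, n), subjects)
    for (g in names(causal)) {
      # solidly rare causal variants, away from the 0.01 partition boundary
      vsel <- which(gene_of == g & qual & maf <= 0.007)
      if (length(vsel) == 0L)
        vsel <- which(gene_of == g & cls == "rare" & maf <= 0.007)
      if (length(vsel) == 0L) next
      w <- beta_weight(pmax(maf[vsel], 1e-4))
      bvec <- drop(ifelse(is.na(dos[, vsel, drop = FALSE]), 0,
                          dos[, vsel, drop = FALSE]) %*% w)
      if (stats::sd(bvec) > 0)
        increment <- increment + causal[[g]] * (bvec - mean(bvec)) / stats::sd(bvec)
    }
    blocks <- make_genotype_blocks(dos, variants)
    list(dosages = dos, variants = variants, blocks = blocks,
         score_increment = increment)
  })
}
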