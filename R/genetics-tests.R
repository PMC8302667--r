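# Gene-based association battery: variant QC, frequency partitioning,
# Beta(1,25) weighting, burden / dispersion / ultra-rare / single-variant
# score tests, and aggregated Cauchy combination.

#' Hard-filter variants on GATK-style site quality metrics
#'
#' SNVs are removed when QD < 2, MQ < 40, FS > 60, SOR > 3,
#' MQRankSum < -12.5, or ReadPosRankSum < -8; indels when QD < 2,
#' ReadPosRankSum < -20, FS > 200, or SOR > 10.  Absent (NA) metrics are
#' treated as passing.
#'
#' @param variants data.frame with columns `ref`, `alt` (or a `type` column
#'   with values `SNV`/`indel`) and any of the metric columns `QD`, `MQ`,
#'   `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`.
#' @return the retained rows, with the removed rows in attribute `removed`.
#' @export
qc_filter <- function(variants) {
  variants <- as.data.frame(variants)
  type <- variant_type(variants)
  metric <- function(name) {
    if (name %in% names(variants)) variants[[name]] else rep(NA_real_, nrow(variants))
  }
  lt <- function(x, cut) !is.na(x) & x < cut
  gt <- function(x, cut) !is.na(x) & x > cut
  fail_snv <- lt(metric("QD"), 2) | lt(metric("MQ"), 40) |
    gt(metric("FS"), 60) | gt(metric("SOR"), 3) |
    lt(metric("MQRankSum"), -12.5) | lt(metric("ReadPosRankSum"), -8)
  fail_indel <- lt(metric("QD"), 2) | lt(metric("ReadPosRankSum"), -20) |
    gt(metric("FS"), 200) | gt(metric("SOR"), 10)
  fail <- ifelse(type == "SNV", fail_snv, fail_indel)
  out <- variants[!fail, , drop = FALSE]
  attr(out, "removed") <- variants[fail, , drop = FALSE]
  out
}

variant_type <- function(variants) {
  if ("type" %in% names(variants)) return(as.character(variants$type))
  if (!all(c("ref", "alt") %in% names(variants)))
    stop("variants need a `type` column or `ref`/`alt` columns")
  ifelse(nchar(as.character(variants$ref)) == 1L &
           nchar(as.character(variants$alt)) == 1L, "SNV", "indel")
}

#' Assemble a per-gene genotype block
#'
#' Orients dosages to the minor allele, computes MAF and MAC on the observed
#' calls of the analysis cohort, and mean-imputes missing genotypes (after
#' the frequency computation).
#'
#' @param gene gene label.
#' @param dosages subjects x variants numeric matrix in [0, 2], NA for
#'   missing calls; variant ids as column names.
#' @param variants optional data.frame of per-variant metadata (one row per
#'   column of `dosages`); recognised columns include `qualifying` (logical
#'   deleterious-variant flag) and `func_weight` (functional weight,
#'   default 1).
#' @return `genotype_block` with elements `gene`, `dosages` (imputed,
#'   minor-allele oriented), `maf`, `mac`, `flipped`, `variants`.
#' @export
genotype_block <- function(gene, dosages, variants = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  flipped <- af > 0.5
  dosages[, flipped] <- 2 - dosages[, flipped]
  maf <- pmin(af, 1 - af)
  mac <- round(colSums(dosages, na.rm = TRUE))
  cm <- colMeans(dosages, na.rm = TRUE)
  nas <- which(is.na(dosages))
  if (length(nas) > 0L) dosages[nas] <- cm[col(dosages)[nas]]
  if (is.null(variants))
    variants <- data.frame(variant_id = colnames(dosages),
                           stringsAsFactors = FALSE)
  if (!"qualifying" %in% names(variants))
    variants$qualifying <- FALSE
  if (!"func_weight" %in% names(variants))
    variants$func_weight <- 1
  structure(list(gene = gene, dosages = dosages,
                 maf = stats::setNames(maf, colnames(dosages)),
                 mac = stats::setNames(as.integer(mac), colnames(dosages)),
                 flipped = flipped, variants = variants),
            class = "genotype_block")
}

#' @export
print.genotype_block <- function(x, ...) {
  cat("Genotype block ", x$gene, ": ", nrow(x$dosages), " subjects x ",
      ncol(x$dosages), " variants\n", sep = "")
  invisible(x)
}

#' Partition a gene's variants by frequency
#'
#' Common/low-frequency: MAF > 0.01 (the boundary MAF = 0.01 is assigned
#' here); rare: MAF < 0.01 and MAC >= 5; ultra-rare: 1 <= MAC < 5.
#' Monomorphic variants (MAC = 0) are excluded from all partitions.
#'
#' @param block `genotype_block`.
#' @return list of integer index vectors `common`, `rare`, `ultra_rare`.
#' @export
partition_variants <- function(block) {
  stopifnot(inherits(block, "genotype_block"))
  maf <- block$maf
  mac <- block$mac
  poly <- mac >= 1L
  list(common = which(poly & mac >= 5L & maf >= 0.01),
       rare = which(poly & mac >= 5L & maf < 0.01),
       ultra_rare = which(poly & mac < 5L))
}

#' Beta-density MAF weight
#'
#' The Beta(a, b) probability density evaluated at the MAF; the default
#' Beta(1, 25) upweights rarer variants (w = 25 (1 - maf)^24).
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param a,b beta shape parameters (defaults 1 and 25).
#' @return positive weight(s).
#' @export
beta_weight <- function(maf, a = 1, b = 25) {
  if (any(maf <= 0)) stop("maf must be positive")
  if (any(maf > 0.5)) stop("maf must not exceed 0.5")
  stats::dbeta(maf, a, b)
}

#' Weighted burden score test
#'
#' Collapses the partition into B_i = sum_j w_j g_ij and performs a 1-df GLM
#' score test of B against the null model (two-sided).
#'
#' @param null `null_score_model`.
#' @param G subjects x variants dosage matrix for the tested partition.
#' @param weights per-variant weights (default all 1).
#' @return p-value in (0, 1].
#' @export
burden_test <- function(null, G, weights = NULL) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) stop("empty variant partition")
  w <- weights %||% rep(1, ncol(G))
  b <- drop(G %*% w)
  if (stats::var(b) == 0) {
    warning("burden is constant across subjects; p = 1")
    return(1)
  }
  score_test_1df(null, b)
}

#' Weighted dispersion (variance-component) score test
#'
#' SKAT-type statistic Q = sum_j (w_j g_j' r)^2 with r the null score
#' residuals; the null distribution (a mixture of 1-df chi-squares with the
#' eigenvalues of the projected genotype covariance) is approximated by
#' moment matching.
#'
#' @inheritParams burden_test
#' @return p-value in (0, 1].
#' @export
dispersion_test <- function(null, G, weights = NULL) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) stop("empty variant partition")
  w <- weights %||% rep(1, ncol(G))
  Gw <- sweep(G, 2L, w, "*")
  if (all(apply(Gw, 2L, stats::var) == 0)) {
    warning("no genotype variance in partition; p = 1")
    return(1)
  }
  if (isTRUE(null$degenerate)) {
    warning("null model has (near-)zero residual variance; p = 1")
    return(1)
  }
  parts <- score_test_parts(null, Gw)
  Q <- sum(parts$U^2)
  lambda <- eigen((parts$V + t(parts$V)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (length(lambda) == 0L) {
    warning("degenerate genotype covariance; p = 1")
    return(1)
  }
  p <- liu_pvalue(Q, lambda)
  min(max(p, .Machine$double.xmin), 1)
}

#' Unweighted burden test of aggregated ultra-rare variants
#'
#' Aggregates minor-allele counts across the ultra-rare partition into a
#' per-subject carrier count and applies the 1-df GLM score test.
#'
#' @param null `null_score_model`.
#' @param G dosage matrix of the ultra-rare partition.
#' @return p-value in (0, 1].
#' @export
ultra_rare_burden <- function(null, G) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) stop("empty ultra-rare partition")
  counts <- rowSums(G)
  if (all(counts == 0) || stats::var(counts) == 0) {
    warning("no ultra-rare carriers; p = 1")
    return(1)
  }
  score_test_1df(null, counts)
}

#' Per-variant single-variant score tests
#'
#' @param null `null_score_model`.
#' @param G dosage matrix; monomorphic columns are skipped.
#' @return named numeric vector of p-values (skipped variants absent).
#' @export
single_variant_tests <- function(null, G) {
  G <- as.matrix(G)
  if (ncol(G) == 0L) stop("no variants to test")
  keep <- apply(G, 2L, stats::var) > 0
  vapply(which(keep), function(j) score_test_1df(null, G[, j]),
         numeric(1), USE.NAMES = FALSE) -> p
  stats::setNames(p, colnames(G)[keep])
}

#' Aggregated Cauchy combination of p-values (ACAT)
#'
#' T = sum_i omega_i tan((0.5 - p_i) pi) / sum_i omega_i, combined
#' p = 0.5 - arctan(T) / pi.  Inputs below 1e-15 are clipped to 1e-15.  A
#' component p-value of exactly 1 (a degenerate test) would dominate the
#' Cauchy sum, so in that case the Bonferroni-style bound
#' min(1, k * min(p)) is returned instead, as in reference Cauchy-combination
#' implementations.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param weights optional non-negative weights (equal by default).
#' @return combined p-value.
#' @export
acat_combine <- function(p_values, weights = NULL) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  w <- weights %||% rep(1, length(p))
  stopifnot(length(w) == length(p), all(w >= 0), sum(w) > 0)
  if (any(p == 1)) {
    if (all(p == 1)) return(1)
    return(min(1, length(p) * min(p)))
  }
  p <- pmax(p, 1e-15)
  T_stat <- sum(w * tan((0.5 - p) * pi)) / sum(w)
  0.5 - atan(T_stat) / pi
}

#' Combined gene-based test of a quantitative risk score
#'
#' Runs the full battery on a gene: Beta(1,25)-weighted burden and
#' dispersion tests for the common/low-frequency and the rare partition,
#' functionally weighted burden and dispersion tests for the qualifying rare
#' variants (Beta weight times the supplied functional weight), an
#' unweighted burden test of the aggregated ultra-rare variants, and
#' single-variant score tests (common + rare partitions).  Component
#' p-values are combined with [acat_combine()] into `p_all`, and separately
#' into `p_common` (common components) and `p_rare` (rare + ultra-rare
#' components).  Empty partitions are skipped; their combinations are NA.
#'
#' @param null `null_score_model`.
#' @param block `genotype_block`.
#' @param beta_a,beta_b shape parameters of the MAF weight (defaults 1, 25).
#' @return `gene_test_result`: gene, named `components`, `single_variant`
#'   p-values, `p_all`, `p_common`, `p_rare`.
#' @export
gene_combined_test <- function(null, block, beta_a = 1, beta_b = 25) {
  stopifnot(inherits(block, "genotype_block"))
  part <- partition_variants(block)
  G <- block$dosages
  comp <- c()
  run2 <- function(idx, w, tag) {
    if (length(idx) == 0L) return(invisible(NULL))
    sub <- G[, idx, drop = FALSE]
    comp[[paste0("burden.", tag)]] <<- burden_test(null, sub, w)
    comp[[paste0("dispersion.", tag)]] <<- dispersion_test(null, sub, w)
  }
  bw <- function(idx) beta_weight(pmax(block$maf[idx], 0.5 / (2 * nrow(G))),
                                  beta_a, beta_b)
  run2(part$common, bw(part$common), "common")
  run2(part$rare, bw(part$rare), "rare")
  qual <- part$rare[block$variants$qualifying[part$rare]]
  if (length(qual) > 0L)
    run2(qual, bw(qual) * block$variants$func_weight[qual], "rare.func")
  if (length(part$ultra_rare) > 0L)
    comp[["burden.ultra_rare"]] <-
      ultra_rare_burden(null, G[, part$ultra_rare, drop = FALSE])
  sv_idx <- c(part$common, part$rare)
  sv <- if (length(sv_idx) > 0L)
    single_variant_tests(null, G[, sv_idx, drop = FALSE]) else numeric(0)
  sv_common <- sv[names(sv) %in% colnames(G)[part$common]]
  sv_rare <- sv[names(sv) %in% colnames(G)[part$rare]]
  common_ps <- c(comp[grepl("\\.common$", names(comp))], sv_common)
  rare_ps <- c(comp[grepl("\\.(rare|rare\\.func|ultra_rare)$", names(comp))],
               sv_rare)
  all_ps <- c(unlist(comp), sv)
  combine_or_na <- function(p) {
    p <- unlist(p)
    p <- p[!is.na(p) & p < 1]   # degenerate (p = 1) components carry no test
    if (length(p) == 0L) NA_real_ else acat_combine(p)
  }
  structure(list(gene = block$gene,
                 components = unlist(comp),
                 single_variant = sv,
                 p_all = combine_or_na(all_ps),
                 p_common = combine_or_na(common_ps),
                 p_rare = combine_or_na(rare_ps)),
            class = "gene_test_result")
}

#' @export
print.gene_test_result <- function(x, ...) {
  cat("Gene ", x$gene, ": p.all = ", format(x$p_all, digits = 4),
      ", p.common = ", format(x$p_common, digits = 4),
      ", p.rare = ", format(x$p_rare, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Exome-wide significance threshold
#'
#' Bonferroni threshold alpha / n_genes; the defaults give
#' 0.05 / 18000 = 2.78e-06.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_genes number of genes tested (default 18000).
#' @return numeric threshold.
#' @export
significance_threshold <- function(alpha = 0.05, n_genes = 18000) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}
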