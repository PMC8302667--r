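# VCF input (via vcfR) and a plain-text VCF writer for simulated genotypes.

#' Read genotype dosages and variant metadata from a VCF
#'
#' Extracts GT-based alternate-allele dosages (subjects x variants) and a
#' variant table including the GATK site metrics used by [qc_filter()]
#' (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum) and the `GENE` INFO field
#' when present.  Multi-allelic records are split into one biallelic variant
#' per alternate allele.
#'
#' @param file VCF path (plain or gzipped).
#' @return list with `dosages` (numeric matrix, NA for missing calls) and
#'   `variants` (data.frame with chrom, pos, id, ref, alt, type, metrics,
#'   gene).
#' @export
read_vcf_dosages <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else suppressWarnings(as.numeric(x))
  }
  gene <- vcfR::extract.info(v, element = "GENE")
  if (is.null(gene)) gene <- rep(NA_character_, nrow(fix))
  metrics <- data.frame(QD = info_num("QD"), MQ = info_num("MQ"),
                        FS = info_num("FS"), SOR = info_num("SOR"),
                        MQRankSum = info_num("MQRankSum"),
                        ReadPosRankSum = info_num("ReadPosRankSum"))
  dos_cols <- list(); var_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      d <- gt_to_dosage(gt[i, ], a)
      vid <- if (length(alts) == 1L && !is.na(fix$ID[i]) && fix$ID[i] != ".")
        fix$ID[i] else paste0(fix$CHROM[i], ":", fix$POS[i], "_",
                              fix$REF[i], "/", alts[a])
      dos_cols[[vid]] <- d
      var_rows[[vid]] <- data.frame(
        variant_id = vid, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[a],
        type = if (nchar(fix$REF[i]) == 1L && nchar(alts[a]) == 1L)
          "SNV" else "indel",
        metrics[i, , drop = FALSE], gene = gene[i],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  dosages <- do.call(cbind, dos_cols)
  rownames(dosages) <- colnames(gt)
  variants <- do.call(rbind, var_rows)
  rownames(variants) <- NULL
  list(dosages = dosages, variants = variants)
}

# Count occurrences of allele index `a` in GT strings like "0/1", "1|1", ".".
gt_to_dosage <- function(gt, a) {
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(x) sum(x == as.character(a)), numeric(1))
  out
}

#' Read gene intervals from a BED-like file
#'
#' Tab-delimited, no header: chrom, start (0-based), end, gene name.
#' Returns 1-based inclusive intervals.
#'
#' @param file path.
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_intervals <- function(file) {
  bed <- utils::read.table(file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[, 1:4]
  names(bed) <- c("chrom", "start", "end", "gene")
  bed$start <- bed$start + 1L
  bed
}

#' Assign variants to genes by interval overlap
#'
#' @param variants data.frame with `chrom` and `pos`.
#' @param intervals data.frame with `chrom`, `start`, `end`, `gene`
#'   (1-based inclusive); first matching interval wins.
#' @return `variants` with a `gene` column filled.
#' @export
assign_genes <- function(variants, intervals) {
  gene <- rep(NA_character_, nrow(variants))
  for (k in seq_len(nrow(intervals))) {
    hit <- is.na(gene) & variants$chrom == intervals$chrom[k] &
      variants$pos >= intervals$start[k] & variants$pos <= intervals$end[k]
    gene[hit] <- intervals$gene[k]
  }
  variants$gene <- gene
  variants
}

#' Split a cohort's dosages into per-gene genotype blocks
#'
#' @param dosages subjects x variants matrix.
#' @param variants data.frame with `variant_id` and `gene` columns (plus any
#'   metadata passed through to [genotype_block()]).
#' @return named list of `genotype_block` objects (unassigned variants are
#'   dropped).
#' @export
make_genotype_blocks <- function(dosages, variants) {
  stopifnot(all(c("variant_id", "gene") %in% names(variants)))
  variants <- variants[!is.na(variants$gene), , drop = FALSE]
  genes <- unique(variants$gene)
  out <- lapply(genes, function(g) {
    vv <- variants[variants$gene == g, , drop = FALSE]
    genotype_block(g, dosages[, vv$variant_id, drop = FALSE], vv)
  })
  stats::setNames(out, genes)
}

#' Write dosages and variant metadata as a VCF 4.2 text file
#'
#' Dosages are rounded to hard genotype calls (0/0, 0/1, 1/1; NA becomes
#' ./.); the QC metrics and gene label are emitted as INFO fields.
#'
#' @param dosages subjects x variants matrix in [0, 2] (NA = missing).
#' @param variants data.frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally the QC metric columns and `gene`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_vcf <- function(dosages, variants, file) {
  stopifnot(ncol(dosages) == nrow(variants))
  subj <- rownames(dosages) %||% paste0("S", seq_len(nrow(dosages)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=qdrisk-simulation",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene label\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", subj), collapse = "\t"))
  info_field <- function(i) {
    keys <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
    parts <- character(0)
    for (k in keys)
      if (k %in% names(variants) && !is.na(variants[[k]][i]))
        parts <- c(parts, paste0(k, "=", signif(variants[[k]][i], 6)))
    if ("gene" %in% names(variants) && !is.na(variants$gene[i]))
      parts <- c(parts, paste0("GENE=", variants$gene[i]))
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }
  gt_strings <- c("0/0", "0/1", "1/1")
  lines <- vapply(seq_len(nrow(variants)), function(i) {
    d <- round(dosages[, i])
    gt <- ifelse(is.na(d), "./.", gt_strings[d + 1L])
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS",
            info_field(i), "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), file)
  invisible(file)
}
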