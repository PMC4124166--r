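## Per-gene Pn/Ps counting per derived-allele-frequency stratum.

#' Classify every SNP in a table against its gene's coding sequence
#'
#' Adds a `func_class` column (`synonymous` / `nonsynonymous` / `other`) by
#' applying [classify_coding_snp()] with each gene's CDS.
#'
#' @param snps SNP data.frame as from [read_snp_table()].
#' @param cds_map Named character vector or list, gene id to ungapped CDS.
#' @return `snps` with a `func_class` column.
#' @export
classify_snps <- function(snps, cds_map) {
  cds_map <- unlist(cds_map)
  missing <- setdiff(unique(snps$gene_id), names(cds_map))
  if (length(missing))
    stop("classify_snps: no CDS for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  snps$func_class <- vapply(seq_len(nrow(snps)), function(i)
    classify_coding_snp(cds_map[[snps$gene_id[i]]], snps$cds_pos0[i],
                        snps$ref[i], snps$alt[i], snps$gene_id[i]),
    character(1))
  snps
}

.stratum_label <- function(type, lo, hi = NA) {
  if (type == "threshold") sprintf("ge_%g", lo)
  else sprintf("int_%g_%g", lo, hi)
}

#' Per-gene Pn/Ps counts per frequency stratum
#'
#' Counts non-synonymous (`Pn`) and synonymous (`Ps`) polymorphic sites per
#' gene in each threshold stratum (frequency >= t, closed below) and each
#' half-open interval stratum \[lo, hi) of the configuration. In DAF mode the
#' stratifying frequency is the derived allele frequency and records with an
#' unresolvable ancestral allele are excluded (tallied in attribute
#' `n_daf_undefined`); in MAF mode the minor allele frequency is used and all
#' records are kept. Sites fixed in the sample (DAF = 1) are not polymorphic
#' and are never counted. SNPs of class `other` (stop gain/loss) are
#' excluded.
#'
#' @param snps SNP data.frame with `func_class` (see [classify_snps()]).
#' @param config An [analysis_config()].
#' @param genes Optional character vector of gene ids to report (genes
#'   without SNPs then appear with zero counts); defaults to the genes
#'   present in `snps`.
#' @return data.frame `gene_id`, `stratum`, `type` (`threshold`/`interval`),
#'   `lo`, `hi`, `Pn`, `Ps`.
#' @export
stratify_by_frequency <- function(snps, config = analysis_config(),
                                  genes = NULL) {
  stopifnot("func_class" %in% names(snps))
  if (is.null(genes)) genes <- unique(snps$gene_id)
  use <- snps$func_class %in% c("synonymous", "nonsynonymous")
  if (config$frequency_mode == "DAF") {
    n_undef <- sum(use & snps$daf_undefined)
    use <- use & !snps$daf_undefined
    freq <- snps$daf
  } else {
    n_undef <- 0L
    freq <- snps$maf
  }
  use <- use & !is.na(freq) & freq < 1
  snp_gene <- factor(snps$gene_id, levels = genes)
  nonsyn <- snps$func_class == "nonsynonymous"
  strata <- rbind(
    data.frame(type = "threshold",
               lo = config$daf_thresholds, hi = NA_real_),
    data.frame(type = "interval",
               lo = vapply(config$daf_intervals, `[`, numeric(1), 1),
               hi = vapply(config$daf_intervals, `[`, numeric(1), 2)))
  out <- lapply(seq_len(nrow(strata)), function(i) {
    ty <- strata$type[i]; lo <- strata$lo[i]; hi <- strata$hi[i]
    inset <- use & freq >= lo & (if (ty == "interval") freq < hi else TRUE)
    data.frame(gene_id = genes,
               stratum = .stratum_label(ty, lo, hi),
               type = ty, lo = lo, hi = hi,
               Pn = as.vector(table(snp_gene[inset & nonsyn])),
               Ps = as.vector(table(snp_gene[inset & !nonsyn])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "n_daf_undefined") <- n_undef
  out
}

#' Genes with at least one polymorphic site in a stratum
#'
#' @param gene_polys Output of [stratify_by_frequency()].
#' @param stratum Stratum label (e.g. `"ge_0.01"`).
#' @return Character vector of gene ids with `Pn + Ps >= 1`.
#' @export
polymorphic_gene_subset <- function(gene_polys, stratum) {
  sub <- gene_polys[gene_polys$stratum == stratum, , drop = FALSE]
  sub$gene_id[sub$Pn + sub$Ps >= 1]
}
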