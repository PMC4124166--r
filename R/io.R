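## Readers and writers for the external plain-text formats: codon-alignment
## FASTA plus manifest, per-branch count tables, SNP tables (tab-delimited or
## minimal VCF) and result tables. Every rejected record is logged exactly
## once with a machine-readable reason code (attribute "log" on the return
## value), so filter tallies are auditable.

.COUNT_BRANCH_LABELS <- c("human", "chimp", "hominoid_ancestor", "macaque",
                          "mouse", "ancestral_other")

.empty_log <- function() {
  data.frame(record = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

.log_reject <- function(log, record, reason) {
  rbind(log, data.frame(record = record, reason = reason,
                        stringsAsFactors = FALSE))
}

## Numeric columns are serialised at full precision (%.17g) so that
## write-then-read round-trips reproduce doubles exactly.
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}

#' Read codon alignments from FASTA plus a family manifest
#'
#' The manifest maps FASTA record names to gene and species. Families
#' violating the [gene_family()] invariants are rejected with a warning and a
#' logged reason code; a record whose length is not a multiple of three is a
#' hard error naming the record (frame errors upstream invalidate every
#' downstream count).
#'
#' @param path FASTA file of aligned coding sequences.
#' @param manifest data.frame with columns `record_id`, `gene_id`, `species`,
#'   or the path of a tab-delimited file with those columns.
#' @return Named list of [gene_family()] objects, with attribute `log`
#'   (data.frame `record`, `reason`) listing each rejected family once.
#' @export
read_codon_alignments <- function(path, manifest) {
  if (is.character(manifest)) manifest <- .read_tsv(manifest)
  stopifnot(all(c("record_id", "gene_id", "species") %in% names(manifest)))
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- stats::setNames(toupper(unlist(lapply(seqs, as.character))),
                          names(seqs))
  badlen <- nchar(seqs) %% 3 != 0
  if (any(badlen))
    stop("read_codon_alignments: record not a multiple of 3 in length: ",
         names(seqs)[which(badlen)[1]])
  log <- .empty_log()
  fams <- list()
  for (g in unique(manifest$gene_id)) {
    rows <- manifest[manifest$gene_id == g, , drop = FALSE]
    have <- rows$record_id %in% names(seqs)
    sqs <- stats::setNames(seqs[rows$record_id[have]], rows$species[have])
    if (!all(.SPECIES %in% names(sqs))) {
      warning("read_codon_alignments: family ", g, " skipped: missing ",
              paste(setdiff(.SPECIES, names(sqs)), collapse = ","))
      log <- .log_reject(log, g, "missing_species")
      next
    }
    fam <- tryCatch(gene_family(g, sqs), error = function(e) e)
    if (inherits(fam, "error")) {
      warning("read_codon_alignments: family ", g, " skipped: ",
              conditionMessage(fam))
      log <- .log_reject(log, g, "invalid_family")
      next
    }
    fams[[g]] <- fam
  }
  attr(fams, "log") <- log
  fams
}

#' Read a per-gene, per-branch substitution count table
#'
#' Tab-delimited with columns `gene_id`, `branch`, `Dn`, `Ds` and optionally
#' `N`, `S` (missing values as `.`). Allows direct import of externally
#' computed counts (e.g. codeml free-ratio output reshaped to this layout).
#' Rows with negative counts or unknown branch labels are rejected and
#' logged.
#'
#' @param path File path.
#' @return data.frame `gene_id`, `branch`, `Dn`, `Ds`, `N`, `S`, `dN`, `dS`,
#'   `omega` (rate columns `NA` when sites are absent), with attribute `log`.
#' @export
read_count_table <- function(path) {
  df <- tryCatch(.read_tsv(path), error = function(e) NULL)
  log <- .empty_log()
  if (is.null(df) || nrow(df) == 0) {
    warning("read_count_table: empty count table: ", path)
    out <- data.frame(gene_id = character(0), branch = character(0),
                      Dn = numeric(0), Ds = numeric(0), N = numeric(0),
                      S = numeric(0), dN = numeric(0), dS = numeric(0),
                      omega = numeric(0), stringsAsFactors = FALSE)
    attr(out, "log") <- log
    return(out)
  }
  stopifnot(all(c("gene_id", "branch", "Dn", "Ds") %in% names(df)))
  if (is.null(df$N)) df$N <- NA_real_
  if (is.null(df$S)) df$S <- NA_real_
  bad_branch <- !df$branch %in% .COUNT_BRANCH_LABELS
  bad_count <- (!is.na(df$Dn) & df$Dn < 0) | (!is.na(df$Ds) & df$Ds < 0)
  drop <- bad_branch | bad_count
  if (any(drop)) {
    warning("read_count_table: rejected ", sum(drop), " row(s)")
    rid <- paste0(df$gene_id, ":", df$branch)[drop]
    why <- ifelse(bad_branch[drop], "unknown_branch", "negative_count")
    for (i in seq_along(rid)) log <- .log_reject(log, rid[i], why[i])
  }
  df <- df[!drop, , drop = FALSE]
  df$dN <- ifelse(!is.na(df$N) & df$N > 0, df$Dn / df$N, NA_real_)
  df$dS <- ifelse(!is.na(df$S) & df$S > 0, df$Ds / df$S, NA_real_)
  df$omega <- ifelse(!is.na(df$dS) & df$dS > 0, df$dN / df$dS, NA_real_)
  rownames(df) <- NULL
  attr(df, "log") <- log
  df
}

#' Write a per-branch count table
#'
#' Inverse of [read_count_table()]; numeric columns are written at full
#' precision so read-back reproduces them exactly.
#'
#' @param counts Count data.frame.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  keep <- intersect(c("gene_id", "branch", "Dn", "Ds", "N", "S", "dN", "dS",
                      "omega"), names(counts))
  .write_tsv(counts[keep], path)
  invisible(path)
}

#' Read a coding-SNP table (tab-delimited or minimal VCF)
#'
#' Tab-delimited layout: columns `gene_id`, `cds_pos` (1-based), `ref`,
#' `alt`, `ancestral` (`.` when unknown), `alt_freq`. A file whose first line
#' starts with `##fileformat=VCF` is parsed as a minimal VCF instead: CHROM is
#' taken as the gene identifier, POS as the 1-based CDS position, and the
#' INFO keys `AA=` (ancestral allele) and `AF=` (alternate allele frequency)
#' are used. Rows with a frequency outside \[0,1\] or with `ref == alt` are
#' rejected and logged. Positions are converted to the internal 0-based
#' convention (`cds_pos0`).
#'
#' @param path File path.
#' @return data.frame `gene_id`, `cds_pos0`, `ref`, `alt`, `ancestral`,
#'   `alt_freq`, `daf` (`NA` when the ancestral allele is missing or matches
#'   neither observed allele; such rows carry `daf_undefined = TRUE`), `maf`;
#'   attribute `log` lists rejected rows.
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    parts <- strsplit(body, "\t")
    info_get <- function(info, key) {
      m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
      v <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
                  character(1))
      v
    }
    info <- vapply(parts, `[`, character(1), 8)
    df <- data.frame(
      gene_id = vapply(parts, `[`, character(1), 1),
      cds_pos = as.integer(vapply(parts, `[`, character(1), 2)),
      ref = toupper(vapply(parts, `[`, character(1), 4)),
      alt = toupper(vapply(parts, `[`, character(1), 5)),
      ancestral = toupper(info_get(info, "AA")),
      alt_freq = as.numeric(info_get(info, "AF")),
      stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv(path)
    stopifnot(all(c("gene_id", "cds_pos", "ref", "alt", "alt_freq")
                  %in% names(df)))
    if (is.null(df$ancestral)) df$ancestral <- NA_character_
  }
  log <- .empty_log()
  if (nrow(df) == 0) {
    warning("read_snp_table: empty SNP table: ", path)
  }
  bad_freq <- is.na(df$alt_freq) | df$alt_freq < 0 | df$alt_freq > 1
  bad_allele <- df$ref == df$alt
  drop <- bad_freq | bad_allele
  if (any(drop)) {
    warning("read_snp_table: rejected ", sum(drop), " row(s)")
    rid <- paste0(df$gene_id, ":", df$cds_pos)[drop]
    why <- ifelse(bad_freq[drop], "freq_out_of_range", "ref_equals_alt")
    for (i in seq_along(rid)) log <- .log_reject(log, rid[i], why[i])
  }
  df <- df[!drop, , drop = FALSE]
  out <- data.frame(gene_id = df$gene_id,
                    cds_pos0 = as.integer(df$cds_pos) - 1L,
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    ancestral = toupper(df$ancestral),
                    alt_freq = df$alt_freq, stringsAsFactors = FALSE)
  out$daf <- ifelse(!is.na(out$ancestral) & out$ancestral == out$ref,
                    out$alt_freq,
                    ifelse(!is.na(out$ancestral) & out$ancestral == out$alt,
                           1 - out$alt_freq, NA_real_))
  out$daf_undefined <- is.na(out$daf)
  out$maf <- pmin(out$alt_freq, 1 - out$alt_freq)
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}

#' Write a SNP table in the tab-delimited layout read by [read_snp_table()]
#'
#' @param snps SNP data.frame (internal 0-based `cds_pos0` layout).
#' @param path Output path.
#' @export
write_snp_table <- function(snps, path) {
  df <- data.frame(gene_id = snps$gene_id, cds_pos = snps$cds_pos0 + 1L,
                   ref = snps$ref, alt = snps$alt,
                   ancestral = snps$ancestral, alt_freq = snps$alt_freq,
                   stringsAsFactors = FALSE)
  extra <- setdiff(names(snps), c(names(df), "cds_pos0", "daf",
                                  "daf_undefined", "maf"))
  for (cn in extra) df[[cn]] <- snps[[cn]]
  .write_tsv(df, path)
  invisible(path)
}

#' Write a generic result table (tab-delimited, full numeric precision)
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_result_table <- function(df, path) {
  .write_tsv(df, path)
  invisible(path)
}
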