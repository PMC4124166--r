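## Human-branch acceleration screen: one-sided Fisher's exact contrasts of
## the human and chimp branches against the hominoid-ancestor branch, NJ
## topology confirmation and dN/dS-matched control sampling.

#' One-sided Fisher's exact test for non-synonymous excess in a branch
#'
#' Tests for an excess of non-synonymous over synonymous substitutions in the
#' focal branch relative to the reference branch, on the 2x2 table with rows
#' (focal Dn, focal Ds) and (reference Dn, reference Ds). Fractional
#' parsimony counts are rounded half-to-even to integers before the exact
#' test. An all-zero table carries no signal and returns p = 1.
#'
#' @param focal_dn,focal_ds Focal-branch counts.
#' @param ref_dn,ref_ds Reference-branch counts.
#' @return One-sided (greater) p-value.
#' @export
fisher_branch_excess <- function(focal_dn, focal_ds, ref_dn, ref_ds) {
  m <- round(matrix(c(focal_dn, focal_ds, ref_dn, ref_ds), nrow = 2,
                    byrow = TRUE))
  if (sum(m) == 0) return(1)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Classify genes as human-branch accelerated
#'
#' A gene is accelerated when the human branch shows a significant
#' non-synonymous excess over the hominoid-ancestor branch
#' (`p_human < level`), the chimp branch does not (`p_chimp >= level`, the
#' chimp veto), and the gene tree recovers the expected species topology.
#' When alignments are supplied the topology is confirmed with
#' [nj_topology_check()]; for imported count tables without alignments
#' `topology_ok` is taken as `TRUE` and reported as such.
#'
#' @param counts Per-branch count table with `human`, `chimp` and
#'   `hominoid_ancestor` rows per gene.
#' @param config An [analysis_config()] (supplies the significance level).
#' @param families Optional named list of [gene_family()] objects for the
#'   topology check.
#' @return Object of class `"accel_screen"`: list with `table` (columns
#'   `gene_id`, `p_human`, `p_chimp`, `topology_ok`, `accelerated`) and
#'   `level`. Genes missing a required branch are skipped and listed in
#'   attribute `log` of the table.
#' @export
accel_screen <- function(counts, config = analysis_config(),
                         families = NULL) {
  genes <- unique(counts$gene_id)
  log <- .empty_log()
  rows <- list()
  for (g in genes) {
    sub <- counts[counts$gene_id == g, , drop = FALSE]
    pick <- function(b) sub[sub$branch == b, c("Dn", "Ds"), drop = FALSE]
    h <- pick("human"); ch <- pick("chimp"); anc <- pick("hominoid_ancestor")
    if (nrow(h) != 1 || nrow(ch) != 1 || nrow(anc) != 1) {
      warning("accel_screen: gene ", g, " skipped: missing branch")
      log <- .log_reject(log, g, "missing_branch")
      next
    }
    p_h <- fisher_branch_excess(h$Dn, h$Ds, anc$Dn, anc$Ds)
    p_c <- fisher_branch_excess(ch$Dn, ch$Ds, anc$Dn, anc$Ds)
    topo <- if (!is.null(families) && !is.null(families[[g]]))
      nj_topology_check(families[[g]]) else TRUE
    rows[[g]] <- data.frame(
      gene_id = g, p_human = p_h, p_chimp = p_c,
      topology_ok = as.logical(topo),
      accelerated = p_h < config$significance_level &
        p_c >= config$significance_level & as.logical(topo),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(0), p_human = numeric(0),
                      p_chimp = numeric(0), topology_ok = logical(0),
                      accelerated = logical(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "log") <- log
  structure(list(table = tab, level = config$significance_level),
            class = "accel_screen")
}

#' @export
print.accel_screen <- function(x, ...) {
  cat("Human-branch acceleration screen (level ", x$level, ")\n", sep = "")
  cat("  genes tested :", nrow(x$table), "\n")
  cat("  accelerated  :", sum(x$table$accelerated), "\n")
  invisible(x)
}

#' @export
as.data.frame.accel_screen <- function(x, ...) x$table

#' Neighbor-joining confirmation of the expected species topology
#'
#' Builds an NJ tree from Jukes-Cantor-corrected pairwise nucleotide
#' distances over the gap-free alignment columns and reports whether human
#' and chimp are sister taxa. Saturated pairwise distances (proportion of
#' differing sites >= 0.75) fall back to the uncorrected distance with a
#' warning. Four identical sequences give no signal against the expected
#' topology and return `TRUE` with attribute `zero_signal = TRUE`.
#'
#' @param family A [gene_family()].
#' @return Logical flag.
#' @export
nj_topology_check <- function(family) {
  cm <- .codon_matrix(family$sequences)
  cols <- .gapfree_columns(cm)
  if (length(cols) < 1)
    stop("nj_topology_check: ", family$gene_id, ": no gap-free column")
  seqs <- apply(cm[, cols, drop = FALSE], 1, paste, collapse = "")
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  n <- length(chars[[1]])
  d <- matrix(0, 4, 4, dimnames = list(.SPECIES, .SPECIES))
  for (i in 1:3) for (j in (i + 1):4) {
    p <- sum(chars[[i]] != chars[[j]]) / n
    dij <- if (p >= 0.75) {
      warning("nj_topology_check: ", family$gene_id,
              ": saturated distance, using uncorrected p-distance")
      p
    } else -3 / 4 * log(1 - 4 * p / 3)
    d[i, j] <- d[j, i] <- dij
  }
  if (all(d == 0)) {
    out <- TRUE
    attr(out, "zero_signal") <- TRUE
    return(out)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr <- ape::root(tr, outgroup = "mouse", resolve.root = TRUE)
  ape::is.monophyletic(tr, c("human", "chimp"))
}

#' Sample a control gene set matched on human-branch dN/dS
#'
#' Bins human-branch dN/dS into fixed-width bins (width 0.1, last bin
#' open-ended above 1) and samples, without replacement from the
#' non-accelerated pool, the same per-bin counts as the accelerated set. Bins
#' with too few pool members borrow from the nearest neighbouring bins (with
#' a warning). The match is verified with a two-sided rank-sum test on dN/dS
#' (requiring p > 0.05) and resampled up to `max_retry` times otherwise.
#'
#' @param pool data.frame `gene_id`, `omega` for all candidate genes
#'   (accelerated genes are removed internally if present).
#' @param accelerated data.frame `gene_id`, `omega` of the accelerated set.
#' @param seed Integer seed for reproducible sampling.
#' @param max_retry Resampling attempts when the rank-sum check fails.
#' @return Character vector of control gene ids (length = accelerated set
#'   size), with attributes `wilcox_p` and `borrowed` (count of borrowed
#'   draws).
#' @export
sample_matched_controls <- function(pool, accelerated, seed = 1L,
                                    max_retry = 20L) {
  pool <- pool[!pool$gene_id %in% accelerated$gene_id, , drop = FALSE]
  pool <- pool[!is.na(pool$omega), , drop = FALSE]
  if (nrow(pool) < nrow(accelerated))
    stop("sample_matched_controls: pool smaller than the accelerated set")
  binof <- function(w) pmin(floor(w / 0.1), 10)  # [1.0, Inf) open-ended
  set.seed(seed)
  target <- table(binof(accelerated$omega))
  pool$bin <- binof(pool$omega)
  best <- NULL
  for (try in seq_len(max_retry)) {
    chosen <- character(0)
    borrowed <- 0L
    avail <- pool
    for (b in names(target)) {
      need <- target[[b]]
      inbin <- avail[avail$bin == as.numeric(b), , drop = FALSE]
      take <- min(need, nrow(inbin))
      if (take > 0) {
        ids <- inbin$gene_id[sample.int(nrow(inbin), take)]
        chosen <- c(chosen, ids)
        avail <- avail[!avail$gene_id %in% ids, , drop = FALSE]
      }
      short <- need - take
      if (short > 0) {
        warning("sample_matched_controls: borrowing ", short,
                " gene(s) for dN/dS bin ", b)
        ord <- order(abs(avail$bin - as.numeric(b)))
        ids <- avail$gene_id[ord[seq_len(short)]]
        chosen <- c(chosen, ids)
        avail <- avail[!avail$gene_id %in% ids, , drop = FALSE]
        borrowed <- borrowed + short
      }
    }
    wp <- stats::wilcox.test(pool$omega[pool$gene_id %in% chosen],
                             accelerated$omega, exact = FALSE)$p.value
    if (is.null(best) || wp > attr(best, "wilcox_p")) {
      best <- chosen
      attr(best, "wilcox_p") <- wp
      attr(best, "borrowed") <- borrowed
    }
    if (wp > 0.05) break
  }
  best
}
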