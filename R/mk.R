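## McDonald-Kreitman statistics: FI, NI, DoS, alpha, the Williams-corrected
## G-test of independence, pooled gene-set values and the
## heterogeneity-robust pooled neutrality index NI_TG.

.mk_zero_reason <- function(Dn, Ds, Pn, Ps, need) {
  vapply(seq_along(Dn), function(i) {
    zeros <- c("Dn_zero", "Ds_zero", "Pn_zero", "Ps_zero")[
      c(Dn[i], Ds[i], Pn[i], Ps[i]) == 0]
    zeros <- intersect(zeros, need)
    paste(zeros, collapse = ";")
  }, character(1))
}

#' Fixation index FI = (Dn/Ds) / (Pn/Ps)
#'
#' Ratio of the fixed non-synonymous/synonymous ratio to the polymorphic one;
#' 1 under strict neutrality, above 1 with an excess of fixed amino-acid
#' changes. Undefined (`NA`) when any of the four counts is zero — such genes
#' are excluded from per-gene FI comparisons rather than assigned 0 or
#' infinity.
#'
#' @param Dn,Ds Non-synonymous / synonymous substitution counts (human
#'   branch); fractional values from parsimony averaging allowed.
#' @param Pn,Ps Non-synonymous / synonymous polymorphic site counts.
#' @return Numeric vector (NA where undefined).
#' @examples
#' fixation_index(13, 1, 5, 4)  # 10.4
#' fixation_index(7, 1, 2, 4)   # 14
#' @export
fixation_index <- function(Dn, Ds, Pn, Ps) {
  ifelse(Dn > 0 & Ds > 0 & Pn > 0 & Ps > 0,
         (Dn / Ds) / (Pn / Ps), NA_real_)
}

#' Neutrality index NI = 1 / FI
#'
#' @inheritParams fixation_index
#' @return Numeric vector (NA where FI is undefined).
#' @export
neutrality_index <- function(Dn, Ds, Pn, Ps) {
  1 / fixation_index(Dn, Ds, Pn, Ps)
}

#' Direction of selection DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps)
#'
#' Bounded in \[-1, 1\]; positive under adaptive fixation, negative under
#' segregating slightly deleterious variation. Defined whenever both the
#' divergence and the polymorphism totals are positive.
#'
#' @inheritParams fixation_index
#' @return Numeric vector (NA where undefined).
#' @export
direction_of_selection <- function(Dn, Ds, Pn, Ps) {
  ifelse(Dn + Ds > 0 & Pn + Ps > 0,
         Dn / (Dn + Ds) - Pn / (Pn + Ps), NA_real_)
}

#' Proportion of adaptive substitutions alpha = 1 - (Ds * Pn) / (Dn * Ps)
#'
#' Equals `1 - 1/FI` whenever FI is defined; defined whenever `Dn > 0` and
#' `Ps > 0` (with `Pn = 0` it is exactly 1).
#'
#' @inheritParams fixation_index
#' @return Numeric vector (NA where undefined).
#' @export
alpha_adaptive <- function(Dn, Ds, Pn, Ps) {
  ifelse(Dn > 0 & Ps > 0, 1 - (Ds * Pn) / (Dn * Ps), NA_real_)
}

#' Williams-corrected G-test of independence on the MK 2x2 table
#'
#' G-test on the table with rows (divergence, polymorphism) and columns
#' (non-synonymous, synonymous): `G = 2 * sum(O * ln(O/E))` with zero cells
#' contributing 0, divided by the Williams continuity correction
#' `q = 1 + (N/r1 + N/r2 - 1) * (N/c1 + N/c2 - 1) / (6N)`; the p-value is the
#' upper chi-squared tail with one degree of freedom. Undefined (all `NA`)
#' when any row or column marginal is zero.
#'
#' @inheritParams fixation_index
#' @return data.frame with columns `G`, `q`, `G_adj`, `p`, `reason`.
#' @examples
#' mk_gtest_williams(9, 2, 0, 4)$p    # 0.0035
#' mk_gtest_williams(13, 1, 5, 4)$p   # 0.044
#' @export
mk_gtest_williams <- function(Dn, Ds, Pn, Ps) {
  n <- max(length(Dn), length(Ds), length(Pn), length(Ps))
  Dn <- rep_len(Dn, n); Ds <- rep_len(Ds, n)
  Pn <- rep_len(Pn, n); Ps <- rep_len(Ps, n)
  out <- data.frame(G = NA_real_, q = NA_real_, G_adj = NA_real_,
                    p = NA_real_, reason = "", stringsAsFactors = FALSE)
  out <- out[rep(1, n), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    O <- matrix(c(Dn[i], Ds[i], Pn[i], Ps[i]), nrow = 2, byrow = TRUE)
    r <- rowSums(O); cl <- colSums(O); N <- sum(O)
    if (any(r == 0) || any(cl == 0)) {
      out$reason[i] <- "zero_marginal"
      next
    }
    E <- outer(r, cl) / N
    G <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
    q <- 1 + (N / r[1] + N / r[2] - 1) * (N / cl[1] + N / cl[2] - 1) / (6 * N)
    out$G[i] <- G
    out$q[i] <- q
    out$G_adj[i] <- G / q
    out$p[i] <- stats::pchisq(G / q, df = 1, lower.tail = FALSE)
  }
  out
}

#' McDonald-Kreitman test of one or more genes
#'
#' The core fitting function: evaluates the full statistic family (FI, NI,
#' DoS, alpha and the Williams-corrected G-test) on one or more MK 2x2
#' tables. Accepts four count vectors, or a data.frame with columns `Dn`,
#' `Ds`, `Pn`, `Ps` (and optionally `gene_id`).
#'
#' @param Dn Either the non-synonymous substitution counts or a data.frame
#'   holding all four count columns.
#' @param Ds,Pn,Ps Count vectors (ignored when `Dn` is a data.frame).
#' @param gene_id Optional gene identifiers.
#' @return Object of class `"mk_test"`: a list with element `table`, a
#'   data.frame with the counts and columns `FI`, `NI`, `DoS`, `alpha`,
#'   `G_adj`, `p`, `undefined_reason`.
#' @examples
#' mk_test(13, 1, 5, 4)
#' @export
mk_test <- function(Dn, Ds = NULL, Pn = NULL, Ps = NULL, gene_id = NULL) {
  if (is.data.frame(Dn)) {
    df <- Dn
    stopifnot(all(c("Dn", "Ds", "Pn", "Ps") %in% names(df)))
    gene_id <- if (!is.null(df$gene_id)) df$gene_id
    Ds <- df$Ds; Pn <- df$Pn; Ps <- df$Ps; Dn <- df$Dn
  }
  stopifnot(all(Dn >= 0), all(Ds >= 0), all(Pn >= 0), all(Ps >= 0))
  n <- length(Dn)
  if (is.null(gene_id)) gene_id <- if (n == 1) "pooled" else
    sprintf("gene%0*d", nchar(n), seq_len(n))
  g <- mk_gtest_williams(Dn, Ds, Pn, Ps)
  tab <- data.frame(gene_id = gene_id, Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps,
                    FI = fixation_index(Dn, Ds, Pn, Ps),
                    NI = neutrality_index(Dn, Ds, Pn, Ps),
                    DoS = direction_of_selection(Dn, Ds, Pn, Ps),
                    alpha = alpha_adaptive(Dn, Ds, Pn, Ps),
                    G_adj = g$G_adj, p = g$p,
                    stringsAsFactors = FALSE)
  tab$undefined_reason <- ifelse(
    is.na(tab$FI),
    .mk_zero_reason(Dn, Ds, Pn, Ps,
                    c("Dn_zero", "Ds_zero", "Pn_zero", "Ps_zero")),
    "")
  tab$undefined_reason <- ifelse(
    g$reason != "" & tab$undefined_reason == "",
    g$reason, tab$undefined_reason)
  structure(list(table = tab), class = "mk_test")
}

#' @export
print.mk_test <- function(x, digits = 4, ...) {
  tab <- x$table
  cat("McDonald-Kreitman test (", nrow(tab), " table",
      if (nrow(tab) != 1) "s", ")\n", sep = "")
  show <- tab[, c("gene_id", "Dn", "Ds", "Pn", "Ps", "FI", "DoS", "alpha",
                  "G_adj", "p")]
  print(format(show, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mk_test <- function(object, level = 0.05, ...) {
  tab <- object$table
  cat("Genes/tables      :", nrow(tab), "\n")
  cat("FI defined        :", sum(!is.na(tab$FI)), "\n")
  if (any(!is.na(tab$FI)))
    cat("Median FI         :", stats::median(tab$FI, na.rm = TRUE), "\n")
  cat("Significant (p <", level, "):",
      sum(!is.na(tab$p) & tab$p < level), "\n")
  invisible(object)
}

#' @export
as.data.frame.mk_test <- function(x, ...) x$table

#' Pool MK counts over genes
#'
#' Component-wise sum of the per-gene Dn, Ds, Pn, Ps, equivalent to analysing
#' a concatenated alignment of the set.
#'
#' @param counts data.frame with columns `Dn`, `Ds`, `Pn`, `Ps`.
#' @return Named numeric vector `c(Dn, Ds, Pn, Ps)`.
#' @export
pool_counts <- function(counts) {
  if (nrow(counts) == 0) return(c(Dn = 0, Ds = 0, Pn = 0, Ps = 0))
  c(Dn = sum(counts$Dn), Ds = sum(counts$Ds),
    Pn = sum(counts$Pn), Ps = sum(counts$Ps))
}

#' Heterogeneity-robust pooled neutrality index NI_TG
#'
#' `NI_TG = sum_i(Ds_i * Pn_i / (Ps_i + Ds_i)) / sum_i(Dn_i * Ps_i /
#' (Ps_i + Ds_i))`, a pooled neutrality-index estimator that weights genes so
#' that gene-to-gene count heterogeneity does not bias the ratio. Genes with
#' `Ps + Ds = 0` carry no information and are skipped.
#'
#' @param counts data.frame with columns `Dn`, `Ds`, `Pn`, `Ps`.
#' @return Scalar NI_TG (NA when the denominator sum is zero).
#' @export
neutrality_index_tg <- function(counts) {
  use <- counts$Ps + counts$Ds > 0
  if (!any(use)) return(NA_real_)
  num <- sum(counts$Ds[use] * counts$Pn[use] /
               (counts$Ps[use] + counts$Ds[use]))
  den <- sum(counts$Dn[use] * counts$Ps[use] /
               (counts$Ps[use] + counts$Ds[use]))
  if (den == 0) return(NA_real_)
  num / den
}

#' Benjamini-Hochberg adjustment of externally supplied p-values
#'
#' Convenience wrapper around [stats::p.adjust()] for flagging imported
#' branch-site test p-values after false-discovery-rate correction. Never
#' applied implicitly by any other operation in this package.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
mk_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Assemble per-gene MK tables from counts and stratified polymorphism
#'
#' Joins human-branch Dn/Ds with per-gene Pn/Ps of one frequency stratum.
#'
#' @param counts Per-branch count table ([count_branch_substitutions_all()]
#'   or [read_count_table()]).
#' @param gene_polys Output of [stratify_by_frequency()].
#' @param stratum Stratum label, e.g. `"ge_0.01"`.
#' @param branch Divergence branch (default `"human"`).
#' @return data.frame `gene_id`, `Dn`, `Ds`, `Pn`, `Ps` for genes present in
#'   both inputs.
#' @export
mk_table <- function(counts, gene_polys, stratum = "ge_0.01",
                     branch = "human") {
  div <- counts[counts$branch == branch, c("gene_id", "Dn", "Ds")]
  pol <- gene_polys[gene_polys$stratum == stratum,
                    c("gene_id", "Pn", "Ps")]
  merge(div, pol, by = "gene_id")
}

#' Pooled MK statistics per gene set and frequency stratum
#'
#' For each gene set and each stratum: restricts the set to genes with at
#' least one polymorphic site in that stratum, pools Dn, Ds, Pn, Ps over the
#' members, and evaluates the pooled statistic family plus NI_TG.
#'
#' @param counts Per-branch count table.
#' @param gene_polys Output of [stratify_by_frequency()].
#' @param sets Named list of gene-id vectors (e.g. `list(all = ...,
#'   accelerated = ...)`).
#' @param strata Stratum labels (default: every stratum in `gene_polys`).
#' @param branch Divergence branch (default `"human"`).
#' @return data.frame, one row per set x stratum, with `set_label`,
#'   `stratum`, `n_genes`, pooled counts, `FI`, `NI`, `DoS`, `alpha`,
#'   `NI_TG`, `G_adj`, `p`.
#' @export
stratum_summary <- function(counts, gene_polys, sets,
                            strata = unique(gene_polys$stratum),
                            branch = "human") {
  rows <- list()
  for (lab in names(sets)) {
    for (st in strata) {
      tab <- mk_table(counts, gene_polys, st, branch)
      tab <- tab[tab$gene_id %in% sets[[lab]], , drop = FALSE]
      tab <- tab[tab$Pn + tab$Ps >= 1, , drop = FALSE]
      pooled <- pool_counts(tab)
      mk <- mk_test(pooled[["Dn"]], pooled[["Ds"]], pooled[["Pn"]],
                    pooled[["Ps"]])$table
      rows[[paste(lab, st)]] <- data.frame(
        set_label = lab, stratum = st, n_genes = nrow(tab),
        Dn = pooled[["Dn"]], Ds = pooled[["Ds"]],
        Pn = pooled[["Pn"]], Ps = pooled[["Ps"]],
        FI = mk$FI, NI = mk$NI, DoS = mk$DoS, alpha = mk$alpha,
        NI_TG = if (nrow(tab)) neutrality_index_tg(tab) else NA_real_,
        G_adj = mk$G_adj, p = mk$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
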