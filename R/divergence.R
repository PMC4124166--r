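## Branch-specific substitution counting on the fixed ((human,chimp),macaque,
## mouse) topology: nucleotide-level small parsimony with uniform averaging
## over equally parsimonious ancestral assignments, NG86 pathway decomposition
## of each branch change, and NG86 site normalisation from the human sequence.

.BRANCHES <- c("human", "chimp", "hominoid_ancestor", "macaque", "mouse")

## Minimal ancestral (hominoid ancestor, root) nucleotide pairs for one
## alignment position. obs = c(h, c, m, mo). Returns list(cost, pairs) where
## pairs is a 2-column matrix of minimising (anc, root) states.
.position_assignments <- function(obs) {
  best <- Inf
  pairs <- matrix(character(0), ncol = 2)
  for (a in .NT) for (r in .NT) {
    cost <- (obs[1] != a) + (obs[2] != a) + (a != r) +
      (obs[3] != r) + (obs[4] != r)
    if (cost < best) {
      best <- cost
      pairs <- matrix(c(a, r), ncol = 2)
    } else if (cost == best) {
      pairs <- rbind(pairs, c(a, r))
    }
  }
  list(cost = best, pairs = pairs)
}

## All minimal (hominoid-ancestor codon, root codon) assignments for one
## gap-free codon column cod = c(h, c, m, mo), obtained by composing the
## per-position minimal assignments (positions contribute independently to the
## change count). Assignments containing stop codons are dropped when a
## stop-free minimal assignment exists.
.column_assignments <- function(cod) {
  per_pos <- lapply(1:3, function(p)
    .position_assignments(substr(cod, p, p)))
  cost <- sum(vapply(per_pos, `[[`, numeric(1), "cost"))
  idx <- expand.grid(lapply(per_pos, function(pp) seq_len(nrow(pp$pairs))))
  anc <- apply(idx, 1, function(i)
    paste0(per_pos[[1]]$pairs[i[1], 1], per_pos[[2]]$pairs[i[2], 1],
           per_pos[[3]]$pairs[i[3], 1]))
  root <- apply(idx, 1, function(i)
    paste0(per_pos[[1]]$pairs[i[1], 2], per_pos[[2]]$pairs[i[2], 2],
           per_pos[[3]]$pairs[i[3], 2]))
  keep <- !(.is_stop(anc) | .is_stop(root))
  if (any(keep)) {
    anc <- anc[keep]
    root <- root[keep]
  }
  list(cost = cost, anc = anc, root = root)
}

## Per-branch (Dn, Ds) for one codon column, averaged uniformly over minimal
## ancestral assignments. Memoised on the column pattern. Returns
## list(mat = 5 x 2 matrix, cost).
.column_branch_counts <- function(cod) {
  key <- paste(cod, collapse = "|")
  if (!is.null(.mk_cache$cols) && exists(key, .mk_cache$cols))
    return(get(key, .mk_cache$cols))
  asg <- .column_assignments(cod)
  k <- length(asg$anc)
  mat <- matrix(0, nrow = 5, ncol = 2,
                dimnames = list(.BRANCHES, c("Dn", "Ds")))
  for (i in seq_len(k)) {
    a <- asg$anc[i]; r <- asg$root[i]
    edges <- rbind(c(a, cod[1]),   # human
                   c(a, cod[2]),   # chimp
                   c(r, a),        # hominoid ancestor
                   c(r, cod[3]),   # macaque
                   c(r, cod[4]))   # mouse side
    for (b in 1:5) {
      if (edges[b, 1] != edges[b, 2]) {
        pc <- ng86_path_counts(edges[b, 1], edges[b, 2])
        mat[b, 1] <- mat[b, 1] + pc[["nonsyn"]]
        mat[b, 2] <- mat[b, 2] + pc[["syn"]]
      }
    }
  }
  out <- list(mat = mat / k, cost = asg$cost)
  if (is.null(.mk_cache$cols))
    .mk_cache$cols <- new.env(hash = TRUE, parent = emptyenv())
  assign(key, out, .mk_cache$cols)
  out
}

#' Parsimony ancestral codons on the fixed four-species topology
#'
#' For each gap-free codon column, enumerates every ancestral codon
#' assignment at the hominoid-ancestor node and the deeper (root) node that
#' attains the minimal nucleotide change count (Fitch small parsimony applied
#' per nucleotide position and composed per codon). Assignments containing a
#' stop codon are dropped whenever a stop-free minimal assignment exists.
#'
#' @param family A [gene_family()].
#' @return A list with one element per gap-free codon column:
#'   `list(column, cost, hominoid_ancestor, root)` where the last two are
#'   character vectors of equally parsimonious codons (parallel vectors).
#' @export
fitch_ancestral_codons <- function(family) {
  cm <- .codon_matrix(family$sequences)
  cols <- .gapfree_columns(cm)
  lapply(cols, function(j) {
    asg <- .column_assignments(cm[, j])
    list(column = j, cost = asg$cost,
         hominoid_ancestor = asg$anc, root = asg$root)
  })
}

#' Count branch-specific substitutions in one gene family
#'
#' Assigns nucleotide changes in every gap-free codon column to the five
#' branches of the unrooted ((human,chimp),macaque,mouse) tree under minimal
#' parsimony, averaging uniformly over equally parsimonious ancestral
#' assignments (so Dn and Ds may be fractional), and decomposes each change
#' into synonymous and non-synonymous parts by NG86 pathway averaging. Site
#' totals N and S are NG86 fractional site counts computed from the human
#' sequence over the same gap-free columns, so `N + S` equals three times the
#' number of columns used.
#'
#' @param family A [gene_family()].
#' @return A data.frame with one row per branch (`human`, `chimp`,
#'   `hominoid_ancestor`, `macaque`, `mouse`) and columns `gene_id`, `branch`,
#'   `Dn`, `Ds`, `N`, `S`, `dN`, `dS`, `omega` (`NA` when `dS` is 0).
#'   Attributes: `total_changes` (minimal parsimony change total),
#'   `n_columns_used`, `misalign_frac` (fraction of human-branch change weight
#'   within 5 codon columns of a gapped column; `NA` when the human branch has
#'   no changes).
#' @export
count_branch_substitutions <- function(family) {
  cm <- .codon_matrix(family$sequences)
  cols <- .gapfree_columns(cm)
  if (length(cols) < 1)
    stop("count_branch_substitutions: ", family$gene_id,
         ": no gap-free codon column")
  acc <- matrix(0, nrow = 5, ncol = 2,
                dimnames = list(.BRANCHES, c("Dn", "Ds")))
  total <- 0
  human_w <- numeric(length(cols))  # human-branch change weight per column
  for (i in seq_along(cols)) {
    cc <- .column_branch_counts(cm[, cols[i]])
    acc <- acc + cc$mat
    total <- total + cc$cost
    human_w[i] <- sum(cc$mat["human", ])
  }
  sitem <- vapply(cols, function(j)
    ng86_site_counts(cm["human", j]), numeric(2))
  N <- sum(sitem["n", ]); S <- sum(sitem["s", ])
  gap_cols <- setdiff(seq_len(ncol(cm)), cols)
  mis <- NA_real_
  if (sum(human_w) > 0) {
    if (length(gap_cols)) {
      near <- vapply(cols, function(j) min(abs(j - gap_cols)) <= 5, logical(1))
      mis <- sum(human_w[near]) / sum(human_w)
    } else mis <- 0
  }
  out <- data.frame(gene_id = family$gene_id, branch = .BRANCHES,
                    Dn = acc[, "Dn"], Ds = acc[, "Ds"], N = N, S = S,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$dN <- out$Dn / out$N
  out$dS <- out$Ds / out$S
  out$omega <- ifelse(out$Ds > 0, out$dN / out$dS, NA_real_)
  attr(out, "total_changes") <- total
  attr(out, "n_columns_used") <- length(cols)
  attr(out, "misalign_frac") <- mis
  out
}

#' Count branch substitutions for a list of families
#'
#' @param families List of [gene_family()] objects.
#' @return Row-bound per-branch count table across genes (see
#'   [count_branch_substitutions()]).
#' @export
count_branch_substitutions_all <- function(families) {
  do.call(rbind, lapply(families, count_branch_substitutions))
}

#' Apply the family-level quality filters
#'
#' A family is discarded (`passed = FALSE`) when any of its four proteins is
#' not strictly longer than `min_protein_len` ungapped amino acids
#' (`short_protein`), or when dN/dS exceeds `max_dnds` on the human, chimp or
#' hominoid-ancestor branch (`dnds_gt_max`; a branch with `Ds = 0` and
#' `Dn > 0` counts as exceeding, while `Ds = 0` and `Dn = 0` passes). A
#' human-branch Dn above 10 raises the non-excluding `high_dn_flag`, together
#' with the misalignment heuristic (fraction of human-branch changes within 5
#' codons of an alignment gap) so that suspicious alignments can be audited;
#' exclusion on that ground is left to the user.
#'
#' @param families List of [gene_family()] (or `NULL` to skip the length
#'   check, e.g. for imported count tables).
#' @param counts Per-branch count table as from
#'   [count_branch_substitutions_all()] or [read_count_table()].
#' @param config An [analysis_config()].
#' @return data.frame with columns `gene_id`, `passed`, `reasons`
#'   (`;`-separated codes), `human_dn`, `misalign_frac`.
#' @export
apply_quality_filters <- function(families = NULL, counts,
                                  config = analysis_config()) {
  fam_by_id <- if (!is.null(families))
    stats::setNames(families, vapply(families, `[[`, character(1), "gene_id"))
  genes <- unique(counts$gene_id)
  res <- lapply(genes, function(g) {
    sub <- counts[counts$gene_id == g, , drop = FALSE]
    reasons <- character(0)
    if (!is.null(families) && !is.null(fam_by_id[[g]])) {
      fam <- fam_by_id[[g]]
      aalen <- vapply(fam$sequences, function(s)
        nchar(gsub("-", "", s)) / 3, numeric(1))
      if (any(aalen <= config$min_protein_len))
        reasons <- c(reasons, "short_protein")
    }
    for (b in c("human", "chimp", "hominoid_ancestor")) {
      row <- sub[sub$branch == b, , drop = FALSE]
      if (nrow(row) != 1) next
      w <- if (!is.null(row$omega) && !is.na(row$omega)) row$omega
      else if (row$Ds == 0 && row$Dn > 0) Inf else NA_real_
      if (!is.na(w) && w > config$max_dnds) {
        reasons <- c(reasons, "dnds_gt_max")
        break
      }
    }
    hdn <- sub$Dn[sub$branch == "human"]
    hdn <- if (length(hdn)) hdn[1] else NA_real_
    if (!is.na(hdn) && hdn > 10) reasons <- c(reasons, "high_dn_flag")
    mis <- NA_real_
    if (!is.null(families) && !is.null(fam_by_id[[g]])) {
      cb <- count_branch_substitutions(fam_by_id[[g]])
      mis <- attr(cb, "misalign_frac")
    }
    data.frame(gene_id = g,
               passed = !any(reasons %in% c("short_protein", "dnds_gt_max")),
               reasons = paste(reasons, collapse = ";"),
               human_dn = hdn, misalign_frac = mis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
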