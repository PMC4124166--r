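## Functional-group comparisons: informative-gene filter, GO group
## construction, rank-sum comparisons of FI distributions and count-based
## category enrichment.

#' Informative genes for per-gene FI comparisons
#'
#' Selects genes with `Dn`, `Ds`, `Pn`, `Ps` all non-zero and
#' `Pn + Ps >= min_poly` (default 4), the filter that keeps per-gene FI
#' estimates usable for distribution comparisons.
#'
#' @param counts data.frame with `gene_id`, `Dn`, `Ds`, `Pn`, `Ps`.
#' @param min_poly Minimum number of polymorphic sites.
#' @return Character vector of gene ids.
#' @export
filter_informative <- function(counts, min_poly = 4) {
  keep <- counts$Dn != 0 & counts$Ds != 0 & counts$Pn != 0 &
    counts$Ps != 0 & counts$Pn + counts$Ps >= min_poly
  counts$gene_id[keep]
}

#' Build GO groups from a flat annotation table
#'
#' Groups genes by term, keeps terms annotating at least `min_size` of the
#' supplied genes, and adds the reserved group `"unknown"` holding genes with
#' no annotation at all.
#'
#' @param annotations data.frame with columns `gene_id`, `term`.
#' @param genes Genes under analysis (e.g. the informative set); annotation
#'   rows for other genes are ignored.
#' @param min_size Minimum group size (default 40).
#' @return Named list of gene-id vectors.
#' @export
go_groups <- function(annotations, genes, min_size = 40) {
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  groups <- split(ann$gene_id, ann$term)
  groups <- lapply(groups, unique)
  groups <- groups[vapply(groups, length, integer(1)) >= min_size]
  unknown <- setdiff(genes, unique(ann$gene_id))
  groups$unknown <- unknown
  groups
}

#' Rank-sum comparison of a group's FI distribution against the background
#'
#' Wilcoxon-Mann-Whitney test of the group's per-gene FI values against the
#' background distribution. The two-sided p-value is always computed; the
#' one-sided (greater) p-value is reported only when the group median exceeds
#' the background median and is suppressed (`NA`, `one_sided_suppressed =
#' TRUE`) otherwise. By default the background includes the group members;
#' set `exclude_group` to compare against non-members only.
#'
#' @param group_fi Per-gene FI values of the group.
#' @param background_fi Per-gene FI values of the background.
#' @param exclude_group Drop the group values from the background first
#'   (matched by value positions is impossible for plain vectors, so supply a
#'   disjoint background yourself when identifiers matter; with `TRUE` the
#'   function removes one background occurrence per group value).
#' @return list `n`, `median_group`, `median_background`, `p_two_sided`,
#'   `p_one_sided`, `one_sided_suppressed`.
#' @export
group_fi_comparison <- function(group_fi, background_fi,
                                exclude_group = FALSE) {
  group_fi <- group_fi[!is.na(group_fi)]
  background_fi <- background_fi[!is.na(background_fi)]
  if (exclude_group) {
    for (v in group_fi) {
      i <- match(v, background_fi)
      if (!is.na(i)) background_fi <- background_fi[-i]
    }
  }
  if (length(group_fi) < 2 || length(background_fi) < 2)
    return(list(n = length(group_fi), median_group = NA_real_,
                median_background = NA_real_, p_two_sided = NA_real_,
                p_one_sided = NA_real_, one_sided_suppressed = NA))
  mg <- stats::median(group_fi)
  mb <- stats::median(background_fi)
  p2 <- stats::wilcox.test(group_fi, background_fi, exact = FALSE)$p.value
  if (mg > mb) {
    p1 <- stats::wilcox.test(group_fi, background_fi,
                             alternative = "greater", exact = FALSE)$p.value
    supp <- FALSE
  } else {
    p1 <- NA_real_
    supp <- TRUE
  }
  list(n = length(group_fi), median_group = mg, median_background = mb,
       p_two_sided = p2, p_one_sided = p1, one_sided_suppressed = supp)
}

#' Category count enrichment within a gene set
#'
#' Compares the observed number of category genes in a set against the
#' expectation under the background category frequency, with a one-sided
#' (greater) exact binomial test by default or a normal-approximation
#' proportion test.
#'
#' @param set_genes Gene ids of the set under study.
#' @param category_genes Gene ids annotated to the category.
#' @param background Gene ids of the background universe.
#' @param method `"binomial"` (exact, default) or `"proportion"`
#'   (chi-squared approximation via [stats::prop.test()]).
#' @return list `observed`, `expected`, `p`, `method`.
#' @export
category_count_test <- function(set_genes, category_genes, background,
                                method = c("binomial", "proportion")) {
  method <- match.arg(method)
  if (length(background) == 0)
    return(list(observed = NA_integer_, expected = NA_real_, p = NA_real_,
                method = method))
  set_genes <- intersect(set_genes, background)
  category_genes <- intersect(category_genes, background)
  obs <- length(intersect(set_genes, category_genes))
  p0 <- length(category_genes) / length(background)
  expected <- length(set_genes) * p0
  if (p0 == 0)
    return(list(observed = obs, expected = 0, p = 1, method = method))
  p <- if (method == "binomial")
    stats::binom.test(obs, length(set_genes), p0,
                      alternative = "greater")$p.value
  else
    stats::prop.test(obs, length(set_genes), p0, alternative = "greater",
                     correct = TRUE)$p.value
  list(observed = obs, expected = expected, p = p, method = method)
}
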