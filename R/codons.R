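## Codon-level machinery shared by the divergence counter, the SNP classifier
## and the simulator: the standard genetic code, single-nucleotide mutant
## tables, NG86 site fractions and stop-avoiding pathway decompositions.

.NT <- c("A", "C", "G", "T")

.CODONS <- as.vector(t(outer(
  as.vector(t(outer(.NT, .NT, paste0))), .NT, paste0)))

## amino acid per codon, from the standard genetic code ('*' = stop)
.CODON_AA <- local({
  aa <- vapply(.CODONS, function(cod)
    seqinr::translate(strsplit(cod, "")[[1]]), character(1))
  names(aa) <- .CODONS
  aa
})

.STOPS <- names(.CODON_AA)[.CODON_AA == "*"]
.SENSE <- setdiff(.CODONS, .STOPS)

.is_stop <- function(codon) codon %in% .STOPS

.is_transition <- function(a, b) {
  purines <- c("A", "G")
  (a %in% purines) == (b %in% purines) & a != b
}

## mutate one position of a codon
.mutate_codon <- function(codon, pos, nt) {
  substr(codon, pos, pos) <- nt
  codon
}

## memoisation caches (filled lazily; cleared only on namespace reload)
.mk_cache <- new.env(parent = emptyenv())

#' NG86 synonymous and non-synonymous site counts of one codon
#'
#' Decomposes each of the three codon positions into the fraction of its three
#' single-nucleotide mutants that are synonymous (Nei and Gojobori 1986).
#' Mutants creating a stop codon count as non-synonymous opportunity, so the
#' two fractions always sum to 3.
#'
#' @param codon A 3-letter sense codon (uppercase A/C/G/T).
#' @return Named numeric vector `c(n = ..., s = ...)` with `n + s == 3`.
#' @examples
#' ng86_site_counts("TTT")  # c(n = 8/3, s = 1/3)
#' ng86_site_counts("TGG")  # c(n = 3, s = 0)
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% .SENSE)
    stop("ng86_site_counts: not a sense codon: ", codon)
  key <- codon
  if (!is.null(.mk_cache$sites) && exists(key, .mk_cache$sites))
    return(get(key, .mk_cache$sites))
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (nt in setdiff(.NT, ref)) {
      mut <- .mutate_codon(codon, pos, nt)
      if (!.is_stop(mut) && .CODON_AA[[mut]] == .CODON_AA[[codon]])
        s <- s + 1 / 3
    }
  }
  out <- c(n = 3 - s, s = s)
  if (is.null(.mk_cache$sites))
    .mk_cache$sites <- new.env(hash = TRUE, parent = emptyenv())
  assign(key, out, .mk_cache$sites)
  out
}

## All minimal mutational pathways between two codons as ordered position
## sequences; returns per-path codon step lists.
.codon_paths <- function(a, b) {
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(list())
  orders <- if (k == 1) list(diff_pos) else
    if (k == 2) list(diff_pos, rev(diff_pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) diff_pos[o])
  lapply(orders, function(ord) {
    steps <- character(k + 1)
    steps[1] <- a
    cur <- a
    for (i in seq_along(ord)) {
      p <- ord[i]
      cur <- .mutate_codon(cur, p, substr(b, p, p))
      steps[i + 1] <- cur
    }
    steps
  })
}

#' NG86 pathway decomposition of the changes between two codons
#'
#' Averages the synonymous/non-synonymous decomposition over all minimal
#' mutational pathways between the two codons whose intermediate codons are
#' not stop codons. If every minimal pathway passes through a stop codon the
#' decomposition falls back to all minimal pathways (steps into or out of a
#' stop counted as non-synonymous) and the result carries attribute
#' `stop_fallback = TRUE`. The two components always sum to the nucleotide
#' Hamming distance of the codons.
#'
#' @param a,b Sense codons.
#' @return Named numeric vector `c(nonsyn = ..., syn = ...)`.
#' @examples
#' ng86_path_counts("TTT", "TTC")  # c(nonsyn = 0, syn = 1)
#' ng86_path_counts("TTT", "GTC")  # c(nonsyn = 1, syn = 1)
#' @export
ng86_path_counts <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!a %in% .SENSE || !b %in% .SENSE)
    stop("ng86_path_counts: both codons must be sense codons: ", a, ", ", b)
  if (a == b) return(c(nonsyn = 0, syn = 0))
  key <- paste0(a, ">", b)
  if (!is.null(.mk_cache$paths) && exists(key, .mk_cache$paths))
    return(get(key, .mk_cache$paths))
  paths <- .codon_paths(a, b)
  ok <- vapply(paths, function(st) !any(.is_stop(st[-c(1, length(st))])),
               logical(1))
  fallback <- !any(ok)
  use <- if (fallback) paths else paths[ok]
  acc <- c(nonsyn = 0, syn = 0)
  for (st in use) {
    for (i in seq_len(length(st) - 1)) {
      aa1 <- .CODON_AA[[st[i]]]
      aa2 <- .CODON_AA[[st[i + 1]]]
      if (aa1 == aa2 && aa1 != "*") acc["syn"] <- acc["syn"] + 1
      else acc["nonsyn"] <- acc["nonsyn"] + 1
    }
  }
  out <- acc / length(use)
  if (fallback) attr(out, "stop_fallback") <- TRUE
  if (is.null(.mk_cache$paths))
    .mk_cache$paths <- new.env(hash = TRUE, parent = emptyenv())
  assign(key, out, .mk_cache$paths)
  out
}

#' Classify one coding SNP as synonymous, non-synonymous or other
#'
#' Substitutes the alternate allele into the coding sequence and compares the
#' encoded amino acids. Changes that create or destroy a stop codon are
#' classified `"other"` and are excluded from Pn/Ps counting downstream.
#'
#' @param cds Coding sequence (in-frame, ungapped, uppercase string).
#' @param cds_pos0 0-based offset of the SNP in `cds`.
#' @param ref,alt Reference and alternate nucleotides; `ref` must match `cds`.
#' @param gene_id Identifier used in error messages.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"other"`.
#' @export
classify_coding_snp <- function(cds, cds_pos0, ref, alt, gene_id = "?") {
  if (cds_pos0 < 0 || cds_pos0 >= nchar(cds))
    stop("classify_coding_snp: position out of range for gene ", gene_id)
  have <- substr(cds, cds_pos0 + 1, cds_pos0 + 1)
  if (have != ref)
    stop("classify_coding_snp: reference mismatch for gene ", gene_id,
         " at 0-based position ", cds_pos0, " (CDS has ", have,
         ", record says ", ref, ")")
  ci <- cds_pos0 %/% 3
  within <- cds_pos0 %% 3
  codon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
  mut <- .mutate_codon(codon, within + 1, alt)
  aa1 <- .CODON_AA[[codon]]
  aa2 <- .CODON_AA[[mut]]
  if (aa1 == "*" || aa2 == "*") return("other")
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}
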