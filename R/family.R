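## Gene families: four-species in-frame codon alignments.

.SPECIES <- c("human", "chimp", "macaque", "mouse")

#' Construct a four-species codon-aligned gene family
#'
#' The unit of the divergence analysis: one-to-one orthologs from human,
#' chimpanzee, macaque and mouse, codon-aligned (alignment length divisible by
#' three, gaps only as whole codons `"---"`). Validation enforces equal
#' lengths, frame, whole-codon gaps and the absence of stop codons in any
#' codon column that is gap-free in all four species (those columns are the
#' ones used for substitution counting).
#'
#' @param gene_id Gene identifier.
#' @param sequences Named character vector or list with elements `human`,
#'   `chimp`, `macaque`, `mouse` (uppercase A/C/G/T/-).
#' @return An object of class `"gene_family"`.
#' @export
gene_family <- function(gene_id, sequences) {
  sequences <- toupper(unlist(sequences))
  missing <- setdiff(.SPECIES, names(sequences))
  if (length(missing))
    stop("gene_family: ", gene_id, ": missing species: ",
         paste(missing, collapse = ", "))
  sequences <- sequences[.SPECIES]
  len <- unique(nchar(sequences))
  if (length(len) != 1)
    stop("gene_family: ", gene_id, ": sequences of unequal length")
  if (len %% 3 != 0)
    stop("gene_family: ", gene_id, ": alignment length ", len,
         " not a multiple of 3")
  cm <- .codon_matrix(sequences)
  gapped <- grepl("-", cm)
  dim(gapped) <- dim(cm)
  bad_gap <- gapped & cm != "---"
  if (any(bad_gap))
    stop("gene_family: ", gene_id, ": partial-codon gap (column ",
         which(bad_gap, arr.ind = TRUE)[1, 2], ")")
  other <- grepl("[^ACGT-]", cm)
  dim(other) <- dim(cm)
  gapfree <- !apply(gapped | other, 2, any)
  if (any(gapfree)) {
    stops <- apply(cm[, gapfree, drop = FALSE], 2, function(col)
      any(.is_stop(col)))
    if (any(stops))
      stop("gene_family: ", gene_id, ": stop codon in gap-free codon column ",
           which(gapfree)[which(stops)[1]])
  }
  structure(list(gene_id = gene_id, sequences = sequences,
                 n_codons = len %/% 3),
            class = "gene_family")
}

## 4 x n_codons matrix of codon strings, species in .SPECIES order
.codon_matrix <- function(sequences) {
  n <- nchar(sequences[[1]]) %/% 3
  m <- vapply(sequences, function(s)
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n)), character(n))
  if (n == 1)  # vapply drops dims for single-codon alignments
    m <- matrix(m, nrow = 1, dimnames = list(NULL, names(sequences)))
  t(m)
}

## indices of codon columns gap-free (and unambiguous) in all species
.gapfree_columns <- function(cm) {
  bad <- grepl("[^ACGT]", cm)
  dim(bad) <- dim(cm)
  which(!apply(bad, 2, any))
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family", x$gene_id, "-", x$n_codons, "codon columns,",
      length(.gapfree_columns(.codon_matrix(x$sequences))), "gap-free\n")
  invisible(x)
}

#' Ungapped coding sequence of one species in a family
#'
#' @param family A `gene_family`.
#' @param species One of `"human"`, `"chimp"`, `"macaque"`, `"mouse"`.
#' @return Ungapped CDS string.
#' @export
family_cds <- function(family, species = "human") {
  gsub("-", "", family$sequences[[species]])
}
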