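# Shared fixture builders: small hand-constructed codon families and tables.

# family of identical repeats of a (sense) codon, with optional per-species
# codon substitutions given as list(species = list(c(column, codon), ...))
make_family <- function(gene_id = "gX", n_codons = 40, base = "GCT",
                        edits = list()) {
  seqs <- stats::setNames(rep(strrep(base, n_codons), 4),
                          c("human", "chimp", "macaque", "mouse"))
  for (sp in names(edits)) {
    for (e in edits[[sp]]) {
      j <- e[[1]]
      substr(seqs[[sp]], 3 * (as.integer(j) - 1) + 1, 3 * as.integer(j)) <-
        e[[2]]
    }
  }
  gene_family(gene_id, seqs)
}

# write a families list to FASTA + manifest in a temp dir
write_family_fasta <- function(families, dir = tempfile("fams")) {
  if (!dir.exists(dir)) dir.create(dir)
  recs <- unlist(lapply(families, function(f)
    stats::setNames(as.list(f$sequences),
                    paste0(f$gene_id, "|", names(f$sequences)))),
    recursive = FALSE)
  fa <- file.path(dir, "aln.fasta")
  seqinr::write.fasta(lapply(recs, function(s) strsplit(s, "")[[1]]),
                      names = names(recs), file.out = fa)
  manifest <- do.call(rbind, lapply(families, function(f)
    data.frame(record_id = paste0(f$gene_id, "|",
                                  c("human", "chimp", "macaque", "mouse")),
               gene_id = f$gene_id,
               species = c("human", "chimp", "macaque", "mouse"),
               stringsAsFactors = FALSE)))
  mf <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fa, manifest = mf, dir = dir)
}

# independent translation oracle (seqinr), used instead of the package's
# internal tables when a test needs its own view of the genetic code
aa_of <- function(codon) seqinr::translate(strsplit(codon, "")[[1]])

SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(nt, nt, nt), 1, paste, collapse = "")
  all3[vapply(all3, aa_of, character(1)) != "*"]
})
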