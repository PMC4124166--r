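# Gene-family validation and the plain-text readers/writers.

test_that("gene_family enforces the alignment invariants", {
  f <- make_family("ok", n_codons = 100)
  expect_s3_class(f, "gene_family")
  expect_equal(f$n_codons, 100)
  seqs <- f$sequences
  expect_error(gene_family("m", seqs[c("human", "chimp", "macaque")]),
               "missing species")
  bad <- seqs
  bad[["mouse"]] <- paste0(bad[["mouse"]], "AAA")
  expect_error(gene_family("l", bad), "unequal")
  bad <- seqs
  bad[["human"]] <- substr(bad[["human"]], 1, 299)
  bad <- lapply(bad, substr, 1, 299)
  expect_error(gene_family("f", bad), "multiple of 3")
  # partial-codon gap
  bad <- seqs
  substr(bad[["human"]], 4, 4) <- "-"
  expect_error(gene_family("g", bad), "partial-codon gap")
  # whole-codon gap is fine and the column is excluded from counting
  ok <- seqs
  substr(ok[["human"]], 4, 6) <- "---"
  fam <- gene_family("h", ok)
  cnt <- count_branch_substitutions(fam)
  expect_equal(attr(cnt, "n_columns_used"), 99)
  # stop codon in a gap-free column rejected
  bad <- seqs
  substr(bad[["chimp"]], 7, 9) <- "TAA"
  expect_error(gene_family("s", bad), "stop codon")
})

test_that("read_codon_alignments accepts good families, skips incomplete ones,
           and hard-errors on frame violations", {
  fams <- list(make_family("gA", 100), make_family("gB", 100))
  ff <- write_family_fasta(fams)
  got <- read_codon_alignments(ff$fasta, ff$manifest)
  expect_length(got, 2)
  expect_equal(attr(got, "log")$record, character(0))
  # drop the mouse record of gB from the manifest -> gB skipped with warning
  mf <- utils::read.delim(ff$manifest)
  mf2 <- mf[!(mf$gene_id == "gB" & mf$species == "mouse"), ]
  expect_warning(got2 <- read_codon_alignments(ff$fasta, mf2), "missing")
  expect_length(got2, 1)
  log <- attr(got2, "log")
  expect_equal(log$record, "gB")
  expect_equal(log$reason, "missing_species")
  # out-of-frame record -> hard error naming it
  writeLines(c(">gC|human", strrep("GCT", 10), ">bad|chimp", "GCTA"),
             file.path(ff$dir, "frame.fasta"))
  mf3 <- data.frame(record_id = c("gC|human", "bad|chimp"),
                    gene_id = "gC", species = c("human", "chimp"))
  expect_error(read_codon_alignments(file.path(ff$dir, "frame.fasta"), mf3),
               "bad\\|chimp")
})

test_that("count tables round-trip exactly and reject bad rows", {
  counts <- data.frame(gene_id = rep("g1", 5),
                       branch = c("human", "chimp", "hominoid_ancestor",
                                  "macaque", "mouse"),
                       Dn = c(1 / 3, 2, 0, 5.5, 1),
                       Ds = c(2 / 3, 1, 0, 2, 7),
                       N = 900.123456789, S = 299.876543211,
                       stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_count_table(counts, path)
  back <- read_count_table(path)
  expect_identical(back$Dn, counts$Dn)  # exact double round-trip
  expect_identical(back$Ds, counts$Ds)
  expect_identical(back$N, counts$N)
  bad <- counts
  bad$Dn[1] <- -1
  bad$branch[2] <- "gibbon"
  write_count_table(bad, path)
  expect_warning(back2 <- read_count_table(path), "rejected 2")
  expect_equal(nrow(back2), 3)
  expect_setequal(attr(back2, "log")$reason,
                  c("negative_count", "unknown_branch"))
  # empty file
  empty <- tempfile(fileext = ".tsv")
  writeLines("gene_id\tbranch\tDn\tDs", empty)
  expect_warning(e <- read_count_table(empty), "empty")
  expect_equal(nrow(e), 0)
})

test_that("snp tables: DAF derivation, rejection rules, round-trip, VCF", {
  snps <- data.frame(gene_id = c("g1", "g1", "g1", "g1"),
                     cds_pos = c(4, 5, 6, 7),
                     ref = c("A", "C", "G", "T"),
                     alt = c("G", "T", "A", "C"),
                     ancestral = c("A", "T", NA, "C"),
                     alt_freq = c(0.7, 0.2, 0.4, 0.9))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  got <- read_snp_table(path)
  expect_equal(got$cds_pos0, c(3L, 4L, 5L, 6L))  # 1-based file -> 0-based
  expect_equal(got$daf, c(0.7, 0.8, NA, 0.1))    # anc=alt flips, missing NA
  expect_equal(got$daf_undefined, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(got$maf, c(0.3, 0.2, 0.4, 0.1))
  # round-trip through the writer
  out <- tempfile(fileext = ".tsv")
  write_snp_table(got, out)
  again <- read_snp_table(out)
  expect_equal(again$alt_freq, got$alt_freq)
  expect_equal(again$daf, got$daf)
  # rejections: freq out of range, ref == alt
  bad <- snps
  bad$alt_freq[1] <- 1.3
  bad$alt[2] <- "C"
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  expect_warning(got2 <- read_snp_table(path), "rejected 2")
  expect_equal(nrow(got2), 2)
  expect_setequal(attr(got2, "log")$reason,
                  c("freq_out_of_range", "ref_equals_alt"))
  # minimal VCF
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "g1\t4\trs1\tA\tG\t.\tPASS\tAA=A;AF=0.7",
               "g1\t9\trs2\tC\tT\t.\tPASS\tAF=0.25"),
             vcf)
  v <- read_snp_table(vcf)
  expect_equal(v$cds_pos0, c(3L, 8L))
  expect_equal(v$daf, c(0.7, NA))
  expect_true(v$daf_undefined[2])
})
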