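# Parsimony branch assignment, NG86 accounting and the quality filters.

test_that("fitch_ancestral_codons reconstructs simple columns", {
  # identical column: ancestors equal the codon, zero changes
  fam <- make_family("f1", n_codons = 3, base = "AAA")
  anc <- fitch_ancestral_codons(fam)
  expect_length(anc, 3)
  expect_equal(anc[[1]]$cost, 0)
  expect_equal(unique(anc[[1]]$hominoid_ancestor), "AAA")
  expect_equal(unique(anc[[1]]$root), "AAA")
  # human AAG vs AAA elsewhere: 3-vs-1 majority, change on human branch
  fam <- make_family("f2", n_codons = 3, base = "AAA",
                     edits = list(human = list(list(2, "AAG"))))
  a2 <- fitch_ancestral_codons(fam)[[2]]
  expect_equal(a2$cost, 1)
  expect_equal(unique(a2$hominoid_ancestor), "AAA")
  expect_equal(unique(a2$root), "AAA")
  # human=chimp=AAA vs macaque=mouse=AAG: unique minimal reconstruction
  # places the single change on the internal (hominoid-ancestor) branch
  fam <- make_family("f3", n_codons = 3, base = "AAA",
                     edits = list(macaque = list(list(2, "AAG")),
                                  mouse = list(list(2, "AAG"))))
  a3 <- fitch_ancestral_codons(fam)[[2]]
  expect_equal(a3$cost, 1)
  expect_equal(unique(a3$hominoid_ancestor), "AAA")
  expect_equal(unique(a3$root), "AAG")
})

test_that("count_branch_substitutions assigns constructed changes", {
  # a single non-synonymous change on the human branch (GCT Ala -> GTT Val)
  fam <- make_family("g1", n_codons = 50,
                     edits = list(human = list(list(10, "GTT"))))
  cnt <- count_branch_substitutions(fam)
  expect_equal(cnt$Dn[cnt$branch == "human"], 1)
  expect_equal(cnt$Ds[cnt$branch == "human"], 0)
  expect_equal(sum(cnt$Dn) + sum(cnt$Ds), 1)
  # site conservation: N + S = 3 * columns
  expect_equal(cnt$N[1] + cnt$S[1], 3 * 50)
  # identical sequences: all zero
  cnt0 <- count_branch_substitutions(make_family("g0", n_codons = 10))
  expect_true(all(cnt0$Dn == 0) && all(cnt0$Ds == 0))
  # one synonymous change on the mouse branch (GCT -> GCC, Ala)
  fam2 <- make_family("g2", n_codons = 50,
                      edits = list(mouse = list(list(3, "GCC"))))
  cnt2 <- count_branch_substitutions(fam2)
  expect_equal(cnt2$Ds[cnt2$branch == "mouse"], 1)
  expect_equal(sum(cnt2$Dn), 0)
})

test_that("parsimony totals are conserved and ties averaged uniformly", {
  cfg <- sim_config(n_genes = 30, codons_per_gene = 100, seed = 91)
  d <- simulate_dataset(cfg)
  for (fam in d$families[1:30]) {
    cnt <- count_branch_substitutions(fam)
    expect_equal(sum(cnt$Dn) + sum(cnt$Ds), attr(cnt, "total_changes"),
                 tolerance = 1e-9)
  }
})

test_that("branch assignment matches exhaustive ancestral enumeration on
           single-change columns", {
  # independent oracle: enumerate all 61 x 61 sense ancestor pairs, keep the
  # minimal-cost set, classify each one-step edge by translation
  nt_mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  ham_to <- function(codon) {
    obs <- strsplit(codon, "")[[1]]
    rowSums(nt_mat != matrix(obs, nrow(nt_mat), 3, byrow = TRUE))
  }
  oracle <- function(h, c_, m, mo) {
    cost_a <- ham_to(h) + ham_to(c_)            # edges into hominoid node
    cost_r <- ham_to(m) + ham_to(mo)            # edges into root node
    cross <- matrix(0, 61, 61)
    for (i in 1:61) cross[i, ] <- rowSums(
      nt_mat != matrix(nt_mat[i, ], 61, 3, byrow = TRUE))
    tot <- outer(cost_a, cost_r, "+") + t(cross)  # [a, r]: + ham(a, r)
    best <- which(tot == min(tot), arr.ind = TRUE)
    acc <- matrix(0, 5, 2)
    cls <- function(from, to) {
      if (from == to) return(c(0, 0))
      if (aa_of(from) == aa_of(to)) c(0, 1) else c(1, 0)
    }
    for (k in seq_len(nrow(best))) {
      a <- SENSE_CODONS[best[k, 1]]
      r <- SENSE_CODONS[best[k, 2]]
      acc <- acc + rbind(cls(a, h), cls(a, c_), cls(r, a), cls(r, m),
                         cls(r, mo))
    }
    acc / nrow(best)
  }
  set.seed(17)
  for (i in 1:120) {
    base <- sample(SENSE_CODONS, 1)
    # mutate one branch tip (or the internal edge via both outgroups)
    repeat {
      p <- sample(1:3, 1)
      nt <- sample(setdiff(c("A", "C", "G", "T"), substr(base, p, p)), 1)
      mut <- base
      substr(mut, p, p) <- nt
      if (aa_of(mut) != "*") break
    }
    col <- rep(base, 4)
    col[sample(1:4, 1)] <- mut
    fam <- gene_family("o1", stats::setNames(as.list(col),
                                             c("human", "chimp", "macaque",
                                               "mouse")))
    got <- count_branch_substitutions(fam)
    want <- oracle(col[1], col[2], col[3], col[4])
    expect_equal(cbind(got$Dn, got$Ds), unname(want), tolerance = 1e-9)
  }
})

test_that("generator truth is recovered exactly for most families at low
           divergence", {
  bl <- c(human = 0.005, chimp = 0.005, hominoid_ancestor = 0.005,
          macaque = 0.005, mouse = 0.005)
  cfg <- sim_config(n_genes = 200, codons_per_gene = 150,
                    branch_lengths = bl, seed = 5)
  d <- simulate_dataset(cfg)
  counts <- count_branch_substitutions_all(d$families)
  m <- merge(counts, d$truth_branch, by = c("gene_id", "branch"))
  exact <- tapply(abs(m$Dn.x - m$Dn.y) < 1e-9 & abs(m$Ds.x - m$Ds.y) < 1e-9,
                  m$gene_id, all)
  expect_gte(mean(exact), 0.9)
})

test_that("quality filters apply the length and dN/dS rules", {
  config <- analysis_config()
  # exactly 100 aa fails the 'longer than 100' rule
  fam100 <- make_family("p100", n_codons = 100)
  fam101 <- make_family("p101", n_codons = 101)
  counts <- rbind(count_branch_substitutions(fam100),
                  count_branch_substitutions(fam101))
  qc <- apply_quality_filters(list(fam100, fam101), counts, config)
  expect_false(qc$passed[qc$gene_id == "p100"])
  expect_match(qc$reasons[qc$gene_id == "p100"], "short_protein")
  expect_true(qc$passed[qc$gene_id == "p101"])
  # imported counts: omega > 10 discards; Ds = 0 with Dn > 0 counts as > 10
  mk_counts <- function(g, dn, ds) data.frame(
    gene_id = g, branch = c("human", "chimp", "hominoid_ancestor"),
    Dn = c(dn, 1, 1), Ds = c(ds, 3, 3), N = 700, S = 200,
    dN = c(dn, 1, 1) / 700, dS = c(ds, 3, 3) / 200,
    omega = ifelse(c(ds, 3, 3) > 0,
                   (c(dn, 1, 1) / 700) / (c(ds, 3, 3) / 200), NA))
  qc2 <- apply_quality_filters(NULL, mk_counts("w", 5, 0), config)
  expect_false(qc2$passed)
  expect_match(qc2$reasons, "dnds_gt_max")
  # Dn = 0, Ds = 0 passes (omega undefined but no evidence)
  qc3 <- apply_quality_filters(NULL, mk_counts("z", 0, 0), config)
  expect_true(qc3$passed)
  # human Dn = 11 raises the non-excluding high-Dn flag
  qc4 <- apply_quality_filters(NULL, mk_counts("h", 11, 3), config)
  expect_true(qc4$passed)
  expect_match(qc4$reasons, "high_dn_flag")
})
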