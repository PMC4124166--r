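# The MK statistic family and the Williams-corrected G-test.

test_that("FI, DoS and alpha evaluate the defining formulas", {
  expect_equal(fixation_index(13, 1, 5, 4), 10.4)
  expect_equal(fixation_index(7, 1, 2, 4), 14)
  expect_equal(fixation_index(1, 1, 1, 1), 1)
  expect_true(is.na(fixation_index(0, 1, 1, 1)))
  expect_true(is.na(fixation_index(1, 1, 0, 1)))
  expect_equal(direction_of_selection(1, 1, 1, 1), 0)
  expect_equal(direction_of_selection(1, 0, 0, 1), 1)
  expect_equal(direction_of_selection(13, 1, 5, 4), 13 / 14 - 5 / 9)
  expect_true(is.na(direction_of_selection(0, 0, 1, 1)))
  expect_equal(alpha_adaptive(1, 1, 1, 1), 0)
  expect_equal(alpha_adaptive(13, 1, 5, 4), 1 - 5 / 52)
  expect_equal(alpha_adaptive(3, 2, 0, 5), 1)  # no nonsyn polymorphism
  expect_true(is.na(alpha_adaptive(0, 1, 1, 1)))
})

test_that("identities NI = 1/FI, alpha = 1 - 1/FI, sign(DoS) = sign(FI - 1)
           hold wherever defined", {
  set.seed(99)
  for (i in 1:500) {
    x <- stats::rpois(4, lambda = sample(1:8, 4, TRUE)) +
      sample(0:1, 4, TRUE) * stats::runif(4)  # mixed integer/fractional
    fi <- fixation_index(x[1], x[2], x[3], x[4])
    if (is.na(fi)) next
    expect_equal(neutrality_index(x[1], x[2], x[3], x[4]), 1 / fi,
                 tolerance = 1e-12)
    expect_equal(alpha_adaptive(x[1], x[2], x[3], x[4]), 1 - 1 / fi,
                 tolerance = 1e-8)
    dos <- direction_of_selection(x[1], x[2], x[3], x[4])
    expect_equal(sign(dos), sign(fi - 1), tolerance = 1e-12)
  }
})

test_that("the uncorrected G equals 2N x mutual information (independent
           oracle) and the Williams correction only shrinks it", {
  # oracle: plug-in mutual information of the 2x2 joint distribution, nats
  mi_nats <- function(O) {
    p <- O / sum(O)
    pr <- rowSums(p); pc <- colSums(p)
    s <- 0
    for (i in 1:2) for (j in 1:2)
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
    s
  }
  set.seed(7)
  for (i in 1:1000) {
    O <- matrix(stats::rpois(4, sample(2:30, 4, TRUE)) + 1, 2)
    g <- mk_gtest_williams(O[1, 1], O[1, 2], O[2, 1], O[2, 2])
    expect_equal(g$G, 2 * sum(O) * mi_nats(O), tolerance = 1e-9)
    expect_gte(g$q, 1)            # Williams q >= 1 so G_adj <= G
    expect_lte(g$G_adj, g$G + 1e-12)
    # invariance under simultaneous row and column swap
    g2 <- mk_gtest_williams(O[2, 2], O[2, 1], O[1, 2], O[1, 1])
    expect_equal(g$G_adj, g2$G_adj, tolerance = 1e-12)
    expect_equal(g$p, g2$p, tolerance = 1e-12)
  }
  # degenerate tables
  expect_equal(mk_gtest_williams(5, 5, 5, 5)$G_adj, 0)
  expect_equal(mk_gtest_williams(5, 5, 5, 5)$p, 1)
  expect_true(is.na(mk_gtest_williams(0, 0, 3, 4)$p))
  expect_equal(mk_gtest_williams(0, 0, 3, 4)$reason, "zero_marginal")
})

test_that("pooling sums counts and preserves ratios for replicated genes", {
  df <- data.frame(Dn = c(1, 2), Ds = c(1, 2), Pn = c(1, 2), Ps = c(1, 2))
  expect_equal(pool_counts(df), c(Dn = 3, Ds = 3, Pn = 3, Ps = 3))
  expect_equal(pool_counts(df[0, ]), c(Dn = 0, Ds = 0, Pn = 0, Ps = 0))
  one <- data.frame(Dn = 6, Ds = 2, Pn = 3, Ps = 4)
  many <- one[rep(1, 7), ]
  p1 <- pool_counts(one); pk <- pool_counts(many)
  expect_equal(fixation_index(pk[1], pk[2], pk[3], pk[4]),
               fixation_index(p1[1], p1[2], p1[3], p1[4]))
})

test_that("NI_TG matches a hand computation and its degenerate cases", {
  one <- data.frame(Dn = 1, Ds = 1, Pn = 1, Ps = 1)
  expect_equal(neutrality_index_tg(one), 1)
  nopn <- data.frame(Dn = c(2, 3), Ds = c(1, 1), Pn = c(0, 0), Ps = c(2, 1))
  expect_equal(neutrality_index_tg(nopn), 0)
  # 3-gene toy set, spreadsheet-style evaluation:
  # gene A: Ds*Pn/(Ps+Ds) = 2*3/(4+2) = 1;       Dn*Ps/(Ps+Ds) = 5*4/6 = 10/3
  # gene B: 1*2/(2+1) = 2/3;                      4*2/3 = 8/3
  # gene C: 3*1/(1+3) = 3/4;                      2*1/4 = 1/2
  toy <- data.frame(Dn = c(5, 4, 2), Ds = c(2, 1, 3),
                    Pn = c(3, 2, 1), Ps = c(4, 2, 1))
  expect_equal(neutrality_index_tg(toy),
               (1 + 2 / 3 + 3 / 4) / (10 / 3 + 8 / 3 + 1 / 2))
  # genes with Ps + Ds = 0 are skipped
  toy2 <- rbind(toy, data.frame(Dn = 9, Ds = 0, Pn = 9, Ps = 0))
  expect_equal(neutrality_index_tg(toy2), neutrality_index_tg(toy))
  expect_true(is.na(neutrality_index_tg(toy2[4, ])))
})

test_that("mk_test assembles the statistic family with reason codes", {
  fit <- mk_test(c(13, 0), c(1, 2), c(5, 3), c(4, 4),
                 gene_id = c("FBF1-like", "noDn"))
  tab <- fit$table
  expect_s3_class(fit, "mk_test")
  expect_equal(tab$FI[1], 10.4)
  expect_equal(tab$alpha[1], 1 - 5 / 52)
  expect_true(is.na(tab$FI[2]))
  expect_match(tab$undefined_reason[2], "Dn_zero")
  expect_output(print(fit), "McDonald-Kreitman")
  expect_output(summary(fit), "Genes")
  expect_identical(as.data.frame(fit), tab)
})

test_that("stratum_summary pools within the polymorphic subset", {
  counts <- data.frame(gene_id = rep(c("gA", "gB", "gC"), each = 1),
                       branch = "human",
                       Dn = c(2, 4, 1), Ds = c(1, 2, 1))
  polys <- data.frame(gene_id = c("gA", "gB", "gC"),
                      stratum = "ge_0.01", type = "threshold",
                      lo = 0.01, hi = NA,
                      Pn = c(1, 2, 0), Ps = c(2, 3, 0))
  s <- stratum_summary(counts, polys,
                       sets = list(all = c("gA", "gB", "gC"),
                                   single = "gA"),
                       strata = "ge_0.01")
  # gC has no polymorphism and is excluded from n and the pooled counts
  expect_equal(s$n_genes[s$set_label == "all"], 2)
  expect_equal(s$Dn[s$set_label == "all"], 6)
  expect_equal(s$FI[s$set_label == "all"],
               fixation_index(6, 3, 3, 5))
  # a single-gene set reproduces that gene's statistics
  expect_equal(s$FI[s$set_label == "single"], fixation_index(2, 1, 1, 2))
  # empty set gives n = 0 and undefined statistics
  s0 <- stratum_summary(counts, polys, sets = list(none = character(0)),
                        strata = "ge_0.01")
  expect_equal(s0$n_genes, 0)
  expect_true(is.na(s0$FI))
})

test_that("mk_fdr is plain Benjamini-Hochberg, never applied implicitly", {
  p <- c(0.001, 0.02, 0.04, 0.5)
  expect_equal(mk_fdr(p), stats::p.adjust(p, "BH"))
  fit <- mk_test(13, 1, 5, 4)
  expect_false("p_adj" %in% names(fit$table))
})
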