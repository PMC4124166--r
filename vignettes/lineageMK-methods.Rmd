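---
title: "Detecting human-lineage positive selection with divergence and polymorphism data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting human-lineage positive selection with divergence and polymorphism data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageMK)
```

## The problem and the model

Positive selection on a protein-coding gene leaves two complementary traces:
an excess of non-synonymous substitutions *fixed* on the lineage of interest
(divergence), and a deficit of non-synonymous variants still *segregating*
in the population (polymorphism), because adaptive mutations fix quickly.
The McDonald-Kreitman (MK) framework contrasts the two on a 2x2 table per
gene. `lineageMK` implements this contrast for the human branch since the
human-chimpanzee split, on four-species codon alignments (human, chimpanzee,
macaque, mouse) together with human coding SNPs:

* **Dn, Ds** — non-synonymous and synonymous substitution counts assigned to
  the human branch;
* **Pn, Ps** — non-synonymous and synonymous polymorphic sites in humans;
* **fixation index** FI = (Dn/Ds)/(Pn/Ps), with NI = 1/FI its neutrality
  index;
* **direction of selection** DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps);
* **proportion of adaptive substitutions** α = 1 − (Ds·Pn)/(Dn·Ps);
* the MK independence test as a **G-test with the Williams continuity
  correction** (G/q, q ≥ 1, one degree of freedom).

Under strict neutrality FI = 1, DoS = 0 and α = 0; adaptive fixation pushes
FI above 1, segregating slightly deleterious variants push it below 1
because they inflate Pn without ever fixing. This motivates the central
stratification of the package: recomputing Pn and Ps only from SNPs above a
derived-allele-frequency (DAF) threshold (1%, 15%, 30%, 60%, and the
matching half-open interval classes) progressively removes the deleterious
class, so FI and α rise toward their adaptive values as the threshold rises.
Gene-set values pool the four counts over member genes (equivalent to a
concatenated alignment); the heterogeneity-robust pooled neutrality index

NI_TG = Σᵢ DsᵢPnᵢ/(Psᵢ+Dsᵢ) / Σᵢ DnᵢPsᵢ/(Psᵢ+Dsᵢ)

is also reported, because the plain pooled ratio can be dominated by a few
high-count genes.

```{r}
# the per-gene MK test on a published-style count table
mk_test(Dn = 13, Ds = 1, Pn = 5, Ps = 4, gene_id = "example")
```

## Branch-specific substitution counting

Divergence counts are obtained from the fixed ((human,chimp),macaque,mouse)
topology by nucleotide-level small parsimony. For every codon column that is
gap-free in all four species, all ancestral state assignments at the two
internal nodes attaining the minimal nucleotide change count are enumerated
(per-position Fitch parsimony composed per codon; assignments containing a
stop codon are dropped whenever a stop-free minimal assignment exists).
Changes on each of the five edges are decomposed into synonymous and
non-synonymous parts by Nei-Gojobori (1986) pathway averaging over minimal
stop-free mutational paths, and equally parsimonious assignments are
averaged with uniform weight, so Dn and Ds may be fractional. Site totals N
and S are NG86 fractional site counts computed from the human sequence
(the human branch is the object of inference), so ω = (Dn/N)/(Ds/S) is
interpretable per branch and N + S equals three times the number of columns
used.

This is a deterministic, auditable substitute for maximum-likelihood
free-ratio counting; ML counts computed externally can be imported through
`read_count_table()` so every downstream statistic remains available
unchanged. The substitution is accurate at primate divergences: on simulated
data the human-branch pooled counts agree with the generative truth to
within a fraction of a percent. Two caveats are documented rather than
hidden. First, exact per-family recovery requires divergence low enough that
multiple hits and parsimony ties are rare; at 0.005 substitutions per site
per branch about 95% of families are recovered exactly, while the long mouse
branch of the realistic tree is systematically undercounted (multiple hits)
— only totals, never the human-branch contrast, depend on it materially.
Second, equally parsimonious assignments are tie-averaged uniformly, which
is unbiased between the human and chimp branches but spreads weight across
branches where the data cannot distinguish them.

Quality control mirrors the study conditions: families are discarded when
any protein is not strictly longer than 100 aligned-ungapped amino acids, or
when ω exceeds 10 on the human, chimp or hominoid-ancestor branch (Ds = 0
with Dn > 0 counts as exceeding; Ds = Dn = 0 passes). A human-branch Dn
above 10 raises a *non-excluding* flag plus a misalignment heuristic (the
fraction of human-branch changes within five codons of an alignment gap), an
automated replacement for manual alignment inspection; exclusion is left to
the user.

## Polymorphism handling

SNPs are taken as CDS-relative records (1-based in files, 0-based
internally) with reference, alternate and ancestral alleles and the
alternate-allele frequency. The DAF is the frequency of the non-ancestral
allele; records whose ancestral allele is missing or matches neither
observed allele have no DAF and are excluded from DAF strata (they are
tallied, and retained in MAF mode — the only non-guessing option). Threshold
strata are closed below (DAF ≥ t), interval strata half-open [lo, hi);
sites with DAF = 1 are fixed, not polymorphic, and never counted.
Stop-gain/stop-loss changes are classified `other` and excluded from Pn, as
the MK table is about amino-acid replacements. Multi-allelic sites enter as
one record per alternate allele.

## The acceleration screen

A gene is called human-accelerated when a one-sided Fisher's exact test
finds an excess of Dn over Ds in the human branch relative to the
hominoid-ancestor branch (p < 0.05) but *not* in the chimp branch (the chimp
veto, same sidedness — a two-sided test would also trigger on chimp
deficits), and a neighbor-joining tree built from Jukes-Cantor distances
over the gap-free columns recovers human and chimp as sisters. Fractional
parsimony counts are rounded half-to-even before the exact test. The dual
test is deliberately conservative: on fully neutral simulations it flags
about 3% of genes at the 5% level. A rate-matched control set is drawn by
binning human-branch ω into width-0.1 bins (open-ended above 1) and sampling
non-accelerated genes with the same bin profile, verified by a rank-sum test
(p > 0.05) with bounded resampling; bins short of members borrow from the
nearest bins, with a warning.

The branch-site likelihood-ratio test is *not* reimplemented; its p-values
are importable and `mk_fdr()` applies Benjamini-Hochberg correction to them
explicitly — no operation in the package adjusts p-values silently.

## Functional groups

Per-gene FI comparisons are restricted to informative genes (Dn, Ds, Pn, Ps
all non-zero and Pn + Ps ≥ 4; below that, per-gene FI is too unstable to
rank). GO groups with at least 40 informative genes are analysed, plus the
reserved group of genes with no annotation. Each group's FI distribution is
compared with the background by a Wilcoxon-Mann-Whitney test; the one-sided
(greater) p-value is reported only when the group median exceeds the
background median, and suppressed otherwise. The background includes the
group by default (comparison against "all genes"), with exclusion available.
Category enrichment within a gene set is an exact one-sided binomial test of
the observed category count against the background frequency (a
normal-approximation proportion test is available for comparison).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
full ground-truth bookkeeping, and stands in for the ortholog and SNP
catalogues that cannot be redistributed. Codon families evolve on the fixed
guide tree ((human 0.01, chimp 0.01) 0.03, macaque 0.04, mouse 0.32)
(expected neutral mutation events per nucleotide site). Root codons are
uniform over the 61 sense codons; candidate changes draw a uniform site and
a kappa-weighted alternative nucleotide (κ = 2), stop-creating candidates
are redrawn, synonymous candidates always fix, non-synonymous candidates fix
with probability min(1, ω). The default ω = 0.22 and 415 codons per gene
put the mean human-branch Dn near 2 and Ds near 3.5, the scale of the real
filtered ortholog set; `theta_syn = 2` synonymous SNPs per gene matches its
observed synonymous SNP density.

Polymorphism is generated directly as (site, allele, class, DAF) records
rather than via a coalescent — the analysis consumes nothing else. The
neutral non-synonymous SNP rate is tied to the divergence process:
`theta_syn · ω_human · Qn/Qs`, where Qn/Qs is the kappa-weighted mutational
non-synonymous/synonymous opportunity of the gene's human CDS. This coupling
is what makes the fully neutral configuration satisfy E[FI] = 1 by
construction. Deleterious non-synonymous SNPs are added at the configured
mixture fraction with DAF from a low-frequency Beta(1, 9); neutral DAF is
uniform, both truncated to [0.01, 0.99] to mirror the MAF ≥ 1% ascertainment
of the common-SNP catalogues the field uses. The uniform neutral DAF is a
deliberate simplification: a real site-frequency spectrum is skewed low even
after ascertainment, but only the *relative* DAF placement of the classes
matters to the stratified statistics, and a flat neutral spectrum keeps
every stratum informative.

Adaptive evolution is injected on the human branch only, never as
polymorphism (adaptive mutations fix too fast to segregate): after each
realized neutral non-synonymous change, a Geometric(1 −
`frac_substitutions_adaptive`) number of extra forced non-synonymous changes
is applied and logged, so the expected adaptive fraction of human-branch
non-synonymous substitutions — the generative α — equals the configured
value exactly. Each gene index derives its own RNG stream from the master
seed, so datasets are reproducible record-for-record and rerunning a
configuration rewrites byte-identical files.

What passing simulation tests does and does not show: the generator has no
linkage, demography, codon-usage bias, site-rate heterogeneity or
CpG-hypermutability, so recovery on simulated data validates the *counting
and statistics*, not robustness to those real-data complications.

## Numerical and design choices

* **Undefined values are values**: FI is `NA` with a reason code when any of
  the four counts is zero (never 0 or ∞); α needs Dn > 0 and Ps > 0; the
  G-test needs all four marginals positive. Pooled set statistics avoid the
  issue by summing first. Zero cells contribute 0 to G (lim x·log x = 0), no
  pseudocounts — this reproduces published worked examples exactly.
* **Coordinates**: 0-based half-open internally, 1-based in files.
* **Gaps** must be whole codons; any column with a gap (or ambiguity code)
  in any species is excluded from counting — partial-codon gaps indicate a
  frame error upstream and are hard errors.
* **Round-trips**: numeric table columns are serialised at 17 significant
  digits so write-then-read reproduces doubles exactly.
* **Tie-breaking** in ancestral reconstruction is uniform averaging;
  rounding of fractional counts (half-to-even) happens only at the Fisher
  test and on output.
* **Problem sizes**: the validation suite simulates 500 genes for
  calibration runs, 1,500 codons per gene with `theta_syn = 8`. The gene
  count matches the scaled study conditions; the per-gene information is
  deliberately larger than the default preset so that the binomial
  sampling error of pooled FI (SE ≈ 0.03) is small against the ±0.1
  calibration band — more information per gene cannot mask a genuine bias,
  it exposes it. The default preset itself (415 codons, θ = 2) is kept
  for scale-realistic examples and the substitution-mean checks.
* **Monotonicity across DAF strata** is asserted strictly where the
  deleterious DAF mass actually differs between thresholds (1% → 15% → 30%)
  and as a plateau within sampling error beyond, because Beta(1, 9) leaves
  essentially no deleterious mass above 30% — the same plateau the real
  stratified tables show at high DAF.

## Known limitations

Parsimony counting undercounts the long mouse branch (multiple hits) and
cannot resolve genuinely tied ancestral assignments; both effects are
quantified above and leave the human-branch contrast essentially unbiased at
primate divergences, but per-branch ω on the mouse side should be read as a
lower bound. The NJ topology check uses Jukes-Cantor distances on
concatenated gap-free columns; genes with almost no signal return the
expected topology by convention (flagged). The generator's DAF model is a
two-class Beta mixture, not a demographic model. GO annotations are taken as
a flat table; no ontology propagation is performed.
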