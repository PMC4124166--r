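## Seeded generator of codon alignments evolved on the fixed four-taxon tree
## with branch-specific omega, and of coding polymorphism with neutral /
## deleterious classes and class-specific DAF distributions, with full
## ground-truth bookkeeping. Codons are handled as integer indices into
## precomputed single-nucleotide mutant tables, so the event loop is cheap.

.SENSE_IDX <- which(.CODONS %in% .SENSE)

## Mutant lookup tables: dimension [codon 1..64, position 1..3, alternative
## 1..3]. .MUT_NEW = resulting codon index; .MUT_SYN = synonymous;
## .MUT_STOP = creates a stop; .MUT_TRS = transition; .MUT_ALT = alt
## nucleotide.
.MUT <- local({
  new <- array(NA_integer_, c(64, 3, 3))
  syn <- array(NA, c(64, 3, 3))
  stp <- array(NA, c(64, 3, 3))
  trs <- array(NA, c(64, 3, 3))
  alt <- array(NA_character_, c(64, 3, 3))
  for (i in seq_along(.CODONS)) {
    cod <- .CODONS[i]
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      alts <- setdiff(.NT, ref)
      for (k in 1:3) {
        mut <- .mutate_codon(cod, p, alts[k])
        j <- match(mut, .CODONS)
        new[i, p, k] <- j
        stp[i, p, k] <- .is_stop(mut)
        syn[i, p, k] <- !stp[i, p, k] && !.is_stop(cod) &&
          .CODON_AA[[mut]] == .CODON_AA[[cod]]
        trs[i, p, k] <- .is_transition(ref, alts[k])
        alt[i, p, k] <- alts[k]
      }
    }
  }
  list(new = new, syn = syn, stop = stp, trs = trs, alt = alt)
})

#' Simulation configuration
#'
#' Defaults are realistic human-lineage study conditions: guide-tree branch lengths
#' ((human 0.01, chimp 0.01) 0.03, macaque 0.04, mouse 0.32) expected
#' substitutions per nucleotide site, a genome-wide purifying omega of 0.22
#' and 415 codons per gene (together these put the mean human-branch Dn near
#' 2 and Ds near 3.5), about 2 synonymous SNPs per gene, uniform derived
#' allele frequencies for neutral variants and a low-frequency Beta(1, 9) for
#' deleterious ones, both truncated to \[0.01, 0.99\] to mirror the MAF >= 1%
#' ascertainment of the common-SNP catalogues.
#'
#' @param n_genes Number of gene families.
#' @param codons_per_gene Codon columns per family.
#' @param branch_lengths Named vector (`human`, `chimp`,
#'   `hominoid_ancestor`, `macaque`, `mouse`), expected neutral mutation
#'   events per nucleotide site.
#' @param branch_omega Named vector of per-branch omega (acceptance
#'   probability of non-synonymous candidate changes, capped at 1).
#' @param kappa Transition/transversion rate ratio.
#' @param theta_syn Expected synonymous SNPs per gene.
#' @param frac_nonsyn_neutral,frac_nonsyn_deleterious Class fractions of
#'   non-synonymous SNPs; must sum to 1.
#' @param frac_substitutions_adaptive Target fraction of human-branch
#'   non-synonymous substitutions that are adaptive (the generative alpha);
#'   adaptive changes are injected as extra forced non-synonymous human-branch
#'   substitutions and never as polymorphism.
#' @param daf_neutral,daf_deleterious `c(shape1, shape2)` of the Beta DAF
#'   distributions of the neutral and deleterious classes.
#' @param frac_ref_derived Fraction of SNP records written with the sampled
#'   (reference) allele as the derived one (ancestral = alt).
#' @param frac_ancestral_missing Fraction of SNP records written without an
#'   ancestral-allele call.
#' @param seed Integer master seed; each gene index derives its own stream.
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       codons_per_gene = 415L,
                       branch_lengths = c(human = 0.01, chimp = 0.01,
                                          hominoid_ancestor = 0.03,
                                          macaque = 0.04, mouse = 0.32),
                       branch_omega = c(human = 0.22, chimp = 0.22,
                                        hominoid_ancestor = 0.22,
                                        macaque = 0.22, mouse = 0.22),
                       kappa = 2,
                       theta_syn = 2,
                       frac_nonsyn_neutral = 1,
                       frac_nonsyn_deleterious = 0,
                       frac_substitutions_adaptive = 0,
                       daf_neutral = c(1, 1),
                       daf_deleterious = c(1, 9),
                       frac_ref_derived = 0.25,
                       frac_ancestral_missing = 0,
                       seed = 1L) {
  stopifnot(n_genes >= 1, codons_per_gene >= 1,
            all(.BRANCHES %in% names(branch_lengths)),
            all(.BRANCHES %in% names(branch_omega)),
            all(branch_lengths >= 0), all(branch_omega >= 0),
            kappa > 0, theta_syn >= 0,
            frac_nonsyn_neutral >= 0, frac_nonsyn_deleterious >= 0,
            abs(frac_nonsyn_neutral + frac_nonsyn_deleterious - 1) < 1e-12,
            frac_nonsyn_deleterious < 1,
            frac_substitutions_adaptive >= 0,
            frac_substitutions_adaptive < 1,
            frac_ref_derived >= 0, frac_ref_derived <= 1,
            frac_ancestral_missing >= 0, frac_ancestral_missing <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 codons_per_gene = as.integer(codons_per_gene),
                 branch_lengths = branch_lengths[.BRANCHES],
                 branch_omega = branch_omega[.BRANCHES],
                 kappa = kappa, theta_syn = theta_syn,
                 frac_nonsyn_neutral = frac_nonsyn_neutral,
                 frac_nonsyn_deleterious = frac_nonsyn_deleterious,
                 frac_substitutions_adaptive = frac_substitutions_adaptive,
                 daf_neutral = daf_neutral,
                 daf_deleterious = daf_deleterious,
                 frac_ref_derived = frac_ref_derived,
                 frac_ancestral_missing = frac_ancestral_missing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.gene_seed <- function(config, gene_index, offset) {
  as.integer(((as.numeric(config$seed) %% 100000) * 20011 +
                gene_index * 7919 + offset) %% 2147483647)
}

## one kappa-weighted, stop-avoiding candidate mutation; returns c(ci, new)
.draw_mutation <- function(codons, kappa) {
  L <- length(codons)
  repeat {
    ci <- sample.int(L, 1L)
    p <- sample.int(3L, 1L)
    idx <- codons[ci]
    w <- ifelse(.MUT$trs[idx, p, ], kappa, 1)
    k <- sample.int(3L, 1L, prob = w)
    if (!.MUT$stop[idx, p, k])
      return(c(ci = ci, new = .MUT$new[idx, p, k],
               syn = as.integer(.MUT$syn[idx, p, k])))
  }
}

## evolve a codon vector along one branch; adaptive_frac injects extra forced
## non-synonymous changes after each realized neutral non-synonymous change so
## that E[adaptive / total nonsyn] = adaptive_frac
.evolve_branch <- function(codons, bl, omega, kappa, adaptive_frac = 0) {
  dn <- 0L; ds <- 0L; n_adapt <- 0L
  n_events <- stats::rpois(1, bl * 3 * length(codons))
  for (e in seq_len(n_events)) {
    m <- .draw_mutation(codons, kappa)
    if (m[["syn"]] == 1L) {
      codons[m[["ci"]]] <- m[["new"]]
      ds <- ds + 1L
    } else if (stats::runif(1) < min(1, omega)) {
      codons[m[["ci"]]] <- m[["new"]]
      dn <- dn + 1L
      if (adaptive_frac > 0) {
        extra <- stats::rgeom(1, 1 - adaptive_frac)
        for (j in seq_len(extra)) {
          repeat {
            a <- .draw_mutation(codons, kappa)
            if (a[["syn"]] == 0L) break
          }
          codons[a[["ci"]]] <- a[["new"]]
          dn <- dn + 1L
          n_adapt <- n_adapt + 1L
        }
      }
    }
  }
  list(codons = codons, Dn = dn, Ds = ds, adaptive = n_adapt)
}

#' Simulate one gene family on the fixed four-taxon tree
#'
#' Root codons are drawn uniformly from the sense codons; each branch
#' receives Poisson(branch length x 3 x codons) candidate mutation events,
#' kappa-weighted over the three alternatives at a uniformly drawn site.
#' Stop-creating candidates are redrawn, synonymous candidates are always
#' accepted and non-synonymous candidates are accepted with probability
#' min(1, omega). Adaptive substitutions are injected on the human branch
#' only (see [sim_config()]). All realized changes are logged per branch.
#'
#' @param config A [sim_config()].
#' @param gene_index Gene index (drives the per-gene RNG stream).
#' @return list `family` (a [gene_family()]) and `truth` (data.frame
#'   `gene_id`, `branch`, `Dn`, `Ds`, `adaptive`).
#' @export
simulate_codon_evolution <- function(config, gene_index) {
  set.seed(.gene_seed(config, gene_index, 0L))
  gid <- sprintf("g%04d", gene_index)
  L <- config$codons_per_gene
  bl <- config$branch_lengths
  om <- config$branch_omega
  root <- .SENSE_IDX[sample.int(length(.SENSE_IDX), L, replace = TRUE)]
  anc <- .evolve_branch(root, bl[["hominoid_ancestor"]],
                        om[["hominoid_ancestor"]], config$kappa)
  hum <- .evolve_branch(anc$codons, bl[["human"]], om[["human"]],
                        config$kappa, config$frac_substitutions_adaptive)
  chi <- .evolve_branch(anc$codons, bl[["chimp"]], om[["chimp"]],
                        config$kappa)
  mac <- .evolve_branch(root, bl[["macaque"]], om[["macaque"]], config$kappa)
  mou <- .evolve_branch(root, bl[["mouse"]], om[["mouse"]], config$kappa)
  tostr <- function(idx) paste(.CODONS[idx], collapse = "")
  fam <- gene_family(gid, c(human = tostr(hum$codons),
                            chimp = tostr(chi$codons),
                            macaque = tostr(mac$codons),
                            mouse = tostr(mou$codons)))
  res <- list(hum, chi, anc, mac, mou)
  truth <- data.frame(gene_id = gid, branch = .BRANCHES,
                      Dn = vapply(res, `[[`, integer(1), "Dn"),
                      Ds = vapply(res, `[[`, integer(1), "Ds"),
                      adaptive = vapply(res, `[[`, integer(1), "adaptive"),
                      stringsAsFactors = FALSE)
  list(family = fam, truth = truth)
}

## site-level mutational opportunity of a CDS (integer codon vector):
## data.frame of all single-nucleotide changes with kappa weight and class
.cds_proposals <- function(codons, kappa) {
  L <- length(codons)
  grid <- expand.grid(ci = seq_len(L), p = 1:3, k = 1:3)
  at <- cbind(codons[grid$ci], grid$p, grid$k)
  data.frame(ci = grid$ci, p = grid$p, k = grid$k,
             w = ifelse(.MUT$trs[at], kappa, 1),
             syn = .MUT$syn[at], stop = .MUT$stop[at],
             alt = .MUT$alt[at], stringsAsFactors = FALSE)
}

.rbeta_trunc <- function(n, shape, lo = 0.01, hi = 0.99) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rbeta(1, shape[1], shape[2])
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Simulate coding polymorphism for one gene
#'
#' Produces SNP records on the gene's human CDS. Synonymous SNP counts are
#' Poisson(`theta_syn`); neutral non-synonymous SNPs arrive at rate
#' `theta_syn * omega_human * Qn/Qs`, where Qn/Qs is the kappa-weighted
#' mutational non-synonymous/synonymous opportunity ratio of the CDS — the
#' same thinning the divergence process applies, so a fully neutral
#' configuration has expected pooled FI of 1. Deleterious non-synonymous
#' SNPs are added so that their expected share of non-synonymous SNPs equals
#' `frac_nonsyn_deleterious`, with DAF drawn from the low-frequency class
#' distribution. Sites and alternate alleles are drawn from the
#' class-compatible proposals of the CDS; the ancestral allele is recorded so
#' the DAF is exactly recoverable.
#'
#' @param config A [sim_config()].
#' @param gene_index Gene index.
#' @param human_cds Ungapped human CDS string (as from the matching
#'   [simulate_codon_evolution()] call).
#' @return list `snps` (data.frame in the [read_snp_table()] layout plus
#'   nothing else) and `truth` (data.frame `gene_id`, `cds_pos0`, `class`
#'   with class `neutral_syn`, `neutral_nonsyn` or `deleterious`, and `daf`).
#' @export
simulate_polymorphism <- function(config, gene_index, human_cds) {
  set.seed(.gene_seed(config, gene_index, 1L))
  gid <- sprintf("g%04d", gene_index)
  codons <- match(substring(human_cds, seq(1, nchar(human_cds), 3),
                            seq(3, nchar(human_cds), 3)), .CODONS)
  props <- .cds_proposals(codons, config$kappa)
  syn_p <- props[props$syn, , drop = FALSE]
  non_p <- props[!props$syn & !props$stop, , drop = FALSE]
  Qs <- sum(syn_p$w); Qn <- sum(non_p$w)
  omega_h <- min(1, config$branch_omega[["human"]])
  mu_s <- config$theta_syn
  mu_nn <- if (Qs > 0) config$theta_syn * omega_h * Qn / Qs else 0
  fd <- config$frac_nonsyn_deleterious
  mu_nd <- if (fd > 0) mu_nn * fd / (1 - fd) else 0
  n_s <- stats::rpois(1, mu_s)
  n_nn <- stats::rpois(1, mu_nn)
  n_nd <- stats::rpois(1, mu_nd)
  draw <- function(pool, n, shape, class) {
    if (n == 0 || nrow(pool) == 0)
      return(NULL)
    rows <- pool[sample.int(nrow(pool), n, replace = TRUE,
                            prob = pool$w), , drop = FALSE]
    daf <- .rbeta_trunc(n, shape)
    pos0 <- (rows$ci - 1L) * 3L + rows$p - 1L
    data.frame(gene_id = gid, cds_pos0 = pos0,
               ref = substring(human_cds, pos0 + 1, pos0 + 1),
               alt = rows$alt, daf = daf, class = class,
               stringsAsFactors = FALSE)
  }
  snps <- rbind(draw(syn_p, n_s, config$daf_neutral, "neutral_syn"),
                draw(non_p, n_nn, config$daf_neutral, "neutral_nonsyn"),
                draw(non_p, n_nd, config$daf_deleterious, "deleterious"))
  if (is.null(snps) || nrow(snps) == 0) {
    empty <- data.frame(gene_id = character(0), cds_pos0 = integer(0),
                        ref = character(0), alt = character(0),
                        ancestral = character(0), alt_freq = numeric(0),
                        daf = numeric(0), daf_undefined = logical(0),
                        maf = numeric(0), stringsAsFactors = FALSE)
    return(list(snps = empty,
                truth = data.frame(gene_id = character(0),
                                   cds_pos0 = integer(0),
                                   class = character(0), daf = numeric(0),
                                   stringsAsFactors = FALSE)))
  }
  n <- nrow(snps)
  missing_anc <- stats::runif(n) < config$frac_ancestral_missing
  flipped <- !missing_anc & stats::runif(n) < config$frac_ref_derived
  snps$ancestral <- ifelse(missing_anc, NA_character_,
                           ifelse(flipped, snps$alt, snps$ref))
  snps$alt_freq <- ifelse(flipped, 1 - snps$daf, snps$daf)
  out <- data.frame(gene_id = snps$gene_id, cds_pos0 = snps$cds_pos0,
                    ref = snps$ref, alt = snps$alt,
                    ancestral = snps$ancestral, alt_freq = snps$alt_freq,
                    stringsAsFactors = FALSE)
  out$daf <- ifelse(!is.na(out$ancestral) & out$ancestral == out$ref,
                    out$alt_freq,
                    ifelse(!is.na(out$ancestral) & out$ancestral == out$alt,
                           1 - out$alt_freq, NA_real_))
  out$daf_undefined <- is.na(out$daf)
  out$maf <- pmin(out$alt_freq, 1 - out$alt_freq)
  truth <- data.frame(gene_id = snps$gene_id, cds_pos0 = snps$cds_pos0,
                      class = snps$class, daf = snps$daf,
                      stringsAsFactors = FALSE)
  list(snps = out, truth = truth)
}

#' Simulate a full dataset, optionally writing all pipeline input files
#'
#' Generates `n_genes` families and their polymorphism, with per-gene seeded
#' RNG streams so reruns (and partial reruns) are reproducible. With `dir`
#' set, writes `alignments.fasta`, `manifest.tsv`, `snps.tsv`,
#' `truth_branch.tsv`, `truth_snps.tsv` and a plain-text `sim_manifest.txt`
#' recording the configuration; outputs are byte-identical across reruns of
#' the same configuration.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed) or `NULL` for in-memory
#'   only.
#' @return (Invisibly when writing) list `families`, `snps`, `truth_branch`,
#'   `truth_snps`, `true_alpha_human` (aggregate adaptive fraction of
#'   human-branch non-synonymous substitutions), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  families <- vector("list", config$n_genes)
  truth_b <- vector("list", config$n_genes)
  snps <- vector("list", config$n_genes)
  truth_s <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    ev <- simulate_codon_evolution(config, i)
    families[[i]] <- ev$family
    truth_b[[i]] <- ev$truth
    pm <- simulate_polymorphism(config, i, family_cds(ev$family, "human"))
    snps[[i]] <- pm$snps
    truth_s[[i]] <- pm$truth
  }
  names(families) <- vapply(families, `[[`, character(1), "gene_id")
  truth_b <- do.call(rbind, truth_b)
  snps <- do.call(rbind, snps)
  truth_s <- do.call(rbind, truth_s)
  hum <- truth_b[truth_b$branch == "human", ]
  true_alpha <- if (sum(hum$Dn) > 0) sum(hum$adaptive) / sum(hum$Dn)
  else NA_real_
  out <- list(families = families, snps = snps, truth_branch = truth_b,
              truth_snps = truth_s, true_alpha_human = true_alpha,
              config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    recs <- do.call(c, unname(lapply(families, function(f)
      stats::setNames(as.list(f$sequences),
                      paste0(f$gene_id, "|", names(f$sequences))))))
    seqinr::write.fasta(lapply(recs, function(s) strsplit(s, "")[[1]]),
                        names = names(recs),
                        file.out = file.path(dir, "alignments.fasta"),
                        nbchar = 60)
    manifest <- do.call(rbind, lapply(families, function(f)
      data.frame(record_id = paste0(f$gene_id, "|", .SPECIES),
                 gene_id = f$gene_id, species = .SPECIES,
                 stringsAsFactors = FALSE)))
    .write_tsv(manifest, file.path(dir, "manifest.tsv"))
    write_snp_table(snps, file.path(dir, "snps.tsv"))
    .write_tsv(truth_b, file.path(dir, "truth_branch.tsv"))
    .write_tsv(truth_s, file.path(dir, "truth_snps.tsv"))
    cfg <- config
    cfglines <- c(
      sprintf("n_genes=%d", cfg$n_genes),
      sprintf("codons_per_gene=%d", cfg$codons_per_gene),
      sprintf("branch_lengths=%s",
              paste(sprintf("%s:%g", names(cfg$branch_lengths),
                            cfg$branch_lengths), collapse = ",")),
      sprintf("branch_omega=%s",
              paste(sprintf("%s:%g", names(cfg$branch_omega),
                            cfg$branch_omega), collapse = ",")),
      sprintf("kappa=%g", cfg$kappa),
      sprintf("theta_syn=%g", cfg$theta_syn),
      sprintf("frac_nonsyn_neutral=%g", cfg$frac_nonsyn_neutral),
      sprintf("frac_nonsyn_deleterious=%g", cfg$frac_nonsyn_deleterious),
      sprintf("frac_substitutions_adaptive=%g",
              cfg$frac_substitutions_adaptive),
      sprintf("daf_neutral=%g,%g", cfg$daf_neutral[1], cfg$daf_neutral[2]),
      sprintf("daf_deleterious=%g,%g", cfg$daf_deleterious[1],
              cfg$daf_deleterious[2]),
      sprintf("frac_ref_derived=%g", cfg$frac_ref_derived),
      sprintf("frac_ancestral_missing=%g", cfg$frac_ancestral_missing),
      sprintf("seed=%d", cfg$seed),
      sprintf("true_alpha_human=%.10g", true_alpha))
    writeLines(cfglines, file.path(dir, "sim_manifest.txt"))
    return(invisible(out))
  }
  out
}
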