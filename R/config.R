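## Analysis configuration.

#' Analysis configuration for DAF stratification and quality filtering
#'
#' Defaults reproduce the study conditions: derived-allele-frequency
#' thresholds 1%, 15%, 30%, 60%; interval strata \[1,15), \[15,30), \[30,60),
#' \[60,100) (in percent); minimum protein length 100 amino acids (strictly
#' longer required); maximum branch dN/dS of 10; significance level 0.05.
#'
#' @param daf_thresholds Strictly increasing frequencies in (0, 1].
#' @param daf_intervals List of `c(lo, hi)` half-open frequency intervals,
#'   non-overlapping and ordered.
#' @param min_protein_len Proteins must be strictly longer than this (aa).
#' @param max_dnds Families with branch dN/dS above this are discarded.
#' @param significance_level Nominal test level.
#' @param random_seed Seed used by sampling operations.
#' @param frequency_mode `"DAF"` (derived allele frequency; records without a
#'   resolvable ancestral allele are excluded) or `"MAF"` (minor allele
#'   frequency; all records kept).
#' @return An object of class `"mk_config"`.
#' @export
analysis_config <- function(daf_thresholds = c(0.01, 0.15, 0.30, 0.60),
                            daf_intervals = list(c(0.01, 0.15),
                                                 c(0.15, 0.30),
                                                 c(0.30, 0.60),
                                                 c(0.60, 1.00)),
                            min_protein_len = 100L,
                            max_dnds = 10,
                            significance_level = 0.05,
                            random_seed = 1L,
                            frequency_mode = c("DAF", "MAF")) {
  frequency_mode <- match.arg(frequency_mode)
  stopifnot(all(daf_thresholds > 0), all(daf_thresholds <= 1),
            !is.unsorted(daf_thresholds, strictly = TRUE),
            min_protein_len > 0, max_dnds > 0,
            significance_level > 0, significance_level < 1)
  lo <- vapply(daf_intervals, `[`, numeric(1), 1)
  hi <- vapply(daf_intervals, `[`, numeric(1), 2)
  if (any(hi <= lo) || is.unsorted(lo, strictly = TRUE) ||
      any(lo[-1] < hi[-length(hi)]))
    stop("analysis_config: intervals must be ordered and non-overlapping")
  structure(list(daf_thresholds = daf_thresholds,
                 daf_intervals = daf_intervals,
                 min_protein_len = as.integer(min_protein_len),
                 max_dnds = max_dnds,
                 significance_level = significance_level,
                 random_seed = as.integer(random_seed),
                 frequency_mode = frequency_mode),
            class = "mk_config")
}

#' @export
print.mk_config <- function(x, ...) {
  cat("mk_config:",
      "\n  frequency mode   :", x$frequency_mode,
      "\n  thresholds       :", paste0(">=", 100 * x$daf_thresholds, "%",
                                       collapse = " "),
      "\n  intervals        :",
      paste(vapply(x$daf_intervals, function(iv)
        sprintf("[%g%%,%g%%)", 100 * iv[1], 100 * iv[2]), character(1)),
        collapse = " "),
      "\n  min protein len  : >", x$min_protein_len, "aa",
      "\n  max dN/dS        :", x$max_dnds,
      "\n  significance     :", x$significance_level, "\n")
  invisible(x)
}
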