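#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic locus. Conditional on the observed
#' allele counts, the number of heterozygotes `n_Aa` under Hardy-Weinberg
#' equilibrium follows the Levene distribution; the p-value is the sum of
#' the probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed configuration (full enumeration, no
#' approximation).
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts.
#' @return The exact two-sided p-value, or `NA` when no individuals are
#'   genotyped.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(NA_real_)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  js <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) -
    lfactorial((nA - js) / 2) - lfactorial(js) - lfactorial((na - js) / 2) +
    js * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(logp)
  obs <- pr[match(n_Aa, js)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Per-population HWE exact p-values for every locus: loci x pops matrix.
hwe_pvalue_matrix <- function(ds) {
  pops <- pop_levels(ds)
  L <- n_loci(ds)
  out <- matrix(NA_real_, L, length(pops),
                dimnames = list(ds$loci$locus_id, pops))
  for (k in seq_along(pops)) {
    d <- ds$dosage[ds$pop == pops[k], , drop = FALSE]
    nAA <- colSums(d == 2L, na.rm = TRUE)
    nAa <- colSums(d == 1L, na.rm = TRUE)
    naa <- colSums(d == 0L, na.rm = TRUE)
    for (j in seq_len(L)) {
      if (nAA[j] + nAa[j] + naa[j] > 0) {
        out[j, k] <- hwe_exact_pvalue(nAA[j], nAa[j], naa[j])
      }
    }
  }
  out
}
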