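#' Weir-Cockerham F-statistics
#'
#' Per-locus variance components `a` (among populations), `b` (among
#' individuals within populations), and `c` (within individuals) of the
#' two-allele Weir-Cockerham theta estimator with unequal sample sizes, and
#' the multi-locus ratio-of-sums estimate
#' `theta = sum(a) / sum(a + b + c)`. A locus contributes only when at
#' least two of the requested populations have a genotyped individual;
#' loci whose components are undefined (e.g. a single genotyped individual
#' everywhere) are reported as `NA` and excluded from the sums. Negative
#' components and negative theta are reported as computed, not truncated.
#'
#' @param ds A [genotype_dataset()].
#' @param pops Populations to include (default: all, in order of first
#'   appearance). At least two are required.
#' @return An object of class `fst_table`: list with `components` (data
#'   frame `locus_id`, `a`, `b`, `c`, `theta`), `theta_multi`, and `pops`.
#' @export
wc_theta <- function(ds, pops = pop_levels(ds)) {
  if (length(pops) < 2) stop("wc_theta needs at least two populations")
  st <- pop_locus_stats(ds, pops)
  comp <- wc_components(st$n, st$p, st$het)
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  theta_multi <- if (any(ok) && denom != 0) sum(comp$a[ok]) / denom else NA_real_
  structure(list(components = data.frame(locus_id = ds$loci$locus_id,
                                         a = comp$a, b = comp$b, c = comp$c,
                                         theta = comp$theta,
                                         stringsAsFactors = FALSE),
                 theta_multi = theta_multi, pops = pops),
            class = "fst_table")
}

# Vectorized Weir-Cockerham components from per-locus, per-population
# matrices of sample size n, allele frequency p, and heterozygote fraction h.
wc_components <- function(n, p, h) {
  use <- n > 0 & !is.na(p)
  n0 <- ifelse(use, n, 0)
  r <- rowSums(use)
  ntot <- rowSums(n0)
  nbar <- ntot / r
  np <- ifelse(use, n0 * p, 0)
  pbar <- rowSums(np) / ntot
  s2 <- rowSums(ifelse(use, n0 * (p - pbar)^2, 0)) / ((r - 1) * nbar)
  hbar <- rowSums(ifelse(use, n0 * h, 0)) / ntot
  nc <- (ntot - rowSums(n0^2) / ntot) / (r - 1)
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  theta <- ifelse(is.finite(a) & (a + b + cc) != 0, a / (a + b + cc), NA_real_)
  list(a = a, b = b, c = cc, theta = theta)
}

#' @export
print.fst_table <- function(x, ...) {
  cat(sprintf("fst_table: %d loci, %d populations (%s)\n",
              nrow(x$components), length(x$pops),
              paste(x$pops, collapse = ", ")))
  cat(sprintf("multi-locus theta (ratio of sums): %.4f\n", x$theta_multi))
  invisible(x)
}

#' Pairwise multi-locus FST matrix
#'
#' @param ds A [genotype_dataset()].
#' @return Symmetric matrix of pairwise multi-locus Weir-Cockerham theta;
#'   diagonal is `NA`.
#' @export
pairwise_fst_matrix <- function(ds) {
  pops <- pop_levels(ds)
  K <- length(pops)
  m <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  st <- pop_locus_stats(ds, pops)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      comp <- wc_components(st$n[, c(i, j), drop = FALSE],
                            st$p[, c(i, j), drop = FALSE],
                            st$het[, c(i, j), drop = FALSE])
      ok <- is.finite(comp$a)
      denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
      m[i, j] <- m[j, i] <- if (any(ok) && denom != 0) sum(comp$a[ok]) / denom else NA_real_
    }
  }
  m
}

#' Observed and expected heterozygosity
#'
#' Per population: observed heterozygosity `H_O` (heterozygote fraction
#' among genotyped individuals) and expected heterozygosity
#' `H_E = 1 - p^2 - q^2`, per locus and averaged over the loci with at
#' least one genotyped individual in that population.
#'
#' @param ds A [genotype_dataset()].
#' @return List with `per_pop` (data frame `pop`, `H_O`, `H_E`, `n_loci`)
#'   and `per_locus` (list of loci x populations matrices `H_O`, `H_E`).
#' @export
heterozygosity <- function(ds) {
  st <- pop_locus_stats(ds)
  he <- 1 - st$p^2 - (1 - st$p)^2
  per_pop <- data.frame(
    pop = colnames(st$n),
    H_O = colMeans(ifelse(st$n > 0, st$het, NA), na.rm = TRUE),
    H_E = colMeans(ifelse(st$n > 0, he, NA), na.rm = TRUE),
    n_loci = colSums(st$n > 0),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_pop = per_pop, per_locus = list(H_O = st$het, H_E = he))
}

#' Flag high-FST loci by empirical quantile
#'
#' Flags loci whose per-locus theta lies strictly above the empirical
#' `q`-quantile (nearest-rank) of the per-locus theta distribution. This is
#' an empirical-quantile outlier utility, not a coalescent-model outlier
#' test: it has no null model and simply ranks the observed distribution.
#'
#' @param fst_table An [wc_theta()] result.
#' @param q Quantile in (0, 1].
#' @return Character vector of flagged locus IDs.
#' @export
flag_fst_outliers_quantile <- function(fst_table, q = 0.95) {
  theta <- fst_table$components$theta
  ok <- is.finite(theta)
  if (sum(ok) < 20) stop("need at least 20 loci with defined theta")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  s <- sort(theta[ok])
  thr <- s[ceiling(q * length(s))]
  ids <- fst_table$components$locus_id[ok & theta > thr]
  sort(ids)
}
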