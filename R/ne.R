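#' Composite (Burrows) r-squared for one locus pair
#'
#' Phase-free LD between two loci in one population, computed over the
#' individuals genotyped at both loci: the composite Burrows disequilibrium
#' `Delta = cov(g_A, g_B) / 2` (sample covariance of the dosage vectors,
#' divisor `S - 1`), standardized by the Burrows variance product
#' `r2 = Delta^2 / ((p(1-p) + D_A)(q(1-q) + D_B))`, where
#' `D_A = P_AA - p^2` is the within-locus homozygote-excess
#' (Hardy-Weinberg) disequilibrium and `p`, `q`, `P_AA` are computed from
#' the same co-genotyped individuals; the result is capped at 1. The
#' homozygote-excess term in the denominator matches the finite-sample
#' expectation `E(r2) = 1/S + 3.19/S^2` that [ne_point()] subtracts.
#'
#' @param ds A [genotype_dataset()].
#' @param pop Population label.
#' @param locus_a,locus_b Locus IDs or indices.
#' @param maf_cutoff Both loci must have minor allele frequency at least
#'   `maf_cutoff` among the co-genotyped individuals.
#' @return List with `ok` (logical), and when usable `S` (co-genotyped
#'   individuals), `r2`, `p_a`, `p_b`; when excluded, `reason`.
#' @export
burrows_r2 <- function(ds, pop, locus_a, locus_b, maf_cutoff = 0.02) {
  rows <- ds$pop == pop
  if (!any(rows)) stop("unknown population: ", pop)
  x <- ds$dosage[rows, locus_a]
  y <- ds$dosage[rows, locus_b]
  ok <- !is.na(x) & !is.na(y)
  S <- sum(ok)
  if (S < 2) return(list(ok = FALSE, reason = "fewer than 2 co-genotyped individuals"))
  x <- as.double(x[ok]); y <- as.double(y[ok])
  p <- mean(x) / 2; q <- mean(y) / 2
  if (min(p, 1 - p) < maf_cutoff || min(q, 1 - q) < maf_cutoff) {
    return(list(ok = FALSE, reason = "allele frequency below cutoff"))
  }
  va <- p * (1 - p) + mean(x == 2) - p^2
  vb <- q * (1 - q) + mean(y == 2) - q^2
  if (stats::var(x) == 0 || stats::var(y) == 0 || va <= 0 || vb <= 0) {
    return(list(ok = FALSE, reason = "zero dosage variance"))
  }
  delta <- stats::cov(x, y) / 2
  r2 <- min(1, delta^2 / (va * vb))
  list(ok = TRUE, S = S, r2 = r2, p_a = p, p_b = q)
}

#' Weighted mean r-squared over locus pairs
#'
#' Pairs are weighted by the number of individuals genotyped at both loci,
#' `w_ij = S_ij`, following the missing-data update of the LD method:
#' `r2_bar = sum(w r2) / sum(w)` and the effective sample size is the
#' weighted harmonic mean `S_eff = sum(w) / sum(w / S)`. With complete data
#' these reduce to the simple mean and the common sample size. When
#' `exclude_same_lg` is set, pairs whose two loci share a linkage group are
#' dropped; pairs with an unmapped locus are retained.
#'
#' @param r2 Per-pair composite r-squared values.
#' @param S Per-pair co-genotyped sample sizes.
#' @param same_lg Logical per pair: both loci on the same linkage group.
#' @param exclude_same_lg Drop same-linkage-group pairs.
#' @return List with `r2_mean`, `S_eff`, `n_used`, `n_excluded_lg`.
#' @export
mean_r2 <- function(r2, S, same_lg = rep(FALSE, length(r2)),
                    exclude_same_lg = FALSE) {
  stopifnot(length(r2) == length(S), length(same_lg) == length(r2))
  same_lg[is.na(same_lg)] <- FALSE
  keep <- if (exclude_same_lg) !same_lg else rep(TRUE, length(r2))
  n_excluded <- sum(!keep)
  r2 <- r2[keep]; S <- S[keep]
  if (length(r2) == 0) {
    stop("no unlinked locus pairs remain",
         if (exclude_same_lg) " after excluding same-linkage-group pairs" else "")
  }
  w <- S
  list(r2_mean = sum(w * r2) / sum(w),
       S_eff = sum(w) / sum(w / S),
       n_used = length(r2),
       n_excluded_lg = n_excluded)
}

#' Point estimate of Ne from mean composite r-squared
#'
#' Random-mating, bias-corrected LD estimator. The finite-sample
#' expectation of r-squared is subtracted first:
#' for `S >= 30`, `E(r2) = 1/S + 3.19/S^2` and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`;
#' for `S < 30`, `E(r2) = 0.0018 + 0.907/S + 4.44/S^2` and
#' `Ne = (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2')`,
#' where `r2' = r2_bar - E(r2)`. When `r2'` is non-positive, or the
#' square-root argument is negative, there is no drift signal and the
#' estimate is infinite.
#'
#' @param r2_mean Weighted mean composite r-squared.
#' @param S_eff Effective (harmonic mean) sample size; must exceed 2.
#' @return The point estimate `Ne` (possibly `Inf`).
#' @export
ne_point <- function(r2_mean, S_eff) {
  if (S_eff <= 2) stop("S_eff must exceed 2")
  r2p <- r2_mean - expected_r2_sample(S_eff)
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S_eff >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' Expected r-squared from finite sampling alone
#'
#' @param S_eff Effective sample size.
#' @return `E(r2_sample)` under the random-mating model.
#' @export
expected_r2_sample <- function(S_eff) {
  if (S_eff >= 30) 1 / S_eff + 3.19 / S_eff^2
  else 0.0018 + 0.907 / S_eff + 4.44 / S_eff^2
}

#' Parametric confidence interval for the LD Ne estimate
#'
#' Chi-square interval on the mean r-squared with degrees of freedom equal
#' to the number of retained locus pairs:
#' bounds `r2_bar * n / qchisq(1 - alpha/2, n)` (low) and
#' `r2_bar * n / qchisq(alpha/2, n)` (high), each mapped through
#' [ne_point()]; the low r-squared bound gives the high Ne bound. The
#' degrees of freedom treat pairs as independent, which is
#' anti-conservative when pairs share loci.
#'
#' @param r2_mean Weighted mean composite r-squared.
#' @param S_eff Effective sample size.
#' @param n_pairs Number of retained pairs (degrees of freedom).
#' @param level Confidence level.
#' @return List with `ci_low`, `ci_high` (Ne scale, possibly `Inf`) and
#'   `r2_low`, `r2_high`.
#' @export
ne_ci_parametric <- function(r2_mean, S_eff, n_pairs, level = 0.95) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  alpha <- 1 - level
  r2_low <- r2_mean * n_pairs / stats::qchisq(1 - alpha / 2, df = n_pairs)
  r2_high <- r2_mean * n_pairs / stats::qchisq(alpha / 2, df = n_pairs)
  list(ci_low = ne_point(r2_high, S_eff),
       ci_high = ne_point(r2_low, S_eff),
       r2_low = r2_low, r2_high = r2_high)
}

# Vectorized per-pair composite r^2 within one population.
# Returns a data-frame-free list of upper-triangle pair statistics.
pair_ld_stats <- function(d, maf_cutoff = 0.02) {
  L <- ncol(d)
  P <- matrix(as.double(!is.na(d)), nrow(d))
  M <- d; M[is.na(M)] <- 0L
  storage.mode(M) <- "double"
  N <- crossprod(P)
  SX <- crossprod(M, P)       # [a,b]: sum of dosage_a over inds genotyped at both
  SXY <- crossprod(M)
  SX2 <- crossprod(M * M, P)
  I2 <- matrix(as.double(!is.na(d) & d == 2L), nrow(d))
  PAA <- crossprod(I2, P) / N # [a,b]: hom-ref fraction at a among joint obs
  cov <- (SXY - SX * t(SX) / N) / (N - 1)
  vx <- (SX2 - SX^2 / N) / (N - 1)
  pfrq <- SX / (2 * N)
  maf <- pmin(pfrq, 1 - pfrq)
  # Burrows denominator with the homozygote-excess correction
  bv <- pfrq * (1 - pfrq) + PAA - pfrq^2
  denom <- bv * t(bv)
  r2 <- pmin(1, (cov / 2)^2 / denom)
  usable <- N >= 2 & maf >= maf_cutoff & t(maf) >= maf_cutoff &
    vx > 0 & t(vx) > 0 & bv > 0 & t(bv) > 0
  ut <- upper.tri(N)
  idx <- which(ut)
  list(i = row(N)[idx], j = col(N)[idx],
       S = N[idx], r2 = r2[idx], usable = usable[idx])
}

#' Estimate Ne from linkage disequilibrium
#'
#' Runs the full LD pipeline for one population: enumerate all
#' within-population locus pairs, compute per-pair composite r-squared
#' ([burrows_r2()], vectorized) with the per-pair MAF screen, form the
#' missing-data-weighted mean ([mean_r2()]) with or without
#' same-linkage-group pairs, and convert to a point estimate
#' ([ne_point()]) with a parametric confidence interval
#' ([ne_ci_parametric()]).
#'
#' @param ds A [genotype_dataset()]; map assignments are taken from its
#'   locus metadata (see [attach_map()]) unless `map` is supplied.
#' @param pop Population label.
#' @param map Optional map table ([read_map_table()]) overriding the
#'   dataset's locus metadata.
#' @param mode `"unlinked"` drops pairs whose loci share a linkage group;
#'   `"all"` keeps every pair.
#' @param mapped_only Restrict the analysis to loci placed on the map
#'   (default), mirroring an analysis in which only map-aligned markers are
#'   used; set `FALSE` to use all loci.
#' @param maf_cutoff Per-pair minor allele frequency cutoff.
#' @param exclude_loci Locus IDs to drop first (e.g. putatively selected
#'   outliers).
#' @param level Confidence level for the parametric CI.
#' @return An `ne_estimate`: list with `pop`, `mode`, `n_loci`, `n_pairs`,
#'   `n_excluded_lg`, `r2_mean`, `S_eff`, `E_r2`, `r2_prime`, `ne`,
#'   `ci_low`, `ci_high`.
#' @export
estimate_ne <- function(ds, pop, map = NULL,
                        mode = c("unlinked", "all"), mapped_only = TRUE,
                        maf_cutoff = 0.02, exclude_loci = character(0),
                        level = 0.95) {
  mode <- match.arg(mode)
  if (!is.null(map)) ds <- attach_map(ds, map)
  keep <- !(ds$loci$locus_id %in% exclude_loci)
  if (mapped_only) keep <- keep & !is.na(ds$loci$linkage_group)
  ds <- ds[, keep]
  if (n_loci(ds) < 2) stop("fewer than 2 loci available for LD estimation")
  rows <- ds$pop == pop
  if (!any(rows)) stop("unknown population: ", pop)
  ps <- pair_ld_stats(ds$dosage[rows, , drop = FALSE], maf_cutoff)
  lg <- ds$loci$linkage_group
  same_lg <- !is.na(lg[ps$i]) & !is.na(lg[ps$j]) & lg[ps$i] == lg[ps$j]
  use <- ps$usable
  if (!any(use)) stop("no usable locus pairs after screening")
  mr <- mean_r2(ps$r2[use], ps$S[use], same_lg[use],
                exclude_same_lg = (mode == "unlinked"))
  ne <- ne_point(mr$r2_mean, mr$S_eff)
  ci <- ne_ci_parametric(mr$r2_mean, mr$S_eff, mr$n_used, level)
  structure(list(pop = pop, mode = mode, n_loci = n_loci(ds),
                 n_pairs = mr$n_used, n_excluded_lg = mr$n_excluded_lg,
                 n_pairs_screened_out = sum(!use),
                 r2_mean = mr$r2_mean, S_eff = mr$S_eff,
                 E_r2 = expected_r2_sample(mr$S_eff),
                 r2_prime = mr$r2_mean - expected_r2_sample(mr$S_eff),
                 ne = ne, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 level = level),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("ne_estimate [%s, %s pairs mode]: %d loci, %d pairs used (%d same-LG excluded)\n",
              x$pop, x$mode, x$n_loci, x$n_pairs, x$n_excluded_lg))
  cat(sprintf("  r2_mean = %.6f, S_eff = %.2f, E(r2) = %.6f\n",
              x$r2_mean, x$S_eff, x$E_r2))
  cat(sprintf("  Ne = %s (%.0f%% CI %s - %s)\n",
              format(round(x$ne, 1)), 100 * x$level,
              format(round(x$ci_low, 1)), format(round(x$ci_high, 1))))
  invisible(x)
}

#' Ratios of effective size to census size
#'
#' `Ne / N` (effective size over mean yearly escapement) and
#' `Ne / (N G)` (effective size over census size per generation, with `G`
#' the generation length in years). Undefined (`NA`) for an infinite Ne.
#'
#' @param ne Point estimate of Ne (a number or an `ne_estimate`).
#' @param N Mean yearly escapement (> 0).
#' @param G Generation length in years (> 0).
#' @return List with `ne_over_n` and `ne_over_ng`.
#' @export
ne_ratios <- function(ne, N, G) {
  if (inherits(ne, "ne_estimate")) ne <- ne$ne
  if (!is.finite(N) || N <= 0) stop("N must be positive")
  if (!is.finite(G) || G <= 0) stop("G must be positive")
  if (!is.finite(ne)) return(list(ne_over_n = NA_real_, ne_over_ng = NA_real_))
  list(ne_over_n = ne / N, ne_over_ng = ne / (N * G))
}
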