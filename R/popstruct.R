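#' Permutation test of genetic differentiation between two populations
#'
#' Recomputes the multi-locus Weir-Cockerham theta after randomly permuting
#' individuals between the two populations. The p-value uses the add-one
#' estimator `p = (1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`, which
#' never returns zero.
#'
#' @param ds A [genotype_dataset()].
#' @param pop_i,pop_j Population labels.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `theta_obs`, `p_value`, `n_perm`.
#' @export
differentiation_test <- function(ds, pop_i, pop_j, n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  rows <- ds$pop %in% c(pop_i, pop_j)
  if (!any(ds$pop == pop_i) || !any(ds$pop == pop_j)) {
    stop("unknown population label")
  }
  d <- ds$dosage[rows, , drop = FALSE]
  lab <- ds$pop[rows]
  theta_obs <- two_pop_theta(d, lab == pop_i)
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(lab) == pop_i
    if (two_pop_theta(d, perm) >= theta_obs) n_ge <- n_ge + 1L
  }
  list(theta_obs = theta_obs, p_value = (1 + n_ge) / (n_perm + 1),
       n_perm = n_perm)
}

# Multi-locus theta for a two-group split of a dosage matrix.
two_pop_theta <- function(d, in_first) {
  stats_for <- function(rows) {
    dd <- d[rows, , drop = FALSE]
    nk <- colSums(!is.na(dd))
    p <- ifelse(nk > 0, colSums(dd, na.rm = TRUE) / (2 * nk), NA_real_)
    h <- ifelse(nk > 0, colSums(dd == 1L, na.rm = TRUE) / nk, NA_real_)
    list(n = nk, p = p, h = h)
  }
  s1 <- stats_for(in_first); s2 <- stats_for(!in_first)
  comp <- wc_components(cbind(s1$n, s2$n), cbind(s1$p, s2$p),
                        cbind(s1$h, s2$h))
  ok <- is.finite(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (any(ok) && denom != 0) sum(comp$a[ok]) / denom else NA_real_
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Nested allele-level analysis of variance with three strata: among groups
#' of populations, among populations within groups, and within populations
#' (alleles within a population are treated as exchangeable; there is no
#' within-individual stratum). Distances are allele mismatches, so for a
#' biallelic locus the sums of squares reduce to allele-frequency algebra.
#' Variance components are estimated locus by locus by the method of
#' moments with unequal-size coefficients, summed over loci, and expressed
#' as percentages of their total; negative components are retained as
#' computed. With a single group the among-group stratum is omitted.
#'
#' @param ds A [genotype_dataset()].
#' @param groups Named character vector mapping every population label to
#'   its group.
#' @return An `amova_result`: data frame with columns `source`, `sigma2`,
#'   `percent`.
#' @export
amova <- function(ds, groups) {
  pops <- pop_levels(ds)
  if (!all(pops %in% names(groups))) {
    stop("every population must be assigned to exactly one group")
  }
  grp <- as.character(groups[pops])
  if (any(is.na(grp) | grp == "")) stop("group labels must be non-empty")
  glev <- unique(grp)
  st <- pop_locus_stats(ds, pops)
  m <- 2 * st$n                       # alleles sampled per pop per locus
  x <- m * st$p                       # reference-allele counts
  L <- n_loci(ds)
  two_level <- length(glev) > 1
  sums <- c(a = 0, b = 0, c = 0)
  for (j in seq_len(L)) {
    use <- m[j, ] > 0
    if (sum(use) < 2) next
    mj <- m[j, use]; xj <- x[j, use]; gj <- grp[use]
    P <- length(mj); G <- length(unique(gj)); M <- sum(mj)
    if (M <= P) next
    pj <- xj / mj
    ss_wp <- sum(mj * pj * (1 - pj))
    xg <- tapply(xj, gj, sum); mg <- tapply(mj, gj, sum)
    pg <- xg / mg
    ss_g <- sum(mg * pg * (1 - pg))
    pT <- sum(xj) / M
    ss_tot <- M * pT * (1 - pT)
    ms_wp <- ss_wp / (M - P)
    sig_c <- ms_wp
    if (two_level && G > 1 && P > G) {
      ms_ap <- (ss_g - ss_wp) / (P - G)
      ms_ag <- (ss_tot - ss_g) / (G - 1)
      sgg <- tapply(mj^2, gj, sum) / mg
      n1 <- (M - sum(sgg)) / (P - G)
      n2 <- (sum(sgg) - sum(mj^2) / M) / (G - 1)
      n3 <- (M - sum(mg^2) / M) / (G - 1)
      sig_b <- (ms_ap - sig_c) / n1
      sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
      sums <- sums + c(a = sig_a, b = sig_b, c = sig_c)
    } else if (!two_level && P > 1) {
      ms_ap <- (ss_tot - ss_wp) / (P - 1)
      n1 <- (M - sum(mj^2) / M) / (P - 1)
      sig_b <- (ms_ap - sig_c) / n1
      sums <- sums + c(a = 0, b = sig_b, c = sig_c)
    }
  }
  if (two_level) {
    out <- data.frame(
      source = c("among_groups", "among_pops_within_groups", "within_pops"),
      sigma2 = c(sums[["a"]], sums[["b"]], sums[["c"]]),
      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(source = c("among_pops", "within_pops"),
                      sigma2 = c(sums[["b"]], sums[["c"]]),
                      stringsAsFactors = FALSE)
  }
  out$percent <- 100 * out$sigma2 / sum(out$sigma2)
  class(out) <- c("amova_result", "data.frame")
  out
}

#' Principal component analysis of individual genotypes with permutation
#' significance
#'
#' Centers each locus on its mean dosage, imputes missing genotypes with
#' the locus mean, and eigendecomposes the individual covariance matrix.
#' Axis significance is assessed by permuting each locus column
#' independently (which destroys all inter-individual structure while
#' preserving per-locus allele frequencies) and comparing observed
#' eigenvalues with their permutation distribution; p-values use the
#' add-one estimator. No allele-frequency scaling is applied by default.
#'
#' @param ds A [genotype_dataset()].
#' @param n_axes Number of leading axes to score and test.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param scale Divide each centered locus by its standard deviation.
#' @return A `pca_result`: list with `scores` (individuals x axes),
#'   `eigenvalues` (all), `proportion` (eigenvalue proportions, summing to
#'   1), `p_values` (per tested axis), `n_perm`.
#' @export
pca_genotypes <- function(ds, n_axes = 2, n_perm = 1000, seed = 1,
                          scale = FALSE) {
  if (n_ind(ds) < 2) stop("PCA needs at least two individuals")
  X <- prepare_pca_matrix(ds$dosage, scale)
  sv <- svd(X, nu = n_axes, nv = 0)
  eig <- sv$d^2 / (nrow(X) - 1)
  n_axes <- min(n_axes, length(eig))
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes)
  rownames(scores) <- rownames(ds$dosage)
  set.seed(seed)
  n_ge <- integer(n_axes)
  raw <- ds$dosage
  for (b in seq_len(n_perm)) {
    perm <- apply(raw, 2, sample)
    d <- svd(prepare_pca_matrix(perm, scale), nu = 0, nv = 0)$d
    lam <- d^2 / (nrow(raw) - 1)
    n_ge <- n_ge + (lam[seq_len(n_axes)] >= eig[seq_len(n_axes)])
  }
  structure(list(scores = scores, eigenvalues = eig,
                 proportion = eig / sum(eig),
                 p_values = (1 + n_ge) / (n_perm + 1),
                 n_perm = n_perm, pop = ds$pop),
            class = "pca_result")
}

prepare_pca_matrix <- function(dosage, scale = FALSE) {
  X <- dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  X <- sweep(X, 2, mu)
  if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  X
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$p_values)
  cat(sprintf("pca_result: %d individuals, %d axes tested (%d permutations)\n",
              nrow(x$scores), k, x$n_perm))
  for (i in seq_len(k)) {
    cat(sprintf("  PC%d: %.2f%% of variance, p = %.4g\n",
                i, 100 * x$proportion[i], x$p_values[i]))
  }
  invisible(x)
}
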