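# Independent brute-force oracles and small fixture builders. Each oracle is
# written directly from the defining algebra, by a different route than the
# package implementation, so agreement is evidence rather than tautology.

# Weir-Cockerham per-locus components from genotype counts (rows = pops,
# cols = c(nAA, nAa, naa)), transcribed term by term with scalar loops.
oracle_wc_locus <- function(counts) {
  n_i <- rowSums(counts)
  use <- n_i > 0
  counts <- counts[use, , drop = FALSE]
  n_i <- n_i[use]
  r <- nrow(counts)
  if (r < 2) return(list(a = NA_real_, b = NA_real_, c = NA_real_))
  p_i <- (2 * counts[, 1] + counts[, 2]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- mean(n_i)
  if (nbar <= 1) return(list(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (!is.finite(nc) || nc <= 0) return(list(a = NA_real_, b = NA_real_, c = NA_real_))
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Genotype counts per population for one locus of a dataset.
locus_counts <- function(ds, j) {
  pops <- unique(ds$pop)
  t(vapply(pops, function(pk) {
    d <- ds$dosage[ds$pop == pk, j]
    c(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
      sum(d == 0, na.rm = TRUE))
  }, numeric(3)))
}

# Levene exact HWE distribution by explicit enumeration of heterozygote
# counts with unnormalized multiplicities, normalized by their sum.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(NA_real_)
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  js <- seq(nA %% 2, min(nA, na), by = 2)
  w <- vapply(js, function(j) {
    exp(j * log(2) - lfactorial((nA - j) / 2) - lfactorial(j) -
          lfactorial((na - j) / 2))
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[js == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Composite Burrows r^2 by explicit scalar sums over individuals.
oracle_burrows_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  S <- length(x)
  sxy <- 0; sx <- 0; sy <- 0
  for (i in seq_len(S)) {
    sxy <- sxy + x[i] * y[i]; sx <- sx + x[i]; sy <- sy + y[i]
  }
  delta <- (sxy - sx * sy / S) / (S - 1) / 2
  p <- sx / (2 * S); q <- sy / (2 * S)
  paa <- sum(x == 2) / S; pbb <- sum(y == 2) / S
  va <- p * (1 - p) + paa - p^2
  vb <- q * (1 - q) + pbb - q^2
  min(1, delta^2 / (va * vb))
}

# Plain squared Pearson correlation by explicit sums.
oracle_r2_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num^2 / (sum((x - mx)^2) * sum((y - my)^2))
}

# Window membership by per-locus interval checks.
oracle_window_members <- function(loci, width, step) {
  mapped <- loci[!is.na(loci$linkage_group), , drop = FALSE]
  out <- list()
  for (lg in sort(unique(mapped$linkage_group))) {
    sub <- mapped[mapped$linkage_group == lg, , drop = FALSE]
    s <- 0
    repeat {
      members <- character(0)
      for (r in seq_len(nrow(sub))) {
        x <- sub$map_position_cM[r]
        if (x >= s && x < s + width) members <- c(members, sub$locus_id[r])
      }
      out[[paste(lg, s, sep = "@")]] <- members
      s <- s + step
      if (s >= max(sub$map_position_cM)) break
    }
  }
  out
}

# Interval union by iterated pairwise merging until fixpoint
# (touching intervals merge).
oracle_merge_intervals <- function(starts, ends) {
  iv <- Map(c, starts, ends)
  repeat {
    merged <- FALSE
    for (i in seq_along(iv)) {
      for (j in seq_along(iv)) {
        if (i >= j) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a[1] <= b[2] && b[1] <= a[2]) {
          iv[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
          iv[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv <- iv[order(vapply(iv, `[`, 0, 1))]
  do.call(rbind, iv)
}

# Small random dataset with missing data.
rand_dataset <- function(n_pops = 3, n_per_pop = 8, n_loci = 10,
                         missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  p <- matrix(runif(n_loci * n_pops, 0.05, 0.95), n_loci, n_pops)
  rows <- list()
  for (k in seq_len(n_pops)) {
    rows[[k]] <- matrix(rbinom(n_per_pop * n_loci, 2, rep(p[, k], each = n_per_pop)),
                        n_per_pop, n_loci)
  }
  d <- do.call(rbind, rows)
  if (missing_rate > 0) {
    d[matrix(runif(length(d)) < missing_rate, nrow(d))] <- NA_integer_
  }
  genotype_dataset(d, rep(paste0("p", seq_len(n_pops)), each = n_per_pop))
}
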