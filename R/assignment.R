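#' Posterior mean allele frequency under a uniform Dirichlet prior
#'
#' `(x + 1/k) / (n + 1)` for `x` copies of an allele among `n` sampled
#' allele copies and `k` possible alleles. This Bayesian smoothing keeps
#' every allele's frequency strictly positive, so an individual carrying an
#' allele unseen in a baseline still has finite log-likelihood.
#'
#' @param x Observed count of the allele.
#' @param n Total allele copies observed.
#' @param k Number of allelic states (2 for SNPs).
#' @return Posterior mean frequency in (0, 1).
#' @export
posterior_freq <- function(x, n, k = 2) {
  if (any(x < 0) || any(n < 0) || any(x > n)) stop("need 0 <= x <= n")
  (x + 1 / k) / (n + 1)
}

#' Log-likelihood of a multilocus genotype in a baseline population
#'
#' Sums, over the individual's non-missing loci, the log genotype
#' probability under Hardy-Weinberg proportions with posterior-mean allele
#' frequencies ([posterior_freq()]) computed from the baseline allele
#' counts: `p^2` for a reference homozygote, `2 p (1 - p)` for a
#' heterozygote, `(1 - p)^2` for an alternate homozygote.
#'
#' @param genotype Dosage vector (0/1/2/`NA`) for the individual.
#' @param baseline_x Reference-allele count per locus in the baseline.
#' @param baseline_n Total allele copies per locus in the baseline.
#' @return The log-likelihood, or `NA` if the individual has no genotyped
#'   locus.
#' @export
genotype_loglik <- function(genotype, baseline_x, baseline_n) {
  ok <- !is.na(genotype)
  if (!any(ok)) return(NA_real_)
  g <- genotype[ok]
  f <- posterior_freq(baseline_x[ok], baseline_n[ok])
  sum(ifelse(g == 2L, 2 * log(f),
             ifelse(g == 1L, log(2) + log(f) + log(1 - f),
                    2 * log(1 - f))))
}

#' Leave-one-out Bayesian assignment test
#'
#' For every individual, its two allele copies per genotyped locus are
#' subtracted from its own population's baseline counts; the individual is
#' then assigned to the population maximizing the [genotype_loglik()]
#' likelihood. The procedure is deterministic. Exact likelihood ties are
#' reported as unassigned rather than broken arbitrarily, as is an
#' individual with no genotyped loci.
#'
#' @param ds A [genotype_dataset()] with at least two individuals per
#'   population.
#' @return An `assignment_result`: list with `individuals` (data frame:
#'   `id`, `origin`, `assigned`, `correct`, per-population log-likelihood
#'   columns `loglik_<pop>`) and `accuracy` (see [accuracy_table()]).
#' @export
leave_one_out_assign <- function(ds) {
  pops <- pop_levels(ds)
  if (any(table(ds$pop) < 2)) stop("every population needs >= 2 individuals")
  d <- ds$dosage
  n <- nrow(d)
  L <- ncol(d)
  obs <- !is.na(d)
  # baseline counts per population per locus
  X <- Nn <- matrix(0, L, length(pops), dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    rows <- ds$pop == pops[k]
    X[, k] <- colSums(d[rows, , drop = FALSE], na.rm = TRUE)
    Nn[, k] <- 2 * colSums(obs[rows, , drop = FALSE])
  }
  ll <- matrix(NA_real_, n, length(pops),
               dimnames = list(rownames(d), pops))
  for (i in seq_len(n)) {
    gi <- d[i, ]
    oi <- obs[i, ]
    if (!any(oi)) next
    for (k in seq_along(pops)) {
      x <- X[, k]; m <- Nn[, k]
      if (ds$pop[i] == pops[k]) {
        x <- x - ifelse(oi, gi, 0L)
        m <- m - 2 * oi
      }
      ll[i, k] <- genotype_loglik(gi, x, m)
    }
  }
  assigned <- apply(ll, 1, function(v) {
    if (all(is.na(v))) return(NA_character_)
    top <- which(v == max(v))
    if (length(top) != 1) NA_character_ else pops[top]
  })
  individuals <- data.frame(id = rownames(d), origin = ds$pop,
                            assigned = assigned,
                            correct = !is.na(assigned) & assigned == ds$pop,
                            stringsAsFactors = FALSE, row.names = NULL)
  colnames(ll) <- paste0("loglik_", pops)
  individuals <- cbind(individuals, as.data.frame(ll, row.names = NULL))
  res <- structure(list(individuals = individuals, pops = pops),
                   class = "assignment_result")
  res$accuracy <- accuracy_table(res)
  res
}

#' Per-population assignment accuracy
#'
#' Percent of assigned individuals from each origin population that were
#' assigned back to it: `100 * correct / assigned` (unassigned individuals
#' are excluded from the denominator).
#'
#' @param result An `assignment_result` from [leave_one_out_assign()].
#' @return Data frame with columns `pop`, `n`, `n_assigned`, `n_correct`,
#'   `pct_correct`.
#' @export
accuracy_table <- function(result) {
  ind <- result$individuals
  out <- do.call(rbind, lapply(result$pops, function(pk) {
    rows <- ind$origin == pk
    n_assigned <- sum(rows & !is.na(ind$assigned))
    n_correct <- sum(rows & ind$correct)
    data.frame(pop = pk, n = sum(rows), n_assigned = n_assigned,
               n_correct = n_correct,
               pct_correct = if (n_assigned > 0) 100 * n_correct / n_assigned
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result (leave-one-out):\n")
  print.data.frame(x$accuracy, row.names = FALSE)
  invisible(x)
}
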