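#' SNP and individual quality-control filters
#'
#' Each `filter_*` function removes loci (or individuals) according to one
#' rule of the validation cascade and returns both the filtered dataset and
#' the IDs removed, so that an audit trail can be kept. Boundary semantics
#' (documented, configurable): a locus genotyped in at least `min_rate` of
#' individuals is kept; a locus at tag position strictly greater than
#' `max_pos` bp is removed; an individual missing strictly more than
#' `max_missing` of its genotypes is removed; a locus with haploid
#' heterozygosity strictly greater than `het_threshold` is removed.
#'
#' @name qc_filters
NULL

filter_result <- function(ds, removed, rule, params, unit = "locus") {
  list(dataset = ds, removed = removed, rule = rule, params = params,
       unit = unit)
}

#' Remove loci with low genotyping call rate
#'
#' @param ds A [genotype_dataset()].
#' @param min_rate Keep a locus iff its fraction of non-missing genotypes is
#'   at least `min_rate`.
#' @return List with `dataset` (filtered) and `removed` (locus IDs).
#' @rdname qc_filters
#' @export
filter_call_rate <- function(ds, min_rate = 0.8) {
  if (min_rate <= 0 || min_rate > 1) stop("min_rate must be in (0, 1]")
  keep <- locus_call_rate(ds) >= min_rate
  keep[is.na(keep)] <- FALSE
  filter_result(ds[, keep], ds$loci$locus_id[!keep], "call_rate",
                list(min_rate = min_rate))
}

#' Remove loci with a low minor allele frequency in every population
#'
#' A locus is removed only when its minor allele frequency (computed from
#' non-missing genotypes per population) is below `threshold` in *all*
#' populations; one population at or above the threshold retains the locus.
#' A population with no genotyped individuals at a locus contributes no
#' evidence and counts as below threshold.
#'
#' @param threshold MAF cutoff in (0, 0.5).
#' @rdname qc_filters
#' @export
filter_maf <- function(ds, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 0.5) stop("threshold must be in (0, 0.5)")
  st <- pop_locus_stats(ds)
  maf <- pmin(st$p, 1 - st$p)
  below <- is.na(maf) | maf < threshold
  remove <- rowSums(!below) == 0
  filter_result(ds[, !remove], ds$loci$locus_id[remove], "maf",
                list(threshold = threshold))
}

#' Remove loci near the error-prone 3' end of the RAD tag
#'
#' @param max_pos Keep a locus iff `tag_position <= max_pos`.
#' @rdname qc_filters
#' @export
filter_tag_position <- function(ds, max_pos = 87) {
  keep <- ds$loci$tag_position <= max_pos
  filter_result(ds[, keep], ds$loci$locus_id[!keep], "tag_position",
                list(max_pos = max_pos))
}

#' Keep only the highest-FST SNP on each RAD tag
#'
#' Reduces within-tag linkage by retaining, per RAD tag, the single SNP
#' with the largest overall Weir-Cockerham theta. Exact ties (and tags
#' whose theta is undefined) are broken deterministically by lowest tag
#' position, then lexicographic locus ID, so the result is invariant to
#' input order.
#'
#' @param fst_per_locus Optional named vector of per-locus theta; computed
#'   with [wc_theta()] over all populations when omitted.
#' @rdname qc_filters
#' @export
select_one_snp_per_tag <- function(ds, fst_per_locus = NULL) {
  if (is.null(fst_per_locus)) {
    ft <- wc_theta(ds)
    fst_per_locus <- stats::setNames(ft$components$theta, ft$components$locus_id)
  }
  theta <- fst_per_locus[ds$loci$locus_id]
  theta[!is.finite(theta)] <- -Inf
  ord <- order(ds$loci$tag_id, -theta, ds$loci$tag_position, ds$loci$locus_id)
  keep_ids <- tapply(ds$loci$locus_id[ord], ds$loci$tag_id[ord], `[`, 1L)
  keep <- ds$loci$locus_id %in% keep_ids
  filter_result(ds[, keep], ds$loci$locus_id[!keep], "one_per_tag", list())
}

#' Remove loci out of Hardy-Weinberg equilibrium in several populations
#'
#' A locus is removed iff its per-population exact HWE p-value
#' ([hwe_exact_pvalue()]) is below `alpha` in at least `min_pops`
#' populations.
#'
#' @param alpha Per-population significance level.
#' @param min_pops Number of deviating populations required for removal.
#' @rdname qc_filters
#' @export
filter_hwe <- function(ds, alpha = 0.05, min_pops = 3) {
  pv <- hwe_pvalue_matrix(ds)
  n_dev <- rowSums(pv < alpha, na.rm = TRUE)
  remove <- n_dev >= min_pops
  filter_result(ds[, !remove], ds$loci$locus_id[remove], "hwe",
                list(alpha = alpha, min_pops = min_pops))
}

#' Genotypic (composite) r-squared between two loci
#'
#' Squared Pearson correlation of allele dosages over the individuals of
#' one population genotyped at both loci. This is the phase-free genotypic
#' measure of linkage disequilibrium; it requires no haplotype inference.
#'
#' @param ds A [genotype_dataset()].
#' @param pop Population label.
#' @param locus_a,locus_b Locus IDs or indices.
#' @return r-squared in \[0, 1\], or `NA` when fewer than two individuals
#'   are genotyped at both loci or either locus has zero dosage variance
#'   among them.
#' @export
pairwise_r2 <- function(ds, pop, locus_a, locus_b) {
  rows <- ds$pop == pop
  if (!any(rows)) stop("unknown population: ", pop)
  x <- ds$dosage[rows, locus_a]
  y <- ds$dosage[rows, locus_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# All-pairs genotypic r^2 within one population, with pairwise-complete
# individuals; pairs with < 2 shared individuals or zero variance are NA.
r2_matrix_pop <- function(d) {
  P <- !is.na(d)
  M <- d; M[!P] <- 0L
  storage.mode(M) <- "double"
  Pn <- matrix(as.double(P), nrow(d))
  N <- crossprod(Pn)
  SX <- crossprod(M, Pn)
  SXY <- crossprod(M)
  SX2 <- crossprod(M * M, Pn)
  cov <- (SXY - SX * t(SX) / N)
  vx <- (SX2 - SX^2 / N)
  r2 <- cov^2 / (vx * t(vx))
  r2[N < 2 | vx <= 0 | t(vx) <= 0] <- NA_real_
  diag(r2) <- NA_real_
  r2
}

#' Prune one locus from each highly correlated pair
#'
#' Flags locus pairs whose genotypic r-squared exceeds `r2_threshold` in at
#' least `min_pops` populations and removes, from each flagged pair, the
#' locus genotyped in fewer individuals. Pairs are processed in a
#' deterministic order (descending maximum r-squared across populations,
#' then locus IDs); once a locus is removed it drops out of later pairs.
#' Call-rate ties are broken by removing the lexicographically later
#' locus ID.
#'
#' @param r2_threshold Pairwise r-squared threshold.
#' @param min_pops Populations in which the threshold must be exceeded.
#' @rdname qc_filters
#' @export
ld_prune <- function(ds, r2_threshold = 0.8, min_pops = 3) {
  pops <- pop_levels(ds)
  L <- n_loci(ds)
  n_exceed <- matrix(0L, L, L)
  max_r2 <- matrix(-Inf, L, L)
  for (pk in pops) {
    r2 <- r2_matrix_pop(ds$dosage[ds$pop == pk, , drop = FALSE])
    hit <- !is.na(r2) & r2 > r2_threshold
    n_exceed <- n_exceed + hit
    max_r2 <- pmax(max_r2, ifelse(is.na(r2), -Inf, r2))
  }
  idx <- which(upper.tri(n_exceed) & n_exceed >= min_pops, arr.ind = TRUE)
  if (nrow(idx)) {
    ids <- ds$loci$locus_id
    ord <- order(-max_r2[idx], ids[idx[, 1]], ids[idx[, 2]])
    idx <- idx[ord, , drop = FALSE]
    cr <- locus_call_rate(ds)
    alive <- rep(TRUE, L)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (!alive[i] || !alive[j]) next
      drop <- if (cr[i] < cr[j]) i
              else if (cr[j] < cr[i]) j
              else if (ids[i] < ids[j]) j else i
      alive[drop] <- FALSE
    }
    removed <- ids[!alive]
  } else {
    removed <- character(0)
  }
  keep <- !(ds$loci$locus_id %in% removed)
  filter_result(ds[, keep], ds$loci$locus_id[!keep], "ld",
                list(r2_threshold = r2_threshold, min_pops = min_pops))
}

#' Detect paralogous sequence variants from a haploid panel
#'
#' A haploid individual cannot be heterozygous at a correctly segregating
#' locus, so loci whose heterozygous-call fraction among genotyped haploids
#' exceeds `het_threshold` are flagged as putative PSVs.
#'
#' @param panel A [haploid_panel()].
#' @param het_threshold Heterozygous-call fraction above which a locus is
#'   flagged.
#' @return Character vector of flagged locus IDs.
#' @export
detect_psv <- function(panel, het_threshold = 0.10) {
  stopifnot(inherits(panel, "haploid_panel"))
  n <- colSums(!is.na(panel$calls))
  het <- colSums(panel$calls == 1L, na.rm = TRUE) / n
  colnames(panel$calls)[!is.na(het) & het > het_threshold]
}

#' Remove paralog-flagged loci using a haploid panel
#'
#' @rdname qc_filters
#' @export
filter_psv <- function(ds, panel, het_threshold = 0.10) {
  flagged <- detect_psv(panel, het_threshold)
  remove <- ds$loci$locus_id %in% flagged
  filter_result(ds[, !remove], ds$loci$locus_id[remove], "psv",
                list(het_threshold = het_threshold))
}

#' Remove individuals with too many missing genotypes
#'
#' @param max_missing Remove an individual iff its missing fraction is
#'   strictly greater than `max_missing`.
#' @rdname qc_filters
#' @export
filter_individual_missingness <- function(ds, max_missing = 0.15) {
  remove <- ind_missing_rate(ds) > max_missing
  filter_result(ds[!remove, ], rownames(ds$dosage)[remove],
                "individual_missingness", list(max_missing = max_missing),
                unit = "individual")
}

#' Identity-based relatedness between two individuals
#'
#' `R = 2 * IBS - 1`, where IBS is the mean over co-genotyped loci of the
#' shared-allele count divided by 2 (identical genotypes share 2 alleles, a
#' homozygote and a heterozygote share 1, opposite homozygotes share 0).
#' This is a deterministic identity-by-state statistic, not a pedigree
#' likelihood: identical individuals have R = 1, opposite homozygotes at
#' every locus give R = -1, and unrelated individuals fall near
#' `2 * E[IBS] - 1` for their population's allele frequencies.
#'
#' @param ds A [genotype_dataset()].
#' @param ind_i,ind_j Individual IDs or row indices.
#' @return The relatedness statistic R, or `NA` when no locus is genotyped
#'   in both individuals.
#' @export
relatedness_R <- function(ds, ind_i, ind_j) {
  x <- ds$dosage[ind_i, ]
  y <- ds$dosage[ind_j, ]
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  ibs <- mean((2 - abs(x[ok] - y[ok])) / 2)
  2 * ibs - 1
}

# All-pairs R via indicator cross-products.
relatedness_matrix <- function(ds) {
  d <- ds$dosage
  P <- matrix(as.double(!is.na(d)), nrow(d))
  I0 <- matrix(as.double(!is.na(d) & d == 0L), nrow(d))
  I1 <- matrix(as.double(!is.na(d) & d == 1L), nrow(d))
  I2 <- matrix(as.double(!is.na(d) & d == 2L), nrow(d))
  n <- tcrossprod(P)
  diff1 <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1)
  diff2 <- tcrossprod(I0, I2) + tcrossprod(I2, I0)
  sum_abs <- diff1 + 2 * diff2
  R <- 2 * (1 - sum_abs / (2 * n)) - 1
  R[n == 0] <- NA_real_
  dimnames(R) <- list(rownames(d), rownames(d))
  R
}

#' Find duplicated individuals
#'
#' Flags all pairs of individuals with relatedness `R > r_threshold`
#' ([relatedness_R()]); in each pair the member with the lower genotyping
#' call rate is marked for removal.
#'
#' @param ds A [genotype_dataset()].
#' @param r_threshold Relatedness threshold.
#' @return Data frame with columns `ind_i`, `ind_j`, `R`, `remove`.
#' @export
find_duplicates <- function(ds, r_threshold = 0.9) {
  R <- relatedness_matrix(ds)
  idx <- which(upper.tri(R) & !is.na(R) & R > r_threshold, arr.ind = TRUE)
  ids <- rownames(ds$dosage)
  cr <- 1 - ind_missing_rate(ds)
  if (nrow(idx)) {
    remove <- ifelse(cr[idx[, 1]] < cr[idx[, 2]], ids[idx[, 1]],
                     ifelse(cr[idx[, 2]] < cr[idx[, 1]], ids[idx[, 2]],
                            pmax(ids[idx[, 1]], ids[idx[, 2]])))
    out <- data.frame(ind_i = ids[idx[, 1]], ind_j = ids[idx[, 2]],
                      R = R[idx], remove = remove, stringsAsFactors = FALSE)
    out[order(out$ind_i, out$ind_j), , drop = FALSE]
  } else {
    data.frame(ind_i = character(0), ind_j = character(0), R = numeric(0),
               remove = character(0), stringsAsFactors = FALSE)
  }
}

#' Remove duplicated individuals
#'
#' @param r_threshold Relatedness threshold above which a pair is treated
#'   as duplicates.
#' @rdname qc_filters
#' @export
filter_duplicates <- function(ds, r_threshold = 0.9) {
  dup <- find_duplicates(ds, r_threshold)
  remove <- unique(dup$remove)
  keep <- !(rownames(ds$dosage) %in% remove)
  filter_result(ds[keep, ], remove, "duplicates",
                list(r_threshold = r_threshold), unit = "individual")
}

#' Default configuration of the filter cascade
#'
#' The default step order follows the audit narrative of the study the
#' package emulates: call rate, tag position, one SNP per tag, MAF, paralog
#' screen, HWE, LD pruning, individual missingness, duplicates. The order
#' and all parameters are configurable.
#'
#' @return List of step descriptors (`rule` plus parameters).
#' @export
default_filter_config <- function() {
  list(list(rule = "call_rate", min_rate = 0.8),
       list(rule = "tag_position", max_pos = 87),
       list(rule = "one_per_tag"),
       list(rule = "maf", threshold = 0.05),
       list(rule = "psv", het_threshold = 0.10),
       list(rule = "hwe", alpha = 0.05, min_pops = 3),
       list(rule = "ld", r2_threshold = 0.8, min_pops = 3),
       list(rule = "individual_missingness", max_missing = 0.15),
       list(rule = "duplicates", r_threshold = 0.9))
}

#' Run the full quality-control cascade
#'
#' Applies the configured filter steps in order and records, per step, the
#' rule, its parameters, and exactly which loci or individuals were
#' removed, so that the input minus the reported removals reproduces the
#' output. Re-running the cascade on its own output removes nothing.
#'
#' @param ds A [genotype_dataset()].
#' @param haploid_panel Optional [haploid_panel()]; without it the `psv`
#'   step is skipped (and recorded as skipped).
#' @param config List of step descriptors, see [default_filter_config()].
#' @return List with `dataset` (the filtered dataset) and `report` (a
#'   `filter_report`: data frame of steps with removed IDs in
#'   `attr(report, "removed")`).
#' @export
run_cascade <- function(ds, haploid_panel = NULL,
                        config = default_filter_config()) {
  steps <- list()
  removed <- list()
  for (stp in config) {
    rule <- stp$rule
    n_loci0 <- n_loci(ds); n_ind0 <- n_ind(ds)
    res <- switch(rule,
      call_rate = filter_call_rate(ds, stp$min_rate %||% 0.8),
      tag_position = filter_tag_position(ds, stp$max_pos %||% 87),
      one_per_tag = select_one_snp_per_tag(ds, stp$fst_per_locus),
      maf = filter_maf(ds, stp$threshold %||% 0.05),
      psv = if (is.null(haploid_panel)) NULL
            else filter_psv(ds, haploid_panel, stp$het_threshold %||% 0.10),
      hwe = filter_hwe(ds, stp$alpha %||% 0.05, stp$min_pops %||% 3),
      ld = ld_prune(ds, stp$r2_threshold %||% 0.8, stp$min_pops %||% 3),
      individual_missingness =
        filter_individual_missingness(ds, stp$max_missing %||% 0.15),
      duplicates = filter_duplicates(ds, stp$r_threshold %||% 0.9),
      stop("unknown filter rule: ", rule))
    if (is.null(res)) {
      steps[[length(steps) + 1L]] <- data.frame(
        rule = rule, unit = "locus", params = "skipped: no haploid panel",
        n_removed = 0L, n_loci_before = n_loci0, n_loci_after = n_loci0,
        n_ind_before = n_ind0, n_ind_after = n_ind0, stringsAsFactors = FALSE)
      removed[[length(removed) + 1L]] <- character(0)
      next
    }
    ds <- res$dataset
    steps[[length(steps) + 1L]] <- data.frame(
      rule = res$rule, unit = res$unit,
      params = paste(names(res$params), unlist(res$params),
                     sep = "=", collapse = ", "),
      n_removed = length(res$removed),
      n_loci_before = n_loci0, n_loci_after = n_loci(ds),
      n_ind_before = n_ind0, n_ind_after = n_ind(ds),
      stringsAsFactors = FALSE)
    removed[[length(removed) + 1L]] <- res$removed
  }
  report <- do.call(rbind, steps)
  if (is.null(report)) {
    report <- data.frame(rule = character(0), unit = character(0),
                         params = character(0), n_removed = integer(0),
                         n_loci_before = integer(0), n_loci_after = integer(0),
                         n_ind_before = integer(0), n_ind_after = integer(0),
                         stringsAsFactors = FALSE)
  }
  report$step <- seq_len(nrow(report))
  report <- report[c("step", setdiff(names(report), "step"))]
  attr(report, "removed") <- removed
  class(report) <- c("filter_report", "data.frame")
  list(dataset = ds, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
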