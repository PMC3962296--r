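#' Build sliding windows along the linkage map
#'
#' Per linkage group, windows of `width_cM` start at 0, `step_cM`,
#' `2 * step_cM`, ... centimorgans while the start lies strictly below the
#' largest mapped position on the group. Membership is half-open:
#' a locus at position `x` belongs to `[start, start + width)`. Windows
#' with fewer than `min_snps` member loci are recorded but marked
#' ineligible for testing.
#'
#' @param loci Data frame with columns `locus_id`, `linkage_group`,
#'   `map_position_cM` (unmapped rows are ignored), e.g. the `loci` table
#'   of a [genotype_dataset()].
#' @param width_cM Window width.
#' @param step_cM Frame shift between consecutive window starts.
#' @param min_snps Minimum member loci for a window to be testable.
#' @return Data frame with columns `linkage_group`, `start_cM`, `end_cM`,
#'   `n_snps`, `eligible`; member locus IDs per window in
#'   `attr(, "members")`.
#' @export
build_windows <- function(loci, width_cM = 5, step_cM = 1, min_snps = 2) {
  mapped <- loci[!is.na(loci$linkage_group) & !is.na(loci$map_position_cM), ,
                 drop = FALSE]
  rows <- list(); members <- list()
  for (lg in sort(unique(mapped$linkage_group))) {
    sub <- mapped[mapped$linkage_group == lg, , drop = FALSE]
    max_pos <- max(sub$map_position_cM)
    starts <- seq(0, by = step_cM,
                  length.out = max(1, ceiling(max_pos / step_cM)))
    starts <- starts[starts < max_pos | starts == 0]
    for (s in starts) {
      inw <- sub$map_position_cM >= s & sub$map_position_cM < s + width_cM
      rows[[length(rows) + 1L]] <- data.frame(
        linkage_group = lg, start_cM = s, end_cM = s + width_cM,
        n_snps = sum(inw), eligible = sum(inw) >= min_snps)
      members[[length(members) + 1L]] <- sub$locus_id[inw]
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(linkage_group = integer(0), start_cM = numeric(0),
               end_cM = numeric(0), n_snps = integer(0), eligible = logical(0))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

# Nearest-rank empirical quantile: smallest value with at least q*B of the
# sample at or below it.
quantile_nearest_rank <- function(x, q) {
  s <- sort(x)
  s[pmax(1L, ceiling(q * length(s)))]
}

#' Bootstrap null distribution for a window mean
#'
#' Draws `B` replicate means of `n_snps` per-locus FST values sampled with
#' replacement from the full per-locus distribution of the population pair,
#' and returns the nearest-rank 90% and 95% quantiles of those replicate
#' means. Negative FST values participate like any other.
#'
#' @param n_snps Number of values per replicate (the window's SNP count).
#' @param fst_values Per-locus FST values of the whole dataset for this
#'   population pair (length >= 2).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return List with `q90`, `q95`, `B`.
#' @export
bootstrap_null <- function(n_snps, fst_values, B, seed = NULL) {
  if (length(fst_values) < 2) stop("need >= 2 FST values for the null")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  means <- colMeans(matrix(sample(fst_values, n_snps * B, replace = TRUE),
                           n_snps, B))
  list(q90 = quantile_nearest_rank(means, 0.90),
       q95 = quantile_nearest_rank(means, 0.95),
       B = B)
}

#' Sliding-window FST scan for one population pair
#'
#' Computes per-locus pairwise Weir-Cockerham theta for the mapped loci,
#' slides windows along each linkage group ([build_windows()]), and tests
#' each eligible window against a bootstrap null ([bootstrap_null()]): the
#' null is first built from `B1` replicates; if the window mean exceeds the
#' 90% null quantile the null is rebuilt with `B2` replicates to sharpen
#' the tail; the window is significant iff its mean strictly exceeds the
#' 95% quantile of the final null. Deterministic given `seed`.
#'
#' @param ds A [genotype_dataset()] with map metadata (see [attach_map()]).
#' @param pop_i,pop_j Population labels.
#' @param width_cM,step_cM,min_snps Window geometry, see [build_windows()].
#' @param B1 Bootstrap replicates for the first pass.
#' @param B2 Replicates after escalation.
#' @param seed Integer seed.
#' @return A `window_scan_result`: list with `pops`, `windows` (data frame
#'   `linkage_group`, `start_cM`, `end_cM`, `n_snps`, `eligible`,
#'   `mean_fst`, `q90`, `q95`, `B`, `significant`) and `fst_values` (the
#'   per-locus values the null resamples).
#' @export
scan_pair <- function(ds, pop_i, pop_j, width_cM = 5, step_cM = 1,
                      min_snps = 2, B1 = 1000, B2 = 5000, seed = 1) {
  sub <- ds[ds$pop %in% c(pop_i, pop_j), ]
  ft <- wc_theta(sub, pops = c(pop_i, pop_j))
  theta <- ft$components$theta
  mapped <- !is.na(sub$loci$linkage_group) & is.finite(theta)
  fst_values <- stats::setNames(theta[mapped], sub$loci$locus_id[mapped])
  if (length(fst_values) < min_snps) stop("not enough mapped loci with defined FST")
  win <- build_windows(sub$loci[mapped, , drop = FALSE], width_cM, step_cM,
                       min_snps)
  members <- attr(win, "members")
  win$mean_fst <- vapply(members, function(m) {
    if (length(m)) mean(fst_values[m]) else NA_real_
  }, numeric(1))
  win$q90 <- win$q95 <- NA_real_
  win$B <- NA_integer_
  win$significant <- FALSE
  set.seed(seed)
  for (w in which(win$eligible)) {
    null1 <- bootstrap_null(win$n_snps[w], fst_values, B1, seed = NULL)
    if (win$mean_fst[w] > null1$q90) {
      null2 <- bootstrap_null(win$n_snps[w], fst_values, B2, seed = NULL)
      win$q90[w] <- null2$q90; win$q95[w] <- null2$q95; win$B[w] <- B2
    } else {
      win$q90[w] <- null1$q90; win$q95[w] <- null1$q95; win$B[w] <- B1
    }
    win$significant[w] <- win$mean_fst[w] > win$q95[w]
  }
  structure(list(pops = c(pop_i, pop_j), windows = win,
                 fst_values = fst_values,
                 width_cM = width_cM, step_cM = step_cM,
                 min_snps = min_snps, B1 = B1, B2 = B2),
            class = "window_scan_result")
}

#' Merge overlapping significant windows into regions
#'
#' Significant windows on the same linkage group whose half-open intervals
#' overlap or touch are merged into one region `[min start, max end)`.
#'
#' @param result A [scan_pair()] result.
#' @return Data frame with columns `linkage_group`, `start_cM`, `end_cM`,
#'   `n_windows`; one row per merged region.
#' @export
merge_regions <- function(result) {
  win <- result$windows
  sig <- win[win$significant, , drop = FALSE]
  out <- list()
  for (lg in sort(unique(sig$linkage_group))) {
    sub <- sig[sig$linkage_group == lg, , drop = FALSE]
    sub <- sub[order(sub$start_cM), , drop = FALSE]
    cur_s <- sub$start_cM[1]; cur_e <- sub$end_cM[1]; n <- 1L
    flush <- function(s, e, n) data.frame(linkage_group = lg, start_cM = s,
                                          end_cM = e, n_windows = n)
    if (nrow(sub) > 1) {
      for (r in 2:nrow(sub)) {
        if (sub$start_cM[r] <= cur_e) {
          cur_e <- max(cur_e, sub$end_cM[r]); n <- n + 1L
        } else {
          out[[length(out) + 1L]] <- flush(cur_s, cur_e, n)
          cur_s <- sub$start_cM[r]; cur_e <- sub$end_cM[r]; n <- 1L
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cur_s, cur_e, n)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(linkage_group = integer(0), start_cM = numeric(0),
               end_cM = numeric(0), n_windows = integer(0))
  rownames(res) <- NULL
  res
}

#' Count significant population pairs per map position
#'
#' For every linkage group and 1-cM bin `[b, b+1)`, counts the population
#' pairs whose merged significant regions cover the bin; used to locate
#' genomic regions divergent in many pairwise comparisons.
#'
#' @param results List of [scan_pair()] results (one per population pair).
#' @return Data frame with columns `linkage_group`, `bin_start_cM`,
#'   `n_pairs`; bins covered by no region are omitted.
#' @export
cross_pair_summary <- function(results) {
  if (!length(results)) stop("need at least one scanned pair")
  regions <- lapply(results, merge_regions)
  counts <- list()
  for (reg in regions) {
    for (r in seq_len(nrow(reg))) {
      bins <- seq(floor(reg$start_cM[r]), ceiling(reg$end_cM[r]) - 1)
      bins <- bins[bins < reg$end_cM[r] & (bins + 1) > reg$start_cM[r]]
      for (b in bins) {
        key <- paste(reg$linkage_group[r], b, sep = "@")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (!length(counts)) {
    return(data.frame(linkage_group = integer(0), bin_start_cM = numeric(0),
                      n_pairs = integer(0)))
  }
  parts <- strsplit(names(counts), "@", fixed = TRUE)
  out <- data.frame(
    linkage_group = as.integer(vapply(parts, `[`, "", 1)),
    bin_start_cM = as.numeric(vapply(parts, `[`, "", 2)),
    n_pairs = unlist(counts, use.names = FALSE))
  out <- out[order(out$linkage_group, out$bin_start_cM), , drop = FALSE]
  rownames(out) <- NULL
  out
}
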