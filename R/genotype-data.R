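#' Diploid SNP genotype dataset
#'
#' Container for a diploid biallelic SNP panel: an individuals x loci matrix
#' of reference-allele dosages (0, 1, 2, or `NA` for a missing genotype), a
#' population label per individual, and per-locus metadata (RAD tag, base
#' position within the tag, and optional linkage-map assignment).
#'
#' @param dosage Integer matrix, individuals in rows, loci in columns.
#'   Non-missing values must be 0, 1, or 2 (copies of the reference allele).
#'   Row names are individual IDs (generated when absent).
#' @param pop Character vector of population labels, one per individual.
#' @param loci Optional data frame of per-locus metadata with columns
#'   `locus_id`, `tag_id`, `tag_position` (1-based bp offset within the RAD
#'   tag), `linkage_group`, and `map_position_cM`. Missing columns are filled
#'   with defaults; `linkage_group` and `map_position_cM` must be present or
#'   absent together for each locus.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosage`, `pop`, and `loci`.
#' @export
genotype_dataset <- function(dosage, pop, loci = NULL) {
  dosage <- as.matrix(dosage)
  if (length(dosage)) storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("non-missing dosages must be 0, 1, or 2")
  }
  pop <- as.character(pop)
  if (length(pop) != nrow(dosage)) {
    stop("'pop' must have one label per individual (row of 'dosage')")
  }
  if (nrow(dosage) > 0 && any(is.na(pop) | pop == "")) {
    stop("population labels must be non-empty")
  }
  loci <- complete_loci(loci, ncol(dosage), colnames(dosage))
  colnames(dosage) <- loci$locus_id
  structure(list(dosage = dosage, pop = pop, loci = loci),
            class = "genotype_dataset")
}

# Fill in defaults for the per-locus metadata table and validate it.
complete_loci <- function(loci, n_loci, ids = NULL) {
  if (is.null(loci)) {
    loci <- data.frame(
      locus_id = if (!is.null(ids)) ids else sprintf("loc_%05d", seq_len(n_loci))
    )
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (nrow(loci) != n_loci) stop("'loci' must have one row per locus")
  if (is.null(loci$locus_id)) {
    loci$locus_id <- if (!is.null(ids)) ids else sprintf("loc_%05d", seq_len(n_loci))
  }
  loci$locus_id <- as.character(loci$locus_id)
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus IDs")
  if (is.null(loci$tag_id)) loci$tag_id <- loci$locus_id
  loci$tag_id <- as.character(loci$tag_id)
  if (is.null(loci$tag_position)) loci$tag_position <- rep(1L, n_loci)
  loci$tag_position <- as.integer(loci$tag_position)
  if (n_loci > 0 && any(loci$tag_position < 1L, na.rm = TRUE)) {
    stop("tag_position must be >= 1")
  }
  if (is.null(loci$linkage_group)) loci$linkage_group <- rep(NA_integer_, n_loci)
  loci$linkage_group <- as.integer(loci$linkage_group)
  if (is.null(loci$map_position_cM)) loci$map_position_cM <- rep(NA_real_, n_loci)
  loci$map_position_cM <- as.numeric(loci$map_position_cM)
  bad <- xor(is.na(loci$linkage_group), is.na(loci$map_position_cM))
  if (any(bad)) {
    stop("map_position_cM must be present exactly when linkage_group is")
  }
  if (any(loci$map_position_cM < 0, na.rm = TRUE)) {
    stop("map_position_cM must be non-negative")
  }
  rownames(loci) <- NULL
  loci[c("locus_id", "tag_id", "tag_position", "linkage_group", "map_position_cM")]
}

#' @export
print.genotype_dataset <- function(x, ...) {
  pops <- table(factor(x$pop, levels = unique(x$pop)))
  cat(sprintf("genotype_dataset: %d individuals x %d loci\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("populations (%d): %s\n", length(pops),
              paste(sprintf("%s [%d]", names(pops), pops), collapse = ", ")))
  n_mapped <- sum(!is.na(x$loci$linkage_group))
  cat(sprintf("mapped loci: %d; missing genotypes: %.2f%%\n",
              n_mapped, 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x A `genotype_dataset`.
#' @param i Individual selector (indices, logical mask, or IDs).
#' @param j Locus selector (indices, logical mask, or locus IDs).
#' @param ... Unused.
#' @return A `genotype_dataset` restricted to the selected individuals/loci.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  if (is.character(i)) i <- match(i, rownames(x$dosage))
  dos <- x$dosage[i, j, drop = FALSE]
  lj <- seq_len(ncol(x$dosage))[j]
  genotype_dataset(dos, x$pop[i], x$loci[lj, , drop = FALSE])
}

n_ind <- function(ds) nrow(ds$dosage)
n_loci <- function(ds) ncol(ds$dosage)
pop_levels <- function(ds) unique(ds$pop)

# Per-locus, per-population genotype summaries used throughout:
# n (genotyped individuals), p (reference-allele frequency), het
# (observed heterozygote fraction). Each is a loci x populations matrix.
pop_locus_stats <- function(ds, pops = pop_levels(ds)) {
  L <- n_loci(ds)
  n <- p <- het <- matrix(NA_real_, L, length(pops),
                          dimnames = list(ds$loci$locus_id, pops))
  for (k in seq_along(pops)) {
    d <- ds$dosage[ds$pop == pops[k], , drop = FALSE]
    nk <- colSums(!is.na(d))
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, colSums(d, na.rm = TRUE) / (2 * nk), NA_real_)
    het[, k] <- ifelse(nk > 0, colSums(d == 1L, na.rm = TRUE) / nk, NA_real_)
  }
  list(n = n, p = p, het = het)
}

locus_call_rate <- function(ds) {
  if (n_ind(ds) == 0) return(rep(NA_real_, n_loci(ds)))
  colMeans(!is.na(ds$dosage))
}

ind_missing_rate <- function(ds) {
  if (n_loci(ds) == 0) return(rep(0, n_ind(ds)))
  rowMeans(is.na(ds$dosage))
}

#' Haploid genotype panel
#'
#' Calls from haploid individuals genotyped with a diploid caller, used to
#' screen for paralogous sequence variants (PSVs). A true single-copy locus
#' can only be called homozygous in a haploid; an apparent heterozygote
#' signals co-amplified paralogs.
#'
#' @param calls Matrix (individuals x loci) with values 2 (reference
#'   homozygote call), 0 (alternate homozygote call), 1 (heterozygous call,
#'   the PSV signal), or `NA` (missing).
#' @param locus_ids Optional locus IDs (defaults to column names).
#' @return An object of class `haploid_panel`.
#' @export
haploid_panel <- function(calls, locus_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (length(calls)) storage.mode(calls) <- "integer"
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("haploid calls must be 0, 1 (heterozygous call), 2, or NA")
  }
  if (is.null(locus_ids)) locus_ids <- sprintf("loc_%05d", seq_len(ncol(calls)))
  colnames(calls) <- locus_ids
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("hap_%03d", seq_len(nrow(calls)))
  }
  structure(list(calls = calls), class = "haploid_panel")
}

#' @export
print.haploid_panel <- function(x, ...) {
  cat(sprintf("haploid_panel: %d individuals x %d loci; %.2f%% heterozygous calls\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}
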