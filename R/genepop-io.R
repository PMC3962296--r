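#' Read a Genepop file
#'
#' Parses the classic Genepop text format (title line, locus names one per
#' line or comma-separated, `POP`-delimited population blocks, individuals as
#' `id , 0101 0202 ...`). Both the 2-digit and 3-digit allele-code dialects
#' are accepted, and may even be mixed across loci. Dosages are counted
#' against the numerically smallest allele code observed at each locus, so
#' the same genotypes encoded in either dialect produce identical datasets.
#'
#' Population labels cannot be stored in the Genepop format itself; when
#' every individual ID has the form `<pop>:<id>` (as written by
#' [write_genepop()]) the prefix is used as the population label, otherwise
#' populations are labelled `pop_1`, `pop_2`, ...
#'
#' An all-zero allele code (`0000` / `000000`) is a missing genotype. A
#' half-missing code (exactly one zero allele) is treated as fully missing,
#' with a warning.
#'
#' @param path Path to a Genepop file.
#' @param ploidy `"diploid"` (default) returns a [genotype_dataset()];
#'   `"haploid"` reinterprets the calls as a [haploid_panel()] in which an
#'   apparent heterozygote is a paralog signal.
#' @return A `genotype_dataset` or `haploid_panel`.
#' @export
read_genepop <- function(path, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("﻿", "", lines)
  keep <- nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) < 2) stop("malformed Genepop header: file too short")

  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("malformed Genepop header: no POP line found")
  if (first_pop < 2) stop("malformed Genepop header: POP before the title line")

  header <- if (first_pop > 2) lines[2:(first_pop - 1)] else character(0)
  locus_ids <- unlist(lapply(header, function(l) {
    trimws(strsplit(l, ",", fixed = TRUE)[[1]])
  }), use.names = FALSE)
  locus_ids <- locus_ids[nzchar(locus_ids)]
  if (anyDuplicated(locus_ids)) stop("malformed Genepop header: duplicate locus names")
  L <- length(locus_ids)

  ids <- character(0)
  pop_idx <- integer(0)
  a1 <- a2 <- NULL   # allele codes as integers, one row per individual
  cur_pop <- 0L
  # per-locus registry of the (at most two) allele codes seen
  alleles <- vector("list", L)
  rows_a1 <- list(); rows_a2 <- list()
  n_half_missing <- 0L

  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { cur_pop <- cur_pop + 1L; next }
    if (cur_pop == 0L) stop("line ", lnum[i], ": genotype data before first POP line")
    line <- lines[i]
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) stop("line ", lnum[i], ": expected 'id , genotypes'")
    id <- trimws(substr(line, 1, comma - 1))
    codes <- strsplit(trimws(substr(line, comma + 1, nchar(line))), "[ \t]+")[[1]]
    codes <- codes[nzchar(codes)]
    if (length(codes) != L) {
      stop("line ", lnum[i], ": expected ", L, " genotypes, found ", length(codes))
    }
    v1 <- integer(L); v2 <- integer(L)
    for (j in seq_len(L)) {
      code <- codes[j]
      nc <- nchar(code)
      if (!(nc %in% c(4L, 6L)) || grepl("[^0-9]", code)) {
        stop("line ", lnum[i], ": malformed allele code '", code,
             "' at locus ", locus_ids[j])
      }
      w <- nc %/% 2L
      x1 <- as.integer(substr(code, 1L, w))
      x2 <- as.integer(substr(code, w + 1L, nc))
      if (xor(x1 == 0L, x2 == 0L)) {
        n_half_missing <- n_half_missing + 1L
        x1 <- 0L; x2 <- 0L
      }
      for (x in unique(c(x1, x2))) {
        if (x != 0L && !(x %in% alleles[[j]])) {
          if (length(alleles[[j]]) >= 2L) {
            stop("line ", lnum[i], ": >2 distinct alleles at locus ", locus_ids[j])
          }
          alleles[[j]] <- c(alleles[[j]], x)
        }
      }
      v1[j] <- x1; v2[j] <- x2
    }
    ids <- c(ids, id)
    pop_idx <- c(pop_idx, cur_pop)
    rows_a1[[length(rows_a1) + 1L]] <- v1
    rows_a2[[length(rows_a2) + 1L]] <- v2
  }
  if (n_half_missing > 0L) {
    warning(n_half_missing,
            " half-missing genotype(s) (one zero allele) treated as fully missing")
  }
  n <- length(ids)
  A1 <- do.call(rbind, rows_a1)
  A2 <- do.call(rbind, rows_a2)
  if (is.null(A1)) A1 <- A2 <- matrix(integer(0), 0, L)

  ref <- vapply(alleles, function(a) if (length(a)) min(a) else NA_integer_,
                integer(1))
  dosage <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    obs <- A1[, j] != 0L
    if (is.na(ref[j])) next
    dosage[obs, j] <- (A1[obs, j] == ref[j]) + (A2[obs, j] == ref[j])
  }
  rownames(dosage) <- ids

  if (ploidy == "haploid") {
    return(haploid_panel(dosage, locus_ids))
  }

  has_prefix <- n > 0 && all(grepl("^[^:]+:.", ids))
  if (has_prefix) {
    pop <- sub(":.*$", "", ids)
    rownames(dosage) <- sub("^[^:]+:", "", ids)
    # prefixes must be consistent with the POP blocks
    if (any(tapply(pop, pop_idx, function(x) length(unique(x))) != 1L)) {
      pop <- paste0("pop_", pop_idx)
      rownames(dosage) <- ids
    }
  } else {
    pop <- paste0("pop_", pop_idx)
  }
  genotype_dataset(dosage, pop,
                   data.frame(locus_id = locus_ids, stringsAsFactors = FALSE))
}

#' Write a Genepop file
#'
#' Writes 3-digit allele codes (`001` = reference allele, `002` = alternate,
#' `000000` = missing), one locus name per line, and one `POP` block per
#' population in order of first appearance. Individual lines are written as
#' `<pop>:<id> , codes...` so that [read_genepop()] recovers the population
#' labels; the result re-reads to a dataset identical in dosages, labels,
#' and locus IDs.
#'
#' @param x A [genotype_dataset()] or [haploid_panel()].
#' @param path Output file path.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "radpopgen export") {
  UseMethod("write_genepop")
}

genepop_code <- function(d) {
  out <- rep("000000", length(d))
  out[!is.na(d) & d == 2L] <- "001001"
  out[!is.na(d) & d == 1L] <- "001002"
  out[!is.na(d) & d == 0L] <- "002002"
  out
}

#' @export
write_genepop.genotype_dataset <- function(x, path, title = "radpopgen export") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci$locus_id, con)
  pops <- pop_levels(x)
  for (pk in pops) {
    writeLines("POP", con)
    for (i in which(x$pop == pk)) {
      codes <- genepop_code(x$dosage[i, ])
      writeLines(paste0(pk, ":", rownames(x$dosage)[i], " ,  ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @export
write_genepop.haploid_panel <- function(x, path, title = "radpopgen haploid panel") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(x$calls), con)
  writeLines("POP", con)
  for (i in seq_len(nrow(x$calls))) {
    codes <- genepop_code(x$calls[i, ])
    writeLines(paste0(rownames(x$calls)[i], " ,  ",
                      paste(codes, collapse = " ")), con)
  }
  invisible(path)
}

#' Read a linkage-map table
#'
#' Tab-separated table with a header and columns `locus_id`,
#' `linkage_group`, and `cM` (or `map_position_cM`). Loci absent from the
#' table simply carry no map assignment.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `locus_id`, `linkage_group`,
#'   `map_position_cM`.
#' @export
read_map_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(tab$cM) && !is.null(tab$map_position_cM)) tab$cM <- tab$map_position_cM
  need <- c("locus_id", "linkage_group", "cM")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("map table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$locus_id)) {
    stop("duplicate locus_id in map table: ",
         paste(unique(tab$locus_id[duplicated(tab$locus_id)]), collapse = ", "))
  }
  cm <- suppressWarnings(as.numeric(tab$cM))
  if (any(is.na(cm) & !is.na(tab$cM) & nzchar(tab$cM))) {
    stop("non-numeric cM value in map table")
  }
  if (any(cm < 0, na.rm = TRUE)) stop("negative cM position in map table")
  data.frame(locus_id = as.character(tab$locus_id),
             linkage_group = as.integer(tab$linkage_group),
             map_position_cM = cm,
             stringsAsFactors = FALSE)
}

#' Attach linkage-map assignments to a dataset
#'
#' @param ds A [genotype_dataset()].
#' @param map Data frame from [read_map_table()].
#' @return The dataset with `linkage_group` and `map_position_cM` filled in
#'   for loci present in the map; other loci are left unmapped.
#' @export
attach_map <- function(ds, map) {
  i <- match(ds$loci$locus_id, map$locus_id)
  ds$loci$linkage_group <- ifelse(is.na(i), NA_integer_, map$linkage_group[i])
  ds$loci$map_position_cM <- ifelse(is.na(i), NA_real_, map$map_position_cM[i])
  ds
}

#' Read a census table
#'
#' Tab-separated table with columns `population`, `N` (mean yearly
#' escapement) and `G` (generation length in years).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `population`, `N`, `G`.
#' @export
read_census_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("population", "N", "G"), names(tab))
  if (length(miss)) stop("census table is missing column(s): ", paste(miss, collapse = ", "))
  tab$N <- as.numeric(tab$N)
  tab$G <- as.numeric(tab$G)
  if (any(!is.finite(tab$N)) || any(tab$N <= 0)) stop("census N must be positive")
  if (any(!is.finite(tab$G)) || any(tab$G <= 0)) stop("generation length G must be positive")
  tab[c("population", "N", "G")]
}

#' Join census records to a dataset's populations
#'
#' @param census Data frame from [read_census_table()].
#' @param pops Character vector of population labels to keep.
#' @return Census rows for `pops`, in that order; extra census populations
#'   are dropped with a warning, and populations without a census row get
#'   `NA` entries.
#' @export
join_census <- function(census, pops) {
  extra <- setdiff(census$population, pops)
  if (length(extra)) {
    warning("census populations not in dataset ignored: ",
            paste(extra, collapse = ", "))
  }
  i <- match(pops, census$population)
  data.frame(population = pops, N = census$N[i], G = census$G[i],
             stringsAsFactors = FALSE)
}
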