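#' Configuration for the hierarchical island-model genotype simulator
#'
#' Defaults emulate the study system the package is built around: five
#' salmon populations (sample sizes 56, 54, 57, 56, 47) in three regional
#' groups, biallelic SNPs with ancestral minor allele frequencies uniform on
#' \[0.05, 0.5\], group-level differentiation around F = 0.05 and
#' population-within-group differentiation around F = 0.005 (overall
#' multi-locus FST near 0.04), a 34-linkage-group map with lengths spanning
#' 27.75-160.23 cM on which roughly 10% of loci are placed, several SNPs per
#' RAD tag at tag positions 1-93 bp, and 3% missing genotypes.
#'
#' @param n_pops Number of populations.
#' @param samples_per_pop Diploid sample size per population (recycled).
#' @param n_loci Number of biallelic SNP loci.
#' @param target_fst Either a single F for a one-level island model
#'   (`group_assignment = NULL`), or `c(among_groups, within_groups)` for the
#'   two-level hierarchy. Values must lie strictly in (0, 1).
#' @param group_assignment Group label per population, or `NULL` for a
#'   single-level model.
#' @param pop_names Population labels.
#' @param maf_range Range of the uniform ancestral allele-frequency draw.
#' @param missing_rate I.i.d. missing-genotype probability.
#' @param mapped_fraction Fraction of loci placed on the linkage map.
#' @param n_linkage_groups Number of linkage groups.
#' @param lg_lengths_cM Linkage-group lengths (cM).
#' @param snps_per_tag_probs Probabilities that a RAD tag carries 1, 2, or 3
#'   of the simulated SNPs.
#' @param seed Integer seed; every draw is reproducible given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 5,
                       samples_per_pop = c(56, 54, 57, 56, 47),
                       n_loci = 10000,
                       target_fst = c(0.05, 0.005),
                       group_assignment = c("norton", "coastal", "coastal",
                                            "coastal", "yukon"),
                       pop_names = c("Tubutulik", "Anvik", "Kogrukluk",
                                     "Koktuli", "BigSalmon"),
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.03,
                       mapped_fraction = 0.105,
                       n_linkage_groups = 34,
                       lg_lengths_cM = seq(27.75, 160.23, length.out = n_linkage_groups),
                       snps_per_tag_probs = c(0.7, 0.2, 0.1),
                       seed = 1) {
  if (n_pops < 1) stop("n_pops must be >= 1")
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  if (any(samples_per_pop < 2)) stop("samples_per_pop must be >= 2")
  if (length(pop_names) < n_pops) pop_names <- paste0("pop_", seq_len(n_pops))
  pop_names <- rep_len(as.character(pop_names), n_pops)
  if (!is.null(group_assignment)) {
    group_assignment <- rep_len(as.character(group_assignment), n_pops)
    if (length(target_fst) != 2) {
      stop("two-level hierarchy needs target_fst = c(among_groups, within_groups)")
    }
  } else if (length(target_fst) != 1) {
    stop("single-level model needs a scalar target_fst")
  }
  if (any(target_fst < 0) || any(target_fst >= 1)) {
    stop("target_fst values must lie in [0, 1); F = 1 is degenerate (fixation)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (mapped_fraction < 0 || mapped_fraction > 1) stop("mapped_fraction must be in [0, 1]")
  if (length(lg_lengths_cM) != n_linkage_groups || any(lg_lengths_cM <= 0)) {
    stop("lg_lengths_cM must give a positive length per linkage group")
  }
  structure(list(n_pops = n_pops, samples_per_pop = samples_per_pop,
                 n_loci = as.integer(n_loci), target_fst = target_fst,
                 group_assignment = group_assignment, pop_names = pop_names,
                 maf_range = maf_range, missing_rate = missing_rate,
                 mapped_fraction = mapped_fraction,
                 n_linkage_groups = as.integer(n_linkage_groups),
                 lg_lengths_cM = lg_lengths_cM,
                 snps_per_tag_probs = snps_per_tag_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: p_pop ~ Beta(p(1-F)/F, (1-p)(1-F)/F), the standard
# island-model marginal with E[p_pop] = p and E[FST] = F. The F -> 0 limit
# is the point mass at p (no differentiation).
rbalding_nichols <- function(p, F) {
  if (F == 0) return(rep_len(p, length(p)))
  lambda <- (1 - F) / F
  stats::rbeta(length(p), p * lambda, (1 - p) * lambda)
}

# RAD-tag scaffolding: group loci into tags of 1-3 SNPs with distinct
# 1-93 bp tag positions, and place a fraction of loci on the linkage map.
sim_loci_metadata <- function(cfg) {
  L <- cfg$n_loci
  sizes <- integer(0)
  while (sum(sizes) < L) {
    sizes <- c(sizes, sample.int(3L, 64L, replace = TRUE,
                                 prob = cfg$snps_per_tag_probs))
  }
  sizes <- sizes[cumsum(sizes) - sizes < L]
  sizes[length(sizes)] <- L - sum(sizes[-length(sizes)])
  tag_id <- rep(sprintf("tag_%06d", seq_along(sizes)), sizes)
  tag_position <- unlist(lapply(sizes, function(s) sort(sample.int(93L, s))),
                         use.names = FALSE)
  locus_id <- paste0(tag_id, "_", tag_position)
  lg <- rep(NA_integer_, L)
  cm <- rep(NA_real_, L)
  n_mapped <- round(cfg$mapped_fraction * L)
  if (n_mapped > 0) {
    on_map <- sample.int(L, n_mapped)
    lg[on_map] <- sample.int(cfg$n_linkage_groups, n_mapped, replace = TRUE)
    cm[on_map] <- stats::runif(n_mapped) * cfg$lg_lengths_cM[lg[on_map]]
  }
  data.frame(locus_id = locus_id, tag_id = tag_id, tag_position = tag_position,
             linkage_group = lg, map_position_cM = cm, stringsAsFactors = FALSE)
}

#' Simulate genotypes under a (hierarchical) island model
#'
#' Per locus, an ancestral frequency is drawn uniformly from the configured
#' range; group frequencies are drawn from a Balding-Nichols distribution
#' around the ancestral frequency (two-level model) and population
#' frequencies around their group frequency; genotypes are binomial(2,
#' p_pop); missingness is i.i.d. The realized per-population frequencies are
#' kept as attributes so downstream power experiments
#' ([plant_selected_region()]) and artifact injection can reuse them.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_dataset()] with simulation truth stored in
#'   `attr(, "sim")` (`p_anc`, `p_pop`, `cfg`).
#' @export
simulate_island_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  loci <- sim_loci_metadata(cfg)
  p_anc <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  p_pop <- matrix(NA_real_, L, cfg$n_pops,
                  dimnames = list(loci$locus_id, cfg$pop_names))
  if (is.null(cfg$group_assignment)) {
    for (k in seq_len(cfg$n_pops)) {
      p_pop[, k] <- rbalding_nichols(p_anc, cfg$target_fst)
    }
  } else {
    groups <- unique(cfg$group_assignment)
    p_group <- matrix(NA_real_, L, length(groups))
    for (g in seq_along(groups)) {
      p_group[, g] <- rbalding_nichols(p_anc, cfg$target_fst[1])
    }
    for (k in seq_len(cfg$n_pops)) {
      g <- match(cfg$group_assignment[k], groups)
      p_pop[, k] <- rbalding_nichols(p_group[, g], cfg$target_fst[2])
    }
  }
  n_tot <- sum(cfg$samples_per_pop)
  dosage <- matrix(NA_integer_, n_tot, L)
  pop <- rep(cfg$pop_names, cfg$samples_per_pop)
  row <- 0L
  for (k in seq_len(cfg$n_pops)) {
    nk <- cfg$samples_per_pop[k]
    g <- matrix(stats::rbinom(nk * L, 2L, rep(p_pop[, k], each = nk)), nk, L)
    dosage[row + seq_len(nk), ] <- g
    row <- row + nk
  }
  if (cfg$missing_rate > 0) {
    dosage[matrix(stats::runif(n_tot * L) < cfg$missing_rate, n_tot, L)] <- NA_integer_
  }
  rownames(dosage) <- paste0(pop, "_", unlist(lapply(cfg$samples_per_pop, seq_len)))
  ds <- genotype_dataset(dosage, pop, loci)
  attr(ds, "sim") <- list(p_anc = p_anc, p_pop = p_pop, cfg = cfg)
  ds
}

#' Configuration for the forward Wright-Fisher simulator
#'
#' @param true_ne True effective (= census) size of the ideal population,
#'   diploid individuals per generation.
#' @param n_generations Generations of random mating before sampling.
#' @param sample_size Diploids sampled (without replacement) at the end.
#' @param n_loci Number of loci (ignored when `map` supplies loci).
#' @param map Optional data frame (`locus_id`, `linkage_group`,
#'   `map_position_cM`) placing loci on a genetic map; adjacent mapped loci
#'   recombine with the Haldane probability of their cM distance, loci on
#'   different linkage groups (and all loci when `map = NULL`) assort
#'   independently.
#' @param init_freq_range Founder allele frequencies are uniform on this
#'   range, with founder haplotypes in linkage equilibrium.
#' @param seed Integer seed.
#' @return A `wf_config` list.
#' @export
wf_config <- function(true_ne, n_generations = 30, sample_size = 50,
                      n_loci = 200, map = NULL,
                      init_freq_range = c(0.05, 0.5), seed = 1) {
  true_ne <- as.integer(true_ne)
  if (true_ne < 2) stop("true_ne must be >= 2")
  if (sample_size > true_ne) stop("sample_size cannot exceed true_ne")
  if (!is.null(map)) {
    if (anyDuplicated(map$locus_id)) stop("duplicate locus_id in map")
    n_loci <- nrow(map)
  }
  structure(list(true_ne = true_ne, n_generations = as.integer(n_generations),
                 sample_size = as.integer(sample_size),
                 n_loci = as.integer(n_loci), map = map,
                 init_freq_range = init_freq_range, seed = as.integer(seed)),
            class = "wf_config")
}

#' Haldane map function
#'
#' Recombination fraction for a map distance `d` in centimorgans:
#' `c = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Map distance in cM.
#' @return Recombination fraction in \[0, 0.5\].
#' @export
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Draw one gamete per parent index. A and B are the parental haplotype
# matrices (individuals x loci, 0/1 alleles); rec[j] is the recombination
# fraction between locus j-1 and locus j (0.5 at linkage-group boundaries).
wf_gametes <- function(A, B, parents, rec) {
  k <- length(parents)
  L <- ncol(A)
  state <- matrix(0L, k, L)
  state[, 1] <- stats::rbinom(k, 1L, 0.5)
  if (L > 1) {
    sw <- matrix(stats::rbinom(k * (L - 1L), 1L, rep(rec[-1], each = k)),
                 k, L - 1L)
    for (j in 2:L) state[, j] <- (state[, j - 1L] + sw[, j - 1L]) %% 2L
  }
  PA <- A[parents, , drop = FALSE]
  PB <- B[parents, , drop = FALSE]
  use_b <- state == 1L
  PA[use_b] <- PB[use_b]
  PA
}

#' Simulate genotypes by forward Wright-Fisher drift
#'
#' A constant-size diploid Wright-Fisher population: each offspring draws
#' two parents uniformly at random (selfing allowed), each parent transmits
#' a recombinant gamete, and after `n_generations` generations
#' `sample_size` individuals are sampled without replacement. The drift
#' linkage disequilibrium among unlinked loci carries the `1/(3*Ne)` signal
#' that the LD effective-size estimator recovers, while tightly linked loci
#' on a shared linkage group accumulate the additional physical-linkage LD
#' that biases the estimator downward unless same-group pairs are excluded.
#'
#' @param cfg A [wf_config()].
#' @return A [genotype_dataset()] (single population `"wf"`) with map
#'   metadata from `cfg$map` when supplied.
#' @export
simulate_wf_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "wf_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  if (!is.null(cfg$map)) {
    ord <- order(cfg$map$linkage_group, cfg$map$map_position_cM)
    map <- cfg$map[ord, , drop = FALSE]
    rec <- c(0.5, ifelse(map$linkage_group[-1] == map$linkage_group[-L],
                         haldane(diff(map$map_position_cM)), 0.5))
    loci <- data.frame(locus_id = map$locus_id,
                       linkage_group = map$linkage_group,
                       map_position_cM = map$map_position_cM,
                       stringsAsFactors = FALSE)
  } else {
    rec <- rep(0.5, L)
    loci <- data.frame(locus_id = sprintf("wf_%05d", seq_len(L)),
                       stringsAsFactors = FALSE)
  }
  Ne <- cfg$true_ne
  p0 <- stats::runif(L, cfg$init_freq_range[1], cfg$init_freq_range[2])
  A <- matrix(stats::rbinom(Ne * L, 1L, rep(p0, each = Ne)), Ne, L)
  B <- matrix(stats::rbinom(Ne * L, 1L, rep(p0, each = Ne)), Ne, L)
  for (g in seq_len(cfg$n_generations)) {
    mothers <- sample.int(Ne, Ne, replace = TRUE)
    fathers <- sample.int(Ne, Ne, replace = TRUE)
    newA <- wf_gametes(A, B, mothers, rec)
    newB <- wf_gametes(A, B, fathers, rec)
    A <- newA; B <- newB
  }
  idx <- sample.int(Ne, cfg$sample_size)
  dosage <- A[idx, , drop = FALSE] + B[idx, , drop = FALSE]
  rownames(dosage) <- sprintf("wf_ind_%03d", seq_len(cfg$sample_size))
  ds <- genotype_dataset(dosage, rep("wf", cfg$sample_size), loci)
  attr(ds, "sim") <- list(cfg = cfg, p0 = p0)
  ds
}

#' Inject genotyping artifacts into a simulated dataset
#'
#' Creates the defect classes that the quality-control cascade is designed
#' to remove, and records the ground truth for scoring filter sensitivity
#' and specificity:
#' \itemize{
#'   \item PSV loci: a chosen fraction of existing loci is overwritten by the
#'     collapsed signal of two independent latent loci (the existing locus
#'     plus a new latent paralog); an individual is called heterozygous
#'     whenever its two paralogous genotypes differ, inflating
#'     heterozygosity and making the locus heterozygous in haploids.
#'   \item Error SNPs: new low-minor-allele-frequency loci appended at RAD
#'     tag positions 88-93 bp, mimicking 3'-end sequencing error.
#'   \item Duplicated individuals: copies of existing individuals with an
#'     independently drawn missingness mask.
#' }
#'
#' @param ds A [genotype_dataset()], typically from
#'   [simulate_island_genotypes()].
#' @param psv_fraction Fraction of loci converted to PSVs.
#' @param duplicate_pairs Number of duplicated individuals to append.
#' @param error_snp_fraction New error loci, as a fraction of `n_loci`.
#' @param missing_rate Missingness applied to injected genotypes.
#' @param seed Integer seed.
#' @return List with elements `dataset` (the contaminated dataset) and
#'   `truth` (list: `psv_loci`, `psv_latent_freq` (per-locus latent allele
#'   frequency pairs, averaged over populations), `error_loci`,
#'   `duplicate_pairs` data frame).
#' @export
inject_artifacts <- function(ds, psv_fraction = 0.02, duplicate_pairs = 2,
                             error_snp_fraction = 0.02, missing_rate = 0.03,
                             seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (psv_fraction < 0 || psv_fraction > 1 ||
      error_snp_fraction < 0 || error_snp_fraction > 1 ||
      missing_rate < 0 || missing_rate > 1) {
    stop("fractions must lie in [0, 1]")
  }
  set.seed(seed)
  L <- n_loci(ds)
  n <- n_ind(ds)
  sim <- attr(ds, "sim")
  truth <- list(psv_loci = character(0),
                psv_latent_freq = list(),
                error_loci = character(0),
                duplicate_pairs = data.frame(original = character(0),
                                             duplicate = character(0),
                                             stringsAsFactors = FALSE))

  n_psv <- round(psv_fraction * L)
  if (n_psv > 0) {
    psv_idx <- sort(sample.int(L, n_psv))
    truth$psv_loci <- ds$loci$locus_id[psv_idx]
    for (j in psv_idx) {
      obs <- !is.na(ds$dosage[, j])
      p1 <- mean(ds$dosage[obs, j]) / 2
      p2 <- stats::runif(1, 0.2, 0.8)
      g2 <- stats::rbinom(n, 2L, p2)
      s <- ds$dosage[, j] + g2
      collapsed <- ifelse(is.na(s), NA_integer_,
                          ifelse(s == 0L, 0L, ifelse(s == 4L, 2L, 1L)))
      ds$dosage[, j] <- collapsed
      truth$psv_latent_freq[[ds$loci$locus_id[j]]] <- c(p1 = p1, p2 = p2)
    }
  }

  n_err <- round(error_snp_fraction * L)
  if (n_err > 0) {
    freqs <- stats::runif(n_err, 0.005, 0.03)
    g <- matrix(stats::rbinom(n * n_err, 2L, rep(freqs, each = n)), n, n_err)
    if (missing_rate > 0) {
      g[matrix(stats::runif(n * n_err) < missing_rate, n, n_err)] <- NA_integer_
    }
    tag <- sprintf("errtag_%04d", seq_len(n_err))
    pos <- sample(88:93, n_err, replace = TRUE)
    err_loci <- data.frame(locus_id = paste0(tag, "_", pos), tag_id = tag,
                           tag_position = pos, linkage_group = NA_integer_,
                           map_position_cM = NA_real_, stringsAsFactors = FALSE)
    truth$error_loci <- err_loci$locus_id
    ds <- genotype_dataset(cbind(ds$dosage, g), ds$pop, rbind(ds$loci, err_loci))
  }

  if (duplicate_pairs > 0) {
    src <- sample.int(n, duplicate_pairs)
    dup_rows <- ds$dosage[src, , drop = FALSE]
    if (missing_rate > 0) {
      dup_rows[matrix(stats::runif(length(dup_rows)) < missing_rate,
                      nrow(dup_rows))] <- NA_integer_
    }
    dup_ids <- paste0(rownames(ds$dosage)[src], "_dup")
    rownames(dup_rows) <- dup_ids
    truth$duplicate_pairs <- data.frame(original = rownames(ds$dosage)[src],
                                        duplicate = dup_ids,
                                        stringsAsFactors = FALSE)
    ds <- genotype_dataset(rbind(ds$dosage, dup_rows),
                           c(ds$pop, ds$pop[src]), ds$loci)
  }
  attr(ds, "sim") <- sim
  list(dataset = ds, truth = truth)
}

#' Simulate a haploid genotyping panel
#'
#' Haploid individuals carry a single allele per true locus, so a correctly
#' segregating locus never yields a heterozygous call; a PSV locus is called
#' heterozygous whenever its two latent paralogs carry different alleles,
#' which for latent reference-allele frequencies `p1`, `p2` happens with
#' probability `p1 (1 - p2) + p2 (1 - p1)`.
#'
#' @param freqs Named vector of reference-allele frequencies per locus in
#'   the haploid source population.
#' @param psv_truth Optional `truth` list from [inject_artifacts()]
#'   identifying PSV loci and their latent frequency pairs.
#' @param n_individuals Number of haploids.
#' @param missing_rate I.i.d. missing-call probability.
#' @param seed Integer seed.
#' @return A [haploid_panel()].
#' @export
simulate_haploid_panel <- function(freqs, psv_truth = NULL,
                                   n_individuals = 50, missing_rate = 0,
                                   seed = 1) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(seed)
  L <- length(freqs)
  ids <- names(freqs)
  if (is.null(ids)) ids <- sprintf("loc_%05d", seq_len(L))
  calls <- matrix(NA_integer_, n_individuals, L, dimnames = list(NULL, ids))
  psv <- if (!is.null(psv_truth)) psv_truth$psv_loci else character(0)
  for (j in seq_len(L)) {
    if (ids[j] %in% psv) {
      lat <- psv_truth$psv_latent_freq[[ids[j]]]
      a <- stats::rbinom(n_individuals, 1L, lat[["p1"]])
      b <- stats::rbinom(n_individuals, 1L, lat[["p2"]])
      calls[, j] <- ifelse(a == b, ifelse(a == 1L, 2L, 0L), 1L)
    } else {
      a <- stats::rbinom(n_individuals, 1L, freqs[j])
      calls[, j] <- ifelse(a == 1L, 2L, 0L)
    }
  }
  if (missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 n_individuals)] <- NA_integer_
  }
  haploid_panel(calls, ids)
}

#' Plant a divergent genomic region into an island-model dataset
#'
#' Redraws the population allele frequencies of all mapped loci inside a
#' linkage-group interval from a Balding-Nichols distribution with the
#' divergence parameter increased by `fst_boost`, then regenerates the
#' genotypes of the chosen populations at those loci (missing genotypes stay
#' missing). Used for power experiments on the sliding-window scan.
#'
#' @param ds Dataset from [simulate_island_genotypes()] (the stored
#'   simulation truth is required).
#' @param linkage_group Linkage group carrying the region.
#' @param center_cM,half_width_cM Region is
#'   `[center_cM - half_width_cM, center_cM + half_width_cM]`.
#' @param fst_boost Added to the population-level Balding-Nichols F.
#' @param pops Populations whose frequencies are redrawn (default all).
#' @param seed Integer seed.
#' @return The modified dataset; affected locus IDs in
#'   `attr(, "planted_region")`.
#' @export
plant_selected_region <- function(ds, linkage_group, center_cM, half_width_cM,
                                  fst_boost, pops = NULL, seed = 1) {
  sim <- attr(ds, "sim")
  if (is.null(sim) || is.null(sim$p_anc)) {
    stop("plant_selected_region needs a dataset from simulate_island_genotypes")
  }
  cfg <- sim$cfg
  if (linkage_group < 1 || linkage_group > cfg$n_linkage_groups) {
    stop("linkage_group outside the simulated map")
  }
  lg_len <- cfg$lg_lengths_cM[linkage_group]
  lo <- center_cM - half_width_cM
  hi <- center_cM + half_width_cM
  if (lo < 0 || hi > lg_len) stop("region extends outside the linkage group")
  if (fst_boost < 0) stop("fst_boost must be >= 0")
  if (is.null(pops)) pops <- pop_levels(ds)
  base_f <- cfg$target_fst[length(cfg$target_fst)]
  if (base_f + fst_boost >= 1) stop("boosted F must stay below 1")
  set.seed(seed)
  in_region <- !is.na(ds$loci$linkage_group) &
    ds$loci$linkage_group == linkage_group &
    ds$loci$map_position_cM >= lo & ds$loci$map_position_cM <= hi
  for (j in which(in_region)) {
    for (pk in pops) {
      k <- match(pk, colnames(sim$p_pop))
      newp <- rbalding_nichols(sim$p_anc[j], base_f + fst_boost)
      sim$p_pop[j, k] <- newp
      rows <- which(ds$pop == pk)
      obs <- rows[!is.na(ds$dosage[rows, j])]
      ds$dosage[obs, j] <- stats::rbinom(length(obs), 2L, newp)
    }
  }
  attr(ds, "sim") <- sim
  attr(ds, "planted_region") <- list(linkage_group = linkage_group,
                                     start_cM = lo, end_cM = hi,
                                     loci = ds$loci$locus_id[in_region],
                                     pops = pops, fst_boost = fst_boost)
  ds
}
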