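make_ds <- function(dosage, pop, ...) genotype_dataset(dosage, pop, ...)

test_that("call-rate filter keeps loci genotyped in at least the threshold", {
  d <- matrix(1L, 100, 3)
  d[1:21, 1] <- NA   # 79% call rate -> removed
  d[1:20, 2] <- NA   # 80% exactly -> kept
  ds <- make_ds(d, rep(c("a", "b"), 50))
  res <- filter_call_rate(ds, 0.8)
  expect_identical(res$removed, ds$loci$locus_id[1])
  expect_identical(ncol(res$dataset$dosage), 2L)
  # fully missing locus removed
  d2 <- cbind(rep(NA_integer_, 4), rep(1L, 4))
  res2 <- filter_call_rate(make_ds(d2, rep("a", 4)))
  expect_identical(length(res2$removed), 1L)
})

test_that("MAF filter removes only loci rare in every population", {
  # 5 pops x 20 inds; locus 1 rare everywhere, locus 2 common in one pop
  set.seed(1)
  pop <- rep(paste0("p", 1:5), each = 20)
  l1 <- unlist(lapply(1:5, function(k) c(1L, rep(0L, 19))))       # maf 0.025
  l2 <- unlist(lapply(1:5, function(k) {
    if (k == 2) rep(c(1L, 0L), 10) else c(1L, rep(0L, 19))        # maf 0.25 in p2
  }))
  l3 <- rep(0L, 100)                                              # monomorphic
  ds <- make_ds(cbind(l1, l2, l3), pop)
  res <- filter_maf(ds, 0.05)
  expect_setequal(res$removed, c("l1", "l3"))
  expect_identical(res$dataset$loci$locus_id, "l2")
})

test_that("tag-position filter uses the 87 bp boundary", {
  loci <- data.frame(locus_id = c("x", "y", "z"), tag_position = c(88L, 87L, 1L))
  ds <- make_ds(matrix(1L, 4, 3), rep("a", 4), loci)
  res <- filter_tag_position(ds)
  expect_identical(res$removed, "x")
})

test_that("one SNP per tag keeps the top-FST locus with deterministic ties", {
  set.seed(2)
  pop <- rep(c("a", "b"), each = 20)
  strong <- c(rep(2L, 20), rep(0L, 20))
  weak <- rep(c(0L, 1L), 20)
  dup <- strong
  loci <- data.frame(locus_id = c("t1_5", "t1_40", "t2_9"),
                     tag_id = c("t1", "t1", "t2"),
                     tag_position = c(5L, 40L, 9L))
  ds <- make_ds(cbind(weak, strong, dup), pop, loci)
  res <- select_one_snp_per_tag(ds)
  expect_identical(res$dataset$loci$locus_id, c("t1_40", "t2_9"))

  # exact tie within a tag: identical columns -> lower tag_position wins
  loci2 <- data.frame(locus_id = c("t9_30", "t9_2"), tag_id = "t9",
                      tag_position = c(30L, 2L))
  ds2 <- make_ds(cbind(strong, strong), pop, loci2)
  res2 <- select_one_snp_per_tag(ds2)
  expect_identical(res2$dataset$loci$locus_id, "t9_2")
  # and the choice is invariant to column order
  ds3 <- ds2[, c(2, 1)]
  expect_identical(select_one_snp_per_tag(ds3)$dataset$loci$locus_id, "t9_2")
})

test_that("HWE exact p-values match the enumeration oracle", {
  expect_identical(hwe_exact_pvalue(1, 0, 0), 1)
  expect_equal(hwe_exact_pvalue(5, 0, 5), oracle_hwe(5, 0, 5), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:300) {
    cnt <- rmultinom(1, sample(2:50, 1), prob = runif(3, 0.05, 1))
    expect_equal(hwe_exact_pvalue(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # enumeration probabilities form a distribution
  n <- 25; nA <- 23
  js <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(js, function(j) {
    exp(lfactorial(n) - lfactorial((nA - j) / 2) - lfactorial(j) -
          lfactorial((2 * n - nA - j) / 2) + j * log(2) +
          lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n))
  }, numeric(1))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("HWE filter needs deviation in at least min_pops populations", {
  # 5 pops; one locus with gross heterozygote deficit in 3 pops
  set.seed(4)
  pop <- rep(paste0("p", 1:5), each = 20)
  bad3 <- unlist(lapply(1:5, function(k) {
    if (k <= 3) rep(c(0L, 2L), 10) else rbinom(20, 2, 0.5)
  }))
  bad2 <- unlist(lapply(1:5, function(k) {
    if (k <= 2) rep(c(0L, 2L), 10) else rbinom(20, 2, 0.5)
  }))
  good <- rbinom(100, 2, 0.4)
  ds <- make_ds(cbind(bad3, bad2, good), pop)
  res <- filter_hwe(ds, alpha = 0.05, min_pops = 3)
  expect_identical(res$removed, "bad3")
})

test_that("pairwise r2 matches the brute-force correlation oracle", {
  x <- c(0L, 1L, 2L, 2L, 0L, 1L)
  y <- c(0L, 1L, 2L, 1L, 0L, 2L)
  ds <- make_ds(cbind(a = x, b = y, c = x), rep("a", 6))
  expect_identical(pairwise_r2(ds, "a", 1, 3), 1)
  expect_equal(pairwise_r2(ds, "a", 1, 2), oracle_r2_pearson(x, y),
               tolerance = 1e-12)
  const <- rep(1L, 6)
  ds2 <- make_ds(cbind(a = x, b = const), rep("a", 6))
  expect_true(is.na(pairwise_r2(ds2, "a", 1, 2)))
})

test_that("LD pruning removes the lower-call-rate member of tight pairs", {
  set.seed(5)
  pop <- rep(paste0("p", 1:3), each = 30)
  base <- rbinom(90, 2, 0.5)
  twin <- base                      # r2 = 1 in all pops
  twin[1:5] <- NA                   # but lower call rate
  indep <- rbinom(90, 2, 0.5)
  ds <- make_ds(cbind(base, twin, indep), pop)
  res <- ld_prune(ds, r2_threshold = 0.8, min_pops = 3)
  expect_identical(res$removed, "twin")

  # exceedance in only 2 of 3 populations -> both kept
  part <- base
  part[61:90] <- rbinom(30, 2, 0.5) # break LD in pop 3
  ds2 <- make_ds(cbind(base, part), pop)
  expect_length(ld_prune(ds2, 0.8, 3)$removed, 0)
})

test_that("PSV detection flags loci heterozygous in haploids", {
  calls <- cbind(rep(c(1L, 0L), c(6, 44)),   # 12% het -> flagged
                 rep(c(1L, 0L), c(5, 45)),   # 10% -> not flagged (strict >)
                 rep(0L, 50))
  colnames(calls) <- c("flag", "edge", "clean")
  expect_identical(detect_psv(haploid_panel(calls), 0.10), "flag")
})

test_that("individual missingness uses a strict 15% boundary", {
  d <- matrix(1L, 3, 100)
  d[1, 1:16] <- NA  # 16% -> removed
  d[2, 1:15] <- NA  # 15% -> kept
  ds <- make_ds(d, rep("a", 3))
  res <- filter_individual_missingness(ds, 0.15)
  expect_identical(res$removed, rownames(ds$dosage)[1])
})

test_that("relatedness R spans [-1, 1] and matches the IBS expectation", {
  d <- rbind(rep(2L, 10), rep(2L, 10), rep(0L, 10))
  ds <- make_ds(d, rep("a", 3))
  expect_identical(relatedness_R(ds, 1, 2), 1)
  expect_identical(relatedness_R(ds, 1, 3), -1)
  # unrelated individuals under HWE: E[IBS share] per locus =
  # sum over genotype pairs of P(g1)P(g2) * share
  set.seed(6)
  p <- runif(400, 0.2, 0.8)
  d2 <- matrix(rbinom(2 * 400 * 50, 2, rep(p, each = 100)), 100, 400)
  ds2 <- make_ds(d2, rep("a", 100))
  gp <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)  # P(dosage = 2,1,0)
  share <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  exp_ibs <- mean(vapply(p, function(pp) {
    g <- gp(pp); sum((g %o% g) * share) / 2
  }, numeric(1)))
  R <- radpopgen:::relatedness_matrix(ds2)
  expect_lt(abs(mean(R[upper.tri(R)]) - (2 * exp_ibs - 1)), 0.01)
})

test_that("duplicate detection flags planted copies and nothing else", {
  ds <- simulate_island_genotypes(
    sim_config(n_pops = 2, samples_per_pop = 25, n_loci = 2000,
               target_fst = 0.02, group_assignment = NULL,
               missing_rate = 0.02, seed = 8))
  expect_identical(nrow(find_duplicates(ds, 0.9)), 0L)
  inj <- inject_artifacts(ds, psv_fraction = 0, duplicate_pairs = 2,
                          error_snp_fraction = 0, seed = 9)
  dup <- find_duplicates(inj$dataset, 0.9)
  expect_identical(nrow(dup), 2L)
  found <- apply(dup[c("ind_i", "ind_j")], 1,
                 function(r) paste(sort(r), collapse = "|"))
  planted <- apply(inj$truth$duplicate_pairs, 1,
                   function(r) paste(sort(unname(r)), collapse = "|"))
  expect_setequal(found, planted)
})

test_that("cascade audit is consistent, ordered, and idempotent", {
  ds <- simulate_island_genotypes(
    sim_config(n_pops = 5, samples_per_pop = 20, n_loci = 300,
               target_fst = 0.04, group_assignment = NULL,
               missing_rate = 0.05, seed = 12))
  inj <- inject_artifacts(ds, psv_fraction = 0.03, duplicate_pairs = 1,
                          error_snp_fraction = 0.03, seed = 13)
  sim <- attr(ds, "sim")
  freqs <- stats::setNames(rowMeans(sim$p_pop), ds$loci$locus_id)
  freqs <- c(freqs, stats::setNames(rep(0.02, length(inj$truth$error_loci)),
                                    inj$truth$error_loci))
  panel <- simulate_haploid_panel(freqs[inj$dataset$loci$locus_id],
                                  inj$truth, n_individuals = 50, seed = 14)
  out <- run_cascade(inj$dataset, panel)
  rep <- out$report
  # audit identity: counts match removals, monotone nesting
  expect_true(all(rep$n_removed ==
    lengths(attr(rep, "removed"))))
  for (r in seq_len(nrow(rep))) {
    if (rep$unit[r] == "locus") {
      expect_identical(rep$n_loci_after[r], rep$n_loci_before[r] - rep$n_removed[r])
      expect_identical(rep$n_ind_after[r], rep$n_ind_before[r])
    } else {
      expect_identical(rep$n_ind_after[r], rep$n_ind_before[r] - rep$n_removed[r])
    }
    if (r > 1) {
      expect_identical(rep$n_loci_before[r], rep$n_loci_after[r - 1])
      expect_identical(rep$n_ind_before[r], rep$n_ind_after[r - 1])
    }
  }
  # replaying the recorded removals reproduces the output
  manual <- inj$dataset
  for (r in seq_len(nrow(rep))) {
    ids <- attr(rep, "removed")[[r]]
    if (!length(ids)) next
    if (rep$unit[r] == "locus") {
      manual <- manual[, !(manual$loci$locus_id %in% ids)]
    } else {
      manual <- manual[!(rownames(manual$dosage) %in% ids), ]
    }
  }
  expect_identical(manual$dosage, out$dataset$dosage)
  # idempotence
  again <- run_cascade(out$dataset, panel)
  expect_identical(sum(again$report$n_removed), 0L)
  # empty config is the identity
  none <- run_cascade(inj$dataset, config = list())
  expect_identical(none$dataset$dosage, inj$dataset$dosage)
})

test_that("artifact filters hit planted defects with high sensitivity", {
  ds <- simulate_island_genotypes(
    sim_config(n_pops = 5, samples_per_pop = 30, n_loci = 600,
               target_fst = 0.03, group_assignment = NULL,
               missing_rate = 0.02, seed = 20))
  inj <- inject_artifacts(ds, psv_fraction = 0.05, duplicate_pairs = 3,
                          error_snp_fraction = 0, seed = 21)
  sim <- attr(ds, "sim")
  freqs <- stats::setNames(rowMeans(sim$p_pop), ds$loci$locus_id)
  panel <- simulate_haploid_panel(freqs, inj$truth, n_individuals = 50,
                                  seed = 22)
  flagged <- detect_psv(panel, 0.10)
  truth <- inj$truth$psv_loci
  sens <- mean(truth %in% flagged)
  fpr <- mean(setdiff(colnames(panel$calls), truth) %in% flagged)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
  dup <- find_duplicates(inj$dataset, 0.9)
  expect_gte(nrow(dup), 3L)
})
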