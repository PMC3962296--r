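test_that("window construction follows the half-open sliding geometry", {
  loci <- data.frame(locus_id = c("a", "b"), linkage_group = c(1L, 1L),
                     map_position_cM = c(1.0, 3.0))
  w <- build_windows(loci, width_cM = 5, step_cM = 1, min_snps = 2)
  first <- w[w$start_cM == 0, ]
  expect_identical(first$n_snps, 2L)
  expect_true(first$eligible)
  members <- attr(w, "members")
  expect_setequal(members[[1]], c("a", "b"))
  # no mapped SNPs on a group -> no windows for it
  loci2 <- data.frame(locus_id = "c", linkage_group = NA_integer_,
                      map_position_cM = NA_real_)
  expect_identical(nrow(build_windows(loci2)), 0L)
})

test_that("window membership matches the brute-force interval oracle", {
  set.seed(81)
  for (rep in 1:40) {
    n <- sample(5:25, 1)
    loci <- data.frame(locus_id = sprintf("l%02d", seq_len(n)),
                       linkage_group = sample(1:3, n, replace = TRUE),
                       map_position_cM = round(runif(n, 0, 30), 2))
    w <- build_windows(loci, width_cM = 5, step_cM = 1, min_snps = 2)
    oracle <- oracle_window_members(loci, 5, 1)
    members <- attr(w, "members")
    keys <- paste(w$linkage_group, w$start_cM, sep = "@")
    expect_setequal(keys, names(oracle))
    for (k in seq_along(keys)) {
      expect_setequal(members[[k]], oracle[[keys[k]]])
    }
    # membership invariant to input order
    sh <- sample(n)
    w2 <- build_windows(loci[sh, ], 5, 1, 2)
    expect_identical(w2[order(w2$linkage_group, w2$start_cM), ]$n_snps,
                     w[order(w$linkage_group, w$start_cM), ]$n_snps)
  }
})

test_that("bootstrap null quantiles behave on degenerate and tiny inputs", {
  # constant values: every replicate mean equals the constant
  bn <- bootstrap_null(3, rep(0.2, 10), B = 200, seed = 1)
  expect_equal(bn$q90, 0.2)
  expect_equal(bn$q95, 0.2)
  expect_false(0.2 > bn$q95)  # no window can strictly exceed

  # exhaustive enumeration for draws of 2 from {0,0,0,0,1}:
  # mean in {0, .5, 1} with probabilities 16/25, 8/25, 1/25
  bn2 <- bootstrap_null(2, c(0, 0, 0, 0, 1), B = 20000, seed = 2)
  expect_identical(bn2$q90, 0.5)   # P(mean <= 0.5) = 24/25 >= 0.9
  expect_identical(bn2$q95, 0.5)   # 24/25 >= 0.95 as well
  same <- bootstrap_null(4, runif(20), B = 100, seed = 7)
  again <- bootstrap_null(4, runif(30), B = 100, seed = 7)
  set.seed(7); x <- runif(20)
  expect_identical(bootstrap_null(4, x, B = 100, seed = 9),
                   bootstrap_null(4, x, B = 100, seed = 9))
})

test_that("scan flags nothing when the per-locus FST is degenerate", {
  # identical genotype columns in identical populations: every per-locus
  # theta is the same constant, so no window mean can strictly exceed the
  # bootstrap 95% quantile
  col <- rep(c(0L, 1L, 2L, 1L), 5)
  block <- matrix(col, 20, 60)
  loci <- data.frame(locus_id = sprintf("l%02d", 1:60),
                     linkage_group = rep(1:3, each = 20),
                     map_position_cM = rep(seq(0.5, 38.5, by = 2), 3))
  ds <- genotype_dataset(rbind(block, block), rep(c("a", "b"), each = 20), loci)
  sc <- scan_pair(ds, "a", "b", B1 = 200, B2 = 500, seed = 3)
  expect_false(any(sc$windows$significant))
})

test_that("identical-copy populations are flagged at no more than chance", {
  set.seed(83)
  block <- matrix(rbinom(20 * 60, 2, 0.4), 20, 60)
  loci <- data.frame(locus_id = sprintf("l%02d", 1:60),
                     linkage_group = rep(1:3, each = 20),
                     map_position_cM = rep(seq(0.5, 38.5, by = 2), 3))
  ds <- genotype_dataset(rbind(block, block), rep(c("a", "b"), each = 20), loci)
  sc <- scan_pair(ds, "a", "b", B1 = 200, B2 = 500, seed = 3)
  w <- sc$windows[sc$windows$eligible, ]
  expect_lte(mean(w$significant), 0.15)
})

test_that("escalation to the larger bootstrap follows the 90% rule", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 30, n_loci = 600,
                    target_fst = 0.03, group_assignment = NULL,
                    missing_rate = 0, mapped_fraction = 1,
                    n_linkage_groups = 4, lg_lengths_cM = rep(40, 4), seed = 84)
  ds <- simulate_island_genotypes(cfg)
  sc <- scan_pair(ds, unique(ds$pop)[1], unique(ds$pop)[2],
                  B1 = 300, B2 = 900, seed = 4)
  w <- sc$windows[sc$windows$eligible, ]
  expect_true(all(w$B %in% c(300L, 900L)))
  expect_true(any(w$B == 900L))           # some windows escalate
  expect_true(all(!w$significant | w$B %in% c(300L, 900L)))
  # significant implies mean above the 95% null quantile
  expect_true(all(w$mean_fst[w$significant] > w$q95[w$significant]))
  # ineligible windows are never tested or significant
  sparse <- sc$windows[!sc$windows$eligible, ]
  expect_true(all(is.na(sparse$B)))
  expect_false(any(sparse$significant))
  # determinism
  sc2 <- scan_pair(ds, unique(ds$pop)[1], unique(ds$pop)[2],
                   B1 = 300, B2 = 900, seed = 4)
  expect_identical(sc$windows, sc2$windows)
})

test_that("region merging matches the interval-union oracle", {
  mk <- function(sig) {
    structure(list(windows = data.frame(
      linkage_group = sig$lg, start_cM = sig$s, end_cM = sig$e,
      n_snps = 3L, eligible = TRUE, mean_fst = 1, q90 = 0, q95 = 0,
      B = 1000L, significant = TRUE)), class = "window_scan_result")
  }
  r <- merge_regions(mk(data.frame(lg = 1L, s = c(0, 1), e = c(5, 6))))
  expect_identical(nrow(r), 1L)
  expect_equal(r$start_cM, 0)
  expect_equal(r$end_cM, 6)
  r2 <- merge_regions(mk(data.frame(lg = 1L, s = c(0, 10), e = c(5, 15))))
  expect_identical(nrow(r2), 2L)

  set.seed(85)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    s <- sample(0:30, n, replace = TRUE)
    sig <- data.frame(lg = 2L, s = s, e = s + 5)
    got <- merge_regions(mk(sig))
    want <- oracle_merge_intervals(sig$s, sig$e)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$start_cM, want[, 1])
    expect_equal(got$end_cM, want[, 2])
  }
})

test_that("cross-pair summary counts overlapping regions per cM bin", {
  mk <- function(lg, s, e) {
    structure(list(windows = data.frame(
      linkage_group = lg, start_cM = s, end_cM = e, n_snps = 3L,
      eligible = TRUE, mean_fst = 1, q90 = 0, q95 = 0, B = 1000L,
      significant = TRUE)), class = "window_scan_result")
  }
  # region shared by 6 of 10 pairs at LG 2, 10-15 cM
  shared <- lapply(1:6, function(i) mk(2L, 10, 15))
  private <- lapply(1:4, function(i) mk(3L, i * 20, i * 20 + 5))
  cs <- cross_pair_summary(c(shared, private))
  expect_identical(max(cs$n_pairs), 6L)
  expect_identical(max(cs$n_pairs[cs$linkage_group == 3]), 1L)
  on2 <- cs[cs$linkage_group == 2, ]
  expect_setequal(on2$bin_start_cM, 10:14)
  expect_true(all(on2$n_pairs == 6L))
})
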