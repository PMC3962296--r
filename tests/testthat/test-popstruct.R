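test_that("wc_theta handles fixation, identity, and a worked example", {
  d <- rbind(matrix(2L, 6, 2), matrix(0L, 6, 2))
  ds <- genotype_dataset(d, rep(c("a", "b"), each = 6))
  expect_equal(wc_theta(ds)$theta_multi, 1)

  # identical genotype counts in both populations -> theta <= 0
  block <- matrix(rep(c(0L, 1L, 2L), 4), 12, 2)
  ds2 <- genotype_dataset(rbind(block, block), rep(c("a", "b"), each = 12))
  expect_lte(wc_theta(ds2)$theta_multi, 0)

  # counts (AA,Aa,aa) = (10,5,5) vs (2,6,12)
  g1 <- rep(c(2L, 1L, 0L), c(10, 5, 5))
  g2 <- rep(c(2L, 1L, 0L), c(2, 6, 12))
  ds3 <- genotype_dataset(cbind(c(g1, g2)), rep(c("a", "b"), each = 20))
  o <- oracle_wc_locus(rbind(c(10, 5, 5), c(2, 6, 12)))
  got <- wc_theta(ds3)$components
  expect_equal(got$a, o$a, tolerance = 1e-12)
  expect_equal(got$b, o$b, tolerance = 1e-12)
  expect_equal(got$c, o$c, tolerance = 1e-12)
  expect_equal(got$theta, o$a / (o$a + o$b + o$c), tolerance = 1e-12)
  expect_error(wc_theta(ds3, pops = "a"), "two populations")
})

test_that("wc_theta components match the oracle on random instances", {
  for (cfg in list(c(2, 8), c(3, 6), c(5, 10))) {
    ds <- rand_dataset(n_pops = cfg[1], n_per_pop = cfg[2], n_loci = 350,
                       missing_rate = 0.15, seed = cfg[1] * 100)
    got <- wc_theta(ds)$components
    for (j in seq_len(ncol(ds$dosage))) {
      o <- oracle_wc_locus(locus_counts(ds, j))
      if (is.na(o$a)) {
        expect_true(is.na(got$a[j]))
      } else {
        expect_equal(got$a[j], o$a, tolerance = 1e-12)
        expect_equal(got$b[j], o$b, tolerance = 1e-12)
        expect_equal(got$c[j], o$c, tolerance = 1e-12)
      }
    }
  }
})

test_that("pairwise FST matrix is symmetric and orders nested divergence", {
  ds <- simulate_island_genotypes(sim_config(n_loci = 1000, seed = 31))
  m <- pairwise_fst_matrix(ds)
  expect_identical(m, t(m))
  expect_true(all(is.na(diag(m))))
  # groups: Tubutulik | Anvik+Kogrukluk+Koktuli | BigSalmon
  within <- c(m["Anvik", "Kogrukluk"], m["Anvik", "Koktuli"],
              m["Kogrukluk", "Koktuli"])
  between <- m["Tubutulik", c("Anvik", "Kogrukluk", "Koktuli", "BigSalmon")]
  expect_true(max(within) < min(between))

  # identical populations -> entries <= 0
  block <- matrix(rep(rbinom(40, 2, 0.4), 3), ncol = 2)
  ds2 <- genotype_dataset(block, rep(c("a", "b", "c"), each = 20))
  m2 <- pairwise_fst_matrix(ds2)
  expect_true(all(m2[upper.tri(m2)] <= 0))
})

test_that("heterozygosity matches closed forms", {
  d <- matrix(1L, 10, 4)
  ds <- genotype_dataset(d, rep("a", 10))
  h <- heterozygosity(ds)
  expect_equal(h$per_pop$H_O, 1)
  expect_equal(h$per_pop$H_E, 0.5)

  d0 <- matrix(2L, 10, 4)
  h0 <- heterozygosity(genotype_dataset(d0, rep("a", 10)))
  expect_equal(h0$per_pop$H_O, 0)
  expect_equal(h0$per_pop$H_E, 0)

  # E[H_E] under MAF ~ U(0.05, 0.5): integral of 2p(1-p)
  ds2 <- simulate_island_genotypes(
    sim_config(n_pops = 2, samples_per_pop = 60, n_loci = 4000,
               target_fst = 0.005, group_assignment = NULL,
               missing_rate = 0, seed = 33))
  f <- function(p) 2 * p * (1 - p)
  expected <- integrate(f, 0.05, 0.5)$value / 0.45
  got <- mean(heterozygosity(ds2)$per_pop$H_E)
  expect_lt(abs(got - expected), 0.01)
})

test_that("differentiation test is calibrated and deterministic", {
  # fixed differences: no permutation can beat the observed theta
  d <- rbind(matrix(2L, 8, 5), matrix(0L, 8, 5))
  ds <- genotype_dataset(d, rep(c("a", "b"), each = 8))
  r <- differentiation_test(ds, "a", "b", n_perm = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
  r2 <- differentiation_test(ds, "a", "b", n_perm = 99, seed = 1)
  expect_identical(r$p_value, r2$p_value)

  # exchangeable data: rejection rate near nominal 0.05
  rej <- vapply(1:120, function(s) {
    set.seed(s * 7)
    p <- runif(40, 0.1, 0.5)
    dd <- matrix(rbinom(30 * 40, 2, rep(p, each = 30)), 30, 40)
    dsx <- genotype_dataset(dd, rep(c("a", "b"), each = 15))
    differentiation_test(dsx, "a", "b", n_perm = 99, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("amova percentages sum to 100 and order hierarchical variance", {
  ds <- simulate_island_genotypes(sim_config(n_loci = 1500, seed = 35))
  grp <- c(Tubutulik = "norton", Anvik = "coastal", Kogrukluk = "coastal",
           Koktuli = "coastal", BigSalmon = "yukon")
  am <- amova(ds, grp)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  pct <- stats::setNames(am$percent, am$source)
  expect_gt(pct["among_groups"], pct["among_pops_within_groups"])
  expect_error(amova(ds, grp[-1]), "every population")

  # i.i.d. populations: both structured strata near zero
  set.seed(36)
  d <- matrix(rbinom(100 * 2000, 2, rep(runif(2000, 0.1, 0.9), each = 100)),
              100, 2000)
  ds0 <- genotype_dataset(d, rep(paste0("p", 1:5), each = 20))
  am0 <- amova(ds0, stats::setNames(c("g1", "g1", "g1", "g2", "g2"),
                                    paste0("p", 1:5)))
  expect_lt(max(abs(am0$percent[1:2])), 2)
})

test_that("one-group amova agrees with the Weir-Cockerham ratio", {
  ds <- simulate_island_genotypes(
    sim_config(n_pops = 3, samples_per_pop = 30, n_loci = 400,
               target_fst = 0.05, group_assignment = NULL,
               missing_rate = 0, seed = 37))
  am <- amova(ds, stats::setNames(rep("g", 3), unique(ds$pop)))
  th_am <- am$sigma2[am$source == "among_pops"] / sum(am$sigma2)
  th_wc <- wc_theta(ds)$theta_multi
  # allele-level two-stratum decomposition vs genotype-aware W&C estimator:
  # identical up to the within-individual (heterozygosity) term
  expect_lt(abs(th_am - th_wc), 0.005)
})

test_that("PCA separates fixed populations and calibrates under no structure", {
  d <- rbind(matrix(2L, 10, 20), matrix(0L, 10, 20))
  d[1, 1] <- NA    # mean imputation path
  ds <- genotype_dataset(d, rep(c("a", "b"), each = 10))
  p <- pca_genotypes(ds, n_axes = 2, n_perm = 99, seed = 1)
  expect_equal(p$p_values[1], 1 / 100)
  expect_true(all(p$scores[1:10, 1] * p$scores[11:20, 1] < 0) ||
              all(sign(p$scores[1:10, 1]) != sign(p$scores[11:20, 1])))
  expect_equal(sum(p$proportion), 1, tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  expect_identical(p$p_values,
                   pca_genotypes(ds, n_axes = 2, n_perm = 99, seed = 1)$p_values)

  rej <- vapply(1:40, function(s) {
    set.seed(s * 13)
    pp <- runif(60, 0.1, 0.5)
    dd <- matrix(rbinom(25 * 60, 2, rep(pp, each = 25)), 25, 60)
    dsx <- genotype_dataset(dd, rep("one", 25))
    pca_genotypes(dsx, n_axes = 1, n_perm = 49, seed = s)$p_values[1] <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("empirical-quantile outlier flagging is a pure rank rule", {
  set.seed(38)
  theta <- c(runif(95, 0, 0.1), runif(5, 0.5, 0.9))
  ft <- structure(list(components = data.frame(
    locus_id = sprintf("l%03d", 1:100), a = NA, b = NA, c = NA,
    theta = theta, stringsAsFactors = FALSE)), class = "fst_table")
  out <- flag_fst_outliers_quantile(ft, 0.95)
  expect_length(out, 5)
  expect_setequal(out, sprintf("l%03d", 96:100))
  expect_length(flag_fst_outliers_quantile(ft, 1), 0)
  small <- ft; small$components <- small$components[1:10, ]
  expect_error(flag_fst_outliers_quantile(small), "at least 20")
})
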