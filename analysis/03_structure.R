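#!/usr/bin/env Rscript
# Stage 3: population structure.
#
# On the filtered panel: pairwise Weir-Cockerham FST with permutation
# significance, observed/expected heterozygosities, hierarchical AMOVA over
# the regional grouping, per-locus FST with empirical-quantile outliers,
# and PCA with permutation-tested axes.

library(radpopgen)

ds <- read_genepop("results/filtered/genotypes.gen")
loci <- read.delim("results/filtered/loci.tsv")
ds$loci <- radpopgen:::complete_loci(loci, ncol(ds$dosage))
dir.create("results/structure", showWarnings = FALSE, recursive = TRUE)

pops <- unique(ds$pop)
fst <- pairwise_fst_matrix(ds)
message("pairwise FST:")
print(round(fst, 3))
write.table(round(fst, 5), "results/structure/pairwise_fst.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

# permutation significance per pair (modest replicate count for a desk run)
sig <- data.frame()
for (i in seq_along(pops)[-length(pops)]) {
  for (j in (i + 1):length(pops)) {
    dt <- differentiation_test(ds, pops[i], pops[j], n_perm = 199,
                               seed = 100 + 10 * i + j)
    sig <- rbind(sig, data.frame(pop_i = pops[i], pop_j = pops[j],
                                 theta = dt$theta_obs, p = dt$p_value))
  }
}
write.table(sig, "results/structure/differentiation_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d/%d pairs significant at p <= 0.01",
                sum(sig$p <= 0.01), nrow(sig)))

het <- heterozygosity(ds)
print(het$per_pop)
write.table(het$per_pop, "results/structure/heterozygosity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

grp <- c(Tubutulik = "norton", Anvik = "coastal", Kogrukluk = "coastal",
         Koktuli = "coastal", BigSalmon = "yukon")
am_all <- amova(ds, grp)
message("AMOVA, all populations:")
print(am_all)
no_yukon <- ds[ds$pop != "BigSalmon", ]
am_sub <- amova(no_yukon, grp[names(grp) != "BigSalmon"])
message("AMOVA, upper-Yukon population excluded:")
print(am_sub)
am_all$analysis <- "all_pops"
am_sub$analysis <- "no_upper_yukon"
write.table(rbind(as.data.frame(am_all), as.data.frame(am_sub)),
            "results/structure/amova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ft <- wc_theta(ds)
out_loci <- flag_fst_outliers_quantile(ft, 0.95)
message(length(out_loci), " loci above the 95% empirical FST quantile")
write.table(ft$components, "results/structure/per_locus_fst.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(out_loci, "results/structure/outlier_loci.txt")

pca <- pca_genotypes(ds, n_axes = 2, n_perm = 199, seed = 7)
print(pca)
scores <- data.frame(id = rownames(pca$scores), pop = ds$pop,
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
write.table(scores, "results/structure/pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
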