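#!/usr/bin/env Rscript
# Stage 1: build the working dataset.
#
# Generates a genotype panel with the structure of the five-river study
# system (five populations in three regional groups, overall FST ~ 0.04,
# a 34-linkage-group map carrying ~10% of loci, several SNPs per RAD tag),
# contaminates it with the defect classes the QC cascade exists to remove
# (paralogs, 3'-end error SNPs, duplicated individuals), and genotypes a
# 50-fish haploid panel for the paralog screen. Everything is written as
# plain text under results/sim/ so later stages start from files, the way
# the real pipeline starts from a Stacks export.

library(radpopgen)

seed <- 1
n_loci <- 3000
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_loci = n_loci, seed = seed)
ds <- simulate_island_genotypes(cfg)
message(sprintf("simulated %d individuals x %d loci in %d populations",
                nrow(ds$dosage), ncol(ds$dosage), length(unique(ds$pop))))

inj <- inject_artifacts(ds, psv_fraction = 0.03, duplicate_pairs = 2,
                        error_snp_fraction = 0.03, missing_rate = 0.03,
                        seed = seed + 1)
dsc <- inj$dataset
message(sprintf("injected %d PSV loci, %d error SNPs, %d duplicate individuals",
                length(inj$truth$psv_loci), length(inj$truth$error_loci),
                nrow(inj$truth$duplicate_pairs)))

# haploid panel from a diverged source population (frequencies averaged)
sim <- attr(ds, "sim")
freqs <- stats::setNames(rowMeans(sim$p_pop), ds$loci$locus_id)
err_f <- stats::setNames(runif(length(inj$truth$error_loci), 0.005, 0.03),
                         inj$truth$error_loci)
panel <- simulate_haploid_panel(c(freqs, err_f)[dsc$loci$locus_id],
                                inj$truth, n_individuals = 50,
                                missing_rate = 0.02, seed = seed + 2)

write_genepop(dsc, file.path(out, "genotypes.gen"),
              title = "simulated five-river SNP panel (contaminated)")
write_genepop(panel, file.path(out, "haploids.gen"))

mapped <- !is.na(dsc$loci$linkage_group)
write.table(data.frame(locus_id = dsc$loci$locus_id[mapped],
                       linkage_group = dsc$loci$linkage_group[mapped],
                       cM = dsc$loci$map_position_cM[mapped]),
            file.path(out, "map.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dsc$loci, file.path(out, "loci.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- rbind(
  data.frame(kind = "psv_locus", id = inj$truth$psv_loci),
  data.frame(kind = "error_locus", id = inj$truth$error_loci),
  data.frame(kind = "duplicate_individual", id = inj$truth$duplicate_pairs$duplicate))
write.table(truth, file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote ", out, "/{genotypes.gen, haploids.gen, map.tsv, loci.tsv, truth.tsv}")
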