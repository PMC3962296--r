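#!/usr/bin/env Rscript
# Stage 6: sliding-window scan for candidate selected regions.
#
# For every population pair: per-locus pairwise FST on the mapped loci,
# 5-cM windows shifted by 1 cM (at least 2 SNPs per window), a bootstrap
# null resampled from the pair's own per-locus FST distribution (1000
# replicates, escalated to 5000 when a window exceeds the 90% quantile),
# significance above the 95% quantile, merged regions per pair, and the
# cross-pair per-cM overlap counts that locate regions divergent in many
# comparisons.

library(radpopgen)

ds <- read_genepop("results/filtered/genotypes.gen")
loci <- read.delim("results/filtered/loci.tsv")
ds$loci <- radpopgen:::complete_loci(loci, ncol(ds$dosage))
dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)

pops <- unique(ds$pop)
scans <- list()
all_windows <- data.frame()
all_regions <- data.frame()
for (i in seq_along(pops)[-length(pops)]) {
  for (j in (i + 1):length(pops)) {
    key <- paste(pops[i], pops[j], sep = "-")
    sc <- scan_pair(ds, pops[i], pops[j], width_cM = 5, step_cM = 1,
                    min_snps = 2, B1 = 1000, B2 = 5000,
                    seed = 500 + 10 * i + j)
    scans[[key]] <- sc
    reg <- merge_regions(sc)
    message(sprintf("%-22s %3d eligible windows, %2d significant, %2d regions",
                    key, sum(sc$windows$eligible),
                    sum(sc$windows$significant), nrow(reg)))
    w <- sc$windows; w$pair <- key
    all_windows <- rbind(all_windows, w)
    if (nrow(reg)) { reg$pair <- key; all_regions <- rbind(all_regions, reg) }
  }
}
write.table(all_windows, "results/scan/windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(all_regions, "results/scan/regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cs <- cross_pair_summary(scans)
write.table(cs, "results/scan/cross_pair_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(cs)) {
  top <- cs[order(-cs$n_pairs), ][1:min(5, nrow(cs)), ]
  message("map bins shared by the most population pairs:")
  print(top)
}
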