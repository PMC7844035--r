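#!/usr/bin/env Rscript
# Population structure of the panel: PCA of the dosage matrix, an NJ
# tree from pairwise p-distances, binned LD decay per population, and
# PLINK-style ROH detection for every sample.

suppressPackageStartupMessages(library(sweepscan))

rd <- read_vcf("results/panel/panel.vcf", "results/panel/popmap.tsv")
panel <- site_filter(rd$panel)
popmap <- rd$popmap
pops <- unique(popmap$pop)

pc <- pca(panel, k = 4)
cat("PCA variance fractions (PC1-4):",
    paste(round(100 * pc$var_frac, 1), collapse = " "), "%\n")
write.table(data.frame(sample = rownames(pc$coords),
                       pop = popmap$pop[match(rownames(pc$coords),
                                              popmap$sample)],
                       round(pc$coords, 4)),
            "results/pca.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
km <- kmeans(pc$coords[, 1:2], centers = length(pops), nstart = 25)
tab <- table(km$cluster, popmap$pop)
cat("k-means on PC1-PC2 recovers populations at",
    round(100 * sum(apply(tab, 2, max)) / sum(tab), 1), "% agreement\n")

tr <- nj_tree(p_distance_matrix(panel))
ape::write.tree(tr, "results/nj.nwk")
cat("NJ tree written to results/nj.nwk\n")

for (p in pops) {
  ld <- ld_decay(panel, popmap, p)
  write.table(ld, paste0("results/ld_", p, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: mean r2 %.3f at 0-10 kb vs %.3f at 200-300 kb\n", p,
              mean(ld$mean_r2[ld$hi <= 1e4], na.rm = TRUE),
              mean(ld$mean_r2[ld$lo >= 2e5], na.rm = TRUE)))
}

rohs <- do.call(rbind, lapply(popmap$sample, function(s)
  detect_roh(panel, s)))
write.table(rohs, "results/roh.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("ROH segments called:", nrow(rohs), "\n")
if (nrow(rohs)) {
  big <- rohs[which.max(rohs$length_kb), ]
  cat(sprintf("largest: %s %s %.0f-%.0f kb (%.0f kb, %d SNPs)\n",
              big$sample, big$chrom, big$start / 1e3, big$end / 1e3,
              big$length_kb, big$n_snps))
}
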