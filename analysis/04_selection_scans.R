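#!/usr/bin/env Rscript
# The three selection scans over the panel: pooled heterozygosity
# (Hp/ZHp, 100-kb windows sliding by 50 kb) per population, windowed
# Weir-Cockerham FST (ZFst) and XP-EHH per population pair. Writes one
# TSV per scan under results/.

suppressPackageStartupMessages(library(sweepscan))

rd <- read_vcf("results/panel/panel.vcf", "results/panel/popmap.tsv")
panel <- site_filter(rd$panel)
popmap <- rd$popmap
pops <- unique(popmap$pop)
chrom_lengths <- tapply(panel$pos, panel$chrom, max) + 1
windows <- make_windows(chrom_lengths[unique(panel$chrom)],
                        size = 100000, step = 50000)

for (p in pops) {
  hp <- pooled_heterozygosity(allele_counts(panel, popmap, p), windows)
  write.table(hp, paste0("results/hp_", p, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  low <- hp[!is.na(hp$z) & hp$z < -4, ]
  cat(sprintf("%s: %d windows with ZHp < -4 (min ZHp %.1f)\n", p,
              nrow(low), suppressWarnings(min(hp$z, na.rm = TRUE))))
}

for (pr in combn(pops, 2, simplify = FALSE)) {
  nm <- paste(pr, collapse = "_vs_")
  fst <- windowed_fst(wc_components(panel, popmap, pr[1], pr[2]), windows)
  write.table(fst, paste0("results/fst_", nm, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hi <- significant_fst_windows(fst)
  cat(sprintf("%s: global FST %.3f, %d windows with ZFst > 4\n", nm,
              global_fst(wc_components(panel, popmap, pr[1], pr[2])),
              nrow(hi)))

  xp <- xpehh(panel, popmap, pr[1], pr[2])
  tails <- top_fraction(xp, q = 0.01, side = "both")
  xw <- xpehh_windows(xp, windows, tails)
  write.table(xp, paste0("results/xpehh_", nm, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(xw, paste0("results/xpehh_windows_", nm, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d SNPs in the top-1%% XP-EHH tail, %d windows flagged\n",
              nm, nrow(tails), sum(xw$in_tail)))
}
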