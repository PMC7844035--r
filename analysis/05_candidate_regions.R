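#!/usr/bin/env Rscript
# Candidate-region extraction: applies the outlier rules (ZHp < -4,
# ZFst > 4, top-1% XP-EHH), merges significant windows into regions,
# lists overlapping genes, intersects the FST and XP-EHH gene sets, and
# runs a hypergeometric enrichment against synthetic gene sets built
# around the planted sweep.

suppressPackageStartupMessages(library(sweepscan))

rd <- read_vcf("results/panel/panel.vcf", "results/panel/popmap.tsv")
panel <- site_filter(rd$panel)
popmap <- rd$popmap
models <- read_gene_models("results/panel/genes.bed")
pops <- unique(popmap$pop)
chrom_lengths <- tapply(panel$pos, panel$chrom, max) + 1
windows <- make_windows(chrom_lengths[unique(panel$chrom)])

method_genes <- list()
all_regions <- list()
for (p in pops) {
  hp <- pooled_heterozygosity(allele_counts(panel, popmap, p), windows)
  reg <- merge_regions(select_windows(hp, "zhp"))
  all_regions[[paste0("zhp_", p)]] <- reg
  method_genes[[paste0("zhp_", p)]] <- genes_in_regions(reg, models)$union
}
for (pr in combn(pops, 2, simplify = FALSE)) {
  nm <- paste(pr, collapse = "_vs_")
  fst <- windowed_fst(wc_components(panel, popmap, pr[1], pr[2]), windows)
  reg <- merge_regions(select_windows(fst, "zfst"))
  all_regions[[paste0("zfst_", nm)]] <- reg
  method_genes[[paste0("zfst_", nm)]] <- genes_in_regions(reg, models)$union
  xp <- xpehh(panel, popmap, pr[1], pr[2])
  xw <- xpehh_windows(xp, windows, top_fraction(xp, 0.01))
  regx <- merge_regions(select_windows(xw, "xpehh"))
  all_regions[[paste0("xpehh_", nm)]] <- regx
  method_genes[[paste0("xpehh_", nm)]] <- genes_in_regions(regx, models)$union
}

regions <- do.call(rbind, lapply(names(all_regions), function(nm) {
  r <- all_regions[[nm]]
  if (nrow(r)) cbind(method = nm, r) else NULL
}))
write.table(regions, "results/candidate_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Candidate regions per method:\n")
for (nm in names(all_regions))
  cat(sprintf("  %-18s %d region(s), %d gene(s)\n", nm,
              nrow(all_regions[[nm]]), length(method_genes[[nm]])))

fst_genes <- unique(unlist(method_genes[grep("^zfst_", names(method_genes))]))
xp_genes <- unique(unlist(method_genes[grep("^xpehh_", names(method_genes))]))
shared <- overlap_genes(list(fst = fst_genes, xpehh = xp_genes))
writeLines(shared, "results/fst_xpehh_shared_genes.tsv")
cat("Genes shared by the ZFst and XP-EHH scans:", length(shared), "\n")

# synthetic gene sets: one centred on the planted sweep, one elsewhere
background <- names(models$genes)
sweep_term <- background[grepl("^chr1_g0(3[0-9])$", background)]
gene_sets <- list(sweep_locus = sweep_term,
                  control_locus = background[grepl("^chr2_g01", background)])
if (length(shared)) {
  enr <- hypergeom_enrich(intersect(shared, background), gene_sets,
                          background)
  write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("Enrichment (hypergeometric upper tail):\n")
  print(enr, row.names = FALSE)
}
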