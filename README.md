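# sweepscan

Genome-wide selection-signature scans for multi-population diploid
panels, in R.

Breeding and local adaptation leave detectable footprints in
resequencing data: long stretches of depressed diversity, elevated
allele-frequency differentiation between populations, and unusually
long shared haplotypes. `sweepscan` implements the three classical
scans used to find them, plus the supporting population-genetic
toolkit, for phased biallelic SNP panels (VCF + population map + gene
models):

* **Hp / ZHp** — windowed pooled heterozygosity
  `Hp = 2·ΣnMAJ·ΣnMIN / (ΣnMAJ+ΣnMIN)²` per population, 100-kb windows
  sliding by 50 kb, Z-transformed genome-wide; outliers at `ZHp < −4`.
* **ZFst** — per-locus Weir–Cockerham (1984) variance components `a`,
  `b`, `c`, aggregated per window as `Σa / Σ(a+b+c)` and
  Z-transformed per population pair; outliers at `ZFst > 4`.
* **XP-EHH** — `ln(iHH_A / iHH_B)` from trapezoid-integrated extended
  haplotype homozygosity around every SNP, standardized genome-wide;
  outliers in the top 1% of SNPs (or `p ≤ 0.01`).

Around the scans: per-population diversity (He, Ho, MAF, FIS),
PLINK-style runs of homozygosity with the standard resequencing flag
set, binned LD decay (r²), PCA and neighbor-joining trees for
population structure, candidate-region merging with gene annotation,
and hypergeometric gene-set enrichment. A Balding–Nichols
founder-mosaic simulator plants hard sweeps and homozygous segments
with known truth, so the whole pipeline validates itself.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
fixed-seed panel: three populations x 15 samples, two 10-Mb
chromosomes, 10,000 SNPs, background differentiation F = 0.05, one
500-kb sweep planted in `pop1` (chr1, 3.0–3.5 Mb) and one 800-kb
homozygous segment in a `pop2` sample.

```sh
Rscript analysis/01_simulate_panel.R     # writes results/panel/{panel.vcf,...}
Rscript analysis/02_filter_diversity.R
Rscript analysis/03_structure.R
Rscript analysis/04_selection_scans.R
Rscript analysis/05_candidate_regions.R
```

`04_selection_scans.R` prints, for that seed:

```
pop1: 9 windows with ZHp < -4 (min ZHp -6.2)
pop2: 0 windows with ZHp < -4 (min ZHp -3.2)
pop3: 0 windows with ZHp < -4 (min ZHp -2.9)
pop1_vs_pop2: global FST 0.072, 10 windows with ZFst > 4
pop1_vs_pop2: 99 SNPs in the top-1% XP-EHH tail, 11 windows flagged
...
pop2_vs_pop3: global FST 0.054, 0 windows with ZFst > 4
```

Only the population carrying the sweep shows ZHp outliers, and only
its comparisons show ZFst outliers; the sweep-free `pop2` vs `pop3`
comparison is clean. `05_candidate_regions.R` then merges the
significant windows, intersects the gene lists of the FST and XP-EHH
scans, and finds the shared genes concentrated in the planted
interval:

```
zhp_pop1           1 region(s), 5 gene(s)
zfst_pop1_vs_pop2  1 region(s), 5 gene(s)
xpehh_pop1_vs_pop2 1 region(s), 6 gene(s)
Genes shared by the ZFst and XP-EHH scans: 5
          term  K k n   N           p  significant
   sweep_locus 10 5 5 200 9.94e-08    TRUE
 control_locus 10 0 5 200 1.00        FALSE
```

The same machinery is available programmatically:

```r
library(sweepscan)
cfg <- sim_config(seed = 1, n_pops = 2, samples_per_pop = 25,
                  sweep_specs = list(sweep_spec("pop1", "chr1",
                                                3e6, 3.5e6, 3.25e6)))
bundle <- run_pipeline(sim = simulate_panel(cfg), outdir = "scan_out")
```

or stage by stage (`read_vcf()`, `site_filter()`,
`pooled_heterozygosity()`, `wc_components()` / `windowed_fst()`,
`xpehh()`, `detect_roh()`, `ld_decay()`, `pca()`, `nj_tree()`,
`merge_regions()`, `hypergeom_enrich()`). See the vignette
(`vignettes/selection-scans.Rmd`) for the statistics, conventions and
simulator design.

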