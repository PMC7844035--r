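---
title: "Detecting selection signatures in multi-population diploid panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures in multi-population diploid panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## Scope

`sweepscan` detects genomic regions under recent positive selection in
panels of phased diploid genotypes from two or more populations. The
workflow is the classical resequencing one: per-population diversity
summaries, a windowed pooled-heterozygosity scan (Hp/ZHp), windowed
Weir–Cockerham FST (ZFst) between population pairs, the
cross-population extended-haplotype-homozygosity statistic (XP-EHH),
PLINK-style runs of homozygosity, binned LD decay, PCA and a
neighbor-joining tree for structure, and finally candidate-region
extraction with gene annotation and hypergeometric gene-set
enrichment. A built-in simulator with planted sweeps and homozygous
segments supplies ground truth, so every stage is testable without
external data.

## The statistics

**Pooled heterozygosity.** For a window containing SNPs with
per-population major/minor allele counts $n_{MAJ,i}, n_{MIN,i}$,

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
             {(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

with sums over the SNPs of the window. $H_p \in [0, 0.5]$, reaching 0
when every SNP is fixed and 0.5 when major and minor sums balance. A
hard sweep depresses $H_p$ because the swept haplotype drags linked
minor alleles to near-fixation. Windows are 100 kb sliding by 50 kb
(the standard geometry for ~5x resequencing panels), and the window
scores of each population are standardized genome-wide to Z-scores
(sample sd, $n-1$); the outlier rule is $ZH_p < -4$. Major/minor
labels are per SNP from the population's own pooled counts; an exact
tie counts the reference allele as major, so the statistic is
deterministic. Windows with fewer than `min_snps = 10` SNPs are left
unscored and excluded from the Z-transformation — the window geometry
guarantees heavy SNP counts at realistic densities, so this only trims
assembly edges.

**Weir–Cockerham FST.** Per biallelic locus we compute the three
variance components of the 1984 ANOVA estimator — $a$ (among
populations), $b$ (among individuals within populations), $c$ (within
individuals) — from the called sample sizes, allele frequencies and
observed heterozygote proportions of the two populations. The window
statistic is the ratio of sums $\Sigma a / \Sigma(a+b+c)$, i.e. the
"weighted" windowed estimator that VCF tooling reports; a
mean-of-ratios mode is available behind `method =` for comparison but
ratio-of-sums is the default because it is the convention of the tools
this pipeline mirrors. Negative per-locus and per-window estimates are
retained rather than clamped — clamping would skew the genome-wide Z
distribution that the $ZF_{ST} > 4$ rule cuts. Loci monomorphic across
both populations carry no information and are skipped; loci where
either population has fewer than two called genotypes are undefined.
Z-scores are computed per population pair across that pair's windows.

**XP-EHH.** EHH at a flanking site $x$ is the probability that two
randomly drawn haplotypes of a population are identical at every SNP
from the core through $x$:
$EHH(x) = \sum_g \binom{n_g}{2} / \binom{n}{2}$ over the identity
classes $g$. Following the cross-population convention, EHH is
computed over *all* haplotypes of the population, not split by core
allele. iHH is the trapezoidal integral of EHH over physical distance,
both directions summed, truncated where EHH falls below 0.05 (that
trapezoid is still included, as is standard) and at inter-SNP gaps
above 200 kb; the paper trail for this statistic fixes none of these,
so the package exposes them as arguments with those conventional
defaults. The raw score $\ln(iHH_A/iHH_B)$ is standardized genome-wide
by mean and sample sd — frequency-binned normalization belongs to iHS,
not XP-EHH. Both outlier modes are provided: the empirical top 1% of
SNPs per tail (default, the operative criterion in the study design
this mirrors) and a two-sided normal $p \le 0.01$ mode. Missing
alleles break haplotype identity (conservative); a missing haplotype
becomes a permanent singleton.

The scan over all cores is implemented in C++ (as the established
haplotype-scan packages do); an independent pure-R route
(`ehh()`/`ihh()`) exists for profile inspection and serves as a
cross-check of the compiled kernel in the test suite.

**ROH.** The scanning-window detector follows the PLINK procedure with
the flag set used for ~5x resequencing data: 50-SNP windows capped at
5 Mb, at most 1 heterozygous and 5 missing calls per passing window,
per-SNP hit-rate threshold 0.05 (the tool default, which the flag set
leaves implicit), candidate runs split at gaps > 1 Mb, trimmed to
called homozygous endpoints, and emitted at $\ge$ 10 SNPs, $\ge$ 200
kb, and $\le$ 50 kb/SNP density. Homozygous-reference and
homozygous-alternate calls both count as homozygous; only
heterozygotes interrupt runs.

**Structure.** PCA operates on the 0/1/2 dosage matrix with per-site
mean imputation of missing entries, centering, and scaling by
$\sqrt{2\hat p(1-\hat p)}$ — the allele-frequency-variance scaling of
genotype-PCA tools (whether the original analysis scaled or only
centered is not recorded; scaling is the dominant convention and is
switchable via `scale = FALSE`). The p-distance between two samples is
the mean over co-called sites of half the absolute dosage difference
(0 / 0.5 / 1 per site), handled pairwise rather than by site deletion.
The NJ tree is built by the Saitou–Nei algorithm (via `ape`), with
negative branch lengths clamped to zero and the deficit moved to the
sister branch so path lengths through the parent are preserved.

**Enrichment.** Candidate regions are maximal unions of significant
windows (book-ended windows merge, `max_gap = 0`, because 50%-overlap
sliding windows make adjacency meaningful); a gene is assigned to a
region on any 1-bp half-open overlap. Gene sets are tested by the
upper-tail hypergeometric $P(X \ge k)$ against a background defaulting
to all genes in the supplied models; the raw $p \le 0.05$ flag is the
operative rule, with Benjamini–Hochberg values always reported
alongside since no multiple-testing correction is part of the mirrored
design. XP-EHH SNP hits are lifted to windows (max |score|) before
cross-method gene intersection, since the other two scans are
window-level.

## The simulator

`simulate_panel()` emulates the features of a multi-breed resequencing
panel that the scans rely on, with known truth:

* **Differentiation.** Per SNP, an ancestral frequency $p$ is uniform
  on [0.05, 0.95] (avoiding monomorphic sites; any that still arise
  are kept in the VCF and removed by the downstream MAF filter); each
  population's frequency is Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, so $F$ is the expected
  genome-wide FST. $F = 0$ copies $p$ exactly; $F = 1$ is rejected.
* **LD.** Haplotypes are mosaics of `n_founders` founder haplotypes
  with switch probability `mosaic_break_rate` per bp (default 1e-5, a
  100-kb founder-segment scale), plus a per-site resampling step
  (`resample_rate = 0.05`) toward the population frequency. Founder
  sharing makes $r^2$ decay with distance; no explicit recombination
  map is modeled.
* **Frequency fidelity.** At each site, the number of founders
  carrying the alternate allele is the randomized rounding of
  $m \cdot p_k$, so the founder-pool frequency is unbiased for the
  Balding–Nichols draw and per-site sampling noise in the emitted
  haplotypes is binomial — which is exactly the noise the
  Weir–Cockerham correction removes. The default of 16 founders keeps
  the residual quantization variance ($\approx \mathbb E[f(1-f)]/m^2$
  per site) at ~+0.003 on a realized FST of 0.15; fewer founders
  inflate it visibly.
* **Sweeps.** `plant_sweep()` raises the derived-allele frequency
  across the interval to `derived_freq`, then overwrites a fraction
  `founder_fraction` of the core-carrier haplotypes with the sweeping
  founder haplotype, taken as derived at every interval SNP. Using the
  fully derived haplotype (rather than an arbitrary carrier) makes
  heavier copying monotonically reduce window Hp, matching the
  intended dial semantics.
* **ROH.** `plant_roh()` copies one haplotype over the other across an
  interval. For detector benchmarking, `force_heterozygous()` builds
  the heterozygote-rich control in which boundary precision is
  meaningful down to a single inter-SNP gap.

What the simulator does **not** emulate: mutation/selection dynamics
over generations, realistic site-frequency spectra, recombination
hotspots, genotyping error, or reference bias. Passing the planted-
signal benchmarks therefore demonstrates that the estimators and the
outlier machinery behave correctly at realistic effect sizes — not
that the thresholds have any particular false-discovery rate on real
resequencing data.

## Default study conditions

The benchmark experiments fix their conditions once:

* FST recovery: 3 populations x 30 samples, 20,000 SNPs over two 10-Mb
  chromosomes, $F = 0.15$, five seeds; the genome-wide ratio-of-sums
  estimate must sit within ±0.03 of $F$.
* Sweep detection: 2 populations x 25 samples, two 8-Mb chromosomes at
  4,000 SNPs each (one SNP per ~2 kb, a 5x-coverage-like density after
  filtering), background $F = 0.05$ (typical between related breeds),
  one 500-kb sweep at derived frequency 0.95 and founder fraction 0.9.
  Each scan must flag the interval in at least 9/10 seeds; the matched
  sweep-free null must produce no window jointly passing
  $ZH_p < -4$ and $ZF_{ST} > 4$ in at least 9/10 seeds.
* ROH recovery: 600-kb planted segment in a forced-heterozygous
  background, 5-Mb chromosome at 2-kb SNP spacing; 100% recall,
  boundary error at most one inter-SNP gap, zero calls on the
  untouched fully heterozygous control.

These sizes keep the full test suite and the acceptance script within
a few minutes on one core while leaving every detection margin wide
(observed sweep hits 10/10, XP-EHH elevation > 5 sd).

## Numerical choices and degenerate inputs

* Z-transformations use the sample sd; zero-spread or <2 defined
  inputs yield all-`NA` with a warning rather than an error.
* `wc_components_counts()` returns `NA` components when either
  population has fewer than two called genotypes or the locus is
  monomorphic across both.
* `ihh()` of a single-point profile is 0; XP-EHH cores where either
  integral is 0 are undefined (`NA`), not errors.
* Ties in the XP-EHH rank tail are resolved by genome order so the
  top-1% set has exactly the requested size.
* Hard filters remove a record only when a *present* field violates
  its threshold (`QD < 10`, `ReadPosRankSum < -8`, `FS > 10`,
  `QUAL < 30`, `DP < 4`, read as exclusion rules); missing annotations
  never remove a record unless `strict = TRUE`. The directionality is
  the only sensible reading of a filter list quoted without one.
* All internal coordinates are 0-based half-open; conversion to
  1-based happens only in VCF/GFF I/O.
* Effect labels (synonymous / non-synonymous) are consumed from
  annotation input, never computed — codon-aware prediction is out of
  scope, and `summarize_annotation()` only performs the reporting
  arithmetic on supplied counts.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_pops = 2, samples_per_pop = 25,
                  chrom_lengths = c(chr1 = 8e6, chr2 = 8e6),
                  n_snps_per_chrom = 4000, fst_target = 0.05,
                  sweep_specs = list(sweep_spec("pop1", "chr1",
                                                3e6, 3.5e6, 3.25e6)))
sim <- simulate_panel(cfg)
bundle <- run_pipeline(sim = sim, outdir = "scan_out")
bundle$regions$zhp_pop1      # candidate regions under ZHp < -4
```

The numbered scripts under `analysis/` run the same workflow step by
step on a fixed-seed three-population panel and leave all tables under
`results/`.

## Known limitations

* XP-EHH requires phased input; no EM phasing or unphased mode.
* LD decay reports binned mean $r^2$ only; no model curve is fitted.
* FST is pairwise only ($k = 2$); no block-jackknife intervals.
* Gene-set enrichment is a plain over-representation test on supplied
  sets; no ontology propagation or database retrieval.
* The simulator's two operative discrepancy points — whether windowed
  FST should be mean-of-ratios, and whether the XP-EHH cut is the
  empirical top 1% or $p \le 0.01$ — are both implemented, with the
  ratio-of-sums and top-1% conventions as defaults.
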