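---
title: "Methods: two-statistic sweep scans in sweepscan"
author: "sweepscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-statistic sweep scans in sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`sweepscan` scans a pair of populations — a *target* suspected of recent
positive selection and a *reference* used as the comparison — for genomic
windows where two independent signals of a selective sweep coincide:
allele-frequency differentiation (windowed Weir–Cockerham Fst,
Z-standardised genome-wide) and extended haplotype homozygosity contrast
(XP-EHH, normalised genome-wide and averaged per window). Candidates are
the windows strictly above the 99th percentile of each statistic; the
intersection of the two candidate sets is the headline call.

The package assumes phased, biallelic SNP input. Phasing itself is out of
scope: haplotype panels are built only from records whose genotypes are all
called and phased, a record with any missing genotype is excluded from the
haplotype panels (it stays in the dosage table, where missingness is
handled per site), and a called-but-unphased genotype is treated as a
contract violation rather than silently repaired. Dosage-based statistics
(Fst, PCA, the frequency filters) never impute: missing genotypes reduce
the per-site sample size.

# The Fst scan

For each site with at least two called diploids per population we compute
the Weir–Cockerham (1984) two-population variance components *a*, *b*, *c*
from the called sample sizes, ALT frequencies and observed heterozygote
proportions. Components are kept unclamped; negative estimates are
legitimate draws around zero and truncating them would bias the
genome-wide mean and hence every percentile threshold downstream.

Windows are 50,000 bp wide with a 25,000 bp step (the common mammalian
genome-scan scale at which sweep footprints span several windows while each
window still holds tens of SNPs at WGS densities), anchored at position 0
of each chromosome, truncated at the chromosome end, and shared between
both statistics so window sets are directly comparable. A window's
estimate is the ratio of sums `Σa / Σ(a+b+c)` over its usable sites — the
"weighted" convention, not the mean of per-site ratios, which would
overweight low-information sites. A site in the overlap of two windows
contributes to both.

Windows with ≤ 5 SNPs are dropped (`min_snps = 6`), and the ZFst transform
`(Fst − μ)/σ` is computed **after** that filter: the sparse windows the
filter exists to distrust should not influence the genome-wide moments
either. This ordering was a genuinely open choice and is exposed as a
config switch (`min_snp_filter_xpehh` likewise applies the SNP filter to
XP-EHH windows, on by default for symmetry between the two statistics).
σ is the sample standard deviation (denominator N − 1); at realistic window
counts the difference from the population form is negligible, but the
choice is fixed so results are bit-reproducible.

# The XP-EHH scan

EHH at extension site *x* is `Σ_g C(k_g, 2) / C(n, 2)` over groups of
haplotypes identical at every site from the core to *x* inclusive. At the
core itself, groups are defined by the core allele, so EHH(core) < 1 in
general; the alternative "EHH(core) = 1" convention would ignore the core
allele's own frequency. Distance is physical bp throughout — no genetic
map enters the pipeline inputs, and map units would cancel in the log
ratio after normalisation anyway.

Extension around a core stops when the EHH of the **pooled** panel (target
and reference concatenated) drops below `xpehh_cutoff = 0.05`, at an
inter-site gap larger than `xpehh_max_gap = 200,000` bp, or at the
chromosome end. The pooled stopping rule makes both populations integrate
over the same physical span, so the ratio compares like with like; 0.05
and 200 kb are the customary defaults of haplotype-scan software and both
are config-exposed. iHH is the trapezoidal integral of EHH against bp,
summed over both sides, with the cutoff crossing located by linear
interpolation on the pooled curve so the boundary trapezoid is included
exactly. The raw score is computed as `log(iHH_t) − log(iHH_r)`, which
makes the antisymmetry under population swap exact in floating point.
Cores where either iHH is 0 are undefined: they are excluded from the
normalisation moments and window means and counted in the run report.
Normalisation is a single genome-wide stratum (mean 0, sd 1 over all
defined scores pooled across chromosomes), with the sample sd, and no
allele-frequency binning.

# Candidate calling and overlap

Thresholds are empirical quantiles with linear interpolation between order
statistics (the default quantile definition in numerical software; fixed
and documented because several definitions exist), and membership is
*strict* exceedance — "higher than the 99th percentile" — so fully tied
values can never all be called. On n distinct continuous values this
yields exactly `n/100` calls at the 0.99 percentile. Scans with fewer than
100 retained windows warn that the percentile is unstable but still
compute. The overlap set intersects windows by exact identity (same
chromosome, start, end) on the shared grid; merged maximal regions are a
reporting convenience (BED export), while the window stays the unit of
record. Internally windows are 0-based half-open intervals anchored at 0;
human-readable TSVs print 1-based inclusive coordinates and BED exports
are 0-based half-open.

A mirrored run (`mirrorScan`) swaps the population roles: window Fst is
symmetric, raw XP-EHH negates exactly, and the forward run's lower-1%
XP-EHH candidates equal the mirrored run's upper-1% candidates — the way a
reference-population scan is obtained without recomputing anything new.

# Site filters

Filters run in pipeline order: GATK-style hard thresholds (QD < 2,
FS > 60, MQ < 40, MQRankSum < −12.5, ReadPosRankSum < −8, SOR > 3; strict
inequalities, a site lacking an annotation is never removed by that
annotation's rule), the cluster rule (every SNP in any run of 3
consecutive SNPs spanning ≤ 10 bp is removed, the usual reading of
clusterWindowSize/clusterSize semantics), then biallelic + MAF ≥ 0.05 +
call-rate ≥ 80% (boundaries retained), then autosome restriction. MAF and
call rate are computed over both populations pooled, mirroring a
joint-genotyped VCF; the call-rate denominator is all samples. Whether the
frequency filters should precede or follow the autosome restriction is not
determined by the workflow being emulated; the order above is fixed, and
because the MAF/call-rate computations are per-site it only affects which
sites are *counted* at each stage, not which survive overall. Every filter
is idempotent and never reorders surviving records.

# LD pruning and PCA

Pruning follows the `indep-pairwise 50 10 0.2` scheme: within 50-SNP
windows advanced by 10 SNPs, pairs are scanned in position order and the
*later* member of any pair with r² > 0.2 is removed — a deterministic
greedy tie-break (the reference tools do not document theirs). Passes
repeat until no violating pair remains among kept sites, so the advertised
invariant — no within-window kept pair with r² > 0.2 — is directly
assertable and is asserted in the tests. Correlations use
pairwise-complete dosages; zero-variance sites have undefined r², are
never removed for LD, and are flagged.

PCA uses the variance-standardised convention: `g' = (g − 2p̂)/√(2p̂(1−p̂))`
per site, missing entries set to 0 after centring (mean imputation — the
deterministic, standard choice), sample relationship matrix `G'G'ᵀ/M`, and
eigendecomposition; coordinates are eigenvectors scaled by the square root
of their (non-negativity-clamped) eigenvalues. Monomorphic sites reaching
PCA are an error by design: they indicate a missing filtering step.

# The simulator: what it emulates, and what it does not

The generator emulates the *output* of a joint-calling and phasing
workflow — a phased, biallelic, autosomal SNP panel for two populations —
not the sequencing process. Its components:

- **Differentiation**: per site, an ancestral frequency
  p ~ Uniform(mafFloor, 1 − mafFloor), then population frequencies
  p_k ~ Beta(p(1−F)/F, (1−p)(1−F)/F) independently per population
  (Balding–Nichols). This parameterisation is chosen precisely because its
  F equals the Fst estimand, giving a parameter-recovery test with a known
  answer; F = 0 short-circuits to p_k = p exactly to avoid Beta
  degeneracy.
- **Background LD**: founder haplotypes drawn site-wise
  Bernoulli(p_k), sample haplotypes as founder mosaics switching founder
  with probability `switchRate` per bp. This yields EHH decay on the
  1/switchRate length scale and is trivially seedable; it is *not* a
  coalescent and makes no claim to realistic recombination-graph
  genealogies, allele-frequency spectra or demographic history.
- **Sweeps**: within a specified interval, `round(carrierFraction × n)`
  target haplotypes are overwritten by one template haplotype drawn from
  among the carriers (so site frequencies stay internally consistent),
  with per-site flip probability `noiseRate` — an idealised hard sweep of
  known location and softness.

Defaults define the package's standard fixture: 20 + 20 diploids, two 5-Mb
chromosomes, SNP density 5 × 10⁻⁴ per bp (≈ 5,000 sites, ≈ 25 SNPs per
50-kb window), background F = 0.05 (closely related populations, the
harder detection setting), 30 founders per population, switchRate
3 × 10⁻⁵ (≈ 33-kb haplotype blocks, so neutral EHH decays within a window
while a 150-kb sweep spans several), mafFloor 0.05 matching the MAF
filter. Positions are a sorted uniform draw without replacement (the
order statistics of a Poisson process conditioned on its count), 1-based,
unique. Output is byte-identical given identical parameters including the
seed.

Consequently, passing tests demonstrate that the *statistics and their
conventions* behave as specified on data with known truth — not that the
pipeline's power on real data equals its power here. Real panels have
phasing errors, mosaic-free LD structure, variable density and
demographic confounders that the generator deliberately omits.

# Problem sizes and numerical tolerances

The test suite validates per-site components against an independent
general-form Weir–Cockerham implementation (1,000 random configurations,
agreement to 10⁻¹⁰), EHH against exhaustive group enumeration (500 random
panels of ≤ 8 haplotypes × ≤ 12 sites, exact equality), XP-EHH
antisymmetry exactly, Fst parameter recovery at F ∈ {0.05, 0.15} (50 + 50
diploids, ≈ 5,000 near-independent sites, 10 seeds, |mean − F| ≤ 0.03),
sweep detection (carrier fraction 0.95 over 150 kb: the truth interval
must reach the two-statistic overlap in ≥ 9 of 10 seeds, and in ≤ 1 of 10
sweep-free runs), and complete PC1 separation at F = 0.15 across 5 seeds.
These sizes were chosen as the smallest at which the binomial/selection
properties are sharp; they keep the whole suite in the minutes range on a
single CPU.

# Known limitations

- Two populations only (r = 2); no multi-population or haplotype-based Fst.
- No iHS/nSL variants, no frequency-bin normalisation, no genetic-map
  input.
- The simulator's LD model is phenomenological; absolute XP-EHH magnitudes
  on simulated data should not be compared to published scans.
- GO/pathway enrichment and functional consequence annotation are out of
  scope; gene annotation stops at GTF interval intersection (≥ 1 bp
  overlap, minimum-overlap configurable).
- Chromosome lengths come from VCF contig headers (overridable); a VCF
  without them requires `chrom_lengths` in the config.
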