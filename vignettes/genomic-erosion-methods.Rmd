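---
title: "Methods: genomic-erosion metrics and diversity indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-erosion metrics and diversity indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erosure)
```

## Scope and data model

`erosure` implements the post-variant-calling half of a genomic
monitoring workflow for wild populations: given hard-called genotypes at
biallelic SNPs for samples grouped into populations and sampling
cohorts, it quantifies inbreeding (runs of homozygosity), genetic
diversity (heterozygosity, nucleotide diversity, F~ST~), deleterious
load (impact-stratified counts, realised load, R~xy~), selection
candidates (Z-transformed windowed F~ST~) and the three-level
genetic-diversity indicators used in conservation monitoring.

Everything operates on a `genotype_matrix`: samples × sites with codes 0
(hom-reference), 1 (het), 2 (hom-alternate), −1 (missing), plus per-site
chromosome/position, an impact category (HIGH / MODERATE / SYNONYMOUS /
OTHER / UNANNOTATED, parsed from SnpEff-style `ANN` annotations) and a
derived-allele orientation flag (from the `AA` ancestral-allele INFO
key). Variant calling, genotype likelihoods and coverage-based QC happen
upstream and are out of scope; cross-population statistics assume the
complete-case SNP set (`complete_case_filter()`), mirroring the common
practice of restricting to SNPs called in every individual so that
sample-size differences cannot masquerade as diversity differences.

Coordinates follow each format's native convention, converted at the
boundary: VCF and GFF3 are 1-based inclusive, BED masks half-open
0-based, and all window tracks half-open 0-based. Multi-allelic records
are dropped (not split): every downstream statistic assumes biallelic
sites. When several annotations hit one site the most severe category
wins (HIGH > MODERATE > SYNONYMOUS > OTHER); annotation tools emit one
entry per transcript and the most damaging consequence is the
conventional summary.

## Runs of homozygosity

`call_roh()` re-implements the PLINK-style scanning-window algorithm.
Per sample and chromosome, every window of `window_snp` consecutive SNPs
is labelled homozygous iff it contains at most `window_het` heterozygous
and `window_missing` missing calls; a SNP is flagged iff at least
`window_threshold` of the fully-fitting windows covering it are
homozygous; maximal runs of flagged SNPs are split at inter-SNP gaps
above `max_gap_kb` and then filtered on span (`min_kb`), SNP count
(`min_snp`), density (`density_kb_per_snp`) and heterozygote count
(`max_het_in_segment`).

The defaults are a deliberately strict set intended to avoid
over-calling long ROH: 100-SNP windows, ≤1 het per window, 5% window
threshold, ≥25 SNPs, ≥100 kb, ≥1 SNP/50 kb, ≤1,000 kb gaps, ≤750 het per
segment. `window_missing = 5` follows the common tool default, as the
strict set leaves it unstated; it is exposed as a parameter. Two
conventions the algorithm description leaves open are fixed here and
matched by the brute-force oracle in the test suite: near chromosome
ends only fully-fitting windows enter the denominator of the SNP's
homozygous-window fraction (a chromosome with fewer SNPs than
`window_snp` therefore yields no calls), and segment boundaries are
reported at the outermost flagged SNP positions, not window edges.

`froh()` divides summed segment length by the autosomal genome size,
optionally per length class (≥100 kb captures older inbreeding, ≥2 Mb
recent inbreeding). `roh_age()` dates the inbreeding event behind a
segment of length *L* Mb as *g* = 100/(2*rL*) generations, with *r* the
recombination rate in cM/Mb — the expected age at which an
identity-by-descent segment of that length has survived recombination.
Defaults are *r* = 1.04 cM/Mb (a red-deer linkage-map estimate, standard
for cervids without their own map) and a 7-year generation time; values
are reported unrounded, and presentation rounding is left to the caller
because no single rounding rule reproduces commonly printed values
exactly.

## Diversity statistics

Heterozygosity is the direct per-sample count of heterozygous calls per
1,000 bp of callable sequence — the quantity itself, not a model-based
estimator of θ; with hard genotypes from high-coverage data the count is
the contract.

Nucleotide diversity per site is the unbiased pairwise estimator
2·c~ref~·c~alt~/(n(n−1)) over called allele copies; `pi_windows()` sums
sites in non-overlapping 50 kb windows and divides by the window length.
Whether masked bases should be excluded from the denominator is a
genuine choice — dividing by the full window length (the default)
matches the common practice of treating π as per-genomic-bp, while a
`callable_bp` argument supports the per-callable-bp variant.

`fst_windows()` offers two estimators on one genotype-based core. The
default is Weir–Cockerham: per-site variance components *a* (between
populations), *b* (between individuals within populations) and *c*
(within individuals) computed from genotype counts, windows aggregated
as the weighted ratio Σa/Σ(a+b+c). The alternative is Hudson's
ratio-of-averages, which is less sensitive to unequal sample sizes and
mirrors SFS-based scans that cannot be replicated exactly from hard
genotypes. Negative per-window values are retained — clamping at zero
would bias the Z-transformation — and windows without informative sites
are missing, never zero.

## Genetic load

Load statistics use derived-allele orientation (ancestral allele from an
outgroup; sites without orientation are excluded) and drop sites fixed
homozygous-derived in all samples, which carry no between-individual
information. Total load per category is the per-sample count of sites
carrying ≥1 derived allele (a per-allele dosage mode is available;
carrier counts are the default reading). Normalised totals divide by the
sample's synonymous count to absorb mapping/annotation bias between
samples. Realised load is the count of homozygous-derived sites over
twice the segregating sites of the category — the fraction of the
potential load actually exposed to selection in that individual, bounded
by 0.5.

R~xy~ compares aggregate derived-allele frequencies of a category
between populations X and Y: L(X¬Y) = Σ f~X~(1−f~Y~) against
L(Y¬X) = Σ f~Y~(1−f~X~), normalised by the same ratio on synonymous
sites (the normaliser is a parameter). R~xy~ = 1 means no frequency
difference; the construction is exactly reciprocal,
R~xy~(X,Y) = 1/R~xy~(Y,X). Uncertainty comes from a delete-one block
jackknife over contiguous genomic blocks (default one per chromosome) so
that linked sites leave the estimate together; the 95% interval is
±1.96·SE. The normal-theory interval needs enough blocks to be
trustworthy — with fewer than ~10 blocks it visibly under-covers, which
is why the simulated validation genome uses 20 chromosomes. On real data
with few chromosomes, raise `blocks` to cut chromosomes into multiple
blocks.

## Selection scan

`zfst()` standardises a windowed F~ST~ track,
Z = (F~ST~ − μ)/σ, using the sample (n−1) standard deviation over
non-missing windows, and flags Z > 5 by default. The outlier rule is
one-sided upper — low-differentiation windows are not selection
candidates — with a `two_sided` flag since "outside 5 standard
deviations" admits either reading. `intersect_genes()` reports genes
overlapping ≥1 outlier window by ≥1 bp on the half-open convention
(a gene starting exactly at a window's end does not overlap), matching
BED-style intersection of window tracks. Temporal scans between cohorts
of one population reuse the same machinery with cohorts as the two
groups; there is no separate code path.

The 5-SD rule presumes near-Gaussian window values. With very few SNPs
per window the window distribution is right-skewed and false outliers
appear even without any true differentiation heterogeneity; the
package's neutral validation therefore simulates the marker density the
scan is meant for (~90 SNPs per 50 kb window, i.e. millions of SNPs on a
multi-Gb genome), where the false-outlier count across 40,000 windows is
zero. Sparse tracks should use a higher threshold or empirical
quantiles.

## Indicators

Three indicators, each mapped to Acceptable / Warning / Alarm:

* **ΔH** (`classify_delta_h()`): per-sample heterozygosity, π or F~ROH~
  compared between two time points with a two-sample t-test and a
  Wilcoxon rank test. Non-significant change (α = 0.05) is Acceptable
  regardless of magnitude; the t-test decides, with a concordance flag
  recording whether the Wilcoxon test agrees. Significant change is
  annualised linearly — 100·(m₂−m₁)/(m₁·years), not compounded, since
  the bands are phrased as annual reductions of a total difference — and
  banded: ≤0.05 %/yr Acceptable, to 0.3 %/yr Warning, above Alarm. For
  F~ROH~ the loss direction is inverted (`loss-when-increasing`): rising
  inbreeding is erosion.
* **Ne** (`classify_ne()`): ≥500 Acceptable, 50–500 Warning, ≤50 Alarm,
  following the published inequalities literally (the 50 < Ne < 500
  Warning band is open, so the boundary 50 falls to Alarm and 500 to
  Acceptable). Ne is consumed as an external estimate (e.g. LD-based);
  estimating it is out of scope.
* **ΔF~ST~** (`classify_delta_fst()`): paired Wilcoxon signed-rank over
  shared windows between time points. Extinction of a population is
  Alarm outright; no significant change is Acceptable; otherwise
  genome-wide mean F~ST~ (median available) is converted to expected
  migrants Nm = (1−F~ST~)/(4·F~ST~) and the relative Nm change banded:
  −25%/−50% reduced migration → Warning/Alarm, +50%/+100% increased →
  Warning/Alarm. The Nm conversion is Wright's island model — an
  equilibrium abstraction flagged here as an assumption, used as a
  relative gene-flow scale rather than a literal migrant count.

ΔH significance is tested per individual (unpaired) for heterozygosity
and F~ROH~, and per window (paired) for π/F~ST~ tracks, because those
are the sampling units actually replicated in each case.

## The simulator

`simulate_cohorts()` generates the statistical structure every stage
assumes, with ground truth. Population allele frequencies follow the
Balding–Nichols model — p~k~ ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around an
ancestral frequency p — giving a closed-form F~ST~ expectation (the
parameter F itself) so estimator accuracy can be asserted analytically.
Genotypes are Binomial(2, p~k~); sites are independent (no linkage), so
ROH structure is imposed by `plant_roh()` (tracts overwritten with the
population-major homozygote) rather than emergent — sufficient for
every validation purpose here, but simulated data will not reproduce
LD-based features of real genomes, and passing recovery tests says
nothing about, e.g., LD-based Ne estimation. Temporal change between two
cohorts is either Wright–Fisher drift (binomial resampling at 2Ne per
generation) or a programmed annual heterozygosity change applied
deterministically to frequencies, which gives an exact known rate for
indicator recovery tests.

Defaults describe the monitoring design the package targets: two
populations of 30 diploids at two time points 40 years apart (7-year
generations), F = 0.10, 50,000 sites on 5×50 Mb chromosomes, ancestral
frequencies Uniform(0.05, 0.95) (near-fixed sites would dominate ratio
statistics without adding information), and an impact mix of 70%
synonymous / 25% moderate / 5% high — the approximate shape of coding
SNP annotations in mammalian resequencing. All randomness flows from one
integer seed; outputs are bit-identical across runs.

## Numerical choices and problem sizes

Degenerate inputs fail loudly rather than silently: zero-variance tracks
in `zfst()`, populations with <2 samples, categories without segregating
sites, F~ST~ outside (0,1) in the Nm conversion, non-positive
denominators everywhere. Ratio statistics (windowed F~ST~, R~xy~) are
ratios of sums, not means of ratios, so sparse windows or blocks cannot
blow up the aggregate.

The validation suite sizes its simulations to exercise each property
well past Monte-Carlo noise while staying desk-scale: 50,000 sites with
30+30 diploids for F~ST~ recovery (±0.01 of the Balding–Nichols
parameter), 2,000×20 windows for the neutral scan, 30,000 sites / 20 Mb
chromosomes for planted-ROH recovery (base-level Jaccard ≥ 0.90), 50
replicates of a programmed −0.5 %/yr heterozygosity loss for the
end-to-end Alarm property. `scripts/acceptance.R` recomputes all of
these from scratch at the same sizes.

## Known limitations

* Hard genotypes only: no genotype likelihoods, no coverage
  downsampling; historical-sample artefacts (damage, low depth) must be
  handled upstream.
* The ROH caller is the scanning-window heuristic, not an HMM/IBD
  model; parameter choices matter and are exposed.
* R~xy~ and realised load require ancestral orientation; mis-specified
  outgroups bias both.
* The island-model Nm conversion and the linear annualisation are
  reporting conventions, not fitted models.
* The simulator has no linkage, no selection and no recombination map;
  it validates estimator mechanics, not population-genetic realism.
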