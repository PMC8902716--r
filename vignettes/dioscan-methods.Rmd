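---
title: "Methods and models behind dioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind dioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioscan)
```

dioscan is a population-genomic toolkit for dioecious plants with young,
largely non-recombining sex chromosomes. It covers four analyses that in
practice are run together on resequencing panels of such species: delimiting
the sex-determination region (SDR), scanning for domestication sweeps,
scanning for interspecific introgression, and molecular dating of X/Y gene
pairs and LTR retrotransposons. Everything operates on a simple container —
a biallelic SNP dosage matrix (`site_table`) read from VCF — and every stage
can be exercised offline on labeled synthetic data from the built-in
generator. This vignette explains the statistical models, the defaults and
why they hold their values, and what the simulation-based validation does
and does not demonstrate.

## Coordinates and containers

Internally all intervals are 0-based half-open; VCF input/output is 1-based;
BED output is written unchanged from the internal convention. Interval
algebra (normalization, gap-limited merging, n-way intersection) is backed
by `IRanges`/`GenomicRanges`. Windows start at 0 and advance by the step; a
terminal window truncated by the chromosome end is kept only while it still
covers at least one step, and densities are normalized by the covered
length, so edge windows are neither dropped silently nor inflated.

Quantile cutoffs use the nearest-rank convention: the cutoff is the
`floor((1-q)*n)+1`-th smallest value and windows pass at `value >= cutoff`.
On a 100-value track, "top 1%" therefore selects exactly the maximum —
the behaviour intended when a track is described by a single printed cutoff.

## Per-site and windowed statistics

Nucleotide diversity is the allele-frequency form of the mean pairwise
difference, `2 c (n - c) / (n (n - 1))` per site, summed over a window and
divided by covered length (monomorphic bases count in the denominator).
Tajima's D uses the standard constants (`a1, a2, b1, b2, c1, c2, e1, e2`);
with missing genotypes the window's sample size is the median per-site
called-allele count, and windows with no segregating sites or fewer than
three chromosomes are undefined rather than zero. Fst is the Weir &
Cockerham (1984) estimator: per-site variance components a, b, c summed over
the window as `sum(a)/sum(a+b+c)`, which can legitimately be negative and is
undefined for a window with no variance. Sex association is an allelic
chi-square on the 2x2 allele-by-sex table with one degree of freedom and no
continuity correction, reported as -log10(P) (computed on the log scale, so
perfect separation does not underflow). A mixed-model association with
kinship correction is deliberately out of scope: the SDR inference needs a
per-site ranking of sex linkage, and the simulated panels are unstructured;
an optional genomic-control rescaling is available for stratified data.

"Male-specific" SNPs — the population analogue of Y-hemizygous markers —
are made operational as: alternate allele carried by at least 90% of
genotyped males, by no genotyped female, with at least 80% of each sex
genotyped. These thresholds are assumptions (the underlying field usage is
qualitative), and both are configurable.

## SDR delimitation

Five independent evidence tracks are computed, each with its own window
grid and cutoff rule: F1 co-segregation contig density (100-kb windows, top
1%), sex-association score projected to 20-kb windows by maximum with a
fixed -log10(P) >= 6 cutoff, male-specific SNP density (20-kb windows, top
1%), male/female Fst (1000-kb windows, top 5%), and the male/female ratio of
Tajima's D (200-kb windows, top 5%). Only the window sizes are inherited
from standard practice; the steps are a design choice here — size/4 for all
but the 1000-kb Fst track (which tiles) — because sliding placement halves
the boundary quantization of the final call.

Two details of the ratio track are interpretations made explicit: windows
where female D is undefined, smaller than 0.05 in magnitude, or opposite in
sign to male D are masked, since a ratio with a near-zero or oppositely
signed denominator carries no ordering information.

A top-quantile rule passes only the strongest ~1% of windows genome-wide,
which inside a genuine SDR means a scattered subset; what identifies the
region is that those passing windows cluster. Each track therefore
contributes the *span of its largest cluster* of passing windows (clusters
formed by merging passing windows up to a 1-Mb gap, `span_gap`). The SDR
call is the longest interval of the n-way intersection of those spans
(by default all available tracks must agree; `min_tracks` relaxes this when
e.g. no F1 data exists), and its boundaries are snapped outward to the
terminals of the contigs containing them. An empty intersection is an
explicit no-call with per-track diagnostics, not an empty interval.

## Sweep scanning

The primary signal is the wild/cultivated diversity ratio in 100-kb windows
with 20-kb steps. A window where cultivated diversity is exactly zero while
wild diversity is positive is assigned `+Inf` and ranks above every finite
ratio — complete local fixation is the strongest possible signal and must
not be masked. The second signal is a generalized likelihood ratio
comparing each 20-kb grid window's folded site-frequency spectrum with the
genome-wide spectrum: `GLR = 2 sum_k m_k log(phat_k / q_k)`, zero when the
window matches the background and non-negative always. Two stabilizing
choices: windows with fewer than 10 polymorphic sites are masked, and the
folded classes are first grouped into at most five contiguous bins of
roughly equal genome-wide mass — with tens of SNPs per window, dozens of raw
classes make the null behave like a high-degree-of-freedom chi-square whose
noise swallows real but small windows. This GLR is a deliberately simple
SFS-distortion statistic; it is not a sweep-model composite likelihood with
a spatial decay, and outputs label it `glr` accordingly. Top-1% windows of
each statistic are flanked by 2 kb, merged across statistics when within
4 kb (inclusive), annotated with overlapping genes, and flagged
high-confidence when both statistics support the region.

## Introgression scanning

Four-taxon analyses fix the topology `[[[P1, P2], P3], O]`. Sites are
polarized by the outgroup major allele (exact 50/50 outgroup ties are
skipped and counted); frequency-weighted pattern counts are
`abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`, Patterson's
`D = sum(abba-baba)/sum(abba+baba)`, and significance comes from a weighted
delete-one block jackknife (Busing et al. 1999) over contiguous equal-site
blocks with weights proportional to each block's informative sum.

One property of the block jackknife is easy to miss and matters for design:
if the introgressed material forms a single contiguous tract spanning a
fraction f of g blocks, the between-block heterogeneity of the signal alone
caps the attainable Z near `sqrt(g) * sqrt(f/(1-f))` (about 3.3 for f = 0.1
and g = 100) regardless of how strong the signal is. Blocks must therefore
be small relative to any tract of interest; the validation experiments use
200 blocks (50-kb blocks against a 1-Mb tract) while the package default
stays at the conventional 100.

The windowed statistic is Malinsky's fd_M in 1-kb windows with 200-bp
steps: the ABBA-BABA imbalance normalized by its value with the dynamic
donor `pD = max(p2, p3)` substituted for both P2 and P3 (mirrored and
negated when p1 > p2), positive for P2-P3 sharing, negative for P1-P3
sharing, bounded in [-1, 1] by construction. Windows with fewer than 3
sites are masked. Candidate regions are windows at or above the 95th
nearest-rank percentile of the positive values, merged where they overlap;
they are labeled candidates because distinguishing introgression from
incomplete lineage sorting requires branch-length evidence outside this
package's scope.

## Molecular dating

X/Y gene pairs are dated from the synonymous rate: NG86 counts synonymous
site fractions per codon (changes to stop codons count as nonsynonymous),
averages pathway counts over all orders of the differing positions while
excluding pathways through stop codons, and applies the Jukes-Cantor
correction to both proportions; proportions at or beyond 3/4 are reported
as saturation errors, never extrapolated. LTR elements are dated from the
Kimura two-parameter distance of their two terminal repeats. Both convert
to ages as `T = K/(2r)` with `r = 2.8e-9` substitutions per site per year,
a fossil-calibrated Amaranthaceae rate; `r` is a parameter everywhere.
Strata are compared by two-sample permutation tests on mean age (10,000
permutations) rather than t-tests, avoiding normality assumptions on
small stratum sizes; the estimator name is recorded in the output metadata
because published Ks values from other estimators are not expected to match
numerically.

## The synthetic-data generator

The generator produces, in seconds, datasets with the statistical structure
each scan assumes — deliberately *not* via a coalescent simulation. Sites
are independent: an ancestral derived-allele frequency is drawn from the
neutral spectrum (density proportional to 1/x), each population's frequency
from the Balding-Nichols Beta distribution around it, and genotypes from
Hardy-Weinberg sampling. On top of this neutral background it overlays:

* **SDR**: dedicated Y-marker sites inside the region, heterozygous in
  every male and absent in every female — the diploid encoding of X/Y
  hemizygosity. The F1 generator builds four founder haplotypes, suppresses
  recombination inside the SDR (the Y block also shares the X allele at
  non-marker sites, so co-segregation is exactly the marker set), and
  assigns offspring sex by Y inheritance.
* **Sweep**: with probability `sweep_strength`, a cultivated-group site's
  frequency is replaced by a near-fixation draw (minor frequency
  Beta(0.2, 3.8)). A sweep that left literally fixed sites would leave the
  region invisible to any SFS statistic (no polymorphism to analyze);
  near-fixation with rare minor alleles is what both the diversity ratio
  and the GLR respond to in real data.
* **Introgression**: inside the admixture region, each recipient (P2)
  haplotype is, with probability gamma, a draw from the donor's frequency.
  The outgroup is held at the ancestral allele apart from 1% residual
  polymorphism, which exercises the polarization code.

Validation experiments fix these study conditions once. The SDR design is
3 chromosomes x 10 Mb, 60 natural samples at 2 SNPs/kb, a 2-Mb SDR, and an
80-offspring F1 family. The sweep design adds wild (15) and cultivated (30)
groups with a 1-Mb swept region at strength 0.95. The introgression designs
are two: a genome-wide D configuration (conspecific sisters, a diverged
donor species at F = 0.9, a 1-Mb tract covering 10% of the genome), and a
fine-mapping configuration for the 1-kb fd_M scan with a dense 40 SNPs/kb
panel, 25-sample sister panels at F = 0.02 and a 100-kb tract. The dense
panel is a resolution requirement, not a tuning knob: a 1-kb window over a
2-3 SNPs/kb panel holds two or three sites, and no per-window ratio
statistic is meaningful at that depth, which is why sparse real-data scans
of this kind report large merged fragment sets rather than crisp tracts.

What passing these experiments shows — and what it does not. Site
independence means no linkage disequilibrium, no realistic block structure
of introgressed haplotypes, no background selection, and no demography;
recombination exists only in the F1 mode. Recovery under these conditions
demonstrates that the estimators, cutoff rules and interval plumbing are
correct and that each scan detects the structure it targets at realistic
effect sizes; it does not calibrate false-discovery rates for real genomes,
where linked selection and population history can mimic several of these
signals.

## Numerical and degenerate-input conventions

Boundary comparisons are inclusive throughout (MAF >= 0.05 retained,
missingness <= 0.20 retained, merge gap <= 4 kb merged, quantile pass at
value >= cutoff, 90% male-carrier boundary flagged). Undefined statistics
propagate as NA and are excluded from quantile computations rather than
coerced to zero. fd_M values are asserted, never clamped, into [-1, 1].
Saturated distances are errors. Identical seeds give byte-identical outputs;
every stochastic routine takes its seed from configuration.

## Problem sizes in the validation suite

The test suite and the acceptance script run the recovery experiments at
the study conditions above with small seed panels (3-5 recovery seeds,
10-20 null seeds), genome sizes of 10-30 Mb and panels of 44-140 samples —
sizes at which each experiment completes in seconds while leaving the
statistics far from their asymptotic regime, which is the regime the
cutoff rules are designed for.
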