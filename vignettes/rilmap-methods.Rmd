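---
title: "Bin maps, genetic maps and QTL scans for RIL populations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin maps, genetic maps and QTL scans for RIL populations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rilmap implements the computational core of a genotyping-by-sequencing
study of a biparental recombinant inbred line (RIL) population: coding and
filtering of biallelic SNP calls against the two inbred parents,
sliding-window bin-genotype calling, two-point linkage mapping with the
Kosambi function, genetic-map-guided anchoring of assembly scaffolds into
pseudomolecules (including the splitting of chimeric scaffolds), and QTL
scanning with genome-wide permutation thresholds.  A forward simulator of
the whole study design, with a complete truth set, makes every stage
verifiable at desk scale.  This vignette explains the models and the
numerical choices; the README shows a worked end-to-end example.

## The population model

The population is derived from two fully homozygous parents by single-seed
descent: the F1 carries one chromosome of each parental origin, and each
subsequent generation is produced by one round of selfing.  Meioses follow
a no-interference count process: the number of crossovers per chromosome
is Poisson with mean equal to the genetic length in Morgans, positions
uniform.  Two consequences anchor the expectations used throughout the
tests:

* residual heterozygosity halves each generation, so an F8 line is
  heterozygous over an expected $(1/2)^7 \approx 0.78\,\%$ of its genome;
* recombinant haplotypes accumulate over the generations, so two loci with
  meiotic recombination fraction $r$ show an observed RIL recombinant
  fraction near the Haldane–Waddington selfing limit
  $R = 2r/(1+2r)$.  (At F8 the observed fraction sits slightly below the
  limit — about 8 % low at $r = 0.2$ — which is well inside the
  sampling noise of a 430-line population and is why the simulator's
  two-locus checks use standard-error bounds rather than exact
  equalities.)

Crossover interference is not modelled: the mapping stage applies the
Kosambi function, but simulating interference would only matter for
multi-locus coincidence patterns that none of the implemented statistics
use.  Obligate chiasmata are not enforced; chromosomes may pass a meiosis
unrecombined.

The simulated assembly context tiles each chromosome with scaffolds of
random (gamma-weighted) lengths and random orientations.  Chimeric
scaffolds — the misjoins the anchoring stage must detect — are created by
fusing two tiling segments from different chromosomes into one scaffold
with a recorded junction.  (Chimeras whose halves come from distant
regions of the *same* chromosome are possible in reality; they are not
part of the simulated conditions, and conflict detection would see them
only through the dispersal rule discussed below.)

### Observation model and default noise

Markers are placed uniformly on each scaffold (about 30 per scaffold,
~10^4 genome-wide under the default 325-scaffold, 13-chromosome genome of
20 Mb chromosomes at 4.25 cM/Mb).  Each RIL call equals the truth except
that with probability `error_rate` it is replaced by one of the two other
states and with probability `missing_rate` it is set missing.  The
defaults, chosen once as typical of RAD-seq genotyping in a large
population, are 25 % missing data and 0.5 % genotyping error for the RILs.
The parents get their own, much lower rates (2 % missing, 0.2 % error):
parents of a mapping population are sequenced far deeper than the
population, and the both-parents-homozygous filter makes the pipeline
extremely sensitive to parent-call quality — at RIL-level parent noise
almost half the markers would be discarded for no biological reason.

Phenotypes are additive: a plot value is a grand mean plus
$\sum_i a_i x_i$ with $x \in \{+1, 0, -1\}$ by parental origin
(heterozygotes contribute 0; no dominance — at F8 the heterozygous
fraction is negligible), plus a per-environment shift and a Gaussian plot
residual.  The residual SD is set from the realized genetic variance so
that plot-level $V_G/(V_G+V_e)$ equals the requested `h2`.  The default
trait set spans marginal line-mean $R^2$ from about 0.03 to 0.46, the
range of the effects the study design is meant to detect.  For a single
QTL with additive effect $a$ and target line-mean $R^2$, the required
plot-level heritability over $E$ environments and $R$ replicates is
$h^2 = R^2 / (E R (1 - R^2) + R^2)$.

## Marker coding and filters

Line calls are coded `A` (parent-1 homozygote), `B` (parent-2 homozygote),
`H` (both alleles) or missing.  Sites with more than two alleles are
dropped.  Markers are removed when (i) the parents are not both homozygous
for different alleles, (ii) more than 70 % of RIL calls are missing, or
(iii) the A:B homozygote counts fail a 1-d.f. chi-square test of the 1:1
RIL expectation at $P < 0.01$.  Heterozygous and missing calls are
excluded from the distortion test (the homozygote classes are what the
map uses), the missingness denominator is all RIL lines, and no Yates
correction is applied (class counts are in the hundreds).  Filtering is
idempotent, and on balanced null data the distortion filter removes a
fraction of markers close to its nominal level.

## Sliding-window bin calling

Each line is scanned along each sequence with a window of 15 informative
calls and step 1; missing calls are skipped so that every window holds
exactly 15 informative calls (heterozygous calls are informative).  A
window is `A` if it contains at least 13 A calls, `B` if at least 13 B
calls, and `H` otherwise.  Window calls are assigned to the window's
center marker.

Three structural facts about this rule drive the implementation; all are
counting arguments, and all are exercised by the test suite.

**The crossover wedge.**  A clean homozygous crossover always produces a
short run of H windows (the windows straddling the exchange hold 3–12
calls of each parent).  That run spans at most `threshold - 1` = 12
windows — the clean transition gives `2*threshold - window - 1` = 10, and
each of up to `window - threshold` = 2 stray invisible het calls in the
transition can add one more.  A genuine het segment visible to the rule
(at least `window - threshold + 1` = 3 H calls) always produces at least
`threshold` = 13 H windows.  The bound therefore separates the two cases
exactly: interior H runs of at most 12 windows flanked by opposite
homozygotes are collapsed into a single A/B breakpoint, and such runs
flanked by the *same* homozygote on both sides (which no crossover can
produce) are dissolved as genotyping-error artifacts — which is also why
an isolated flipped call inside a homozygous run can never create a
block.

**Marker-level breakpoints.**  The breakpoint between two blocks is placed
at the midpoint between the last SNP supporting the left block and the
first SNP giving sustained support to the right block (at least two of
the following three calls also leave the left class, so a sub-threshold
stray run cannot masquerade as the junction).  This is the leftmost
minimal-misclassification changepoint.  Placing breakpoints at marker
level rather than between window centers matters twice over: positions
are accurate to the local marker gap, and they are identical across lines
whose crossovers fall in the same marker interval — which is what lets
the population bin map merge coincident breakpoints instead of inflating
the bin count with per-line jitter from missing-data patterns.

**Terminal refinement.**  No window on the far side of a genotype change
that lies within 15 informative markers of a sequence end can reach 13
calls, so the window rule alone silently discards terminal recombination —
and, on chimeric scaffolds, whole misjoined tails.  A terminal H run whose
underlying calls begin with at least 3 homozygous calls of one parent
(tolerating at most 2 consecutive het calls, and not preceded by 3 or
more het calls, which would be a genuine het head) is refined at marker
level: the terminal block is re-called and the breakpoint placed between
flanking markers.  If the H windows were instead caused by an interior
opposite-parent stretch, the terminal block is prepended and the H run
kept.  Sub-threshold homozygous stretches adjacent to genuine het tracts
remain absorbed — a resolution limit of the 15/13 rule itself, not of the
implementation.

Bins are the intervals between the sorted union of all lines'
breakpoints on each sequence, so the bin count per sequence is the number
of distinct breakpoints plus one, and no line recombines strictly inside
any bin.  H block calls are retained through binning and treated as
missing in the linkage and QTL stages.  Coordinates are 1-based inclusive
externally (VCF/AGP convention); BED output is 0-based half-open.

## Two-point linkage and the genetic map

For each bin pair, lines homozygous at both bins are informative;
$R = \text{recombinants}/\text{informative}$, the two-point LOD is
$n_p \log_{10} 2(1-R) + n_r \log_{10} 2R$ (zero-count terms contribute
zero; $R$ is capped at 0.5 in the likelihood), and the meiotic fraction is
recovered by the Haldane–Waddington inversion $r = R/(2(1-R))$ before any
distance is computed.  Bins whose heterozygous-plus-missing fraction
exceeds 0.70 are left unplaced before mapping — the study's missing-data
filter applied to the bin markers (H is treated as missing by the
two-point estimates, so such bins, which arise as mosaics around chimeric
junctions, carry almost no information and only destabilize ordering).
Grouping is single-linkage transitive closure over pairs with LOD ≥ 4.0
whose observed fraction is significantly below independence: with
thousands of bin markers there are millions of between-chromosome pairs,
so a raw $R < 0.5$ edge rule admits expected-by-chance borderline links
(a single pair at LOD 4.05, $R = 0.395$, $n = 420$ is ~4.3 SD below 0.5 —
an ordinary extreme at $10^7$ comparisons — and one such link glues two
chromosomes under single linkage).  An edge therefore also requires $R$
below a Bonferroni-scaled cap $0.5 - z\sqrt{0.25/n}$ with
$z = \Phi^{-1}(1-\alpha/n_{\text{pairs}})$; genuine chains are unaffected
since adjacent bins recombine in at most a handful of lines.  Groups are
numbered by descending size, and singletons are reported unplaced.

Ordering minimizes the sum of adjacent meiotic fractions.  The initial
order is the first principal coordinate of the $r$ matrix (classical
scaling computed by a deterministic power iteration), refined by 2-opt
segment reversals plus Or-opt relocation of segments of up to three bins
(a reversal cannot carry a displaced bin across the path; a relocation
can), iterated until neither move improves the objective; for groups
above 600 bins the reversal search is windowed to segments spanning at
most 40 positions — only the merged groups that exist transiently while
chimeric scaffolds are unresolved are that large, and they only need a
rough order for conflict detection.  The principal-coordinate
initialization was chosen over greedy path growing because it is robust
on exactly those merged groups.  The orientation of a group is arbitrary
and is canonicalized so the smallest-id bin lies in the first half.

A genuine limit of any ordering from two-point data: adjacent micro-bins
whose only separating event is heterozygous or missing in the single
recombinant line have zero *observed* recombinants, so their relative
order is undefined.  With genotyping error, one or two apparent
recombinant lines between tightly linked bins cannot be told from error
either.  The recovery tests therefore assert order consistency for every
bin pair with observed recombinant evidence (at least three recombinant
lines on noisy data — the same evidential threshold as the window rule's
visibility bound), all such pairs ordered as in the truth up to global
reversal, rather than literal permutation equality.

Adjacent distances use the Kosambi function
$d = 25 \ln\left(\frac{1+2r}{1-2r}\right)$ cM; an adjacent fraction at or
above 0.5 is surfaced as an ordering error, never clamped silently (an
internal relaxation exists solely for the transient maps used during
chimera resolution).  The map summary reports total length, per-group
lengths, the mean adjacent interval `total_cm / (n_bins - n_groups)`, the
fraction of intervals below 6 cM, and cM/Mb against the anchored physical
length.  (On the published totals — 1,522 bins, 13 groups, 1090.99 cM —
these identities give 0.72 cM and 83.92 cM.  The genome-wide cM/Mb from
printed totals is 1090.99/259.73 ≈ 4.20, whereas the study quotes a mean
rate of 4.25 with an unstated averaging basis; the summary therefore
reports cM/Mb without validating it against 4.25.)

## Anchoring and chimeric scaffolds

Scaffolds are assigned to the group holding their bins, ranked by mean
bin cM (ties by scaffold id), and oriented by the sign of the Spearman
correlation between scaffold-local bin position and cM (`?` when fewer
than two distinct genetic positions support the scaffold).

A chimeric scaffold does *not* reliably appear as "bins in two groups":
windows smoothed across the misjoin create mosaic bins correlated with
both sides, which can glue the two chromosomes into a single apparent
linkage group.  Conflicts are therefore detected on the ordered map
through three signatures: bins in more than one group; bins straddling a
weak junction (an adjacent map interval longer than 15 cM — in a dense
bin map genuine adjacent intervals are almost all below 6 cM, so a
30 cM-scale gap is the footprint of a glue, not of linkage); and bins
dispersed into runs separated by more than 3 foreign bins.  Splitting is
done at marker level: per-line consensus genotypes of the first and last
5 markers represent the scaffold ends; every marker is classified to the
end it matches better, and the split point is the single changepoint
minimizing misclassifications.  A split requires the two ends to be
genuinely discordant (mismatch ≥ 0.2; the ends of a contiguous scaffold
are tightly linked and fall far below) and a clean two-part structure
(misfit ≤ 20 % at the changepoint); anything else is unresolvable and
left unplaced.  After splitting, markers are re-binned and the map is
rebuilt — the regroup/reorder/split loop runs until no conflict remains
(two passes by default).  On the default simulation this recovers all six
chimeric scaffolds with junctions inside the bracketing marker gap and no
false splits.

Pseudomolecules are built by joining placed components in rank order with
100-bp `N` gaps (AGP v2.1, U-type scaffold gaps, linkage yes, evidence
map; the study's true gap convention is unstated).  Minus components are
reverse-complemented; `?` components are written as-is with `?` in the
AGP orientation column.  The AGP always rebuilds byte-identical FASTA,
and unanchored scaffolds go to a leftovers FASTA.

## QTL scanning

Scanning uses Haley–Knott regression at the bin markers: bins are
recombination-free within the population, so the likelihood is flat
inside a bin and pseudo-positions add nothing.  At each bin,
$y = \mu + a x$ is fitted to the line means ($x = \pm 1$, heterozygous
and missing excluded), giving LOD $=(n/2)\log_{10}(RSS_0/RSS_1)$,
additive effect $a$ (half the homozygote class-mean difference, positive
when the parent-A allele increases the trait), and
$R^2 = 1 - RSS_1/RSS_0$.  Perfect fits are guarded by flooring $RSS_1$
at $10^{-12} RSS_0$.  LOD and $R^2$ are invariant under affine phenotype
transformations.  A composite-interval variant adds forward-selected
cofactor bins (entry $P < 0.01$, at most 5, near-collinear candidates
pruned) and drops cofactors within 10 cM of the test position; these
control parameters are conventional defaults, not reconstructions of the
original software's settings.

The genome-wide threshold is the $\lceil (1-\alpha) n \rceil$-th order
statistic of the maximum LOD over label permutations (1,000 by default;
the scan over all permutations is a single batched matrix computation).
Peaks are the maxima of contiguous runs above
$\max(\text{threshold}, 2.5)$; linked QTLs whose valley stays above the
threshold merge in the plain scan (separating them is what the cofactor
scan is for).  Support intervals extend while LOD stays within 1.5 of the
peak (the study reports flanking bins without stating an interval rule;
1.5-LOD is the community convention), flanking bins bracket the peak, the
physical span is the distance between the outer flanking-bin boundaries,
and peaks co-detected across environments are merged by overlapping
support intervals with per-environment flags.  Names follow
`q<Trait>-<group>.<index>` with the index increasing along the group.

## Trait statistics

CV is sd/mean of the RIL line means.  Broad-sense heritability on a
line-mean basis comes from the expected mean squares of the two-way
line-by-environment ANOVA:
$\hat\sigma^2_e = MS_e$, $\hat\sigma^2_{GE} = (MS_{GE}-MS_e)/R$,
$\hat\sigma^2_G = (MS_G - MS_{GE})/(ER)$ and
$H^2 = \hat\sigma^2_G/(\hat\sigma^2_G + \hat\sigma^2_{GE}/E +
\hat\sigma^2_e/(ER))$, with negative component estimates clamped to zero
(and flagged).  The exact estimator used by the original study is not
stated, so only properties of the estimator (range, variance-ratio
recovery) are validated, never published values.  Correlations are
Pearson on pairwise-complete line means; transgressive segregation counts
lines strictly beyond either parent mean.

## Problem sizes, determinism and limitations

Everything is deterministic given a seed.  The test suite runs the full
default study (13 chromosomes, 325 scaffolds with 6 chimeras, 430 F8
lines, ~9,600 SNPs, default noise) once for the grouping/anchoring
recovery checks; the breakpoint-recovery suite uses 13 chromosomes of
4 Mb with dense noiseless markers so that the truth-side visibility
oracle applies; the QTL calibration uses a 13-chromosome, 430-line map
with 600 null traits and 100 power replicates at the strongest
plant-height effect scale ($R^2 = 0.23$), reusing one 1,000-permutation
threshold across replicates (all are exchangeable permutations of the
same design).  These sizes were chosen as the smallest designs that still
exercise every code path at the study's line count.

What passing tests do *not* show about real data: the simulator draws
missingness and error independently per call, has no depth-dependent
allele dropout (real RAD heterozygotes are undercalled), no segregation
distortion, no marker clustering at restriction sites, and no
interference; chimeras are always two-part and cross-chromosome.  The
headline counts of the original study (1,522 bins, 41 + 9 QTLs, per-QTL
effects) depend on its real dataset and are not reproduction targets;
what the package reproduces are the method's identities, calibrations and
recovery properties under its own stated conditions.
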