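---
title: "Models and methods behind primedhs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind primedhs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, the synthetic-data
generator, the numerical choices and the known limitations of
`primedhs`. Nothing here reports an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The biological setting

T cells that have been activated once respond to restimulation within
hours rather than days. `primedhs` analyses the chromatin side of that
memory: strand-specific DNase-Seq cut profiles from six conditions —
naive (`TN`), blast (`TB`) and memory-phenotype (`TM`) cells, each
with and without a short stimulation (`_stim`). Four DHS behaviours
matter:

* **primed** (pDHS): created on first activation, stably maintained in
  blasts and memory cells without stimulation, weak or absent in naive
  cells; enriched for constitutive-factor motifs (ETS, RUNX, often as
  a tightly spaced composite element);
* **inducible** (iDHS): appears only during stimulation of previously
  activated cells, dominated by inducible-factor motifs (AP-1, NFAT,
  frequently the composite NFAT/AP-1 element);
* **diminished** (dDHS): loses at least fourfold accessibility upon
  stimulation (not exclusive with the primed flag);
* **invariant**: present at comparable strength in all three cell
  types; used as a size-matched random control.

## DHS calling and quantification

Peaks are called per condition from both-strand cut totals in 200-bp
windows stepped every 20 bp. Each window is tested against a Poisson
null whose rate is estimated genome-wide, re-estimated once after
masking windows that clear a loose (0.999-quantile) first-pass bound.
Windows significant at Benjamini–Hochberg FDR < 0.01 are merged
(gap < 200 bp), peaks shorter than 150 bp are dropped, and — because
window-level FDR leaves isolated marginal windows that would otherwise
surface as sub-background "peaks" — a merged peak must also exceed
`peak_min_enrich` (default 1.5) times the estimated background rate
over its whole width. The summit is the centre of the 150-bp
sub-window with maximal cuts, ties resolved leftmost.

Tag counts are raw both-strand cuts in a fixed 400-bp summit-centered
window, scaled to cuts per 10 million library cuts; the fixed window
makes fold changes comparable across peaks of different widths. Fold
changes use a pseudocount of 1 normalized tag, which bounds the fold
change of weak peaks. Density maps bin a 2-kb summit-centered window
into 100 bins of 20 bp.

Classification applies, in order: `primed` (TM/TN fold change ≥ 3,
≥ 1 bp overlap with a TB peak, and a TM tag above the configurable
minor-peak floor — the 60th percentile of TM tags over the union set;
the percentile is a design choice, since "minor peaks" has no published
rule); `idhs_inclusive` (TB_stim/TB ≥ 5.5) and `idhs_stringent`
(≥ 11); `diminished` (TB/TB_stim ≥ 4). Flags are not exclusive. The
invariant control is a seeded, size-matched uniform sample from peaks
present in TN, TB and TM, carrying no other flag, with a max/min tag
ratio ≤ 1.5 across the three cell types — the ratio guard makes the
control meaningfully invariant rather than merely ubiquitous.

## Digital footprinting

A bound protein blocks DNase I inside its footprint while cuts
accumulate immediately outside: plus-strand cut events pile up just 5′
of the footprint and minus-strand events just 3′ of it. For a footprint
of length $f$ with abutting flanks of length $l$, let $k^+_{fp}$ and
$k^+_{5'}$ be plus-strand cuts in the footprint and 5′ flank, and
analogously $k^-_{fp}$, $k^-_{3'}$ on the minus strand. Under no
protection, cuts split between footprint and flank in proportion to
length, so with $p_0 = f/(f+l)$,

$$\mathrm{score} = \log_{10} F\!\left(k^+_{fp};\, k^+_{fp}+k^+_{5'},\,
p_0\right) + \log_{10} F\!\left(k^-_{fp};\, k^-_{fp}+k^-_{3'},\,
p_0\right)$$

where $F$ is the exact binomial CDF (no normal approximation; a strand
with zero cuts contributes $\log_{10} 1 = 0$). The score is ≤ 0 and
more negative with stronger protection. For Poisson cut counts the
conditional law of $k_{fp}$ given the footprint+flank total is exactly
this binomial, so the per-strand tails are honestly calibrated.
The sum of the two per-strand log tails is the simplest statistic
encoding the two-sided strand polarity; it is intentionally plain
rather than a reimplementation of any published footprinter's exact
parameterization.

Calling evaluates the score at every position of each DHS over a grid
(footprint 11–25 bp odd, flanks 35 and 50 bp), takes the per-position
minimum (ties to the smallest footprint, then smallest flank), and
accepts candidates scoring ≤ −10 greedily by ascending score,
discarding overlaps. A grid configuration only contributes where the
footprint *and* both flanks fit inside the DHS: the binomial model
assumes locally uniform accessibility, and letting a flank cross the
DHS boundary into background chromatin manufactures one-strand
imbalance — on null fixtures this edge artifact alone produced ~0.24
spurious calls per DHS, versus ~0 with the shoulder constraint. The
threshold −10 corresponds to a per-position joint tail probability of
10⁻¹⁰, far beyond what uniform accessibility fluctuations reach even
after minimizing over the 16-point grid.

Differential footprinting scores externally supplied sites (e.g. AP-1
motif hits inside primed DHSs) identically in two conditions and tests
the per-site deltas (score_B − score_A) with a one-sided Wilcoxon
signed-rank test for gained protection in B. Zero deltas are dropped,
as is standard for the signed-rank statistic; when every delta is zero
(identical profiles) the test carries no evidence and p = 0.5 is
reported. Below 10 sites the exact signed-rank distribution is used
with a warning.

## Motif library, scanning and co-association

The library holds 14 motifs: the five most abundant inducible-factor
motifs (AP-1 `TGASTCA`, NFAT `TTTTCC`, EGR `GCGTGGGCG`, NF-kB
`GGGACTTTCC`, CREB/ATF `TGACGTCA`), the five most abundant
constitutive-factor motifs (ETS `ACAGGAAGT`, RUNX `TGTGGTTT`, KLF
`GGGGCGGGG`, GATA `WGATAR`, E-box `CANNTG`), and STAT, IRF, RFX and a
composite NFAT:AP-1 element (`TTTTCCNNTGASTCA`) carried unclassified.
PWMs derive from the IUPAC consensus: allowed bases at a position share
probability 0.7 (a fully degenerate position is uniform), disallowed
bases share 0.3; scores are log2-odds against a uniform background. A
hit requires ≥ 80% of the maximal score; overlapping same-motif,
same-strand hits collapse to the best one. Matrices are overridable
from a per-position probability table so users can substitute
discovery-derived matrices.

Palindromic motifs (AP-1, CREB/ATF, E-box) match both strands at the
same position and therefore contribute two hits per instance under the
same-strand collapse rule; the per-class content ratios below are
stated in these scanner-visible units.

Co-association: for each distinct motif pair, the observed statistic is
the fraction of target regions containing hits of both motifs with
centres within 50 bp. The background resamples `n_background_regions`
regions (without replacement per draw, across `n_boot = 100` draws)
from the accessible universe — the union peak set minus the targets —
and Z is the standardized excess. Pairs with zero background sd are
reported as missing rather than infinite. Note that the Z-score
measures excess relative to the *bootstrap* spread of the background
draws, so its null distribution is standard-normal-like only when the
target set is large compared with the draw size; the package's null
calibration test uses 400 targets against draws of 50 from a universe
of 1,000, where the bootstrap spread dominates.

## Distance analyses and nulls

TM-specific inducible genes have a log2 expression fold change ≥ 1 in
TM (stimulated vs unstimulated replicate means) but not in TN.
Distances are strand-ignorant point distances (peak summit to TSS, or
summit to summit); the convention is a package choice. Proximity
enrichment counts features within a radius (25 kb near, 150 kb far) of
any anchor and compares with `n_null_draws` null draws of three kinds:
width-matched intervals at uniform random coordinates (chromosome
chosen proportional to length; the synthetic genome has no
mappability mask), or equally sized without-replacement samples from a
labelled peak pool (constitutive DHSs, or iDHSs). Both a two-cell
Pearson χ² p-value (1 df, expectation = null mean) and the empirical
permutation p-value `(1 + #draws ≥ obs)/(1 + n_draws)` are reported;
the empirical value is preferred for inference, and the analytic tail
is provided because extreme published values of this kind of statistic
are only reachable analytically. When a peak pool has exactly the size
of the feature set, every without-replacement draw is the whole pool:
the null sd is 0 and the empirical p-value degenerates to its minimum
when the observed count strictly exceeds the pool's — a limiting case
the default synthetic design hits for the random-iDHS null, since
equal numbers of primed and inducible DHSs are planted.

Sample clustering selects the top 1% of genes by expression variance
(ties to higher mean, with a floor of 10 genes so correlations stay
defined on small tables), computes Pearson correlations between sample
columns and clusters by average linkage on 1 − r.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
package's reference conditions: a 10-Mb two-chromosome genome, 400
genes on a jittered slot grid, 600 DHSs (150 primed / 150 inducible /
50 diminished / 250 invariant, widths uniform 300–700 bp), fold
parameters 8 (primed TM and TB vs TN), 20 (inducible on stimulation),
0.15 (diminished on stimulation), 1 (invariant), and exactly 10⁷ cuts
per condition. These sizes keep the full reference analysis within a
few minutes on one CPU while leaving all classification margins wide.

**Rates and sequencing.** `background_rate` (0.1 per strand) and
`base_open_rate` (1.0 both strands, times the class/condition
multiplier) are *relative* intensities; open-chromatin signal rides
additively on the background, so a strongly depleted DHS approaches
background instead of dropping below it. Exactly
`depth_per_condition` cuts are then drawn multinomially with
probabilities proportional to the rate field. This is the exact
conditional law of independent Poisson counts given their total, so
per-base counts keep Poisson statistics while the library total is
exact — the property the Poisson peak caller and the binomial
footprint score both rely on. (The seemingly natural alternative —
draw Poisson counts, then resample them multinomially to the target
depth — doubles the per-base variance and floods any Poisson-based
caller with false positives.)

**Composition balance.** Forcing equal library depth across conditions
with asymmetric open chromatin distorts cross-condition tag ratios. The
generator therefore plants naive-specific decoy DHSs (open only in
TN/TN_stim, count equal to the primed count, multiplier chosen to
mirror the primed mass gained in TB/TM) so the unstimulated conditions
have identical expected composition — the analogue of the
naive-enriched DHS population visible in real ranked density maps.
Stimulated conditions keep the iDHS surplus; the residual composition
effect mildly dilutes stimulated-condition tags and is absorbed by the
classification margins.

**Motifs and scrubbing.** Primed DHSs receive 2×ETS + 2×RUNX + KLF +
GATA + AP-1 (6 constitutive vs 2 inducible visible hits, ratio 3);
inducible DHSs KLF + GATA + AP-1 + NFAT + EGR (2 vs 4, ratio 0.5);
only primed DHSs get the ETS/RUNX pair planted as an adjacent
composite, only inducible DHSs the NFAT/AP-1 composite; invariant
DHSs carry unpaired ETS and RUNX at random spacing so the
co-association background has nonzero variance. Instances are placed
at random non-overlapping offsets within the DHS interior. Because
several library motifs are short and degenerate (E-box matches a
uniform random 500-bp region ~4 times by chance), the generator
mutates chance library-motif matches out of each DHS neighbourhood
(±300 bp, covering the extent of called peaks) while leaving planted
spans untouched: the planted composition is the measured composition.
The genome outside DHS neighbourhoods remains i.i.d. uniform.

**Footprints.** ETS/RUNX instances in primed DHSs are occupied in
TB/TB_stim/TM/TM_stim; AP-1 and NFAT instances in primed and inducible
DHSs only in the stimulated conditions. An occupied 15-bp footprint
multiplies both strands by `footprint_depletion = 0.1`, with a 2× boost
over the 10 bp immediately 5′ (plus strand) and 3′ (minus strand) —
the red/green polarity the footprint score detects at detectable
magnitude.

**Linkage.** A configured fraction (default 0.4) of primed/inducible
DHS pairs is anchored to an inducible gene: the primed summit lies
2–25 kb from the TSS and the inducible DHS 5–25 kb beyond the primed
DHS on the side away from the TSS. This mirrors the observed triad
structure — pDHSs close to inducible promoters, iDHSs within tens of
kilobases of their pDHS but typically farther from the TSS — and is
what gives the proximity enrichment discriminating power against the
random-iDHS null. The number of inducible genes equals the number of
linked pairs; inducible genes gain a log2 expression effect of 2.0 in
stimulated TB/TM only, with Gaussian noise (sd 0.2). An optional
`expr_effect_range` grades the effect and shrinks linked distances for
strongly induced genes, for analyses of distance versus induction
strength; the default keeps the constant effect.

**Determinism.** Every stage draws from a seed derived from the
configuration seed (per-condition streams for cut simulation), and the
full `run_pipeline` output is byte-identical across reruns — asserted
by the test suite on files including the report and bedGraphs.

## What the synthetic data does and does not show

Planted DHSs are rectangles of uniform rate: average profiles
therefore show a central plateau rather than a sharp apex, and summit
localization within a flat-topped weak DHS is arbitrary within the
plateau (harmless, since quantification uses a 400-bp window). There
is no sequence bias of cutting, no fragment-length structure, no
replicate structure in the DNase data, no mappability mask and no
ChIP-Seq. Passing tests demonstrate that the statistics recover what
they are defined to detect under their own model assumptions — not
that those assumptions hold for any particular real library. The
published headline counts (thousands of pDHSs/iDHSs in primary mouse T
cells) depend on the original sequencing depth and peak caller and are
deliberately not targets here.

## Numerical choices

* Binomial and Poisson tails via `pbinom`/`ppois` with `log.p = TRUE`
  (exact to double precision); the test oracle recomputes tails by
  log-space summation of the mass function and agrees to 1e-9.
* Window sums via cumulative sums (exact for integer counts).
* Fold-change ordering ties break by genomic position; footprint grid
  ties toward the smaller footprint, then the smaller flank; greedy
  footprint selection ties by position; nearest-distance ties toward
  the smaller coordinate; variance-ranking ties toward the higher
  mean.
* Degenerate inputs: all-zero profiles yield empty peak lists (not
  errors); a zero-cut strand contributes 0 to the footprint score;
  empty region sets produce zero rows with a warning; zero-variance
  samples, undersized null pools and undersized invariant candidate
  sets raise informative errors.
* File coordinates are 0-based half-open (BED/bedGraph convention)
  everywhere; in-memory `GRanges` are 1-based closed.
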