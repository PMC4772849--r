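# primedhs

Classification and digital footprinting of primed and inducible DNase I
hypersensitive sites (DHSs) in T cells.

## The problem

Previously activated T cells (proliferating blasts, T<sub>B</sub>, and
quiescent memory-phenotype cells, T<sub>M</sub>) respond to restimulation
much faster than naive cells (T<sub>N</sub>). A chromatin-level
explanation is *epigenetic priming*: activation creates thousands of
stably maintained DNase I hypersensitive sites — **primed DHSs
(pDHSs)** — that are absent in naive cells, carry constitutive-factor
binding sites (ETS, RUNX), lack classical enhancer activity, and sit
near genes that will be rapidly induced. Upon a short stimulation, a
separate class of **inducible DHSs (iDHSs)** appears transiently,
dominated by inducible-factor motifs (AP-1, NFAT), typically within
tens of kilobases of a pDHS.

`primedhs` implements the computational side of this analysis as a
reusable, fully testable R pipeline:

* **DHS calling and quantification** — sliding-window Poisson test with
  Benjamini–Hochberg FDR against an iteratively estimated background;
  tag counts in a 400-bp summit-centered window, normalized to cuts per
  10 million library cuts; ranked density maps in a 2-kb window.
* **DHS classification** — fold-change flags across six conditions
  (T<sub>N</sub>, T<sub>B</sub>, T<sub>M</sub>, each ± stimulation):
  primed (TM/TN ≥ 3, present in T<sub>B</sub>, above a minor-peak
  floor), inducible (TB⁺/TB ≥ 5.5; stringent ≥ 11), diminished
  (TB/TB⁺ ≥ 4), and a seeded size-matched invariant control.
* **Digital footprinting** — the strand-imbalance statistic
  `score = log10 P_binom(k⁺_fp; k⁺_fp + k⁺_5′flank, p0) +
  log10 P_binom(k⁻_fp; k⁻_fp + k⁻_3′flank, p0)` with
  `p0 = fp/(fp+flank)`, evaluated exactly over a footprint/flank grid;
  greedy non-overlapping calls and a one-sided Wilcoxon signed-rank
  test for differential protection between conditions.
* **Motif analysis** — a 14-motif consensus-derived PWM library
  (5 inducible, 5 constitutive, plus STAT/IRF/RFX and a composite
  NFAT:AP-1 element), both-strand scanning, per-class
  constitutive:inducible content ratios, composite ETS/RUNX and
  NFAT/AP-1 detection, and bootstrap co-association Z-scores of motif
  co-occurrence within 50 bp against randomly sampled accessible
  background regions.
* **Distance analyses** — TM-specific inducible genes from expression
  (log2 FC ≥ 1 in T<sub>M</sub> but not T<sub>N</sub>), nearest-distance
  relations among pDHSs, iDHSs and TSSs, and proximity enrichment at
  25/150-kb radii with two-cell χ² and empirical permutation p-values
  against three null constructions (random coordinates, random
  constitutive DHSs, random iDHSs).
* **Synthetic-data generator** — a seeded toy genome with planted DHS
  classes, motif instances, occupied footprints and linked inducible
  genes, so that every stage is verifiable against known truth without
  any external download.

## Worked example

```r
library(primedhs)

# a small landscape: 1.2-Mb genome, 48 planted DHSs, 1.2M cuts/condition
scfg <- sim_config(seed = 7,
                   chrom_lengths = c(chrA = 6e5, chrB = 6e5),
                   n_genes = 60,
                   n_dhs = c(primed = 12, inducible = 12,
                             diminished = 4, invariant = 20),
                   depth_per_condition = 1.2e6, linked_fraction = 0.5)
acfg <- analysis_config(n_background_regions = 30, n_null_draws = 199,
                        n_boot = 50, seed = 7)
report <- run_pipeline("demo_run", scfg, acfg)

report$class_counts
#> $union_peaks    [1] 60
#> $primed         [1] 12
#> $idhs_inclusive [1] 12
#> $idhs_stringent [1] 12
#> $diminished     [1] 3
#> $invariant      [1] 12

report$truth_comparison$primed
#> $recall    [1] 1
#> $precision [1] 1
#> $n_flagged [1] 12
#> $n_planted [1] 12

report$motif_ratio
#> $primed         [1] 3      # constitutive : inducible hits
#> $idhs_stringent [1] 0.5
#> $invariant      [1] 17.5
```

The 60 union peaks are the 48 planted DHSs plus 12 naive-specific
decoy DHSs the generator adds to balance library composition (see the
methods vignette). All 12 planted primed DHSs are recovered with no
false positives (one of the four planted diminished DHSs falls just
under the fourfold cut at this small sequencing depth); the planted 3:1 constitutive:inducible motif mix of
primed DHSs and the inverted ~1:2 mix of inducible DHSs are recovered
from the scanned hits. `report$enrichment` holds the proximity
enrichment of primed DHSs around TM-specific TSSs under the three
nulls, and `report$diff_footprint_p` the one-sided p-value for gained
AP-1 protection after stimulation.

A thin command-line shell over the same stage functions is installed at
`system.file("cli", "primedhs.R", package = "primedhs")`, with
subcommands `simulate`, `quantify`, `classify`, `footprint`,
`diff-footprint`, `scan-motifs`, `coassoc`, `distances`, `expression`
and `report`.

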