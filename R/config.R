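#' Experimental conditions
#'
#' The six T-cell conditions modelled throughout the package: naive
#' (`TN`), blast (`TB`, recently activated and proliferating) and
#' memory-phenotype (`TM`) cells, each unstimulated or after a short
#' PMA/calcium-ionophore stimulation (`_stim`).
#'
#' @return Character vector of the six condition labels, in canonical order.
#' @export
conditions <- function() {
  c("TN", "TN_stim", "TB", "TB_stim", "TM", "TM_stim")
}

#' DHS classes planted by the synthetic generator
#' @return Character vector of class labels.
#' @export
dhs_classes <- function() {
  c("primed", "inducible", "diminished", "invariant")
}

.check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% conditions()) {
    stop("unknown condition '", paste(condition, collapse = ","),
         "'; must be one of: ", paste(conditions(), collapse = ", "),
         call. = FALSE)
  }
  condition
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
## state afterwards so seeded operations do not perturb each other.
with_seed <- function(seed, code) {
  seed <- as.integer(seed %% .Machine$integer.max)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a stream-specific seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 101 * as.numeric(offset)) %%
               (.Machine$integer.max - 1L)) + 1L
}

#' Simulation configuration
#'
#' Parameters of the synthetic T-cell regulatory landscape. The defaults
#' define the package's reference simulation: a 10-Mb two-chromosome
#' genome carrying 400 genes and 600 DHSs
#' (150 primed / 150 inducible / 50 diminished / 250 invariant),
#' sequenced to 10 million cuts per condition.
#'
#' @param seed Integer seed governing every random draw downstream.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_genes Total number of genes to place.
#' @param n_dhs Named integer vector: DHSs per class
#'   (`primed`, `inducible`, `diminished`, `invariant`).
#' @param fold Named list of per-class fold parameters, each
#'   `c(fc_TM_TN, fc_TB_TN, fc_stim)`. `fc_TM_TN` / `fc_TB_TN` scale the
#'   open-chromatin cut rate in TM / TB relative to TN; `fc_stim`
#'   multiplies the rate upon stimulation. Defaults: primed `(8, 8, 1)`,
#'   inducible `(1, 1, 20)`, diminished `(1, 1, 0.15)`,
#'   invariant `(1, 1, 1)`.
#' @param fold_jitter_sd Lognormal sd applied to per-DHS multipliers
#'   (0 = point values, the default).
#' @param base_open_rate Relative cut intensity per bp (both strands
#'   together) inside an open DHS at multiplier 1. Intensities are
#'   scaled per condition so that the expected total equals
#'   `depth_per_condition`; only the ratio to `background_rate` matters.
#' @param background_rate Relative cut intensity per bp per strand
#'   outside DHSs.
#' @param depth_per_condition Exact total cuts per condition (the
#'   library is "sequenced" to exactly this depth).
#' @param balance_naive Plant naive-specific decoy DHSs (open only in
#'   TN/TN_stim) that balance the open-chromatin mass of the
#'   unstimulated conditions, so equal-depth libraries do not distort
#'   cross-cell-type tag ratios (default `TRUE`).
#' @param footprint_depletion Multiplier in [0,1) applied to the cut rate
#'   inside an occupied footprint.
#' @param flank_boost,flank_boost_width Fold boost and width (bp) of the
#'   strand-polarised cut accumulation flanking an occupied footprint:
#'   the boost applies to plus-strand cuts immediately 5' and minus-strand
#'   cuts immediately 3' of the footprint.
#' @param footprint_width Width (bp) of planted footprints (protein
#'   coverage around the motif core).
#' @param dhs_width_range Planted DHS widths are drawn uniformly from this
#'   range (bp).
#' @param motif_mix Named list: per class, named integer vector of planted
#'   motif instances per DHS. Defaults plant a constitutive-heavy mix in
#'   primed DHSs and an inducible-heavy mix in inducible DHSs, so that the
#'   scanned constitutive:inducible hit ratio is 3:1 in primed and 1:2 in
#'   inducible DHSs (palindromic motifs are visible on both strands and
#'   count twice; see the methods vignette).
#' @param linked_fraction Fraction of primed/inducible DHS pairs anchored
#'   near an inducible gene's TSS; the number of inducible genes equals the
#'   number of linked pairs.
#' @param pdhs_tss_range Distance range (bp) from an inducible TSS to its
#'   linked primed DHS summit.
#' @param idhs_offset_range Distance range (bp) from a linked primed DHS to
#'   its linked inducible DHS, placed on the side away from the TSS.
#' @param expr_baseline_mean,expr_baseline_sd Log2 expression baseline
#'   distribution per gene.
#' @param expr_effect Log2 induction added to inducible genes in the
#'   stimulated TB and TM conditions.
#' @param expr_effect_range Optional length-2 numeric; when set, inducible
#'   genes receive graded log2 effects drawn from this range and their
#'   linked DHS distances shrink with increasing induction.
#' @param expr_noise_sd Gaussian noise sd (log2 units) per measurement.
#' @param n_replicates Replicates per condition in the expression table.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 400L,
                       n_dhs = c(primed = 150L, inducible = 150L,
                                 diminished = 50L, invariant = 250L),
                       fold = list(primed     = c(8, 8, 1),
                                   inducible  = c(1, 1, 20),
                                   diminished = c(1, 1, 0.15),
                                   invariant  = c(1, 1, 1)),
                       fold_jitter_sd = 0,
                       base_open_rate = 1.0,
                       background_rate = 0.1,
                       depth_per_condition = 1e7,
                       balance_naive = TRUE,
                       footprint_depletion = 0.1,
                       flank_boost = 2,
                       flank_boost_width = 10L,
                       footprint_width = 15L,
                       dhs_width_range = c(300L, 700L),
                       motif_mix = NULL,
                       linked_fraction = 0.4,
                       pdhs_tss_range = c(2000L, 25000L),
                       idhs_offset_range = c(5000L, 25000L),
                       expr_baseline_mean = 7,
                       expr_baseline_sd = 1.5,
                       expr_effect = 2.0,
                       expr_effect_range = NULL,
                       expr_noise_sd = 0.2,
                       n_replicates = 2L) {
  if (is.null(motif_mix)) {
    ## the ETS/RUNX composite is a primed-DHS signature and the NFAT/AP-1
    ## composite an inducible-enhancer signature; the other classes get
    ## mixes without co-planted pairs
    motif_mix <- list(
      primed     = c(ETS = 2L, RUNX = 2L, KLF = 1L, GATA = 1L, `AP-1` = 1L),
      inducible  = c(KLF = 1L, GATA = 1L, `AP-1` = 1L, NFAT = 1L, EGR = 1L),
      diminished = c(ETS = 1L, KLF = 1L, `AP-1` = 1L),
      invariant  = c(ETS = 1L, RUNX = 1L, KLF = 1L)
    )
  }
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes),
              n_dhs = n_dhs,
              fold = fold,
              fold_jitter_sd = fold_jitter_sd,
              base_open_rate = base_open_rate,
              background_rate = background_rate,
              depth_per_condition = depth_per_condition,
              balance_naive = isTRUE(balance_naive),
              footprint_depletion = footprint_depletion,
              flank_boost = flank_boost,
              flank_boost_width = as.integer(flank_boost_width),
              footprint_width = as.integer(footprint_width),
              dhs_width_range = as.integer(dhs_width_range),
              motif_mix = motif_mix,
              linked_fraction = linked_fraction,
              pdhs_tss_range = as.integer(pdhs_tss_range),
              idhs_offset_range = as.integer(idhs_offset_range),
              expr_baseline_mean = expr_baseline_mean,
              expr_baseline_sd = expr_baseline_sd,
              expr_effect = expr_effect,
              expr_effect_range = expr_effect_range,
              expr_noise_sd = expr_noise_sd,
              n_replicates = as.integer(n_replicates))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    stop("chrom_lengths must be named", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  need <- dhs_classes()
  if (!all(need %in% names(cfg$n_dhs)))
    stop("n_dhs must name all classes: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(cfg$n_dhs < 0)) stop("n_dhs counts must be >= 0", call. = FALSE)
  if (!all(need %in% names(cfg$fold)))
    stop("fold must name all classes", call. = FALSE)
  rates <- c(cfg$base_open_rate, cfg$background_rate, unlist(cfg$fold))
  if (any(rates < 0)) stop("all rates and fold parameters must be >= 0", call. = FALSE)
  if (cfg$footprint_depletion < 0 || cfg$footprint_depletion >= 1)
    stop("footprint_depletion must lie in [0, 1)", call. = FALSE)
  if (cfg$depth_per_condition <= 0) stop("depth_per_condition must be > 0", call. = FALSE)
  if (cfg$linked_fraction < 0 || cfg$linked_fraction > 1)
    stop("linked_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$expr_noise_sd < 0) stop("expr_noise_sd must be >= 0", call. = FALSE)
  if (diff(cfg$dhs_width_range) < 0 || cfg$dhs_width_range[1] < 50L)
    stop("dhs_width_range must be increasing and >= 50 bp", call. = FALSE)
  cfg
}

#' Analysis configuration
#'
#' Thresholds, windows and null-model sizes used by the classification,
#' footprinting, motif and distance analyses. The defaults encode the
#' pipeline's published operating point: primed DHSs are at least
#' threefold enriched in memory vs naive cells, inducible DHSs at least
#' 5.5-fold (11-fold for the stringent subset) induced on stimulation,
#' diminished DHSs at least fourfold reduced; inducible genes have a log2
#' fold change of at least 1; densities are computed in a 2-kb
#' summit-centered window; proximity is tested at 25-kb and 150-kb radii;
#' motif co-occurrence within 50 bp is compared with 1,000 randomly
#' selected accessible background regions.
#'
#' @param fc_primed Minimum TM/TN tag fold change for the primed flag.
#' @param fc_idhs_inclusive,fc_idhs_stringent Minimum TB_stim/TB fold
#'   changes for the inclusive and stringent inducible flags.
#' @param fc_diminished Minimum TB/TB_stim fold change for the diminished flag.
#' @param expr_log2fc Log2 fold-change threshold for inducible genes.
#' @param density_window Width (bp) of the summit-centered density window.
#' @param quant_window Width (bp) of the summit-centered tag quantification
#'   window.
#' @param promoter_window Distance (bp) from a TSS within which a summit is
#'   classified as promoter-proximal.
#' @param near_tss,far_tss Proximity radii (bp).
#' @param cooccur_window Maximum centre-to-centre distance (bp) for a motif
#'   pair to count as co-occurring.
#' @param n_background_regions Accessible background regions per bootstrap
#'   draw.
#' @param n_null_draws Null draws for proximity enrichment.
#' @param n_boot Bootstrap draws for co-association.
#' @param fp_lengths,flank_lengths Footprint/flank length grid (bp).
#' @param score_threshold Maximum (most permissive) footprint score for a
#'   call; scores are log10-scale and negative.
#' @param min_signal_pct Percentile (0-100) of TM tags below which peaks are
#'   treated as minor and excluded from the primed flag.
#' @param invariant_max_ratio Maximum max/min tag ratio across TN/TB/TM for
#'   invariant-control candidates.
#' @param pseudocount Pseudocount (normalized tag units) for fold changes.
#' @param peak_window,peak_step,peak_fdr,peak_merge_gap,peak_min_width
#'   Peak-caller parameters: scanning window and step (bp), BH FDR,
#'   merge gap and minimum peak width (bp).
#' @param peak_min_enrich Minimum mean cut rate of a merged peak as a
#'   multiple of the estimated background rate; removes isolated
#'   marginal windows that survive window-level FDR control.
#' @param hit_threshold Motif hit threshold as a fraction of the maximal
#'   PWM score.
#' @param seed Seed for the analysis-side randomness (invariant-control
#'   selection, null draws, bootstraps).
#'
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(fc_primed = 3.0,
                            fc_idhs_inclusive = 5.5,
                            fc_idhs_stringent = 11.0,
                            fc_diminished = 4.0,
                            expr_log2fc = 1.0,
                            density_window = 2000L,
                            quant_window = 400L,
                            promoter_window = 1000L,
                            near_tss = 25000L,
                            far_tss = 150000L,
                            cooccur_window = 50L,
                            n_background_regions = 1000L,
                            n_null_draws = 1000L,
                            n_boot = 100L,
                            fp_lengths = seq(11L, 25L, by = 2L),
                            flank_lengths = c(35L, 50L),
                            score_threshold = -10,
                            min_signal_pct = 60,
                            invariant_max_ratio = 1.5,
                            pseudocount = 1.0,
                            peak_window = 200L,
                            peak_step = 20L,
                            peak_fdr = 0.01,
                            peak_merge_gap = 200L,
                            peak_min_width = 150L,
                            peak_min_enrich = 1.5,
                            hit_threshold = 0.8,
                            seed = 1L) {
  cfg <- list(fc_primed = fc_primed,
              fc_idhs_inclusive = fc_idhs_inclusive,
              fc_idhs_stringent = fc_idhs_stringent,
              fc_diminished = fc_diminished,
              expr_log2fc = expr_log2fc,
              density_window = as.integer(density_window),
              quant_window = as.integer(quant_window),
              promoter_window = as.integer(promoter_window),
              near_tss = as.integer(near_tss),
              far_tss = as.integer(far_tss),
              cooccur_window = as.integer(cooccur_window),
              n_background_regions = as.integer(n_background_regions),
              n_null_draws = as.integer(n_null_draws),
              n_boot = as.integer(n_boot),
              fp_lengths = as.integer(fp_lengths),
              flank_lengths = as.integer(flank_lengths),
              score_threshold = score_threshold,
              min_signal_pct = min_signal_pct,
              invariant_max_ratio = invariant_max_ratio,
              pseudocount = pseudocount,
              peak_window = as.integer(peak_window),
              peak_step = as.integer(peak_step),
              peak_fdr = peak_fdr,
              peak_merge_gap = as.integer(peak_merge_gap),
              peak_min_width = as.integer(peak_min_width),
              peak_min_enrich = peak_min_enrich,
              hit_threshold = hit_threshold,
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
}

validate_analysis_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  thr <- c(cfg$fc_primed, cfg$fc_idhs_inclusive, cfg$fc_idhs_stringent,
           cfg$fc_diminished, cfg$expr_log2fc)
  if (any(thr <= 0)) stop("all fold-change thresholds must be > 0", call. = FALSE)
  win <- c(cfg$density_window, cfg$quant_window, cfg$promoter_window,
           cfg$near_tss, cfg$far_tss, cfg$cooccur_window)
  if (any(win <= 0)) stop("all windows must be > 0", call. = FALSE)
  if (cfg$fc_idhs_stringent < cfg$fc_idhs_inclusive)
    stop("fc_idhs_stringent must be >= fc_idhs_inclusive", call. = FALSE)
  if (length(cfg$fp_lengths) == 0L || length(cfg$flank_lengths) == 0L)
    stop("footprint grid must be non-empty", call. = FALSE)
  if (any(cfg$fp_lengths <= 0) || any(cfg$flank_lengths <= 0))
    stop("footprint grid lengths must be > 0", call. = FALSE)
  if (cfg$hit_threshold <= 0 || cfg$hit_threshold > 1)
    stop("hit_threshold must lie in (0, 1]", call. = FALSE)
  if (cfg$peak_fdr <= 0 || cfg$peak_fdr >= 1)
    stop("peak_fdr must lie in (0, 1)", call. = FALSE)
  cfg
}
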