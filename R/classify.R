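## DHS class flags: primed, inducible (inclusive/stringent), diminished,
## and the size-matched invariant control, plus overlap fractions and
## genomic distribution relative to gene models.

.get_fc <- function(peaks, comparison) {
  col <- paste0("fc.", comparison)
  fc <- S4Vectors::mcols(peaks)[[col]]
  if (is.null(fc))
    stop("missing fold-change column ", col,
         "; run fold_change() first", call. = FALSE)
  fc
}

#' Flag primed DHSs
#'
#' A union peak is primed when its TM/TN tag fold change is at least
#' `fc_primed`, it overlaps (by at least 1 bp) a peak called in the
#' unstimulated blast (TB) condition, and its TM tag count clears the
#' minor-peak floor (the `min_signal_pct` percentile of TM tags over the
#' union set).
#'
#' @param peaks Union peak `GRanges` with `fc.TM_vs_TN` and `tags.TM`.
#' @param tb_peaks Peaks called in the TB condition.
#' @param cfg An [analysis_config()].
#' @return The peaks with a logical `primed` column.
#' @export
flag_primed <- function(peaks, tb_peaks, cfg = analysis_config()) {
  fc <- .get_fc(peaks, "TM_vs_TN")
  tags_tm <- S4Vectors::mcols(peaks)$tags.TM
  if (is.null(tags_tm)) stop("missing tags.TM column", call. = FALSE)
  min_signal <- stats::quantile(tags_tm, cfg$min_signal_pct / 100,
                                names = FALSE)
  in_tb <- GenomicRanges::countOverlaps(peaks, tb_peaks) > 0
  S4Vectors::mcols(peaks)$primed <-
    fc >= cfg$fc_primed & in_tb & tags_tm >= min_signal
  peaks
}

#' Flag inducible DHSs
#'
#' Inclusive iDHSs are induced at least `fc_idhs_inclusive`-fold
#' (TB_stim vs TB); the stringent subset at least `fc_idhs_stringent`-fold.
#' Stringent is always a subset of inclusive.
#'
#' @inheritParams flag_primed
#' @return The peaks with logical `idhs_inclusive` and `idhs_stringent`
#'   columns.
#' @export
flag_inducible <- function(peaks, cfg = analysis_config()) {
  fc <- .get_fc(peaks, "TB_stim_vs_TB")
  S4Vectors::mcols(peaks)$idhs_inclusive <- fc >= cfg$fc_idhs_inclusive
  S4Vectors::mcols(peaks)$idhs_stringent <- fc >= cfg$fc_idhs_stringent
  peaks
}

#' Flag diminished DHSs
#'
#' A peak is diminished when its accessibility drops at least
#' `fc_diminished`-fold after stimulation (TB vs TB_stim). The flag may
#' co-occur with the primed flag; flags are not exclusive.
#'
#' @inheritParams flag_primed
#' @return The peaks with a logical `diminished` column.
#' @export
flag_diminished <- function(peaks, cfg = analysis_config()) {
  fc <- .get_fc(peaks, "TB_vs_TB_stim")
  S4Vectors::mcols(peaks)$diminished <- fc >= cfg$fc_diminished
  peaks
}

#' Select the invariant control set
#'
#' Candidates are union peaks present (>= 1 bp overlap) in the called
#' peak sets of all of TN, TB and TM, carrying no other class flag, and
#' with a max/min tag ratio across the three cell types of at most
#' `invariant_max_ratio`. A seeded uniform sample of size `n` (by
#' default, the number of primed peaks — a size-matched control) is
#' drawn without replacement.
#'
#' @param peaks Union peaks with class flags and `tags.TN`, `tags.TB`,
#'   `tags.TM`.
#' @param cond_peaks Named list with called peak `GRanges` for `TN`,
#'   `TB`, `TM`.
#' @param n Control size; default = number of primed peaks.
#' @param cfg An [analysis_config()].
#' @param seed Seed for the sample (defaults to `cfg$seed`).
#' @return The peaks with a logical `invariant` column.
#' @export
select_invariant <- function(peaks, cond_peaks, n = NULL,
                             cfg = analysis_config(), seed = cfg$seed) {
  mc <- S4Vectors::mcols(peaks)
  for (col in c("primed", "idhs_inclusive", "idhs_stringent", "diminished"))
    if (is.null(mc[[col]]))
      stop("missing flag column '", col, "'; flag peaks first", call. = FALSE)
  present_all <- Reduce(`&`, lapply(c("TN", "TB", "TM"), function(cond)
    GenomicRanges::countOverlaps(peaks, cond_peaks[[cond]]) > 0))
  tags3 <- cbind(mc$tags.TN, mc$tags.TB, mc$tags.TM)
  mx <- apply(tags3, 1, max); mn <- apply(tags3, 1, min)
  ratio_ok <- mn > 0 & mx / mn <= cfg$invariant_max_ratio
  unflagged <- !(mc$primed | mc$idhs_inclusive | mc$idhs_stringent |
                   mc$diminished)
  cand <- which(present_all & unflagged & ratio_ok)
  if (is.null(n)) n <- sum(mc$primed)
  if (length(cand) < n)
    stop("only ", length(cand), " invariant candidates for a requested ",
         "control of size ", n, call. = FALSE)
  sel <- with_seed(seed, sort(sample(cand, n)))
  inv <- logical(length(peaks))
  inv[sel] <- TRUE
  S4Vectors::mcols(peaks)$invariant <- inv
  peaks
}

#' Fraction of one interval set overlapping another
#'
#' @param set_a,set_b `GRanges`.
#' @return Fraction of `set_a` intervals with at least 1 bp overlap in
#'   `set_b` (0 for an empty `set_a`).
#' @export
overlap_fraction <- function(set_a, set_b) {
  if (length(set_a) == 0L) return(0)
  mean(GenomicRanges::countOverlaps(set_a, set_b) > 0)
}

#' Genomic distribution of peak summits
#'
#' Classifies each summit as promoter (within `promoter_window` bp of
#' any TSS), intragenic (inside any gene body) or intergenic, in that
#' priority order. Proportions sum to 1.
#'
#' @param peaks Peak `GRanges` with summits.
#' @param genes Gene `GRanges` with a `tss` column (see
#'   [read_genes_bed()]).
#' @param promoter_window Promoter radius (bp).
#' @return List with `proportions` and `counts`, each named
#'   promoter/intragenic/intergenic.
#' @export
genomic_distribution <- function(peaks, genes, promoter_window = 1000L) {
  cls <- rep("intergenic", length(peaks))
  if (length(peaks) > 0) {
    summits <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(peaks),
      IRanges::IRanges(S4Vectors::mcols(peaks)$summit, width = 1L))
    tss <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(genes),
      IRanges::IRanges(S4Vectors::mcols(genes)$tss, width = 1L))
    ## two width-1 ranges at distance d have an inter-range gap of d-1,
    ## so |summit - tss| <= promoter_window means maxgap = window - 1
    prom <- GenomicRanges::countOverlaps(
      summits, tss, maxgap = promoter_window - 1L) > 0
    body <- GenomicRanges::countOverlaps(
      summits, genes, ignore.strand = TRUE) > 0
    cls[body] <- "intragenic"
    cls[prom] <- "promoter"
  }
  counts <- c(promoter = sum(cls == "promoter"),
              intragenic = sum(cls == "intragenic"),
              intergenic = sum(cls == "intergenic"))
  props <- if (length(peaks) > 0) counts / length(peaks) else
    c(promoter = NA_real_, intragenic = NA_real_, intergenic = NA_real_)
  list(proportions = props, counts = counts)
}

#' Flags as a comma-joined string column
#'
#' Collapses the logical class-flag columns into a single `flags`
#' character column ('.' when unflagged) for BED6+ export.
#'
#' @param peaks Flagged union peaks.
#' @return Character vector of flag strings.
#' @export
flags_string <- function(peaks) {
  mc <- S4Vectors::mcols(peaks)
  cols <- intersect(c("primed", "idhs_inclusive", "idhs_stringent",
                      "diminished", "invariant"), names(mc))
  apply(as.data.frame(mc[, cols, drop = FALSE]), 1, function(row) {
    f <- cols[as.logical(row)]
    if (length(f) == 0) "." else paste(f, collapse = ",")
  })
}
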