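## DHS peak calling from cut profiles, cross-condition union peaks,
## normalized tag quantification, fold changes and density maps.

## Sliding-window both-strand cut totals for one chromosome.
window_counts <- function(total, window, step) {
  len <- length(total)
  if (len < window) return(list(starts = integer(0), counts = numeric(0)))
  cs <- c(0, cumsum(as.numeric(total)))
  starts <- seq(1L, len - window + 1L, by = step)
  list(starts = starts, counts = cs[starts + window] - cs[starts])
}

#' Call DHS peaks from a cut profile
#'
#' Scans both-strand cut totals in sliding windows and tests each window
#' against a genome-wide Poisson background; windows significant at a
#' Benjamini-Hochberg FDR are merged into peaks. The background rate is
#' estimated from the genome after masking candidate windows, iterated
#' once. The summit is the centre of the 150-bp sub-window with maximal
#' cuts (ties go leftmost).
#'
#' @param profiles A `cut_profiles` object.
#' @param cfg An [analysis_config()] (peak_window, peak_step, peak_fdr,
#'   peak_merge_gap, peak_min_width).
#' @return `GRanges` of peaks with `summit` (1-based bp) and
#'   `summit_signal` (normalized cuts in the 150-bp summit window).
#' @export
call_peaks <- function(profiles, cfg = analysis_config()) {
  W <- cfg$peak_window; step <- cfg$peak_step
  chroms <- names(profiles$chroms)
  totals <- lapply(profiles$chroms, function(p)
    p$plus + p$minus)
  genome_len <- sum(vapply(totals, length, numeric(1)))
  all_cuts <- sum(vapply(totals, function(t) sum(as.numeric(t)), numeric(1)))
  if (all_cuts == 0) return(GenomicRanges::GRanges())
  wc <- lapply(totals, window_counts, window = W, step = step)
  rate_bp <- all_cuts / genome_len
  ## first pass: mask windows that clear a loose Poisson bound, then
  ## re-estimate the background from what is left
  thr0 <- stats::qpois(0.999, rate_bp * W)
  masked_cuts <- 0; masked_len <- 0
  for (ch in chroms) {
    hot <- wc[[ch]]$counts > thr0
    if (!any(hot)) next
    ir <- IRanges::reduce(IRanges::IRanges(wc[[ch]]$starts[hot],
                                           wc[[ch]]$starts[hot] + W - 1L))
    masked_len <- masked_len + sum(IRanges::width(ir))
    v <- IRanges::Views(S4Vectors::Rle(totals[[ch]]), ir)
    masked_cuts <- masked_cuts + sum(IRanges::viewSums(v))
  }
  if (genome_len - masked_len > 0)
    rate_bp <- (all_cuts - masked_cuts) / (genome_len - masked_len)
  lambda <- rate_bp * W
  pvals <- unlist(lapply(chroms, function(ch)
    stats::ppois(wc[[ch]]$counts - 1, lambda, lower.tail = FALSE)))
  padj <- stats::p.adjust(pvals, method = "BH")
  keep <- padj < cfg$peak_fdr
  out <- list()
  off <- 0L
  for (ch in chroms) {
    n <- length(wc[[ch]]$counts)
    k <- keep[off + seq_len(n)]
    off <- off + n
    if (!any(k)) next
    ir <- IRanges::reduce(IRanges::IRanges(wc[[ch]]$starts[k],
                                           wc[[ch]]$starts[k] + W - 1L),
                          min.gapwidth = cfg$peak_merge_gap)
    ir <- ir[IRanges::width(ir) >= cfg$peak_min_width]
    if (length(ir) == 0L) next
    tot <- totals[[ch]]
    cs <- c(0, cumsum(as.numeric(tot)))
    ## drop marginal merged windows: a real DHS clears the background
    ## rate by a comfortable multiple over its whole width
    peak_cuts <- cs[IRanges::end(ir) + 1L] - cs[IRanges::start(ir)]
    enriched <- peak_cuts / IRanges::width(ir) >=
      cfg$peak_min_enrich * rate_bp
    ir <- ir[enriched]
    if (length(ir) == 0L) next
    sw <- 150L
    summit <- integer(length(ir))
    signal <- numeric(length(ir))
    for (i in seq_along(ir)) {
      s <- IRanges::start(ir)[i]; e <- IRanges::end(ir)[i]
      if (e - s + 1L <= sw) {
        summit[i] <- s + floor((e - s) / 2)
        signal[i] <- cs[e + 1L] - cs[s]
      } else {
        sub_starts <- s:(e - sw + 1L)
        sums <- cs[sub_starts + sw] - cs[sub_starts]
        b <- sub_starts[which.max(sums)]  # leftmost maximum
        summit[i] <- b + floor((sw - 1L) / 2)
        signal[i] <- max(sums)
      }
    }
    gr <- GenomicRanges::GRanges(ch, ir)
    S4Vectors::mcols(gr)$summit <- summit
    S4Vectors::mcols(gr)$summit_signal <-
      signal * 1e7 / profiles$library_total
    out[[ch]] <- gr
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  res <- suppressWarnings(do.call(c, unname(out)))
  res[order(as.character(GenomicRanges::seqnames(res)),
            GenomicRanges::start(res))]
}

#' Union of peak sets across conditions
#'
#' Peaks overlapping by at least 1 bp are merged; the union peak inherits
#' the summit of the contributing peak with the largest summit signal
#' (ties go to the leftmost contributor).
#'
#' @param peak_lists List of peak `GRanges` from [call_peaks()].
#' @return Merged, sorted `GRanges` with `summit` and `summit_signal`.
#' @export
union_peaks <- function(peak_lists) {
  peak_lists <- peak_lists[vapply(peak_lists, length, integer(1)) > 0]
  if (length(peak_lists) == 0L)
    stop("need at least one non-empty peak list", call. = FALSE)
  all_peaks <- suppressWarnings(do.call(c, unname(peak_lists)))
  merged <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(all_peaks, merged)
  contrib <- S4Vectors::queryHits(hit)
  target <- S4Vectors::subjectHits(hit)
  sig <- S4Vectors::mcols(all_peaks)$summit_signal[contrib]
  pos <- GenomicRanges::start(all_peaks)[contrib]
  ord <- order(target, -sig, pos)
  first <- !duplicated(target[ord])
  best <- contrib[ord][first]
  best_target <- target[ord][first]
  summit <- integer(length(merged))
  signal <- numeric(length(merged))
  summit[best_target] <- S4Vectors::mcols(all_peaks)$summit[best]
  signal[best_target] <- S4Vectors::mcols(all_peaks)$summit_signal[best]
  S4Vectors::mcols(merged)$summit <- summit
  S4Vectors::mcols(merged)$summit_signal <- signal
  merged <- merged[order(as.character(GenomicRanges::seqnames(merged)),
                         GenomicRanges::start(merged))]
  S4Vectors::mcols(merged)$peak_id <- sprintf("peak_%05d",
                                              seq_along(merged))
  merged
}

#' Normalized tag counts in a summit-centered window
#'
#' The tag count of a peak in a condition is the number of both-strand
#' cuts within a fixed window centered on the summit, scaled to cuts per
#' 10 million library cuts. The window is clipped at chromosome edges.
#'
#' @param peaks Peak `GRanges` with a `summit` column.
#' @param profiles A `cut_profiles` object.
#' @param quant_window Window width (bp).
#' @return Numeric vector of normalized tags, one per peak.
#' @export
peak_tags <- function(peaks, profiles, quant_window = 400L) {
  if (profiles$library_total <= 0)
    stop("library_total must be > 0", call. = FALSE)
  half <- floor(quant_window / 2)
  summits <- S4Vectors::mcols(peaks)$summit
  if (is.null(summits)) stop("peaks need a 'summit' column", call. = FALSE)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  tags <- numeric(length(peaks))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    tot <- profiles$chroms[[ch]]$plus + profiles$chroms[[ch]]$minus
    cs <- c(0, cumsum(as.numeric(tot)))
    len <- length(tot)
    ## 0-based half-open window [summit-half, summit+half), clipped
    s0 <- pmax(summits[idx] - 1L - half, 0L)
    e0 <- pmin(summits[idx] - 1L + (quant_window - half), len)
    tags[idx] <- cs[e0 + 1L] - cs[s0 + 1L]
  }
  tags * 1e7 / profiles$library_total
}

#' Quantify tags across conditions
#'
#' Adds one `tags.<condition>` column per supplied profile set.
#'
#' @param peaks Peak `GRanges` with summits.
#' @param profile_list Named list of `cut_profiles`, one per condition.
#' @param cfg An [analysis_config()].
#' @return The peaks with tag columns added.
#' @export
quantify_peaks <- function(peaks, profile_list, cfg = analysis_config()) {
  for (cond in names(profile_list)) {
    S4Vectors::mcols(peaks)[[paste0("tags.", cond)]] <-
      peak_tags(peaks, profile_list[[cond]], cfg$quant_window)
  }
  peaks
}

#' Tag fold change between two conditions
#'
#' fc = (tags_a + pseudocount) / (tags_b + pseudocount), stored as
#' `fc.<a>_vs_<b>`. The pseudocount bounds fold changes of weak peaks.
#'
#' @param peaks Peak `GRanges` with `tags.` columns for both conditions.
#' @param cond_a,cond_b Condition labels (numerator, denominator).
#' @param pseudocount Pseudocount in normalized tag units.
#' @return The peaks with the fold-change column added.
#' @export
fold_change <- function(peaks, cond_a, cond_b, pseudocount = 1.0) {
  ca <- paste0("tags.", cond_a); cb <- paste0("tags.", cond_b)
  mc <- S4Vectors::mcols(peaks)
  if (!ca %in% names(mc)) stop("missing tag column ", ca, call. = FALSE)
  if (!cb %in% names(mc)) stop("missing tag column ", cb, call. = FALSE)
  fc <- (mc[[ca]] + pseudocount) / (mc[[cb]] + pseudocount)
  S4Vectors::mcols(peaks)[[paste0("fc.", cond_a, "_vs_", cond_b)]] <- fc
  peaks
}

#' Order peaks by a fold-change column
#'
#' Ascending fold change, ties broken by ascending genomic position —
#' the ordering used for ranked density maps.
#'
#' @param peaks Peak `GRanges` with the fold-change column.
#' @param comparison Name such as "TM_vs_TN" (matching a `fc.` column).
#' @return Integer permutation of the peaks.
#' @export
order_by_fold_change <- function(peaks, comparison) {
  col <- paste0("fc.", comparison)
  fc <- S4Vectors::mcols(peaks)[[col]]
  if (is.null(fc)) stop("missing fold-change column ", col, call. = FALSE)
  order(fc, as.character(GenomicRanges::seqnames(peaks)),
        GenomicRanges::start(peaks))
}

#' Summit-centered density map and average profile
#'
#' Per-peak, per-bin normalized both-strand cuts in a window centered on
#' the peak summit. Rows clipped at chromosome edges are zero-padded and
#' flagged in the `clipped` attribute.
#'
#' @param peaks Peak `GRanges` with summits.
#' @param profiles A `cut_profiles` object.
#' @param window Window width (bp), must be divisible by `bins`.
#' @param bins Number of bins.
#' @return `density_map`: numeric matrix peaks x bins (attribute
#'   `clipped`); `average_profile`: its column means.
#' @export
density_map <- function(peaks, profiles, window = 2000L, bins = 100L) {
  if (window %% bins != 0L)
    stop("window (", window, ") must be divisible by bins (", bins, ")",
         call. = FALSE)
  if (length(peaks) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = bins)
    attr(m, "clipped") <- logical(0)
    return(m)
  }
  bw <- window %/% bins
  half <- window %/% 2L
  summits <- S4Vectors::mcols(peaks)$summit
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  m <- matrix(0, nrow = length(peaks), ncol = bins)
  clipped <- logical(length(peaks))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    tot <- profiles$chroms[[ch]]$plus + profiles$chroms[[ch]]$minus
    len <- length(tot)
    for (i in idx) {
      ws <- summits[i] - half
      we <- ws + window - 1L
      lo <- max(ws, 1L); hi <- min(we, len)
      if (lo > ws || hi < we) clipped[i] <- TRUE
      seg <- numeric(window)
      seg[(lo - ws + 1L):(hi - ws + 1L)] <- tot[lo:hi]
      m[i, ] <- colSums(matrix(seg, nrow = bw))
    }
  }
  m <- m * 1e7 / profiles$library_total
  attr(m, "clipped") <- clipped
  m
}

#' @rdname density_map
#' @export
average_profile <- function(peaks, profiles, window = 2000L, bins = 100L) {
  colMeans(density_map(peaks, profiles, window, bins))
}
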