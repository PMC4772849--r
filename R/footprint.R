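## Digital genomic footprinting by strand-imbalanced binomial scoring.
##
## A bound protein blocks DNase I inside its footprint while cuts
## accumulate immediately outside it: plus-strand cut events pile up 5'
## of the footprint and minus-strand events 3' of it. Each strand is
## scored by an exact binomial lower tail: under no protection, cuts
## distribute between footprint and abutting flank proportionally to
## length (p0 = fp_len / (fp_len + flank_len)); a depleted footprint
## gives a small lower-tail probability. The score is the sum of the two
## per-strand log10 tail probabilities (<= 0; more negative = stronger).

## Per-strand log10 binomial lower-tail. Zero cuts on a strand
## contribute log10(1) = 0 (pbinom with n = 0 already returns 1).
.log10_binom_tail <- function(k_fp, k_flank, p0) {
  stats::pbinom(k_fp, k_fp + k_flank, p0, log.p = TRUE) / log(10)
}

## Footprint interval for a centre position:
## [centre - floor(fp/2), centre + ceiling(fp/2)) in 0-based terms;
## in 1-based closed coordinates: start = centre - floor(fp/2),
## end = start + fp - 1.
.fp_bounds <- function(center, fp_len) {
  start <- center - floor(fp_len / 2)
  c(start, start + fp_len - 1L)
}

#' Strand-imbalance footprint score at one position
#'
#' @param profiles A `cut_profiles` object.
#' @param chrom Chromosome name.
#' @param center Footprint centre (1-based bp).
#' @param fp_len Footprint length (bp).
#' @param flank_len Flank length (bp); flanks abut the footprint with no
#'   gap — the 5' flank on the plus strand, the 3' flank on the minus
#'   strand.
#' @return The score: log10 of the plus-strand binomial lower tail plus
#'   log10 of the minus-strand tail (exact evaluation, no normal
#'   approximation).
#' @export
footprint_score <- function(profiles, chrom, center, fp_len, flank_len) {
  prof <- profiles$chroms[[chrom]]
  if (is.null(prof)) stop("unknown chromosome ", chrom, call. = FALSE)
  len <- length(prof$plus)
  b <- .fp_bounds(center, fp_len)
  if (b[1] - flank_len < 1L || b[2] + flank_len > len)
    stop("footprint and flanks must lie inside the chromosome",
         call. = FALSE)
  k_plus_fp <- sum(prof$plus[b[1]:b[2]])
  k_plus_5 <- sum(prof$plus[(b[1] - flank_len):(b[1] - 1L)])
  k_minus_fp <- sum(prof$minus[b[1]:b[2]])
  k_minus_3 <- sum(prof$minus[(b[2] + 1L):(b[2] + flank_len)])
  p0 <- fp_len / (fp_len + flank_len)
  .log10_binom_tail(k_plus_fp, k_plus_5, p0) +
    .log10_binom_tail(k_minus_fp, k_minus_3, p0)
}

## Vectorized scores for many centres on one chromosome at one grid
## point. Returns NA where the footprint or a flank leaves the
## allowed bounds (chromosome, or the containing region).
.scores_at <- function(plus_cs, minus_cs, len, centers, fp_len, flank_len,
                       lo = 1L, hi = len) {
  start <- centers - floor(fp_len / 2)
  end <- start + fp_len - 1L
  ok <- start - flank_len >= pmax(lo, 1L) & end + flank_len <= pmin(hi, len)
  out <- rep(NA_real_, length(centers))
  if (!any(ok)) return(out)
  s <- start[ok]; e <- end[ok]
  k_pf <- plus_cs[e + 1L] - plus_cs[s]
  k_p5 <- plus_cs[s] - plus_cs[s - flank_len]
  k_mf <- minus_cs[e + 1L] - minus_cs[s]
  k_m3 <- minus_cs[e + flank_len + 1L] - minus_cs[e + 1L]
  p0 <- fp_len / (fp_len + flank_len)
  out[ok] <- .log10_binom_tail(k_pf, k_p5, p0) +
    .log10_binom_tail(k_mf, k_m3, p0)
  out
}

## Best-of-grid score per centre; ties resolved toward the earlier grid
## point (grids ordered by fp_len then flank_len, i.e. smallest first).
.best_grid_scores <- function(prof, centers, fp_lengths, flank_lengths,
                              lo = 1L, hi = NULL) {
  plus_cs <- c(0, cumsum(as.numeric(prof$plus)))
  minus_cs <- c(0, cumsum(as.numeric(prof$minus)))
  len <- length(prof$plus)
  if (is.null(hi)) hi <- len
  best <- rep(Inf, length(centers))
  best_fp <- rep(NA_integer_, length(centers))
  best_flank <- rep(NA_integer_, length(centers))
  for (fp in sort(fp_lengths)) {
    for (fl in sort(flank_lengths)) {
      sc <- .scores_at(plus_cs, minus_cs, len, centers, fp, fl, lo, hi)
      upd <- !is.na(sc) & sc < best
      best[upd] <- sc[upd]
      best_fp[upd] <- fp
      best_flank[upd] <- fl
    }
  }
  best[is.infinite(best)] <- NA_real_
  list(score = best, fp_len = best_fp, flank_len = best_flank)
}

#' Call non-overlapping footprints within DHSs
#'
#' Every position inside each DHS is scored over the footprint/flank
#' grid and assigned its best (minimum) score, ties resolved toward the
#' smallest footprint then the smallest flank. A grid configuration
#' contributes only where the footprint and both flanks fit inside the
#' DHS: the binomial model assumes locally uniform accessibility, and
#' letting a flank leave the open region manufactures spurious
#' imbalance at DHS edges. Candidate positions scoring at or below
#' `score_threshold` are accepted greedily in order of ascending score
#' (ties by position), discarding candidates whose footprint interval
#' overlaps an already accepted one.
#'
#' @param profiles A `cut_profiles` object.
#' @param dhs `GRanges` of DHS intervals to search (a `dhs_id` or `name`
#'   column is propagated when present).
#' @param cfg An [analysis_config()] (fp_lengths, flank_lengths,
#'   score_threshold).
#' @return `GRanges` of footprints with `score`, `fp_len`, `flank_len`,
#'   `center` and `dhs_id` columns, plus per-strand footprint/flank cut
#'   counts.
#' @export
call_footprints <- function(profiles, dhs, cfg = analysis_config()) {
  if (length(cfg$fp_lengths) == 0L || length(cfg$flank_lengths) == 0L)
    stop("footprint grid is empty", call. = FALSE)
  ids <- S4Vectors::mcols(dhs)$dhs_id
  if (is.null(ids)) ids <- S4Vectors::mcols(dhs)$name
  if (is.null(ids)) ids <- as.character(seq_along(dhs))
  chroms <- as.character(GenomicRanges::seqnames(dhs))
  out <- list()
  for (ch in unique(chroms)) {
    prof <- profiles$chroms[[ch]]
    if (is.null(prof)) stop("no profile for chromosome ", ch, call. = FALSE)
    idx <- which(chroms == ch)
    centers <- integer(0)
    center_dhs <- character(0)
    center_lo <- integer(0)
    center_hi <- integer(0)
    for (i in idx) {
      cs <- GenomicRanges::start(dhs)[i]:GenomicRanges::end(dhs)[i]
      centers <- c(centers, cs)
      center_dhs <- c(center_dhs, rep(ids[i], length(cs)))
      center_lo <- c(center_lo, rep(GenomicRanges::start(dhs)[i],
                                    length(cs)))
      center_hi <- c(center_hi, rep(GenomicRanges::end(dhs)[i],
                                    length(cs)))
    }
    gb <- .best_grid_scores(prof, centers, cfg$fp_lengths,
                            cfg$flank_lengths, lo = center_lo,
                            hi = center_hi)
    cand <- which(!is.na(gb$score) & gb$score <= cfg$score_threshold)
    if (length(cand) == 0L) next
    ord <- cand[order(gb$score[cand], centers[cand])]
    sel <- integer(0)
    sel_start <- integer(0); sel_end <- integer(0)
    for (k in ord) {
      b <- .fp_bounds(centers[k], gb$fp_len[k])
      if (any(sel_start <= b[2] & sel_end >= b[1])) next
      sel <- c(sel, k)
      sel_start <- c(sel_start, b[1]); sel_end <- c(sel_end, b[2])
    }
    if (length(sel) == 0L) next
    o <- order(sel_start)
    sel <- sel[o]; sel_start <- sel_start[o]; sel_end <- sel_end[o]
    plus_cs <- c(0, cumsum(as.numeric(prof$plus)))
    minus_cs <- c(0, cumsum(as.numeric(prof$minus)))
    fl <- gb$flank_len[sel]
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(sel_start, sel_end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      score = gb$score[sel],
      fp_len = gb$fp_len[sel],
      flank_len = fl,
      center = centers[sel],
      dhs_id = center_dhs[sel],
      k_plus_fp = as.integer(plus_cs[sel_end + 1L] - plus_cs[sel_start]),
      k_plus_5flank = as.integer(plus_cs[sel_start] -
                                   plus_cs[sel_start - fl]),
      k_minus_fp = as.integer(minus_cs[sel_end + 1L] -
                                minus_cs[sel_start]),
      k_minus_3flank = as.integer(minus_cs[sel_end + fl + 1L] -
                                    minus_cs[sel_end + 1L]))
    out[[ch]] <- gr
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  res <- suppressWarnings(do.call(c, unname(out)))
  res[order(as.character(GenomicRanges::seqnames(res)),
            GenomicRanges::start(res))]
}

#' Differential footprinting between two conditions
#'
#' Scores each site (best-of-grid, computed identically in both
#' conditions) and tests for a global gain of protection in condition B
#' with a one-sided Wilcoxon signed-rank test on the per-site deltas
#' (score_b - score_a; protection gained means more negative scores in
#' B). Zero deltas are dropped, as usual for the signed-rank test; if
#' all deltas are zero the test carries no evidence and p = 0.5 is
#' reported. With fewer than 10 sites a warning is issued and the exact
#' signed-rank distribution is used.
#'
#' @param profiles_a,profiles_b `cut_profiles` for the two conditions
#'   (same genome layout).
#' @param sites `GRanges` of site centres (width-1 or wider; the midpoint
#'   is used), e.g. AP-1 motif hits within primed DHSs.
#' @param cfg An [analysis_config()].
#' @return List with `table` (site, score_a, score_b, delta),
#'   `median_delta` and `p_value` (one-sided: B more protected).
#' @export
differential_footprints <- function(profiles_a, profiles_b, sites,
                                    cfg = analysis_config()) {
  chroms <- as.character(GenomicRanges::seqnames(sites))
  centers <- as.integer(floor((GenomicRanges::start(sites) +
                                 GenomicRanges::end(sites)) / 2))
  score_a <- rep(NA_real_, length(sites))
  score_b <- rep(NA_real_, length(sites))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    ga <- .best_grid_scores(profiles_a$chroms[[ch]], centers[idx],
                            cfg$fp_lengths, cfg$flank_lengths)
    gbv <- .best_grid_scores(profiles_b$chroms[[ch]], centers[idx],
                             cfg$fp_lengths, cfg$flank_lengths)
    score_a[idx] <- ga$score
    score_b[idx] <- gbv$score
  }
  ok <- !is.na(score_a) & !is.na(score_b)
  delta <- score_b[ok] - score_a[ok]
  n <- sum(ok)
  exact <- FALSE
  if (n < 10L) {
    warning("only ", n, " scorable sites; using the exact signed-rank ",
            "distribution", call. = FALSE)
    exact <- TRUE
  }
  nz <- delta[delta != 0]
  p <- if (length(nz) == 0L) 0.5 else
    suppressWarnings(stats::wilcox.test(nz, mu = 0, alternative = "less",
                                        exact = exact)$p.value)
  list(table = data.frame(chrom = chroms, center = centers,
                          score_a = score_a, score_b = score_b,
                          delta = score_b - score_a),
       median_delta = stats::median(delta),
       n_sites = n,
       p_value = p)
}
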