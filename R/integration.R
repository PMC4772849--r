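## Inducible-gene classification from expression, distance analyses
## between DHS classes and TSSs with chi-square / permutation enrichment
## against constructed nulls, and sample correlation clustering.

#' Classify TM-specific inducible genes
#'
#' Per condition, the log2 fold change is the mean of stimulated
#' replicates minus the mean of unstimulated replicates. A gene is
#' TM-specific when its TM log2 fold change reaches `expr_log2fc` while
#' its TN log2 fold change stays below it — induced in memory cells but
#' not in naive cells.
#'
#' @param expr Log2 expression matrix (genes x samples) with columns
#'   named `<condition>_<replicate>`, e.g. from [simulate_expression()].
#' @param cfg An [analysis_config()].
#' @return List with `tm_specific` and `other` gene-id vectors, and
#'   `log2fc` (data frame of per-cell-type fold changes).
#' @export
classify_tm_genes <- function(expr, cfg = analysis_config()) {
  cols <- colnames(expr)
  fc_for <- function(cell) {
    stim <- grep(paste0("^", cell, "_stim_"), cols)
    base <- grep(paste0("^", cell, "_[0-9]+$"), cols)
    if (length(stim) == 0L || length(base) == 0L)
      stop("expression table lacks ", cell, " / ", cell,
           "_stim replicate columns", call. = FALSE)
    rowMeans(expr[, stim, drop = FALSE]) -
      rowMeans(expr[, base, drop = FALSE])
  }
  fc <- data.frame(TN = fc_for("TN"), TB = fc_for("TB"), TM = fc_for("TM"),
                   row.names = rownames(expr))
  tm <- fc$TM >= cfg$expr_log2fc & fc$TN < cfg$expr_log2fc
  list(tm_specific = rownames(expr)[tm],
       other = rownames(expr)[!tm],
       log2fc = fc)
}

## Point positions (chrom, pos) from a GRanges: summit column when
## present, tss column for genes, otherwise the interval midpoint.
## Data frames with chrom/pos columns pass through.
point_positions <- function(gr) {
  if (is.data.frame(gr)) {
    if (!all(c("chrom", "pos") %in% names(gr)))
      stop("data-frame features need 'chrom' and 'pos' columns",
           call. = FALSE)
    if (is.null(gr$width)) gr$width <- 1
    return(gr[, c("chrom", "pos", "width")])
  }
  mc <- S4Vectors::mcols(gr)
  pos <- if (!is.null(mc$summit)) mc$summit
  else if (!is.null(mc$tss)) mc$tss
  else floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = as.numeric(pos),
             width = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Nearest-subject distance for each query point
#'
#' Distances are strand-ignorant point distances (summit-to-TSS or
#' summit-to-summit); a query lying on a subject position has distance
#' 0. Ties between equidistant subjects are resolved toward the smaller
#' coordinate. Queries on chromosomes without subjects receive `Inf`.
#'
#' @param query,subject `GRanges` (summits/TSSs used when present) or
#'   data frames with `chrom` and `pos` columns.
#' @return Data frame with `distance` and the matched `subject_chrom` /
#'   `subject_pos` per query.
#' @export
nearest_distance <- function(query, subject) {
  q <- if (methods::is(query, "GRanges")) point_positions(query) else query
  s <- if (methods::is(subject, "GRanges")) point_positions(subject) else
    subject
  n <- nrow(q)
  dist <- rep(Inf, n)
  sub_pos <- rep(NA_real_, n)
  if (nrow(s) > 0) {
    for (ch in unique(q$chrom)) {
      qi <- which(q$chrom == ch)
      sp <- sort(s$pos[s$chrom == ch])
      if (length(sp) == 0L) next
      idx <- findInterval(q$pos[qi], sp)
      lo <- pmax(idx, 1L)
      hi <- pmin(idx + 1L, length(sp))
      d_lo <- abs(q$pos[qi] - sp[lo])
      d_hi <- abs(q$pos[qi] - sp[hi])
      ## ties -> smaller coordinate (the left neighbour)
      use_lo <- idx >= 1L & (idx >= length(sp) | d_lo <= d_hi)
      dist[qi] <- ifelse(use_lo, d_lo, d_hi)
      sub_pos[qi] <- ifelse(use_lo, sp[lo], sp[hi])
    }
  }
  data.frame(distance = dist, subject_chrom = q$chrom,
             subject_pos = sub_pos)
}

## Merged anchor windows (anchor position +- radius) per chromosome,
## as sorted boundary vectors for O(log n) membership tests.
.anchor_windows <- function(anchors, radius) {
  a <- if (methods::is(anchors, "GRanges")) point_positions(anchors) else
    anchors
  out <- list()
  for (ch in unique(a$chrom)) {
    ir <- IRanges::reduce(IRanges::IRanges(
      pmax(1, a$pos[a$chrom == ch] - radius),
      a$pos[a$chrom == ch] + radius))
    ## boundaries [s_i, e_i]: pos inside iff findInterval over the
    ## flattened sorted vector c(s_1, e_1+1, s_2, e_2+1, ...) is odd
    out[[ch]] <- as.numeric(rbind(IRanges::start(ir),
                                  IRanges::end(ir) + 1L))
  }
  out
}

.count_within <- function(chrom, pos, windows) {
  inside <- logical(length(pos))
  for (ch in unique(chrom)) {
    b <- windows[[ch]]
    i <- which(chrom == ch)
    if (is.null(b)) next
    inside[i] <- findInterval(pos[i], b) %% 2L == 1L
  }
  sum(inside)
}

#' Proximity enrichment of a feature set around anchors
#'
#' Counts the features lying within `radius` of at least one anchor and
#' compares the count with a constructed null: either width-matched
#' intervals placed uniformly at random (chromosome chosen proportional
#' to length), or an equally sized sample (without replacement) from a
#' labelled peak pool such as constitutive DHSs or inducible DHSs. Both
#' a two-cell Pearson chi-square p-value (1 df, expectation = null
#' mean) and an empirical permutation p-value
#' `(1 + #draws >= observed) / (1 + n_draws)` are reported; the
#' empirical p-value is preferred for inference.
#'
#' @param features Feature `GRanges` (summits used when present).
#' @param anchors Anchor `GRanges` (TSSs or summits).
#' @param radius Radius in bp (e.g. 25000 or 150000).
#' @param null_kind One of `random_coordinates`,
#'   `random_constitutive_dhs`, `random_idhs` (the latter two need
#'   `null_pool`).
#' @param null_pool Peak `GRanges` pool for the peak-based nulls.
#' @param chrom_lengths Named chromosome lengths, required for
#'   `random_coordinates`.
#' @param cfg An [analysis_config()] (n_null_draws).
#' @param seed Seed for the null draws (defaults to `cfg$seed`).
#' @return List of class `enrichment_result`: observed, expected,
#'   null_sd, chi2, p_chi2, p_empirical, null_kind, n_features, n_draws.
#' @export
proximity_enrichment <- function(features, anchors, radius,
                                 null_kind = c("random_coordinates",
                                               "random_constitutive_dhs",
                                               "random_idhs"),
                                 null_pool = NULL, chrom_lengths = NULL,
                                 cfg = analysis_config(),
                                 seed = cfg$seed) {
  null_kind <- match.arg(null_kind)
  f <- point_positions(features)
  N <- nrow(f)
  windows <- .anchor_windows(anchors, radius)
  observed <- .count_within(f$chrom, f$pos, windows)
  n_draws <- cfg$n_null_draws
  if (null_kind == "random_coordinates") {
    if (is.null(chrom_lengths))
      stop("chrom_lengths required for random_coordinates null",
           call. = FALSE)
    null_counts <- with_seed(seed, {
      vapply(seq_len(n_draws), function(d) {
        ci <- sample.int(length(chrom_lengths), N, replace = TRUE,
                         prob = chrom_lengths)
        len <- as.numeric(chrom_lengths)[ci]
        start <- floor(stats::runif(N) * pmax(1, len - f$width)) + 1
        pos <- start + floor(f$width / 2)  # width-matched midpoints
        .count_within(names(chrom_lengths)[ci], pos, windows)
      }, numeric(1))
    })
  } else {
    if (is.null(null_pool))
      stop("null_pool required for ", null_kind, call. = FALSE)
    p <- point_positions(null_pool)
    if (nrow(p) < N)
      stop("null pool (", nrow(p), ") smaller than the feature set (",
           N, ")", call. = FALSE)
    inside <- logical(nrow(p))
    for (ch in unique(p$chrom)) {
      b <- windows[[ch]]
      i <- which(p$chrom == ch)
      if (!is.null(b)) inside[i] <- findInterval(p$pos[i], b) %% 2L == 1L
    }
    null_counts <- with_seed(seed, {
      vapply(seq_len(n_draws), function(d)
        sum(inside[sample.int(nrow(p), N, replace = FALSE)]), numeric(1))
    })
  }
  expected <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  chi2 <- chi2_two_cell(observed, expected, N)
  p_chi2 <- if (is.na(chi2)) NA_real_ else
    stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected,
                 null_sd = null_sd, chi2 = chi2, p_chi2 = p_chi2,
                 p_empirical = (1 + sum(null_counts >= observed)) /
                   (1 + n_draws),
                 null_kind = null_kind, n_features = N,
                 n_draws = n_draws, radius = radius),
            class = "enrichment_result")
}

#' Two-cell Pearson chi-square statistic
#'
#' `(obs-exp)^2/exp + ((N-obs)-(N-exp))^2/(N-exp)` for a feature set of
#' size `N`, tested on 1 df. Degenerate expectations (exp <= 0 or
#' exp >= N) give `NA`; obs == exp gives exactly 0.
#'
#' @param observed,expected Counts within the radius.
#' @param n Feature-set size.
#' @return The statistic.
#' @export
chi2_two_cell <- function(observed, expected, n) {
  if (expected <= 0 || expected >= n) return(NA_real_)
  (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
}

#' Median nearest-DHS distance by induction strength
#'
#' Genes are binned on their TM log2 fold change; per bin, the median
#' distance from the gene TSS to the nearest DHS is reported. Genes
#' farther than `max_dist` from every DHS are excluded; bins with fewer
#' than 5 genes are flagged.
#'
#' @param gene_fc Named numeric vector: log2 fold change (TM) per gene.
#' @param gene_tss `GRanges` of the genes (with `tss` and `gene_id`
#'   columns) or data frame with `chrom`, `pos`, `gene_id`.
#' @param dhs `GRanges` of the DHS set (summits used when present).
#' @param bin_edges Lower bin edges on log2 fold change (upper-open
#'   last bin); the default top bin starts at log2(10), i.e. >10-fold.
#' @param max_dist Exclusion distance (bp).
#' @return Data frame: bin, n_genes, median_distance, flagged.
#' @export
distance_by_induction <- function(gene_fc, gene_tss, dhs,
                                  bin_edges = c(1, 2, 3, log2(10)),
                                  max_dist = 1e6) {
  g <- if (methods::is(gene_tss, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gene_tss)),
               pos = S4Vectors::mcols(gene_tss)$tss,
               gene_id = S4Vectors::mcols(gene_tss)$gene_id,
               stringsAsFactors = FALSE)
  } else gene_tss
  g <- g[g$gene_id %in% names(gene_fc), , drop = FALSE]
  fc <- gene_fc[g$gene_id]
  nd <- nearest_distance(g, dhs)$distance
  keep <- nd <= max_dist & fc >= bin_edges[1]
  fc <- fc[keep]; nd <- nd[keep]
  labels <- paste0("[", bin_edges, ",",
                   c(bin_edges[-1], Inf), ")")
  bins <- cut(fc, breaks = c(bin_edges, Inf), right = FALSE,
              labels = labels)
  out <- data.frame(bin = labels,
                    n_genes = as.integer(table(bins)[labels]),
                    median_distance = vapply(labels, function(l) {
                      v <- nd[bins == l]
                      if (length(v) == 0) NA_real_ else stats::median(v)
                    }, numeric(1)))
  out$flagged <- out$n_genes < 5L
  rownames(out) <- NULL
  out
}

#' Sample correlation clustering of high-variance genes
#'
#' Selects the top fraction of genes by expression variance across
#' samples (ties resolved toward higher mean), computes Pearson
#' correlations between sample columns and clusters samples by
#' average linkage on correlation distance (1 - r). The leaf order is
#' deterministic.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param top_frac Fraction of genes to keep (default 0.01, the top 1%).
#' @param min_genes Lower bound on the number of genes used, so the
#'   correlation stays defined on small tables.
#' @return List with `correlation` (samples x samples), `order`
#'   (clustered sample ordering), `hclust` and `genes_used`.
#' @export
sample_correlation_clustering <- function(expr, top_frac = 0.01,
                                          min_genes = 10L) {
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  sample_sd <- apply(expr, 2, stats::sd)
  if (any(sample_sd == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(expr)[sample_sd == 0], collapse = ", "),
         call. = FALSE)
  n_top <- max(1L, min_genes, ceiling(top_frac * nrow(expr)))
  v <- apply(expr, 1, stats::var)
  m <- rowMeans(expr)
  sel <- order(-v, -m)[seq_len(min(n_top, nrow(expr)))]
  cc <- stats::cor(expr[sel, , drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(correlation = cc, order = colnames(expr)[hc$order], hclust = hc,
       genes_used = rownames(expr)[sel])
}
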