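## Motif library, PWM scanning, per-class motif content, composite
## elements, and bootstrap co-association Z-scores.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

BASES <- c("A", "C", "G", "T")

.default_motif_specs <- function() {
  list(
    list(name = "AP-1",      tf_class = "inducible",    consensus = "TGASTCA"),
    list(name = "NFAT",      tf_class = "inducible",    consensus = "TTTTCC"),
    list(name = "EGR",       tf_class = "inducible",    consensus = "GCGTGGGCG"),
    list(name = "NF-kB",     tf_class = "inducible",    consensus = "GGGACTTTCC"),
    list(name = "CREB/ATF",  tf_class = "inducible",    consensus = "TGACGTCA"),
    list(name = "ETS",       tf_class = "constitutive", consensus = "ACAGGAAGT"),
    list(name = "RUNX",      tf_class = "constitutive", consensus = "TGTGGTTT"),
    list(name = "KLF",       tf_class = "constitutive", consensus = "GGGGCGGGG"),
    list(name = "GATA",      tf_class = "constitutive", consensus = "WGATAR"),
    list(name = "E-box",     tf_class = "constitutive", consensus = "CANNTG"),
    list(name = "STAT",      tf_class = "other",        consensus = "TTCYNRGAA"),
    list(name = "IRF",       tf_class = "other",        consensus = "TTTCANTTTC"),
    list(name = "RFX",       tf_class = "other",        consensus = "GTTGCCATGGCAAC"),
    list(name = "NFAT:AP-1", tf_class = "other",        consensus = "TTTTCCNNTGASTCA")
  )
}

## Probability matrix from an IUPAC consensus: the allowed bases at each
## position share probability 0.7 (a fully degenerate position is uniform),
## the disallowed bases share the remaining 0.3.
consensus_to_probs <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("invalid IUPAC letter(s) in consensus '", consensus, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  probs <- vapply(letters, function(l) {
    allowed <- IUPAC_SETS[[l]]
    p <- numeric(4L)
    names(p) <- BASES
    if (length(allowed) == 4L) {
      p[] <- 0.25
    } else {
      p[allowed] <- 0.7 / length(allowed)
      p[setdiff(BASES, allowed)] <- 0.3 / (4L - length(allowed))
    }
    p
  }, numeric(4L))
  rownames(probs) <- BASES
  probs
}

new_motif <- function(name, tf_class, consensus = NA_character_,
                      probs = NULL, hit_threshold = 0.8) {
  if (is.null(probs)) probs <- consensus_to_probs(consensus)
  pwm <- log2(probs / 0.25)
  structure(list(name = name, tf_class = tf_class, consensus = consensus,
                 probs = probs, pwm = pwm,
                 max_score = sum(apply(pwm, 2, max)),
                 hit_threshold = hit_threshold),
            class = "motif")
}

#' Build the transcription-factor motif library
#'
#' Constructs position weight matrices (log2-odds against a uniform
#' background) for 14 motifs: the five most abundant inducible-factor
#' motifs (AP-1, NFAT, EGR, NF-kB, CREB/ATF), the five most abundant
#' constitutive-factor motifs (ETS, RUNX, KLF, GATA, E-box), plus STAT,
#' IRF, RFX and the composite NFAT:AP-1 element, which are carried
#' unclassified for the constitutive:inducible ratio. PWMs are derived
#' from IUPAC consensi: allowed bases at a position share probability
#' 0.7, disallowed bases share 0.3.
#'
#' @param overrides Optional matrix overrides: a data frame (or TSV path)
#'   with columns `name`, `tf_class`, `pos`, `A`, `C`, `G`, `T` giving
#'   per-position base probabilities; listed motifs replace or extend the
#'   built-in set verbatim.
#' @param hit_threshold Hit threshold as a fraction of the maximal PWM
#'   score (default 0.8).
#' @return A named list of motifs (class `motif_library`).
#' @export
build_motif_library <- function(overrides = NULL, hit_threshold = 0.8) {
  lib <- lapply(.default_motif_specs(), function(s)
    new_motif(s$name, s$tf_class, s$consensus, hit_threshold = hit_threshold))
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      overrides <- utils::read.delim(overrides, check.names = FALSE,
                                     stringsAsFactors = FALSE)
    }
    need <- c("name", "tf_class", "pos", "A", "C", "G", "T")
    if (!all(need %in% names(overrides)))
      stop("overrides must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    for (nm in unique(overrides$name)) {
      sub <- overrides[overrides$name == nm, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      probs <- t(as.matrix(sub[, BASES]))
      rownames(probs) <- BASES
      if (any(probs < 0) || any(abs(colSums(probs) - 1) > 1e-6))
        stop("override probabilities for '", nm,
             "' must be non-negative and sum to 1 per position", call. = FALSE)
      lib[[nm]] <- new_motif(nm, sub$tf_class[1], probs = probs,
                             hit_threshold = hit_threshold)
    }
  }
  structure(lib, class = "motif_library")
}

#' @export
print.motif_library <- function(x, ...) {
  cat("motif_library with", length(x), "motifs:\n")
  for (m in x)
    cat(sprintf("  %-10s %-13s %s\n", m$name, m$tf_class,
                ifelse(is.na(m$consensus), "<matrix>", m$consensus)))
  invisible(x)
}

## Encode an upper-case DNA string into codes 1..4 (A,C,G,T); other -> NA.
encode_dna <- function(seq_str) {
  match(strsplit(toupper(seq_str), "")[[1]], BASES)
}

revcomp_codes <- function(codes) 5L - rev(codes)

## Score every window of `codes` against a 4 x L pwm.
## Returns numeric vector of length length(codes) - L + 1 (NA where the
## window contains a non-ACGT base).
pwm_window_scores <- function(codes, pwm) {
  L <- ncol(pwm)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  offs <- seq_len(n) - 1L
  for (j in seq_len(L)) {
    sc <- sc + pwm[, j][codes[j + offs]]
  }
  sc
}

## Hits of one motif in one encoded sequence (both strands).
## start is 1-based within the sequence; collapse overlapping same-strand
## hits to the best-scoring (ties -> leftmost).
scan_codes_one <- function(codes, motif) {
  L <- ncol(motif$pwm)
  thr <- motif$hit_threshold * motif$max_score
  res <- list()
  fwd <- pwm_window_scores(codes, motif$pwm)
  ifwd <- which(!is.na(fwd) & fwd >= thr)
  if (length(ifwd))
    res[[1]] <- data.frame(start = ifwd, strand = "+", score = fwd[ifwd])
  rc <- revcomp_codes(codes)
  rev <- pwm_window_scores(rc, motif$pwm)
  irev <- which(!is.na(rev) & rev >= thr)
  if (length(irev)) {
    n <- length(codes)
    res[[length(res) + 1L]] <-
      data.frame(start = n - irev - L + 2L, strand = "-", score = rev[irev])
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, res)
  keep <- logical(nrow(out))
  for (str in unique(out$strand)) {
    idx <- which(out$strand == str)
    sub <- out[idx, , drop = FALSE]
    ord <- order(-sub$score, sub$start)
    taken_end <- integer(0)
    taken_start <- integer(0)
    for (k in ord) {
      s <- sub$start[k]; e <- s + L - 1L
      if (!any(taken_start <= e & taken_end >= s)) {
        keep[idx[k]] <- TRUE
        taken_start <- c(taken_start, s)
        taken_end <- c(taken_end, e)
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan sequences or genomic regions for motif hits
#'
#' Scores every position of every sequence on both strands against each
#' PWM in the library; positions scoring at least
#' `hit_threshold * max_score` are hits. Overlapping hits of the same
#' motif on the same strand are collapsed to the best-scoring one
#' (ties go to the leftmost).
#'
#' @param x Either a named character vector / `DNAStringSet` of sequences,
#'   or a `GRanges` of regions (requires `genome`).
#' @param library A `motif_library` from [build_motif_library()].
#' @param genome Named `DNAStringSet` (or character vector) of chromosome
#'   sequences, required when `x` is a `GRanges`.
#' @return A data frame of hits with columns `motif`, `region_id`,
#'   `chrom`, `start` (1-based, genomic when regions were given, else
#'   within-sequence), `end`, `strand`, `score`, `center`.
#' @export
scan_motifs <- function(x, library = build_motif_library(), genome = NULL) {
  if (methods::is(x, "GRanges")) {
    if (is.null(genome)) stop("genome is required to scan GRanges regions",
                              call. = FALSE)
    gseq <- stats::setNames(as.character(genome), names(genome))
    ids <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
           else as.character(seq_along(x))
    chroms <- as.character(GenomicRanges::seqnames(x))
    starts <- GenomicRanges::start(x)
    ends <- GenomicRanges::end(x)
    bad <- !(chroms %in% names(gseq)) | starts < 1L |
      ends > nchar(gseq)[match(chroms, names(gseq))]
    if (any(bad))
      stop("region(s) outside the genome: ",
           paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
    seqs <- substring(gseq[match(chroms, names(gseq))], starts, ends)
    names(seqs) <- ids
    offset <- starts - 1L
  } else {
    seqs <- stats::setNames(as.character(x), names(x))
    if (is.null(names(seqs)))
      names(seqs) <- as.character(seq_along(seqs))
    chroms <- rep(NA_character_, length(seqs))
    offset <- rep(0L, length(seqs))
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    codes <- encode_dna(seqs[[i]])
    per_motif <- lapply(library, function(m) {
      h <- scan_codes_one(codes, m)
      if (nrow(h) == 0L) return(NULL)
      L <- ncol(m$pwm)
      data.frame(motif = m$name,
                 region_id = names(seqs)[i],
                 chrom = chroms[i],
                 start = h$start + offset[i],
                 end = h$start + offset[i] + L - 1L,
                 strand = h$strand,
                 score = h$score,
                 center = h$start + offset[i] + (L - 1) / 2,
                 stringsAsFactors = FALSE)
    })
    per_motif <- per_motif[!vapply(per_motif, is.null, logical(1))]
    if (length(per_motif)) out[[i]] <- do.call(rbind, per_motif)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(motif = character(0), region_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), center = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-class motif content of region sets
#'
#' For each region set, tabulates the fraction of regions with at least
#' one hit and the mean hits per region, per motif, and aggregates total
#' constitutive and inducible hit counts and their ratio.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param region_sets Named list of region-id character vectors.
#' @param library The `motif_library` used for the scan (supplies the
#'   inducible/constitutive class of each motif).
#' @return A list with `table` (long data frame: set, motif, tf_class,
#'   frac_regions, mean_hits) and `totals` (per set: constitutive_total,
#'   inducible_total, ratio = constitutive/inducible).
#' @export
motif_table <- function(hits, region_sets, library = build_motif_library()) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  motifs <- vapply(library, `[[`, character(1), "name")
  classes <- vapply(library, `[[`, character(1), "tf_class")
  rows <- list()
  totals <- list()
  for (set_name in names(region_sets)) {
    ids <- as.character(region_sets[[set_name]])
    if (length(ids) == 0L)
      warning("region set '", set_name, "' is empty", call. = FALSE)
    sub <- hits[hits$region_id %in% ids, , drop = FALSE]
    n_regions <- length(ids)
    cnt_by <- table(factor(sub$motif, levels = motifs),
                    factor(sub$region_id, levels = ids))
    n_hits <- rowSums(cnt_by)
    frac <- if (n_regions > 0) rowSums(cnt_by > 0) / n_regions else
      rep(0, length(motifs))
    mean_hits <- if (n_regions > 0) n_hits / n_regions else
      rep(0, length(motifs))
    rows[[set_name]] <- data.frame(set = set_name, motif = motifs,
                                   tf_class = unname(classes),
                                   frac_regions = unname(frac),
                                   mean_hits = unname(mean_hits),
                                   n_hits = unname(n_hits),
                                   stringsAsFactors = FALSE)
    const_total <- sum(n_hits[classes == "constitutive"])
    ind_total <- sum(n_hits[classes == "inducible"])
    totals[[set_name]] <- data.frame(
      set = set_name, constitutive_total = const_total,
      inducible_total = ind_total,
      ratio = if (ind_total > 0) const_total / ind_total else NA_real_,
      stringsAsFactors = FALSE)
  }
  out_table <- do.call(rbind, rows)
  rownames(out_table) <- NULL
  out_totals <- do.call(rbind, totals)
  rownames(out_totals) <- NULL
  list(table = out_table, totals = out_totals)
}

#' Composite element detection
#'
#' A region carries a composite element when it contains hits of two
#' motifs whose centres lie within a maximum gap of each other, e.g. the
#' ETS/RUNX composite of primed DHSs or the NFAT/AP-1 composite of
#' inducible enhancers.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param region_sets Named list of region-id vectors.
#' @param pair_specs List of `list(a=, b=, max_gap=)`; defaults to
#'   ETS/RUNX at 20 bp and NFAT/AP-1 at 10 bp.
#' @param library Motif library (used to validate motif names).
#' @return Data frame: set, pair, n_regions, n_composite, fraction.
#' @export
composite_elements <- function(hits, region_sets,
                               pair_specs = NULL,
                               library = build_motif_library()) {
  if (is.null(pair_specs)) {
    pair_specs <- list(list(a = "ETS", b = "RUNX", max_gap = 20),
                       list(a = "NFAT", b = "AP-1", max_gap = 10))
  }
  known <- vapply(library, `[[`, character(1), "name")
  rows <- list()
  for (spec in pair_specs) {
    if (!all(c(spec$a, spec$b) %in% known))
      stop("unknown motif in pair spec: ",
           paste(setdiff(c(spec$a, spec$b), known), collapse = ", "),
           call. = FALSE)
    for (set_name in names(region_sets)) {
      ids <- as.character(region_sets[[set_name]])
      n_comp <- 0L
      for (id in ids) {
        ca <- hits$center[hits$region_id == id & hits$motif == spec$a]
        cb <- hits$center[hits$region_id == id & hits$motif == spec$b]
        if (length(ca) && length(cb) &&
            min(abs(outer(ca, cb, "-"))) <= spec$max_gap)
          n_comp <- n_comp + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, pair = paste(spec$a, spec$b, sep = "/"),
        max_gap = spec$max_gap, n_regions = length(ids),
        n_composite = n_comp,
        fraction = if (length(ids)) n_comp / length(ids) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Region x pair co-occurrence indicator matrix. Pairs are unordered
## distinct motif pairs; a region co-occurs when it has an A-hit and a
## B-hit with centres within `window` bp.
cooccurrence_matrix <- function(hits, region_ids, motifs, window) {
  pairs <- utils::combn(motifs, 2)
  np <- ncol(pairs)
  M <- matrix(FALSE, nrow = length(region_ids), ncol = np,
              dimnames = list(region_ids,
                              paste(pairs[1, ], pairs[2, ], sep = "|")))
  sub <- hits[hits$region_id %in% region_ids, , drop = FALSE]
  if (nrow(sub) == 0L) return(M)
  by_region <- split(sub, sub$region_id)
  for (id in names(by_region)) {
    h <- by_region[[id]]
    centers <- split(h$center, h$motif)
    present <- names(centers)
    for (p in seq_len(np)) {
      a <- pairs[1, p]; b <- pairs[2, p]
      if (a %in% present && b %in% present &&
          min(abs(outer(centers[[a]], centers[[b]], "-"))) <= window)
        M[id, p] <- TRUE
    }
  }
  M
}

#' Motif co-association Z-scores
#'
#' For every distinct motif pair, the observed statistic is the fraction
#' of target regions containing hits of both motifs with centres within
#' `cooccur_window` bp. The background distribution is obtained by
#' bootstrap: `n_boot` times, `n_background_regions` regions are sampled
#' without replacement from the accessible universe (the union DHS set
#' minus the targets) and the same fraction computed. The Z-score is the
#' standardized excess of observed over background; pairs with zero
#' background sd are reported as missing. Rows and columns are ordered by
#' average-linkage hierarchical clustering of the Z matrix under
#' correlation distance.
#'
#' @param hits Hit table from [scan_motifs()] covering both targets and
#'   universe.
#' @param target_ids Character vector of target region ids.
#' @param universe_ids Character vector of accessible background region
#'   ids (must not intersect targets and must contain at least
#'   `n_background_regions` regions).
#' @param cfg An [analysis_config()].
#' @param seed Seed for the bootstrap (defaults to `cfg$seed`).
#' @param motifs Motif names to include (default: all motifs present in
#'   `hits`).
#' @return List with the pairwise `Z` matrix, `observed`, `bg_mean`,
#'   `bg_sd` matrices, and `order` (clustered motif ordering).
#' @export
coassociation <- function(hits, target_ids, universe_ids,
                          cfg = analysis_config(), seed = cfg$seed,
                          motifs = NULL) {
  target_ids <- as.character(target_ids)
  universe_ids <- setdiff(as.character(universe_ids), target_ids)
  if (length(universe_ids) < cfg$n_background_regions)
    stop("accessible universe too small: ", length(universe_ids),
         " regions < n_background_regions = ", cfg$n_background_regions,
         call. = FALSE)
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  if (length(motifs) < 2L) stop("need at least two motifs", call. = FALSE)
  M_t <- cooccurrence_matrix(hits, target_ids, motifs, cfg$cooccur_window)
  M_u <- cooccurrence_matrix(hits, universe_ids, motifs, cfg$cooccur_window)
  obs <- colMeans(M_t)
  boots <- with_seed(seed, {
    vapply(seq_len(cfg$n_boot), function(b) {
      idx <- sample.int(nrow(M_u), cfg$n_background_regions, replace = FALSE)
      colMeans(M_u[idx, , drop = FALSE])
    }, numeric(ncol(M_u)))
  })
  bg_mean <- rowMeans(boots)
  bg_sd <- apply(boots, 1, stats::sd)
  z <- ifelse(bg_sd > 0, (obs - bg_mean) / bg_sd, NA_real_)
  to_mat <- function(v) {
    m <- matrix(NA_real_, length(motifs), length(motifs),
                dimnames = list(motifs, motifs))
    pairs <- utils::combn(motifs, 2)
    for (p in seq_len(ncol(pairs))) {
      m[pairs[1, p], pairs[2, p]] <- v[p]
      m[pairs[2, p], pairs[1, p]] <- v[p]
    }
    m
  }
  Z <- to_mat(unname(z))
  ord <- motifs
  Zc <- Z
  Zc[is.na(Zc)] <- 0
  if (nrow(Zc) > 2L) {
    cc <- suppressWarnings(stats::cor(t(Zc)))
    cc[is.na(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    ord <- motifs[hc$order]
  }
  list(Z = Z, observed = to_mat(unname(obs)),
       bg_mean = to_mat(unname(bg_mean)), bg_sd = to_mat(unname(bg_sd)),
       order = ord, n_targets = length(target_ids),
       n_universe = length(universe_ids))
}
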