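## Synthetic T-cell regulatory landscape: a seeded toy genome with
## planted DHS classes, motif instances, occupied footprints, linked
## inducible genes, strand-specific cut profiles and expression tables.

#' Generate a synthetic genome with gene models
#'
#' Draws an i.i.d. uniform A/C/G/T background sequence for each
#' chromosome and places non-overlapping genes (both strands) on a
#' jittered slot grid. The TSS is the 5' end of the gene body given its
#' strand.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `synthetic_genome`: a list with `layout`
#'   (chromosome lengths and a gene `GRanges` with `gene_id` and `tss`
#'   columns) and `seqs` (named character vector of chromosome
#'   sequences).
#' @export
generate_genome <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  body_range <- c(2000L, 5000L)
  slot_w <- body_range[2] + 1000L
  n_slots <- pmax(0L, floor(cfg$chrom_lengths / slot_w) - 1L)
  if (sum(n_slots) < cfg$n_genes)
    stop("genome too small: ", cfg$n_genes, " genes need at least ",
         cfg$n_genes * slot_w, " bp but only ",
         sum(cfg$chrom_lengths), " bp are available (deficit ",
         cfg$n_genes * slot_w - sum(cfg$chrom_lengths), " bp)",
         call. = FALSE)
  with_seed(cfg$seed, {
    seqs <- vapply(cfg$chrom_lengths, function(len)
      paste(sample(BASES, len, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- names(cfg$chrom_lengths)
    ## genes per chromosome, proportional to slot counts
    n_per <- floor(n_slots * cfg$n_genes / sum(n_slots))
    i <- 1L
    while (sum(n_per) < cfg$n_genes) {  # distribute the remainder
      k <- ((i - 1L) %% length(n_per)) + 1L
      if (n_per[k] < n_slots[k]) n_per[k] <- n_per[k] + 1L
      i <- i + 1L
    }
    recs <- list()
    gi <- 0L
    for (ci in seq_along(cfg$chrom_lengths)) {
      if (n_per[ci] == 0L) next
      slots <- sort(sample.int(n_slots[ci], n_per[ci]))
      body <- sample(seq(body_range[1], body_range[2]), n_per[ci],
                     replace = TRUE)
      jit <- vapply(slot_w - body, function(m) sample.int(m, 1L), integer(1))
      start <- (slots - 1L) * slot_w + jit + 1L
      strand <- sample(c("+", "-"), n_per[ci], replace = TRUE)
      recs[[ci]] <- data.frame(
        chrom = names(cfg$chrom_lengths)[ci],
        start = start, end = start + body - 1L, strand = strand,
        gene_id = sprintf("g%04d", gi + seq_len(n_per[ci])),
        stringsAsFactors = FALSE)
      gi <- gi + n_per[ci]
    }
    genes_df <- do.call(rbind, recs)
    genes <- GenomicRanges::GRanges(
      seqnames = genes_df$chrom,
      ranges = IRanges::IRanges(genes_df$start, genes_df$end),
      strand = genes_df$strand)
    S4Vectors::mcols(genes)$gene_id <- genes_df$gene_id
    S4Vectors::mcols(genes)$tss <- ifelse(genes_df$strand == "+",
                                          genes_df$start, genes_df$end)
    layout <- structure(list(chrom_lengths = cfg$chrom_lengths,
                             genes = genes),
                        class = "genome_layout")
    structure(list(layout = layout, seqs = seqs),
              class = "synthetic_genome")
  })
}

## Multiplier of the open-chromatin cut rate for a DHS class in a
## condition. Inducible DHSs open only in stimulated TB/TM (naive cells
## do not open them even when stimulated); the other classes are open in
## every condition, weakly (multiplier from fc_*_TN) in naive cells.
class_condition_multiplier <- function(class, condition, cfg) {
  cell <- sub("_stim$", "", condition)
  stim <- grepl("_stim$", condition)
  if (class == "inducible") {
    f <- cfg$fold[["inducible"]]
    if (stim && cell %in% c("TB", "TM")) return(f[3])
    return(0)  # closed: background rate only
  }
  if (class == "tn_specific") {
    ## naive-specific decoys balance the primed mass gained in TB/TM
    if (cell == "TN") return(max(cfg$fold[["primed"]][2] - 1, 0))
    return(0)
  }
  f <- cfg$fold[[class]]
  m <- switch(cell, TN = 1, TB = f[2], TM = f[1])
  if (stim) m <- m * f[3]
  m
}

## Conditions in which a planted DHS is open (rate above background).
class_open_in <- function(class) {
  if (class == "inducible") return(c("TB_stim", "TM_stim"))
  if (class == "tn_specific") return(c("TN", "TN_stim"))
  conditions()
}

## A maximal-scoring realization of an IUPAC consensus (degenerate
## positions sampled uniformly over their allowed set).
realize_consensus <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(letters, function(l) {
    allowed <- IUPAC_SETS[[l]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1)), collapse = "")
}

## Mutate chance library-motif hits out of a DHS interior, leaving the
## planted spans untouched. `planted` is a 2-column matrix of (start,end)
## spans, 1-based within `seq_str`.
scrub_sequence <- function(seq_str, planted, library, max_iter = 30L) {
  in_planted <- rep(FALSE, nchar(seq_str))
  if (nrow(planted) > 0) {
    for (k in seq_len(nrow(planted)))
      in_planted[planted[k, 1]:planted[k, 2]] <- TRUE
  }
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (iter in seq_len(max_iter)) {
    hits <- scan_motifs(stats::setNames(seq_str, "x"), library)
    if (nrow(hits) == 0L) break
    mutated <- FALSE
    for (h in seq_len(nrow(hits))) {
      span <- hits$start[h]:hits$end[h]
      free <- span[!in_planted[span]]
      if (length(free) == 0L) next  # legitimate planted hit
      pos <- free[ceiling(length(free) / 2)]
      old <- substr(seq_str, pos, pos)
      substr(seq_str, pos, pos) <- rot[[old]]
      in_planted[pos] <- TRUE  # freeze so we do not oscillate
      mutated <- TRUE
    }
    if (!mutated) break
  }
  seq_str
}

## Simple interval accumulator used to keep planted DHSs apart.
.overlaps_any <- function(occ, chrom, s, e, pad) {
  iv <- occ[[chrom]]
  if (is.null(iv) || length(iv$start) == 0L) return(FALSE)
  any(iv$start <= e + pad & iv$end >= s - pad)
}
.occupy <- function(occ, chrom, s, e) {
  occ[[chrom]]$start <- c(occ[[chrom]]$start, s)
  occ[[chrom]]$end <- c(occ[[chrom]]$end, e)
  occ
}

#' Plant the regulatory landscape into a synthetic genome
#'
#' Places the configured numbers of primed, inducible, diminished and
#' invariant DHSs (widths drawn from `dhs_width_range`), writes motif
#' instances into the genome sequence at planted positions, assigns
#' occupied footprints, and links a fraction of primed/inducible DHS
#' pairs to inducible genes: the linked primed DHS summit lies within
#' `pdhs_tss_range` of the gene's TSS and the linked inducible DHS within
#' `idhs_offset_range` of the primed DHS, on the side away from the TSS.
#' Primed DHSs receive a constitutive-heavy motif mix and inducible DHSs
#' an inducible-heavy mix; DHSs carrying both ETS and RUNX (or both NFAT
#' and AP-1) get the pair planted as an adjacent composite element.
#' Chance library-motif matches arising in the random background within
#' DHS interiors are mutated away so the planted composition is the
#' measured composition (see the methods vignette).
#'
#' @param genome A `synthetic_genome` from [generate_genome()].
#' @param cfg The [sim_config()] used to generate it.
#' @param library Motif library used for planting and scrubbing.
#' @return A list with the modified `genome` and `truth` (class
#'   `synthetic_truth`): planted DHS `GRanges` (with class, summit,
#'   open-in conditions and linked gene), footprint and motif-placement
#'   `GRanges`, the inducible gene set and per-gene log2 induction
#'   effects.
#' @export
plant_landscape <- function(genome, cfg = sim_config(),
                            library = build_motif_library()) {
  validate_sim_config(cfg)
  layout <- genome$layout
  seqs <- genome$seqs
  min_interior <- cfg$dhs_width_range[1] - 100L
  max_motif_len <- max(vapply(library, function(m) ncol(m$pwm), integer(1)))
  if (max_motif_len > min_interior)
    stop("motif of length ", max_motif_len,
         " does not fit inside the smallest DHS interior (",
         min_interior, " bp)", call. = FALSE)
  with_seed(derive_seed(cfg$seed, 1L), {
    n_linked <- round(cfg$linked_fraction *
                        min(cfg$n_dhs[["primed"]], cfg$n_dhs[["inducible"]]))
    genes <- layout$genes
    tss <- S4Vectors::mcols(genes)$tss
    gchrom <- as.character(GenomicRanges::seqnames(genes))
    gid <- S4Vectors::mcols(genes)$gene_id
    ## pick inducible genes with >= 60 kb separation and room for a triad
    reach <- cfg$pdhs_tss_range[2] + cfg$idhs_offset_range[2] + 1000L
    cand <- sample(seq_along(genes))
    chosen <- integer(0)
    for (g in cand) {
      if (length(chosen) >= n_linked) break
      same <- chosen[gchrom[chosen] == gchrom[g]]
      if (length(same) && min(abs(tss[same] - tss[g])) < 60000L) next
      len <- layout$chrom_lengths[[gchrom[g]]]
      if (tss[g] - reach < 1L && tss[g] + reach > len) next
      chosen <- c(chosen, g)
    }
    if (length(chosen) < n_linked)
      stop("genome too small to host ", n_linked,
           " linked inducible loci (placed ", length(chosen), ")",
           call. = FALSE)
    inducible_genes <- gid[chosen]
    ## graded induction effects, optionally coupled to linkage distance
    if (!is.null(cfg$expr_effect_range)) {
      effects <- stats::runif(n_linked, cfg$expr_effect_range[1],
                              cfg$expr_effect_range[2])
    } else {
      effects <- rep(cfg$expr_effect, n_linked)
    }
    names(effects) <- inducible_genes

    widths_for <- function(n) sample(seq(cfg$dhs_width_range[1],
                                         cfg$dhs_width_range[2]), n,
                                     replace = TRUE)
    occ <- stats::setNames(vector("list", length(layout$chrom_lengths)),
                           names(layout$chrom_lengths))
    dhs <- list()
    add_dhs <- function(chrom, summit, width, class, linked_gene) {
      s <- summit - floor(width / 2)
      e <- s + width - 1L
      list(chrom = chrom, start = s, end = e, summit = summit,
           class = class, linked_gene = linked_gene)
    }
    ## linked triads
    for (k in seq_len(n_linked)) {
      g <- chosen[k]
      chrom <- gchrom[g]; t <- tss[g]
      len <- layout$chrom_lengths[[chrom]]
      if (!is.null(cfg$expr_effect_range)) {
        ## stronger induction -> closer linked DHSs
        er <- cfg$expr_effect_range
        frac <- if (diff(er) > 0) (er[2] - effects[k]) / diff(er) else 0.5
        d1_base <- cfg$pdhs_tss_range[1] +
          frac * diff(cfg$pdhs_tss_range)
        d2_base <- cfg$idhs_offset_range[1] +
          frac * diff(cfg$idhs_offset_range)
      } else {
        d1_base <- d2_base <- NA
      }
      placed <- FALSE
      for (try in 1:200) {
        o <- sample(c(-1L, 1L), 1L)
        d1 <- if (is.na(d1_base))
          sample(seq(cfg$pdhs_tss_range[1], cfg$pdhs_tss_range[2]), 1L)
        else round(d1_base * stats::runif(1, 0.9, 1.1))
        d2 <- if (is.na(d2_base))
          sample(seq(cfg$idhs_offset_range[1], cfg$idhs_offset_range[2]), 1L)
        else round(d2_base * stats::runif(1, 0.9, 1.1))
        d1 <- min(max(d1, cfg$pdhs_tss_range[1]), cfg$pdhs_tss_range[2])
        d2 <- min(max(d2, cfg$idhs_offset_range[1]), cfg$idhs_offset_range[2])
        wp <- widths_for(1L); wi <- widths_for(1L)
        sp <- t + o * d1          # primed summit
        si <- sp + o * d2         # inducible summit, away from the TSS
        lo_p <- sp - floor(wp / 2); hi_p <- lo_p + wp - 1L
        lo_i <- si - floor(wi / 2); hi_i <- lo_i + wi - 1L
        if (min(lo_p, lo_i) < 1000L || max(hi_p, hi_i) > len - 1000L) next
        if (.overlaps_any(occ, chrom, lo_p, hi_p, 1000L)) next
        if (.overlaps_any(occ, chrom, lo_i, hi_i, 1000L)) next
        occ <- .occupy(occ, chrom, lo_p, hi_p)
        occ <- .occupy(occ, chrom, lo_i, hi_i)
        dhs[[length(dhs) + 1L]] <- add_dhs(chrom, sp, wp, "primed", gid[g])
        dhs[[length(dhs) + 1L]] <- add_dhs(chrom, si, wi, "inducible", gid[g])
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place linked DHS pair for gene ", gid[g], call. = FALSE)
    }
    ## remaining DHSs, uniform across the genome; naive-specific decoys
    ## (same count and widths as primed) balance the unstimulated
    ## open-chromatin mass across cell types
    remaining <- c(primed = cfg$n_dhs[["primed"]] - n_linked,
                   inducible = cfg$n_dhs[["inducible"]] - n_linked,
                   diminished = cfg$n_dhs[["diminished"]],
                   invariant = cfg$n_dhs[["invariant"]])
    if (cfg$balance_naive && cfg$fold[["primed"]][2] > 1)
      remaining <- c(remaining, tn_specific = cfg$n_dhs[["primed"]])
    chrom_names <- names(layout$chrom_lengths)
    chrom_prob <- layout$chrom_lengths / sum(layout$chrom_lengths)
    for (class in names(remaining)) {
      for (k in seq_len(remaining[[class]])) {
        placed <- FALSE
        for (try in 1:500) {
          chrom <- sample(chrom_names, 1L, prob = chrom_prob)
          len <- layout$chrom_lengths[[chrom]]
          w <- widths_for(1L)
          summit <- sample.int(len - 2L * (w + 1000L), 1L) + w + 1000L
          lo <- summit - floor(w / 2); hi <- lo + w - 1L
          if (.overlaps_any(occ, chrom, lo, hi, 1000L)) next
          occ <- .occupy(occ, chrom, lo, hi)
          dhs[[length(dhs) + 1L]] <- add_dhs(chrom, summit, w, class,
                                             NA_character_)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("genome too small to place all DHSs: failed at ", class,
               " DHS ", k, " of ", remaining[[class]], call. = FALSE)
      }
    }
    dhs_df <- do.call(rbind, lapply(dhs, as.data.frame,
                                    stringsAsFactors = FALSE))
    dhs_df$dhs_id <- sprintf("dhs_%04d", seq_len(nrow(dhs_df)))
    ## plant motifs and footprints
    placements <- list()
    footprints <- list()
    fp_half <- floor(cfg$footprint_width / 2)
    for (r in seq_len(nrow(dhs_df))) {
      class <- dhs_df$class[r]
      mix <- cfg$motif_mix[[class]]
      if (is.null(mix) && class == "tn_specific")
        mix <- cfg$motif_mix[["invariant"]]
      if (is.null(mix) || sum(mix) == 0L) next
      unknown <- setdiff(names(mix), names(library))
      if (length(unknown))
        stop("motif_mix names not in library: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      instances <- rep(names(mix), mix)
      ## class-signature composite pairs are planted adjacently; other
      ## motif instances become independently placed blocks
      blocks <- list()
      if (class == "primed" && all(c("ETS", "RUNX") %in% instances)) {
        blocks[[length(blocks) + 1L]] <- c("ETS", "RUNX")
        instances <- instances[-match(c("ETS", "RUNX"), instances)]
      }
      if (class == "inducible" && all(c("NFAT", "AP-1") %in% instances)) {
        blocks[[length(blocks) + 1L]] <- c("NFAT", "AP-1")
        instances <- instances[-match(c("NFAT", "AP-1"), instances)]
      }
      for (m in instances) blocks[[length(blocks) + 1L]] <- m
      blocks <- blocks[sample.int(length(blocks))]
      block_len <- vapply(blocks, function(b)
        sum(vapply(b, function(m) ncol(library[[m]]$pwm), integer(1))) +
          2L * (length(b) - 1L), integer(1))
      interior_lo <- dhs_df$start[r] + 50L
      interior_hi <- dhs_df$end[r] - 50L
      avail <- interior_hi - interior_lo + 1L
      min_gap <- 6L
      need <- sum(block_len) + min_gap * (length(blocks) - 1L)
      if (need > avail)
        stop("motif mix for class '", class, "' (", need,
             " bp) does not fit inside a ", avail, " bp DHS interior",
             call. = FALSE)
      ## random non-overlapping block offsets with >= min_gap spacing
      slack <- avail - sum(block_len) - min_gap * (length(blocks) - 1L)
      u <- sort(floor(stats::runif(length(blocks)) * (slack + 1)))
      for (bi in seq_along(blocks)) {
        bstart <- interior_lo + u[bi] +
          (if (bi > 1L) sum(block_len[seq_len(bi - 1L)]) +
             min_gap * (bi - 1L) else 0L)
        p <- bstart
        for (m in blocks[[bi]]) {
          L <- ncol(library[[m]]$pwm)
          realization <- realize_consensus(library[[m]]$consensus)
          chrom <- dhs_df$chrom[r]
          substr(seqs[[chrom]], p, p + L - 1L) <- realization
          center <- p + (L - 1) / 2
          placements[[length(placements) + 1L]] <- data.frame(
            chrom = chrom, start = p, end = p + L - 1L, motif = m,
            dhs_id = dhs_df$dhs_id[r], dhs_class = class,
            center = center, stringsAsFactors = FALSE)
          occupied <- NULL
          if (class == "primed" && m %in% c("ETS", "RUNX"))
            occupied <- c("TB", "TB_stim", "TM", "TM_stim")
          if (m %in% c("AP-1", "NFAT") && class %in% c("primed", "inducible"))
            occupied <- c("TB_stim", "TM_stim")
          if (!is.null(occupied)) {
            fc <- round(center)
            footprints[[length(footprints) + 1L]] <- data.frame(
              chrom = chrom, start = fc - fp_half,
              end = fc - fp_half + cfg$footprint_width - 1L,
              motif = m, dhs_id = dhs_df$dhs_id[r],
              occupied_in = paste(occupied, collapse = ","),
              stringsAsFactors = FALSE)
          }
          p <- p + L + 2L
        }
      }
    }
    placements_df <- if (length(placements)) do.call(rbind, placements) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 motif = character(0), dhs_id = character(0),
                 dhs_class = character(0), center = numeric(0))
    footprints_df <- if (length(footprints)) do.call(rbind, footprints) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 motif = character(0), dhs_id = character(0),
                 occupied_in = character(0))
    ## scrub chance hits from DHS neighbourhoods (called peaks extend a
    ## little past the planted interval, so the scrub window does too)
    for (r in seq_len(nrow(dhs_df))) {
      chrom <- dhs_df$chrom[r]
      pad <- 300L
      s <- max(1L, dhs_df$start[r] - pad)
      e <- min(layout$chrom_lengths[[chrom]], dhs_df$end[r] + pad)
      pl <- placements_df[placements_df$dhs_id == dhs_df$dhs_id[r], ,
                          drop = FALSE]
      spans <- cbind(pl$start - s + 1L, pl$end - s + 1L)
      ## merge near-adjacent planted spans (composite blocks) so their
      ## internal spacer bases are not treated as mutable
      if (nrow(spans) > 1L) {
        ir <- IRanges::reduce(IRanges::IRanges(spans[, 1], spans[, 2]),
                              min.gapwidth = 4L)
        spans <- cbind(IRanges::start(ir), IRanges::end(ir))
      }
      piece <- substr(seqs[[chrom]], s, e)
      scrubbed <- scrub_sequence(piece, spans, library)
      if (!identical(scrubbed, piece))
        substr(seqs[[chrom]], s, e) <- scrubbed
    }
    dhs_gr <- GenomicRanges::GRanges(
      seqnames = dhs_df$chrom,
      ranges = IRanges::IRanges(dhs_df$start, dhs_df$end))
    S4Vectors::mcols(dhs_gr) <- S4Vectors::DataFrame(
      dhs_id = dhs_df$dhs_id, class = dhs_df$class,
      summit = dhs_df$summit,
      open_in = vapply(dhs_df$class, function(cl)
        paste(class_open_in(cl), collapse = ","), character(1)),
      linked_gene = dhs_df$linked_gene)
    fp_gr <- GenomicRanges::GRanges(
      seqnames = footprints_df$chrom,
      ranges = IRanges::IRanges(footprints_df$start, footprints_df$end))
    S4Vectors::mcols(fp_gr) <- S4Vectors::DataFrame(
      motif = footprints_df$motif, dhs_id = footprints_df$dhs_id,
      occupied_in = footprints_df$occupied_in)
    pl_gr <- GenomicRanges::GRanges(
      seqnames = placements_df$chrom,
      ranges = IRanges::IRanges(placements_df$start, placements_df$end))
    S4Vectors::mcols(pl_gr) <- S4Vectors::DataFrame(
      motif = placements_df$motif, dhs_id = placements_df$dhs_id,
      dhs_class = placements_df$dhs_class, center = placements_df$center)
    truth <- structure(list(dhs = dhs_gr, footprints = fp_gr,
                            motif_placements = pl_gr,
                            inducible_genes = inducible_genes,
                            gene_effects = effects,
                            config = cfg),
                       class = "synthetic_truth")
    genome$seqs <- seqs
    list(genome = genome, truth = truth)
  })
}

#' Simulate strand-specific DNase I cut profiles for one condition
#'
#' A per-base relative cut-intensity field is laid down for each strand:
#' `background_rate` everywhere, plus — inside a DHS open in the
#' condition — `base_open_rate` times the class/condition fold
#' multiplier, split equally between strands (open-chromatin signal
#' rides additively on the nonspecific background, so a strongly
#' depleted DHS approaches background rather than dropping below it). Inside an occupied footprint both strands
#' are depleted by `footprint_depletion`, while the `flank_boost_width`
#' bp immediately 5' (plus strand) and 3' (minus strand) of the
#' footprint are boosted `flank_boost`-fold — the strand-imbalance
#' signature that digital footprinting detects. Exactly
#' `depth_per_condition` cuts are then drawn multinomially with
#' probabilities proportional to the rate field — the conditional
#' distribution of independent Poisson counts given their total — so
#' per-base counts keep Poisson statistics while the library total is
#' exact. Deterministic given (seed, condition).
#'
#' @param truth `synthetic_truth` from [plant_landscape()].
#' @param genome The matching `synthetic_genome`.
#' @param condition One of [conditions()].
#' @param cfg The [sim_config()].
#' @return Object of class `cut_profiles`: per-chromosome integer vectors
#'   `plus` and `minus`, plus `library_total` and `condition`.
#' @export
simulate_cuts <- function(truth, genome, condition, cfg = sim_config()) {
  .check_condition(condition)
  layout <- genome$layout
  cond_idx <- match(condition, conditions())
  dhs <- truth$dhs
  fps <- truth$footprints
  open_sets <- strsplit(S4Vectors::mcols(dhs)$open_in, ",", fixed = TRUE)
  fp_occ <- strsplit(S4Vectors::mcols(fps)$occupied_in, ",", fixed = TRUE)
  jitter <- if (cfg$fold_jitter_sd > 0) {
    with_seed(derive_seed(cfg$seed, 9L),
              stats::rlnorm(length(dhs), 0, cfg$fold_jitter_sd))
  } else rep(1, length(dhs))
  with_seed(derive_seed(cfg$seed, 10L + cond_idx), {
    profs <- list()
    for (chrom in names(layout$chrom_lengths)) {
      len <- layout$chrom_lengths[[chrom]]
      rate_p <- rep(cfg$background_rate, len)
      rate_m <- rep(cfg$background_rate, len)
      on_chrom <- which(as.character(GenomicRanges::seqnames(dhs)) == chrom)
      for (r in on_chrom) {
        if (!condition %in% open_sets[[r]]) next
        m <- class_condition_multiplier(S4Vectors::mcols(dhs)$class[r],
                                        condition, cfg) * jitter[r]
        if (m <= 0) next
        idx <- GenomicRanges::start(dhs)[r]:GenomicRanges::end(dhs)[r]
        ## open-chromatin signal rides on the nonspecific background
        rate_p[idx] <- rate_p[idx] + cfg$base_open_rate * m / 2
        rate_m[idx] <- rate_m[idx] + cfg$base_open_rate * m / 2
      }
      on_chrom_fp <- which(as.character(GenomicRanges::seqnames(fps)) == chrom)
      for (r in on_chrom_fp) {
        if (!condition %in% fp_occ[[r]]) next
        s <- GenomicRanges::start(fps)[r]; e <- GenomicRanges::end(fps)[r]
        rate_p[s:e] <- rate_p[s:e] * cfg$footprint_depletion
        rate_m[s:e] <- rate_m[s:e] * cfg$footprint_depletion
        w <- cfg$flank_boost_width
        lo <- max(1L, s - w); hi <- min(len, e + w)
        if (lo <= s - 1L) rate_p[lo:(s - 1L)] <- rate_p[lo:(s - 1L)] * cfg$flank_boost
        if (e + 1L <= hi) rate_m[(e + 1L):hi] <- rate_m[(e + 1L):hi] * cfg$flank_boost
      }
      profs[[chrom]] <- list(plus = rate_p, minus = rate_m)
    }
    ## "Sequence" exactly depth_per_condition cuts: a multinomial draw
    ## with probabilities proportional to the rate field is the exact
    ## conditional distribution of independent Poisson counts given
    ## their total, so per-base counts keep Poisson statistics while
    ## the library total is exact. Drawn hierarchically (totals per
    ## chromosome/strand, then within) to keep vectors small.
    target <- cfg$depth_per_condition
    groups <- list()
    for (ch in names(profs)) {
      groups[[paste0(ch, ":plus")]] <- sum(profs[[ch]]$plus)
      groups[[paste0(ch, ":minus")]] <- sum(profs[[ch]]$minus)
    }
    gsum <- unlist(groups)
    if (sum(gsum) <= 0)
      stop("cut-rate field is all zero; cannot sequence", call. = FALSE)
    gtot <- as.integer(stats::rmultinom(1L, size = target, prob = gsum))
    names(gtot) <- names(gsum)
    for (ch in names(profs)) {
      profs[[ch]]$plus <- as.integer(stats::rmultinom(
        1L, size = gtot[[paste0(ch, ":plus")]], prob = profs[[ch]]$plus))
      profs[[ch]]$minus <- as.integer(stats::rmultinom(
        1L, size = gtot[[paste0(ch, ":minus")]], prob = profs[[ch]]$minus))
    }
    structure(list(chroms = profs, library_total = target,
                   condition = condition),
              class = "cut_profiles")
  })
}

#' Simulate a log2 expression table
#'
#' Each gene receives a baseline log2 level shared by every condition;
#' inducible genes additionally receive their log2 induction effect in
#' stimulated TB and TM samples only (stimulated naive cells do not
#' induce them, and unstimulated conditions share steady-state levels).
#' Gaussian noise of sd `expr_noise_sd` is added per measurement.
#'
#' @param truth `synthetic_truth` from [plant_landscape()].
#' @param genome The matching `synthetic_genome`.
#' @param cfg The [sim_config()].
#' @return Numeric matrix, genes x (6 conditions x `n_replicates`),
#'   with columns named `<condition>_<replicate>`.
#' @export
simulate_expression <- function(truth, genome, cfg = sim_config()) {
  genes <- genome$layout$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  conds <- conditions()
  cols <- as.vector(t(outer(conds, seq_len(cfg$n_replicates),
                            function(c, r) paste0(c, "_", r))))
  with_seed(derive_seed(cfg$seed, 20L), {
    baseline <- stats::rnorm(length(gid), cfg$expr_baseline_mean,
                             cfg$expr_baseline_sd)
    mat <- matrix(rep(baseline, length(cols)), nrow = length(gid),
                  dimnames = list(gid, cols))
    ind <- gid %in% truth$inducible_genes
    eff <- rep(0, length(gid))
    eff[ind] <- truth$gene_effects[gid[ind]]
    stim_cols <- grep("^(TB|TM)_stim_", cols)
    for (j in stim_cols) mat[, j] <- mat[, j] + eff
    if (cfg$expr_noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, cfg$expr_noise_sd),
                          nrow = nrow(mat))
    mat
  })
}
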