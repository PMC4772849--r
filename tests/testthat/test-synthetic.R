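# Synthetic genome, planted landscape, cut simulation and expression.

mini_cfg <- function(...) {
  sim_config(seed = 11L, chrom_lengths = c(c1 = 2e5, c2 = 2e5),
             n_genes = 20L,
             n_dhs = c(primed = 4L, inducible = 4L, diminished = 2L,
                       invariant = 6L),
             depth_per_condition = 4e5, linked_fraction = 0.5, ...)
}

test_that("genome generation is deterministic and respects gene invariants", {
  cfg <- mini_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(as.data.frame(g1$layout$genes),
                   as.data.frame(g2$layout$genes))
  genes <- g1$layout$genes
  expect_length(genes, cfg$n_genes)
  expect_false(any(duplicated(S4Vectors::mcols(genes)$gene_id)))
  expect_setequal(unique(as.character(GenomicRanges::strand(genes))),
                  c("+", "-"))
  # non-overlapping bodies, inside chromosomes
  expect_identical(
    sum(IRanges::width(GenomicRanges::reduce(genes, ignore.strand = TRUE))),
    sum(IRanges::width(genes)))
  for (ch in names(cfg$chrom_lengths)) {
    on_ch <- genes[as.character(GenomicRanges::seqnames(genes)) == ch]
    expect_true(all(GenomicRanges::start(on_ch) >= 1))
    expect_true(all(GenomicRanges::end(on_ch) <= cfg$chrom_lengths[[ch]]))
  }
  # TSS is the 5' end of the body
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  expect_identical(S4Vectors::mcols(genes)$tss[plus],
                   GenomicRanges::start(genes)[plus])
  expect_identical(S4Vectors::mcols(genes)$tss[!plus],
                   GenomicRanges::end(genes)[!plus])
})

test_that("an infeasible genome raises a sizing error", {
  expect_error(generate_genome(sim_config(chrom_lengths = c(c1 = 1e4),
                                          n_genes = 400L)),
               "too small")
})

test_that("planted landscape satisfies the truth invariants", {
  cfg <- mini_cfg()
  pl <- plant_landscape(generate_genome(cfg), cfg)
  truth <- pl$truth
  dhs <- truth$dhs
  mc <- S4Vectors::mcols(dhs)
  # class counts (plus naive-specific decoys matching the primed count)
  cnt <- table(mc$class)
  for (cl in dhs_classes()) expect_equal(unname(cnt[[cl]]),
                                         unname(cfg$n_dhs[[cl]]))
  expect_equal(unname(cnt[["tn_specific"]]), unname(cfg$n_dhs[["primed"]]))
  # non-overlapping intervals, widths in range
  expect_identical(sum(IRanges::width(GenomicRanges::reduce(dhs))),
                   sum(IRanges::width(dhs)))
  expect_true(all(IRanges::width(dhs) >= cfg$dhs_width_range[1] &
                    IRanges::width(dhs) <= cfg$dhs_width_range[2]))
  # every footprint lies inside exactly one planted DHS
  ov <- GenomicRanges::countOverlaps(truth$footprints, dhs, type = "within")
  expect_true(all(ov == 1L))
  # every motif placement lies inside its DHS
  pl_ov <- GenomicRanges::countOverlaps(truth$motif_placements, dhs,
                                        type = "within")
  expect_true(all(pl_ov >= 1L))
  # linkage: every inducible gene has a primed DHS within the configured
  # TSS bound and an inducible DHS within the offset bound of that pDHS
  genes <- pl$genome$layout$genes
  gmc <- S4Vectors::mcols(genes)
  for (gid in truth$inducible_genes) {
    tss <- gmc$tss[gmc$gene_id == gid]
    p <- dhs[!is.na(mc$linked_gene) & mc$linked_gene == gid &
               mc$class == "primed"]
    i <- dhs[!is.na(mc$linked_gene) & mc$linked_gene == gid &
               mc$class == "inducible"]
    expect_true(length(p) >= 1 && length(i) >= 1)
    dp <- abs(S4Vectors::mcols(p)$summit - tss)
    expect_true(any(dp >= cfg$pdhs_tss_range[1] &
                      dp <= cfg$pdhs_tss_range[2]))
    di <- abs(S4Vectors::mcols(i)$summit - S4Vectors::mcols(p)$summit)
    expect_true(any(di >= cfg$idhs_offset_range[1] &
                      di <= cfg$idhs_offset_range[2]))
  }
  # primed DHSs carry an adjacent ETS/RUNX composite pair
  pmc <- S4Vectors::mcols(truth$motif_placements)
  for (id in mc$dhs_id[mc$class == "primed"]) {
    ets <- pmc$center[pmc$dhs_id == id & pmc$motif == "ETS"]
    runx <- pmc$center[pmc$dhs_id == id & pmc$motif == "RUNX"]
    expect_true(min(abs(outer(ets, runx, "-"))) <= 20)
  }
})

test_that("full linkage gives every inducible gene a linked pair", {
  cfg <- mini_cfg()
  cfg$linked_fraction <- 1.0
  cfg <- primedhs:::validate_sim_config(cfg)
  truth <- plant_landscape(generate_genome(cfg), cfg)$truth
  expect_length(truth$inducible_genes,
                min(cfg$n_dhs[["primed"]], cfg$n_dhs[["inducible"]]))
  linked <- S4Vectors::mcols(truth$dhs)$linked_gene
  for (gid in truth$inducible_genes) {
    cls <- S4Vectors::mcols(truth$dhs)$class[!is.na(linked) & linked == gid]
    expect_setequal(cls, c("primed", "inducible"))
  }
})

test_that("motifs that cannot fit inside a DHS raise a placement error", {
  cfg <- mini_cfg(dhs_width_range = c(100L, 110L))
  expect_error(plant_landscape(generate_genome(cfg), cfg),
               "does not fit")
})

test_that("cut simulation is deterministic, depth-exact and rejects bad labels", {
  cfg <- mini_cfg()
  pl <- plant_landscape(generate_genome(cfg), cfg)
  expect_error(simulate_cuts(pl$truth, pl$genome, "T_whatever", cfg),
               "unknown condition")
  p1 <- simulate_cuts(pl$truth, pl$genome, "TB", cfg)
  p2 <- simulate_cuts(pl$truth, pl$genome, "TB", cfg)
  expect_identical(p1, p2)
  total <- sum(vapply(p1$chroms, function(p)
    sum(as.numeric(p$plus)) + sum(as.numeric(p$minus)), numeric(1)))
  expect_identical(total, cfg$depth_per_condition)
})

test_that("planted rate structure is recovered from the cut profiles", {
  cfg <- mini_cfg()
  pl <- plant_landscape(generate_genome(cfg), cfg)
  truth <- pl$truth
  mc <- S4Vectors::mcols(truth$dhs)
  prof <- list(TN = simulate_cuts(truth, pl$genome, "TN", cfg),
               TB = simulate_cuts(truth, pl$genome, "TB", cfg),
               TM = simulate_cuts(truth, pl$genome, "TM", cfg))
  dhs_mean <- function(prof, r) {
    ch <- as.character(GenomicRanges::seqnames(truth$dhs))[r]
    idx <- GenomicRanges::start(truth$dhs)[r]:GenomicRanges::end(truth$dhs)[r]
    mean(prof$chroms[[ch]]$plus[idx] + prof$chroms[[ch]]$minus[idx])
  }
  inv <- which(mc$class == "invariant")
  # invariant DHSs: TB/TN count ratio ~ 1 (the decoy-balanced design)
  ratios <- vapply(inv, function(r) dhs_mean(prof$TB, r) / dhs_mean(prof$TN, r),
                   numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
  # primed DHSs: TM/TN rate ratio near (bg + 8) / (bg + 1), diluted by
  # the shared background
  pr <- which(mc$class == "primed")
  pr_ratio <- mean(vapply(pr, function(r)
    dhs_mean(prof$TM, r) / dhs_mean(prof$TN, r), numeric(1)))
  expect_gt(pr_ratio, 5)
  expect_lt(pr_ratio, 9)
})

test_that("occupied footprints show depletion and polarized flank boosts", {
  cfg <- mini_cfg()
  pl <- plant_landscape(generate_genome(cfg), cfg)
  truth <- pl$truth
  prof <- simulate_cuts(truth, pl$genome, "TB", cfg)
  fps <- truth$footprints
  occ <- strsplit(S4Vectors::mcols(fps)$occupied_in, ",")
  active <- which(vapply(occ, function(o) "TB" %in% o, logical(1)))
  # composite footprints overlap each other's flanks; measure isolated ones
  iso <- GenomicRanges::countOverlaps(fps + 35L, fps) == 1L
  active <- active[iso[active]]
  expect_gt(length(active), 0)
  inner <- flank5 <- flank_far <- numeric(0)
  for (r in active) {
    ch <- as.character(GenomicRanges::seqnames(fps))[r]
    s <- GenomicRanges::start(fps)[r]; e <- GenomicRanges::end(fps)[r]
    p <- prof$chroms[[ch]]
    inner <- c(inner, mean(p$plus[s:e] + p$minus[s:e]))
    flank5 <- c(flank5, mean(p$plus[(s - 10):(s - 1)]))
    flank_far <- c(flank_far, mean(p$plus[(s - 30):(s - 21)]))
  }
  # interior ~ depletion x the unboosted open rate; 5' plus-strand flank
  # boosted ~2x over the open rate just beyond it
  expect_lt(mean(inner) / (2 * mean(flank_far)), 0.2)
  expect_gt(mean(flank5) / mean(flank_far), 1.5)
})

test_that("mean cut rates match the configured relative rates across seeds", {
  cfg <- sim_config(seed = 3L, chrom_lengths = c(c1 = 5e4, c2 = 5e4),
                    n_genes = 8L,
                    n_dhs = c(primed = 1L, inducible = 1L,
                              diminished = 1L, invariant = 2L),
                    depth_per_condition = 1e5, linked_fraction = 0)
  pl <- plant_landscape(generate_genome(cfg), cfg)
  truth <- pl$truth
  mc <- S4Vectors::mcols(truth$dhs)
  inv <- which(mc$class == "invariant")[1]
  ch <- as.character(GenomicRanges::seqnames(truth$dhs))[inv]
  idx <- GenomicRanges::start(truth$dhs)[inv]:GenomicRanges::end(truth$dhs)[inv]
  in_dhs <- rep(FALSE, cfg$chrom_lengths[[ch]])
  on_ch <- truth$dhs[as.character(GenomicRanges::seqnames(truth$dhs)) == ch]
  for (r in seq_along(on_ch)) {
    lo <- max(1L, GenomicRanges::start(on_ch)[r] - 100L)
    hi <- min(length(in_dhs), GenomicRanges::end(on_ch)[r] + 100L)
    in_dhs[lo:hi] <- TRUE
  }
  bg_idx <- which(!in_dhs)
  ratios <- vapply(1:100, function(s) {
    cfg2 <- cfg
    cfg2$seed <- 1000L + s
    p <- simulate_cuts(truth, pl$genome, "TB", cfg2)
    dhs_rate <- mean(p$chroms[[ch]]$plus[idx] + p$chroms[[ch]]$minus[idx])
    bg_rate <- mean(p$chroms[[ch]]$plus[bg_idx] + p$chroms[[ch]]$minus[bg_idx])
    dhs_rate / bg_rate
  }, numeric(1))
  # configured contrast: (background + open) / background
  expected <- (2 * cfg$background_rate + cfg$base_open_rate) /
    (2 * cfg$background_rate)
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected), 3 * se + 0.02 * expected)
})

test_that("expression tables carry the planted induction structure", {
  cfg <- mini_cfg(expr_noise_sd = 0)
  pl <- plant_landscape(generate_genome(cfg), cfg)
  expr <- simulate_expression(pl$truth, pl$genome, cfg)
  expect_identical(dim(expr), c(cfg$n_genes, 12L))
  ind <- rownames(expr) %in% pl$truth$inducible_genes
  fc_tm <- rowMeans(expr[, grep("^TM_stim", colnames(expr))]) -
    rowMeans(expr[, grep("^TM_[0-9]", colnames(expr))])
  fc_tn <- rowMeans(expr[, grep("^TN_stim", colnames(expr))]) -
    rowMeans(expr[, grep("^TN_[0-9]", colnames(expr))])
  expect_equal(unname(fc_tm[ind]), rep(cfg$expr_effect, sum(ind)))
  expect_equal(unname(fc_tm[!ind]), rep(0, sum(!ind)))
  expect_equal(unname(fc_tn), rep(0, length(fc_tn)))
  # non-inducible genes: all six condition means equal
  other <- expr[!ind, , drop = FALSE]
  expect_equal(apply(other, 1, function(x) diff(range(x))),
               stats::setNames(rep(0, nrow(other)), rownames(other)))
  # determinism
  expect_identical(expr, simulate_expression(pl$truth, pl$genome, cfg))
})
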