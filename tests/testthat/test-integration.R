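# Gene classification, distances, enrichment machinery, clustering.

test_that("TM-specific gene classification applies both thresholds", {
  mk_expr <- function(fc_tm, fc_tn) {
    cols <- as.vector(outer(conditions(), 1:2,
                            function(c, r) paste0(c, "_", r)))
    mat <- matrix(7, nrow = length(fc_tm), ncol = length(cols),
                  dimnames = list(paste0("g", seq_along(fc_tm)), cols))
    mat[, c("TM_stim_1", "TM_stim_2")] <- 7 + fc_tm
    mat[, c("TN_stim_1", "TN_stim_2")] <- 7 + fc_tn
    mat
  }
  cls <- classify_tm_genes(mk_expr(c(1.2, 1.2, 0.9), c(0.5, 1.1, 0.2)),
                           analysis_config())
  expect_identical(cls$tm_specific, "g1")
  expect_setequal(cls$other, c("g2", "g3"))
  bad <- mk_expr(1, 1)
  colnames(bad) <- sub("^TM", "TX", colnames(bad))
  expect_error(classify_tm_genes(bad, analysis_config()), "TM")
})

test_that("nearest distances honour ties, overlaps and empty subjects", {
  q <- data.frame(chrom = "chr1", pos = c(1000, 1000, 5000))
  s <- data.frame(chrom = "chr1", pos = c(1000, 26100, 900, 1100))
  nd <- nearest_distance(q, s)
  expect_equal(nd$distance[1], 0)
  # equidistant neighbours resolve to the smaller coordinate
  q2 <- data.frame(chrom = "chr1", pos = 1000)
  s2 <- data.frame(chrom = "chr1", pos = c(900, 1100))
  nd2 <- nearest_distance(q2, s2)
  expect_equal(nd2$distance, 100)
  expect_equal(nd2$subject_pos, 900)
  # a near-miss of the 25-kb radius: summits at 1,000 and 26,100
  nd3 <- nearest_distance(data.frame(chrom = "chr1", pos = 1000),
                          data.frame(chrom = "chr1", pos = 26100))
  expect_equal(nd3$distance, 25100)
  # empty subject set -> infinite sentinel
  nd4 <- nearest_distance(q, data.frame(chrom = character(0),
                                        pos = numeric(0)))
  expect_true(all(is.infinite(nd4$distance)))
  # different chromosome only
  nd5 <- nearest_distance(data.frame(chrom = "chr2", pos = 1),
                          data.frame(chrom = "chr1", pos = 1))
  expect_true(is.infinite(nd5$distance))
})

test_that("the two-cell chi-square matches its closed form and edge cases", {
  expect_equal(chi2_two_cell(10, 10, 100), 0)
  expect_equal(chi2_two_cell(20, 10, 100), 10 + 100 / 90)
  expect_true(is.na(chi2_two_cell(5, 0, 100)))
  expect_true(is.na(chi2_two_cell(5, 100, 100)))
})

test_that("proximity enrichment reports both p-values and validates pools", {
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(seq(5e4, 9.5e5,
                                                         by = 5e4),
                                                     width = 1))
  feats <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(5e4, 9.5e5,
                                                       by = 5e4) + 100,
                                                   width = 200))
  S4Vectors::mcols(feats)$summit <- seq(5e4, 9.5e5, by = 5e4) + 200L
  cfg <- analysis_config(n_null_draws = 99L, seed = 2)
  r <- proximity_enrichment(feats, anchors, radius = 1000,
                            null_kind = "random_coordinates",
                            chrom_lengths = c(chr1 = 1e6), cfg = cfg)
  expect_equal(r$observed, length(feats))
  expect_lte(r$p_empirical, 1 / 50)
  expect_lt(r$p_chi2, 1e-6)
  expect_error(proximity_enrichment(feats, anchors, 1000,
                                    null_kind = "random_idhs",
                                    null_pool = feats[1:3], cfg = cfg),
               "smaller")
  pool <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(sample(1e6, 100),
                                                  width = 100))
  r2 <- proximity_enrichment(feats, anchors, 1000,
                             null_kind = "random_idhs",
                             null_pool = pool, cfg = cfg)
  expect_true(r2$p_empirical > 0 && r2$p_empirical <= 1)
})

test_that("distance-by-induction bins, excludes and flags correctly", {
  gene_fc <- c(gA = 1.5, gB = 2.5, gC = 4.0, gD = 1.5, gE = 0.5)
  tss <- data.frame(chrom = "chr1", pos = c(1e4, 2e4, 3e4, 5e6, 4e4),
                    gene_id = names(gene_fc))
  dhs <- data.frame(chrom = "chr1", pos = c(1e4 + 500, 2e4 + 300, 3e4 + 100))
  out <- distance_by_induction(gene_fc, tss, dhs)
  expect_identical(nrow(out), 4L)
  # gD is > 1 Mb from every DHS -> excluded; gE sits below the first edge
  expect_equal(out$n_genes[1], 1L)        # [1,2): gA only
  expect_equal(out$median_distance[1], 500)
  expect_equal(out$median_distance[2], 300)
  expect_true(is.na(out$median_distance[3]))
  expect_equal(out$median_distance[4], 100)
  expect_true(all(out$flagged))
  # all genes sitting on DHSs -> all medians zero
  dhs0 <- data.frame(chrom = "chr1", pos = tss$pos)
  out0 <- distance_by_induction(gene_fc, tss, dhs0)
  expect_true(all(out0$median_distance[out0$n_genes > 0] == 0))
})

test_that("graded planted linkage yields shorter distances for stronger genes", {
  cfg <- sim_config(seed = 19L, chrom_lengths = c(c1 = 2e6, c2 = 2e6),
                    n_genes = 140L,
                    n_dhs = c(primed = 30L, inducible = 30L,
                              diminished = 5L, invariant = 30L),
                    depth_per_condition = 2e6,
                    linked_fraction = 1.0,
                    expr_effect_range = c(1.2, 4),
                    expr_noise_sd = 0.1)
  pl <- plant_landscape(generate_genome(cfg), cfg)
  expr <- simulate_expression(pl$truth, pl$genome, cfg)
  cls <- classify_tm_genes(expr, analysis_config())
  fc_tm <- stats::setNames(cls$log2fc$TM, rownames(cls$log2fc))
  idhs <- pl$truth$dhs[S4Vectors::mcols(pl$truth$dhs)$class == "inducible"]
  out <- distance_by_induction(fc_tm[cls$tm_specific],
                               pl$genome$layout$genes, idhs,
                               bin_edges = c(1, 2, 3))
  meds <- out$median_distance[!is.na(out$median_distance)]
  expect_lt(meds[length(meds)], meds[1])
})

test_that("sample clustering groups duplicated and planted structure", {
  withr::local_seed(13)
  expr <- matrix(rnorm(600, 7, 1), nrow = 100,
                 dimnames = list(paste0("g", 1:100),
                                 c("s1", "s2", "s3", "s4", "s5", "s6")))
  expr[, "s2"] <- expr[, "s1"]  # duplicated sample
  cl <- sample_correlation_clustering(expr, top_frac = 1.0)
  expect_equal(cl$correlation["s1", "s2"], 1.0)
  pos <- match(c("s1", "s2"), cl$order)
  expect_equal(abs(diff(pos)), 1L)
  expect_length(cl$genes_used, 100)
  # top_frac selects ceil(frac * n) genes, high variance first
  cl2 <- sample_correlation_clustering(expr, top_frac = 0.05,
                                       min_genes = 1L)
  expect_length(cl2$genes_used, 5)
  expr[, "s3"] <- 5
  expect_error(sample_correlation_clustering(expr), "s3")
})

test_that("stimulated TB/TM samples cluster apart from naive samples", {
  run <- get_small_run()
  expr <- read_expression(pipeline_files(run$dir)$expression)
  cl <- sample_correlation_clustering(expr, top_frac = 0.2)
  ord <- cl$order
  stim <- grep("^(TB|TM)_stim", ord)
  expect_equal(max(diff(sort(stim))), 1)  # contiguous block
})
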