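## End-to-end orchestration. Stages communicate only through files in
## the output directory, so each stage is independently re-runnable:
##   simulate -> quantify -> classify -> footprint -> scan-motifs ->
##   coassoc -> diff-footprint -> distances -> expression -> report

#' @rdname run_pipeline
#' @export
pipeline_files <- function(out_dir) {
  f <- function(...) file.path(out_dir, paste0(...))
  list(genome = f("genome.fa"), genes = f("genes.bed"),
       truth = f("truth.json"), sim_config = f("sim_config.json"),
       analysis_config = f("analysis_config.json"),
       expression = f("expression.tsv"),
       cuts = function(cond, strand) f("cuts_", cond, "_", strand,
                                       ".bedGraph"),
       peaks = function(cond) f("peaks_", cond, ".tsv"),
       union_peaks = f("union_peaks.tsv"),
       footprints = f("footprints.bed"),
       diff_footprints = f("diff_footprints.tsv"),
       motif_hits = f("motif_hits.tsv"),
       motif_table = f("motif_table.tsv"),
       motif_totals = f("motif_totals.tsv"),
       composites = f("composites.tsv"),
       coassociation = f("coassociation.tsv"),
       gene_classes = f("gene_classes.tsv"),
       enrichment = f("enrichment.json"),
       distance_bins = f("distance_bins.tsv"),
       correlation = f("correlation.tsv"),
       report = f("report.json"))
}

## Peak tables are stored as TSV with 0-based half-open coordinates
## (like BED); summits are stored 0-based as well.
write_peaks_tsv <- function(peaks, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks))
  mc <- as.data.frame(S4Vectors::mcols(peaks))
  if ("summit" %in% names(mc)) mc$summit <- mc$summit - 1L
  dt <- cbind(dt, data.table::as.data.table(mc))
  data.table::fwrite(dt, path, sep = "\t", na = ".", quote = FALSE,
                     scipen = 50)
  invisible(path)
}

read_peaks_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = ".",
                          colClasses = list(character = "chrom"))
  gr <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
  mc <- as.data.frame(dt[, -(1:3)])
  if ("summit" %in% names(mc)) mc$summit <- mc$summit + 1L
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  gr
}

write_truth_json <- function(truth, path) {
  gr_df <- function(gr) {
    d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
    cbind(d, as.data.frame(S4Vectors::mcols(gr)))
  }
  dhs <- gr_df(truth$dhs)
  dhs$summit <- dhs$summit - 1L
  obj <- list(dhs = dhs,
              footprints = gr_df(truth$footprints),
              motif_placements = gr_df(truth$motif_placements),
              inducible_genes = truth$inducible_genes,
              gene_effects = as.list(truth$gene_effects))
  write_json_file(obj, path)
}

read_truth_json <- function(path) {
  obj <- read_json_file(path)
  df_gr <- function(d) {
    if (length(d) == 0 || nrow(d) == 0) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start + 1L, d$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      d[, setdiff(names(d), c("chrom", "start", "end")), drop = FALSE])
    gr
  }
  dhs <- df_gr(obj$dhs)
  if (length(dhs)) S4Vectors::mcols(dhs)$summit <-
    S4Vectors::mcols(dhs)$summit + 1L
  structure(list(dhs = dhs,
                 footprints = df_gr(obj$footprints),
                 motif_placements = df_gr(obj$motif_placements),
                 inducible_genes = unlist(obj$inducible_genes),
                 gene_effects = unlist(obj$gene_effects)),
            class = "synthetic_truth")
}

read_chrom_lengths <- function(out_dir) {
  seqs <- read_genome_fasta(pipeline_files(out_dir)$genome)
  stats::setNames(nchar(seqs), names(seqs))
}

load_profiles <- function(out_dir, condition, chrom_lengths = NULL) {
  p <- pipeline_files(out_dir)
  if (is.null(chrom_lengths)) chrom_lengths <- read_chrom_lengths(out_dir)
  read_cut_bedgraphs(p$cuts(condition, "plus"), p$cuts(condition, "minus"),
                     chrom_lengths, condition = condition)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from and writes its outputs to
#' `out_dir`; see [run_pipeline()] for the stage order and the file
#' inventory in [pipeline_files()].
#'
#' @param out_dir Pipeline directory.
#' @param sim_cfg A [sim_config()].
#' @param an_cfg An [analysis_config()].
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(out_dir, sim_cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- pipeline_files(out_dir)
  genome <- generate_genome(sim_cfg)
  planted <- plant_landscape(genome, sim_cfg)
  genome <- planted$genome
  truth <- planted$truth
  write_genome_fasta(genome$seqs, p$genome)
  write_genes_bed(genome$layout$genes, p$genes)
  write_truth_json(truth, p$truth)
  cfg_echo <- sim_cfg
  class(cfg_echo) <- NULL
  write_json_file(cfg_echo, p$sim_config)
  for (cond in conditions()) {
    prof <- simulate_cuts(truth, genome, cond, sim_cfg)
    write_cut_bedgraphs(prof, p$cuts(cond, "plus"), p$cuts(cond, "minus"))
  }
  expr <- simulate_expression(truth, genome, sim_cfg)
  write_expression(expr, p$expression)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  chrom_lengths <- read_chrom_lengths(out_dir)
  profs <- stats::setNames(
    lapply(conditions(), load_profiles, out_dir = out_dir,
           chrom_lengths = chrom_lengths), conditions())
  per_cond <- lapply(profs, call_peaks, cfg = an_cfg)
  for (cond in conditions()) write_peaks_tsv(per_cond[[cond]],
                                             p$peaks(cond))
  union <- union_peaks(per_cond)
  union <- quantify_peaks(union, profs, an_cfg)
  union <- fold_change(union, "TM", "TN", an_cfg$pseudocount)
  union <- fold_change(union, "TB", "TN", an_cfg$pseudocount)
  union <- fold_change(union, "TB_stim", "TB", an_cfg$pseudocount)
  union <- fold_change(union, "TB", "TB_stim", an_cfg$pseudocount)
  union <- fold_change(union, "TM_stim", "TM", an_cfg$pseudocount)
  write_peaks_tsv(union, p$union_peaks)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  cond_peaks <- stats::setNames(
    lapply(c("TN", "TB", "TM"), function(cond)
      read_peaks_tsv(p$peaks(cond))), c("TN", "TB", "TM"))
  union <- flag_primed(union, cond_peaks$TB, an_cfg)
  union <- flag_inducible(union, an_cfg)
  union <- flag_diminished(union, an_cfg)
  union <- select_invariant(union, cond_peaks, cfg = an_cfg)
  write_peaks_tsv(union, p$union_peaks)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_footprint <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  primed <- union[S4Vectors::mcols(union)$primed]
  if (length(primed)) {
    S4Vectors::mcols(primed)$dhs_id <- S4Vectors::mcols(primed)$peak_id
  }
  prof_tb <- load_profiles(out_dir, "TB")
  fps <- call_footprints(prof_tb, primed, an_cfg)
  gr <- fps
  if (length(gr)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = S4Vectors::mcols(fps)$dhs_id,
      score = pmin(pmax(round(-10 * S4Vectors::mcols(fps)$score), 0), 1000))
  }
  write_bed_intervals(gr, p$footprints)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_scan_motifs <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  seqs <- read_genome_fasta(p$genome)
  lib <- build_motif_library(hit_threshold = an_cfg$hit_threshold)
  names(union) <- S4Vectors::mcols(union)$peak_id
  hits <- scan_motifs(union, lib, genome = seqs)
  data.table::fwrite(hits, p$motif_hits, sep = "\t", quote = FALSE)
  mc <- S4Vectors::mcols(union)
  sets <- list(primed = mc$peak_id[mc$primed],
               idhs_stringent = mc$peak_id[mc$idhs_stringent],
               invariant = mc$peak_id[mc$invariant])
  tab <- motif_table(hits, sets, lib)
  data.table::fwrite(tab$table, p$motif_table, sep = "\t", quote = FALSE)
  data.table::fwrite(tab$totals, p$motif_totals, sep = "\t", quote = FALSE)
  comp <- composite_elements(hits, sets, library = lib)
  data.table::fwrite(comp, p$composites, sep = "\t", quote = FALSE)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_coassoc <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  hits <- as.data.frame(data.table::fread(p$motif_hits, sep = "\t"))
  mc <- S4Vectors::mcols(union)
  targets <- mc$peak_id[mc$primed]
  universe <- setdiff(mc$peak_id, targets)
  co <- coassociation(hits, targets, universe, an_cfg)
  z <- co$Z[co$order, co$order]
  dt <- data.table::data.table(motif = rownames(z))
  dt <- cbind(dt, data.table::as.data.table(z))
  data.table::fwrite(dt, p$coassociation, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(out_dir)
}

#' @rdname pipeline_stages
#' @export
stage_diff_footprint <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  hits <- as.data.frame(data.table::fread(p$motif_hits, sep = "\t"))
  mc <- S4Vectors::mcols(union)
  in_sets <- mc$peak_id[mc$primed | mc$idhs_stringent]
  ap1 <- hits[hits$motif == "AP-1" & hits$region_id %in% in_sets, ,
              drop = FALSE]
  ap1 <- ap1[!duplicated(ap1[, c("chrom", "center")]), , drop = FALSE]
  sites <- GenomicRanges::GRanges(
    ap1$chrom, IRanges::IRanges(round(ap1$center), width = 1L))
  prof_a <- load_profiles(out_dir, "TB")
  prof_b <- load_profiles(out_dir, "TB_stim")
  res <- differential_footprints(prof_a, prof_b, sites, an_cfg)
  tab <- res$table
  attr_row <- data.frame(chrom = "#p_value", center = NA,
                         score_a = NA, score_b = NA, delta = res$p_value)
  data.table::fwrite(rbind(tab, attr_row), p$diff_footprints, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(res)
}

#' @rdname pipeline_stages
#' @export
stage_distances <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  genes <- read_genes_bed(p$genes)
  expr <- read_expression(p$expression)
  cls <- classify_tm_genes(expr, an_cfg)
  gene_tab <- data.frame(gene_id = rownames(cls$log2fc), cls$log2fc,
                         tm_specific = rownames(cls$log2fc) %in%
                           cls$tm_specific)
  data.table::fwrite(gene_tab, p$gene_classes, sep = "\t", quote = FALSE)
  mc <- S4Vectors::mcols(union)
  primed <- union[mc$primed]
  idhs <- union[mc$idhs_inclusive]
  invariant_pool <- union[mc$invariant]
  tm_genes <- genes[S4Vectors::mcols(genes)$gene_id %in% cls$tm_specific]
  chrom_lengths <- read_chrom_lengths(out_dir)
  enr <- list()
  for (kind in c("random_coordinates", "random_constitutive_dhs",
                 "random_idhs")) {
    pool <- switch(kind, random_coordinates = NULL,
                   random_constitutive_dhs = invariant_pool,
                   random_idhs = idhs)
    r <- proximity_enrichment(primed, tm_genes, an_cfg$near_tss,
                              null_kind = kind, null_pool = pool,
                              chrom_lengths = chrom_lengths, cfg = an_cfg)
    enr[[kind]] <- unclass(r)
  }
  write_json_file(enr, p$enrichment)
  fc_tm <- stats::setNames(cls$log2fc$TM, rownames(cls$log2fc))
  bins <- distance_by_induction(fc_tm[cls$tm_specific], genes,
                                union[mc$idhs_stringent])
  data.table::fwrite(bins, p$distance_bins, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(enr)
}

#' @rdname pipeline_stages
#' @export
stage_expression <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  expr <- read_expression(p$expression)
  cl <- sample_correlation_clustering(expr)
  dt <- data.table::data.table(sample = rownames(cl$correlation))
  dt <- cbind(dt, data.table::as.data.table(cl$correlation))
  data.table::fwrite(dt, p$correlation, sep = "\t", quote = FALSE)
  invisible(cl)
}

## Truth-aware recovery metrics: recall and precision of a flag against
## the planted DHS class, by >= 1 bp interval overlap.
flag_recovery <- function(union, truth, flag, truth_class) {
  flagged <- union[S4Vectors::mcols(union)[[flag]]]
  planted <- truth$dhs[S4Vectors::mcols(truth$dhs)$class == truth_class]
  list(recall = overlap_fraction(planted, flagged),
       precision = overlap_fraction(flagged, planted),
       n_flagged = length(flagged), n_planted = length(planted))
}

#' @rdname pipeline_stages
#' @export
stage_report <- function(out_dir, an_cfg = analysis_config()) {
  p <- pipeline_files(out_dir)
  union <- read_peaks_tsv(p$union_peaks)
  genes <- read_genes_bed(p$genes)
  mc <- S4Vectors::mcols(union)
  counts <- list(union_peaks = length(union),
                 primed = sum(mc$primed),
                 idhs_inclusive = sum(mc$idhs_inclusive),
                 idhs_stringent = sum(mc$idhs_stringent),
                 diminished = sum(mc$diminished),
                 invariant = sum(mc$invariant))
  gd <- genomic_distribution(union[mc$primed], genes,
                             an_cfg$promoter_window)
  totals <- as.data.frame(data.table::fread(p$motif_totals, sep = "\t"))
  comp <- as.data.frame(data.table::fread(p$composites, sep = "\t"))
  co <- as.data.frame(data.table::fread(p$coassociation, sep = "\t",
                                        na.strings = "NA"))
  zvals <- unlist(co[, -1])
  dfp <- as.data.frame(data.table::fread(p$diff_footprints, sep = "\t",
                                         na.strings = "NA"))
  dfp_p <- dfp$delta[dfp$chrom == "#p_value"]
  enr <- read_json_file(p$enrichment)
  fp_bed <- read_bed_intervals(p$footprints)
  report <- list(
    schema_version = "1.0",
    analysis_config = unclass(an_cfg),
    class_counts = counts,
    primed_genomic_distribution = as.list(gd$proportions),
    motif_ratio = stats::setNames(as.list(totals$ratio), totals$set),
    composite_fractions = stats::setNames(
      as.list(comp$fraction), paste(comp$set, comp$pair, sep = ":")),
    coassociation_z_extremes = list(max = max(zvals, na.rm = TRUE),
                                    min = min(zvals, na.rm = TRUE)),
    n_footprints_primed_tb = length(fp_bed),
    diff_footprint_p = dfp_p,
    enrichment = enr)
  if (file.exists(p$truth)) {
    truth <- read_truth_json(p$truth)
    gene_tab <- as.data.frame(data.table::fread(p$gene_classes,
                                                sep = "\t"))
    tm_called <- gene_tab$gene_id[gene_tab$tm_specific]
    report$truth_comparison <- list(
      primed = flag_recovery(union, truth, "primed", "primed"),
      idhs_stringent = flag_recovery(union, truth, "idhs_stringent",
                                     "inducible"),
      diminished = flag_recovery(union, truth, "diminished",
                                 "diminished"),
      tm_genes = list(
        recall = mean(truth$inducible_genes %in% tm_called),
        precision = if (length(tm_called))
          mean(tm_called %in% truth$inducible_genes) else NA,
        n_called = length(tm_called),
        n_planted = length(truth$inducible_genes)))
  }
  write_json_file(report, p$report)
  invisible(report)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when `sim_cfg` is given), quantify, classify,
#' footprint, scan-motifs, coassoc, diff-footprint, distances,
#' expression and report, in order, in `out_dir`. A stage failure
#' aborts with the stage name and cause. With a fixed seed the report
#' is byte-identical across reruns.
#'
#' @param out_dir Output directory (created if needed). When `sim_cfg`
#'   is `NULL` the directory must already contain the input files
#'   (genome.fa, genes.bed, cut bedGraphs, expression.tsv); a planted
#'   truth is optional.
#' @param sim_cfg A [sim_config()], or `NULL` to analyse existing data.
#' @param an_cfg An [analysis_config()].
#' @return The report, invisibly.
#' @export
run_pipeline <- function(out_dir, sim_cfg = NULL,
                         an_cfg = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  if (!is.null(sim_cfg))
    stages$simulate <- function() stage_simulate(out_dir, sim_cfg)
  stages <- c(stages, list(
    quantify = function() stage_quantify(out_dir, an_cfg),
    classify = function() stage_classify(out_dir, an_cfg),
    footprint = function() stage_footprint(out_dir, an_cfg),
    `scan-motifs` = function() stage_scan_motifs(out_dir, an_cfg),
    coassoc = function() stage_coassoc(out_dir, an_cfg),
    `diff-footprint` = function() stage_diff_footprint(out_dir, an_cfg),
    distances = function() stage_distances(out_dir, an_cfg),
    expression = function() stage_expression(out_dir, an_cfg)))
  cfg_echo <- an_cfg
  class(cfg_echo) <- NULL
  write_json_file(cfg_echo, pipeline_files(out_dir)$analysis_config)
  for (name in names(stages)) {
    tryCatch(stages[[name]](),
             error = function(e)
               stop("stage '", name, "' failed: ", conditionMessage(e),
                    call. = FALSE))
  }
  tryCatch(stage_report(out_dir, an_cfg),
           error = function(e)
             stop("stage 'report' failed: ", conditionMessage(e),
                  call. = FALSE))
}
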