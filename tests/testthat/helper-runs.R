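# Shared synthetic runs, computed once per session and reused across
# test files.

.run_cache <- new.env(parent = emptyenv())

small_sim_cfg <- function(seed = 7L) {
  sim_config(seed = seed,
             chrom_lengths = c(chrA = 6e5, chrB = 6e5),
             n_genes = 60L,
             n_dhs = c(primed = 12L, inducible = 12L,
                       diminished = 4L, invariant = 20L),
             depth_per_condition = 1.2e6,
             linked_fraction = 0.5)
}

small_an_cfg <- function(seed = 7L) {
  analysis_config(n_background_regions = 30L, n_null_draws = 199L,
                  n_boot = 50L, seed = seed)
}

# Small end-to-end pipeline run (1.2 Mb genome, 1.2M cuts/condition).
get_small_run <- function() {
  if (is.null(.run_cache$small)) {
    dir <- file.path(tempdir(), "primedhs-small-run")
    run_pipeline(dir, small_sim_cfg(), small_an_cfg())
    .run_cache$small <- list(dir = dir, sim_cfg = small_sim_cfg(),
                             an_cfg = small_an_cfg())
  }
  .run_cache$small
}

default_sim_cfg <- function() sim_config(seed = 1L)

default_an_cfg <- function() {
  analysis_config(n_background_regions = 300L, n_null_draws = 999L,
                  seed = 1L)
}

# The reference simulation: 10 Mb genome, 600 planted DHSs
# (150/150/50/250), fold parameters 8/20/0.15/1, 10M cuts per condition.
get_default_run <- function() {
  if (is.null(.run_cache$default)) {
    dir <- file.path(tempdir(), "primedhs-default-run")
    run_pipeline(dir, default_sim_cfg(), default_an_cfg())
    .run_cache$default <- list(dir = dir, sim_cfg = default_sim_cfg(),
                               an_cfg = default_an_cfg())
  }
  .run_cache$default
}

read_run_report <- function(run) {
  jsonlite::read_json(pipeline_files(run$dir)$report,
                      simplifyVector = TRUE)
}

read_run_union <- function(run) {
  primedhs:::read_peaks_tsv(pipeline_files(run$dir)$union_peaks)
}

read_run_truth <- function(run) {
  primedhs:::read_truth_json(pipeline_files(run$dir)$truth)
}

# A tiny flat cut-profile builder for unit tests.
flat_profiles <- function(len = 1000L, plus = 0L, minus = 0L,
                          chrom = "chr1", library_total = NULL) {
  p <- list()
  p[[chrom]] <- list(plus = rep(as.integer(plus), len),
                     minus = rep(as.integer(minus), len))
  total <- sum(as.numeric(p[[chrom]]$plus)) +
    sum(as.numeric(p[[chrom]]$minus))
  structure(list(chroms = p,
                 library_total = if (is.null(library_total)) max(total, 1)
                 else library_total,
                 condition = NA),
            class = "cut_profiles")
}

# Independent brute-force oracle for the per-strand binomial lower tail,
# via log-space summation of the probability mass function.
log10_binom_tail_oracle <- function(k, n, p0) {
  if (n == 0) return(0)
  i <- 0:k
  lt <- lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
    i * log(p0) + (n - i) * log1p(-p0)
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

footprint_score_oracle <- function(prof, center, fp_len, flank_len) {
  s <- center - floor(fp_len / 2)
  e <- s + fp_len - 1L
  p0 <- fp_len / (fp_len + flank_len)
  log10_binom_tail_oracle(sum(prof$plus[s:e]),
                          sum(prof$plus[s:e]) +
                            sum(prof$plus[(s - flank_len):(s - 1)]), p0) +
    log10_binom_tail_oracle(sum(prof$minus[s:e]),
                            sum(prof$minus[s:e]) +
                              sum(prof$minus[(e + 1):(e + flank_len)]), p0)
}

# Fabricated hits at matched density in targets and universe.
null_coassoc_hits <- function(region_ids, motifs, seed, p_present = 0.3,
                              region_len = 500) {
  withr::with_seed(seed, {
    rows <- list()
    for (id in region_ids) for (m in motifs) {
      if (runif(1) < p_present) {
        rows[[length(rows) + 1]] <- data.frame(
          motif = m, region_id = id, chrom = NA, start = 1, end = 2,
          strand = "+", score = 1, center = runif(1, 1, region_len))
      }
    }
    do.call(rbind, rows)
  })
}
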