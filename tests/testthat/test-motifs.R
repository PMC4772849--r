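# Motif library, scanning, composition tables, composites, co-association.

test_that("the default library has 14 motifs with fixed class assignments", {
  lib <- build_motif_library()
  expect_length(lib, 14)
  classes <- vapply(lib, `[[`, character(1), "tf_class")
  expect_setequal(names(classes)[classes == "inducible"],
                  c("AP-1", "NFAT", "EGR", "NF-kB", "CREB/ATF"))
  expect_setequal(names(classes)[classes == "constitutive"],
                  c("ETS", "RUNX", "KLF", "GATA", "E-box"))
  # AP-1's maximal sequences realize the S degeneracy
  pwm <- lib[["AP-1"]]$pwm
  best <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  expect_true(best %in% c("TGACTCA", "TGAGTCA"))
  expect_error(build_motif_library(
    overrides = data.frame(name = "X", tf_class = "other", pos = 1,
                           A = 0.5, C = 0.5, G = 0.2, T = 0.2)),
    "sum to 1")
  expect_error(primedhs:::consensus_to_probs("ACGJ"), "IUPAC")
})

test_that("matrix overrides are used verbatim", {
  ov <- data.frame(name = "ETS", tf_class = "constitutive",
                   pos = 1:2, A = c(1, 0), C = c(0, 1),
                   G = c(0, 0), T = c(0, 0))
  lib <- build_motif_library(overrides = ov)
  expect_identical(ncol(lib$ETS$pwm), 2L)
  expect_identical(unname(lib$ETS$probs[, 1]), c(1, 0, 0, 0))
  expect_length(lib, 14)
})

test_that("scanning finds planted sites with strand symmetry", {
  lib <- build_motif_library()
  hits <- scan_motifs(c(s1 = "TTGACTCAT"), lib["AP-1"])
  # one planted AP-1 at 0-based offset 1; palindromic, so both strands
  expect_identical(sort(unique(hits$start)), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  # a non-palindromic motif: reverse complement flips the strand only
  fwd <- scan_motifs(c(s = "TTTACAGGAAGTTTT"), lib["ETS"])
  rc <- scan_motifs(c(s = "AAAACTTCCTGTAAA"), lib["ETS"])
  expect_identical(nrow(fwd), nrow(rc))
  expect_identical(fwd$score, rc$score)
  expect_false(any(fwd$strand == rc$strand))
  # all-A sequence has no RUNX hits
  expect_identical(nrow(scan_motifs(c(a = strrep("A", 200)), lib["RUNX"])),
                   0L)
})

test_that("scanning matches a brute-force position-by-position scorer", {
  lib <- build_motif_library()
  brute_scan <- function(seq_str, motif) {
    codes <- primedhs:::encode_dna(seq_str)
    L <- ncol(motif$pwm)
    thr <- motif$hit_threshold * motif$max_score
    out <- list()
    for (str in c("+", "-")) {
      cs <- if (str == "+") codes else primedhs:::revcomp_codes(codes)
      for (i in seq_len(length(cs) - L + 1)) {
        sc <- 0
        for (j in seq_len(L)) sc <- sc + motif$pwm[cs[i + j - 1], j]
        if (!is.na(sc) && sc >= thr) {
          st <- if (str == "+") i else length(codes) - i - L + 2L
          out[[length(out) + 1]] <- data.frame(start = st, strand = str,
                                               score = sc)
        }
      }
    }
    if (!length(out)) return(data.frame(start = integer(0),
                                        strand = character(0),
                                        score = numeric(0)))
    h <- do.call(rbind, out)
    keep <- logical(nrow(h))  # same-strand greedy collapse, best first
    for (str in unique(h$strand)) {
      idx <- which(h$strand == str)
      ord <- idx[order(-h$score[idx], h$start[idx])]
      taken <- integer(0)
      for (k in ord) {
        if (!any(abs(taken - h$start[k]) < L)) {
          keep[k] <- TRUE
          taken <- c(taken, h$start[k])
        }
      }
    }
    h <- h[keep, , drop = FALSE]
    h[order(h$start, h$strand), , drop = FALSE]
  }
  withr::local_seed(17)
  for (rep in 1:20) {
    seq_str <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                     collapse = "")
    for (m in c("AP-1", "E-box", "GATA", "NFAT")) {
      mine <- scan_motifs(stats::setNames(seq_str, "x"), lib[m])
      ref <- brute_scan(seq_str, lib[[m]])
      expect_identical(mine$start, ref$start)
      expect_identical(mine$strand, ref$strand)
      expect_equal(mine$score, ref$score)
    }
  }
})

test_that("motif tables count per-set content and class totals", {
  hits <- data.frame(
    motif = c("ETS", "ETS", "AP-1", "RUNX"),
    region_id = c("r1", "r1", "r1", "r2"),
    chrom = NA, start = 1:4, end = 2:5, strand = "+",
    score = 1, center = c(10, 40, 100, 20))
  lib <- build_motif_library()
  tab <- motif_table(hits, list(setA = c("r1", "r2")), lib)
  row <- tab$table[tab$table$motif == "ETS", ]
  expect_equal(row$frac_regions, 0.5)
  expect_equal(row$mean_hits, 1.0)
  expect_equal(tab$totals$constitutive_total, 3)
  expect_equal(tab$totals$inducible_total, 1)
  expect_equal(tab$totals$ratio, 3)
  expect_warning(motif_table(hits, list(empty = character(0)), lib),
                 "empty")
})

test_that("composite elements respect the centre-gap boundary", {
  mk_hits <- function(gap) data.frame(
    motif = c("ETS", "RUNX"), region_id = "r1", chrom = NA,
    start = 1:2, end = 2:3, strand = "+", score = 1,
    center = c(100, 100 + gap))
  lib <- build_motif_library()
  sets <- list(s = "r1")
  expect_equal(composite_elements(mk_hits(10), sets, library = lib)$n_composite[1],
               1L)
  expect_equal(composite_elements(mk_hits(20), sets, library = lib)$n_composite[1],
               1L)
  expect_equal(composite_elements(mk_hits(25), sets, library = lib)$n_composite[1],
               0L)
  expect_error(composite_elements(mk_hits(10), sets,
                                  pair_specs = list(list(a = "NOPE", b = "ETS",
                                                         max_gap = 5)),
                                  library = lib),
               "unknown motif")
})

test_that("co-association Z matrices are symmetric and validated", {
  motifs <- c("ETS", "RUNX", "AP-1", "NFAT")
  ids <- paste0("r", 1:300)
  hits <- null_coassoc_hits(ids, motifs, seed = 5)
  cfg <- analysis_config(n_background_regions = 50L, n_boot = 50L, seed = 5)
  co <- coassociation(hits, ids[1:100], ids[101:300], cfg, motifs = motifs)
  expect_true(isSymmetric(co$Z) ||
                all(co$Z == t(co$Z), na.rm = TRUE))
  expect_true(all(is.na(diag(co$Z))))
  expect_setequal(co$order, motifs)
  expect_error(coassociation(hits, ids[1:100], ids[101:120], cfg),
               "too small")
})

test_that("planted pairs in targets produce a strong ETS/RUNX Z-score", {
  motifs <- c("ETS", "RUNX", "AP-1", "NFAT")
  ids <- paste0("r", 1:400)
  hits <- null_coassoc_hits(ids, motifs, seed = 8)
  # plant tight ETS/RUNX pairs in every target region
  planted <- do.call(rbind, lapply(ids[1:100], function(id) data.frame(
    motif = c("ETS", "RUNX"), region_id = id, chrom = NA, start = 1,
    end = 2, strand = "+", score = 1, center = c(250, 262))))
  cfg <- analysis_config(n_background_regions = 60L, n_boot = 100L,
                         seed = 8)
  co <- coassociation(rbind(hits, planted), ids[1:100], ids[101:400],
                      cfg, motifs = motifs)
  expect_gte(co$Z["ETS", "RUNX"], 5)
})
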