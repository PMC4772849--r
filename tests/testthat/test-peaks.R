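# Peak calling, union, quantification, fold change, density maps.

# Profile with flat background plus rectangular elevated regions.
bumpy_profiles <- function(len, bg, bumps = list(), seed = 5L) {
  rate_p <- rep(bg / 2, len)
  for (b in bumps) rate_p[b$start:b$end] <- rate_p[b$start:b$end] + b$rate / 2
  withr::with_seed(seed, {
    p <- list(chr1 = list(plus = rpois(len, rate_p),
                          minus = rpois(len, rate_p)))
    total <- sum(p$chr1$plus) + sum(p$chr1$minus)
    structure(list(chroms = p, library_total = total, condition = NA),
              class = "cut_profiles")
  })
}

test_that("a background-only profile yields no peaks", {
  prof <- bumpy_profiles(1e6, bg = 1.0)
  expect_length(call_peaks(prof), 0)
  # an all-zero profile is an empty list, not an error
  zero <- flat_profiles(1e4, 0, 0, library_total = 1)
  expect_length(call_peaks(zero), 0)
})

test_that("a single open region yields exactly one containing peak", {
  prof <- bumpy_profiles(2e5, bg = 1.0,
                         bumps = list(list(start = 100001, end = 100500,
                                           rate = 8)))
  pk <- call_peaks(prof)
  expect_length(pk, 1)
  expect_lte(GenomicRanges::start(pk), 100001)
  expect_gte(GenomicRanges::end(pk), 100500)
  s <- S4Vectors::mcols(pk)$summit
  expect_gt(s, 100001); expect_lt(s, 100500)
})

test_that("peaks separated by less than the merge gap fuse", {
  prof <- bumpy_profiles(1e5, bg = 1.0,
                         bumps = list(list(start = 50001, end = 50300, rate = 8),
                                      list(start = 50401, end = 50700, rate = 8)))
  pk <- call_peaks(prof)
  expect_length(pk, 1)
})

test_that("tag quantification follows the cuts-per-10M definition and clips", {
  prof <- flat_profiles(2000, 0, 0, library_total = 1e7)
  prof$chroms$chr1$plus[801:1200] <- 0L
  # 300 cuts spread in the 400-bp window around the summit
  prof$chroms$chr1$plus[801:1100] <- 1L
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  S4Vectors::mcols(peaks)$summit <- 1000L
  expect_equal(peak_tags(peaks, prof, 400L), 300)
  prof$library_total <- 2e7
  expect_equal(peak_tags(peaks, prof, 400L), 150)
  # summit 100 bp from the chromosome start: window clipped to [0, 300)
  prof2 <- flat_profiles(2000, 1, 0, library_total = 1e7)
  peaks2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
  S4Vectors::mcols(peaks2)$summit <- 101L
  expect_equal(peak_tags(peaks2, prof2, 400L), 300)
  prof2$library_total <- 0
  expect_error(peak_tags(peaks2, prof2), "library_total")
})

test_that("tags are invariant to a global depth change", {
  prof <- bumpy_profiles(5e4, 1, list(list(start = 2e4, end = 2.05e4,
                                           rate = 10)))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e4, 2.05e4))
  S4Vectors::mcols(peaks)$summit <- 20250L
  t1 <- peak_tags(peaks, prof, 400L)
  prof3 <- prof
  prof3$chroms$chr1$plus <- prof$chroms$chr1$plus * 3L
  prof3$chroms$chr1$minus <- prof$chroms$chr1$minus * 3L
  prof3$library_total <- prof$library_total * 3
  expect_equal(peak_tags(peaks, prof3, 400L), t1)
})

test_that("fold changes use the pseudocount and order stably", {
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 101, 201), width = 50))
  S4Vectors::mcols(peaks)$summit <- c(25L, 125L, 225L)
  S4Vectors::mcols(peaks)$tags.TM <- c(29, 0, 109)
  S4Vectors::mcols(peaks)$tags.TN <- c(9, 0, 9)
  peaks <- fold_change(peaks, "TM", "TN", pseudocount = 1)
  expect_equal(S4Vectors::mcols(peaks)$fc.TM_vs_TN, c(3, 1, 11))
  expect_error(fold_change(peaks, "TM", "TB"), "tags.TB")
  ord <- order_by_fold_change(peaks, "TM_vs_TN")
  expect_identical(ord, c(2L, 1L, 3L))
  # ties break by genomic position
  S4Vectors::mcols(peaks)$tags.TM <- c(9, 9, 9)
  S4Vectors::mcols(peaks)$tags.TN <- c(9, 9, 9)
  peaks <- fold_change(peaks, "TM", "TN", pseudocount = 1)
  expect_identical(order_by_fold_change(peaks, "TM_vs_TN"), 1:3)
})

test_that("union peaks merge on >= 1 bp overlap and keep the best summit", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 300), c(100, 400)))
  S4Vectors::mcols(a)$summit <- c(50L, 350L)
  S4Vectors::mcols(a)$summit_signal <- c(5, 7)
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 250))
  S4Vectors::mcols(b)$summit <- 170L
  S4Vectors::mcols(b)$summit_signal <- 9
  u <- union_peaks(list(a, b))
  expect_length(u, 2)
  expect_identical(S4Vectors::mcols(u)$summit, c(170L, 350L))
  # identical lists reduce to the same list; disjoint lists concatenate
  expect_length(union_peaks(list(a, a)), 2)
  expect_length(union_peaks(list(a[1], a[2])), 2)
  # adjacent but non-overlapping intervals stay separate
  c1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  c2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  S4Vectors::mcols(c1)$summit <- 50L; S4Vectors::mcols(c1)$summit_signal <- 1
  S4Vectors::mcols(c2)$summit <- 150L; S4Vectors::mcols(c2)$summit_signal <- 1
  expect_length(union_peaks(list(c1, c2)), 2)
  # overlap chains merge into one
  c3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 150))
  S4Vectors::mcols(c3)$summit <- 100L; S4Vectors::mcols(c3)$summit_signal <- 2
  expect_length(union_peaks(list(c1, c2, c3)), 1)
})

test_that("density maps are summit-centered and validated", {
  prof <- flat_profiles(4000, 1, 1, library_total = 1e7)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1900, 2100))
  S4Vectors::mcols(peaks)$summit <- 2000L
  m <- density_map(peaks, prof, window = 2000L, bins = 100L)
  expect_identical(dim(m), c(1L, 100L))
  expect_true(all(m == m[1, 1]))  # flat profile, flat map
  expect_false(attr(m, "clipped"))
  expect_error(density_map(peaks, prof, window = 2000L, bins = 33L),
               "divisible")
  # empty peak set
  m0 <- density_map(GenomicRanges::GRanges(), prof)
  expect_identical(nrow(m0), 0L)
  # edge-clipped rows are flagged and zero-padded
  S4Vectors::mcols(peaks)$summit <- 100L
  mc <- density_map(peaks, prof, 2000L, 100L)
  expect_true(attr(mc, "clipped"))
  expect_equal(mc[1, 1], 0)
})

test_that("average profiles peak centrally over the planted summits", {
  # flat-topped DHSs of mixed widths: only the central bins are covered
  # by every region, so the average peaks on a central plateau
  half <- c(100, 200, 300)
  prof <- bumpy_profiles(1e5, 1,
                         lapply(seq_along(half), function(i)
                           list(start = i * 2.5e4 - half[i],
                                end = i * 2.5e4 + half[i], rate = 10)))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges((1:3) * 2.5e4 - half,
                                                   (1:3) * 2.5e4 + half))
  S4Vectors::mcols(peaks)$summit <- as.integer((1:3) * 2.5e4)
  ap <- average_profile(peaks, prof, 2000L, 100L)
  expect_true(which.max(ap) %in% 44:57)
  expect_gt(mean(ap[46:55]), 2 * mean(ap[c(1:20, 81:100)]))
})
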