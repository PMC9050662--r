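make_sam <- function(lines, ln = 60000) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:chr1\tLN:%d", ln), lines), path)
  path
}

test_that("read counting applies the MAPQ, duplicate and pair rules", {
  bins <- make_bins(data.frame(chrom = "chr1", length = 60000), 20000)
  sam <- make_sam(c(
    "r1\t0\tchr1\t100\t60\t50M\t*\t0\t0\t*\t*",     # bin 1
    "r2\t0\tchr1\t150\t29\t50M\t*\t0\t0\t*\t*",     # MAPQ 29: dropped
    "r3\t1024\tchr1\t200\t60\t50M\t*\t0\t0\t*\t*",  # duplicate: dropped
    "p1\t99\tchr1\t30100\t60\t50M\t=\t30200\t150\t*\t*",   # pair, same bin
    "p1\t147\tchr1\t30200\t60\t50M\t=\t30100\t-150\t*\t*", # counted once
    "q1\t99\tchr1\t19990\t60\t50M\t=\t20100\t160\t*\t*",   # pair straddling
    "q1\t147\tchr1\t20100\t60\t50M\t=\t19990\t-160\t*\t*"))# counted twice
  counts <- count_reads(sam, bins)
  expect_equal(counts, c(2, 2, 0))

  # MAPQ exactly at the threshold is kept
  sam30 <- make_sam("r\t0\tchr1\t100\t30\t50M\t*\t0\t0\t*\t*")
  expect_equal(count_reads(sam30, bins), c(1, 0, 0))

  other <- make_bins(data.frame(chrom = "chrZ", length = 60000), 20000,
                     include_sex = TRUE)
  expect_error(count_reads(sam30, other), "chr1")
})

test_that("coverage filtering is a clean partition at the threshold", {
  counts <- cbind(a = rep(1, 10), b = rep(2, 10))
  counts <- counts * c(19999.9, 10000)  # totals 199999, 200000
  fl <- filter_low_coverage(round(counts))
  expect_equal(colnames(fl$kept), "b")
  expect_equal(colnames(fl$discarded), "a")
  empty <- filter_low_coverage(matrix(0, 3, 0))
  expect_equal(ncol(empty$kept), 0)
  expect_equal(ncol(empty$discarded), 0)
})

test_that("count correction follows the mappability and GC-median rules", {
  bins <- flat_bins(chrom_len = 2e6)
  # mappability division
  bins$mappability <- 0.5
  r <- rep(7, nrow(bins))
  expect_equal(unique(correct_counts(r, bins, min_class_bins = 1)), 14)

  # equal GC: correction is the identity
  bins$mappability <- 1
  set.seed(1)
  r2 <- rpois(nrow(bins), 20)
  expect_equal(correct_counts(r2, bins, min_class_bins = 1), as.numeric(r2))

  # two GC classes, hand-evaluated: {gc .3, rm 10} and {gc .6, rm 20}
  half <- nrow(bins) / 2
  bins$gc <- rep(c(0.3, 0.6), each = half)
  r3 <- rep(c(10, 20), each = half)
  corrected <- correct_counts(r3, bins, min_class_bins = 1)
  expect_equal(unique(corrected), 15)

  expect_error(correct_counts(rep(0, nrow(bins)), bins), "no signal")
})

test_that("corrections preserve zeros and are scale-equivariant", {
  bins <- flat_bins(chrom_len = 4e6)
  set.seed(2)
  bins$gc <- round(runif(nrow(bins), 0.3, 0.6), 2)
  bins$mappability <- runif(nrow(bins), 0.85, 1.2)
  r <- rpois(nrow(bins), 15)
  r[c(3, 50)] <- 0
  c1 <- correct_counts(r, bins)
  expect_equal(c1[c(3, 50)], c(0, 0))
  c5 <- correct_counts(r * 5, bins)
  expect_equal(c5, c1 * 5, tolerance = 1e-12)
})

test_that("DIMAPD matches the brute-force definition on toy vectors", {
  # two cells, counts constant within 500-kb windows
  bins <- flat_bins(chrom_len = 2e6)      # 100 bins, 4 windows of 500 kb
  win <- rep(1:4, each = 25)
  mk <- function(w) w[win]
  counts <- cbind(c1 = mk(c(100, 100, 100, 100)),
                  c2 = mk(c(100, 200, 100, 200)))
  out <- compute_dimapd(counts, bins)
  gs <- 2  # genome Mb
  o1 <- oracle_mapdc(c(100, 100, 100, 100) * 25, rep("chr1", 4), gs)
  o2 <- oracle_mapdc(c(100, 200, 100, 200) * 25, rep("chr1", 4), gs)
  expect_equal(out$mapd_c, c(o1$mapdc, o2$mapdc), tolerance = 1e-12)
  expect_equal(o1$mapdc, 0)  # constant windows: no bin-to-bin variation
  expect_equal(out$coverage_sqrt, c(o1$c, o2$c), tolerance = 1e-12)

  # identical cells share one DIMAPD value
  same <- cbind(a = mk(c(4, 8, 4, 8)), b = mk(c(4, 8, 4, 8)))
  ds <- compute_dimapd(same, bins)
  expect_equal(ds$dimapd[1], ds$dimapd[2])

  expect_error(compute_dimapd(counts[, 1, drop = FALSE], bins), "manual")
})

test_that("a replicating cell has strictly higher DIMAPD than a quiet one", {
  m <- synth_model(seed = 31, clone_fractions = 1)
  bins <- m$bins
  set.seed(5)
  lam <- 6 * bins$mappability
  quiet <- rpois(nrow(bins), 2 * lam)
  mosaic <- rpois(nrow(bins), 2 * lam *
                    (1 + (runif(nrow(bins) / 10)[rep(seq_len(nrow(bins) / 10),
                                                     each = 10)] < 0.5)))
  d <- compute_dimapd(cbind(g = quiet, s = mosaic), bins)
  expect_gt(d$dimapd[2], d$dimapd[1])
})

test_that("copy-number quantisation solves the printed examples", {
  seg1 <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6,
                         n_bins = 50, mean_count = 100, size = 1e6)
  e1 <- estimate_cn(seg1)
  expect_equal(e1$segments$cn, 1)
  expect_lt(min(e1$chi_curve$chi), 1e-3)

  seg3 <- tibble::tibble(chrom = "chr1", start = c(0, 1, 2) * 1e6,
                         end = c(1, 2, 3) * 1e6, n_bins = 50,
                         mean_count = c(100, 200, 200), size = 1e6)
  e3 <- estimate_cn(seg3)
  expect_equal(e3$x_min, 100, tolerance = 1e-3)
  expect_equal(e3$segments$cn, c(1, 2, 2))
  expect_equal(e3$ploidy, 5 / 3, tolerance = 1e-9)
})

test_that("chi is non-negative and vanishes only on integer ratios", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, n_bins = 10,
                        mean_count = c(60, 90, 120), size = c(1, 2, 1) * 1e6)
  chi <- function(x) sqrt(sum(seg$size / 1e6 * sin(pi * seg$mean_count / x)^2))
  expect_equal(chi(30), 0, tolerance = 1e-12)   # 2, 3, 4 copies
  for (x in c(25, 40, 50, 80)) expect_gt(chi(x), 0)
})

test_that("an infeasible ploidy window raises an error with the curve", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, n_bins = 50,
                        mean_count = c(100, 105), size = 1e6)
  err <- tryCatch(estimate_cn(seg, ploidy_limits = c(5, 6)),
                  error = function(e) e)
  expect_match(conditionMessage(err), "feasible")
  expect_true(is.data.frame(err$chi_curve))
})

test_that("mean ploidy is the size-weighted copy-number mean", {
  seg <- tibble::tibble(size = c(1e6, 1e6), cn = c(2, 2))
  expect_equal(mean_ploidy(seg), 2)
  seg2 <- tibble::tibble(size = c(1e6, 3e6), cn = c(2, 4))
  expect_equal(mean_ploidy(seg2), 3.5)
  # 80 autosomes spread over 22 equal-size autosome types
  karyo <- tibble::tibble(size = rep(1e6, 22),
                          cn = c(rep(4, 14), rep(3, 8)))
  expect_equal(sum(karyo$cn), 80)
  expect_equal(round(mean_ploidy(karyo), 2), 3.64)
})

test_that("an aneuploid cell's ploidy is recovered within 2% at high coverage", {
  # karyotype with mean ploidy 80/22 = 3.64 at 425 reads per Mb
  set.seed(9)
  bins <- flat_bins(n_chrom = 4, chrom_len = 1e7)  # 40 Mb
  cn_levels <- rep(c(4, 3, 5, 2), each = nrow(bins) / 4)
  cn_levels[1:200] <- 1  # a sizeable deletion anchors the depth quantum
  ploidy_true <- mean(cn_levels)
  rpmb <- 425
  d <- rpmb / ploidy_true * 0.02
  counts <- rpois(nrow(bins), d * cn_levels)
  corrected <- correct_counts(counts, bins)
  segs <- segment_profile(corrected, bins)
  est <- estimate_cn(segs, ploidy_limits = c(1, 8))
  expect_lt(abs(est$ploidy - ploidy_true) / ploidy_true, 0.02)
  expect_true(est$reliable)
})

test_that("count matrices round-trip through the TSV writer", {
  bins <- flat_bins(chrom_len = 1e5)
  counts <- matrix(rpois(nrow(bins) * 3, 10), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(counts, bins, path)
  back <- read_count_matrix(path)
  expect_equal(unname(back$counts), unname(counts))
  expect_equal(back$coords$start, bins$start)
})
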