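test_that("binning tiles chromosomes exactly, with remainder bins", {
  b <- make_bins(data.frame(chrom = "chr1", length = 60000), 20000)
  expect_equal(b$start, c(0, 20000, 40000))
  expect_equal(b$end, c(20000, 40000, 60000))

  b2 <- make_bins(data.frame(chrom = "chr1", length = 50000), 20000)
  expect_equal(b2$end - b2$start, c(20000, 20000, 10000))

  # tiling conservation over random layouts
  set.seed(1)
  for (i in 1:5) {
    lens <- sample(30000:300000, 3)
    gi <- data.frame(chrom = paste0("chr", 1:3), length = lens)
    bb <- make_bins(gi, 20000)
    expect_equal(as.numeric(tapply(bb$end - bb$start, bb$chrom, sum))[
      order(unique(bb$chrom))], lens[order(gi$chrom)])
  }
})

test_that("sex chromosomes are excluded unless requested", {
  gi <- data.frame(chrom = c("chr1", "chrX"), length = c(40000, 40000))
  expect_false("chrX" %in% make_bins(gi, 20000)$chrom)
  expect_true("chrX" %in% make_bins(gi, 20000, include_sex = TRUE)$chrom)
  expect_error(make_bins(data.frame(chrom = character(0),
                                    length = numeric(0))),
               "empty")
  expect_error(make_bins(gi, 500), "1 kb")
})

test_that("GC content counts G+C over unambiguous bases only", {
  g <- Biostrings::DNAStringSet(c(
    chr1 = paste0(strrep("GC", 10000),           # gc = 1
                  strrep("AT", 10000),           # gc = 0
                  strrep("ACGTNN", 3334))))      # gc = 0.5 over ACGT
  bins <- make_bins(data.frame(chrom = "chr1", length = 60004), 20000)
  bins <- gc_content(bins, g)
  expect_equal(bins$gc[1:3], c(1, 0, 0.5), tolerance = 1e-6)

  # mostly-N bin is masked
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("N", 15000), strrep("ACGT", 1250), strrep("ACGT", 5000))))
  b2 <- gc_content(make_bins(data.frame(chrom = "chr1", length = 40000),
                             20000), g2)
  expect_true(is.na(b2$gc[1]))
  expect_equal(b2$gc[2], 0.5)

  short <- make_bins(data.frame(chrom = "chr1", length = 80000), 20000)
  expect_error(gc_content(short, g2), "beyond sequence end")
})

test_that("mappability is 1 on unique sequence and invariant to bin order", {
  tg <- make_toy_genome(seed = 3)
  pr <- read_params(read_length = 50, error_rate = 0)
  b <- compute_mappability(gc_content(tg$bins, tg$genome), tg$genome, pr,
                           seed = 1)
  expect_true(all(b$mappability == 1))
  expect_true(all(b$usable))

  shuf <- b[sample(nrow(b)), ]
  b_shuf <- compute_mappability(shuf, tg$genome, pr, seed = 1)
  merged <- merge(as.data.frame(b), as.data.frame(b_shuf),
                  by = c("chrom", "start"))
  expect_equal(merged$mappability.x, merged$mappability.y)
})

test_that("multi-mapper tie policies shape the mappability of repeats", {
  tg <- make_toy_genome(repeat_block = list(start = 20001, width = 20000),
                        seed = 4)
  pr <- read_params(read_length = 50, error_rate = 0)
  b0 <- gc_content(tg$bins, tg$genome)
  rep_rows <- which(b0$start == 20000)

  # uniform tie-breaking: copies re-collect their source counts on average
  br <- compute_mappability(b0, tg$genome, pr, seed = 1)
  expect_true(all(abs(br$mappability[rep_rows] - 1) < 0.15))

  # leftmost-hit: first copy becomes a repeat sink (M ~ 2, > 1.5 band),
  # second copy loses everything; both excluded
  bf <- compute_mappability(b0, tg$genome, pr,
                            aligner = function(r, g)
                              kmer_aligner(r, g, ties = "first"),
                            seed = 1)
  expect_equal(bf$mappability[rep_rows], c(2, 0))
  expect_false(any(bf$usable[rep_rows]))

  # unique-only mapping: repeats drop out entirely
  bd <- compute_mappability(b0, tg$genome, pr,
                            aligner = function(r, g)
                              kmer_aligner(r, g, ties = "drop"),
                            seed = 1)
  expect_equal(bd$mappability[rep_rows], c(0, 0))
})

test_that("substitution errors lower remapping uniformly but keep bins usable", {
  tg <- make_toy_genome(seed = 5)
  pr <- read_params(read_length = 100, error_rate = 0.001)
  b <- compute_mappability(gc_content(tg$bins, tg$genome), tg$genome, pr,
                           seed = 2)
  expect_true(all(b$mappability <= 1))
  expect_true(all(b$mappability > 0.8))
  expect_true(all(b$usable))
  expect_error(read_params(error_rate = 1), "error_rate")
  expect_error(read_params(layout = "paired-end"), "fragment_size")
})

test_that("blacklisted bins become unusable", {
  tg <- make_toy_genome(seed = 6)
  b <- compute_mappability(gc_content(tg$bins, tg$genome), tg$genome,
                           read_params(read_length = 50, error_rate = 0),
                           seed = 1)
  bl <- data.frame(chrom = "chr1", start = 25000, end = 26000)
  b2 <- apply_blacklist(b, bl)
  hit <- b2$chrom == "chr1" & b2$start == 20000
  expect_false(any(b2$usable[hit]))
  expect_true(all(b2$usable[!hit]))
})

test_that("bin tables round-trip through their TSV writer", {
  tg <- make_toy_genome(seed = 7)
  b <- gc_content(tg$bins, tg$genome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bins(b, path)
  b2 <- read_bins(path)
  expect_equal(as.data.frame(b2), as.data.frame(b)[, colnames(b2)],
               tolerance = 1e-12, ignore_attr = TRUE)
})
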