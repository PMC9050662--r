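test_that("automatic phase calling isolates DIMAPD outliers", {
  set.seed(3)
  qc <- tibble::tibble(cell_id = sprintf("c%03d", 1:110),
                       dimapd = c(rnorm(100, 1, 0.01), rep(1.5, 10)))
  ph <- call_phase_auto(qc)
  expect_equal(ph$phase, c(rep("G1G2", 100), rep("S", 10)))

  flat <- tibble::tibble(cell_id = c("a", "b", "c"), dimapd = rep(1, 3))
  expect_warning(ph0 <- call_phase_auto(flat), "degenerate")
  expect_true(all(ph0$phase == "G1G2"))
})

test_that("phase calling is stable under cell order and majority duplication", {
  set.seed(4)
  qc <- tibble::tibble(cell_id = sprintf("c%03d", 1:120),
                       dimapd = c(rnorm(100, 1, 0.05), rnorm(20, 1.6, 0.05)))
  ph1 <- call_phase_auto(qc)
  perm <- sample(nrow(qc))
  ph2 <- call_phase_auto(qc[perm, ])
  expect_equal(ph2$phase[match(qc$cell_id, ph2$cell_id)], ph1$phase)

  dup <- dplyr::bind_rows(qc, dplyr::mutate(qc[1:100, ],
                                            cell_id = paste0(cell_id, "_d")))
  ph3 <- call_phase_auto(dup)
  expect_lt(abs(ph3$dimapd_threshold[1] - ph1$dimapd_threshold[1]) /
              ph1$dimapd_threshold[1], 0.01)
})

test_that("manual thresholds and unknown gates behave literally", {
  qc <- tibble::tibble(cell_id = letters[1:6], dimapd = seq(1, 2, by = 0.2),
                       ploidy = rep(2, 6))
  expect_true(all(call_phase_manual(qc, 3)$phase == "G1G2"))
  expect_true(all(call_phase_manual(qc, 0.5)$phase == "S"))
  gated <- call_phase_manual(qc, 1.5,
                             unknown_gate = list(dimapd = c(1.2, 1.6)))
  expect_equal(sum(gated$phase == "unknown"), 3)
})

test_that("metadata phases override and unmatched cells are reported", {
  qc <- tibble::tibble(cell_id = c("a", "b", "c"), dimapd = 1:3)
  md <- data.frame(cell_id = c("a", "b", "c"),
                   phase = c("G1", "S", "G2"))
  ph <- apply_phase_metadata(qc, md)
  expect_equal(ph$phase, c("G1G2", "S", "G1G2"))
  expect_length(attr(ph, "unmatched"), 0)

  ph2 <- apply_phase_metadata(qc, md[1:2, ])
  expect_equal(attr(ph2, "unmatched"), "c")
  expect_equal(ph2$phase[3], "unknown")

  bad <- rbind(md, data.frame(cell_id = "a", phase = "S"))
  expect_error(apply_phase_metadata(qc, bad), "conflicting")
})

test_that("the halved S branch is rescaled back onto the S distribution", {
  set.seed(6)
  pg <- 2
  f <- runif(60, 0.1, 0.9)
  halved <- seq_along(f) %% 2 == 0
  measured <- (1 + f) * pg * ifelse(halved, 0.5, 1) * rnorm(60, 1, 0.005)
  qc <- tibble::tibble(
    cell_id = c(sprintf("g%02d", 1:40), sprintf("s%02d", 1:60)),
    ploidy = c(rnorm(40, pg, 0.01), measured),
    dimapd = c(rnorm(40, 1, 0.02), rnorm(60, 1.8, 0.1)))
  phases <- tibble::tibble(cell_id = qc$cell_id,
                           phase = rep(c("G1G2", "S"), c(40, 60)))
  corr <- correct_s_progression(qc, phases)
  expect_equal(corr$second_branch_shift, 2)
  expect_equal(corr$mode, "monomodal")
  s_cells <- corr$cells[corr$cells$phase == "S", ]
  expect_true(all(s_cells$ploidy >= corr$g1g2_ploidy * 0.99))
  expect_gte(cor(s_cells$replication_fraction, f, method = "spearman"),
             0.95)
})

test_that("S cells already above the G1/G2 ploidy are left untouched", {
  qc <- tibble::tibble(cell_id = c("g1", "g2", "s1", "s2"),
                       ploidy = c(2, 2, 2.5, 3.8),
                       dimapd = c(1, 1, 2, 2))
  phases <- tibble::tibble(cell_id = qc$cell_id,
                           phase = c("G1G2", "G1G2", "S", "S"))
  corr <- correct_s_progression(qc, phases)
  expect_equal(corr$cells$shift, rep(1, 4))
  # replication fractions span the definition range
  expect_equal(corr$cells$replication_fraction[3:4], c(0.25, 0.9))
  expect_error(correct_s_progression(qc,
    tibble::tibble(cell_id = qc$cell_id, phase = rep("S", 4))),
    "G1/G2")
})

test_that("manual shifts override the automatic branch correction", {
  qc <- tibble::tibble(cell_id = c("g", "s"), ploidy = c(2, 1.2),
                       dimapd = c(1, 2))
  phases <- tibble::tibble(cell_id = qc$cell_id, phase = c("G1G2", "S"))
  corr <- correct_s_progression(qc, phases, shift_second = 2.5)
  expect_equal(corr$mode, "manual")
  expect_equal(corr$cells$ploidy[2], 3)
})

test_that("coverage thresholds default to 160 RPMb per haploid genome", {
  thr <- coverage_threshold_by_downsampling()
  expect_equal(thr$rpmb_per_haploid, 160)
  expect_true(thr$default_used)
  # the printed per-haploid conversion
  expect_equal(per_haploid_coverage(425, 3.64), 117)
})

test_that("down-sampling clean cells accepts the lowest tested coverage", {
  set.seed(10)
  bins <- flat_bins(n_chrom = 3, chrom_len = 8e6)
  cn <- rep(c(2, 1, 3), each = nrow(bins) / 3)
  counts <- vapply(1:6, function(i) rpois(nrow(bins), 8 * cn),
                   numeric(nrow(bins)))
  colnames(counts) <- sprintf("hc%02d", 1:6)
  thr <- coverage_threshold_by_downsampling(counts, bins,
                                            target_rpmbs = c(150, 300),
                                            seed = 1,
                                            ploidy_limits = c(1, 6))
  expect_equal(thr$rpmb_per_haploid, 150)
  expect_false(thr$default_used)
  expect_equal(nrow(thr$curve), 2)
})
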