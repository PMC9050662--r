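test_that("embeddings are deterministic given a seed and separate clones", {
  skip_if_not_installed("uwot")
  skip_if_not_installed("cluster")
  set.seed(31)
  # two clones with a disjoint whole-chromosome copy-number difference
  base <- matrix(2, 40, 100)
  base[21:40, 81:100] <- 3
  noisy <- base + matrix(rnorm(4000, 0, 0.05), 40)
  rownames(noisy) <- sprintf("c%02d", 1:40)
  e1 <- embed_cells(noisy, method = "umap", input = "cnv", seed = 5)
  e2 <- embed_cells(noisy, method = "umap", input = "cnv", seed = 5)
  expect_equal(e1$x, e2$x)
  expect_equal(e1$y, e2$y)
  sil <- cluster::silhouette(rep(1:2, each = 20),
                             dist(cbind(e1$x, e1$y)))
  expect_gt(mean(sil[, 3]), 0.5)
  expect_error(embed_cells(noisy, method = "umap", input = "cnv"),
               "seed")
})

test_that("t-SNE consumes distance input deterministically", {
  skip_if_not_installed("Rtsne")
  set.seed(32)
  m <- rbind(matrix(0, 15, 60), matrix(1, 15, 60))
  m[cbind(sample(30, 30, TRUE), sample(60, 30, TRUE))] <- NA
  rownames(m) <- sprintf("s%02d", 1:30)
  d <- smc_distances(m)
  e1 <- embed_cells(d, method = "tsne", input = "rt-distance", seed = 9)
  e2 <- embed_cells(d, method = "tsne", input = "rt-distance", seed = 9)
  expect_equal(e1$x, e2$x)
  within <- mean(dist(cbind(e1$x, e1$y)[1:15, ]))
  across <- mean(as.matrix(dist(cbind(e1$x, e1$y)))[1:15, 16:30])
  expect_gt(across, within * 2)
})

test_that("gates label points with closed boundaries and partition gated area", {
  emb <- tibble::tibble(cell_id = letters[1:5],
                        x = c(0, 1, 2, 3, 1), y = c(0, 1, 2, 3, 0))
  all_gate <- list(g = list(xmin = -1, xmax = 4, ymin = -1, ymax = 4))
  expect_true(all(gate_subpopulations(emb, all_gate)$label == "g"))

  two <- list(lo = list(xmin = 0, xmax = 1, ymin = 0, ymax = 1),
              hi = list(xmin = 2, xmax = 3, ymin = 2, ymax = 3))
  lab <- gate_subpopulations(emb, two,
                             reference_of = c(lo = "g_lo", hi = "g_hi"))
  expect_equal(lab$label, c("lo", "lo", "hi", "hi", "lo"))
  expect_equal(lab$reference, c("g_lo", "g_lo", "g_hi", "g_hi", "g_lo"))

  # boundary vertex of a polygon is inside
  tri <- matrix(c(0, 0, 2, 0, 0, 2), ncol = 2, byrow = TRUE)
  lab2 <- gate_subpopulations(tibble::tibble(cell_id = "p", x = 0, y = 0),
                              list(t = tri))
  expect_equal(lab2$label, "t")
})

test_that("stage probabilities are per-bin fractions of gated cells", {
  scrt <- matrix(0, 40, 5)
  scrt[1:2, 3] <- 1
  pct <- rep(0.2, 40)
  sp <- stage_probability(scrt, pct, "early")
  expect_equal(sp$probability[3], 0.05)
  expect_equal(sp$n_cells, 40)
  expect_error(stage_probability(scrt, pct, "late"), "empty stage")
})

test_that("stage probabilities rise with S progression on synthetic data", {
  run <- default_run()
  rtm <- run$rt$rtm
  kept <- rtm$retained
  scrt <- rtm$scrt[kept, , drop = FALSE]
  pct <- rtm$rep_pct[kept]
  pe <- stage_probability(scrt, pct, "early")$probability
  pm <- stage_probability(scrt, pct, "mid")$probability
  pl <- stage_probability(scrt, pct, "late")$probability
  ok <- !is.na(pe) & !is.na(pm) & !is.na(pl)
  expect_gte(mean(pe[ok] <= pm[ok] + 1e-9), 0.95)
  expect_gte(mean(pm[ok] <= pl[ok] + 1e-9), 0.95)

  # early-stage probability tracks the population RT
  pb <- run$rt$pseudobulk$rt
  expect_gte(cor(pe, pb, method = "spearman", use = "complete"), 0.8)
})

test_that("the initiation landscape comes from early-S cells only", {
  scrt <- rbind(e1 = c(1, 0, 0), e2 = c(1, 1, 0), l1 = c(1, 1, 1))
  ip <- extract_ipls(scrt, c(0.2, 0.3, 0.9))
  expect_equal(ip, c(1, 0.5, 0))
  expect_error(extract_ipls(scrt, c(0.5, 0.6, 0.9)), "empty")
})

test_that("out-of-schedule events are counted with recurrence and runs", {
  rt <- c(rep(0.9, 3), rep(0.1, 3))       # 3 early bins, 3 late bins
  scrt <- rbind(c1 = c(1, 1, 1, 0, 0, 0),  # on schedule
                c2 = c(1, 1, 1, 1, 1, 0),  # late bins 4,5 fired early
                c3 = c(1, 1, 1, 1, 0, 0),  # late bin 4 fired early
                l1 = c(1, 1, 0, 1, 1, 1))  # early bin 3 missed, late cell
  pct <- c(0.1, 0.25, 0.3, 0.8)
  ev <- out_of_schedule(scrt, pct, rt)
  early <- ev$cells[ev$cells$stage == "early", ]
  expect_equal(unname(early$n_events), c(0, 2, 1))
  rec <- ev$recurrence$early
  expect_equal(rec$recurrence[rec$bin == 4], 2)   # seen in cells c2 and c3
  expect_equal(rec$recurrence[rec$bin == 5], 1)
  late <- ev$cells[ev$cells$stage == "late", ]
  expect_equal(unname(late$n_events), 1)
  expect_equal(sort(ev$run_lengths$early), c(1, 2))
  expect_equal(ev$early_rate, 3 / 9)
})

test_that("a deterministic programme yields events only at the noise floor", {
  m <- synth_model(seed = 41, ectopic_rate = 0, firing_noise = 0.02,
                   clone_fractions = 1, s_prob = 0.5)
  sim <- simulate_population(m, 60, seed = 42)
  cnv <- call_cnv(sim$counts, sim$bins, min_reads = 5e4,
                  ploidy_limits = c(1, 6))
  ph <- apply_phase_metadata(cnv$qc, sim$truth[, c("cell_id", "phase")])
  corr <- correct_s_progression(cnv$qc, ph)
  rt <- compute_rt(cnv, corr)
  ev <- out_of_schedule(rt$rtm$scrt, rt$rtm$rep_pct, rt$pseudobulk$rt)
  nf <- g1g2_noise_floor(rt$cn200_g, rt$cng[["all"]], rt$pseudobulk$rt)
  expect_lt(ev$early_rate, 0.01)
  expect_lt(nf$rate, 0.01)
})
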