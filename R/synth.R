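# Ground-truthed synthetic single-cell WGS count generator.
#
# The generator emulates the statistical structure the pipeline consumes:
# G1/G2 cells draw Poisson counts proportional to their clone's integer
# copy number with multiplicative GC and mappability bias; S cells double
# the rate on bins whose firing time (a bimodal early/late timing
# landscape plus per-(cell,bin) logistic jitter, with rare ectopic
# inversions) lies before the cell's replication fraction. Copy-number-1
# blocks are planted inside late-replicating domains so the per-copy depth
# quantum is identifiable for G1/G2 cells while S cells straddle the
# solver's percentile bound, reproducing the two-branch ploidy artefact
# that the staging step corrects.

#' Define a synthetic population model
#'
#' Defaults are the bundled study conditions: a 200-Mb genome (5
#' chromosomes x 40 Mb) in 20-kb bins; a replication-timing landscape of
#' alternating early/late domains (2-5 Mb) with extreme-heavy timing
#' levels; logistic firing jitter of scale 0.07 (a T-width of about
#' 1.5 h under a 10-h S phase, the scale observed in human cell lines);
#' 1% ectopic inversions; two clones (50/50) sharing a base
#' karyotype with three planted CN-1 blocks, the second clone carrying a
#' whole-chromosome gain; 30% S cells with replication fractions uniform
#' on [0.1, 0.9] (cells at the extreme edges of S phase are
#' indistinguishable from G1/G2 and are not modelled); coverage normal
#' around 300 reads per Mb per haploid genome.
#'
#' @param seed seed fixing the landscape, karyotype and bias tracks.
#' @param n_chroms,chrom_length,bin_size genome layout.
#' @param domain_mb range of replication-domain lengths (Mb).
#' @param early_level,late_level extreme firing times in [0, 1] (0 =
#'   earliest); with `level_shape = NULL` the landscape is binary with
#'   these two plateaus only.
#' @param level_shape Beta shape of the per-domain timing-level
#'   distribution across `[early_level, late_level]`; the default 0.3
#'   gives a strongly extreme-heavy (U-shaped) continuum, matching the
#'   bimodal genome-wide RT distributions of mammalian cells. NULL
#'   selects the binary two-plateau programme.
#' @param firing_noise logistic jitter scale of per-(cell,bin) firing
#'   times.
#' @param ectopic_rate probability a (cell, unit) replicates out of
#'   schedule: a late-domain unit fires at S entry, an early-domain unit
#'   fails to fire until S exit. The rate of late bins replicated in
#'   early-S cells therefore estimates this parameter directly.
#' @param clone_fractions mixture weights (must sum to 1).
#' @param gain_chrom chromosome gained (+1 copy) by the last clone; NA for
#'   identical clones.
#' @param s_prob fraction of cells in S phase.
#' @param s_fraction_range range of per-cell replication fractions.
#' @param rpmb_haploid_mean,rpmb_haploid_sd coverage distribution (reads
#'   per Mb per haploid genome).
#' @param gc_slope strength of the monotone (exponential) GC bias.
#' @param dispersion negative-binomial size; `Inf` (default) gives Poisson
#'   sampling.
#' @param firing_unit replicon-scale span (bp) sharing one firing
#'   decision per cell (default 200 kb).
#' @return object of class `scrt_synth_model` with `bins`, `rt_truth`,
#'   `clones` (list of per-bin integer CN vectors), `domains` and all
#'   parameters.
#' @export
synth_model <- function(seed = 20210813L, n_chroms = 5L,
                        chrom_length = 4e7, bin_size = 20000L,
                        domain_mb = c(2, 5),
                        early_level = 0.08, late_level = 0.92,
                        level_shape = 0.3,
                        firing_noise = 0.07, ectopic_rate = 0.01,
                        clone_fractions = c(0.5, 0.5), gain_chrom = 5L,
                        s_prob = 0.3, s_fraction_range = c(0.1, 0.9),
                        rpmb_haploid_mean = 300, rpmb_haploid_sd = 40,
                        gc_slope = 0.6, dispersion = Inf,
                        firing_unit = 200000L) {
  set.seed(seed)
  gi <- data.frame(chrom = paste0("chr", seq_len(n_chroms)),
                   length = rep(chrom_length, n_chroms))
  bins <- make_bins(gi, bin_size = bin_size)
  nb <- nrow(bins)
  bpm <- 1e6 / bin_size   # bins per Mb
  # replication-domain layout: alternating early/late plateaus, smoothed
  rt <- numeric(nb)
  domains <- list()
  for (chr in gi$chrom) {
    idx <- which(bins$chrom == chr)
    pos <- 0L
    type <- sample(c("early", "late"), 1L)
    while (pos < length(idx)) {
      len <- round(stats::runif(1, domain_mb[1L], domain_mb[2L]) * bpm)
      sel <- idx[(pos + 1L):min(pos + len, length(idx))]
      level <- if (is.null(level_shape)) {
        # binary timing programme: two plateaus only
        if (type == "early") early_level else late_level
      } else {
        # U-shaped continuum: extreme-heavy, like genome-wide RT
        # distributions, but with mass at intermediate timings
        lo <- min(early_level, 1 - late_level)
        lo + (1 - 2 * lo) * stats::rbeta(1, level_shape, level_shape)
      }
      level <- pmin(pmax(level + stats::rnorm(1, 0, 0.02), 0.02), 0.98)
      rt[sel] <- level
      domains[[length(domains) + 1L]] <-
        tibble::tibble(chrom = chr, start = bins$start[sel[1L]],
                       end = bins$end[sel[length(sel)]],
                       level = level,
                       type = if (level > 0.5) "late" else "early")
      pos <- pos + len
      type <- if (type == "early") "late" else "early"
    }
  }
  domains <- dplyr::bind_rows(domains)
  rt <- as.numeric(stats::filter(rt, rep(1 / 11, 11), sides = 2))
  ok <- !is.na(rt)
  rt <- stats::approx(which(ok), rt[ok], xout = seq_len(nb), rule = 2)$y
  # GC track: smooth Mb-scale wave, and a mappability track with a few
  # unusable or repeat-inflated bins
  mid <- (bins$start + bins$end) / 2
  phase <- stats::runif(n_chroms, 0, 2 * pi)[match(bins$chrom, gi$chrom)]
  bins$gc <- pmin(pmax(0.45 + 0.12 * sin(2 * pi * mid / 7e6 + phase) +
                         stats::rnorm(nb, 0, 0.01), 0.25), 0.65)
  mp <- stats::rnorm(nb, 1, 0.03)
  low <- sample.int(nb, round(0.02 * nb))
  mp[low] <- stats::runif(length(low), 0.3, 0.7)
  high <- sample(setdiff(seq_len(nb), low), round(0.01 * nb))
  mp[high] <- stats::runif(length(high), 1.2, 1.45)
  bins$mappability <- mp
  bins <- refresh_usable(bins)
  # karyotype: base CN per chromosome plus CN-1 blocks inside late domains
  base_cn <- rep(c(2, 3, 4, 2, 2), length.out = n_chroms)
  cn <- base_cn[match(bins$chrom, gi$chrom)]
  # deletion blocks live in very-late domains: they stay unreplicated in
  # most S cells, keeping the per-copy depth quantum identifiable
  for (chr in gi$chrom[seq(1L, min(4L, n_chroms))]) {
    cand <- domains[domains$chrom == chr, ]
    very_late <- cand[cand$level >= 0.75, ]
    cand <- if (nrow(very_late)) very_late else
      cand[order(-cand$level), ][1L, ]
    cand <- cand[order(-(cand$end - cand$start)), ]
    block_len <- min(cand$end[1L] - cand$start[1L], 6e6)
    mid_d <- (cand$start[1L] + cand$end[1L]) / 2
    sel <- bins$chrom == chr & bins$start >= mid_d - block_len / 2 &
      bins$end <= mid_d + block_len / 2
    cn[sel] <- 1
  }
  clones <- list(clone1 = cn)
  if (length(clone_fractions) > 1L) {
    for (k in 2:length(clone_fractions)) {
      ck <- cn
      if (!is.na(gain_chrom))
        ck[bins$chrom == paste0("chr", gain_chrom)] <-
          ck[bins$chrom == paste0("chr", gain_chrom)] + 1L
      clones[[paste0("clone", k)]] <- ck
    }
  }
  stopifnot(abs(sum(clone_fractions) - 1) < 1e-9)
  structure(list(bins = bins, rt_truth = rt, clones = clones,
                 clone_fractions = clone_fractions, domains = domains,
                 firing_noise = firing_noise, ectopic_rate = ectopic_rate,
                 s_prob = s_prob, s_fraction_range = s_fraction_range,
                 rpmb_haploid_mean = rpmb_haploid_mean,
                 rpmb_haploid_sd = rpmb_haploid_sd,
                 gc_slope = gc_slope, dispersion = dispersion,
                 bin_size = bin_size, firing_unit = firing_unit,
                 seed = seed),
            class = "scrt_synth_model")
}

#' Simulate a single-cell population with ground truth
#'
#' @param model from [synth_model()].
#' @param n_cells number of cells (at least 2).
#' @param seed RNG seed for the population draw (simulation is
#'   bit-reproducible given model and seed).
#' @return list of class `scrt_synth`: `counts` (bins x cells integer
#'   matrix), `truth` tibble (cell_id, phase, clone, s_fraction,
#'   true_ploidy), `replicated` (bins x S-cells logical matrix),
#'   `bins`, `rt_truth`, `model`.
#' @export
simulate_population <- function(model, n_cells, seed = 1L) {
  stopifnot(inherits(model, "scrt_synth_model"), n_cells >= 2L)
  set.seed(seed)
  bins <- model$bins
  nb <- nrow(bins)
  bin_mb <- (bins$end - bins$start) / 1e6
  gc_fac <- exp(model$gc_slope * (bins$gc - 0.45))
  bias <- gc_fac * bins$mappability
  clone_id <- sample(names(model$clones), n_cells, replace = TRUE,
                     prob = model$clone_fractions)
  phase <- ifelse(stats::runif(n_cells) < model$s_prob, "S", "G1G2")
  s_frac <- ifelse(phase == "S",
                   stats::runif(n_cells, model$s_fraction_range[1L],
                                model$s_fraction_range[2L]), NA_real_)
  rpmb_h <- pmax(stats::rnorm(n_cells, model$rpmb_haploid_mean,
                              model$rpmb_haploid_sd), 50)
  counts <- matrix(0L, nb, n_cells)
  colnames(counts) <- sprintf("cell_%04d", seq_len(n_cells))
  fu <- model$firing_unit %||% 200000L
  un_key <- paste(bins$chrom, bins$start %/% fu)
  unit <- match(un_key, unique(un_key))
  n_units <- max(unit)
  unit_rt <- as.numeric(tapply(model$rt_truth, unit, mean))
  s_cols <- which(phase == "S")
  replicated <- matrix(FALSE, nb, length(s_cols))
  colnames(replicated) <- colnames(counts)[s_cols]
  true_ploidy <- numeric(n_cells)
  genome_mb <- sum(bin_mb)
  for (i in seq_len(n_cells)) {
    cn <- model$clones[[clone_id[i]]]
    if (phase[i] == "S") {
      # firing decisions are taken per replicon-scale unit (200 kb by
      # default): all bins of a unit share one jitter draw and one
      # ectopic displacement, so adjacent large bins genuinely replicate
      # asynchronously and out-of-schedule events are visible at RT
      # resolution. Ectopic units jump to the opposite end of the
      # programme (an early-firing event in a late domain, or a
      # fire-failure in an early domain).
      t_unit <- unit_rt + stats::rlogis(n_units, 0, model$firing_noise)
      flip <- stats::runif(n_units) < model$ectopic_rate
      t_unit[flip] <- ifelse(unit_rt[flip] > 0.5, -Inf, Inf)
      # the cell's progression is its replicated genome fraction: the
      # firing front is the per-cell quantile of the firing times
      tau <- stats::quantile(t_unit, s_frac[i], type = 1L)
      rep_mask <- t_unit[unit] <= tau
      replicated[, match(i, s_cols)] <- rep_mask
      cn <- cn * (1 + rep_mask)
    }
    lam <- rpmb_h[i] * bin_mb * cn * bias
    counts[, i] <- if (is.finite(model$dispersion)) {
      stats::rnbinom(nb, size = model$dispersion, mu = lam)
    } else {
      stats::rpois(nb, lam)
    }
    true_ploidy[i] <- sum(cn * bin_mb) / genome_mb
  }
  truth <- tibble::tibble(cell_id = colnames(counts), phase = phase,
                          clone = clone_id, s_fraction = s_frac,
                          true_ploidy = true_ploidy,
                          rpmb_haploid = rpmb_h)
  structure(list(counts = counts, truth = truth, replicated = replicated,
                 bins = bins, rt_truth = model$rt_truth, model = model),
            class = "scrt_synth")
}

#' Aggregate the true timing landscape to RT resolution
#'
#' Mean firing time per RT bin, returned on the pseudo-bulk scale
#' (1 = early) for direct comparison with [pseudo_bulk()] output.
#'
#' @param sim `scrt_synth` object.
#' @param rt_bin_size RT bin width (default 200 kb).
#' @return numeric vector, one value per RT bin.
#' @export
truth_rt_200 <- function(sim, rt_bin_size = 200000L) {
  key <- paste(sim$bins$chrom, sim$bins$start %/% rt_bin_size)
  v <- tapply(sim$rt_truth, factor(key, levels = unique(key)), mean)
  1 - as.numeric(v)
}

#' Build a small genome with controlled GC and planted repeats
#'
#' Random unique sequence with a GC gradient along each chromosome;
#' optionally a block of chromosome 1 is copied verbatim into the other
#' chromosomes, creating known multi-mapping (low-mappability) bins.
#'
#' @param n_chroms,chrom_length,bin_size layout (default 2 x 60 kb,
#'   20-kb bins).
#' @param gc_range GC fraction range spanned along each chromosome.
#' @param repeat_block NULL, or `list(start=, width=)` (1-based, bp) of
#'   the chr1 block to duplicate into every other chromosome at the same
#'   offset.
#' @param seed RNG seed.
#' @param fasta optional path; when given the genome is also written as
#'   FASTA.
#' @return list: `genome` (`DNAStringSet`), `bins` (coordinates only),
#'   `repeat_block`.
#' @export
make_toy_genome <- function(n_chroms = 2L, chrom_length = 60000L,
                            bin_size = 20000L, gc_range = c(0.3, 0.6),
                            repeat_block = NULL, seed = 1L, fasta = NULL) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chroms), function(k) {
    gc <- seq(gc_range[1L], gc_range[2L], length.out = chrom_length)
    p_gc <- gc / 2
    base <- c("A", "T", "G", "C")
    paste(base[1L + (stats::runif(chrom_length) < 2 * p_gc) * 2L +
                 (stats::runif(chrom_length) < 0.5)], collapse = "")
  }, character(1))
  if (!is.null(repeat_block)) {
    blk <- substr(seqs[1L], repeat_block$start,
                  repeat_block$start + repeat_block$width - 1L)
    for (k in seq_len(n_chroms)[-1L]) {
      substr(seqs[k], repeat_block$start,
             repeat_block$start + repeat_block$width - 1L) <- blk
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  if (!is.null(fasta)) Biostrings::writeXStringSet(genome, fasta)
  bins <- make_bins(data.frame(chrom = names(genome),
                               length = rep(chrom_length, n_chroms)),
                    bin_size = bin_size)
  list(genome = genome, bins = bins, repeat_block = repeat_block)
}
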