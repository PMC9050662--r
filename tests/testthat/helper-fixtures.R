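# Shared fixtures, built in code and memoised for the test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a mid-size default-model population pushed through CNV calling, reused
# by staging / rt / heterogeneity tests
default_run <- function() {
  fixture("default_run", function() {
    m <- synth_model(seed = 7)
    sim <- simulate_population(m, 120, seed = 202)
    cnv <- call_cnv(sim$counts, sim$bins, min_reads = 5e4,
                    ploidy_limits = c(1, 6))
    phases <- call_phase_auto(cnv$qc)
    corr <- correct_s_progression(cnv$qc, phases)
    grp <- stats::setNames(sim$truth$clone, sim$truth$cell_id)
    rt <- compute_rt(cnv, corr, groups = grp)
    list(model = m, sim = sim, cnv = cnv, phases = phases, corr = corr,
         rt = rt)
  })
}

# simple flat bin table (no GC/mappability structure), fully usable
flat_bins <- function(n_chrom = 1L, chrom_len = 2e6, bin_size = 20000L) {
  bins <- make_bins(data.frame(chrom = paste0("chr", seq_len(n_chrom)),
                               length = rep(chrom_len, n_chrom)),
                    bin_size = bin_size)
  bins$gc <- 0.45
  bins$mappability <- 1
  bins$usable <- TRUE
  bins
}

# independent brute-force DIMAPD oracle (explicit loops over the printed
# definitions, 500-kb aggregation assumed done by the caller)
oracle_mapdc <- function(r500, chroms, genome_mb) {
  d <- c()
  for (chr in unique(chroms)) {
    v <- r500[chroms == chr]
    if (length(v) > 1L)
      for (i in seq_len(length(v) - 1L)) d <- c(d, v[i] - v[i + 1L])
  }
  d <- d / mean(r500)
  cx <- sqrt(sum(r500) / genome_mb)
  list(mapdc = stats::median(abs(d - stats::median(d))) * cx, c = cx)
}

# exhaustive-grid binarization oracle
oracle_binarize <- function(ncn, step = 1e-3) {
  th <- seq(0, 1, by = step)
  v <- ncn[!is.na(ncn)]
  eps <- vapply(th, function(t) sum((v - as.numeric(v >= t))^2), numeric(1))
  list(threshold = th[which.min(eps)], epsilon = min(eps))
}

# brute-force optimal penalized segmentation for tiny signals
oracle_partition <- function(x, beta, min_width) {
  n <- length(x)
  best <- list(cost = Inf, bp = integer(0))
  splits <- function(bp) {
    bounds <- c(0L, bp, n)
    if (any(diff(bounds) < min_width)) return(Inf)
    cost <- length(bounds) - 1L
    tot <- 0
    for (i in seq_len(length(bounds) - 1L)) {
      seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
      tot <- tot + sum((seg - mean(seg))^2)
    }
    tot + beta * (length(bounds) - 1L)
  }
  all_bp <- unlist(lapply(0:(n - 1L), function(k)
    utils::combn(seq_len(n - 1L), k, simplify = FALSE)), recursive = FALSE)
  for (bp in all_bp) {
    cst <- splits(bp)
    if (cst < best$cost) best <- list(cost = cst, bp = bp)
  }
  best
}
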