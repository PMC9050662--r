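#' Count high-quality reads per bin for one cell
#'
#' Counts alignments with mapping quality at or above `mapq_min`, skipping
#' duplicate-flagged and unmapped records. Read pairs falling in the same
#' bin are counted once; mates in different bins count independently
#' (unique (read name, bin) pairs).
#'
#' @param alignments path to a BAM (or SAM, converted on the fly) file for
#'   one cell, or a data frame with columns `qname`, `chrom`, `pos`
#'   (1-based leftmost position) and `mapq`.
#' @param bins bin table from the binning step.
#' @param mapq_min minimum mapping quality (default 30).
#' @return integer vector of raw counts, one entry per bin row.
#' @export
count_reads <- function(alignments, bins, mapq_min = 30L) {
  if (is.character(alignments)) {
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      path <- Rsamtools::asBam(path,
                               destination = tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isDuplicate = FALSE,
                                    isSecondaryAlignment = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flags,
                                 what = c("qname", "rname", "pos", "mapq"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    alignments <- data.frame(qname = b$qname, chrom = as.character(b$rname),
                             pos = b$pos, mapq = b$mapq)
  }
  stopifnot(all(c("qname", "chrom", "pos", "mapq") %in% names(alignments)))
  aln <- alignments[!is.na(alignments$pos) &
                      alignments$mapq >= mapq_min, , drop = FALSE]
  bad <- setdiff(unique(aln$chrom), unique(bins$chrom))
  if (length(bad))
    stop("alignment contigs absent from bin table: ",
         paste(bad, collapse = ", "))
  counts <- integer(nrow(bins))
  for (chr in unique(aln$chrom)) {
    idx <- which(bins$chrom == chr)
    idx <- idx[order(bins$start[idx])]
    sel <- aln[aln$chrom == chr, , drop = FALSE]
    j <- findInterval(sel$pos - 1L, bins$start[idx])
    ok <- j >= 1L & (sel$pos - 1L) < bins$end[idx][pmax(j, 1L)]
    key <- paste(sel$qname[ok], j[ok])
    j <- j[ok][!duplicated(key)]
    tab <- tabulate(j, nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  counts
}

#' Discard low-coverage cells
#'
#' @param counts bins x cells integer matrix (column names = cell ids).
#' @param min_reads minimum total reads per cell (default 2e5).
#' @return list with `kept` and `discarded` count matrices and a
#'   `discarded_totals` named vector.
#' @export
filter_low_coverage <- function(counts, min_reads = 200000) {
  totals <- colSums(counts)
  keep <- totals >= min_reads
  list(kept = counts[, keep, drop = FALSE],
       discarded = counts[, !keep, drop = FALSE],
       discarded_totals = totals[!keep])
}

#' Mappability- and GC-correct one cell's bin counts
#'
#' Two-step correction on usable bins: counts are first divided by bin
#' mappability (`rm = r / M`), then rescaled within GC classes so every
#' class shares the global median (`R = rm * median(rm) /
#' median(rm[same GC class])`). GC classes are formed by rounding gc to
#' `gc_grid`; classes with fewer than `min_class_bins` members are merged
#' with the nearest class so medians stay stable. Short trailing bins are
#' corrected but excluded from the median pools.
#'
#' @param raw integer vector of raw per-bin counts.
#' @param bins bin table with gc/mappability/usable filled.
#' @param gc_grid GC rounding step (default 0.01).
#' @param min_class_bins minimum bins per GC class (default 20).
#' @return numeric vector of corrected counts (NA on unusable bins).
#' @export
correct_counts <- function(raw, bins, gc_grid = 0.01, min_class_bins = 20L) {
  if (sum(raw[bins$usable], na.rm = TRUE) == 0) stop("no signal: all-zero cell")
  corrected <- rep(NA_real_, nrow(bins))
  use <- bins$usable
  rm_ <- raw[use] / bins$mappability[use]
  gc <- round(bins$gc[use] / gc_grid) * gc_grid
  cls <- merge_small_classes(gc, min_class_bins)
  pool <- !short_bins(bins)[use]
  med_all <- stats::median(rm_[pool])
  med_cls <- tapply(rm_[pool], cls[pool], stats::median)
  # classes present only among short bins fall back to the global median
  cls_med <- med_cls[as.character(cls)]
  cls_med[is.na(cls_med) | cls_med == 0] <- med_all
  corrected[use] <- rm_ * med_all / cls_med
  corrected
}

# internal: merge GC classes with few members into the nearest class
merge_small_classes <- function(gc, min_n) {
  lv <- sort(unique(gc))
  repeat {
    n <- table(factor(gc, levels = lv))
    small <- which(n < min_n & n > 0)
    if (!length(small) || length(lv) == 1L) break
    i <- small[which.min(n[small])]
    others <- setdiff(seq_along(lv), i)
    j <- others[which.min(abs(lv[others] - lv[i]))]
    gc[gc == lv[i]] <- lv[j]
    lv <- lv[-i]
  }
  gc
}

#' Intracellular bin-to-bin variability (DIMAPD)
#'
#' Aggregates raw counts into 500-kb windows per chromosome and computes,
#' per cell, the median absolute deviation of neighbouring-window
#' differences scaled by the mean window count, times the square root of
#' coverage (MAPDC). Because MAPDC grows linearly with the square root of
#' coverage, a population-level linear fit of MAPDC against centred
#' coverage is removed, giving the depth-independent score
#' `DIMAPD = 1 + MAPDC - a (C - median C) - b`. With fewer than 8 cells
#' the slope is not identifiable and `a = 0`, `b = median(MAPDC)` is used.
#'
#' @param counts bins x cells raw count matrix.
#' @param bins bin table.
#' @param agg_size aggregation window in bp (default 500 kb).
#' @return tibble with `cell_id`, `mapd_c`, `coverage_sqrt`, `dimapd`.
#' @export
compute_dimapd <- function(counts, bins, agg_size = 500000L) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("DIMAPD normalisation needs at least 2 cells; ",
         "set thresholds manually for a single cell")
  gs_mb <- sum(bins$end - bins$start) / 1e6
  win <- paste(bins$chrom, bins$start %/% agg_size)
  win <- factor(win, levels = unique(win))
  mapdc <- numeric(ncol(counts))
  cov_sqrt <- numeric(ncol(counts))
  for (x in seq_len(ncol(counts))) {
    r500 <- rowsum(counts[, x], win, reorder = FALSE)[, 1L]
    chr <- bins$chrom[!duplicated(win)]
    d <- unlist(lapply(split(r500, factor(chr, unique(chr))), diff),
                use.names = FALSE)
    d <- d / mean(r500)
    cov_sqrt[x] <- sqrt(sum(r500) / gs_mb)
    mapdc[x] <- stats::median(abs(d - stats::median(d))) * cov_sqrt[x]
  }
  cc <- cov_sqrt - stats::median(cov_sqrt)
  if (ncol(counts) >= 8L && stats::sd(cc) > 1e-9) {
    # trimmed least squares: the fit describes the G1/G2 bulk. S cells
    # have both higher coverage (more DNA) and higher MAPDC, which an
    # unguarded OLS absorbs into the slope, so the fit starts from the
    # MAPDC bulk and then iterates residual trimming.
    # start from the lower MAPDC half: a guaranteed G1/G2 majority as
    # long as S cells are a minority of the population
    keep <- mapdc <= stats::median(mapdc)
    if (sum(keep) < 4L) keep <- rep(TRUE, length(cc))
    for (it in 1:3) {
      fit <- stats::lm.fit(cbind(1, cc[keep]), mapdc[keep])
      res <- mapdc - cbind(1, cc) %*% fit$coefficients
      s <- stats::mad(res[keep])
      if (!is.finite(s) || s == 0) break
      keep <- abs(res - stats::median(res[keep])) < 3 * s
    }
    b <- fit$coefficients[1L]; a <- fit$coefficients[2L]
  } else {
    a <- 0; b <- stats::median(mapdc)
  }
  tibble::tibble(cell_id = colnames(counts) %||% as.character(seq_along(mapdc)),
                 mapd_c = mapdc, coverage_sqrt = cov_sqrt,
                 dimapd = 1 + mapdc - a * cc - b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment one cell's corrected profile
#'
#' Runs change-point segmentation per chromosome over usable bins and
#' summarises each segment by its mean corrected count per bin and its
#' usable size. A chromosome with fewer than two usable bins yields a
#' single segment.
#'
#' @param corrected corrected counts from [correct_counts()].
#' @param bins bin table.
#' @param ... passed to [segment_signal()].
#' @return tibble of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_count`, `size` (usable bp).
#' @export
segment_profile <- function(corrected, bins, ...) {
  acc <- list()
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr & bins$usable & !is.na(corrected))
    if (!length(idx)) next
    x <- corrected[idx]
    seg_id <- if (length(idx) < 2L) rep(1L, length(idx)) else
      segment_signal(x, ...)
    first <- !duplicated(seg_id)
    last <- !duplicated(seg_id, fromLast = TRUE)
    acc[[chr]] <- data.frame(
      chrom = chr,
      start = bins$start[idx[first]],
      end = bins$end[idx[last]],
      n_bins = as.integer(tabulate(seg_id)),
      mean_count = as.numeric(tapply(x, seg_id, mean)),
      size = as.numeric(tapply(bins$end[idx] - bins$start[idx],
                               seg_id, sum)))
  }
  tibble::as_tibble(do.call(rbind, acc))
}

#' Integer copy number and ploidy by sine-quantisation of segment depth
#'
#' Searches for the per-copy read-depth quantum X minimising
#' `chi(X) = sqrt(sum_n S_n sin^2(pi R_n / X))` (S_n segment size in Mb,
#' R_n mean corrected count per bin), over a dense grid between the 5th
#' and 95th percentile of segment depths, with local refinement of each
#' local minimum. Minima whose implied mean ploidy falls outside
#' `ploidy_limits` are rejected; the global feasible minimum is selected
#' (or, with `target_ploidy`, the feasible minimum nearest the target).
#' Copy number is `CN_n = round(R_n / X_min)` (half away from zero) and
#' mean ploidy is the size-weighted mean CN. The confidence is the chi gap
#' between the best and runner-up feasible minima; below 2 the call is
#' unreliable, and a target-imposed pick that is not the global minimum is
#' reported with negative confidence.
#'
#' @param segments segment tibble from [segment_profile()].
#' @param ploidy_limits length-2 feasible mean-ploidy range (default
#'   c(1, 8)).
#' @param grid_n grid density (default 2000).
#' @param target_ploidy optional; select the feasible minimum closest to
#'   this value instead of the global one.
#' @return list with `segments` (cn filled), `ploidy`,
#'   `ploidy_confidence`, `x_min`, `chi_curve`, `reliable`.
#' @export
estimate_cn <- function(segments, ploidy_limits = c(1, 8), grid_n = 2000L,
                        target_ploidy = NULL) {
  stopifnot(nrow(segments) >= 1L)
  pos <- segments$mean_count > 0 & is.finite(segments$mean_count)
  if (!any(pos)) stop("no segments with positive depth")
  r <- segments$mean_count[pos]
  s_mb <- segments$size[pos] / 1e6
  chi_of <- function(x) {
    vapply(x, function(xx)
      sqrt(sum(s_mb * sin(pi * r / xx)^2)), numeric(1))
  }
  # percentiles of segment depth weighted by segment size, so the search
  # range reflects genome fractions rather than segment counts
  qw <- weighted_quantile(r, s_mb, c(0.05, 0.95))
  lo <- qw[1L]
  hi <- qw[2L]
  if (hi <= lo) { lo <- lo * 0.999; hi <- hi * 1.001 + 1e-9 }
  grid <- seq(lo, hi, length.out = grid_n)
  chi <- chi_of(grid)
  cand <- local_minima(chi)
  # refine each local minimum within its bracketing interval
  xs <- vapply(cand, function(i) {
    a <- grid[max(i - 1L, 1L)]; b <- grid[min(i + 1L, grid_n)]
    if (a == b) return(grid[i])
    stats::optimize(chi_of, c(a, b), tol = 1e-10)$minimum
  }, numeric(1))
  # chi dips exactly where a segment depth is an integer multiple of X:
  # evaluating the rational candidates X = R_n / k catches minima narrower
  # than the grid spacing
  rational <- unlist(lapply(r, function(rr) {
    ks <- seq_len(max(1L, ceiling(rr / lo)))
    rr / ks
  }))
  rational <- unique(round(rational[rational >= lo & rational <= hi], 8))
  if (length(rational)) {
    step <- (hi - lo) / (grid_n - 1L)
    chi_rat <- chi_of(rational)
    near <- pmin(pmax(round((rational - lo) / step) + 1L, 1L), grid_n)
    dip <- chi_rat < chi[near] - 1e-12   # dips the grid did not see
    refined <- vapply(rational[dip], function(x)
      stats::optimize(chi_of, c(max(lo, x - step),
                                min(hi, x + step)),
                      tol = 1e-10)$minimum, numeric(1))
    xs <- c(xs, refined)
  }
  xs <- unique(round(xs, 10))
  sols <- lapply(xs, function(x) {
    cn <- round_half_up(segments$mean_count / x)
    cn[!is.finite(cn)] <- 0
    p <- sum(segments$size * cn) / sum(segments$size)
    list(x = x, chi = chi_of(x), cn = cn, ploidy = p)
  })
  ok <- vapply(sols, function(s)
    is.finite(s$chi) && is.finite(s$ploidy), logical(1))
  sols <- sols[ok]
  # near-duplicate X values give the same CN assignment; keep the best
  # representative of each assignment so minima are genuinely distinct
  key <- vapply(sols, function(s) paste(s$cn, collapse = ","), character(1))
  chis_all <- vapply(sols, `[[`, numeric(1), "chi")
  sols <- lapply(split(seq_along(sols), key), function(ix)
    sols[[ix[which.min(chis_all[ix])]]])
  feas <- vapply(sols, function(s)
    s$ploidy >= ploidy_limits[1L] && s$ploidy <= ploidy_limits[2L] &&
      s$ploidy > 0, logical(1))
  if (!any(feas)) {
    err <- simpleError("no feasible chi minimum within ploidy limits")
    err$chi_curve <- data.frame(x = grid, chi = chi)
    stop(err)
  }
  sols <- sols[feas]
  chis <- vapply(sols, `[[`, numeric(1), "chi")
  best_global <- which.min(chis)
  pick <- if (is.null(target_ploidy)) best_global else
    which.min(abs(vapply(sols, `[[`, numeric(1), "ploidy") - target_ploidy))
  gap <- if (length(chis) > 1L)
    sort(chis)[2L] - chis[best_global] else Inf
  conf <- if (pick == best_global) gap else
    -abs(chis[pick] - chis[best_global])
  segments$cn <- sols[[pick]]$cn
  list(segments = segments, ploidy = sols[[pick]]$ploidy,
       ploidy_confidence = conf, x_min = sols[[pick]]$x,
       chi_curve = data.frame(x = grid, chi = chi),
       reliable = conf >= 2)
}

#' Size-weighted mean copy number of a cell
#'
#' @param segments segment tibble with `size` and `cn` filled.
#' @return mean ploidy.
#' @export
mean_ploidy <- function(segments) {
  stopifnot(!is.null(segments$cn))
  sum(segments$size * segments$cn) / sum(segments$size)
}

#' Per-cell CNV calling over a whole population
#'
#' Convenience wrapper running coverage filtering, bias correction, DIMAPD,
#' segmentation and copy-number estimation for every cell of a bins x
#' cells count matrix.
#'
#' @param counts bins x cells raw count matrix (column names = cell ids).
#' @param bins bin table.
#' @param min_reads coverage filter (default 2e5 reads).
#' @param ploidy_limits,target_ploidy,grid_n passed to [estimate_cn()].
#' @param mapq_min recorded in the result for provenance.
#' @param ... passed to [segment_profile()].
#' @return object of class `scrt_cnv`: list with `qc` tibble (cell_id,
#'   total_reads, rpmb, dimapd, ploidy, ploidy_confidence, x_min),
#'   `segments` (named list of per-cell segment tibbles), `bins`.
#' @export
call_cnv <- function(counts, bins, min_reads = 200000,
                     ploidy_limits = c(1, 8), target_ploidy = NULL,
                     grid_n = 2000L, mapq_min = 30L, ...) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell_%04d", seq_len(ncol(counts)))
  fl <- filter_low_coverage(counts, min_reads)
  counts <- fl$kept
  if (!ncol(counts)) stop("no cells pass the coverage filter")
  dim_tbl <- compute_dimapd(counts, bins)
  usable_mb <- sum((bins$end - bins$start)[bins$usable]) / 1e6
  segs <- list(); ploidy <- conf <- xmin <- numeric(ncol(counts))
  for (x in seq_len(ncol(counts))) {
    corr <- correct_counts(counts[, x], bins)
    sp <- segment_profile(corr, bins, ...)
    est <- estimate_cn(sp, ploidy_limits = ploidy_limits,
                       grid_n = grid_n, target_ploidy = target_ploidy)
    segs[[colnames(counts)[x]]] <- est$segments
    ploidy[x] <- est$ploidy; conf[x] <- est$ploidy_confidence
    xmin[x] <- est$x_min
  }
  qc <- tibble::tibble(cell_id = colnames(counts),
                       total_reads = colSums(counts),
                       rpmb = colSums(counts) / usable_mb,
                       dimapd = dim_tbl$dimapd,
                       ploidy = ploidy, ploidy_confidence = conf,
                       x_min = xmin)
  structure(list(qc = qc, segments = segs, bins = bins,
                 params = list(min_reads = min_reads, mapq_min = mapq_min,
                               ploidy_limits = ploidy_limits)),
            class = "scrt_cnv")
}

#' Read / write a bins x cells count matrix
#'
#' TSV with chrom, start, end followed by one column per cell.
#' @param counts bins x cells matrix.
#' @param bins bin table.
#' @param path file path.
#' @export
write_count_matrix <- function(counts, bins, path) {
  df <- cbind(as.data.frame(bins)[, c("chrom", "start", "end")],
              as.data.frame(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  list(counts = counts,
       coords = tibble::as_tibble(df[, 1:3]))
}
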