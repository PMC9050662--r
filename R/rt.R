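#' Re-bin per-cell segments to the RT resolution
#'
#' Each RT bin (default 200 kb) receives the weighted median copy number
#' of the segments overlapping it, weights being the overlap sizes in bp.
#' Even splits take the mean of the two straddling CN values. An optional
#' per-cell multiplicative `shift` (from the S-progression correction)
#' rescales the depth quantum before rounding, so halved branch-2 cells
#' are re-quantised rather than having their rounded CNs doubled.
#'
#' @param segments named list of per-cell segment tibbles with `cn` (and
#'   `mean_count` when shifts are used).
#' @param bins 20-kb bin table (defines chromosome extents).
#' @param rt_bin_size RT bin width in bp (default 200 kb).
#' @param shifts optional named numeric vector of per-cell shifts;
#'   together with `x_min` the CN is recomputed as
#'   `round(mean_count * shift / x_min)`.
#' @param x_min optional named vector of per-cell depth quanta.
#' @return list with `cn200` (cells x RT-bins matrix) and `rt_bins`
#'   (tibble chrom/start/end).
#' @export
rebin_cn <- function(segments, bins, rt_bin_size = 200000L,
                     shifts = NULL, x_min = NULL) {
  chroms <- unique(bins$chrom)
  rt_bins <- dplyr::bind_rows(lapply(chroms, function(chr) {
    len <- max(bins$end[bins$chrom == chr])
    start <- seq(0L, len - 1L, by = rt_bin_size)
    tibble::tibble(chrom = chr, start = start,
                   end = pmin(start + rt_bin_size, len))
  }))
  cells <- names(segments)
  cn200 <- matrix(NA_real_, nrow = length(cells), ncol = nrow(rt_bins),
                  dimnames = list(cells, NULL))
  rb <- GenomicRanges::GRanges(rt_bins$chrom,
                               IRanges::IRanges(rt_bins$start + 1L,
                                                rt_bins$end))
  for (cell in cells) {
    seg <- segments[[cell]]
    cn <- seg$cn
    if (!is.null(shifts) && !is.null(x_min)) {
      sh <- shifts[[cell]] %||% 1
      if (is.na(sh)) sh <- 1
      cn <- round_half_up(seg$mean_count * sh / x_min[[cell]])
    }
    sg <- GenomicRanges::GRanges(seg$chrom,
                                 IRanges::IRanges(seg$start + 1L, seg$end))
    ov <- GenomicRanges::findOverlaps(rb, sg)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(rb)[S4Vectors::queryHits(ov)],
      IRanges::ranges(sg)[S4Vectors::subjectHits(ov)]))
    q <- S4Vectors::queryHits(ov)
    v <- cn[S4Vectors::subjectHits(ov)]
    for (b in unique(q)) {
      sel <- q == b
      cn200[cell, b] <- weighted_median(v[sel], w[sel])
    }
  }
  list(cn200 = cn200, rt_bins = rt_bins)
}

#' G1/G2 reference copy-number profile
#'
#' Per-bin median across G1/G2 cells; bins with a zero or undefined
#' reference are masked genome-wide (log-ratio normalisation is undefined
#' there).
#'
#' @param cn200_g cells x bins CN matrix of G1/G2 cells.
#' @return numeric vector (NA = masked).
#' @export
g1g2_reference <- function(cn200_g) {
  cng <- matrixStats::colMedians(as.matrix(cn200_g), na.rm = TRUE)
  cng[!is.finite(cng) | cng == 0] <- NA_real_
  cng
}

#' Normalise an S-phase cell against the G1/G2 reference
#'
#' `nCN = log2(CN200 / CNG)`: replicated bins (doubled CN) sit near 1,
#' unreplicated bins near 0.
#'
#' @param cn200_row one cell's CN vector at RT resolution.
#' @param cng reference from [g1g2_reference()].
#' @return log2-ratio vector (NA where either side is missing or zero).
#' @export
normalize_s_cell <- function(cn200_row, cng) {
  out <- log2(cn200_row / cng)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Binarise a normalised profile into replicated / unreplicated
#'
#' Scans the threshold th over [0, 1] (1e-3 grid) and picks the value
#' minimising the squared distance between nCN and its 0/1 assignment
#' (bins at or above th are 1). Ties take the smallest threshold. Profiles
#' entirely below 0 or above 1 give degenerate all-0 / all-1 calls, which
#' is permitted at the boundaries.
#'
#' @param ncn_row normalised log2-ratio vector.
#' @param step threshold grid step (default 1e-3).
#' @return list with `scrt` (0/1 vector, NA preserved), `threshold`,
#'   `epsilon` (minimised squared distance).
#' @export
binarize_profile <- function(ncn_row, step = 1e-3) {
  def <- which(!is.na(ncn_row))
  if (!length(def)) stop("all-missing profile")
  v <- ncn_row[def]
  th <- seq(0, 1, by = step)
  vs <- sort(v)
  cs <- cumsum(vs)
  cs2 <- cumsum(vs^2)
  n <- length(vs)
  tot <- cs[n]; tot2 <- cs2[n]
  # k = number of values below th; eps = sum(v<th: v^2) + sum(v>=th: (v-1)^2)
  k <- findInterval(th, vs, left.open = TRUE)
  below2 <- ifelse(k > 0, cs2[pmax(k, 1L)], 0)
  above <- tot - ifelse(k > 0, cs[pmax(k, 1L)], 0)
  above2 <- tot2 - below2
  eps <- below2 + above2 - 2 * above + (n - k)
  i <- which.min(eps)
  thm <- th[i]
  scrt <- rep(NA_real_, length(ncn_row))
  scrt[def] <- as.numeric(v >= thm)
  list(scrt = scrt, threshold = thm, epsilon = eps[i])
}

#' Filter divergent cells by simple-matching distance
#'
#' Removes cells whose binary profile differs by at least `max_dist` from
#' at least `frac` of the other cells.
#'
#' @param scrt cells x bins binary matrix.
#' @param max_dist divergence distance (default 0.25).
#' @param frac population fraction (default 0.6).
#' @return logical vector: TRUE = cell retained.
#' @export
smc_filter <- function(scrt, max_dist = 0.25, frac = 0.6) {
  n <- nrow(scrt)
  if (n < 3L) return(rep(TRUE, n))
  d <- smc_distances(scrt)
  keep <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    mean(di >= max_dist, na.rm = TRUE) < frac
  }, logical(1))
  if (sum(keep) < 2L) {
    warning("divergence filter would discard the whole population; ",
            "keeping all cells")
    keep <- rep(TRUE, n)
  }
  keep
}

#' Pseudo-bulk replication timing from binary profiles
#'
#' Cells are grouped into replication-percentage intervals (default 2.5%
#' wide); per-interval mean profiles are computed; extreme intervals are
#' trimmed from the heavier tail until the retained cells' mean
#' replication percentage is within `balance_tol` of 50%; the pseudo-bulk
#' RT is the unweighted mean of the interval means (1 = early).
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage in [0, 1] (defaults to
#'   the row means of `scrt`).
#' @param interval_width interval width (default 0.025).
#' @param balance_tol symmetry tolerance on the mean percentage (0.05).
#' @return list with `rt` (per-bin proportion in [0, 1]), `n_cells`,
#'   `intervals_used`.
#' @export
pseudo_bulk <- function(scrt, rep_pct = NULL, interval_width = 0.025,
                        balance_tol = 0.05) {
  scrt <- as.matrix(scrt)
  if (nrow(scrt) < 2L) stop("pseudo-bulk needs at least 2 cells")
  if (is.null(rep_pct)) rep_pct <- rowMeans(scrt, na.rm = TRUE)
  iv <- pmin(floor(rep_pct / interval_width), 1 / interval_width - 1)
  keep_iv <- sort(unique(iv))
  # trim on interval centres (not cell means) so the result does not
  # depend on how many cells populate an interval
  centre <- function(k) (k + 0.5) * interval_width
  repeat {
    if (length(keep_iv) <= 2L) break
    m <- mean(centre(keep_iv))
    if (abs(m - 0.5) <= balance_tol) break
    keep_iv <- if (m > 0.5) keep_iv[-length(keep_iv)] else keep_iv[-1L]
  }
  cells <- which(iv %in% keep_iv)
  means <- t(vapply(keep_iv, function(k) {
    colMeans(scrt[iv == k, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(scrt))))
  rt <- colMeans(means, na.rm = TRUE)
  rt[!is.finite(rt)] <- NA_real_
  list(rt = rt, n_cells = length(cells), intervals_used = keep_iv)
}

#' Binary replication profiles for a whole S population
#'
#' Runs normalisation and binarisation for every S cell against the G1/G2
#' reference, masks bins missing in at least `max_missing` of cells, and
#' applies the simple-matching divergence filter.
#'
#' @param cn200_s S cells x bins CN matrix (already shift-corrected).
#' @param cng G1/G2 reference profile.
#' @param max_missing mask bins missing in at least this fraction of cells
#'   (default 0.25).
#' @param smc apply the divergence filter (default TRUE).
#' @return object of class `scrt_rt`: `scrt` matrix, `ncn` matrix,
#'   `thresholds`, `rep_pct`, `retained` (SMC filter), `masked_bins`.
#' @export
build_rt_matrix <- function(cn200_s, cng, max_missing = 0.25, smc = TRUE) {
  cn200_s <- as.matrix(cn200_s)
  ncn <- t(apply(cn200_s, 1L, normalize_s_cell, cng = cng))
  miss <- colMeans(is.na(ncn))
  masked <- miss >= max_missing
  ncn[, masked] <- NA_real_
  scrt <- matrix(NA_real_, nrow(ncn), ncol(ncn),
                 dimnames = dimnames(cn200_s))
  thm <- numeric(nrow(ncn))
  for (i in seq_len(nrow(ncn))) {
    b <- binarize_profile(ncn[i, ])
    scrt[i, ] <- b$scrt
    thm[i] <- b$threshold
  }
  rep_pct <- rowMeans(scrt, na.rm = TRUE)
  retained <- if (smc) smc_filter(scrt) else rep(TRUE, nrow(scrt))
  structure(list(scrt = scrt, ncn = ncn, thresholds = thm,
                 rep_pct = rep_pct, retained = retained,
                 masked_bins = masked),
            class = "scrt_rt")
}

#' End-to-end replication-timing extraction
#'
#' Ties the CNV, staging and RT steps together: re-bins per-cell segments
#' at the RT resolution (applying S-progression shifts), builds the G1/G2
#' reference, binarises every S cell, filters divergent profiles and
#' computes the pseudo-bulk RT.
#'
#' @param cnv `scrt_cnv` object from [call_cnv()].
#' @param correction `scrt_scorrection` from [correct_s_progression()].
#' @param rt_bin_size RT bin width (default 200 kb).
#' @param groups optional named character vector (cell id to
#'   sub-population label, e.g. from [gate_subpopulations()]): each S
#'   cell is normalised against the G1/G2 reference of its own
#'   sub-population, which is essential in heterogeneous samples where a
#'   pooled reference would blur clone-specific copy-number differences.
#' @param ... passed to [build_rt_matrix()].
#' @return object of class `scrt_result`: `rt_bins`, `cng` (per group),
#'   `cn200_g`, `cn200_s`, `rtm` (`scrt_rt`), `pseudobulk`, `cells`.
#' @export
compute_rt <- function(cnv, correction, rt_bin_size = 200000L,
                       groups = NULL, ...) {
  cells <- correction$cells
  g_ids <- cells$cell_id[cells$phase == "G1G2" & !is.na(cells$phase)]
  s_ids <- cells$cell_id[cells$phase == "S" & !is.na(cells$phase)]
  g_ids <- intersect(g_ids, names(cnv$segments))
  s_ids <- intersect(s_ids, names(cnv$segments))
  if (!length(g_ids) || !length(s_ids))
    stop("need both G1/G2 and S cells with segments")
  if (is.null(groups))
    groups <- stats::setNames(rep("all", nrow(cells)), cells$cell_id)
  shifts <- stats::setNames(cells$shift, cells$cell_id)
  x_min <- stats::setNames(cnv$qc$x_min, cnv$qc$cell_id)
  rb_g <- rebin_cn(cnv$segments[g_ids], cnv$bins, rt_bin_size)
  rb_s <- rebin_cn(cnv$segments[s_ids], cnv$bins, rt_bin_size,
                   shifts = shifts, x_min = x_min)
  cng <- list()
  ncn_input <- rb_s$cn200
  ref_of <- groups[s_ids]
  ref_of[is.na(ref_of)] <- "all"
  cng_all <- g1g2_reference(rb_g$cn200)
  for (grp in unique(ref_of)) {
    grp_g <- g_ids[!is.na(groups[g_ids]) & groups[g_ids] == grp]
    cng[[grp]] <- if (length(grp_g) >= 3L)
      g1g2_reference(rb_g$cn200[grp_g, , drop = FALSE]) else cng_all
  }
  # divide each S row by its group reference; build_rt_matrix then sees a
  # unit reference
  ratio <- ncn_input
  for (i in seq_along(s_ids))
    ratio[i, ] <- ncn_input[i, ] / cng[[ref_of[i]]]
  rtm <- build_rt_matrix(ratio, rep(1, ncol(ratio)), ...)
  kept <- which(rtm$retained)
  pb <- pseudo_bulk(rtm$scrt[kept, , drop = FALSE],
                    rtm$rep_pct[kept])
  structure(list(rt_bins = rb_s$rt_bins, cng = cng,
                 cn200_g = rb_g$cn200, cn200_s = rb_s$cn200,
                 rtm = rtm, pseudobulk = pb, cells = cells,
                 groups = ref_of),
            class = "scrt_result")
}
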