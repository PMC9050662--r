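#' Automatic S-phase calling from DIMAPD outliers
#'
#' Assumes the majority of cells are in G1/G2, where bin-to-bin variability
#' is minimal. The bulk of the DIMAPD distribution is fitted robustly
#' (median location, MAD scale) and cells beyond the one-sided
#' `1 - alpha` Gaussian quantile of that fit are called S phase.
#'
#' @param qc tibble with `cell_id` and `dimapd` (from [call_cnv()] or
#'   [compute_dimapd()]).
#' @param alpha one-sided tail probability (default 0.01).
#' @return tibble `cell_id`, `phase` ("S"/"G1G2"), `source`,
#'   `dimapd_threshold`.
#' @export
call_phase_auto <- function(qc, alpha = 0.01) {
  d <- qc$dimapd
  # Gaussian bulk fit robust to the S-phase upper tail: initialise the
  # scale from the lower half-distribution (uncontaminated), then
  # re-estimate location and a two-sided scale on the trimmed bulk (the
  # trim removes S cells; the two-sided MAD keeps the G1/G2 right tail)
  m <- stats::median(d)
  s <- 1.4826 * stats::median(m - d[d <= m])
  if (is.finite(s) && s > 0) {
    for (it in 1:3) {
      bulk <- d[d <= m + 2.5 * s]
      m_new <- stats::median(bulk)
      s_new <- stats::mad(bulk)
      if (!is.finite(s_new) || s_new == 0) break
      if (abs(m_new - m) < 1e-12 && abs(s_new - s) < 1e-12) break
      m <- m_new; s <- s_new
    }
  }
  if (!is.finite(s) || s == 0) {
    warning("degenerate DIMAPD distribution; all cells called G1/G2")
    thr <- Inf
  } else {
    thr <- m + stats::qnorm(1 - alpha) * s
  }
  tibble::tibble(cell_id = qc$cell_id,
                 phase = ifelse(d > thr, "S", "G1G2"),
                 source = "auto", dimapd_threshold = thr)
}

#' Manual S-phase calling with an optional unknown gate
#'
#' @param qc tibble with `cell_id`, `dimapd` and (for gating) `ploidy`.
#' @param s_threshold DIMAPD value above which a cell is S phase.
#' @param unknown_gate optional list with `ploidy = c(min, max)` and/or
#'   `dimapd = c(min, max)`; cells inside the gate (closed bounds) are
#'   labelled "unknown" and excluded downstream.
#' @return tibble as in [call_phase_auto()] with `source = "manual"`.
#' @export
call_phase_manual <- function(qc, s_threshold, unknown_gate = NULL) {
  stopifnot(is.finite(s_threshold))
  phase <- ifelse(qc$dimapd > s_threshold, "S", "G1G2")
  if (!is.null(unknown_gate)) {
    inside <- rep(TRUE, nrow(qc))
    if (!is.null(unknown_gate$ploidy))
      inside <- inside & qc$ploidy >= unknown_gate$ploidy[1L] &
        qc$ploidy <= unknown_gate$ploidy[2L]
    if (!is.null(unknown_gate$dimapd))
      inside <- inside & qc$dimapd >= unknown_gate$dimapd[1L] &
        qc$dimapd <= unknown_gate$dimapd[2L]
    phase[inside] <- "unknown"
  }
  tibble::tibble(cell_id = qc$cell_id, phase = phase, source = "manual",
                 dimapd_threshold = s_threshold)
}

#' Assign phases from sorted-population metadata
#'
#' For FACS-sorted designs the phase is known; metadata overrides any
#' inferred label. Unmatched cells are reported in the `unmatched`
#' attribute and kept with phase "unknown".
#'
#' @param qc tibble with `cell_id`.
#' @param metadata data frame with `cell_id` and `phase` (values "S",
#'   "G1G2"/"G1"/"G2", or "unknown").
#' @return phase tibble with `source = "metadata"`.
#' @export
apply_phase_metadata <- function(qc, metadata) {
  stopifnot(all(c("cell_id", "phase") %in% names(metadata)))
  if (anyDuplicated(metadata$cell_id)) {
    dup <- unique(metadata$cell_id[duplicated(metadata$cell_id)])
    conflict <- vapply(dup, function(id) {
      length(unique(metadata$phase[metadata$cell_id == id])) > 1L
    }, logical(1))
    if (any(conflict))
      stop("conflicting phase metadata for: ",
           paste(dup[conflict], collapse = ", "))
    metadata <- metadata[!duplicated(metadata$cell_id), , drop = FALSE]
  }
  phase <- metadata$phase[match(qc$cell_id, metadata$cell_id)]
  phase[phase %in% c("G1", "G2")] <- "G1G2"
  unmatched <- qc$cell_id[is.na(phase)]
  phase[is.na(phase)] <- "unknown"
  out <- tibble::tibble(cell_id = qc$cell_id, phase = phase,
                        source = "metadata", dimapd_threshold = NA_real_)
  attr(out, "unmatched") <- unmatched
  out
}

#' Correct the two-branch S-phase ploidy artefact
#'
#' The discrete copy-number solver under-scales S cells whose per-copy
#' depth quantum falls below the 5th-percentile search bound (it locks
#' onto an integer multiple of the quantum), splitting the S population
#' into a normal branch (ploidy above the G1/G2 median) and a scaled-down
#' branch approaching it from below. Because the artefact is a quantum
#' ratio, the admissible corrections are small integer factors: each
#' branch-2 cell is rescaled by the smallest integer multiplier that
#' reunites it with the S distribution inside (G1/G2 ploidy, about twice
#' the G1/G2 ploidy], restoring a single S mode while preserving (indeed
#' maximising) its ploidy spread. Whether the merged distribution ends up
#' monomodal is checked on a kernel density estimate and reported. Manual
#' multiplicative shifts for either branch override the automatic rule.
#'
#' @param qc tibble with `cell_id`, `ploidy` and `dimapd`.
#' @param phases phase tibble (cells labelled "S" and "G1G2").
#' @param shift_first,shift_second optional manual multiplicative shifts
#'   for branch 1 / branch 2.
#' @param headroom upper tolerance above twice the G1/G2 ploidy when
#'   choosing the integer multiplier (default 0.05).
#' @return list of class `scrt_scorrection`: `cells` tibble (cell_id,
#'   phase, branch, ploidy_raw, ploidy, replication_fraction, shift),
#'   `mode`, `first_branch_shift`, `second_branch_shift`,
#'   `g1g2_ploidy`.
#' @export
correct_s_progression <- function(qc, phases, shift_first = NULL,
                                  shift_second = NULL, headroom = 0.05) {
  ph <- phases$phase[match(qc$cell_id, phases$cell_id)]
  if (!any(ph == "G1G2", na.rm = TRUE))
    stop("no G1/G2 reference cells")
  pg <- stats::median(qc$ploidy[ph == "G1G2"], na.rm = TRUE)
  s_idx <- which(ph == "S")
  branch <- rep(NA_integer_, nrow(qc))
  branch[s_idx] <- ifelse(qc$ploidy[s_idx] < pg, 2L, 1L)
  s1 <- shift_first %||% 1
  shift <- rep(1, nrow(qc))
  shift[branch %in% 1L] <- s1
  manual <- !is.null(shift_second)
  if (manual) {
    shift[branch %in% 2L] <- shift_second
  } else {
    for (i in which(branch == 2L)) {
      # smallest integer multiplier landing inside (pg, (2 + headroom) pg]
      k <- floor(pg / qc$ploidy[i]) + 1
      if (k * qc$ploidy[i] > (2 + headroom) * pg)
        k <- max(k - 1, 1)   # overshoot: stay at the nearest admissible
      shift[i] <- k
    }
  }
  corrected <- qc$ploidy * shift
  s2 <- if (manual) shift_second else
    if (any(branch == 2L, na.rm = TRUE))
      stats::median(shift[which(branch == 2L)]) else 1
  mode <- if (manual) "manual" else
    if (n_density_modes(corrected[s_idx]) > 1L) "bimodal" else "monomodal"
  repfrac <- pmin(pmax((corrected - pg) / pg, 0), 1)
  repfrac[is.na(ph) | ph != "S"] <- NA_real_
  cells <- tibble::tibble(cell_id = qc$cell_id, phase = ph, branch = branch,
                          ploidy_raw = qc$ploidy, ploidy = corrected,
                          replication_fraction = repfrac, shift = shift)
  structure(list(cells = cells, mode = mode, first_branch_shift = s1,
                 second_branch_shift = s2, g1g2_ploidy = pg),
            class = "scrt_scorrection")
}

# internal: count well-separated modes of a kernel density estimate;
# KDE wiggles on flat distributions do not count as extra modes
n_density_modes <- function(x, adjust = 2) {
  if (length(x) < 5L || stats::sd(x) == 0) return(1L)
  y <- stats::density(x, adjust = adjust)$y
  peaks <- which(diff(sign(diff(y))) == -2L) + 1L
  if (length(peaks) < 2L) return(max(length(peaks), 1L))
  # a second mode must rise substantially above the valley between modes
  peaks <- peaks[order(-y[peaks])]
  main <- peaks[1L]
  n <- 1L
  for (pk in peaks[-1L]) {
    valley <- min(y[seq(min(main, pk), max(main, pk))])
    if (y[pk] > 0.25 * y[main] && valley < 0.75 * y[pk]) n <- n + 1L
  }
  n
}

#' Coverage threshold from down-sampling
#'
#' Binomially thins each high-coverage cell's counts to a series of target
#' coverages, re-estimates ploidy, and reports the smallest target at
#' which at least 75% of cells stay within 5% of their original ploidy.
#' Without down-sampling data the default threshold is 160 reads per Mb
#' per haploid genome.
#'
#' @param counts bins x cells raw counts of high-coverage cells (NULL to
#'   return the default).
#' @param bins bin table.
#' @param target_rpmbs increasing vector of target coverages (reads per Mb
#'   of usable genome).
#' @param n_reps thinning replicates per target (default 1).
#' @param seed RNG seed.
#' @param keep_fraction required fraction of stable cells (default 0.75).
#' @param tolerance relative ploidy deviation considered stable (0.05).
#' @param ... passed to [call_cnv()] (e.g. ploidy_limits).
#' @return list of class `scrt_coverage_threshold`: `rpmb_per_haploid`,
#'   `curve` tibble (target_rpmb, fraction_within), `default_used`.
#' @export
coverage_threshold_by_downsampling <- function(counts = NULL, bins = NULL,
                                               target_rpmbs = NULL,
                                               n_reps = 1L, seed = 1L,
                                               keep_fraction = 0.75,
                                               tolerance = 0.05, ...) {
  if (is.null(counts) || is.null(target_rpmbs)) {
    return(structure(list(rpmb_per_haploid = 160,
                          curve = tibble::tibble(target_rpmb = numeric(0),
                                                 fraction_within = numeric(0)),
                          default_used = TRUE),
                     class = "scrt_coverage_threshold"))
  }
  counts <- as.matrix(counts)
  set.seed(seed)
  extra <- list(...)
  cnv_call <- function(x) do.call(call_cnv,
                                  c(list(x, bins, min_reads = 0), extra))
  usable_mb <- sum((bins$end - bins$start)[bins$usable]) / 1e6
  base <- cnv_call(counts)
  p0 <- base$qc$ploidy[match(colnames(counts), base$qc$cell_id)]
  rpmb0 <- colSums(counts) / usable_mb
  if (any(rpmb0 < max(target_rpmbs)))
    stop("cells must exceed the maximum target coverage")
  frac <- vapply(sort(target_rpmbs), function(tgt) {
    ok <- replicate(n_reps, {
      thin <- vapply(seq_len(ncol(counts)), function(x) {
        stats::rbinom(nrow(counts), counts[, x], tgt / rpmb0[x])
      }, numeric(nrow(counts)))
      colnames(thin) <- colnames(counts)
      est <- cnv_call(thin)
      p1 <- est$qc$ploidy[match(colnames(counts), est$qc$cell_id)]
      abs(p1 - p0) / p0 <= tolerance
    })
    mean(ok)
  }, numeric(1))
  curve <- tibble::tibble(target_rpmb = sort(target_rpmbs),
                          fraction_within = frac)
  ok <- which(frac >= keep_fraction)
  thr <- if (length(ok)) curve$target_rpmb[min(ok)] else
    max(target_rpmbs)
  structure(list(rpmb_per_haploid = thr, curve = curve,
                 default_used = FALSE),
            class = "scrt_coverage_threshold")
}

#' Coverage per haploid genome
#'
#' Converts reads per megabase into reads per megabase per haploid genome
#' by dividing by the mean ploidy, rounding to the nearest integer as
#' conventionally reported.
#'
#' @param rpmb reads per Mb of usable genome.
#' @param ploidy mean ploidy.
#' @param digits 0 for integer reporting (default), NULL for unrounded.
#' @return coverage per haploid genome.
#' @export
per_haploid_coverage <- function(rpmb, ploidy, digits = 0) {
  x <- rpmb / ploidy
  if (is.null(digits)) x else round(x, digits)
}
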