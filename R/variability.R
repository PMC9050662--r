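#' Replication-timing variability as T-width
#'
#' Each cell is placed on a pseudo-time axis `t = replication_percentage *
#' s_length_h` (a uniform 10-h S phase by convention). For a set of bins,
#' the fraction of replicated (bin, cell) observations is aggregated in
#' pseudo-time windows (default 2.5% of S length), smoothed with isotonic
#' regression to enforce monotonicity, and T-width is the pseudo-time span
#' between the interpolated 25% and 75% crossings: the time a region needs
#' to go from replicated-in-a-quarter to replicated-in-three-quarters of
#' cells. A logistic rise of scale s gives 2 s ln 3; a linear rise over
#' the whole S phase gives half its length.
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage in [0, 1].
#' @param bin_subset integer or logical index of the bins (category) to
#'   score; default all bins.
#' @param s_length_h assumed S-phase length in hours (default 10).
#' @param window_frac pseudo-time window width as a fraction of S length
#'   (default 0.025).
#' @return list of class `scrt_twidth`: `t_width` (hours), `n_bins`,
#'   `curve` tibble (t, fraction, n_obs, fitted).
#' @export
twidth <- function(scrt, rep_pct, bin_subset = NULL, s_length_h = 10,
                   window_frac = 0.025) {
  scrt <- as.matrix(scrt)
  if (is.null(bin_subset)) bin_subset <- seq_len(ncol(scrt))
  sub <- scrt[, bin_subset, drop = FALSE]
  stat <- window_stats(sub, rep_pct, window_frac)
  tw <- crossing_width(stat$t * s_length_h, stat$frac, stat$n_obs)
  structure(list(t_width = tw$t_width, n_bins = ncol(sub),
                 curve = tibble::tibble(t = stat$t * s_length_h,
                                        fraction = stat$frac,
                                        n_obs = stat$n_obs,
                                        fitted = tw$fitted)),
            class = "scrt_twidth")
}

# internal: per-window replicated fraction for a bin subset
window_stats <- function(sub, rep_pct, window_frac) {
  w <- pmin(floor(rep_pct / window_frac), 1 / window_frac - 1)
  lv <- sort(unique(w))
  k <- vapply(lv, function(x) sum(sub[w == x, ], na.rm = TRUE), numeric(1))
  n <- vapply(lv, function(x) sum(!is.na(sub[w == x, ])), numeric(1))
  list(t = (lv + 0.5) * window_frac, frac = k / n, n_obs = n)
}

# internal: isotonic fit + interpolated 25/75% crossing span, clamped to
# the observed pseudo-time range
crossing_width <- function(t, frac, n_obs) {
  ok <- is.finite(frac) & n_obs > 0
  t <- t[ok]; frac <- frac[ok]; n_obs <- n_obs[ok]
  if (length(t) < 2L) {
    if (length(t) == 1L) return(list(t_width = 0, fitted = frac))
    stop("no defined replication fractions in the bin subset")
  }
  if (all(frac >= 1 - 1e-12) || all(frac <= 1e-12))
    stop("bin subset is uniformly replicated or unreplicated; ",
         "T-width undefined")
  fit <- stats::isoreg(t, frac)$yf
  t_at <- function(q) {
    if (fit[1L] >= q) return(t[1L])
    if (fit[length(fit)] < q) return(t[length(t)])
    i <- which(fit >= q)[1L]
    if (fit[i] == fit[i - 1L]) return(t[i])
    t[i - 1L] + (q - fit[i - 1L]) / (fit[i] - fit[i - 1L]) * (t[i] - t[i - 1L])
  }
  list(t_width = max(t_at(0.75) - t_at(0.25), 0), fitted = fit)
}

#' Built-in pseudo-bulk RT categories
#'
#' The five-class scheme (Very early > 0.8, Early (0.6, 0.8], Mid
#' (0.4, 0.6], Late (0.2, 0.4], Very late <= 0.2) and the two-class scheme
#' (Early > 0.5, Late <= 0.5).
#'
#' @param rt per-bin pseudo-bulk RT in [0, 1] (1 = early).
#' @param scheme `"five"` (default) or `"two"`.
#' @return factor of category labels (NA where rt is NA).
#' @export
rt_categories <- function(rt, scheme = c("five", "two")) {
  scheme <- match.arg(scheme)
  if (scheme == "five") {
    cut(rt, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
        labels = c("Very late", "Late", "Mid", "Early", "Very early"))
  } else {
    cut(rt, breaks = c(-Inf, 0.5, Inf), labels = c("Late", "Early"))
  }
}

#' Bootstrap comparison of two groups' T-widths
#'
#' Null-hypothesis test of equal T-width between two bin groups: bins are
#' randomly reassigned to the two groups (group sizes fixed), T-widths are
#' recomputed, and the p-value is the fraction of the N permutations whose
#' absolute T-width difference is at least the observed one (no
#' smoothing).
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage.
#' @param bins_a,bins_b integer indices of the two bin groups.
#' @param n_iter permutations (default 1e4; fewer than 100 warns).
#' @param seed RNG seed.
#' @param s_length_h,window_frac as in [twidth()].
#' @return list of class `scrt_twcompare`: `t_width_a`, `t_width_b`,
#'   `observed` (|difference|), `p`, `n_iter`, `group_sizes`.
#' @export
compare_tw <- function(scrt, rep_pct, bins_a, bins_b, n_iter = 10000L,
                       seed = 1L, s_length_h = 10, window_frac = 0.025) {
  stopifnot(length(bins_a) > 0L, length(bins_b) > 0L)
  if (n_iter < 100L) warning("fewer than 100 permutations: p resolution ",
                             "is coarse")
  scrt <- as.matrix(scrt)
  pool <- c(bins_a, bins_b)
  na <- length(bins_a)
  w <- pmin(floor(rep_pct / window_frac), 1 / window_frac - 1)
  lv <- sort(unique(w))
  # per-window, per-bin sufficient statistics over the pooled bins
  k_wb <- vapply(lv, function(x)
    colSums(scrt[w == x, pool, drop = FALSE], na.rm = TRUE),
    numeric(length(pool)))
  n_wb <- vapply(lv, function(x)
    colSums(!is.na(scrt[w == x, pool, drop = FALSE])),
    numeric(length(pool)))
  t_h <- (lv + 0.5) * window_frac * s_length_h
  tw_of <- function(sel) {
    k <- colSums(k_wb[sel, , drop = FALSE])
    n <- colSums(n_wb[sel, , drop = FALSE])
    crossing_width(t_h, k / n, n)$t_width
  }
  idx_a <- seq_len(na)
  obs_a <- tw_of(idx_a)
  obs_b <- tw_of(-idx_a)
  observed <- abs(obs_a - obs_b)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_iter)) {
    p <- sample.int(length(pool))
    d <- abs(tw_of(p[idx_a]) - tw_of(p[-idx_a]))
    if (d >= observed) exceed <- exceed + 1L
  }
  structure(list(t_width_a = obs_a, t_width_b = obs_b, observed = observed,
                 p = exceed / n_iter, n_iter = n_iter,
                 group_sizes = c(length(bins_a), length(bins_b)),
                 seed = seed),
            class = "scrt_twcompare")
}
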