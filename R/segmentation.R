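# Change-point segmentation of per-bin read-depth signals.
#
# The default engine is exact penalized least-squares partitioning (PELT
# pruning) under a BIC-style cost of penalty * sigma^2 * log(n) per
# breakpoint; replicating cells produce alternating square-wave profiles
# on which greedy splitting stalls, so an exact optimiser is required.
# Greedy binary segmentation and a circular variant ("cbs", which
# re-tests each accepted segment for an internal (start, end) pair) are
# available behind the same interface.

# internal: best single split of x[lo..hi]; returns (gain, split index)
best_split <- function(cs, cs2, lo, hi, min_width) {
  n <- hi - lo + 1L
  if (n < 2L * min_width) return(c(0, NA))
  total_sum <- cs[hi + 1L] - cs[lo]
  sse0 <- (cs2[hi + 1L] - cs2[lo]) - total_sum^2 / n
  k <- (lo + min_width - 1L):(hi - min_width)   # last index of left part
  nl <- k - lo + 1L
  nr <- n - nl
  sl <- cs[k + 1L] - cs[lo]
  sr <- total_sum - sl
  sse1 <- (cs2[hi + 1L] - cs2[lo]) - sl^2 / nl - sr^2 / nr
  i <- which.min(sse1)
  c(sse0 - sse1[i], k[i])
}

# internal: recursive binary segmentation, returns breakpoints (last index
# of each segment except the final one)
binseg_rec <- function(cs, cs2, lo, hi, thr, min_width) {
  bs <- best_split(cs, cs2, lo, hi, min_width)
  if (is.na(bs[2L]) || bs[1L] <= thr) return(integer(0))
  k <- as.integer(bs[2L])
  c(binseg_rec(cs, cs2, lo, k, thr, min_width), k,
    binseg_rec(cs, cs2, k + 1L, hi, thr, min_width))
}

# internal: optimal penalized least-squares partitioning (PELT pruning);
# returns breakpoints (last index of each segment except the final one)
pelt_segment <- function(y, beta, min_width) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sse <- function(a, b) {   # a, b inclusive 1-based
    s <- cs[b + 1L] - cs[a]
    (cs2[b + 1L] - cs2[a]) - s^2 / (b - a + 1L)
  }
  f <- rep(Inf, n + 1L)
  f[1L] <- -beta
  cp <- integer(n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    ok <- cand <= t - min_width
    if (!any(ok)) { f[t + 1L] <- Inf; cp[t + 1L] <- 0L }
    taus <- cand[ok]
    if (length(taus)) {
      costs <- f[taus + 1L] + beta +
        (cs2[t + 1L] - cs2[taus + 1L]) -
        (cs[t + 1L] - cs[taus + 1L])^2 / (t - taus)
      i <- which.min(costs)
      f[t + 1L] <- costs[i]
      cp[t + 1L] <- taus[i]
      cand <- cand[!(cand %in% taus[costs > f[t + 1L] + beta])]
    }
    if (t - min_width + 1L >= min_width || t - min_width + 1L == 0L)
      cand <- c(cand, t - min_width + 1L)
  }
  # backtrack
  bp <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- cp[t + 1L]
    if (tau > 0L) bp <- c(tau, bp)
    t <- tau
  }
  bp
}

#' Segment a per-bin signal into constant-mean pieces
#'
#' @param x numeric signal (one chromosome's corrected bin counts).
#' @param penalty multiplier of `sigma^2 * log(n)` a split must beat
#'   (default 2, the BIC cost; conservative on pure-noise input while
#'   resolving replicon-scale alternation).
#' @param min_width minimum segment length in bins (default 5).
#' @param method `"pelt"` (default; exact penalized least-squares
#'   partitioning, required for the alternating copy-number mosaics of
#'   mid-S cells where greedy splitting stalls), `"binseg"` (greedy
#'   binary segmentation) or `"cbs"` (binary segmentation with a
#'   circular re-test splitting accepted segments on an internal
#'   interval).
#' @param smooth apply a light running-median (k = 5) before locating
#'   change points (off by default: the median blunts the edges of the
#'   short alternating segments of mid-S cells); segment means are
#'   always computed from the raw signal.
#' @return integer vector assigning each position to a segment (1, 2, ...).
#' @export
segment_signal <- function(x, penalty = 2, min_width = 5L,
                           method = c("pelt", "binseg", "cbs"),
                           smooth = FALSE) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2L * min_width) return(rep(1L, max(n, 0L)))
  y <- if (smooth && n >= 5L) stats::runmed(x, 5L) else x
  # noise scale from the raw signal (the smoothed trace underestimates
  # it), using the lower quartile of |diff|: in replicating cells up to
  # half the first differences are genuine copy-number steps, which would
  # inflate a MAD estimate and cause under-segmentation. For pure
  # Gaussian noise q25(|diff|) = 0.451 sigma.
  ad <- abs(diff(x))
  sigma <- stats::quantile(ad, 0.25, names = FALSE) / 0.4506
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::mad(ad) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-12
  thr <- penalty * sigma^2 * log(n)
  if (method == "pelt") {
    bp <- pelt_segment(y, thr, min_width)
    bounds <- c(0L, bp, n)
    return(rep(seq_len(length(bounds) - 1L), diff(bounds)))
  }
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  bp <- binseg_rec(cs, cs2, 1L, n, thr, min_width)
  if (method == "cbs" && length(bp)) {
    # circular re-test: try carving an interior interval out of each segment
    bounds <- c(0L, bp, n)
    extra <- integer(0)
    for (s in seq_len(length(bounds) - 1L)) {
      lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
      if (hi - lo + 1L < 3L * min_width) next
      b1 <- best_split(cs, cs2, lo, hi, min_width)
      if (!is.na(b1[2L]) && b1[1L] > thr) {
        k <- as.integer(b1[2L])
        b2 <- best_split(cs, cs2, k + 1L, hi, min_width)
        if (!is.na(b2[2L]) && b2[1L] > thr) extra <- c(extra, k, b2[2L])
      }
    }
    bp <- sort(unique(c(bp, extra)))
  }
  bounds <- c(0L, sort(bp), n)
  lens <- diff(bounds)
  rep(seq_along(lens), lens)
}
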