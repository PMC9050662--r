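#' Round half away from zero
#'
#' Nearest-integer rounding with ties broken away from zero, the convention
#' used when converting segment read depth to integer copy number. `round()`
#' in R rounds half to even, which would map a quantised depth of exactly
#' 2.5 copies to 2; copy-number callers conventionally round 0.5 up.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Weighted median with an even-split tie rule
#'
#' Returns the value whose cumulative weight first reaches half the total.
#' When the cumulative weight hits exactly one half at a value boundary
#' (an even split), the mean of the two straddling values is returned.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w) {
  keep <- !is.na(x) & !is.na(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' Simple matching coefficient distances between binary profiles
#'
#' Distance is the fraction of disagreeing positions over positions defined
#' in both profiles (1 - simple matching coefficient).
#'
#' @param m cells x bins binary matrix (0/1, NA allowed).
#' @return symmetric cells x cells distance matrix.
#' @export
smc_distances <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  def <- !is.na(m)
  m0 <- m
  m0[!def] <- 0
  # agreements = both-1 + both-0 over shared defined bins
  both1 <- tcrossprod(m0)
  shared <- tcrossprod(def * 1)
  ones <- def * (m0 == 1)
  zeros <- def * (m0 == 0)
  both0 <- tcrossprod(zeros * 1)
  d <- 1 - (both1 + both0) / shared
  d[shared == 0] <- NA
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(m)
  d
}

#' Write a four-column bedGraph track
#'
#' @param bins data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param score numeric per-bin score; NA rows are skipped.
#' @param path output file.
#' @export
write_bedgraph <- function(bins, score, path) {
  keep <- !is.na(score)
  df <- data.frame(bins$chrom[keep], bins$start[keep], bins$end[keep],
                   score[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: step-function weighted quantile (weights act like repeat
# counts): smallest x whose cumulative weight reaches the probability
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

# internal: first local minima indices of a numeric vector, endpoints included
local_minima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  left <- c(Inf, y[-n])
  right <- c(y[-1L], Inf)
  which(y <= left & y < right | (y < left & y <= right))
}
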