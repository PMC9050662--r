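#' Embed cells in two dimensions
#'
#' Low-dimensional embedding of genome-wide single-cell copy-number
#' profiles (raw values) or binary replication profiles (simple-matching
#' distances) for sub-population discovery. t-SNE uses perplexity
#' `max(n/50, 10)`, theta 0.25 and 5000 iterations; both methods are
#' deterministic given the seed.
#'
#' @param x cells x features matrix (`input = "cnv"`) or a pairwise
#'   distance matrix / `dist` (`input = "rt-distance"`).
#' @param method `"umap"` (default) or `"tsne"`.
#' @param input `"cnv"` or `"rt-distance"`.
#' @param seed integer seed (required: embeddings are stochastic).
#' @return tibble of class `scrt_embedding`: `cell_id`, `x`, `y`.
#' @export
embed_cells <- function(x, method = c("umap", "tsne"),
                        input = c("cnv", "rt-distance"), seed) {
  method <- match.arg(method)
  input <- match.arg(input)
  if (missing(seed)) stop("an explicit seed is required")
  is_dist <- input == "rt-distance"
  ids <- if (is_dist) attr(x, "Labels") %||% rownames(as.matrix(x)) else
    rownames(x)
  m <- if (is_dist) stats::as.dist(x) else {
    mm <- as.matrix(x)
    mm[is.na(mm)] <- 0
    mm
  }
  n <- if (is_dist) attr(m, "Size") else nrow(m)
  if (n < 10L) stop("embedding needs at least 10 cells")
  if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("Rtsne is required for method = 'tsne'")
    set.seed(seed)
    perplexity <- max(n / 50, 10)
    perplexity <- min(perplexity, floor((n - 1) / 3))
    fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity, theta = 0.25,
                        max_iter = 5000, is_distance = is_dist,
                        check_duplicates = FALSE, pca = !is_dist,
                        partial_pca = !is_dist && ncol(as.matrix(x)) > 50)
    coords <- fit$Y
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("uwot is required for method = 'umap'")
    set.seed(seed)
    n_neighbors <- min(15, n - 1)
    coords <- if (is_dist) {
      uwot::umap(m, n_neighbors = n_neighbors)
    } else {
      uwot::umap(m, n_neighbors = n_neighbors)
    }
  }
  out <- tibble::tibble(cell_id = ids %||% as.character(seq_len(n)),
                        x = coords[, 1L], y = coords[, 2L])
  class(out) <- c("scrt_embedding", class(out))
  out
}

#' Label cells by manual gates on an embedding
#'
#' Gates are rectangles (`list(xmin=, xmax=, ymin=, ymax=)`) or polygons
#' (two-column matrix of vertices); boundaries are inside (closed gates).
#' Cells outside all gates are labelled "none". S-phase gates can be
#' mapped to their matching G1/G2 gate via `reference_of` so each
#' sub-population is normalised against its own G1/G2 pool downstream.
#'
#' @param embedding tibble from [embed_cells()].
#' @param gates named list of gates.
#' @param reference_of optional named character vector mapping S gate
#'   names to G1/G2 gate names.
#' @return tibble `cell_id`, `label`, `reference`.
#' @export
gate_subpopulations <- function(embedding, gates, reference_of = NULL) {
  label <- rep("none", nrow(embedding))
  for (g in names(gates)) {
    gate <- gates[[g]]
    inside <- if (is.matrix(gate)) {
      point_in_polygon(embedding$x, embedding$y, gate)
    } else {
      embedding$x >= gate$xmin & embedding$x <= gate$xmax &
        embedding$y >= gate$ymin & embedding$y <= gate$ymax
    }
    label[inside & label == "none"] <- g
  }
  reference <- if (is.null(reference_of)) NA_character_ else
    unname(reference_of[label])
  tibble::tibble(cell_id = embedding$cell_id, label = label,
                 reference = reference)
}

# internal: even-odd ray casting, boundary points count as inside
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # boundary check
    d <- abs((xj - xi) * (py - yi) - (px - xi) * (yj - yi))
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (d < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Per-bin replication probability at an S-phase stage
#'
#' Fraction of stage-gated cells with the bin replicated. Stages follow
#' the representative gates: early-S cells have completed at most 30% of
#' replication, mid-S 40-60%, late-S at least 70%.
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage.
#' @param stage `"early"`, `"mid"`, `"late"`, or a numeric
#'   `c(min, max)` gate on the replication percentage (closed bounds).
#' @param gates named list overriding the default stage bounds.
#' @return list of class `scrt_stageprob`: `probability` per bin,
#'   `n_cells`, `stage`.
#' @export
stage_probability <- function(scrt, rep_pct,
                              stage = c("early", "mid", "late"),
                              gates = list(early = c(0, 0.30),
                                           mid = c(0.40, 0.60),
                                           late = c(0.70, 1))) {
  if (is.character(stage)) {
    stage <- match.arg(stage)
    bounds <- gates[[stage]]
  } else {
    bounds <- stage
    stage <- sprintf("[%g, %g]", bounds[1L], bounds[2L])
  }
  sel <- which(rep_pct >= bounds[1L] & rep_pct <= bounds[2L])
  if (!length(sel)) stop("empty stage: no cells in ", stage)
  p <- colMeans(as.matrix(scrt)[sel, , drop = FALSE], na.rm = TRUE)
  p[!is.finite(p)] <- NA_real_
  structure(list(probability = p, n_cells = length(sel), stage = stage),
            class = "scrt_stageprob")
}

#' Initiation probability landscape from early-S cells
#'
#' The per-bin probability of being replicated in early S-phase cells
#' (at most 30% of the genome replicated), the input landscape expected by
#' stochastic replication simulators.
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage.
#' @param max_pct early-S gate (default 0.30).
#' @return numeric per-bin landscape (non-negative; NA on masked bins).
#' @export
extract_ipls <- function(scrt, rep_pct, max_pct = 0.30) {
  sp <- stage_probability(scrt, rep_pct, stage = c(0, max_pct))
  sp$probability
}

#' Out-of-schedule replication events
#'
#' Flags bins replicated far ahead of or behind their population timing:
#' late bins (pseudo-bulk RT < 0.5) replicated in early-S cells (at most
#' 30% replicated) and early bins (RT > 0.5) unreplicated in late-S cells
#' (at least 70% replicated). Reports per-cell event counts and rates
#' (events over opportunities), per-bin recurrence (number of distinct
#' cells sharing the event) and event-run lengths, which show whether
#' events cluster into large domains.
#'
#' @param scrt cells x bins binary matrix.
#' @param rep_pct per-cell replication percentage.
#' @param rt per-bin pseudo-bulk RT in [0, 1] (1 = early).
#' @param early_max,late_min stage gates (defaults 0.30 and 0.70).
#' @return list of class `scrt_events`: `cells` tibble (cell_id, stage,
#'   n_events, n_opportunities, rate), `recurrence` tibbles for early and
#'   late events, `run_lengths`, `early_rate`, `late_rate`.
#' @export
out_of_schedule <- function(scrt, rep_pct, rt, early_max = 0.30,
                            late_min = 0.70) {
  scrt <- as.matrix(scrt)
  ids <- rownames(scrt) %||% as.character(seq_len(nrow(scrt)))
  late_bins <- which(!is.na(rt) & rt < 0.5)
  early_bins <- which(!is.na(rt) & rt > 0.5)
  early_cells <- which(rep_pct <= early_max)
  late_cells <- which(rep_pct >= late_min)
  ev_early <- scrt[early_cells, late_bins, drop = FALSE] == 1
  ev_late <- scrt[late_cells, early_bins, drop = FALSE] == 0
  cell_tab <- function(ev, cells, stage) {
    tibble::tibble(cell_id = ids[cells], stage = stage,
                   n_events = rowSums(ev, na.rm = TRUE),
                   n_opportunities = rowSums(!is.na(ev)),
                   rate = rowSums(ev, na.rm = TRUE) / rowSums(!is.na(ev)))
  }
  cells <- dplyr::bind_rows(cell_tab(ev_early, early_cells, "early"),
                            cell_tab(ev_late, late_cells, "late"))
  rec <- function(ev, bins) {
    tibble::tibble(bin = bins, recurrence = colSums(ev, na.rm = TRUE))
  }
  runs <- function(ev) {
    if (!nrow(ev)) return(integer(0))
    unlist(apply(ev, 1L, function(z) {
      z[is.na(z)] <- FALSE
      r <- rle(z)
      r$lengths[r$values]
    }), use.names = FALSE)
  }
  rate_of <- function(ev) {
    n <- sum(!is.na(ev))
    if (n == 0) NA_real_ else sum(ev, na.rm = TRUE) / n
  }
  structure(list(cells = cells,
                 recurrence = list(early = rec(ev_early, late_bins),
                                   late = rec(ev_late, early_bins)),
                 run_lengths = list(early = runs(ev_early),
                                    late = runs(ev_late)),
                 early_rate = rate_of(ev_early),
                 late_rate = rate_of(ev_late)),
            class = "scrt_events")
}

#' Binarisation noise floor from G1/G2 cells
#'
#' Pushes G1/G2 cells through the same normalisation and binarisation as S
#' cells and measures the apparent early-event rate on late bins. Real
#' out-of-schedule replication in early-S cells should exceed this control
#' (a one-sided paired comparison across bins is the standard test).
#'
#' @param cn200_g G1/G2 cells x bins CN matrix.
#' @param cng G1/G2 reference profile.
#' @param rt per-bin pseudo-bulk RT.
#' @return list: `rate` (apparent event rate on late bins), `per_bin`
#'   probability vector.
#' @export
g1g2_noise_floor <- function(cn200_g, cng, rt) {
  rtm <- build_rt_matrix(cn200_g, cng, smc = FALSE)
  late_bins <- which(!is.na(rt) & rt < 0.5)
  ev <- rtm$scrt[, late_bins, drop = FALSE] == 1
  list(rate = sum(ev, na.rm = TRUE) / sum(!is.na(ev)),
       per_bin = colMeans(rtm$scrt == 1, na.rm = TRUE))
}
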