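# Pattern comparison metrics: the 16-bin neighborhood error E16D, the
# scale-by-scale error Esbs, the time-averaged L1 neighborhood objective
# used for parameter optimization, and PCA of error-vector populations.

#' Neighborhood-configuration error E16D
#'
#' L2 norm, normalized by the scale count ns, of the 16-dimensional vector
#' of differences (simulated minus observed) in neighbor-configuration
#' counts n(S, i), S in (green, black), i in 0..7:
#' E16D = (1/ns) sqrt(sum_i (dGreen_i)^2 + (dBlack_i)^2).
#'
#' @param lattice a `scale_lattice`.
#' @param sim,obs `pattern_state`s on that lattice.
#' @return list with `value` (scalar) and `vector` (the 16 signed
#'   differences divided by ns, so that its L2 norm equals `value`;
#'   ordered green 0..7 then black 0..7).
#' @export
e16d <- function(lattice, sim, obs) {
  if (length(sim$states) != length(obs$states))
    stop("pattern size mismatch")
  ns <- length(sim$states)
  d <- (neighbor_stats(lattice, sim) - neighbor_stats(lattice, obs))
  vec <- c(d["green", ], d["black", ]) / ns
  names(vec) <- c(paste0("green", 0:7), paste0("black", 0:7))
  list(value = sqrt(sum(vec^2)), vector = vec)
}

#' Scale-by-scale error Esbs
#'
#' Color mode: Esbs = (1/ns) sum_i ||C_i^sim - C_i^obs|| / ||Cb - Cg||.
#' Binary mode (two `pattern_state`s): reduces to the fraction of
#' mismatched scales.
#'
#' @param sim,obs two `color_state`s or two `pattern_state`s on the same
#'   lattice.
#' @param clusters a `color_clusters` supplying Cg, Cb (required in color
#'   mode).
#' @return scalar error (binary mode in \[0, 1\]).
#' @export
esbs <- function(sim, obs, clusters = NULL) {
  if (inherits(sim, "pattern_state")) {
    if (length(sim$states) != length(obs$states)) stop("size mismatch")
    return(mean(sim$states != obs$states))
  }
  stopifnot(inherits(sim, "color_state"), inherits(obs, "color_state"))
  if (is.null(clusters)) stop("color mode requires cluster centers")
  sep <- sqrt(sum((clusters$Cb - clusters$Cg)^2))
  if (sep < 1e-12) stop("Cg and Cb coincide")
  d <- sqrt(rowSums((sim$colors - obs$colors)^2))
  mean(d) / sep
}

#' Time-averaged L1 neighborhood objective
#'
#' f = (1/nk) sum_k (1/ns) sum_i |dGreen_i| + |dBlack_i| at time k. Color
#' series are thresholded to patterns by nearest cluster center first.
#'
#' @param lattice a `scale_lattice`.
#' @param sim_series,obs_series lists of `pattern_state`s (or
#'   `color_state`s, thresholded with `clusters`), aligned in time.
#' @param clusters a `color_clusters`, needed when either series is colors.
#' @return scalar objective f >= 0.
#' @export
pattern_objective <- function(lattice, sim_series, obs_series,
                              clusters = NULL) {
  if (length(sim_series) != length(obs_series))
    stop("time grids are misaligned")
  ns <- n_scales(lattice)
  as_pattern <- function(x) {
    if (inherits(x, "pattern_state")) x else threshold_colors(x, clusters)
  }
  vals <- mapply(function(s, o) {
    d <- neighbor_stats(lattice, as_pattern(s)) -
      neighbor_stats(lattice, as_pattern(o))
    sum(abs(d)) / ns
  }, sim_series, obs_series)
  mean(vals)
}

#' PCA of a population of 16-dimensional error vectors
#'
#' Centered principal component analysis of error vectors (rows); returns
#' explained-variance ratios and low-dimensional projections.
#'
#' @param vectors m x 16 matrix (rows = error vectors, e.g. `e16d()$vector`).
#' @param ncomp number of components to return (<= min(m - 1, 16)).
#' @return list with `components` (16 x ncomp loadings), `eigenvalues`,
#'   `explained` (variance ratios), `projections` (m x ncomp scores).
#' @export
error_pca <- function(vectors, ncomp = 3) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("need at least 2 vectors")
  ncomp <- min(ncomp, ncol(vectors), nrow(vectors) - 1)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(components = pc$rotation[, seq_len(ncomp), drop = FALSE],
       eigenvalues = ev,
       explained = ev / sum(ev),
       projections = pc$x[, seq_len(ncomp), drop = FALSE])
}
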