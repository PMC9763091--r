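# Polygonal scale lattices: construction, geometry bookkeeping and
# per-pattern neighborhood statistics shared by every model in the package.

## ---- low-level polygon geometry -------------------------------------------

#' Polygon area (shoelace formula)
#'
#' @param poly numeric matrix (m x 2) of vertices, open loop (last vertex
#'   implicitly connects to the first).
#' @return positive area.
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Clip a convex polygon by the half-plane {x : (x - p) . n <= 0}
# (Sutherland-Hodgman, single edge). Returns matrix possibly with 0 rows.
clip_halfplane <- function(poly, p, n) {
  m <- nrow(poly)
  if (m == 0L) return(poly)
  d <- (poly[, 1] - p[1]) * n[1] + (poly[, 2] - p[2]) * n[2]
  inside <- d <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, m + 2L, 2L); k <- 0L
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if (inside[i]) { k <- k + 1L; out[k, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Length of the chord where polygon boundary meets the perpendicular
# bisector of segment (ci, cj); this is the shared Voronoi edge length.
# Vertices lying on the bisector within a relative tolerance are included:
# for a Voronoi cell the shared edge lies exactly on the bisector, so its
# endpoints are on-line rather than crossings.
bisector_chord <- function(poly, ci, cj) {
  n <- cj - ci
  nn <- sqrt(sum(n^2))
  p <- (ci + cj) / 2
  # signed distance of vertices to the bisector line
  d <- ((poly[, 1] - p[1]) * n[1] + (poly[, 2] - p[2]) * n[2]) / nn
  diam <- max(abs(poly[, 1] - ci[1]), abs(poly[, 2] - ci[2])) + nn
  tol <- 1e-9 * diam
  m <- nrow(poly)
  pts <- poly[abs(d) <= tol, , drop = FALSE]
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    if ((d[i] < -tol && d[j] > tol) || (d[i] > tol && d[j] < -tol)) {
      t <- d[i] / (d[i] - d[j])
      pts <- rbind(pts, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(pts) < 2L) return(0)
  tdir <- c(-n[2], n[1]) / nn
  s <- pts %*% tdir
  as.numeric(max(s) - min(s))
}

## ---- ScaleLattice -----------------------------------------------------------

#' Construct a ScaleLattice object
#'
#' Container for a polygonal tessellation of skin scales: scale centers,
#' cell polygons, symmetric adjacency, cell areas \eqn{A_i}, shared-edge
#' lengths \eqn{L_{ij}}, the interscale boundary width \eqn{\epsilon} and
#' the mean edge length \eqn{S}. Geometry is unit-agnostic (pixels or mm).
#'
#' @param centers n x 2 matrix of scale centers.
#' @param polygons list of n vertex matrices (open loops).
#' @param adjacency list of n integer vectors of neighbor indices.
#' @param areas numeric vector of cell areas.
#' @param edge_lengths n x n sparse symmetric matrix of shared-edge lengths.
#' @param epsilon interscale boundary width (same units as centers).
#' @param S mean shared-edge length; computed from `edge_lengths` if `NULL`.
#' @return object of class `scale_lattice`.
#' @export
scale_lattice <- function(centers, polygons, adjacency, areas, edge_lengths,
                          epsilon = 1, S = NULL) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  stopifnot(length(polygons) == n, length(adjacency) == n, length(areas) == n)
  if (any(areas <= 0)) stop("all cell areas must be positive")
  for (i in seq_len(n)) {
    if (any(adjacency[[i]] == i)) stop("adjacency must be irreflexive")
    for (j in adjacency[[i]]) {
      if (!(i %in% adjacency[[j]])) stop("adjacency must be symmetric")
    }
  }
  if (is.null(S)) {
    el <- edge_lengths[lower.tri(edge_lengths)]
    el <- el[el > 0]
    S <- if (length(el)) mean(el) else sqrt(mean(areas) / (3 * sqrt(3) / 2))
  }
  structure(list(centers = centers, polygons = polygons,
                 adjacency = adjacency, areas = as.numeric(areas),
                 edge_lengths = edge_lengths, epsilon = epsilon, S = S),
            class = "scale_lattice")
}

#' @export
print.scale_lattice <- function(x, ...) {
  deg <- lengths(x$adjacency)
  cat(sprintf("scale_lattice: %d scales, mean degree %.2f, S = %.4g, epsilon = %.4g\n",
              nrow(x$centers), mean(deg), x$S, x$epsilon))
  invisible(x)
}

#' Number of scales in a lattice
#' @param lattice a `scale_lattice`.
#' @return integer count.
#' @export
n_scales <- function(lattice) nrow(lattice$centers)

#' Build a regular hexagonal scale lattice
#'
#' Cells are regular hexagons of edge length `S` arranged in `ny` offset rows
#' of `nx` cells; interior cells have six neighbors. For this lattice the
#' general polygon quantities reduce exactly to \eqn{A_i = (3\sqrt{3}/2)S^2}
#' and \eqn{L_{ij} = S}.
#'
#' @param nx,ny cell counts per row / number of rows (>= 1).
#' @param S hexagon edge length (> 0).
#' @param epsilon interscale boundary width; default 1.
#' @return a `scale_lattice`.
#' @examples
#' lat <- build_hex_lattice(3, 3, S = 2)
#' lat$areas[1] - 3 * sqrt(3) / 2 * 4   # ~ 0
#' @export
build_hex_lattice <- function(nx, ny, S, epsilon = 1) {
  if (S <= 0) stop("S must be positive")
  stopifnot(nx >= 1, ny >= 1)
  d <- sqrt(3) * S                       # center-to-center distance
  centers <- matrix(0, nx * ny, 2)
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      centers[k, ] <- c((ix - 1) * d + ((iy - 1) %% 2) * d / 2,
                        (iy - 1) * d * sqrt(3) / 2)
    }
  }
  # pointy-left hexagon: vertices at angles 0, 60, ..., 300 with radius S
  ang <- (0:5) * pi / 3
  hex <- cbind(S * cos(ang + pi / 6), S * sin(ang + pi / 6))
  polygons <- lapply(seq_len(nx * ny), function(i)
    sweep(hex, 2, centers[i, ], "+"))
  adjacency <- vector("list", nx * ny)
  tol <- 1e-8 * d
  trip_i <- integer(0); trip_j <- integer(0)
  for (i in seq_len(nx * ny)) {
    dd <- sqrt((centers[, 1] - centers[i, 1])^2 +
               (centers[, 2] - centers[i, 2])^2)
    nb <- which(dd > tol & dd < d + tol)
    adjacency[[i]] <- nb
    trip_i <- c(trip_i, rep.int(i, length(nb)))
    trip_j <- c(trip_j, nb)
  }
  edge_lengths <- Matrix::sparseMatrix(i = trip_i, j = trip_j,
                                       x = rep(S, length(trip_i)),
                                       dims = c(nx * ny, nx * ny))
  scale_lattice(centers, polygons, adjacency,
                areas = rep(3 * sqrt(3) / 2 * S^2, nx * ny),
                edge_lengths = edge_lengths, epsilon = epsilon, S = S)
}

#' Build a Voronoi scale lattice from scale centers
#'
#' Each cell is the Voronoi region of its center clipped to `clip_region`
#' (convex polygon; defaults to the bounding box of the centers). Two cells
#' are adjacent iff they share a Voronoi edge of positive length. Cells are
#' computed by half-plane clipping against the perpendicular bisectors,
#' nearest centers first, stopping once no further center can cut the cell.
#'
#' @param centers n x 2 matrix (n >= 3, distinct points).
#' @param clip_region convex polygon matrix (m x 2); default bounding box
#'   padded by half the median nearest-neighbor distance.
#' @param epsilon interscale boundary width stored on the lattice.
#' @return a `scale_lattice`.
#' @export
build_voronoi_lattice <- function(centers, clip_region = NULL, epsilon = 1) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 3) stop("need at least 3 centers")
  D2 <- as.matrix(stats::dist(centers))^2
  diag(D2) <- Inf
  if (min(D2) < 1e-20) stop("duplicate centers")
  nnd <- sqrt(apply(D2, 1, min))
  # collinearity check via covariance rank
  ev <- eigen(stats::cov(centers), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] / max(ev[1], .Machine$double.xmin) < 1e-12)
    stop("degenerate input: centers are collinear")
  if (is.null(clip_region)) {
    pad <- stats::median(nnd) / 2
    rx <- range(centers[, 1]) + c(-pad, pad)
    ry <- range(centers[, 2]) + c(-pad, pad)
    clip_region <- cbind(c(rx[1], rx[2], rx[2], rx[1]),
                         c(ry[1], ry[1], ry[2], ry[2]))
  }
  polygons <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- clip_region
    ord <- order(D2[i, ])
    for (j in ord) {
      dij2 <- D2[i, j]
      if (!is.finite(dij2)) break
      # farthest current vertex from the center bounds future cuts
      r2 <- max((poly[, 1] - centers[i, 1])^2 + (poly[, 2] - centers[i, 2])^2)
      if (dij2 / 4 > r2) break
      mid <- (centers[i, ] + centers[j, ]) / 2
      poly <- clip_halfplane(poly, mid, centers[j, ] - centers[i, ])
      if (nrow(poly) == 0L) stop("center ", i, " has empty Voronoi cell")
    }
    polygons[[i]] <- poly
  }
  areas <- vapply(polygons, polygon_area, 0)
  adjacency <- vector("list", n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  scale_tol <- stats::median(nnd)
  for (i in seq_len(n)) {
    r2 <- max((polygons[[i]][, 1] - centers[i, 1])^2 +
              (polygons[[i]][, 2] - centers[i, 2])^2)
    cand <- which(D2[i, ] / 4 <= r2 * (1 + 1e-9))
    nb <- integer(0); nl <- numeric(0)
    for (j in cand) {
      L <- bisector_chord(polygons[[i]], centers[i, ], centers[j, ])
      if (L > 1e-9 * scale_tol) { nb <- c(nb, j); nl <- c(nl, L) }
    }
    adjacency[[i]] <- nb
    trip_i <- c(trip_i, rep.int(i, length(nb)))
    trip_j <- c(trip_j, nb); trip_x <- c(trip_x, nl)
  }
  # symmetrize edge lengths (chord computed from either cell is identical up
  # to clipping roundoff; keep the mean)
  E <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n))
  E <- (E + Matrix::t(E)) / 2
  adjacency <- lapply(seq_len(n), function(i) sort(unique(c(
    adjacency[[i]], which(E[i, ] > 0)))))
  scale_lattice(centers, polygons, adjacency, areas, E, epsilon = epsilon)
}

## ---- pattern / color states -------------------------------------------------

#' Per-scale binary pattern state
#'
#' @param states character or factor vector with values "green"/"black".
#' @param time time-point tag (numeric), default `NA`.
#' @return object of class `pattern_state`.
#' @export
pattern_state <- function(states, time = NA_real_) {
  states <- as.character(states)
  if (!all(states %in% c("green", "black")))
    stop("states must be 'green' or 'black'")
  structure(list(states = states, time = time), class = "pattern_state")
}

#' @export
print.pattern_state <- function(x, ...) {
  cat(sprintf("pattern_state: %d scales (%d green, %d black), time = %s\n",
              length(x$states), sum(x$states == "green"),
              sum(x$states == "black"), format(x$time)))
  invisible(x)
}

#' Per-scale continuous CIELAB color state
#'
#' @param colors n x 3 matrix of CIELAB (L*, a*, b*) triples; L* in \[0, 100\].
#' @param time time-point tag.
#' @return object of class `color_state`.
#' @export
color_state <- function(colors, time = NA_real_) {
  colors <- as.matrix(colors)
  stopifnot(ncol(colors) == 3)
  if (any(colors[, 1] < -1e-9 | colors[, 1] > 100 + 1e-9))
    stop("L* must lie in [0, 100]")
  colnames(colors) <- c("L", "a", "b")
  structure(list(colors = colors, time = time), class = "color_state")
}

#' @export
print.color_state <- function(x, ...) {
  cat(sprintf("color_state: %d scales, mean L* = %.1f, time = %s\n",
              nrow(x$colors), mean(x$colors[, 1]), format(x$time)))
  invisible(x)
}

## ---- neighborhood statistics ------------------------------------------------

#' Count of isochromatic neighbors per scale
#'
#' @param lattice a `scale_lattice`.
#' @param pattern a `pattern_state` on the same lattice.
#' @param cap maximum count reported (irregular Voronoi cells can have more
#'   than 7 neighbors; counts are clipped to keep the 16-configuration set).
#' @return integer vector, one entry per scale, in `0:cap`.
#' @export
iso_neighbor_counts <- function(lattice, pattern, cap = 7L) {
  s <- pattern$states
  if (length(s) != n_scales(lattice)) stop("pattern/lattice size mismatch")
  cnt <- vapply(seq_along(s), function(i)
    sum(s[lattice$adjacency[[i]]] == s[i]), 0L)
  pmin(cnt, cap)
}

#' Neighborhood-configuration counts n(S, i)
#'
#' Tabulates, for each state S in (green, black) and each isochromatic
#' neighbor count i in 0..7, the number of scales in that configuration.
#' Boundary scales enter with their actual (reduced) neighbor counts unless
#' `include_boundary = FALSE`, in which case scales with fewer neighbors
#' than `interior_degree` are dropped.
#'
#' @inheritParams iso_neighbor_counts
#' @param include_boundary include scales on the jagged patch boundary.
#' @param interior_degree neighbor count defining "interior" (default 6).
#' @return 2 x 8 integer matrix with rownames green/black, colnames 0..7;
#'   entries sum to the number of scales counted.
#' @export
neighbor_stats <- function(lattice, pattern, include_boundary = TRUE,
                           interior_degree = 6L) {
  cnt <- iso_neighbor_counts(lattice, pattern)
  keep <- if (include_boundary) rep(TRUE, length(cnt)) else
    lengths(lattice$adjacency) >= interior_degree
  tab <- matrix(0L, 2, 8, dimnames = list(c("green", "black"), 0:7))
  for (i in which(keep)) {
    tab[pattern$states[i], cnt[i] + 1L] <- tab[pattern$states[i], cnt[i] + 1L] + 1L
  }
  tab
}

#' Number of scales whose label differs between two patterns
#'
#' @param p1,p2 `pattern_state`s on the same lattice.
#' @return integer flip count (Hamming distance).
#' @export
flips_between <- function(p1, p2) {
  if (length(p1$states) != length(p2$states))
    stop("pattern size mismatch")
  sum(p1$states != p2$states)
}

## ---- serialization ----------------------------------------------------------

#' Write / read a lattice as JSON
#'
#' Stores centers, polygons, adjacency (1-based), areas, positive edge
#' lengths as (i, j, L) triplets, epsilon and S.
#'
#' @param lattice a `scale_lattice`.
#' @param path file path.
#' @return `read_lattice_json` returns a `scale_lattice`.
#' @export
write_lattice_json <- function(lattice, path) {
  E <- Matrix::summary(Matrix::triu(lattice$edge_lengths))
  obj <- list(centers = unname(lattice$centers),
              polygons = lapply(lattice$polygons, unname),
              adjacency = lattice$adjacency,
              areas = lattice$areas,
              edges = data.frame(i = E$i, j = E$j, L = E$x),
              epsilon = lattice$epsilon, S = lattice$S)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lattice_json
#' @export
read_lattice_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- nrow(obj$centers)
  E <- Matrix::sparseMatrix(i = obj$edges$i, j = obj$edges$j, x = obj$edges$L,
                            dims = c(n, n))
  E <- E + Matrix::t(E)
  adj <- lapply(obj$adjacency, as.integer)
  polys <- lapply(obj$polygons, function(p) matrix(unlist(p), ncol = 2))
  scale_lattice(obj$centers, polys, adj, obj$areas, E,
                epsilon = obj$epsilon, S = obj$S)
}

#' Write / read pattern and color time series as CSV
#'
#' Patterns: columns scale_id, time, state. Colors: scale_id, time, L, a, b.
#'
#' @param x list of `pattern_state` or `color_state` objects.
#' @param path file path.
#' @return read functions return a list of states ordered by time.
#' @export
write_states_csv <- function(x, path) {
  rows <- lapply(x, function(st) {
    if (inherits(st, "pattern_state")) {
      data.frame(scale_id = seq_along(st$states), time = st$time,
                 state = st$states)
    } else {
      data.frame(scale_id = seq_len(nrow(st$colors)), time = st$time,
                 L = st$colors[, 1], a = st$colors[, 2], b = st$colors[, 3])
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$time), function(d) {
    d <- d[order(d$scale_id), ]
    if ("state" %in% names(d)) pattern_state(d$state, time = d$time[1])
    else color_state(as.matrix(d[, c("L", "a", "b")]), time = d$time[1])
  })
}
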