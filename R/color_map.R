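# CIELAB color handling and the affine transforms linking color space to
# the RD concentration space: projection onto the green-black color line
# (T1), transfer to the dominating-eigenvector line (T2), contraction
# toward the HSS (T3), and the PCA-ellipsoid map Te back to colors.

#' Convert sRGB colors to CIELAB
#'
#' Uses the D65/2-degree standard observer via [grDevices::convertColor()].
#'
#' @param rgb n x 3 matrix with components in \[0, 1\].
#' @return n x 3 CIELAB matrix.
#' @export
rgb_to_lab <- function(rgb) {
  out <- grDevices::convertColor(as.matrix(rgb), from = "sRGB", to = "Lab")
  colnames(out) <- c("L", "a", "b")
  out
}

#' @rdname rgb_to_lab
#' @param lab n x 3 CIELAB matrix.
#' @export
lab_to_rgb <- function(lab) {
  grDevices::convertColor(as.matrix(lab), from = "Lab", to = "sRGB")
}

#' Two-cluster color classification
#'
#' K-means with k = 2 in CIELAB; centers are relabeled so the green center
#' has the higher lightness (L_g > L_b).
#'
#' @param colors a [color_state()] or n x 3 CIELAB matrix.
#' @param seed RNG seed (k-means initialization).
#' @return object of class `color_clusters` with `Cg`, `Cb` (centers),
#'   `assignment` (character vector "green"/"black").
#' @export
kmeans2 <- function(colors, seed = 1) {
  X <- if (inherits(colors, "color_state")) colors$colors else as.matrix(colors)
  if (nrow(unique(X)) < 2) stop("all colors identical; cannot cluster")
  set.seed(seed)
  km <- stats::kmeans(X, centers = 2, nstart = 10)
  g <- which.max(km$centers[, 1])
  Cg <- km$centers[g, ]; Cb <- km$centers[-g, ]
  assignment <- ifelse(km$cluster == g, "green", "black")
  structure(list(Cg = Cg, Cb = Cb, assignment = assignment),
            class = "color_clusters")
}

#' @export
print.color_clusters <- function(x, ...) {
  cat(sprintf("color_clusters: Cg = (%.1f, %.1f, %.1f), Cb = (%.1f, %.1f, %.1f), %d/%d green/black\n",
              x$Cg[1], x$Cg[2], x$Cg[3], x$Cb[1], x$Cb[2], x$Cb[3],
              sum(x$assignment == "green"), sum(x$assignment == "black")))
  invisible(x)
}

#' Threshold continuous colors to a binary pattern
#'
#' Assigns each scale to the nearer of the two cluster centers (the
#' consistent analogue, for simulated colors, of K-means thresholding of
#' observed colors).
#'
#' @param colors a [color_state()] or matrix.
#' @param clusters a `color_clusters` object.
#' @param time time tag for the returned pattern.
#' @return a [pattern_state()].
#' @export
threshold_colors <- function(colors, clusters, time = NA_real_) {
  X <- if (inherits(colors, "color_state")) colors$colors else as.matrix(colors)
  dg <- rowSums(sweep(X, 2, clusters$Cg)^2)
  db <- rowSums(sweep(X, 2, clusters$Cb)^2)
  if (inherits(colors, "color_state") && is.na(time)) time <- colors$time
  pattern_state(ifelse(dg <= db, "green", "black"), time = time)
}

## ---- homogeneous 4x4 affine maps -------------------------------------------

unit_between <- function(x, xp) {
  d <- x - xp
  nd <- sqrt(sum(d^2))
  if (nd < 1e-14) stop("degenerate line: endpoints coincide")
  d / nd
}

#' Affine transform constructors T1, T2, T3
#'
#' `affine_T1(x, xp)` projects 3-vectors orthogonally onto the line through
#' x and xp. `affine_T2(x, xp, y, yp)` maps the x--xp line onto the y--yp
#' line (x to y, xp to yp, affinely in between). `affine_T3(r, ustar)`
#' contracts points toward `ustar` by factor `r` (r = 0 collapses to ustar,
#' r = 1 is the identity). All return 4 x 4 homogeneous matrices acting on
#' (x, 1) column vectors.
#'
#' @param x,xp,y,yp length-3 vectors (line endpoints).
#' @param r contraction factor in \[0, 1\].
#' @param ustar length-3 contraction center.
#' @return 4 x 4 matrix with last row (0, 0, 0, 1).
#' @export
affine_T1 <- function(x, xp) {
  e <- unit_between(x, xp)
  Pm <- e %*% t(e)
  rbind(cbind(Pm, (diag(3) - Pm) %*% x), c(0, 0, 0, 1))
}

#' @rdname affine_T1
#' @export
affine_T2 <- function(x, xp, y, yp) {
  ex <- unit_between(x, xp); ey <- unit_between(y, yp)
  s <- sqrt(sum((y - yp)^2)) / sqrt(sum((x - xp)^2))
  Qm <- s * (ey %*% t(ex))
  rbind(cbind(Qm, y - Qm %*% x), c(0, 0, 0, 1))
}

#' @rdname affine_T1
#' @export
affine_T3 <- function(r, ustar) {
  rbind(cbind(r * diag(3), (1 - r) * ustar), c(0, 0, 0, 1))
}

#' Apply a homogeneous 4x4 affine map to 3D points
#'
#' @param Tm 4 x 4 matrix.
#' @param X n x 3 matrix (or length-3 vector).
#' @return transformed points, same shape as `X`.
#' @export
apply_affine <- function(Tm, X) {
  if (is.null(dim(X))) {
    as.numeric(Tm[1:3, 1:3] %*% X + Tm[1:3, 4])
  } else {
    Y <- t(Tm[1:3, 1:3] %*% t(as.matrix(X)) + Tm[1:3, 4])
    dimnames(Y) <- NULL
    Y
  }
}

#' Convert juvenile colors to RD initial conditions
#'
#' Composite map u1 = T3(r, u*) T2(Cg, Cb, ug, ub) T1(Cg, Cb) C: each
#' CIELAB color is projected onto the green-black color line, transferred
#' affinely to the dominating-eigenvector line between the extremities ug
#' and ub, then contracted toward the HSS by factor r.
#'
#' @param colors a [color_state()] or n x 3 CIELAB matrix.
#' @param clusters a `color_clusters` (supplies Cg, Cb).
#' @param stability a `stability_report` (supplies ug, ub, u*).
#' @param r contraction factor; defaults to the one carried by `params`
#'   upstream (pass explicitly here).
#' @return an [rd_state()] with one node per scale.
#' @export
colors_to_rd <- function(colors, clusters, stability, r = 1) {
  X <- if (inherits(colors, "color_state")) colors$colors else as.matrix(colors)
  Tm <- affine_T3(r, stability$u_star) %*%
    affine_T2(clusters$Cg, clusters$Cb, stability$ug, stability$ub) %*%
    affine_T1(clusters$Cg, clusters$Cb)
  U <- apply_affine(Tm, X)
  tm <- if (inherits(colors, "color_state")) colors$time else NA_real_
  rd_state(U[, 1], U[, 2], U[, 3], time = tm)
}

## ---- Te: RD -> color via PCA ellipsoids -------------------------------------

# eigen-decomposition of the covariance of a point cloud with sign-canonical
# eigenvectors (largest-magnitude component positive)
cloud_pca <- function(X, jitter_warn = TRUE) {
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < 1e-12 * max(vals)) {
    if (jitter_warn) warning("rank-deficient covariance; regularized with jitter")
    vals <- vals + 1e-10 * max(vals, 1e-12)
  }
  V <- eg$vectors
  for (k in 1:3) {
    m <- which.max(abs(V[, k]))
    if (V[m, k] < 0) V[, k] <- -V[, k]
  }
  list(V = V, D = vals, center = colMeans(X))
}

#' Fit the RD-to-color affine transform Te from matched point clouds
#'
#' Maps the PCA ellipsoid of the RD cloud onto the PCA ellipsoid of the
#' color cloud: Q = V_C D_C^(1/2) (V_u D_u^(1/2))^(-1), Te maps the RD
#' centroid to the color centroid. Eigenvector sign ambiguity is resolved
#' by requiring the projections of the paired points on matched axes to
#' correlate positively.
#'
#' @param rd_cloud an [rd_state()] or n x 3 matrix of (u, v, w) points.
#' @param color_cloud a [color_state()] or n x 3 CIELAB matrix, paired
#'   row-by-row with `rd_cloud`.
#' @return 4 x 4 homogeneous matrix Te.
#' @export
fit_color_transform <- function(rd_cloud, color_cloud) {
  U <- if (inherits(rd_cloud, "rd_state"))
    cbind(rd_cloud$u, rd_cloud$v, rd_cloud$w) else as.matrix(rd_cloud)
  C <- if (inherits(color_cloud, "color_state"))
    color_cloud$colors else as.matrix(color_cloud)
  stopifnot(nrow(U) == nrow(C), nrow(U) >= 4)
  pu <- cloud_pca(U); pc <- cloud_pca(C)
  # orient RD axes so paired projections correlate positively
  for (k in 1:3) {
    su <- U %*% pu$V[, k]; sc <- C %*% pc$V[, k]
    if (stats::var(su) > 0 && stats::var(sc) > 0 &&
        stats::cor(su, sc) < 0) pu$V[, k] <- -pu$V[, k]
  }
  Q <- (pc$V %*% diag(sqrt(pc$D))) %*% solve(pu$V %*% diag(sqrt(pu$D)))
  rbind(cbind(Q, pc$center - Q %*% pu$center), c(0, 0, 0, 1))
}

#' Map RD states to CIELAB colors
#'
#' Applies the affine map Te per node; lightness clipped into \[0, 100\].
#'
#' @param state an [rd_state()].
#' @param Te 4 x 4 matrix from [fit_color_transform()] (or any affine map).
#' @return a [color_state()].
#' @export
rd_to_colors <- function(state, Te) {
  U <- cbind(state$u, state$v, state$w)
  C <- apply_affine(Te, U)
  C[, 1] <- pmin(pmax(C[, 1], 0), 100)
  color_state(C, time = state$time)
}
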