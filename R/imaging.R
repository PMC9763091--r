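# Scale detection from photometric-stereo normal maps: 16-bit normal-map
# decoding, mean curvature from the fundamental forms, filtering +
# watershed + Voronoi segmentation, per-scale color extraction, cross-time
# scale matching by local affine growth, and unification into a space-time
# network with invariant topology.

#' Decode a 16-bit RGB normal map
#'
#' Each channel stores one normal component linearly transferred from
#' (-1, 1) to (0, 65535); decoding maps channel value v to 2 v / 65535 - 1.
#' Accepts a file path or an array as read by [png::readPNG()] (values in
#' \[0, 1\], i.e. already divided by 65535).
#'
#' @param image path to a 16-bit PNG, or a h x w x 3 array in \[0, 1\].
#' @param pitch physical size of one pixel (default 1).
#' @param renormalize divide by the vector norm after decoding (default
#'   TRUE; quantization leaves norms within ~1e-3 of 1).
#' @return object of class `normal_field`: arrays `n1`, `n2`, `n3`
#'   (x-right, y-up, z-out components, rows = image rows) and `pitch`.
#' @export
decode_normal_map <- function(image, pitch = 1, renormalize = TRUE) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("need a 3-channel image")
  n1 <- 2 * image[, , 1] - 1
  n2 <- 2 * image[, , 2] - 1
  n3 <- 2 * image[, , 3] - 1
  if (renormalize) {
    nn <- sqrt(n1^2 + n2^2 + n3^2)
    nn[nn == 0] <- 1
    n1 <- n1 / nn; n2 <- n2 / nn; n3 <- n3 / nn
  }
  structure(list(n1 = n1, n2 = n2, n3 = n3, pitch = pitch),
            class = "normal_field")
}

#' Encode unit normals as a 16-bit RGB array
#'
#' Inverse of [decode_normal_map()]: component c maps to (c + 1)/2,
#' quantized to 16 bits.
#'
#' @param nf a `normal_field`.
#' @return h x w x 3 array in \[0, 1\] (write with
#'   `png::writePNG(..., target = path)`; 16-bit when saved as such).
#' @export
encode_normal_map <- function(nf) {
  enc <- function(a) round((a + 1) / 2 * 65535) / 65535
  array(c(enc(nf$n1), enc(nf$n2), enc(nf$n3)), dim = c(dim(nf$n1), 3))
}

#' @export
print.normal_field <- function(x, ...) {
  cat(sprintf("normal_field: %d x %d px, pitch = %g, mean n3 = %.4f\n",
              nrow(x$n1), ncol(x$n1), x$pitch, mean(x$n3)))
  invisible(x)
}

# central differences along rows (u = x, dim 1) and columns (v = y, dim 2),
# one-pixel border left NA
central_diff <- function(A, along, h) {
  D <- array(NA_real_, dim(A))
  if (along == 1) D[2:(nrow(A) - 1), ] <- (A[3:nrow(A), ] - A[1:(nrow(A) - 2), ]) / (2 * h)
  else D[, 2:(ncol(A) - 1)] <- (A[, 3:ncol(A)] - A[, 1:(ncol(A) - 2)]) / (2 * h)
  D
}

#' Mean curvature from a normal field
#'
#' For a graph surface z(u, v) with unit normal n, the first and second
#' fundamental forms follow from z_u = -n1/n3, z_v = -n2/n3:
#' E = 1 + (n1/n3)^2, F = n1 n2 / n3^2, G = 1 + (n2/n3)^2,
#' L = -n3 d_u(n1/n3), M = -n3 d_v(n1/n3), N = -n3 d_v(n2/n3), and
#' H = (E N - 2 F M + G L) / (2 (E G - F^2)). Derivatives are central
#' differences; the one-pixel border and pixels with n3 ~ 0 are NA.
#'
#' @param nf a `normal_field`.
#' @param n3_min mask threshold on n3 (default 1e-3).
#' @return matrix H (same size as the image, NA where masked).
#' @export
mean_curvature <- function(nf, n3_min = 1e-3) {
  n1 <- nf$n1; n2 <- nf$n2; n3 <- nf$n3
  bad <- n3 < n3_min
  n3s <- ifelse(bad, NA_real_, n3)
  p <- n1 / n3s; q <- n2 / n3s     # -z_u, -z_v
  h <- nf$pitch
  E <- 1 + p^2; Fm <- p * q; G <- 1 + q^2
  L <- -n3s * central_diff(p, 1, h)
  M <- -n3s * central_diff(p, 2, h)
  N <- -n3s * central_diff(q, 2, h)
  (E * N - 2 * Fm * M + G * L) / (2 * (E * G - Fm^2))
}

#' Detect scales in a curvature field
#'
#' Gaussian filter (sigma = s/10) then median filter on H; watershed
#' segmentation of the filtered field with scales at the local minima
#' (h-minima suppression at `tol_frac` of the dynamic range); segment
#' centroids become the generators of a Voronoi scale lattice. The median
#' window defaults to s/3: it must stay well inside a scale basin, which
#' at this package's working resolutions (tens of pixels per scale) rules
#' out a full (s, s) window.
#'
#' @param H curvature matrix (NAs allowed at the border; replaced by the
#'   median before filtering).
#' @param s expected scale size in pixels (>= 10).
#' @param tol_frac watershed tolerance as a fraction of the dynamic range
#'   of the filtered field (default 0.05).
#' @param median_size median filter radius; default ~s/6 (window ~s/3).
#' @param drop_border discard watershed segments touching the image edge
#'   (clipped basins; default TRUE).
#' @param deep_frac fraction of a basin's dynamic range counted as its
#'   "deep" (near-minimum) region for center estimation.
#' @return list with `centers` (k x 2 pixel coordinates, x = row, y =
#'   column), `lattice` (a `scale_lattice`), `labels` (segment label
#'   matrix), `filtered` (the filtered curvature).
#' @export
detect_scales <- function(H, s, tol_frac = 0.05,
                          median_size = max(1L, round(s / 6)),
                          drop_border = TRUE, deep_frac = 0.3) {
  if (s < 10) stop("expected scale size must be >= 10 px")
  H[!is.finite(H)] <- stats::median(H, na.rm = TRUE)
  Hf <- EBImage::gblur(H, sigma = s / 10)
  Hf <- EBImage::medianFilter(EBImage::normalize(Hf), size = median_size)
  # watershed fills from maxima; scales are minima, so invert
  inv <- max(Hf) - Hf
  labels <- EBImage::watershed(inv, tolerance = tol_frac * diff(range(inv)),
                               ext = 1)
  if (drop_border) {
    bl <- setdiff(unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)])), 0)
    labels[labels %in% bl] <- 0L
    old <- sort(unique(labels[labels > 0]))
    labels[] <- match(labels, old, nomatch = 0L) # compact relabel
  }
  k <- max(labels)
  if (k == 0) stop("no minima found")
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  val <- Hf[labels > 0]
  # centroid of each basin's deep region (near its curvature minimum);
  # unbiased even when a basin is clipped asymmetrically
  centers <- t(vapply(seq_len(k), function(l) {
    sel <- lab == l
    v <- val[sel]
    deep <- v <= min(v) + deep_frac * (max(v) - min(v) + 1e-12)
    c(mean(idx[sel, 1][deep]), mean(idx[sel, 2][deep]))
  }, numeric(2)))
  colnames(centers) <- c("x", "y")
  lattice <- if (k >= 3)
    build_voronoi_lattice(centers,
                          clip_region = cbind(c(1, nrow(H), nrow(H), 1),
                                              c(1, 1, ncol(H), ncol(H))))
  else NULL
  list(centers = centers, lattice = lattice, labels = labels, filtered = Hf)
}

#' Extract per-scale colors from an albedo image
#'
#' Pixels are assigned to the nearest scale center (the Voronoi cell);
#' pixels closer than s/10 to the cell boundary are excluded to avoid the
#' shading artifacts of high-curvature scale rims. Returns the mean color
#' per scale plus the median and per-channel mode of the retained pixel
#' distribution (needed by the measurement-uncertainty analyses).
#'
#' @param albedo h x w x 3 array (RGB in \[0, 1\]) or h x w x 3 CIELAB
#'   array when `space = "Lab"`.
#' @param lattice a `scale_lattice` in pixel coordinates (x = row,
#'   y = column).
#' @param s expected scale size in pixels.
#' @param space `"sRGB"` (converted to CIELAB) or `"Lab"` (taken as is).
#' @return list with `mean` (a [color_state()]), `median`, `mode` (n x 3
#'   matrices), `n_pixels` (retained per scale; scales with zero retained
#'   pixels are flagged in attribute `empty` and carry NA colors).
#' @export
extract_scale_colors <- function(albedo, lattice, s, space = c("sRGB", "Lab")) {
  space <- match.arg(space)
  h <- dim(albedo)[1]; w <- dim(albedo)[2]
  px <- rep(seq_len(h), times = w); py <- rep(seq_len(w), each = h)
  cx <- lattice$centers[, 1]; cy <- lattice$centers[, 2]
  D2 <- outer(px, cx, function(a, b) (a - b)^2) +
    outer(py, cy, function(a, b) (a - b)^2)
  id1 <- max.col(-D2)
  d1 <- D2[cbind(seq_along(px), id1)]
  D2[cbind(seq_along(px), id1)] <- Inf
  id2 <- max.col(-D2)
  d2 <- D2[cbind(seq_along(px), id2)]
  cc <- sqrt((cx[id2] - cx[id1])^2 + (cy[id2] - cy[id1])^2)
  bdist <- (d2 - d1) / (2 * cc)
  keep <- bdist >= s / 10
  cols <- matrix(albedo, nrow = h * w)
  if (space == "sRGB") cols <- rgb_to_lab(cols)
  n <- n_scales(lattice)
  fid <- factor(id1[keep], levels = seq_len(n))
  agg <- function(fun) sapply(1:3, function(ch)
    as.numeric(tapply(cols[keep, ch], fid, fun)))
  mode1 <- function(x) {
    if (length(x) < 2 || stats::sd(x) == 0) return(x[1])
    de <- stats::density(x)
    de$x[which.max(de$y)]
  }
  mu <- agg(mean); md <- agg(stats::median); mo <- agg(mode1)
  npix <- as.numeric(table(fid))
  empty <- npix == 0
  if (any(empty)) warning(sum(empty), " scale(s) with zero retained pixels")
  mu[empty, ] <- NA_real_
  out_mean <- color_state(
    cbind(pmin(pmax(mu[, 1], 0), 100), mu[, 2], mu[, 3]))
  structure(list(mean = out_mean, median = md, mode = mo, n_pixels = npix),
            empty = empty, class = "scale_colors")
}

## ---- cross-time matching ----------------------------------------------------

# least-squares 2D affine from matched point pairs (>= 3), A -> B
fit_affine2d <- function(A, B) {
  X <- cbind(A, 1)
  coef <- qr.solve(X, B)          # 3 x 2
  t(coef)                         # 2 x 3: [M | t]
}

apply_affine2d <- function(Tm, P) {
  t(Tm[, 1:2] %*% t(P) + Tm[, 3])
}

#' Match scales between two lattices by local affine growth
#'
#' Starting from at least 3 seed correspondences, iteratively considers
#' lattice-A neighbors of matched scales: each candidate gets an affine
#' transform fitted on its 3-10 nearest already-matched neighbors, its
#' center is transferred, and the nearest unmatched B center is accepted
#' if closer than eps = `eps_frac` times the mean neighbor distance. Ties
#' are broken by distance then by smaller id. Iterates to a fixpoint.
#'
#' @param latticeA,latticeB `scale_lattice`s at two time points.
#' @param seed_matches m x 2 integer matrix (id in A, id in B), m >= 3.
#' @param eps_frac acceptance radius as a fraction of the mean neighbor
#'   center distance in B (default 0.05).
#' @return integer vector of length n_A: matched B id or NA; attribute
#'   `eps` records the acceptance radius.
#' @export
match_pair <- function(latticeA, latticeB, seed_matches, eps_frac = 0.05) {
  seed_matches <- matrix(as.integer(seed_matches), ncol = 2)
  if (nrow(seed_matches) < 3) stop("need at least 3 seed matches")
  A <- latticeA$centers; B <- latticeB$centers
  nA <- nrow(A)
  # mean neighbor-center distance in B
  nbd <- unlist(lapply(seq_len(nrow(B)), function(i) {
    nb <- latticeB$adjacency[[i]]
    if (!length(nb)) return(numeric(0))
    sqrt((B[nb, 1] - B[i, 1])^2 + (B[nb, 2] - B[i, 2])^2)
  }))
  eps <- eps_frac * mean(nbd)
  match <- rep(NA_integer_, nA)
  match[seed_matches[, 1]] <- seed_matches[, 2]
  used <- rep(FALSE, nrow(B))
  used[seed_matches[, 2]] <- TRUE
  repeat {
    matched_ids <- which(!is.na(match))
    frontier <- setdiff(unique(unlist(latticeA$adjacency[matched_ids])),
                        matched_ids)
    if (!length(frontier)) break
    # candidate transfers this sweep; accept deterministically afterwards
    cand <- lapply(sort(frontier), function(i) {
      dd <- sqrt((A[matched_ids, 1] - A[i, 1])^2 +
                 (A[matched_ids, 2] - A[i, 2])^2)
      take <- matched_ids[order(dd)][seq_len(min(10, length(matched_ids)))]
      if (length(take) < 3) return(NULL)
      # collinear support points make the affine underdetermined; skip the
      # candidate for this sweep (revisited once more matches exist)
      Tm <- tryCatch(fit_affine2d(A[take, , drop = FALSE],
                                  B[match[take], , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(Tm)) return(NULL)
      p <- as.numeric(apply_affine2d(Tm, A[i, , drop = FALSE]))
      db <- sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2)
      db[used] <- Inf
      j <- which.min(db)
      if (db[j] < eps) c(i = i, j = j, d = db[j]) else NULL
    })
    cand <- do.call(rbind, cand)
    if (is.null(cand) || !nrow(cand)) break
    # smaller distance first, then smaller A id; skip claimed targets
    cand <- cand[order(cand[, "d"], cand[, "i"]), , drop = FALSE]
    new_any <- FALSE
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (!is.na(match[i]) || used[j]) next
      match[i] <- j; used[j] <- TRUE; new_any <- TRUE
    }
    if (!new_any) break
  }
  attr(match, "eps") <- eps
  match
}

#' Closed-form similarity transform (rotation, isotropic scale, translation)
#'
#' Least-squares fit of x_p = s R(theta) (x_t + t) mapping target centers
#' onto reference centers, excluding shear and anisotropic scaling:
#' t aligns the centroids, then theta = arctan((mean(yr xt') - mean(xr yt'))
#' / (mean(xr xt') + mean(yr yt'))) and s follows from the normal
#' equations.
#'
#' @param ref,tgt n x 2 matrices of corresponding centers.
#' @return list with `theta`, `s`, `t` (length-2), and `transform(P)`
#'   mapping target-space points to reference space.
#' @export
fit_similarity <- function(ref, tgt) {
  stopifnot(nrow(ref) == nrow(tgt), nrow(ref) >= 2)
  tvec <- colMeans(ref) - colMeans(tgt)
  tp <- sweep(tgt, 2, colMeans(tgt))       # centered target = x_t + t - mean(ref)... centered
  rp <- sweep(ref, 2, colMeans(ref))
  num <- mean(rp[, 2] * tp[, 1] - rp[, 1] * tp[, 2])
  den <- mean(rp[, 1] * tp[, 1] + rp[, 2] * tp[, 2])
  theta <- atan2(num, den)
  s <- (cos(theta) * den + sin(theta) * num) / mean(tp[, 1]^2 + tp[, 2]^2)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ctr_t <- colMeans(tgt); ctr_r <- colMeans(ref)
  transform <- function(P)
    sweep(s * t(R %*% t(sweep(as.matrix(P), 2, ctr_t))), 2, ctr_r, "+")
  list(theta = theta, s = s, t = tvec, transform = transform)
}

#' Similarity-fit residual (sum of squared distances)
#'
#' The least-squares error E = sum_i ||x_r,i - x_p,i||^2 of mapping `tgt`
#' onto `ref` with rotation `theta`, scale `s`, and centroid-aligning
#' translation. Used for spot checks of global optimality.
#'
#' @param ref,tgt n x 2 corresponding centers.
#' @param theta,s rotation and isotropic scale.
#' @return scalar E.
#' @export
similarity_error <- function(ref, tgt, theta, s) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  P <- s * t(R %*% t(sweep(as.matrix(tgt), 2, colMeans(tgt))))
  sum((sweep(as.matrix(ref), 2, colMeans(ref)) - P)^2)
}

#' Unify pairwise matches into a space-time network
#'
#' Keeps scales matched in every time point (relative to the first), maps
#' all time points onto the first by the closed-form similarity transform,
#' averages each scale's centers across time, and rebuilds the final
#' Voronoi lattice on the averaged centers (making topology time-
#' invariant by construction).
#'
#' @param lattices list of `scale_lattice`s, one per time point.
#' @param matches list of length nt - 1: `matches[[k]]` maps ids of time
#'   point 1 to ids of time point k+1 (as returned by [match_pair()]
#'   applied to (lattice 1, lattice k+1)).
#' @param colors optional list of `color_state`s aligned with `lattices`.
#' @return object of class `space_time_network`: `lattice` (unified),
#'   `ids` (kept x nt matrix of per-time ids), `transforms` (per-time
#'   theta/s/t), `colors` (kept x 3 x nt array or NULL), `times`.
#' @export
unify_network <- function(lattices, matches, colors = NULL) {
  nt <- length(lattices)
  stopifnot(length(matches) == nt - 1)
  n1 <- n_scales(lattices[[1]])
  ids <- matrix(NA_integer_, n1, nt)
  ids[, 1] <- seq_len(n1)
  for (k in seq_len(nt - 1)) ids[, k + 1] <- matches[[k]]
  keep <- stats::complete.cases(ids)
  if (!any(keep)) stop("no scale is matched across all time points")
  ids <- ids[keep, , drop = FALSE]
  ref <- lattices[[1]]$centers[ids[, 1], , drop = FALSE]
  acc <- ref
  transforms <- vector("list", nt)
  transforms[[1]] <- list(theta = 0, s = 1, t = c(0, 0))
  for (k in 2:nt) {
    tgt <- lattices[[k]]$centers[ids[, k], , drop = FALSE]
    fit <- fit_similarity(ref, tgt)
    transforms[[k]] <- fit[c("theta", "s", "t")]
    acc <- acc + fit$transform(tgt)
  }
  avg <- acc / nt
  lattice <- build_voronoi_lattice(avg, epsilon = lattices[[1]]$epsilon)
  col_arr <- NULL
  if (!is.null(colors)) {
    col_arr <- array(NA_real_, c(nrow(ids), 3, nt))
    for (k in seq_len(nt))
      col_arr[, , k] <- colors[[k]]$colors[ids[, k], , drop = FALSE]
  }
  structure(list(lattice = lattice, ids = ids, transforms = transforms,
                 colors = col_arr,
                 times = vapply(seq_len(nt), function(k)
                   if (!is.null(colors)) colors[[k]]$time else k, 0)),
            class = "space_time_network")
}

#' @export
print.space_time_network <- function(x, ...) {
  cat(sprintf("space_time_network: %d scales tracked over %d time points\n",
              nrow(x$ids), ncol(x$ids)))
  invisible(x)
}
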