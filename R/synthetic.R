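# Synthetic-data generators: every input the pipeline consumes (random
# binary patterns spanning all length scales, logistic growth curves,
# forward-model color time series, bump-array normal maps, matched point
# sets, noisy color perturbations), as pure functions of (config, seed).

#' Random binary patterns spanning a range of length scales
#'
#' Each pattern is a Gaussian random field on the scale centers (squared-
#' exponential spatial kernel) with correlation length drawn log-uniformly
#' from `length_scale_range` (in units of the lattice S), thresholded at
#' the quantile giving the requested expected green fraction.
#'
#' @param lattice a `scale_lattice`.
#' @param n number of patterns.
#' @param length_scale_range (min, max) correlation lengths in units of S;
#'   values well below 1 give near-independent scales.
#' @param green_fraction expected fraction of green scales.
#' @param seed RNG seed.
#' @return list of n `pattern_state`s.
#' @export
gen_random_patterns <- function(lattice, n, length_scale_range = c(0.5, 8),
                                green_fraction = 0.5, seed = 1) {
  stopifnot(n >= 1)
  if (length_scale_range[2] < length_scale_range[1] ||
      length_scale_range[1] <= 0) stop("empty length-scale range")
  set.seed(seed)
  ns <- n_scales(lattice)
  D2 <- as.matrix(stats::dist(lattice$centers))^2
  lapply(seq_len(n), function(i) {
    ell <- lattice$S * exp(stats::runif(1, log(length_scale_range[1]),
                                        log(length_scale_range[2])))
    K <- exp(-D2 / (2 * ell^2)) + 1e-8 * diag(ns)
    z <- as.numeric(t(chol(K)) %*% stats::rnorm(ns))
    thr <- stats::quantile(z, 1 - green_fraction, type = 7)
    states <- ifelse(z > thr, "green", "black")
    if (green_fraction >= 1) states <- rep("green", ns)
    if (green_fraction <= 0) states <- rep("black", ns)
    pattern_state(states, time = 0)
  })
}

#' Forward-model color time series with known ground truth
#'
#' Simulates the discrete RD model from a given initial state, maps the
#' per-scale (u, v, w) trajectories to CIELAB through the line-to-line
#' transform built from the linear stability analysis (extremities ug/ub
#' to cluster colors Cg/Cb), and adds i.i.d. Gaussian measurement noise.
#' The ground-truth parameters and RD states are returned alongside, for
#' parameter-recovery experiments.
#'
#' @param lattice a `scale_lattice`.
#' @param params an [rd_params()] object (Turing-unstable HSS for
#'   pattern-forming truths).
#' @param ic an [rd_state()] initial condition.
#' @param times tau grid of observation time points.
#' @param noise_sd CIELAB measurement noise s.d. (units of CIELAB).
#' @param seed RNG seed.
#' @param Cg,Cb CIELAB cluster colors (lightness of Cg above Cb).
#' @return list with `colors` (list of [color_state()]s), `states` (list
#'   of [rd_state()]s), `Te` (the 4 x 4 RD-to-color map), `params`,
#'   `clusters` (a `color_clusters` built from Cg/Cb).
#' @export
gen_truth_series <- function(lattice, params, ic, times, noise_sd = 2,
                             seed = 1, Cg = c(65, -35, 45),
                             Cb = c(28, 2, 8)) {
  sr <- linear_stability(params, S = lattice$S, eps = lattice$epsilon)
  states <- simulate_drd(lattice, params, ic, times)
  Te <- affine_T2(sr$ug, sr$ub, Cg, Cb) %*% affine_T1(sr$ug, sr$ub)
  set.seed(seed)
  colors <- lapply(states, function(st) {
    C <- apply_affine(Te, cbind(st$u, st$v, st$w))
    C <- C + matrix(stats::rnorm(length(C), 0, noise_sd), ncol = 3)
    C[, 1] <- pmin(pmax(C[, 1], 0), 100)
    color_state(C, time = st$time)
  })
  clusters <- structure(list(Cg = Cg, Cb = Cb,
                             assignment = rep(NA_character_,
                                              n_scales(lattice))),
                        class = "color_clusters")
  list(colors = colors, states = states, Te = Te, params = params,
       clusters = clusters)
}

#' Synthetic normal map of a super-Gaussian bump array
#'
#' Builds an analytic height field of hexagonally arranged bumps
#' h(r) = h_e + (h_c - h_e) exp(-(r^2 / 2 sigma^2)^p) (pointwise maximum
#' across bumps), derives exact unit normals from the analytic gradient,
#' and encodes them as a 16-bit RGB array. Pixel (i, j) maps to physical
#' (x, y) = (i, j) * pitch.
#'
#' @param S bump spacing (physical units).
#' @param sigma,p super-Gaussian width and exponent.
#' @param height bump center height h_c.
#' @param floor edge height h_e (default 0).
#' @param nx,ny bump grid size.
#' @param px_per_scale resolution (>= 20 px per bump spacing; the scanning
#'   regime is >= 400 px per scale area).
#' @return list with `image` (encoded array), `height` (matrix), `normals`
#'   (a `normal_field`), `centers_px` (bump centers in pixels), `pitch`.
#' @export
gen_normal_map <- function(S, sigma, p = 1, height = 1, floor = 0,
                           nx = 8, ny = 8, px_per_scale = 24) {
  if (px_per_scale < 20) stop("resolution too coarse")
  pitch <- S / px_per_scale
  centers <- hex_bump_centers(nx, ny, S)
  pad <- S
  xr <- range(centers[, 1]) + c(-pad, pad)
  yr <- range(centers[, 2]) + c(-pad, pad)
  xs <- seq(xr[1], xr[2], by = pitch)
  ys <- seq(yr[1], yr[2], by = pitch)
  hb <- super_gaussian_surface(xs, ys, centers, sigma, p,
                               rep(height, nrow(centers)), floor)
  # analytic gradient of the active (max) bump
  gx <- hb$gx; gy <- hb$gy
  nn <- sqrt(gx^2 + gy^2 + 1)
  nf <- structure(list(n1 = -gx / nn, n2 = -gy / nn, n3 = 1 / nn,
                       pitch = pitch), class = "normal_field")
  centers_px <- cbind((centers[, 1] - xr[1]) / pitch + 1,
                      (centers[, 2] - yr[1]) / pitch + 1)
  list(image = encode_normal_map(nf), height = hb$h, normals = nf,
       centers_px = centers_px, pitch = pitch)
}

# hexagonal arrangement of bump centers, spacing S
hex_bump_centers <- function(nx, ny, S) {
  centers <- matrix(0, nx * ny, 2)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    centers[k, ] <- c((ix - 1) * S + ((iy - 1) %% 2) * S / 2,
                      (iy - 1) * S * sqrt(3) / 2)
  }
  centers
}

# evaluate the max-blended super-Gaussian surface and its analytic gradient
# on the grid xs x ys; heights per bump, common floor (or per-bump floor)
super_gaussian_surface <- function(xs, ys, centers, sigma, p, heights,
                                   floors) {
  if (length(floors) == 1) floors <- rep(floors, nrow(centers))
  nxp <- length(xs); nyp <- length(ys)
  h <- matrix(-Inf, nxp, nyp); gx <- matrix(0, nxp, nyp); gy <- gx
  X <- matrix(xs, nxp, nyp); Y <- matrix(ys, nxp, nyp, byrow = TRUE)
  for (b in seq_len(nrow(centers))) {
    dx <- X - centers[b, 1]; dy <- Y - centers[b, 2]
    r2 <- dx^2 + dy^2
    z <- (r2 / (2 * sigma^2))^p
    e <- exp(-z)
    hb <- floors[b] + (heights[b] - floors[b]) * e
    # dh/dx = (hc-he) * e * (-p z^{(p-1)/p->via r2}) ... chain rule:
    # dz/dr2 = p (r2/2s^2)^(p-1) / (2 s^2); dh/dr2 = -(hc-he) e dz/dr2
    dzdr2 <- ifelse(r2 > 0, p * (r2 / (2 * sigma^2))^(p - 1) / (2 * sigma^2),
                    if (p == 1) 1 / (2 * sigma^2) else 0)
    dhdr2 <- -(heights[b] - floors[b]) * e * dzdr2
    upd <- hb > h
    h[upd] <- hb[upd]
    gx[upd] <- (2 * dx * dhdr2)[upd]
    gy[upd] <- (2 * dy * dhdr2)[upd]
  }
  list(h = h, gx = gx, gy = gy)
}

#' Matched point-set pair with known ground truth
#'
#' The second center set is the first mapped through a similarity
#' transform (rotation `theta`, isotropic scale `s`, translation `t`),
#' plus Gaussian jitter, minus a Bernoulli dropout; the ground-truth
#' correspondence survives in the return value.
#'
#' @param lattice a `scale_lattice` supplying the first center set.
#' @param theta,s,t similarity parameters (s > 0; t length-2).
#' @param jitter_sd isotropic Gaussian jitter s.d. added to the second set.
#' @param dropout per-scale probability of being absent from the second
#'   set.
#' @param seed RNG seed.
#' @return list with `A` (first centers), `B` (second centers), `truth`
#'   (length n_A integer vector: row of B or NA for dropped scales).
#' @export
gen_matched_pair <- function(lattice, theta = 0, s = 1, t = c(0, 0),
                             jitter_sd = 0, dropout = 0, seed = 1) {
  if (s <= 0) stop("scale factor must be positive")
  set.seed(seed)
  A <- lattice$centers
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  B_full <- s * t(R %*% t(sweep(A, 2, -t)))
  B_full <- B_full + matrix(stats::rnorm(length(B_full), 0, jitter_sd),
                            ncol = 2)
  kept <- which(stats::runif(nrow(A)) >= dropout)
  truth <- rep(NA_integer_, nrow(A))
  truth[kept] <- seq_along(kept)
  list(A = A, B = B_full[kept, , drop = FALSE], truth = truth)
}

#' Perturb a reference color state
#'
#' C = Cref + s C' with s ~ U(0, 1) and rows of C' drawn from
#' N(0, Sigma_ref), Sigma_ref the 3 x 3 covariance of the reference
#' colors (diagonal fallback, with a warning, when singular). This is the
#' noisy-initial-condition model of the sensitivity analysis.
#'
#' @param Cref a [color_state()] with >= 2 scales.
#' @param seed RNG seed.
#' @param s_fixed optional fixed value for the scalar s (e.g. 0 returns
#'   the reference exactly).
#' @return a [color_state()] with attributes `s` (the drawn scalar) and
#'   `Cprime` (the raw noise matrix).
#' @export
perturb_colors <- function(Cref, seed = 1, s_fixed = NULL) {
  X <- Cref$colors
  if (nrow(X) < 2) stop("need >= 2 scales for a covariance")
  Sg <- stats::cov(X)
  ch <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular color covariance; using diagonal fallback")
    ch <- diag(sqrt(pmax(diag(Sg), 1e-12)))
  }
  set.seed(seed)
  s <- if (is.null(s_fixed)) stats::runif(1) else s_fixed
  Cp <- matrix(stats::rnorm(3 * nrow(X)), ncol = 3) %*% ch
  Cnew <- X + s * Cp
  Cnew[, 1] <- pmin(pmax(Cnew[, 1], 0), 100)
  out <- color_state(Cnew, time = Cref$time)
  attr(out, "s") <- s
  attr(out, "Cprime") <- Cp
  out
}
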