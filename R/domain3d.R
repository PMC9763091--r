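# 3D skin domains: hexagonal lattices of super-Gaussian bumps (homogeneous
# or with per-bump/per-edge height noise), chromatophore-depth mapping
# dm(d), a Laplacian for curvilinear structured grids with least-squares
# metric estimation, backward-Euler 3D reaction-diffusion with BiCGSTAB,
# and the skin-thickness uncertainty experiment.

#' Super-Gaussian bump specification
#'
#' Radial bump profile h(r) = h_e + (h_c - h_e) exp(-(r^2/2 sigma^2)^p)
#' around each scale center, blended by pointwise maximum; h_c and h_e are
#' drawn per bump / per edge from N(hc_mean, hc_sd) and N(he_mean, he_sd).
#'
#' @param S bump spacing (> 0).
#' @param sigma,p super-Gaussian width (> 0) and exponent (>= 1).
#' @param hc_mean,hc_sd bump center height mean / s.d.
#' @param he_mean,he_sd edge (saddle) height mean / s.d.
#' @return object of class `bump_spec`.
#' @export
bump_spec <- function(S, sigma, p = 1, hc_mean, hc_sd = 0,
                      he_mean = 0, he_sd = 0) {
  stopifnot(S > 0, sigma > 0, p >= 1, hc_sd >= 0, he_sd >= 0)
  structure(list(S = S, sigma = sigma, p = p, hc_mean = hc_mean,
                 hc_sd = hc_sd, he_mean = he_mean, he_sd = he_sd),
            class = "bump_spec")
}

#' Build a 3D skin domain of super-Gaussian bumps
#'
#' Hexagonal nx x ny bump array; per-bump center heights h_c and per-edge
#' saddle heights h_e sampled from the spec's normal laws (non-positive
#' draws are resampled). Each bump's floor is the mean of its incident
#' edge heights. The top surface is the max-blend of the bump profiles;
#' the bottom surface is flat zero, or `top - dm(top)` when a
#' chromatophore-depth map `dm` is supplied (clamped to keep a positive
#' gap). Nodes form a structured (nx1 x ny1 x nz) grid with z interpolated
#' between the two surfaces.
#'
#' @param spec a [bump_spec()].
#' @param nx,ny bump grid (default 8 x 8 = 64 bumps).
#' @param nz vertical layers (>= 4).
#' @param px_per_S horizontal grid resolution per bump spacing.
#' @param seed RNG seed (irrelevant when both s.d. are zero).
#' @param dm optional function d -> chromatophore-layer thickness.
#' @return object of class `domain3d`: grid dims `nx1`, `ny1`, `nz`,
#'   coordinate arrays `X`, `Y`, `Z` (nx1 x ny1 x nz), surfaces `top`,
#'   `bottom`, per-column thickness `d`, bump `centers`, drawn `hc`, `he`,
#'   `scale_id` (nx1 x ny1, nearest bump), `spec`.
#' @export
build_super_gaussian_domain <- function(spec, nx = 8, ny = 8, nz = 8,
                                        px_per_S = 6, seed = 1, dm = NULL) {
  centers <- hex_bump_centers(nx, ny, spec$S)
  nb <- nrow(centers)
  set.seed(seed)
  draw_pos <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= 0)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- which(x <= 0); tries <- tries + 1L
    }
    if (length(bad)) x[bad] <- mean
    x
  }
  hc <- draw_pos(nb, spec$hc_mean, spec$hc_sd)
  # edges between adjacent bumps (spacing ~ S)
  D <- as.matrix(stats::dist(centers))
  pairs <- which(D > 0 & D < 1.1 * spec$S & upper.tri(D), arr.ind = TRUE)
  he_edges <- draw_pos(nrow(pairs), spec$he_mean, spec$he_sd)
  floors <- vapply(seq_len(nb), function(b) {
    inc <- pairs[, 1] == b | pairs[, 2] == b
    if (any(inc)) mean(he_edges[inc]) else spec$he_mean
  }, 0)
  h <- spec$S / px_per_S
  xr <- range(centers[, 1]); yr <- range(centers[, 2])
  xs <- seq(xr[1], xr[2], by = h)
  ys <- seq(yr[1], yr[2], by = h)
  surf <- super_gaussian_surface(xs, ys, centers, spec$sigma, spec$p,
                                 hc, floors)
  top <- surf$h
  dcol <- top                      # full-skin thickness above z = 0
  # minimum shell thickness 2% of the maximum: thinner cells are far below
  # physical resolution and only degrade the operator conditioning
  bottom <- if (is.null(dm)) top * 0 else
    top - pmin(pmax(dm(dcol), 0.02 * max(dcol)), dcol)
  nx1 <- length(xs); ny1 <- length(ys)
  X <- array(rep(xs, times = ny1 * nz), c(nx1, ny1, nz))
  Y <- array(rep(rep(ys, each = nx1), times = nz), c(nx1, ny1, nz))
  Z <- array(0, c(nx1, ny1, nz))
  for (k in seq_len(nz))
    Z[, , k] <- bottom + (k - 1) / (nz - 1) * (top - bottom)
  sid <- matrix(0L, nx1, ny1)
  for (j in seq_len(ny1)) {
    dd <- outer(xs, centers[, 1], "-")^2 +
      matrix(rep((ys[j] - centers[, 2])^2, each = nx1), nx1)
    sid[, j] <- max.col(-dd)
  }
  structure(list(nx1 = nx1, ny1 = ny1, nz = nz, X = X, Y = Y, Z = Z,
                 top = top, bottom = bottom, d = dcol - bottom,
                 centers = centers, hc = hc, he = he_edges,
                 scale_id = sid, spec = spec, xs = xs, ys = ys),
            class = "domain3d")
}

#' @export
print.domain3d <- function(x, ...) {
  cat(sprintf("domain3d: %d x %d x %d grid, %d bumps, thickness %.3g-%.3g\n",
              x$nx1, x$ny1, x$nz, nrow(x$centers), min(x$d), max(x$d)))
  invisible(x)
}

#' Fit the chromatophore-depth mapping dm(d)
#'
#' Bins skin thickness d, takes per bin the 75th percentile of the paired
#' chromatophore (melanophore) depths, and fits a quadratic through the
#' bin boundaries by least squares.
#'
#' @param d_samples skin thickness per sample.
#' @param melanophore_depth_samples paired melanophore depth per sample.
#' @param nbins number of d bins (>= 3 usable bins required).
#' @param prob boundary quantile (default 0.75).
#' @return list with `coef` (quadratic c0 + c1 d + c2 d^2), `fn`
#'   (vectorized dm(d)), `boundary` (data.frame d_mid, dm75).
#' @export
fit_dm_mapping <- function(d_samples, melanophore_depth_samples,
                           nbins = 12, prob = 0.75) {
  stopifnot(length(d_samples) == length(melanophore_depth_samples))
  br <- seq(min(d_samples), max(d_samples), length.out = nbins + 1)
  bin <- cut(d_samples, br, include.lowest = TRUE)
  dm75 <- tapply(melanophore_depth_samples, bin, stats::quantile,
                 probs = prob, names = FALSE)
  mid <- (br[-1] + br[-length(br)]) / 2
  ok <- !is.na(dm75)
  if (sum(ok) < 3) stop("fewer than 3 usable thickness bins")
  fit <- stats::lm(dm75[ok] ~ mid[ok] + I(mid[ok]^2))
  cf <- unname(stats::coef(fit))
  list(coef = cf,
       fn = function(d) cf[1] + cf[2] * d + cf[3] * d^2,
       boundary = data.frame(d_mid = mid[ok], dm75 = as.numeric(dm75[ok])))
}

#' Fit a bump spec to a target thickness histogram
#'
#' Derivative-free (Nelder-Mead, restarts) minimization of the L2 distance
#' between the thickness histogram of a generated domain and a target
#' histogram, over the free parameters (sigma, p, hc_mean, he_mean, hc_sd,
#' he_sd). Histograms are compared as densities on the target's breaks.
#'
#' @param target_hist object from [graphics::hist()] (or a list with
#'   `breaks` and `density`).
#' @param init a [bump_spec()] initial guess (also fixes S).
#' @param nx,ny,nz,px_per_S domain size used during fitting.
#' @param seed RNG seed used for every candidate evaluation (common random
#'   numbers).
#' @param restarts Nelder-Mead restarts (default 3).
#' @param maxit iterations per restart.
#' @return list with `spec` (optimized [bump_spec()]), `distance`,
#'   `initial_distance`.
#' @export
fit_depth_histogram <- function(target_hist, init, nx = 6, ny = 6, nz = 4,
                                px_per_S = 5, seed = 1, restarts = 3,
                                maxit = 60) {
  breaks <- target_hist$breaks
  tdens <- target_hist$density
  dist_of <- function(th) {
    sp <- tryCatch(
      bump_spec(init$S, sigma = exp(th[1]), p = 1 + exp(th[2]),
                hc_mean = exp(th[3]), hc_sd = exp(th[4]),
                he_mean = exp(th[5]), he_sd = exp(th[6])),
      error = function(e) NULL)
    if (is.null(sp)) return(1e6)
    dom <- tryCatch(build_super_gaussian_domain(sp, nx, ny, nz,
                                                px_per_S, seed = seed),
                    error = function(e) NULL)
    if (is.null(dom)) return(1e6)
    dv <- pmin(pmax(as.vector(dom$d), breaks[1]), breaks[length(breaks)])
    hh <- graphics::hist(dv, breaks = breaks, plot = FALSE)
    sqrt(sum((hh$density - tdens)^2))
  }
  th0 <- c(log(init$sigma), log(max(init$p - 1, 1e-3)), log(init$hc_mean),
           log(max(init$hc_sd, 1e-3)), log(max(init$he_mean, 1e-3)),
           log(max(init$he_sd, 1e-3)))
  d0 <- dist_of(th0)
  best <- list(par = th0, value = d0)
  set.seed(seed)
  for (r in seq_len(restarts)) {
    start <- if (r == 1) th0 else best$par + stats::rnorm(6, 0, 0.2)
    fit <- stats::optim(start, dist_of, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (fit$value < best$value) best <- fit
  }
  if (best$value >= d0 - 1e-12 && d0 > 0)
    warning("histogram fit did not improve on the initial guess")
  th <- best$par
  list(spec = bump_spec(init$S, sigma = exp(th[1]), p = 1 + exp(th[2]),
                        hc_mean = exp(th[3]), hc_sd = exp(th[4]),
                        he_mean = exp(th[5]), he_sd = exp(th[6])),
       distance = best$value, initial_distance = d0)
}

## ---- curvilinear Laplacian --------------------------------------------------

# reflect an index into 1..n (mirror at the boundary node)
reflect_idx <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Sparse Laplacian operator for a curvilinear structured grid
#'
#' Writes the Laplacian in computational (index) coordinates:
#' lap u = sum_ij (b^i . b^j) d2u/dyi dyj + sum_i div(b^i) du/dyi,
#' with the covariant basis b^i = grad y_i estimated per node by
#' least-squares linear regression of the index offsets on the Cartesian
#' offsets over the 3x3x3 stencil (reduced stencils at boundaries), and
#' div(b^i) from finite differences of the basis fields. Derivatives of u
#' use central differences with mirror (zero-flux) closure at the grid
#' boundary. On a rectilinear grid this reduces exactly to the standard
#' 7-point stencil.
#'
#' @param domain a `domain3d` (or any list with arrays X, Y, Z and dims
#'   nx1, ny1, nz).
#' @return list with `L` (sparse N x N matrix, N = nx1 ny1 nz), `volume`
#'   (per-node volume weights 1/|det b|), `dims`.
#' @export
curvilinear_laplacian_operator <- function(domain) {
  nx <- domain$nx1; ny <- domain$ny1; nz <- domain$nz
  N <- nx * ny * nz
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  I3 <- rep(seq_len(nx), times = ny * nz)
  J3 <- rep(rep(seq_len(ny), each = nx), times = nz)
  K3 <- rep(seq_len(nz), each = nx * ny)
  Xv <- as.vector(domain$X); Yv <- as.vector(domain$Y); Zv <- as.vector(domain$Z)
  # Jacobian d x / d y by least squares over the stencil, per node; then
  # invert to get b (= d y / d x). Regression: Delta x ~ Delta y (3x3).
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  B <- array(0, c(N, 3, 3))     # B[n, i, j] = b_ij = dy_i/dx_j
  Jac <- array(0, c(N, 3, 3))   # dx_i/dy_j
  # accumulate normal equations sum(dy dy^T) and sum(dy dx^T) vectorized
  Syy <- array(0, c(N, 3, 3)); Syx <- array(0, c(N, 3, 3))
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    if (all(d == 0)) next
    Ii <- I3 + d[1]; Jj <- J3 + d[2]; Kk <- K3 + d[3]
    ok <- Ii >= 1 & Ii <= nx & Jj >= 1 & Jj <= ny & Kk >= 1 & Kk <= nz
    tgt <- nid(pmax(pmin(Ii, nx), 1L), pmax(pmin(Jj, ny), 1L),
               pmax(pmin(Kk, nz), 1L))
    dx <- cbind(Xv[tgt] - Xv, Yv[tgt] - Yv, Zv[tgt] - Zv)
    w <- as.numeric(ok)
    for (a in 1:3) for (b in 1:3) {
      Syy[, a, b] <- Syy[, a, b] + w * d[a] * d[b]
      Syx[, a, b] <- Syx[, a, b] + w * d[a] * dx[, b]
    }
  }
  for (n in seq_len(N)) {
    # dx/dy solves Syy %*% Jac = Syx  (rows: dy index)
    Jn <- tryCatch(solve(Syy[n, , ], Syx[n, , ]), error = function(e) NULL)
    if (is.null(Jn)) stop("degenerate stencil at node ", n)
    Jac[n, , ] <- t(Jn)                       # dx_i/dy_j
    B[n, , ] <- solve(Jac[n, , ])             # dy_i/dx_j
  }
  vol <- abs(Jac[, 1, 1] * (Jac[, 2, 2] * Jac[, 3, 3] - Jac[, 2, 3] * Jac[, 3, 2]) -
             Jac[, 1, 2] * (Jac[, 2, 1] * Jac[, 3, 3] - Jac[, 2, 3] * Jac[, 3, 1]) +
             Jac[, 1, 3] * (Jac[, 2, 1] * Jac[, 3, 2] - Jac[, 2, 2] * Jac[, 3, 1]))
  # G_ij = b^i . b^j ; c_i = div b^i = sum_jk dB[i,j]/dy_k * B[k,j]
  G <- array(0, c(N, 3, 3))
  for (a in 1:3) for (b in a:3) {
    g <- rowSums(B[, a, ] * B[, b, ])
    G[, a, b] <- g; G[, b, a] <- g
  }
  dims <- c(nx, ny, nz)
  # central differences of the basis fields along index axes (mirror ends)
  dB <- array(0, c(N, 3, 3, 3))   # dB[n, i, j, k] = d b_ij / d y_k
  for (k in 1:3) {
    dplus <- c(0L, 0L, 0L); dplus[k] <- 1L
    Ip <- reflect_idx(I3 + dplus[1], nx); Jp <- reflect_idx(J3 + dplus[2], ny)
    Kp <- reflect_idx(K3 + dplus[3], nz)
    Im <- reflect_idx(I3 - dplus[1], nx); Jm <- reflect_idx(J3 - dplus[2], ny)
    Km <- reflect_idx(K3 - dplus[3], nz)
    tp <- nid(Ip, Jp, Kp); tm <- nid(Im, Jm, Km)
    for (a in 1:3) for (b in 1:3)
      dB[, a, b, k] <- (B[tp, a, b] - B[tm, a, b]) / 2
  }
  Cc <- matrix(0, N, 3)
  for (a in 1:3) {
    acc <- 0
    for (j in 1:3) for (k in 1:3) acc <- acc + dB[, a, j, k] * B[, k, j]
    Cc[, a] <- acc
  }
  # assemble triplets with mirror closure
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  push <- function(di, dj, dk, coefs) {
    Ii <- reflect_idx(I3 + di, nx); Jj <- reflect_idx(J3 + dj, ny)
    Kk <- reflect_idx(K3 + dk, nz)
    ti <<- c(ti, seq_len(N)); tj <<- c(tj, nid(Ii, Jj, Kk))
    tx <<- c(tx, coefs)
  }
  e <- diag(3)
  # pure second derivatives + first derivatives
  for (a in 1:3) {
    push(e[a, 1], e[a, 2], e[a, 3], G[, a, a] + Cc[, a] / 2)
    push(-e[a, 1], -e[a, 2], -e[a, 3], G[, a, a] - Cc[, a] / 2)
    push(0, 0, 0, -2 * G[, a, a])
  }
  # mixed second derivatives
  for (a in 1:2) for (b in (a + 1):3) {
    for (sa in c(-1, 1)) for (sb in c(-1, 1)) {
      d <- sa * e[a, ] + sb * e[b, ]
      push(d[1], d[2], d[3], 2 * G[, a, b] * sa * sb / 4)
    }
  }
  L <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
  # trapezoidal quadrature weights (half at grid boundaries); together with
  # the cell volumes these make the mirror-closed operator conservative on
  # rectilinear grids: t(volume * wquad) %*% L = 0
  wq <- ifelse(I3 == 1L | I3 == nx, 0.5, 1) *
    ifelse(J3 == 1L | J3 == ny, 0.5, 1) *
    ifelse(K3 == 1L | K3 == nz, 0.5, 1)
  list(L = L, volume = vol, wquad = wq, dims = dims)
}

#' Flux-form diffusion operator for a curvilinear structured grid
#'
#' Finite-volume two-point-flux discretization of div(grad u): every node
#' owns the unit index-space cell around it; the flux through the face
#' between adjacent nodes is T (u_j - u_i) with transmissibility
#' T = (A . A) / (A . d), A the metric face-area vector (cross product of
#' the face tangents) and d the center-to-center vector. Outer boundaries
#' carry no faces (zero flux), so total volume-weighted concentration is
#' conserved exactly and thin shell necks throttle transport through their
#' small face areas. On a rectilinear grid the operator reduces to the
#' standard 7-point stencil (with halved boundary cells).
#'
#' @param domain a `domain3d` (or list with arrays X, Y, Z and dims).
#' @return list with `L` (sparse N x N matrix, rows premultiplied by
#'   1/volume), `volume` (node cell volumes, boundary cells halved),
#'   `dims`.
#' @export
curvilinear_flux_operator <- function(domain) {
  nx <- domain$nx1; ny <- domain$ny1; nz <- domain$nz
  N <- nx * ny * nz
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  I3 <- rep(seq_len(nx), times = ny * nz)
  J3 <- rep(rep(seq_len(ny), each = nx), times = nz)
  K3 <- rep(seq_len(nz), each = nx * ny)
  P <- cbind(as.vector(domain$X), as.vector(domain$Y), as.vector(domain$Z))
  # tangents dx/dy_a per node: central differences, one-sided at borders
  tang <- function(axis) {
    d <- c(0L, 0L, 0L); d[axis] <- 1L
    up <- nid(pmin(I3 + d[1], nx), pmin(J3 + d[2], ny), pmin(K3 + d[3], nz))
    dn <- nid(pmax(I3 - d[1], 1L), pmax(J3 - d[2], 1L), pmax(K3 - d[3], 1L))
    span <- (pmin(I3 + d[1], nx) - pmax(I3 - d[1], 1L)) * d[1] +
      (pmin(J3 + d[2], ny) - pmax(J3 - d[2], 1L)) * d[2] +
      (pmin(K3 + d[3], nz) - pmax(K3 - d[3], 1L)) * d[3]
    (P[up, ] - P[dn, ]) / span
  }
  Tx <- tang(1); Ty <- tang(2); Tz <- tang(3)
  crossp <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vol <- abs(rowSums(Tx * crossp(Ty, Tz)))
  # horizontal directions are cell-centered (full cells, matching the 2D
  # solver's convention); vertical nodes sit on the shell surfaces, so the
  # top and bottom cells are half-height
  wq <- ifelse(K3 == 1L | K3 == nz, 0.5, 1)
  V <- vol * wq
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add_axis <- function(axis, Tb, Tc) {
    d <- c(0L, 0L, 0L); d[axis] <- 1L
    ok <- (I3 + d[1]) <= nx & (J3 + d[2]) <= ny & (K3 + d[3]) <= nz
    a <- which(ok)
    b <- nid(I3[a] + d[1], J3[a] + d[2], K3[a] + d[3])
    Af <- (crossp(Tb[a, , drop = FALSE], Tc[a, , drop = FALSE]) +
             crossp(Tb[b, , drop = FALSE], Tc[b, , drop = FALSE])) / 2
    # horizontal faces of half-height surface cells have half area
    if (axis != 3) Af <- Af * wq[a]
    dd <- P[b, , drop = FALSE] - P[a, , drop = FALSE]
    Tt <- rowSums(Af * Af) / abs(rowSums(Af * dd))
    ti <<- c(ti, a, b); tj <<- c(tj, b, a)
    tx <<- c(tx, Tt / V[a], Tt / V[b])
  }
  add_axis(1, Ty, Tz)
  add_axis(2, Tz, Tx)
  add_axis(3, Tx, Ty)
  L <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
  # diagonal set to the exact negative row sum: constants are in the null
  # space to machine precision even when transmissibilities are huge
  L <- L - Matrix::Diagonal(N, Matrix::rowSums(L))
  list(L = L, volume = V, dims = c(nx, ny, nz))
}

#' Apply the curvilinear Laplacian to a field
#'
#' @param field numeric array (nx1 x ny1 x nz) or vector.
#' @param domain a `domain3d`.
#' @param op optional precomputed [curvilinear_laplacian_operator()].
#' @return vector of Laplacian values (column-major node order).
#' @export
curvilinear_laplacian <- function(field, domain, op = NULL) {
  if (is.null(op)) op <- curvilinear_laplacian_operator(domain)
  as.numeric(op$L %*% as.vector(field))
}

#' BiCGSTAB sparse linear solver with diagonal preconditioning
#'
#' Stabilized bi-conjugate gradient iteration for Ax = b.
#'
#' @param A sparse matrix.
#' @param b right-hand side.
#' @param x0 initial guess (default 0).
#' @param tol relative residual tolerance.
#' @param maxit iteration cap.
#' @return list with `x`, `iterations`, `converged`, `residual`.
#' @export
bicgstab <- function(A, b, x0 = NULL, tol = 1e-8, maxit = 500L) {
  n <- length(b)
  Dinv <- 1 / Matrix::diag(A)
  Dinv[!is.finite(Dinv)] <- 1
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - as.numeric(A %*% x)
  rhat <- r
  rho <- alpha <- omega <- 1
  v <- p <- numeric(n)
  bn <- sqrt(sum(b^2)); if (bn == 0) bn <- 1
  for (it in seq_len(maxit)) {
    rho1 <- sum(rhat * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    ph <- Dinv * p
    v <- as.numeric(A %*% ph)
    alpha <- rho / sum(rhat * v)
    s <- r - alpha * v
    if (sqrt(sum(s^2)) / bn < tol) {
      x <- x + alpha * ph
      return(list(x = x, iterations = it, converged = TRUE,
                  residual = sqrt(sum(s^2)) / bn))
    }
    sh <- Dinv * s
    t <- as.numeric(A %*% sh)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    if (sqrt(sum(r^2)) / bn < tol)
      return(list(x = x, iterations = it, converged = TRUE,
                  residual = sqrt(sum(r^2)) / bn))
  }
  list(x = x, iterations = maxit, converged = FALSE,
       residual = sqrt(sum(r^2)) / bn)
}

#' 3D continuous RD on a curvilinear domain
#'
#' Backward-Euler diffusion with the conservative flux-form operator of
#' [curvilinear_flux_operator()] (zero-flux outer boundaries; shell necks
#' throttle transport through their face areas), explicit reaction/decay.
#' Linear systems are solved with [bicgstab()] (diagonal preconditioner);
#' strongly anisotropic grids can defeat that preconditioner, in which
#' case the step falls back to a cached sparse LU factorization.
#'
#' @param domain a `domain3d`.
#' @param params an [rd_params()] object (P is not used: boundary thinning
#'   is encoded by the geometry itself in 3D).
#' @param ic an [rd_state()] with one node per grid point.
#' @param tau_grid report times; fixed internal step `dtau`.
#' @param dtau time step.
#' @param reaction logical, as in [simulate_drd()].
#' @param tol,maxit BiCGSTAB controls.
#' @return list of [rd_state()]s at `tau_grid`.
#' @export
simulate_crd3d <- function(domain, params, ic, tau_grid, dtau = 1,
                           reaction = TRUE, tol = 1e-8, maxit = 500L) {
  op <- curvilinear_flux_operator(domain)
  N <- nrow(op$L)
  stopifnot(length(ic$u) == N)
  p <- params
  I <- Matrix::Diagonal(N)
  taus <- sort(unique(tau_grid))
  u <- ic$u; v <- ic$v; w <- ic$w
  t_now <- taus[1]
  Au <- NULL; Aw <- NULL; dt_cached <- NA_real_
  lu_u <- NULL; lu_w <- NULL; use_direct <- FALSE
  solve_step <- function(A, b, x0, which) {
    if (!use_direct) {
      s <- bicgstab(A, b, x0 = x0, tol = tol, maxit = maxit)
      if (s$converged) return(s$x)
      use_direct <<- TRUE
    }
    if (which == "u") {
      if (is.null(lu_u)) lu_u <<- Matrix::lu(A)
      as.numeric(Matrix::solve(lu_u, b))
    } else {
      if (is.null(lu_w)) lu_w <<- Matrix::lu(A)
      as.numeric(Matrix::solve(lu_w, b))
    }
  }
  out <- vector("list", length(taus))
  out[[1]] <- rd_state(u, v, w, time = t_now)
  for (kk in seq_along(taus)[-1]) {
    while (t_now < taus[kk] - 1e-12) {
      dt <- min(dtau, taus[kk] - t_now)
      if (is.na(dt_cached) || abs(dt - dt_cached) > 1e-12) {
        Au <- I - (dt * p$q * p$Du) * op$L
        Aw <- I - (dt * p$q * p$Dw) * op$L
        lu_u <- NULL; lu_w <- NULL
        dt_cached <- dt
      }
      if (reaction) {
        rt <- reaction_terms(u, v, w, p)
        ru <- rt$F - p$cu * u; rv <- rt$G - p$cv * v; rw <- rt$H - p$cw * w
      } else ru <- rv <- rw <- 0
      u <- solve_step(Au, u + dt * p$q * ru, u, "u")
      v <- solve_step(Au, v + dt * p$q * rv, v, "u")
      w <- solve_step(Aw, w + dt * p$q * rw, w, "w")
      if (!all(is.finite(u)))
        stop("3D-cRD step diverged at tau = ", t_now)
      t_now <- t_now + dt
    }
    out[[kk]] <- rd_state(u, v, w, time = taus[kk])
  }
  attr(out, "volume") <- op$volume
  out
}

#' Per-bump means of a 3D RD state
#'
#' Averages each component over all grid nodes of each bump's column
#' (nearest-center assignment).
#'
#' @param domain a `domain3d`.
#' @param state an [rd_state()] on the grid.
#' @return an [rd_state()] with one node per bump.
#' @export
crd3d_scale_means <- function(domain, state) {
  nb <- nrow(domain$centers)
  sid <- rep(as.vector(domain$scale_id), times = domain$nz)
  f <- factor(sid, levels = seq_len(nb))
  agg <- function(x) as.numeric(tapply(x, f, mean))
  rd_state(agg(state$u), agg(state$v), agg(state$w), time = state$time)
}

## ---- GEV fit and thickness experiment --------------------------------------

#' Generalized extreme-value maximum-likelihood fit
#'
#' MLE of the GEV(location mu, scale sigma, shape xi) distribution by
#' direct likelihood optimization (Gumbel limit used for |xi| < 1e-6).
#'
#' @param x positive sample (length >= 10 recommended).
#' @return list with `mu`, `sigma`, `xi`, `mean` (distribution mean; Inf
#'   when xi >= 1), `loglik`, `converged`.
#' @export
fit_gev <- function(x) {
  n <- length(x)
  nll <- function(th) {
    mu <- th[1]; sg <- exp(th[2]); xi <- th[3]
    z <- (x - mu) / sg
    if (abs(xi) < 1e-6) {
      val <- n * th[2] + sum(z + exp(-z))
    } else {
      t1 <- 1 + xi * z
      if (any(t1 <= 0)) return(1e10)
      val <- n * th[2] + sum((1 + 1 / xi) * log(t1) + t1^(-1 / xi))
    }
    if (!is.finite(val)) 1e10 else val
  }
  init <- c(mean(x) - 0.45 * stats::sd(x), log(stats::sd(x) * sqrt(6) / pi), 0.1)
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  mu <- fit$par[1]; sg <- exp(fit$par[2]); xi <- fit$par[3]
  gmean <- if (abs(xi) < 1e-6) mu + sg * 0.5772156649
  else if (xi < 1) mu + sg * (gamma(1 - xi) - 1) / xi else Inf
  list(mu = mu, sigma = sg, xi = xi, mean = gmean, loglik = -fit$value,
       converged = fit$convergence == 0)
}

#' Skin-thickness heterogeneity error experiment
#'
#' Simulates the 3D RD model on `n_domains` noisy super-Gaussian domains
#' (heights resampled per domain) and on the homogeneous reference domain
#' (s.d. set to zero), all from the same per-scale initial colors; the
#' scale-by-scale error of each noisy run against the reference final
#' pattern is reported with a GEV fit. With both s.d. zero every Esbs is
#' exactly zero.
#'
#' @param spec a [bump_spec()] (its `hc_sd`, `he_sd` define the noise).
#' @param n_domains number of noisy domains.
#' @param ic_scale an [rd_state()] with one entry per bump (e.g. from
#'   [colors_to_rd()] on observed juvenile colors); broadcast over each
#'   bump's column.
#' @param params an [rd_params()] object.
#' @param tau_end simulation horizon (single comparison time).
#' @param nx,ny,nz,px_per_S domain resolution.
#' @param dtau solver step.
#' @param seed RNG seed (domain d draws seeds per replicate).
#' @param dm optional chromatophore-depth map passed to the builder.
#' @return list with `esbs` (per noisy domain, binary per-scale error),
#'   `n_failed`, `gev` (from [fit_gev()] or NULL), `mean`,
#'   `reference_pattern` (per-bump "green"/"black").
#' @export
thickness_error_experiment <- function(spec, n_domains, ic_scale, params,
                                       tau_end = 600, nx = 4, ny = 4,
                                       nz = 6, px_per_S = 5, dtau = 5,
                                       seed = 1, dm = NULL) {
  ref_spec <- bump_spec(spec$S, spec$sigma, spec$p, spec$hc_mean, 0,
                        spec$he_mean, 0)
  run1 <- function(sp, sd_seed) {
    dom <- build_super_gaussian_domain(sp, nx, ny, nz, px_per_S,
                                       seed = sd_seed, dm = dm)
    N <- dom$nx1 * dom$ny1 * dom$nz
    sid <- rep(as.vector(dom$scale_id), times = dom$nz)
    ic <- rd_state(ic_scale$u[sid], ic_scale$v[sid], ic_scale$w[sid])
    out <- simulate_crd3d(dom, params, ic, c(0, tau_end), dtau = dtau)
    sm <- crd3d_scale_means(dom, out[[length(out)]])
    ustar <- solve_hss(params)$u_star
    ifelse(sm$u > ustar[1], "black", "green")   # high u = melanophore-rich
  }
  ref_pat <- run1(ref_spec, seed)
  esbs_v <- numeric(0); n_failed <- 0L
  for (i in seq_len(n_domains)) {
    pat <- tryCatch(run1(spec, seed + i), error = function(e) NULL)
    if (is.null(pat)) { n_failed <- n_failed + 1L; next }
    esbs_v <- c(esbs_v, mean(pat != ref_pat))
  }
  gev <- if (length(esbs_v) >= 10 && stats::sd(esbs_v) > 0)
    tryCatch(fit_gev(esbs_v), error = function(e) NULL) else NULL
  list(esbs = esbs_v, n_failed = n_failed, gev = gev, mean = mean(esbs_v),
       reference_pattern = ref_pat)
}
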