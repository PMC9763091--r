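# Shared fixtures: small lattices, random patterns, and the default
# (published) RD parameter set at the Turing-unstable fixture geometry
# S = 4, eps = 1.

fix_hex <- function(nx = 6, ny = 6, S = 1, epsilon = 1)
  build_hex_lattice(nx, ny, S, epsilon)

fix_voronoi <- function(n = 50, seed = 1, side = 10) {
  set.seed(seed)
  build_voronoi_lattice(cbind(stats::runif(n, 0, side),
                              stats::runif(n, 0, side)),
                        clip_region = cbind(c(0, side, side, 0),
                                            c(0, 0, side, side)))
}

random_pattern <- function(n, seed = 1, p_green = 0.5) {
  set.seed(seed)
  pattern_state(ifelse(stats::runif(n) < p_green, "green", "black"))
}

# published reaction/decay/diffusion values; S = 4 puts the fastest-growing
# diffusion mode inside the hex-lattice spectrum (Turing-unstable HSS)
fix_params <- function(...) rd_params(...)
FIX_S <- 4

# brute-force neighborhood tabulation, independent of neighbor_stats
brute_neighbor_stats <- function(lattice, pattern) {
  tab <- matrix(0L, 2, 8, dimnames = list(c("green", "black"), 0:7))
  for (i in seq_len(nrow(lattice$centers))) {
    st <- pattern$states[i]
    cnt <- 0L
    for (j in lattice$adjacency[[i]])
      if (pattern$states[j] == st) cnt <- cnt + 1L
    cnt <- min(cnt, 7L)
    tab[st, cnt + 1L] <- tab[st, cnt + 1L] + 1L
  }
  tab
}

# small ring lattice (every scale has 2 neighbors); trivial geometry
ring_lattice <- function(n) {
  th <- 2 * pi * (0:(n - 1)) / n
  centers <- cbind(cos(th), sin(th))
  adj <- lapply(seq_len(n), function(i)
    sort(c((i - 2) %% n + 1, i %% n + 1)))
  E <- Matrix::sparseMatrix(i = rep(seq_len(n), each = 2),
                            j = unlist(adj), x = 1, dims = c(n, n))
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  scale_lattice(centers, lapply(seq_len(n), function(i)
    sweep(tri * 0.1, 2, centers[i, ], "+")),
    adj, rep(0.04 / 2, n), E)
}

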