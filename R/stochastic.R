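# Two-state stochastic models of scale color dynamics: the 16-rule
# stochastic cellular automaton (flip probability depends on own state and
# the 0..7 isochromatic-neighbor count) with Bayesian rule inference, and
# the two-parameter Lenz-Ising model with Metropolis dynamics and
# pseudo-likelihood parameter fitting.

#' Stochastic cellular automaton rules
#'
#' Per configuration (S, i): trial count n, flip count k, posterior mean
#' flip probability E\[p\] = (k+1)/(n+2) (flat Beta prior), and the MAP
#' estimate k/n where defined. Empty bins give E\[p\] = 1/2.
#'
#' @param n,k 2 x 8 integer matrices (rows green/black, columns i = 0..7).
#' @return object of class `sca_rules` with fields `n`, `k`, `E_p`, `p_map`.
#' @export
sca_rules <- function(n, k) {
  stopifnot(all(dim(n) == c(2, 8)), all(dim(k) == c(2, 8)), all(k <= n))
  dimnames(n) <- dimnames(k) <- list(c("green", "black"), 0:7)
  E_p <- (k + 1) / (n + 2)
  p_map <- ifelse(n > 0, k / n, NA_real_)
  structure(list(n = n, k = k, E_p = E_p, p_map = p_map),
            class = "sca_rules")
}

#' @export
print.sca_rules <- function(x, ...) {
  cat("sca_rules: E[p] (posterior mean flip probabilities)\n")
  print(round(x$E_p, 4))
  invisible(x)
}

#' Infer sCA rules from a pattern time series
#'
#' For every non-final time point, each scale contributes one trial to its
#' configuration bin (S, i); a success is a color flip by the next time
#' point. Trials and successes are summed across all time points and
#' converted to posterior-mean probabilities.
#'
#' @param lattice a `scale_lattice` (topology is time-invariant).
#' @param patterns list of >= 2 `pattern_state`s in time order.
#' @return an [sca_rules()] object.
#' @export
infer_sca_rules <- function(lattice, patterns) {
  if (length(patterns) < 2) stop("need at least 2 time points")
  n <- matrix(0L, 2, 8, dimnames = list(c("green", "black"), 0:7))
  k <- n
  for (t in seq_len(length(patterns) - 1)) {
    p1 <- patterns[[t]]; p2 <- patterns[[t + 1]]
    cnt <- iso_neighbor_counts(lattice, p1)
    flip <- p1$states != p2$states
    for (i in seq_along(cnt)) {
      n[p1$states[i], cnt[i] + 1L] <- n[p1$states[i], cnt[i] + 1L] + 1L
      if (flip[i]) k[p1$states[i], cnt[i] + 1L] <- k[p1$states[i], cnt[i] + 1L] + 1L
    }
  }
  sca_rules(n, k)
}

#' Simulate the stochastic cellular automaton
#'
#' Synchronous iterations: at each step every scale flips independently
#' with the E\[p\] of its current configuration. The run stops at the first
#' iteration where the cumulative flip count reaches `target_flips` (one
#' iteration typically flips several scales, so the final count can exceed
#' the target), or at `max_iter` with a warning if the target is
#' unreachable.
#'
#' @param lattice a `scale_lattice`.
#' @param p0 initial `pattern_state`.
#' @param rules an [sca_rules()] object.
#' @param target_flips cumulative flip budget; `NULL` runs exactly
#'   `max_iter` iterations (useful for stepping the chain).
#' @param seed RNG seed.
#' @param max_iter iteration cap.
#' @param keep_trajectory also return the per-iteration states.
#' @return final `pattern_state`, with attributes `iterations` and
#'   `cumulative_flips` (and `trajectory` if requested).
#' @export
simulate_sca <- function(lattice, p0, rules, target_flips, seed = 1,
                         max_iter = 10000L, keep_trajectory = FALSE) {
  set.seed(seed)
  s <- p0$states
  cum <- 0L; it <- 0L
  open_ended <- is.null(target_flips)
  if (open_ended) target_flips <- Inf
  traj <- if (keep_trajectory) list(p0) else NULL
  while (cum < target_flips && it < max_iter) {
    it <- it + 1L
    cnt <- iso_neighbor_counts(lattice, pattern_state(s))
    pr <- rules$E_p[cbind(match(s, c("green", "black")), cnt + 1L)]
    flip <- stats::runif(length(s)) < pr
    s[flip] <- ifelse(s[flip] == "green", "black", "green")
    cum <- cum + sum(flip)
    if (keep_trajectory) traj[[it + 1L]] <- pattern_state(s, time = it)
  }
  if (!open_ended && cum < target_flips)
    warning("flip target not reached within max_iter iterations")
  out <- pattern_state(s, time = it)
  attr(out, "iterations") <- it
  attr(out, "cumulative_flips") <- cum
  if (keep_trajectory) attr(out, "trajectory") <- traj
  out
}

## ---- Lenz-Ising -------------------------------------------------------------

#' Lenz-Ising parameters
#'
#' Dimensionless coupling and field (inverse temperature absorbed). Green
#' scales are spin +1, black are -1; under this convention a fitted
#' negative `betaJ` is antiferromagnetic (labyrinthine patterns) and a
#' negative `betaB` favors black scales.
#'
#' @param betaJ coupling.
#' @param betaB external field.
#' @return object of class `ising_params`.
#' @export
ising_params <- function(betaJ, betaB) {
  stopifnot(is.finite(betaJ), is.finite(betaB))
  structure(list(betaJ = betaJ, betaB = betaB), class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat(sprintf("ising_params: betaJ = %.4g (%s), betaB = %.4g\n", x$betaJ,
              if (x$betaJ < 0) "antiferromagnetic" else "ferromagnetic",
              x$betaB))
  invisible(x)
}

pattern_spins <- function(pattern) ifelse(pattern$states == "green", 1L, -1L)

#' Dimensionless Ising energy of a pattern
#'
#' beta H = -betaJ sum_(ij) s_i s_j - betaB sum_i s_i over the lattice
#' adjacency (each unordered pair counted once), with green = +1,
#' black = -1.
#'
#' @param lattice a `scale_lattice`.
#' @param pattern a `pattern_state`.
#' @param params an [ising_params()] object.
#' @return scalar beta H.
#' @export
ising_energy <- function(lattice, pattern, params) {
  s <- pattern_spins(pattern)
  pair_sum <- 0
  for (i in seq_along(s)) {
    nb <- lattice$adjacency[[i]]
    pair_sum <- pair_sum + sum(s[i] * s[nb])
  }
  pair_sum <- pair_sum / 2
  -params$betaJ * pair_sum - params$betaB * sum(s)
}

#' Metropolis simulation of the Lenz-Ising model
#'
#' Single-site Metropolis sweeps sampling the canonical distribution
#' exp(-beta H). Stops after `n_sweeps` full sweeps, or earlier once the
#' Hamming distance from the initial pattern (net flips) reaches
#' `target_flips`, for comparability with sCA runs.
#'
#' @param lattice a `scale_lattice`.
#' @param p0 initial `pattern_state`.
#' @param params an [ising_params()] object.
#' @param n_sweeps number of full lattice sweeps.
#' @param target_flips optional net-flip stop threshold (`NULL` = none).
#' @param seed RNG seed.
#' @return final `pattern_state` with attribute `sweeps`.
#' @export
simulate_ising <- function(lattice, p0, params, n_sweeps, target_flips = NULL,
                           seed = 1) {
  set.seed(seed)
  s <- pattern_spins(p0)
  s0 <- s
  n <- length(s)
  adj <- lattice$adjacency
  bJ <- params$betaJ; bB <- params$betaB
  sweeps_done <- 0L
  for (sw in seq_len(n_sweeps)) {
    ord <- sample.int(n)
    us <- stats::runif(n)
    for (idx in seq_len(n)) {
      i <- ord[idx]
      nb_sum <- sum(s[adj[[i]]])
      dE <- 2 * s[i] * (bJ * nb_sum + bB)   # beta H change of flipping i
      if (dE <= 0 || us[idx] < exp(-dE)) s[i] <- -s[i]
    }
    sweeps_done <- sw
    if (!is.null(target_flips) && sum(s != s0) >= target_flips) break
  }
  out <- pattern_state(ifelse(s == 1L, "green", "black"), time = sweeps_done)
  attr(out, "sweeps") <- sweeps_done
  out
}

#' Fit Ising parameters by maximum pseudo-likelihood
#'
#' Under the Ising measure, the conditional law of one spin given its
#' neighbors is logistic: P(s_i = +1 | rest) = 1 / (1 + exp(-2(betaJ m_i +
#' betaB))) with m_i the neighbor spin sum. The pseudo-likelihood is the
#' product of these conditionals; it is maximized by a logistic regression
#' of (s_i + 1)/2 on m_i, whose coefficients are 2 betaB and 2 betaJ.
#' Estimates hitting the box bound (e.g. a uniform pattern, where betaB is
#' unbounded) are flagged.
#'
#' @param lattice a `scale_lattice`.
#' @param pattern an adult `pattern_state`.
#' @param bound box half-width on (betaJ, betaB); default 10.
#' @return an [ising_params()] with attribute `bound_hit` (logical).
#' @export
fit_ising_params <- function(lattice, pattern, bound = 10) {
  s <- pattern_spins(pattern)
  m <- vapply(seq_along(s), function(i) sum(s[lattice$adjacency[[i]]]), 0L)
  nll <- function(th) {
    eta <- 2 * (th[1] * m + th[2])
    sum(log1p(exp(-s * eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "L-BFGS-B",
                      lower = c(-bound, -bound), upper = c(bound, bound))
  hit <- any(abs(abs(fit$par) - bound) < 1e-6)
  out <- ising_params(fit$par[1], fit$par[2])
  attr(out, "bound_hit") <- hit
  if (hit) warning("pseudo-likelihood estimate hit the parameter bound")
  out
}
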