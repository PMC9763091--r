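# Sensitivity to initial conditions: divergence of perturbed RD
# trajectories, Lyapunov exponent estimation from the pre-saturation
# growth of the state distance, and the mapping from initial to final
# scale-by-scale error.

#' Divergence trace between a perturbed and a reference trajectory
#'
#' @param times tau grid.
#' @param delta Euclidean distances ||S_tau - S_tau^ref|| in the full
#'   (3 x ns)-dimensional state space.
#' @return object of class `divergence_trace` (fields `times`, `delta`,
#'   `delta0`).
#' @export
divergence_trace <- function(times, delta) {
  stopifnot(length(times) == length(delta), all(delta >= 0))
  if (delta[1] <= 0) stop("initial distance must be positive")
  structure(list(times = times, delta = delta, delta0 = delta[1]),
            class = "divergence_trace")
}

state_matrix <- function(st) cbind(st$u, st$v, st$w)

#' Perturbed-trajectory divergence experiment
#'
#' Runs `n_perturbations` simulations from noisy initial colors (reference
#' colors plus s C' noise, see [perturb_colors()]), converts each to RD
#' space through the juvenile color transform, simulates alongside the
#' reference run, and records the full-state Euclidean distance over time
#' plus the scale-by-scale color errors at the first and final time
#' points. Zero-distance perturbations (s = 0 draws) are discarded.
#'
#' @param lattice a `scale_lattice`.
#' @param params an [rd_params()] object.
#' @param ref_colors a [color_state()], the observed juvenile colors.
#' @param clusters a `color_clusters` for the color transform and Esbs.
#' @param times tau grid (first entry = juvenile, last = adult).
#' @param n_perturbations number of noisy runs.
#' @param seed RNG seed.
#' @param r IC contraction passed to [colors_to_rd()].
#' @return list with `traces` (list of `divergence_trace`), `esbs0`,
#'   `esbsf` (per run, against the reference trajectory), `reference`
#'   (list of [rd_state()]s), `n_discarded`.
#' @export
divergence_trajectories <- function(lattice, params, ref_colors, clusters,
                                    times, n_perturbations, seed = 1,
                                    r = params$r) {
  sr <- linear_stability(params, S = lattice$S, eps = lattice$epsilon)
  ref_ic <- colors_to_rd(ref_colors, clusters, sr, r = r)
  ref_run <- simulate_drd(lattice, params, ref_ic, times)
  ref_mat <- lapply(ref_run, state_matrix)
  Te <- affine_T2(sr$ug, sr$ub, clusters$Cg, clusters$Cb) %*%
    affine_T1(sr$ug, sr$ub)
  ref_cols_f <- rd_to_colors(ref_run[[length(times)]], Te)
  traces <- list(); esbs0 <- numeric(0); esbsf <- numeric(0)
  n_disc <- 0L
  for (i in seq_len(n_perturbations)) {
    pc <- perturb_colors(ref_colors, seed = seed + i)
    ic <- colors_to_rd(pc, clusters, sr, r = r)
    d0 <- sqrt(sum((state_matrix(ic) - state_matrix(ref_ic))^2))
    if (d0 <= 0) { n_disc <- n_disc + 1L; next }
    run <- simulate_drd(lattice, params, ic, times)
    delta <- vapply(seq_along(times), function(k)
      sqrt(sum((state_matrix(run[[k]]) - ref_mat[[k]])^2)), 0)
    traces[[length(traces) + 1L]] <- divergence_trace(times, delta)
    esbs0 <- c(esbs0, esbs(pc, ref_colors, clusters))
    esbsf <- c(esbsf, esbs(rd_to_colors(run[[length(times)]], Te),
                           ref_cols_f, clusters))
  }
  list(traces = traces, esbs0 = esbs0, esbsf = esbsf,
       reference = ref_run, n_discarded = n_disc)
}

#' Lyapunov exponent from a divergence trace
#'
#' Least-squares slope of log(delta_tau / delta_0) against (tau - tau_0)
#' over the pre-saturation window: samples with delta below `sat_frac`
#' times the trace maximum and tau within the first `window_frac` of the
#' horizon (at least `min_points` samples; the window is extended to the
#' earliest `min_points` samples if the rules leave fewer).
#'
#' @param trace a [divergence_trace()] (or list with `times`, `delta`).
#' @param sat_frac saturation cutoff as a fraction of max(delta).
#' @param window_frac early-time window as a fraction of the horizon.
#' @param min_points minimum samples used in the fit.
#' @return slope estimate lambda (1/tau units).
#' @export
lyapunov_exponent <- function(trace, sat_frac = 0.5, window_frac = 0.5,
                              min_points = 5L) {
  tt <- trace$times; dd <- trace$delta
  if (any(dd <= 0)) stop("non-positive distances in trace")
  t0 <- tt[1]
  sel <- dd < sat_frac * max(dd) & tt <= t0 + window_frac * (max(tt) - t0)
  sel[1] <- TRUE
  if (sum(sel) < min_points) sel <- seq_along(tt) <= min_points
  y <- log(dd[sel] / dd[1]); x <- tt[sel] - t0
  as.numeric(stats::coef(stats::lm(y ~ x))[2])
}

#' Map initial scale-by-scale error to final error
#'
#' Isotonic (monotone non-decreasing) trend of Esbs_final against
#' Esbs_initial across runs; each probe value returns the fitted trend
#' value and the empirical spread (s.d. of the `k` nearest runs).
#'
#' @param esbs0,esbsf per-run initial and final errors (>= 50 runs
#'   recommended).
#' @param probes Esbs_initial values at which to read off the mapping.
#' @param k neighborhood size for the empirical spread.
#' @return data.frame with columns probe, fitted, spread, extrapolated.
#' @export
ic_to_final_error <- function(esbs0, esbsf, probes, k = 25L) {
  stopifnot(length(esbs0) == length(esbsf))
  ord <- order(esbs0)
  x <- esbs0[ord]; y <- esbsf[ord]
  iso <- stats::isoreg(x, y)
  yfit <- iso$yf
  interp <- stats::approxfun(x, yfit, rule = 2, ties = mean)
  out <- lapply(probes, function(p) {
    extrap <- p < min(x) || p > max(x)
    if (extrap) warning("probe ", format(p), " outside the observed range")
    nn <- order(abs(x - p))[seq_len(min(k, length(x)))]
    data.frame(probe = p, fitted = interp(p), spread = stats::sd(y[nn]),
               extrapolated = extrap)
  })
  do.call(rbind, out)
}
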