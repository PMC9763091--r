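# Bayesian optimization of RD parameters: Matern-5/2 ARD Gaussian process
# surrogate, expected-improvement acquisition, hyper-parameter fitting by
# marginal likelihood, greedy forward parameter selection, and the
# parameter-perturbation sensitivity scan.

#' Matern-5/2 ARD covariance
#'
#' k(x, x') = sigma_f^2 (1 + sqrt(5) h + 5/3 h^2) exp(-sqrt(5) h) with
#' h^2 = (x - x') diag(sigma)^-2 (x - x')^T (one length scale per
#' dimension).
#'
#' @param x,xp numeric vectors (same length) or matrices (rows = points).
#' @param sigma_f signal standard deviation (> 0).
#' @param sigma_l length scales, one per dimension (> 0).
#' @return scalar or matrix of covariances (rows of x by rows of xp).
#' @export
matern52 <- function(x, xp, sigma_f, sigma_l) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(xp))) xp <- matrix(xp, 1)
  stopifnot(all(sigma_l > 0), sigma_f > 0)
  xs <- sweep(x, 2, sigma_l, "/"); xps <- sweep(xp, 2, sigma_l, "/")
  h2 <- outer(rowSums(xs^2), rowSums(xps^2), "+") - 2 * xs %*% t(xps)
  h <- sqrt(pmax(h2, 0))
  K <- sigma_f^2 * (1 + sqrt(5) * h + 5 / 3 * h^2) * exp(-sqrt(5) * h)
  if (length(K) == 1L) as.numeric(K) else K
}

#' Fit a noise-free GP surrogate (prior mean zero)
#'
#' Cholesky-factorizes the kernel matrix with diagonal jitter, escalated
#' tenfold (up to `max_jitter`) when factorization fails.
#'
#' @param X n x d matrix of training inputs.
#' @param f length-n outputs.
#' @param sigma_f,sigma_l hyper-parameters as in [matern52()].
#' @param jitter initial diagonal jitter.
#' @param max_jitter jitter ceiling before giving up.
#' @return object of class `gp_model`.
#' @export
gp_fit <- function(X, f, sigma_f, sigma_l, jitter = 1e-10,
                   max_jitter = 1e-6) {
  X <- as.matrix(X)
  K <- matern52(X, X, sigma_f, sigma_l)
  n <- nrow(X)
  repeat {
    ch <- tryCatch(chol(K + jitter * sigma_f^2 * diag(n)),
                   error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- jitter * 10
    if (jitter > max_jitter) stop("kernel matrix not positive definite")
  }
  alpha <- backsolve(ch, backsolve(ch, f, transpose = TRUE))
  structure(list(X = X, f = f, sigma_f = sigma_f, sigma_l = sigma_l,
                 chol = ch, alpha = alpha, jitter = jitter),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("gp_model: %d points, d = %d, sigma_f = %.3g\n",
              nrow(x$X), ncol(x$X), x$sigma_f))
  invisible(x)
}

#' GP posterior mean and variance
#'
#' m_post(x*) = k*^T K^-1 f, k_post(x*) = k(x*, x*) - k*^T K^-1 k* (prior
#' mean zero, noise-free observations).
#'
#' @param model a [gp_fit()] object.
#' @param Xstar query points (matrix rows, or single vector).
#' @return list with vectors `mean` and `var` (variance floored at 0).
#' @export
gp_posterior <- function(model, Xstar) {
  if (is.null(dim(Xstar))) Xstar <- matrix(Xstar, 1)
  ks <- matern52(model$X, Xstar, model$sigma_f, model$sigma_l)
  ks <- matrix(ks, nrow = nrow(model$X))
  m <- as.numeric(t(ks) %*% model$alpha)
  Vh <- backsolve(model$chol, ks, transpose = TRUE)
  v <- model$sigma_f^2 - colSums(Vh^2)
  list(mean = m, var = pmax(v, 0))
}

# log marginal likelihood of a noise-free GP with Matern-5/2 ARD kernel
gp_lml <- function(X, f, sigma_f, sigma_l, jitter = 1e-10) {
  K <- matern52(X, X, sigma_f, sigma_l) + jitter * sigma_f^2 * diag(nrow(X))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  alpha <- backsolve(ch, backsolve(ch, f, transpose = TRUE))
  -0.5 * sum(f * alpha) - sum(log(diag(ch))) - 0.5 * length(f) * log(2 * pi)
}

# fit hypers by marginal-likelihood ascent with random restarts
gp_fit_hypers <- function(X, f, n_restarts = 5, seed = 1) {
  X <- as.matrix(X); d <- ncol(X)
  rng <- apply(X, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  f_sd <- max(stats::sd(f), 1e-6)
  set.seed(seed)
  obj <- function(lt) -gp_lml(X, f, exp(lt[1]), exp(lt[-1]))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- c(log(f_sd * stats::runif(1, 0.5, 2)),
              log(rng * stats::runif(d, 0.2, 2)))
    fit <- tryCatch(stats::optim(init, obj, method = "L-BFGS-B",
                                 lower = c(log(f_sd) - 6, log(rng) - 5),
                                 upper = c(log(f_sd) + 6, log(rng) + 3)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) list(sigma_f = f_sd, sigma_l = rng)
  else list(sigma_f = exp(best$par[1]), sigma_l = exp(best$par[-1]))
}

#' Expected improvement acquisition
#'
#' EI(x*) = (f_min - m) Phi(z) + s phi(z), z = (f_min - m)/s, s =
#' sqrt(k_post); EI = 0 where s = 0 and m >= f_min.
#'
#' @param mean,var posterior mean and variance (from [gp_posterior()]).
#' @param f_min best (lowest) objective value so far.
#' @return vector of EI values (>= 0).
#' @export
expected_improvement <- function(mean, var, f_min) {
  s <- sqrt(pmax(var, 0))
  d <- f_min - mean
  ei <- ifelse(s > 0,
               d * stats::pnorm(d / s) + s * stats::dnorm(d / s),
               pmax(d, 0))
  pmax(ei, 0)
}

#' Bayesian optimization loop
#'
#' Minimizes `objective` over a box: initial space-filling design, then
#' iterations of (refit hyper-parameters by marginal-likelihood ascent,
#' maximize expected improvement by multi-start local search, evaluate the
#' objective). Stops at `budget` evaluations or after `no_improve` proposals
#' without improvement. Non-finite objective values are recorded as a large
#' penalty. Evaluations are cached by parameter vector.
#'
#' @param objective function taking a named numeric vector, returning a
#'   scalar.
#' @param lower,upper named bound vectors (finite).
#' @param budget total number of objective evaluations.
#' @param n_init size of the initial random design (default max(5, 2d)).
#' @param no_improve stop after this many successive non-improving
#'   evaluations (default 50; the full-scale analysis used 1000).
#' @param seed RNG seed (design, restarts, EI multi-start).
#' @return list with `best_x`, `best_f`, and `trace` (data.frame with one
#'   row per evaluation: parameters, objective, best_so_far).
#' @export
bayes_opt <- function(objective, lower, upper, budget = 60,
                      n_init = NULL, no_improve = 50, seed = 1) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  d <- length(lower)
  nms <- names(lower)
  if (is.null(nms)) nms <- paste0("x", seq_len(d))
  if (is.null(n_init)) n_init <- max(5, 2 * d)
  n_init <- min(n_init, budget)
  set.seed(seed)
  # stratified (latin-hypercube style) initial design
  U <- sapply(seq_len(d), function(j) (sample.int(n_init) - stats::runif(n_init)) / n_init)
  X <- sweep(sweep(matrix(U, n_init, d), 2, upper - lower, "*"), 2, lower, "+")
  cache <- new.env(hash = TRUE)
  penalty_base <- NULL
  eval_obj <- function(x) {
    key <- paste(format(x, digits = 15), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(objective(stats::setNames(x, nms)), error = function(e) NA_real_)
    if (!is.finite(val)) {
      val <- if (is.null(penalty_base)) 1e6 else 10 * abs(penalty_base) + 1e3
    }
    cache[[key]] <- val
    val
  }
  f <- numeric(n_init)
  for (i in seq_len(n_init)) {
    f[i] <- eval_obj(X[i, ])
    if (is.null(penalty_base)) penalty_base <- f[i]
  }
  since_improve <- 0L
  while (nrow(X) < budget && since_improve < no_improve) {
    hyp <- gp_fit_hypers(X, f, seed = seed + nrow(X))
    model <- gp_fit(X, f - mean(f), hyp$sigma_f, hyp$sigma_l)
    f_min <- min(f)
    neg_ei <- function(x) {
      po <- gp_posterior(model, pmin(pmax(x, lower), upper))
      -expected_improvement(po$mean + mean(f), po$var, f_min)
    }
    starts <- rbind(X[which.min(f), , drop = FALSE],
                    sweep(sweep(matrix(stats::runif(10 * d), 10, d), 2,
                                upper - lower, "*"), 2, lower, "+"))
    best_x <- NULL; best_v <- Inf
    for (si in seq_len(nrow(starts))) {
      op <- tryCatch(stats::optim(starts[si, ], neg_ei, method = "L-BFGS-B",
                                  lower = lower, upper = upper),
                     error = function(e) NULL)
      if (!is.null(op) && op$value < best_v) { best_v <- op$value; best_x <- op$par }
    }
    if (is.null(best_x))
      best_x <- lower + stats::runif(d) * (upper - lower)
    newf <- eval_obj(best_x)
    X <- rbind(X, best_x); f <- c(f, newf)
    since_improve <- if (newf < f_min - 1e-12) 0L else since_improve + 1L
  }
  trace <- as.data.frame(X)
  names(trace) <- nms
  trace$objective <- f
  trace$best_so_far <- cummin(f)
  ib <- which.min(f)
  list(best_x = stats::setNames(X[ib, ], nms), best_f = f[ib], trace = trace)
}

#' Greedy forward selection of RD parameters to optimize
#'
#' Starts from the base subset (growth rate q and IC contraction r); each
#' round optimizes every augmented subset and permanently adds the
#' candidate whose inclusion yields the lowest objective; stops when no
#' candidate reduces the best objective.
#'
#' @param candidates character vector of candidate parameter names.
#' @param base_values named vector of all parameter values (defaults for
#'   parameters not currently optimized).
#' @param objective function of a full named parameter vector.
#' @param lower,upper named bound vectors covering base and candidates.
#' @param budget evaluations per [bayes_opt()] call.
#' @param base character vector, the always-optimized subset.
#' @param seed RNG seed.
#' @return list with `selected` (ordered names added after the base),
#'   `table` (data.frame round/parameter/objective), `best_objective`.
#' @export
iterative_param_addition <- function(candidates, base_values, objective,
                                     lower, upper, budget = 30,
                                     base = c("q", "r"), seed = 1) {
  stopifnot(length(candidates) >= 1)
  run_subset <- function(subset, sd) {
    obj_sub <- function(x) {
      full <- base_values
      full[names(x)] <- x
      objective(full)
    }
    bo <- bayes_opt(obj_sub, lower[subset], upper[subset], budget = budget,
                    no_improve = budget, seed = sd)
    bo$best_f
  }
  selected <- character(0)
  best <- run_subset(base, seed)
  tab <- data.frame(round = 0L, parameter = "(base)", objective = best,
                    stringsAsFactors = FALSE)
  remaining <- setdiff(candidates, base)
  round_i <- 0L
  while (length(remaining)) {
    round_i <- round_i + 1L
    vals <- vapply(seq_along(remaining), function(ci)
      run_subset(c(base, selected, remaining[ci]), seed + 100 * round_i + ci),
      0)
    best_ci <- which.min(vals)
    if (vals[best_ci] >= best - 1e-12) break
    selected <- c(selected, remaining[best_ci])
    best <- vals[best_ci]
    tab <- rbind(tab, data.frame(round = round_i,
                                 parameter = remaining[best_ci],
                                 objective = best))
    remaining <- remaining[-best_ci]
  }
  list(selected = selected, table = tab, best_objective = best)
}

#' Parameter-perturbation sensitivity scan
#'
#' Runs `n_samples` simulations with parameters jointly perturbed by
#' uniform draws within +/- `frac` of the fitted GP length scales (the
#' per-parameter normalization of the surrogate), computes the
#' scale-by-scale error of each against the unperturbed run, and fits a
#' gamma distribution to the error histogram.
#'
#' @param simulate function from a named parameter vector to the quantity
#'   compared (e.g. a final `color_state` or `pattern_state`).
#' @param params_opt named vector of optimal parameter values.
#' @param sigma_l named vector of per-parameter length scales.
#' @param n_samples number of perturbed runs.
#' @param error_fn function(sim_out, ref_out) -> scalar Esbs.
#' @param frac half-width of the uniform perturbation as a multiple of
#'   `sigma_l` (default 0.1).
#' @param seed RNG seed.
#' @return list with `esbs` (vector, failures dropped), `n_failed`,
#'   `gamma_fit` (shape/rate, or NULL when degenerate), `mean`, `sd`.
#' @export
sensitivity_scan <- function(simulate, params_opt, sigma_l, n_samples,
                             error_fn, frac = 0.1, seed = 1) {
  set.seed(seed)
  ref <- simulate(params_opt)
  esbs_vals <- numeric(0); n_failed <- 0L
  d <- length(params_opt)
  for (i in seq_len(n_samples)) {
    delta <- stats::runif(d, -frac, frac) * sigma_l[names(params_opt)]
    out <- tryCatch(simulate(params_opt + delta), error = function(e) NULL)
    if (is.null(out)) { n_failed <- n_failed + 1L; next }
    esbs_vals <- c(esbs_vals, error_fn(out, ref))
  }
  gf <- NULL
  pos <- esbs_vals[esbs_vals > 0]
  if (length(pos) >= 10 && stats::sd(pos) > 0) {
    # fitdistr probes invalid parameter regions while optimizing; its
    # NaN warnings are internal noise
    gf <- tryCatch(suppressWarnings(MASS::fitdistr(pos, "gamma")),
                   error = function(e) NULL)
  }
  list(esbs = esbs_vals, n_failed = n_failed, gamma_fit = gf,
       mean = mean(esbs_vals), sd = stats::sd(esbs_vals))
}
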