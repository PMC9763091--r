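# sCA rule inference and simulation; Lenz-Ising energy, Metropolis
# dynamics against exact enumeration, and pseudo-likelihood fitting.

test_that("Bayesian rule estimates match the printed posterior formulas", {
  n <- matrix(0L, 2, 8); k <- matrix(0L, 2, 8)
  n[1, 3] <- 10L; k[1, 3] <- 3L
  r <- sca_rules(n, k)
  expect_equal(r$E_p[1, 3], 4 / 12, tolerance = 1e-15)
  expect_equal(r$p_map[1, 3], 0.3, tolerance = 1e-15)
  expect_equal(r$E_p[2, 5], 0.5)            # empty bin
  expect_true(is.na(r$p_map[2, 5]))
  # E[p] equals the quadrature mean of f(p|k,n) = (n+1) C(n,k) p^k (1-p)^(n-k)
  for (cs in list(c(0, 0), c(3, 10), c(7, 7), c(1, 25))) {
    kk <- cs[1]; nn <- cs[2]
    post_mean <- stats::integrate(function(p)
      p * (nn + 1) * choose(nn, kk) * p^kk * (1 - p)^(nn - kk),
      0, 1, rel.tol = 1e-12)$value
    expect_equal((kk + 1) / (nn + 2), post_mean, tolerance = 1e-9)
  }
})

test_that("rule inference counts trials and flips across time points", {
  lat <- fix_hex(4, 4)
  p1 <- pattern_state(rep("green", 16))
  s2 <- rep("green", 16); s2[c(1, 6)] <- "black"
  p2 <- pattern_state(s2)
  r <- infer_sca_rules(lat, list(p1, p2))
  expect_equal(sum(r$n), 16L)
  expect_equal(sum(r$k), 2L)
  # scale 6 is interior (6 neighbors, all green): trial in (green, 6)
  expect_equal(r$k["green", "6"], 1L)
  expect_error(infer_sca_rules(lat, list(p1)))
})

test_that("sCA limit rules behave as expected", {
  lat <- fix_hex(4, 4)
  p0 <- random_pattern(16, seed = 1)
  # all-zero-ish rules: nothing flips, stops at cap
  rules0 <- sca_rules(matrix(10000L, 2, 8), matrix(0L, 2, 8))
  expect_warning(
    out <- simulate_sca(lat, p0, rules0, target_flips = 5, seed = 1,
                        max_iter = 30),
    "target")
  expect_lt(flips_between(out, p0), 3)
  # E[p] ~ 1 for every configuration: one synchronous full inversion
  rules1 <- sca_rules(matrix(0L, 2, 8) + 100000L,
                      matrix(0L, 2, 8) + 100000L)
  out1 <- simulate_sca(lat, p0, rules1, target_flips = 16, seed = 1)
  expect_equal(attr(out1, "iterations"), 1L)
  expect_gte(flips_between(out1, p0), 15L)
})

test_that("long-run sCA bin frequencies match the exact Markov stationary law", {
  n <- 10L
  lat <- ring_lattice(n)
  # hand-set rules depending on state and isochromatic count
  n_tab <- matrix(1000L, 2, 8); k_tab <- matrix(0L, 2, 8)
  k_tab[1, 1] <- 300L; k_tab[1, 2] <- 150L; k_tab[1, 3] <- 50L
  k_tab[2, 1] <- 100L; k_tab[2, 2] <- 200L; k_tab[2, 3] <- 400L
  rules <- sca_rules(n_tab, k_tab)
  # exact transition matrix over the 2^10 state space
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))  # 1 = green
  flip_prob <- function(svec) {
    vapply(seq_len(n), function(i) {
      iso <- sum(svec[lat$adjacency[[i]]] == svec[i])
      rules$E_p[2 - svec[i], iso + 1]
    }, 0)
  }
  P <- matrix(0, 2^n, 2^n)
  for (a in seq_len(2^n)) {
    pf <- flip_prob(states[a, ])
    for (b in seq_len(2^n)) {
      diffv <- states[a, ] != states[b, ]
      P[a, b] <- prod(ifelse(diffv, pf, 1 - pf))
    }
  }
  ev <- Re(eigen(t(P))$vectors[, 1])
  pi_exact <- ev / sum(ev)
  # exact stationary bin distribution n(S, i)
  bins_exact <- matrix(0, 2, 8)
  for (a in seq_len(2^n)) {
    sv <- states[a, ]
    for (i in seq_len(n)) {
      iso <- sum(sv[lat$adjacency[[i]]] == sv[i])
      bins_exact[2 - sv[i], iso + 1] <-
        bins_exact[2 - sv[i], iso + 1] + pi_exact[a]
    }
  }
  bins_exact <- bins_exact / n
  # empirical long run
  set.seed(42)
  cur <- random_pattern(n, seed = 5)
  bins_emp <- matrix(0, 2, 8)
  burn <- 200L; keep <- 4000L
  for (it in seq_len(burn + keep)) {
    cur <- simulate_sca(lat, cur, rules, target_flips = NULL, seed = it,
                        max_iter = 1)
    if (it > burn)
      bins_emp <- bins_emp + neighbor_stats(lat, cur) / n
  }
  bins_emp <- bins_emp / keep
  expect_lt(sum(abs(bins_emp - bins_exact)) / 2, 0.02)
})

test_that("Ising energy matches hand counts and incremental flips", {
  one <- build_hex_lattice(1, 1, S = 1)
  expect_equal(ising_energy(one, pattern_state("green"),
                            ising_params(0.7, 0.3)), -0.3)
  two <- build_hex_lattice(2, 1, S = 1)
  expect_equal(ising_energy(two, pattern_state(c("green", "green")),
                            ising_params(0.7, 0.3)), -0.7 - 0.6,
               tolerance = 1e-12)
  lat <- fix_voronoi(n = 30, seed = 3)
  ip <- ising_params(-0.4, 0.2)
  for (seed in 1:5) {
    pat <- random_pattern(30, seed = seed)
    i <- sample.int(30, 1)
    flipped <- pat$states
    flipped[i] <- ifelse(flipped[i] == "green", "black", "green")
    dE_full <- ising_energy(lat, pattern_state(flipped), ip) -
      ising_energy(lat, pat, ip)
    s <- ifelse(pat$states == "green", 1, -1)
    dE_inc <- 2 * s[i] * (ip$betaJ * sum(s[lat$adjacency[[i]]]) + ip$betaB)
    expect_equal(dE_full, dE_inc, tolerance = 1e-12)
  }
})

test_that("Metropolis detailed balance holds analytically on single flips", {
  lat <- ring_lattice(6)
  ip <- ising_params(-0.6, 0.25)
  pat <- random_pattern(6, seed = 2)
  for (i in 1:6) {
    flipped <- pat$states
    flipped[i] <- ifelse(flipped[i] == "green", "black", "green")
    Ea <- ising_energy(lat, pat, ip)
    Eb <- ising_energy(lat, pattern_state(flipped), ip)
    # pi(a) P(a->b) = pi(b) P(b->a) with Metropolis acceptance
    lhs <- exp(-Ea) * min(1, exp(-(Eb - Ea)))
    rhs <- exp(-Eb) * min(1, exp(-(Ea - Eb)))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Metropolis sampling matches the exact Boltzmann law on a 6-cycle", {
  n <- 6L
  lat <- ring_lattice(n)
  ip <- ising_params(-0.5, -0.3)
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  energies <- apply(states, 1, function(s) {
    pair <- sum(vapply(seq_len(n), function(i)
      sum(s[i] * s[lat$adjacency[[i]]]), 0)) / 2
    -ip$betaJ * pair - ip$betaB * sum(s)
  })
  pi_exact <- exp(-energies) / sum(exp(-energies))
  # empirical distribution from a long chain, sampled every sweep
  counts <- numeric(2^n)
  cur <- random_pattern(n, seed = 1)
  key <- function(p) sum((ifelse(p$states == "green", 1, 0)) * 2^(0:(n - 1))) + 1
  keymap <- apply(states, 1, function(s) sum((s + 1) / 2 * 2^(0:(n - 1))) + 1)
  ord <- order(keymap)
  for (it in 1:60000) {
    cur <- simulate_ising(lat, cur, ip, n_sweeps = 1, seed = it)
    counts[key(cur)] <- counts[key(cur)] + 1
  }
  pi_emp <- counts / sum(counts)
  tv <- sum(abs(pi_emp - pi_exact[ord])) / 2
  expect_lt(tv, 0.02)
})

test_that("zero-coupling Metropolis gives 0.5 green frequency and logistic field response", {
  lat <- fix_hex(5, 5)
  # betaJ = betaB = 0: uniform stationary law
  out <- simulate_ising(lat, random_pattern(25, 1), ising_params(0, 0),
                        n_sweeps = 2000, seed = 3)
  # single long run: average green fraction over last sweeps via re-runs
  fr <- mean(vapply(1:40, function(s)
    mean(simulate_ising(lat, random_pattern(25, s), ising_params(0, 0),
                        n_sweeps = 50, seed = s)$states == "green"), 0))
  expect_equal(fr, 0.5, tolerance = 0.03)
  # betaB > 0, betaJ = 0: per-site green probability = logistic(2 betaB)
  bB <- 0.6
  frB <- mean(vapply(1:40, function(s)
    mean(simulate_ising(lat, random_pattern(25, s), ising_params(0, bB),
                        n_sweeps = 50, seed = s)$states == "green"), 0))
  expect_equal(frB, 1 / (1 + exp(-2 * bB)), tolerance = 0.03)
})

test_that("pseudo-likelihood recovers Ising parameters on simulated patches", {
  lat <- build_hex_lattice(20, 20, S = 1)
  truth <- ising_params(-0.5, -0.3)
  # occasional near-uniform draws hit the box bound; the median is robust
  ests <- t(vapply(1:12, function(s) {
    pat <- simulate_ising(lat, random_pattern(400, seed = s), truth,
                          n_sweeps = 150, seed = 1000 + s)
    fit <- suppressWarnings(fit_ising_params(lat, pat))
    c(fit$betaJ, fit$betaB)
  }, numeric(2)))
  expect_lt(abs(stats::median(ests[, 1]) - (-0.5)) / 0.5, 0.10)
  expect_lt(abs(stats::median(ests[, 2]) - (-0.3)) / 0.3, 0.10)
  # checkerboard-ish pattern fits antiferromagnetic
  chk <- pattern_state(ifelse((rep(1:20, 20) + rep(1:20, each = 20)) %% 2
                              == 0, "green", "black"))
  # a perfect checkerboard separates the logistic: betaJ runs to the
  # antiferromagnetic bound (and is flagged), with the correct sign
  expect_warning(fit_chk <- fit_ising_params(lat, chk), "bound")
  expect_lt(fit_chk$betaJ, 0)
  # uniform pattern hits the bound and is flagged
  expect_warning(fit0 <- fit_ising_params(lat,
                                          pattern_state(rep("black", 400))),
                 "bound")
  expect_true(attr(fit0, "bound_hit"))
})

test_that("symmetric sCA rules preserve the expected green fraction", {
  lat <- fix_hex(6, 6)
  # E[p] depending only on i (not on state): green/black symmetric
  n_tab <- matrix(1000L, 2, 8)
  k_tab <- rbind(seq(50L, 400L, by = 50L), seq(50L, 400L, by = 50L))
  rules <- sca_rules(n_tab, k_tab)
  fr <- mean(vapply(1:60, function(s) {
    out <- simulate_sca(lat, random_pattern(36, seed = s), rules,
                        target_flips = NULL, seed = s + 500, max_iter = 25)
    mean(out$states == "green")
  }, 0))
  expect_equal(fr, 0.5, tolerance = 0.03)
})

test_that("rule inference inverts simulation on long trajectories", {
  lat <- fix_hex(6, 6)
  n_tab <- matrix(1000L, 2, 8)
  k_tab <- matrix(0L, 2, 8)
  k_tab[1, ] <- c(400L, 300L, 250L, 200L, 150L, 100L, 80L, 50L)
  k_tab[2, ] <- c(350L, 320L, 240L, 180L, 120L, 90L, 60L, 40L)
  rules <- sca_rules(n_tab, k_tab)
  traj <- simulate_sca(lat, random_pattern(36, seed = 2), rules,
                       target_flips = NULL, seed = 77, max_iter = 400,
                       keep_trajectory = TRUE)
  est <- infer_sca_rules(lat, attr(traj, "trajectory"))
  # every well-populated configuration is recovered within its posterior
  # uncertainty (3 posterior s.d.)
  pop <- est$n >= 100
  post_sd <- sqrt(est$E_p * (1 - est$E_p) / (est$n + 3))
  expect_true(all(abs(est$E_p - rules$E_p)[pop] <=
                    3 * post_sd[pop] + 0.02))
})
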