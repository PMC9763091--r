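# Reaction terms, steady state, linear theory and the two 2D solvers.

test_that("reaction terms clamp exactly as specified", {
  p <- fix_params(Fmax = 0.5)
  # force the linear form negative / above the cap / in the middle
  expect_equal(reaction_terms(0, 0, 0, fix_params(c3 = -1))$F, 0)
  expect_equal(reaction_terms(0, 0, 0, fix_params(c3 = 1.5, Fmax = 0.5))$F,
               0.5)
  v <- 3.2; w <- 3.3
  expect_equal(reaction_terms(0, v, w, p)$F, p$c1 * v + p$c2 * w + p$c3,
               tolerance = 1e-15)
})

test_that("the HSS solves the printed linear system with tiny residual", {
  p <- fix_params()
  hss <- solve_hss(p)
  # independent 3x3 solve
  A <- matrix(c(-p$cu, p$c1, p$c2, p$c4, -p$cv, p$c5, p$c7, p$c8, -p$cw),
              3, 3, byrow = TRUE)
  expect_equal(unname(hss$u_star), solve(A, -c(p$c3, p$c6, p$c9)),
               tolerance = 1e-12)
  rt <- reaction_terms(hss$u_star[1], hss$u_star[2], hss$u_star[3], p)
  resid <- c(rt$F - p$cu * hss$u_star[1], rt$G - p$cv * hss$u_star[2],
             rt$H - p$cw * hss$u_star[3])
  expect_lt(max(abs(resid)), 1e-10)
  expect_true(hss$valid)
  # homogeneous system
  p0 <- fix_params(c3 = 0, c6 = 0, c9 = 0)
  expect_equal(unname(solve_hss(p0)$u_star), c(0, 0, 0), tolerance = 1e-12)
  # caps below the branch values invalidate the middle-branch assumption
  expect_false(solve_hss(fix_params(Fmax = 0.01))$valid)
})

test_that("linear stability reduces to the reaction Jacobian as P -> 0", {
  p <- fix_params(P = 1e-12)
  # the pure reaction Jacobian has a complex eigenpair; only M is checked
  sr <- suppressWarnings(linear_stability(p, S = 1))
  A <- matrix(c(-p$cu, p$c1, p$c2, p$c4, -p$cv, p$c5, p$c7, p$c8, -p$cw),
              3, 3, byrow = TRUE)
  expect_equal(sr$M, A, tolerance = 1e-9)
})

test_that("extremities lie on the clamping planes and the fixture geometry is Turing-unstable", {
  p <- fix_params()
  sr <- linear_stability(p, S = FIX_S)
  expect_gt(sr$lambda1, 0)
  bv <- function(u) c(p$c1 * u[2] + p$c2 * u[3] + p$c3,
                      p$c4 * u[1] + p$c5 * u[3] + p$c6,
                      p$c7 * u[1] + p$c8 * u[2] + p$c9)
  on_plane <- function(u) {
    b <- bv(u)
    any(abs(b) < 1e-9) || any(abs(b - c(p$Fmax, p$Gmax, p$Hmax)) < 1e-9)
  }
  expect_true(on_plane(sr$ug))
  expect_true(on_plane(sr$ub))
  expect_gt(sr$ug[2], sr$ub[2])   # v_g > v_b labeling
  # stationarity: M u* + b = 0
  expect_lt(max(abs(sr$M %*% sr$u_star + sr$b)), 1e-10)
})

test_that("the closed-form linear solution matches adaptive ODE integration", {
  p <- fix_params()
  sr <- linear_stability(p, S = FIX_S)
  u0 <- sr$u_star + c(0.3, -0.2, 0.1)
  expect_equal(analytic_linear_solution(u0, sr$M, sr$b, 0)[1, ],
               u0, tolerance = 1e-12, ignore_attr = TRUE)
  tt <- seq(0, 10, by = 0.5)
  ana <- analytic_linear_solution(u0, sr$M, sr$b, tt)
  ode <- deSolve::ode(u0, tt, function(t, y, par)
    list(as.numeric(sr$M %*% y + sr$b)), NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(ana), unname(ode[, 2:4]), tolerance = 1e-6)
  # stable system converges to u* = -M^-1 b
  p0 <- fix_params()
  sr0 <- linear_stability(p0, S = 0.3)       # strong coupling: all stable
  expect_true(all(Re(sr0$eigenvalues) < 0))
  late <- analytic_linear_solution(sr0$u_star + c(1, 1, 1), sr0$M, sr0$b,
                                   5000)
  expect_equal(late[1, ], -solve(sr0$M, sr0$b), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("late-time linear trajectories align with the dominating eigenvector", {
  p <- fix_params()
  sr <- linear_stability(p, S = FIX_S)
  u0 <- sr$u_star + c(0.05, 0.02, -0.03)
  tt <- c(600, 900)
  pts <- analytic_linear_solution(u0, sr$M, sr$b, tt)
  dirv <- pts[2, ] - pts[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  angle <- acos(min(abs(sum(dirv * sr$v1)), 1)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("sign of lambda1 predicts growth or decay of a tiny perturbation", {
  # lambda1 describes one scale whose neighbors sit at the HSS; simulate
  # that nonlinear single-scale model directly (clamped reactions + the
  # hexagonal coupling toward u*) as the independent oracle
  p <- fix_params()
  us <- solve_hss(p)$u_star
  run <- function(S, horizon) {
    kcoef <- 2 * p$P / (3 * sqrt(3) * S)
    Dm <- c(p$Du, p$Dv, p$Dw)
    rhs <- function(t, y, par) {
      rt <- reaction_terms(y[1], y[2], y[3], p)
      list(c(rt$F, rt$G, rt$H) - c(p$cu, p$cv, p$cw) * y +
             6 * kcoef * Dm * (us - y))
    }
    y0 <- us + c(1e-3, 0, 0)
    sol <- deSolve::ode(y0, c(0, horizon), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    list(lambda1 = linear_stability(p, S = S)$lambda1,
         growth = sqrt(sum((sol[2, 2:4] - us)^2)) / 1e-3)
  }
  unstable <- run(FIX_S, 400)
  expect_gt(unstable$lambda1, 0)
  expect_gt(unstable$growth, 1)
  stable <- run(0.3, 400)
  expect_lt(stable$lambda1, 0)
  expect_lt(stable$growth, 1)
})

test_that("polygon dRD right-hand side reduces to the hexagonal closed form", {
  p <- fix_params()
  lat <- build_hex_lattice(5, 5, S = 2, epsilon = 0.7)
  set.seed(3)
  st <- rd_state(runif(25, 2, 4), runif(25, 2, 4), runif(25, 2, 4))
  rhs <- drd_rhs(lat, p, st)
  kcoef <- 2 * p$P / (3 * sqrt(3) * 2 * 0.7)
  rt <- reaction_terms(st$u, st$v, st$w, p)
  hex_du <- vapply(seq_len(25), function(i) {
    nb <- lat$adjacency[[i]]
    p$q * (rt$F[i] - p$cu * st$u[i] +
             kcoef * p$Du * sum(st$u[nb] - st$u[i]))
  }, 0)
  expect_equal(rhs$du, hex_du, tolerance = 1e-12)
})

test_that("dRD holds the HSS stationary and stays within the clamp bound", {
  p <- fix_params()
  lat <- build_hex_lattice(5, 5, S = FIX_S)
  out <- simulate_drd(lat, p, hss_state(25, p), c(0, 200))
  expect_lt(max(abs(out[[2]]$u - out[[1]]$u)), 1e-8)
  # perturbed run stays bounded by caps / decay + IC
  ic <- hss_state(25, p, perturb = 0.1, seed = 5)
  outp <- simulate_drd(lat, p, ic, c(0, 1500))
  bound <- max(p$Fmax, p$Gmax, p$Hmax) / min(p$cu, p$cv, p$cw) +
    max(abs(c(ic$u, ic$v, ic$w)))
  expect_lt(max(abs(unlist(outp[[2]][c("u", "v", "w")]))), bound + 1e-9)
})

test_that("growth rescales the discrete diffusion by (S_ref/S)^2", {
  p <- fix_params(k1 = 2, k2 = 1, k3 = 2, q = 1)
  lat <- build_hex_lattice(4, 4, S = 2)
  set.seed(9)
  st <- rd_state(runif(16, 2, 4), runif(16, 2, 4), runif(16, 2, 4))
  # at tau = tau_ref the factor is 1: rhs equals the no-growth rhs
  r_ref <- drd_rhs(lat, p, st, tau = 0)
  r_plain <- drd_rhs(lat, fix_params(), st, tau = 0)
  expect_equal(r_ref$du, r_plain$du, tolerance = 1e-12)
  # drd_rhs uses tau_ref = tau, so scan the factor through simulate_drd
  g <- (gen_growth_series(2, 1, 2, 10) / gen_growth_series(2, 1, 2, 0))^2
  expect_gt(g, 1)   # early lattice smaller => stronger coupling
})

test_that("2D-cRD preserves uniform states with P = 1 and the HSS in general", {
  p1 <- fix_params(P = 1)
  lat <- build_hex_lattice(3, 3, S = FIX_S, epsilon = 0.8)
  dom <- make_crd_domain(lat, h = 0.8)
  N <- dom$nx * dom$ny
  us <- solve_hss(p1)$u_star
  out <- simulate_crd2d(dom, p1, rd_state(rep(1, N), rep(2, N), rep(3, N)),
                        c(0, 20), dtau = 1, reaction = FALSE)
  expect_lt(max(abs(out[[2]]$u - 1)), 1e-10)
  p <- fix_params()
  out2 <- simulate_crd2d(dom, p, hss_state(N, p), c(0, 50), dtau = 1)
  expect_lt(max(abs(out2[[2]]$u - us[1])), 1e-8)
})

test_that("2D-cRD diffusion conserves total concentration", {
  lat <- build_hex_lattice(3, 3, S = FIX_S, epsilon = 0.8)
  dom <- make_crd_domain(lat, h = 0.8)
  N <- dom$nx * dom$ny
  set.seed(2)
  ic <- rd_state(runif(N), runif(N), runif(N))
  out <- simulate_crd2d(dom, fix_params(), ic, c(0, 30), dtau = 0.5,
                        reaction = FALSE)
  expect_lt(abs(sum(out[[2]]$u) - sum(ic$u)) / sum(ic$u), 1e-8)
})

test_that("coarse-grained cRD agrees with dRD on a 16-scale fixture", {
  p <- fix_params()
  lat <- build_hex_lattice(4, 4, S = FIX_S, epsilon = 0.6)
  dom <- make_crd_domain(lat, h = 0.5)
  N <- dom$nx * dom$ny
  # a pattern-biased IC pins mode selection for both discretizations:
  # pre-form a pattern with the dRD solver, contract it toward the HSS,
  # and hand the same per-scale IC to both solvers
  us <- solve_hss(p)$u_star
  pre <- simulate_drd(lat, p, hss_state(16, p, perturb = 0.05, seed = 7),
                      c(0, 3000))[[2]]
  ctr <- 0.5
  ic_d <- rd_state(us[1] + ctr * (pre$u - us[1]),
                   us[2] + ctr * (pre$v - us[2]),
                   us[3] + ctr * (pre$w - us[3]))
  sid <- as.vector(dom$scale_id)
  ic_c <- rd_state(ic_d$u[sid], ic_d$v[sid], ic_d$w[sid])
  taus <- c(0, 1500, 3000)
  out_d <- simulate_drd(lat, p, ic_d, taus)
  out_c <- simulate_crd2d(dom, p, ic_c, taus, dtau = 1)
  um_c <- crd2d_scale_means(dom, out_c[[3]], 16)
  # same two-phase structure: compare per-scale states after normalising
  # each field to its own dynamic range (solver-specific amplitudes differ)
  rng <- function(x) (x - min(x)) / diff(range(x))
  rms <- sqrt(mean((rng(um_c$u) - rng(out_d[[3]]$u))^2))
  expect_lt(rms, 0.10)
})
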