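# Normal-map decoding, curvature, scale detection, color extraction,
# matching and network unification.

test_that("normal-map decoding maps channels linearly and checks shape", {
  img <- array(0, c(2, 2, 3))
  img[, , 1] <- 32768 / 65535; img[, , 2] <- 32768 / 65535; img[, , 3] <- 1
  nf <- decode_normal_map(img, renormalize = FALSE)
  expect_lt(max(abs(nf$n1)), 1 / 65535)
  expect_equal(nf$n3[1, 1], 1)
  img0 <- array(0, c(2, 2, 3)); img0[, , 3] <- 1
  nf0 <- decode_normal_map(img0, renormalize = FALSE)
  expect_equal(c(nf0$n1[1, 1], nf0$n2[1, 1], nf0$n3[1, 1]), c(-1, -1, 1))
  expect_error(decode_normal_map(array(0, c(2, 2))), "3-channel")
  # 16-bit file round trip (the png package writes 8-bit only, so the
  # 16-bit on-disk check uses TIFF; readPNG decodes 16-bit PNGs the same)
  gm <- gen_normal_map(S = 30, sigma = 9, height = 4, nx = 2, ny = 2,
                       px_per_scale = 20)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(aperm(gm$image, c(2, 1, 3)), f, bits.per.sample = 16)
  back <- tiff::readTIFF(f)
  nfb <- decode_normal_map(aperm(back, c(2, 1, 3)), renormalize = FALSE)
  expect_lt(max(abs(nfb$n1 - gm$normals$n1)), 2 / 65535)
})

test_that("curvature is exact on flat fields and accurate on analytic surfaces", {
  flat <- structure(list(n1 = matrix(0, 20, 20), n2 = matrix(0, 20, 20),
                         n3 = matrix(1, 20, 20), pitch = 1),
                    class = "normal_field")
  H <- mean_curvature(flat)
  expect_true(all(abs(H[2:19, 2:19]) < 1e-14))
  # hemisphere of radius R: |H| = 1/R within 2% away from the rim
  R <- 40; pitch <- 1
  xs <- seq(-30, 30, by = pitch)
  X <- matrix(xs, length(xs), length(xs)); Y <- t(X)
  z2 <- pmax(R^2 - X^2 - Y^2, 1e-9)
  zx <- -X / sqrt(z2); zy <- -Y / sqrt(z2)
  nn <- sqrt(zx^2 + zy^2 + 1)
  nf <- structure(list(n1 = -zx / nn, n2 = -zy / nn, n3 = 1 / nn,
                       pitch = pitch), class = "normal_field")
  Hs <- mean_curvature(nf)
  core <- X^2 + Y^2 < (0.6 * R)^2
  expect_lt(max(abs(abs(Hs[core]) * R - 1), na.rm = TRUE), 0.02)
  # quadratic z = a x^2 + b y^2: H at the origin tends to a + b
  a <- 0.01; b <- 0.025
  err <- vapply(c(1, 0.5, 0.25), function(h) {
    xs <- seq(-5, 5, by = h); n <- length(xs)
    X <- matrix(xs, n, n); Y <- t(X)
    zx <- 2 * a * X; zy <- 2 * b * Y
    nn <- sqrt(zx^2 + zy^2 + 1)
    nfq <- structure(list(n1 = -zx / nn, n2 = -zy / nn, n3 = 1 / nn,
                          pitch = h), class = "normal_field")
    Hq <- mean_curvature(nfq)
    abs(Hq[(n + 1) / 2, (n + 1) / 2] - (a + b))
  }, 0)
  expect_lt(err[3], 1e-4)
})

test_that("detect_scales recovers a synthetic bump array exactly", {
  gm <- gen_normal_map(S = 30, sigma = 9, p = 1, height = 6, nx = 8,
                       ny = 8, px_per_scale = 24)
  H <- mean_curvature(gm$normals)
  det <- detect_scales(H, s = 24)
  expect_equal(nrow(det$centers), 64)
  d <- vapply(seq_len(64), function(i)
    min(sqrt((det$centers[, 1] - gm$centers_px[i, 1])^2 +
             (det$centers[, 2] - gm$centers_px[i, 2])^2)), 0)
  expect_lt(max(d), 24 / 10)
  # determinism and monotone-rescale invariance of the count
  expect_identical(detect_scales(H, s = 24)$centers, det$centers)
  expect_equal(nrow(detect_scales(3 * H + 2, s = 24)$centers), 64)
  # single bump
  gm1 <- gen_normal_map(S = 30, sigma = 9, height = 6, nx = 1, ny = 1,
                        px_per_scale = 24)
  expect_equal(nrow(detect_scales(mean_curvature(gm1$normals),
                                  s = 24)$centers), 1)
  expect_error(detect_scales(H, s = 5), ">= 10")
})

test_that("scale colors exclude the rim and agree across statistics", {
  lat <- build_voronoi_lattice(hex_centers <- {
    set.seed(2)
    cbind(rep(seq(15, 75, by = 20), 4),
          rep(seq(15, 75, by = 20), each = 4)) + matrix(rnorm(32, 0, 1),
                                                        16)
  }, clip_region = cbind(c(1, 90, 90, 1), c(1, 1, 90, 90)))
  # uniform image: every scale gets that color exactly
  alb <- array(0, c(90, 90, 3))
  alb[, , 1] <- 0.4; alb[, , 2] <- 0.6; alb[, , 3] <- 0.2
  sc <- extract_scale_colors(alb, lat, s = 20)
  ref <- rgb_to_lab(matrix(c(0.4, 0.6, 0.2), 1))
  for (i in seq_len(16))
    expect_equal(unname(sc$mean$colors[i, ]), as.numeric(ref),
                 tolerance = 1e-6)
  # mean/median/mode agree on symmetric unimodal pixel noise
  set.seed(7)
  alb2 <- alb + array(rnorm(90 * 90 * 3, 0, 0.008), c(90, 90, 3))
  alb2 <- pmin(pmax(alb2, 0), 1)
  sc2 <- extract_scale_colors(alb2, lat, s = 20)
  expect_lt(max(abs(sc2$mean$colors - sc2$median)), 1)
  expect_lt(max(abs(sc2$mean$colors - sc2$mode)), 1)
  # two-tone scale: rim pixels (< s/10 of the boundary) are ignored
  ctr <- round(lat$centers[6, ])
  d2b <- function(px, py) {
    d2 <- rowSums(sweep(lat$centers, 2, c(px, py))^2)
    o <- order(d2)
    (d2[o[2]] - d2[o[1]]) /
      (2 * sqrt(sum((lat$centers[o[2], ] - lat$centers[o[1], ])^2)))
  }
  alb3 <- alb
  for (px in 1:90) for (py in 1:90)
    if (d2b(px, py) < 2) alb3[px, py, ] <- 0.01   # dark rim everywhere
  sc3 <- extract_scale_colors(alb3, lat, s = 20)
  expect_equal(unname(sc3$mean$colors[6, ]), as.numeric(ref),
               tolerance = 1e-6)
})

test_that("matching recovers ground truth and collapses under heavy jitter", {
  lat <- build_hex_lattice(8, 8, S = 2)
  # identity pair, 3 seeds: all scales matched
  idp <- gen_matched_pair(lat, seed = 1)
  latB <- build_voronoi_lattice(idp$B)
  m_id <- match_pair(lat, latB, cbind(c(1, 10, 40), c(1, 10, 40)))
  expect_equal(m_id, idp$truth, ignore_attr = TRUE)
  # known similarity + dropout, zero jitter: all survivors matched
  mp <- gen_matched_pair(lat, theta = 0.12, s = 1.2, t = c(5, -3),
                         dropout = 0.08, seed = 3)
  latB2 <- build_voronoi_lattice(mp$B)
  seeds <- which(!is.na(mp$truth))[c(1, 12, 40)]
  m2 <- match_pair(lat, latB2, cbind(seeds, mp$truth[seeds]))
  expect_equal(m2[!is.na(mp$truth)], mp$truth[!is.na(mp$truth)],
               ignore_attr = TRUE)
  expect_true(all(is.na(m2[is.na(mp$truth)])))
  # jitter far above the acceptance radius: match rate collapses
  mj <- gen_matched_pair(lat, jitter_sd = 1.5, seed = 4)
  latB3 <- build_voronoi_lattice(mj$B)
  m3 <- match_pair(lat, latB3, cbind(c(1, 10, 40), mj$truth[c(1, 10, 40)]))
  expect_lt(mean(!is.na(m3[-c(1, 10, 40)])), 0.10)
  expect_error(match_pair(lat, latB, cbind(1:2, 1:2)), "3")
})

test_that("matching is symmetric on noise-free pairs", {
  lat <- build_hex_lattice(7, 7, S = 2)
  mp <- gen_matched_pair(lat, theta = 0.05, s = 1.1, seed = 5)
  latB <- build_voronoi_lattice(mp$B)
  sAB <- cbind(c(1, 10, 30), mp$truth[c(1, 10, 30)])
  mAB <- match_pair(lat, latB, sAB)
  mBA <- match_pair(latB, lat, sAB[, 2:1])
  for (i in which(!is.na(mAB))) expect_equal(mBA[mAB[i]], i,
                                             ignore_attr = TRUE)
})

test_that("similarity recovery is exact and globally optimal on clean pairs", {
  lat <- build_hex_lattice(6, 6, S = 2)
  mp <- gen_matched_pair(lat, theta = 0.1, s = 1.2, t = c(2, 1), seed = 2)
  # forward fit: map the original onto the transformed set
  fit <- fit_similarity(mp$B, lat$centers)
  expect_equal(fit$theta, 0.1, tolerance = 1e-6)
  expect_equal(fit$s, 1.2, tolerance = 1e-6)
  expect_equal(fit$transform(lat$centers), mp$B, tolerance = 1e-6,
               ignore_attr = TRUE)
  # the closed form beats 10^4 random (theta, s) candidates
  e_opt <- similarity_error(mp$B, lat$centers, fit$theta, fit$s)
  set.seed(8)
  rand_e <- replicate(1e4, similarity_error(mp$B, lat$centers,
                                            runif(1, -pi, pi),
                                            runif(1, 0.5, 2)))
  expect_true(all(e_opt <= rand_e + 1e-9))
})

test_that("network unification keeps complete tracks and averages centers", {
  lat <- build_hex_lattice(6, 6, S = 2)
  # three time points: identity, then a known similarity, then a dropout
  mp2 <- gen_matched_pair(lat, theta = 0.1, s = 1.2, seed = 3)
  mp3 <- gen_matched_pair(lat, theta = -0.05, s = 0.9, dropout = 0.1,
                          seed = 9)
  lats <- list(lat, build_voronoi_lattice(mp2$B),
               build_voronoi_lattice(mp3$B))
  net <- unify_network(lats, list(mp2$truth, mp3$truth))
  kept <- which(!is.na(mp3$truth))
  expect_equal(nrow(net$ids), length(kept))
  expect_equal(net$ids[, 1], kept, ignore_attr = TRUE)
  expect_equal(net$transforms[[2]]$theta, -0.1, tolerance = 1e-6)
  expect_equal(net$transforms[[2]]$s, 1 / 1.2, tolerance = 1e-6)
  # identical time points: identity transform and unchanged centers
  net_id <- unify_network(list(lat, lat),
                          list(seq_len(36)))
  expect_equal(net_id$transforms[[2]]$theta, 0, tolerance = 1e-12)
  expect_equal(net_id$transforms[[2]]$s, 1, tolerance = 1e-12)
  expect_equal(net_id$lattice$centers, lat$centers, tolerance = 1e-6,
               ignore_attr = TRUE)
})
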