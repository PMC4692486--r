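# helper: wrap a precomputed states matrix as a trajectory sampled at 100 Hz
fake_traj <- function(states) {
  structure(list(states = states, dt = 0.1, record_stride = 100,
                 times = seq_len(nrow(states)) * 10, record = "mean_output"),
            class = "trajectory")
}

test_that("balloon kernel matches its closed form and truncation bound", {
  h <- balloon_kernel(0.01, normalize = FALSE)
  expect_equal(h[1], 0)                              # sin(0)
  omega <- sqrt(1 / 0.4 - 1 / (4 * 0.8 * 10))
  expect_equal(omega, 1.5712, tolerance = 1e-4)
  t <- 0.5
  expect_equal(h[51], exp(-0.5 * t / 0.8) * sin(omega * t) / omega,
               tolerance = 1e-12)
  expect_lt(exp(-15 / 1.6), 1e-4)                    # envelope at support
  # unit-area normalization
  hn <- balloon_kernel(0.01)
  expect_equal(sum(hn) * 0.01, 1, tolerance = 1e-12)
  # alternative omega reading stays available
  expect_silent(balloon_kernel(0.01, omega_form = "tau_s_sq"))
  expect_error(balloon_kernel(0.01, tau_f = 100, T_param = 0.01),
               "omega")
})

test_that("BOLD reconstruction is linear, causal on impulses, and detrended", {
  set.seed(2)
  x1 <- matrix(rnorm(4000 * 3), 4000, 3)
  x2 <- matrix(rnorm(4000 * 3), 4000, 3)
  b1 <- simulate_bold(fake_traj(x1))
  b2 <- simulate_bold(fake_traj(x2))
  b12 <- simulate_bold(fake_traj(2 * x1 + 3 * x2))
  expect_equal(b12$values, 2 * b1$values + 3 * b2$values, tolerance = 1e-10)

  # constant input -> all-zero detrended output (warm-up is discarded, so no
  # onset transient leaks through)
  bc <- simulate_bold(fake_traj(matrix(1, 4000, 2)))
  expect_lt(max(abs(bc$values)), 1e-9)

  # impulse response just after warm-up: that node's BOLD is the decimated
  # kernel, mean-removed
  h <- balloon_kernel(0.01)
  warm <- length(h) - 1L
  imp <- matrix(0, 4000, 2); imp[warm + 1, 1] <- 1
  bi <- simulate_bold(fake_traj(imp))
  hp <- c(h * 0.01, numeric(4000 - warm))[seq_len(4000 - warm)]
  want <- hp[seq(1, 4000 - warm, by = 200)]
  expect_equal(bi$values[, 1], want - mean(want), tolerance = 1e-10)
  expect_equal(bi$values[, 2], rep(0, length(want)))

  expect_lt(max(abs(colMeans(b1$values))),
            1e-9 * min(apply(b1$values, 2, sd)))
})

test_that("sliding-window FC reproduces the window arithmetic", {
  set.seed(3)
  b <- bold_series(matrix(rnorm(450 * 4), 450, 4), rate = 0.5)  # 15 min
  fcs <- sliding_fc(b, window_min = 1, step = 1)
  expect_length(fcs, 421)                     # 450 - 30 + 1
  expect_equal(attr(fcs, "window_samples"), 30L)

  # perfectly correlated pair
  t <- seq_len(100)
  m <- cbind(sin(t / 5), sin(t / 5) * 2 + 1, rnorm(100))
  fc2 <- sliding_fc(bold_series(m, 0.5))
  expect_equal(vapply(fc2, function(f) f[1, 2], numeric(1)),
               rep(1, length(fc2)), tolerance = 1e-12)

  # independent white noise: weak FC on average
  wn <- bold_series(matrix(rnorm(200 * 2), 200, 2), 0.5)
  fcw <- sliding_fc(wn)
  expect_lt(mean(abs(vapply(fcw, function(f) f[1, 2], numeric(1)))), 0.4)

  # zero-variance node -> 0 with warning
  zv <- bold_series(cbind(rnorm(60), 0), 0.5)
  expect_warning(fz <- sliding_fc(zv), "zero-variance")
  expect_equal(fz[[1]][1, 2], 0)

  expect_error(sliding_fc(bold_series(matrix(rnorm(20), 10, 2), 0.5)),
               "window longer")
})

test_that("FCD matrices are symmetric, unit-diagonal, and reflect FC epochs", {
  # stationary FC -> all ones
  fc <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3)
  f <- fcd_matrix(rep(list(fc), 6))
  expect_equal(unclass(f), matrix(1, 6, 6), ignore_attr = TRUE)

  # block-alternating FC -> checkerboard
  fcA <- diag(4); fcA[1, 2] <- fcA[2, 1] <- 0.9
  fcB <- diag(4); fcB[3, 4] <- fcB[4, 3] <- 0.9
  f2 <- fcd_matrix(c(rep(list(fcA), 5), rep(list(fcB), 5),
                     rep(list(fcA), 5)))
  expect_equal(f2[1, 15], 1)            # same-epoch block
  expect_lt(f2[1, 8], 0)                # cross-epoch block
  expect_equal(unclass(f2), t(unclass(f2)), ignore_attr = TRUE)
  expect_equal(diag(f2), rep(1, 15))
  expect_true(all(f2 >= -1 & f2 <= 1))

  # node subset restricts the vectorization
  f3 <- fcd_matrix(c(rep(list(fcA), 3), rep(list(fcB), 3)),
                   node_subset = 1:3)
  expect_equal(dim(f3), c(6L, 6L))
  expect_error(fcd_matrix(list(fcA)), "at least 2")
})

test_that("attractor-based FC captures co-activation across the set", {
  s <- attractor_set(4)
  s <- absorb_or_add(c(1, 1, 0, 0), s)
  s <- absorb_or_add(c(0, 0, 1, 1), s)
  fc <- suppressWarnings(attractor_fc(s))
  expect_equal(fc[1, 2], 1)    # co-active pair
  expect_equal(fc[1, 3], -1)   # anti-correlated pair

  # constant node -> zero row with warning
  s2 <- attractor_set(3)
  s2 <- absorb_or_add(c(1, 1, 0), s2)
  s2 <- absorb_or_add(c(0, 1, 1), s2)
  expect_warning(fc2 <- attractor_fc(s2), "constant")
  expect_equal(fc2[2, ], c(0, 0, 0))

  # cardinality weighting changes the correlation
  s3 <- attractor_set(3)
  for (p in list(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
    s3 <- absorb_or_add(p, s3)
  expect_false(isTRUE(all.equal(attractor_fc(s3, weighted = TRUE),
                                attractor_fc(s3, weighted = FALSE))))
  expect_error(attractor_fc(attractor_set(3)), "at least 2")
})

test_that("compare_fc respects hemispheric masks", {
  set.seed(4)
  a <- matrix(rnorm(36), 6); a <- (a + t(a)) / 2; diag(a) <- 1
  expect_equal(compare_fc(a, a), 1)
  expect_equal(compare_fc(a, -a), -1)
  hemi <- rep(c("L", "R"), each = 3)
  ri <- compare_fc(a, a, "intra_hemispheric", hemi)
  expect_equal(ri, 1)
  expect_error(compare_fc(a, a, "intra_hemispheric"), "hemisphere")
  # masks select disjoint entry sets: perturbing only inter-hemispheric
  # entries leaves the intra correlation at 1
  b <- a
  b[1, 4] <- b[4, 1] <- 9
  expect_equal(compare_fc(a, b, "intra_hemispheric", hemi), 1)
  expect_lt(compare_fc(a, b, "inter_hemispheric", hemi), 1)

  # null distribution: random pair nearly uncorrelated
  x <- matrix(rnorm(100^2), 100); x <- (x + t(x)) / 2
  y <- matrix(rnorm(100^2), 100); y <- (y + t(y)) / 2
  expect_lt(abs(compare_fc(x, y)), 0.1)
})

test_that("noise-driven DG runs near the multistability edge show FC epochs
           absent from a monostable run", {
  # scaled-down end-to-end check: 30 nodes, 3-minute runs, 5 seeds; the DG
  # model at sparse P with moderate noise visits metastable patterns, so
  # windowed FC stays correlated across epochs; a monostable SL run (G below
  # G_c) decorrelates.
  w <- small_net()
  gc <- critical_gain_sl(w)
  med_offdiag <- function(cfg, seed) {
    a0 <- random_initial_pattern(30, 0.5, seed = seed)
    tr <- simulate_net(a0, cfg, w, duration = 3 * 60 * 1000,
                       record_stride = 100, record = "mean_output",
                       seed = seed + 100)
    f <- fcd_matrix(sliding_fc(simulate_bold(tr)))
    stats::median(f[upper.tri(f)])
  }
  wins <- vapply(1:5, function(s) {
    multi <- med_offdiag(model_config("DG", G = 900, P = 0.6,
                                      tau_theta = 80, sigma_x = 0.2,
                                      sigma_theta = 0.2), s)
    mono <- med_offdiag(model_config("SL", G = 0.5 * gc, P = 1,
                                     sigma_x = 0.2), s)
    multi > mono
  }, logical(1))
  expect_gte(sum(wins), 4)
})
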