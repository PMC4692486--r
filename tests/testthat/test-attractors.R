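test_that("similarity measures match hand computations", {
  expect_equal(pearson_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_similarity(c(0.2, 0.8), 1 - c(0.2, 0.8)), -1)
  expect_equal(pearson_similarity(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_warning(z <- pearson_similarity(rep(1, 4), c(0, 1, 0, 1)),
                 "zero-variance")
  expect_equal(z, 0)

  expect_equal(euclidean_similarity(1:4, 1:4), 1)
  expect_equal(euclidean_similarity(c(0, 0), c(1, 0)), 0.5)
  expect_equal(euclidean_similarity(c(1, 0), c(0, 1)), 1 / (1 + sqrt(2)))
})

test_that("absorb_or_add applies the double-dissimilarity rule", {
  s <- attractor_set(4)
  s <- absorb_or_add(c(1, 1, 0, 0), s)
  expect_equal(nrow(s$patterns), 1)
  expect_equal(s$cardinality, 1L)

  # identical pattern absorbed
  s <- absorb_or_add(c(1, 1, 0, 0), s)
  expect_equal(nrow(s$patterns), 1)
  expect_equal(s$cardinality, 2L)

  # complementary half-active patterns: pearson -1, distance 2 -> both kept
  s <- absorb_or_add(c(0, 0, 1, 1), s)
  expect_equal(nrow(s$patterns), 2)

  # high Euclidean similarity alone blocks novelty (low-density pair)
  s2 <- attractor_set(50)
  s2 <- absorb_or_add(rep(0, 50), s2)
  tiny <- rep(0, 50); tiny[1] <- 0.05
  s2 <- absorb_or_add(tiny, s2)      # distance 0.05 -> eucl sim ~ 0.95
  expect_equal(nrow(s2$patterns), 1)
  expect_equal(s2$cardinality, 2L)

  # high Pearson alone blocks novelty even at large distance
  s3 <- attractor_set(10)
  base <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  s3 <- absorb_or_add(base, s3)
  s3 <- absorb_or_add(base * 10, s3)  # corr 1, distance large
  expect_equal(nrow(s3$patterns), 1)

  # conservation: cardinalities sum to samples fed in
  expect_equal(sum(s$cardinality), s$n_samples)
})

test_that("sampling the single self-coupled node finds exactly the 1-D
           oracle attractors", {
  w <- one_node()
  cfg <- model_config("SL", G = 900, P = 1)
  set <- sample_attractors(w, cfg, density_grid = c(0.1, 0.9),
                           n_per_density = 50, seed = 1)
  expect_equal(nrow(set$patterns), 2)
  expect_equal(sort(set$density), c(0, 1), tolerance = 1e-6)
  expect_equal(sum(set$cardinality), set$n_samples)
  expect_equal(set$n_samples + set$n_failed, 100)
})

test_that("below the first bifurcation sampling finds one attractor", {
  w <- small_net(20, seed = 9)
  cfg <- model_config("SL", G = 0.5 * critical_gain_sl(w), P = 1)
  set <- sample_attractors(w, cfg, density_grid = c(0.2, 0.5, 0.8),
                           n_per_density = 10, seed = 2)
  expect_equal(nrow(set$patterns), 1)
})

test_that("oracle equivalence: corner enumeration is recovered by sampling", {
  cfg <- model_config("SL", G = 900, P = 1)
  for (seed in c(11, 13)) {
    w <- small_net(6, seed = seed, n_modules = 2, p_intra = 0.8,
                   p_inter = 0.3)
    bf <- brute_force_attractors(w, cfg)
    smp <- sample_attractors(w, cfg, n_per_density = 8, seed = 5)  # 264 >= 256
    expect_gte(nrow(bf$patterns), nrow(smp$patterns))  # superset count-wise
    # every sampled attractor appears in the brute-force set and vice versa
    expect_true(all(best_match_sims(smp$patterns, bf$patterns) >= 0.9))
    expect_true(all(best_match_sims(bf$patterns, smp$patterns) >= 0.9))
  }
})

test_that("SL complement symmetry at P = 1 mirrors attractor densities", {
  w <- small_net(12, seed = 21, p_intra = 0.5, p_inter = 0.2)
  cfg <- model_config("SL", G = 900, P = 1)
  rs <- rowSums(w$weights)
  for (s in 1:5) {
    a0 <- random_initial_pattern(12, 0.5, seed = s)
    r <- relax_pattern(a0, cfg, w)
    rc <- relax_pattern(rs - a0, cfg, w)  # mirror: x -> rowsum - x
    expect_true(r$equilibrated && rc$equilibrated)
    # mirrored potentials: x -> rowsum - x maps attractors to attractors
    expect_equal(rc$x, rs - r$x, tolerance = 1e-5)
    expect_equal(mean(rc$A), 1 - mean(r$A), tolerance = 1e-5)
  }
})

test_that("the potential function matches its 1-D closed form", {
  w <- one_node()
  cfg <- model_config("SL", G = 3, P = 1)
  # V(0) = 0 for zero diagonal (every term carries x_i or W_ii)
  wz <- small_net(10, seed = 6)
  expect_equal(lyapunov_value(rep(0, 5), wz, model_config("SL", G = 2)), 0)
  # N = 1: dV/dx = x - A(x), checked by central differences
  for (x in c(0.2, 0.5, 0.8)) {
    h <- 1e-6
    num <- (lyapunov_value(x + h, w, cfg) -
              lyapunov_value(x - h, w, cfg)) / (2 * h)
    expect_equal(num, x - activation(x, 0.5, 3, 1), tolerance = 1e-6)
  }
  # N = 1 minima of V coincide with the stable fixed points
  cfg9 <- model_config("SL", G = 900, P = 1)
  grid <- seq(-0.2, 1.2, by = 1e-3)
  v <- vapply(grid, lyapunov_value, numeric(1), w = w, cfg = cfg9)
  loc <- grid[which(diff(sign(diff(v))) == 2) + 1]   # interior local minima
  expect_equal(sort(loc), c(0, 1), tolerance = 2e-3)
})

test_that("Ising energies expand as expected on 2-node networks", {
  w <- connectome(matrix(c(0, 0.3, 0.3, 0), 2), normalized = TRUE)
  th <- c(0.15, 0.15)
  expect_equal(ising_energy(c(0, 0), w, th), 0)
  expect_equal(ising_energy(c(1, 1), w, th), -0.3 - 2 * 0.15)
  expect_equal(ising_energy(c(1, 0), w, th), -0.15)
  expect_error(ising_energy(c(0.5, 1), w, th))
})

test_that("Boltzmann distribution and entropy agree with closed forms", {
  expect_equal(boltzmann_distribution(c(1, 1), 2), c(0.5, 0.5))
  expect_equal(boltzmann_distribution(c(0, 5, 9), 0), rep(1 / 3, 3))
  expect_equal(boltzmann_distribution(c(0, log(2)), 1), c(2 / 3, 1 / 3))
  # max-shift stability at extreme beta
  p <- boltzmann_distribution(c(0, 1, 2), 5000)
  expect_equal(p, c(1, 0, 0))
  expect_equal(boltzmann_entropy(c(3, 3), 1), log(2))
  expect_equal(boltzmann_entropy(c(0, 1, 2), 5000), 0)
  # the two printed entropy forms agree
  e <- c(0, 1, 2); beta <- 1
  p <- boltzmann_distribution(e, beta)
  z <- sum(exp(-beta * e))
  alt <- sum(beta * e * exp(-beta * e) / z) + log(z)
  expect_equal(boltzmann_entropy(e, beta), alt, tolerance = 1e-10)
})

test_that("empirical entropy is base 2 and properly bounded", {
  expect_equal(empirical_entropy(7), 0)
  expect_equal(empirical_entropy(c(2, 2)), 1)
  expect_equal(round(empirical_entropy(rep(1, 3300)), 2), 11.69)
  for (i in 1:5) {
    card <- sample.int(20, sample(2:10, 1), replace = TRUE)
    h <- empirical_entropy(card)
    expect_gte(h, 0)
    expect_lte(h, log2(length(card)) + 1e-12)
  }
})

test_that("gain sweep brackets the 1-node pitchfork at G = 2", {
  w <- one_node()
  cfg <- model_config("SL", G = 1, P = 1)
  sw <- sweep_gain(w, cfg, G_values = seq(1.2, 3.2, by = 0.4),
                   density_grid = c(0.25, 0.75), n_per_density = 10)
  counts <- sw$summary$n_attractors
  expect_true(all(counts[sw$summary$G < 2] == 1))
  expect_true(all(counts[sw$summary$G > 2.2] == 2))
  expect_lte(abs(first_bifurcation(sw) - 2), 0.4 + 1e-9)
  expect_equal(critical_gain_sl(w), 2)
})

test_that("attractor sets round-trip to TSV with annotations", {
  w <- one_node()
  cfg <- model_config("SL", G = 900, P = 1)
  set <- sample_attractors(w, cfg, density_grid = c(0.1, 0.9),
                           n_per_density = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_attractor_set(set, f, w = w, cfg = cfg)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("density", "cardinality", "V", "E") %in% names(tab)))
  prov <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(prov$G, 900)
})
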