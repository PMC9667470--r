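test_that("identical seeds give bit-identical trajectories and datasets", {
  cfg <- langevin_config(n_steps = 5000, seed = 42)
  t1 <- simulate_langevin(harmonic_potential(500), config = cfg)
  t2 <- simulate_langevin(harmonic_potential(500), config = cfg)
  expect_identical(t1, t2)
  cfg2 <- cfg; cfg2$seed <- 43L
  t3 <- simulate_langevin(harmonic_potential(500), config = cfg2)
  expect_false(identical(t1$positions, t3$positions))

  pot <- double_well_potential(5, 1)
  ws1 <- generate_umbrella_dataset(pot, c(-1, 0, 1), 200, langevin_config(seed = 7),
                                   n_samples = 200)
  ws2 <- generate_umbrella_dataset(pot, c(-1, 0, 1), 200, langevin_config(seed = 7),
                                   n_samples = 200)
  expect_identical(ws1$windows, ws2$windows)
})

test_that("a harmonic trap equipartitions: var(z) = k_B T / k", {
  k <- 1000
  cfg <- langevin_config(temperature = 310, n_steps = 2.6e6, seed = 3,
                         burn_in = 10000L, stride = 500L)
  traj <- simulate_langevin(harmonic_potential(k), config = cfg)
  v <- var(traj$positions)
  expected <- KB_KJ_MOL_K * 310 / k
  se <- expected * sqrt(2 / length(traj$positions))
  expect_lt(abs(v - expected), 3 * se + 0.005 * expected)
})

test_that("free diffusion obeys MSD = 2 D t across an ensemble of seeds", {
  D <- 0.01
  n_seeds <- 120
  n_steps <- 400L
  finals <- t(vapply(seq_len(n_seeds), function(s) {
    cfg <- langevin_config(diffusion_coeff = D, n_steps = n_steps, seed = s,
                           stride = 100L)
    simulate_langevin(flat_potential(), config = cfg)$positions
  }, numeric(n_steps / 100L)))
  times <- (1:4) * 100 * 0.001
  msd <- colMeans(finals^2)
  slope <- unname(coef(lm(msd ~ 0 + times)))
  expect_lt(abs(slope - 2 * D) / (2 * D), 0.25)
})

test_that("a biased flat potential is a harmonic trap at the bias center", {
  cfg <- langevin_config(n_steps = 1.3e6, seed = 9, burn_in = 10000L, stride = 500L)
  traj <- simulate_langevin(flat_potential(), bias_spec(1.0, 1000), cfg)
  expect_lt(abs(mean(traj$positions) - 1.0), 0.005)
  expect_lt(abs(var(traj$positions) - KB_KJ_MOL_K * 310 / 1000), 4e-4)
})

test_that("the divergence guard aborts with the offending step", {
  cfg <- langevin_config(n_steps = 10000, seed = 1, domain = c(-0.05, 0.05))
  expect_error(simulate_langevin(flat_potential(), config = cfg),
               "escaped domain.*step")
})

test_that("the default umbrella geometry spans the translocation coordinate", {
  centers <- seq(0, by = 0.2, length.out = 60)
  expect_equal(max(centers) - min(centers), 11.8)
  pot <- flat_potential()
  ws <- generate_umbrella_dataset(pot, centers[1:5], 1000, langevin_config(seed = 2),
                                  n_samples = 400)
  means <- vapply(ws$windows, function(w) mean(w$samples), numeric(1))
  # on a flat potential every window is a harmonic trap at its own center
  expect_lt(max(abs(means - centers[1:5])), 0.01)
})

test_that("zero spring makes every window sample the unbiased ensemble", {
  # confining harmonic background, no restraint: windows differ only by seed
  pot <- harmonic_potential(200, 1)
  ws <- generate_umbrella_dataset(pot, c(0, 1, 2), 0,
                                  langevin_config(seed = 5), n_samples = 1500)
  sig <- sqrt(KB_KJ_MOL_K * 310 / 200)
  means <- vapply(ws$windows, function(w) mean(w$samples), numeric(1))
  sds <- vapply(ws$windows, function(w) sd(w$samples), numeric(1))
  expect_lt(max(abs(means - 1)), 5 * sig / sqrt(300))
  expect_lt(max(abs(sds / sig - 1)), 0.2)
  expect_error(generate_umbrella_dataset(flat_potential(), numeric(0), 0,
                                         langevin_config(seed = 1)),
               "non-empty")
})

test_that("bonded ensembles follow the Boltzmann density of their potential", {
  p <- bonded_params("bond", 0.47, 1250)
  x <- sample_bonded_ensemble(p, 5e4, 310, seed = 4)
  expect_lt(abs(mean(x) - 0.47), 0.001)
  expect_lt(abs(var(x) - KB_KJ_MOL_K * 310 / 1250) / (KB_KJ_MOL_K * 310 / 1250), 0.05)

  stiff <- bonded_params("bond", 0.47, 1e9)
  xs <- sample_bonded_ensemble(stiff, 1e4, 310, seed = 4)
  expect_lt(max(xs) - min(xs), 1e-3)

  # harmonic-cosine angle histogram against the quadrature density
  pa <- bonded_params("angle", 120, 150, "harmonic_cosine")
  xa <- sample_bonded_ensemble(pa, 5e4, 310, seed = 6)
  grid <- seq(0, 180, length.out = 2001)
  dens <- quadrature_density(function(th) 0.5 * 150 * (cos(th * pi / 180) - cos(120 * pi / 180))^2,
                             grid, 310)
  cdf_ref <- cumsum(dens) / sum(dens)
  cdf_fun <- approxfun(grid, cdf_ref, rule = 2)
  ks <- suppressWarnings(ks.test(xa, cdf_fun))
  expect_gt(ks$p.value, 1e-4)

  expect_error(sample_bonded_ensemble(p, 0), "positive")
})

test_that("release-curve generation evaluates the power law exactly", {
  expect_equal(generate_release_curve(1, 1, 0.5)$fraction_released, 0.5)
  expect_equal(generate_release_curve(0.7, 0.3, 0)$fraction_released, 0)
  expect_equal(generate_release_curve(0.3, 0.45, 4)$fraction_released, 0.3 * 4^0.45)
  # clipping keeps fractions physical under noise
  set.seed(1)
  c2 <- generate_release_curve(0.5, 0.8, seq(0, 20, 0.5), noise_sigma = 0.3, seed = 2)
  expect_true(all(c2$fraction_released >= 0 & c2$fraction_released <= 1))
  expect_error(generate_release_curve(0.3, 0.45, 1:3, noise_sigma = -0.1), ">= 0")
})

test_that("planted particle configurations are recovered by brute force", {
  cfg <- generate_particle_config(c(5, 4), intra_spacing = 0.45,
                                  inter_separation = 5, box = 15, seed = 3)
  oracle <- brute_force_clusters(cfg$positions, cfg$box, 0.6)
  expect_equal(oracle$sizes, c(5L, 4L))
  expect_equal(attr(cfg, "truth")$sizes, c(5L, 4L))

  cfg27 <- generate_particle_config(rep(1L, 27), inter_separation = 5, box = 15, seed = 8)
  expect_equal(brute_force_clusters(cfg27$positions, cfg27$box, 0.6)$sizes,
               rep(1L, 27))

  # a pair pushed across the periodic boundary stays one cluster
  pair <- generate_particle_config(2L, intra_spacing = 0.45, seed = 1,
                                   offset = c(12.3, 0, 0))
  d_raw <- sqrt(sum((pair$positions[1, ] - pair$positions[2, ])^2))
  expect_gt(d_raw, 10) # members wrapped to opposite faces of the box
  expect_equal(brute_force_clusters(pair$positions, pair$box, 0.6)$sizes, 2L)

  expect_error(generate_particle_config(rep(1L, 64), inter_separation = 5, box = 15,
                                        seed = 1),
               "cannot place")
})

test_that("alchemical datasets carry consistent dimensions and planted truth", {
  lam <- seq(0, 1, by = 0.25)
  u_fun <- function(x, l) 0.5 * (100 + 900 * l) * x^2
  ds <- generate_alchemical_dataset(u_fun, lam, 300L, temperature = 300, seed = 12)
  expect_equal(dim(ds$u), c(5L, 1500L))
  expect_equal(ds$n_k, rep(300L, 5))
  ds2 <- generate_alchemical_dataset(u_fun, lam, 300L, temperature = 300, seed = 12)
  expect_identical(ds$u, ds2$u)
})
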