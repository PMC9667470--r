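make_harmonic_pair <- function(k1 = 1000, k2 = 100, n = 2000, temperature = 300,
                               seed = 42) {
  beta <- 1 / (KB_KJ_MOL_K * temperature)
  set.seed(seed)
  x <- c(rnorm(n, 0, sqrt(1 / (beta * k1))), rnorm(n, 0, sqrt(1 / (beta * k2))))
  u <- rbind(beta * 0.5 * k1 * x^2, beta * 0.5 * k2 * x^2)
  reduced_potential_matrix(u, c(n, n), temperature)
}

test_that("two identical states have zero free-energy difference", {
  set.seed(5)
  x <- rnorm(1000)
  u <- rbind(0.5 * x^2, 0.5 * x^2)
  res <- mbar_solve(reduced_potential_matrix(u, c(500, 500), 300))
  expect_equal(res$f[2] - res$f[1], 0, tolerance = 1e-12)
})

test_that("harmonic pair free energy matches the closed form 0.5 ln(k1/k2)", {
  m <- make_harmonic_pair()
  res <- mbar_solve(m)
  df <- res$f[2] - res$f[1]
  se <- sqrt(res$covariance[1, 1] + res$covariance[2, 2] - 2 * res$covariance[1, 2])
  expect_lt(abs(df - (-0.5 * log(10))), 2 * se)
  expect_gt(se, 0)
})

test_that("anharmonic pair matches quadrature partition functions", {
  T0 <- 300
  u1 <- function(x) 2 * x^2 + x^4
  u2 <- function(x) 5 * (x - 0.3)^2
  ds <- generate_alchemical_dataset(function(x, l) (1 - l) * u1(x) + l * u2(x),
                                    seq(0, 1, 0.25), 1500, T0, seed = 9)
  r <- solvation_dg(lambda_schedule(seq(0, 1, 0.25)), ds)
  oracle <- -(quadrature_logz(u2, -5, 5, T0) - quadrature_logz(u1, -5, 5, T0)) *
    KB_KJ_MOL_K * T0
  expect_lt(abs(r$delta_g - oracle), 2 * r$stderr + 0.02)
})

test_that("reversing the state order negates the free-energy difference", {
  m <- make_harmonic_pair(n = 800)
  rev_m <- reduced_potential_matrix(m$u[2:1, ], m$n_k, m$temperature)
  f1 <- mbar_solve(m)$f
  f2 <- mbar_solve(rev_m)$f
  expect_equal(f1[2] - f1[1], -(f2[2] - f2[1]), tolerance = 1e-9)
})

test_that("MBAR mixture weights are normalized per state", {
  m <- make_harmonic_pair(n = 500)
  res <- mbar_solve(m)
  expect_equal(rowSums(res$weights), rep(1, 2), tolerance = 1e-8)
})

test_that("reported stderr tracks the empirical spread over replicates", {
  reps <- vapply(1:50, function(s) {
    m <- make_harmonic_pair(n = 250, seed = 1000 + s)
    res <- mbar_solve(m)
    c(df = res$f[2] - res$f[1],
      se = sqrt(res$covariance[1, 1] + res$covariance[2, 2] - 2 * res$covariance[1, 2]))
  }, numeric(2))
  emp <- sd(reps["df", ])
  rep_se <- mean(reps["se", ])
  expect_lt(emp / rep_se, 2)
  expect_gt(emp / rep_se, 0.5)
})

test_that("solvation free energy over a 10-state schedule matches quadrature", {
  T0 <- 300
  lam <- seq(0, 1, by = 1 / 9)
  # toy decoupling: a particle in a lambda-scaled well on a bounded domain
  u_fun <- function(x, l) l * (-8 * exp(-x^2 / 0.32)) + 0.5 * 20 * x^2
  ds <- generate_alchemical_dataset(u_fun, lam, 800, T0, seed = 13)
  r <- solvation_dg(lambda_schedule(lam), ds)
  oracle <- -(quadrature_logz(function(x) u_fun(x, 1), -3, 3, T0) -
                quadrature_logz(function(x) u_fun(x, 0), -3, 3, T0)) * KB_KJ_MOL_K * T0
  expect_lt(abs(r$delta_g - oracle), 2 * r$stderr + 0.02)

  # identical states everywhere: zero
  u0 <- matrix(rep(0.5 * rnorm(300)^2, each = 2), nrow = 2)
  sch2 <- lambda_schedule(c(0, 1))
  r0 <- solvation_dg(sch2, reduced_potential_matrix(u0, c(150, 150), T0))
  expect_equal(r0$delta_g, 0, tolerance = 1e-9)

  expect_error(solvation_dg(lambda_schedule(c(0, 0.5, 1)), ds), "states")
})

test_that("lambda schedules validate endpoints and stacked modes", {
  expect_error(lambda_schedule(c(0, 0.5)), "endpoints")
  expect_error(lambda_schedule(c(0, 0.5, 0.5, 1)), "strictly increasing")
  s10 <- lambda_schedule(seq(0, 1, 1 / 9))
  expect_equal(s10$n_states, 10L)
  s20 <- lambda_schedule(list(coulomb = seq(0, 1, 1 / 9), lj = seq(0, 1, 1 / 9)),
                         coupling_mode = "coulomb_then_lj")
  expect_equal(s20$n_states, 20L)
})

test_that("non-overlapping states are diagnosed by name", {
  beta <- 1 / (KB_KJ_MOL_K * 300)
  set.seed(8)
  x1 <- rnorm(200, 0, 0.001)
  x2 <- rnorm(200, 100, 0.001)
  x <- c(x1, x2)
  u <- rbind(beta * 0.5 * 1e6 * x^2, beta * 0.5 * 1e6 * (x - 100)^2)
  u[u > 700] <- 700 # keep entries finite-exponentiable; overlap is still nil
  m <- reduced_potential_matrix(u, c(200, 200), 300)
  expect_error(mbar_solve(m), "non-overlapping")
})

test_that("transfer free energies compose and validate temperature", {
  a <- free_energy_result(-10, 0.3, temperature = 300)
  b <- free_energy_result(-4, 0.4, temperature = 300)
  tr <- transfer_dg(a, b)
  expect_equal(tr$delta_g, 6)
  expect_equal(tr$stderr, 0.5)
  expect_equal(transfer_dg(a, a)$delta_g, 0)

  # cycle closure is exact by construction
  ppn <- free_energy_result(-22.4, 0.2, temperature = 300)
  oct <- free_energy_result(-17.1, 0.2, temperature = 300)
  wat <- free_energy_result(-3.9, 0.2, temperature = 300)
  expect_equal(transfer_dg(ppn, wat)$delta_g,
               transfer_dg(ppn, oct)$delta_g + transfer_dg(oct, wat)$delta_g)

  expect_error(transfer_dg(a, free_energy_result(-4, 0.1, temperature = 310)),
               "temperature mismatch")
})

test_that("planted solvation differences propagate through transfer", {
  T0 <- 300
  lam <- seq(0, 1, 0.25)
  mk <- function(depth, seed) {
    u_fun <- function(x, l) l * depth * exp(-x^2 / 0.5) + 0.5 * 30 * x^2
    solvation_dg(lambda_schedule(lam),
                 generate_alchemical_dataset(u_fun, lam, 1200, T0, seed = seed))
  }
  # wells differing by a planted energy scale: the transfer recovers it
  a <- mk(-6, 21)
  b <- mk(-6, 22)
  tr <- transfer_dg(a, b)
  expect_lt(abs(tr$delta_g), 3 * tr$stderr + 0.05)
})

test_that("log P follows the transfer free energy at fixed temperature", {
  expect_equal(logp_from_transfer(0, 300), 0)
  dgs <- c(1, 5, 10, 20)
  lps <- vapply(dgs, logp_from_transfer, numeric(1), temperature = 300)
  expect_true(all(diff(lps) > 0))
  # closed-form inversion: the hydrophobicity of docetaxel
  dg <- 4.4 * log(10) * KB_KJ_MOL_K * 300
  expect_equal(logp_from_transfer(dg, 300), 4.4)
  r <- free_energy_result(dg, temperature = 300)
  expect_equal(logp_from_transfer(r), 4.4)
})

test_that("soft-core potential has the right limits and no singularity", {
  sc <- softcore_params(alpha = 0.5, sigma = 0.47, epsilon = 2)
  set.seed(4)
  r <- runif(1000, 0.05, 2)
  lj <- 4 * 2 * ((0.47 / r)^12 - (0.47 / r)^6)
  expect_equal(softcore_lj(r, 1, sc), lj, tolerance = 1e-14)
  expect_equal(softcore_lj(r, 0, sc), rep(0, 1000))
  v0 <- softcore_lj(0, 0.5, sc)
  a6 <- 0.5 * 0.47^6 * 0.5
  expect_equal(v0, 4 * 2 * 0.5 * (0.47^12 / a6^2 - 0.47^6 / a6))
  expect_true(is.finite(v0))
})
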