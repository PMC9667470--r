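test_that("a single unbiased window on a flat potential gives a flat profile", {
  set.seed(1)
  w <- umbrella_window(0, 0, runif(20000, -1, 1))
  ws <- window_set(list(w), temperature = 310)
  pmf <- wham(ws, bin_width = 0.1)
  # interior bins only: the outermost bins straddle the sample support edge
  interior <- !is.na(pmf$free_energy) & abs(pmf$z_grid) < 0.9
  G <- pmf$free_energy[interior]
  expect_lt(max(G) - min(G), 0.5)
})

test_that("WHAM recovers a double-well potential from umbrella windows", {
  d <- make_double_well_windows(n_samples = 2000, seed = 11)
  pmf <- wham(d$ws, reference_region = c(-0.5, 0.5))
  expect_lt(pmf_rmse(pmf, d$pot), 1.5)
  # the profile is anchored at zero over its reference region
  ref <- !is.na(pmf$free_energy) & pmf$z_grid >= -0.5 & pmf$z_grid <= 0.5
  expect_equal(mean(pmf$free_energy[ref]), 0, tolerance = 1e-10)
})

test_that("a constant added to the underlying potential leaves G unchanged", {
  pot0 <- make_translocation_potential(-20, 1, 3, 1)
  pot1 <- make_translocation_potential(-20, 1, 3, 1, plateau_value = 50)
  centers <- seq(0, 6, by = 0.25)
  ws0 <- generate_umbrella_dataset(pot0, centers, 500, langevin_config(seed = 21),
                                   n_samples = 800)
  ws1 <- generate_umbrella_dataset(pot1, centers, 500, langevin_config(seed = 21),
                                   n_samples = 800)
  p0 <- wham(ws0)
  p1 <- wham(ws1)
  expect_equal(p0$free_energy, p1$free_energy, tolerance = 1e-8)
})

test_that("WHAM matches random analytic potentials within bootstrap error", {
  # oracle-equivalence property: several seeded anharmonic potentials
  for (trial in 1:5) {
    set.seed(trial)
    a <- runif(1, 1, 3)
    h <- runif(1, 2, 8)
    pot <- double_well_potential(h, a)
    centers <- seq(-a - 1, a + 1, by = 0.2)
    ws <- generate_umbrella_dataset(pot, centers, 500,
                                    langevin_config(seed = 100 + trial),
                                    n_samples = 1500)
    pmf <- bootstrap_pmf_error(ws, n_boot = 8, seed = trial)
    rmse <- pmf_rmse(pmf, pot)
    med_se <- median(pmf$stderr[!is.na(pmf$free_energy)], na.rm = TRUE)
    expect_lt(rmse, max(3 * med_se, 0.6))
  }
})

test_that("well-depth bias shrinks as samples per window grow", {
  pot <- double_well_potential(10, 4)
  centers <- seq(-5.9, 5.9, by = 0.2)
  errs <- vapply(c(500, 2000, 8000), function(n) {
    ws <- generate_umbrella_dataset(pot, centers, 1000, langevin_config(seed = 31),
                                    n_samples = n)
    pmf_rmse(wham(ws, reference_region = c(-0.5, 0.5)), pot)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.8)
})

test_that("WHAM fixed-point residuals decrease after burn-in", {
  d <- make_double_well_windows(n_samples = 1000, seed = 41)
  pmf <- wham(d$ws)
  h <- pmf$f_history
  if (length(h) >= 3) {
    tail3 <- tail(h, 3)
    expect_true(all(diff(tail3) <= 1e-12))
  }
  expect_lt(tail(h, 1), 1e-8)
})

test_that("non-convergence raises a diagnostic carrying the F history", {
  d <- make_double_well_windows(n_samples = 1000, seed = 51)
  err <- tryCatch(wham(d$ws, tol = 1e-14, max_iter = 1),
                  wham_convergence_error = function(e) e)
  expect_s3_class(err, "wham_convergence_error")
  expect_true(length(err$history) >= 1)
})

test_that("a disconnected window graph is rejected", {
  set.seed(2)
  w1 <- umbrella_window(0, 1000, rnorm(500, 0, 0.05))
  w2 <- umbrella_window(10, 1000, rnorm(500, 10, 0.05))
  expect_error(wham(window_set(list(w1, w2))), "disconnected")
})

test_that("overlap report matches a quadrature oracle for adjacent Gaussians", {
  set.seed(3)
  sd <- 0.05
  w1 <- umbrella_window(0, 1000, rnorm(40000, 0, sd))
  w2 <- umbrella_window(0.2, 1000, rnorm(40000, 0.2, sd))
  rep <- check_overlap(window_set(list(w1, w2)), bin_width = 0.01)
  grid <- seq(-0.5, 0.7, length.out = 20001)
  p1 <- dnorm(grid, 0, sd); p2 <- dnorm(grid, 0.2, sd)
  oracle <- sum(pmin(p1, p2)) * mean(diff(grid))
  expect_equal(rep$overlap, oracle, tolerance = 0.05)

  # identical windows overlap fully; disjoint supports are flagged at zero
  id <- check_overlap(window_set(list(w1, w1)))
  expect_equal(id$overlap, 1)
  far <- check_overlap(window_set(list(w1, umbrella_window(5, 1000, rnorm(100, 5, 0.01)))))
  expect_equal(far$overlap, 0)
  expect_true(far$flagged)
})

test_that("bootstrap errors behave like sampling errors", {
  # zero-variance windows have zero stderr everywhere (all windows pinned to
  # one shared value so the window graph stays connected)
  w <- lapply(c(0, 0.2, 0.4), function(c0) umbrella_window(c0, 1000, rep(0.2, 50)))
  pmf0 <- bootstrap_pmf_error(window_set(w), n_boot = 4, seed = 1, bin_width = 0.2)
  expect_true(all(pmf0$stderr[!is.na(pmf0$free_energy)] == 0))
  expect_true(all(pmf0$stderr >= 0, na.rm = TRUE))

  # doubling the samples per window shrinks the median stderr by ~ 1/sqrt(2)
  pot <- double_well_potential(5, 2)
  centers <- seq(-3, 3, by = 0.25)
  med_se <- vapply(c(600, 2400), function(n) {
    ws <- generate_umbrella_dataset(pot, centers, 500, langevin_config(seed = 61),
                                    n_samples = n)
    pmf <- bootstrap_pmf_error(ws, n_boot = 12, seed = 5)
    median(pmf$stderr[!is.na(pmf$free_energy)])
  }, numeric(1))
  # quadrupling samples should halve the error; allow a broad stochastic band
  expect_lt(med_se[2] / med_se[1], 0.75)
  expect_gt(med_se[2] / med_se[1], 0.25)
})

test_that("barrier extraction uses the deepest populated bin vs the plateau", {
  # constant profile: zero barrier
  flat <- structure(list(z_grid = seq(0, 5, 0.1), free_energy = rep(1.5, 51),
                         stderr = rep(NA_real_, 51), reference_region = c(4.5, 5),
                         counts = rep(10, 51), temperature = 310),
                    class = "pmf_profile")
  b <- extract_barrier(flat)
  expect_equal(b$delta_g, 0)

  # interfacial minimum deeper than the interior well wins
  z <- seq(0, 10, 0.05)
  G <- -60 * (z < 4) - 80 * exp(-(z - 4.5)^2 / 0.08)
  prof <- structure(list(z_grid = z, free_energy = G - mean(G[z >= 9]),
                         stderr = rep(NA_real_, length(z)),
                         reference_region = c(9, 10),
                         counts = rep(10, length(z)), temperature = 310),
                    class = "pmf_profile")
  bi <- extract_barrier(prof)
  expect_lt(abs(bi$minimum_location - 4.5), 0.2)
  expect_lt(bi$delta_g, -75)

  expect_error(extract_barrier(flat, reference_region = c(90, 100)), "3 populated")
})

test_that("planted translocation wells are recovered with honest errors", {
  pot <- make_translocation_potential(-30, 1.5, 4, 1.2)
  centers <- seq(0, 8, by = 0.2)
  ws <- generate_umbrella_dataset(pot, centers, 1000, langevin_config(seed = 71),
                                  n_samples = 2500)
  pmf <- bootstrap_pmf_error(ws, n_boot = 12, seed = 7)
  bar <- extract_barrier(pmf)
  expect_lt(abs(bar$delta_g - (-30)), max(2 * bar$stderr, 1.0))
  expect_lt(bar$minimum_location, 4)
})
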