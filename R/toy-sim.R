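#' Configuration for the overdamped Langevin engine
#'
#' The synthetic-data engine integrates position-only (overdamped) Langevin
#' dynamics with the Euler-Maruyama scheme
#' \deqn{z \leftarrow z - \beta D\, U'(z)\, \Delta t + \sqrt{2 D \Delta t}\,\xi,}
#' which samples the Boltzmann distribution of U at the configured
#' temperature. It stands in for an MD engine's stochastic-dynamics
#' integrator: downstream estimators only need correctly distributed samples
#' of the reaction coordinate, not inertial dynamics.
#'
#' @param temperature simulation temperature, K.
#' @param diffusion_coeff diffusion coefficient D, nm^2/ps.
#' @param timestep integration step, ps.
#' @param n_steps number of steps (may be `NULL` when the caller derives it,
#'   as [generate_umbrella_dataset()] does).
#' @param seed RNG seed; the seed fixes the full trajectory.
#' @param initial_position starting coordinate, nm.
#' @param burn_in steps discarded before recording.
#' @param stride record every `stride`-th step.
#' @param domain length-2 numeric; a position escaping it aborts with a
#'   diagnostic naming the step (divergence guard).
#' @return A `langevin_config` list.
#' @export
langevin_config <- function(temperature = 310, diffusion_coeff = 0.01,
                            timestep = 0.001, n_steps = NULL, seed = 1L,
                            initial_position = 0, burn_in = 0L, stride = 1L,
                            domain = c(-Inf, Inf)) {
  stopifnot(temperature > 0, diffusion_coeff > 0, timestep > 0,
            length(domain) == 2L, domain[1] < domain[2],
            burn_in >= 0, stride >= 1)
  if (!is.null(n_steps)) stopifnot(n_steps >= 1)
  structure(list(temperature = temperature, diffusion_coeff = diffusion_coeff,
                 timestep = timestep, n_steps = n_steps, seed = as.integer(seed),
                 initial_position = initial_position, burn_in = as.integer(burn_in),
                 stride = as.integer(stride), domain = domain),
            class = "langevin_config")
}

#' Harmonic bias of an umbrella window
#'
#' w(z) = 1/2 k (z - center)^2, the restraint applied on top of the
#' underlying potential during biased sampling.
#'
#' @param center restraint center, nm.
#' @param spring_constant k, kJ mol^-1 nm^-2 (>= 0).
#' @export
bias_spec <- function(center, spring_constant) {
  stopifnot(is.finite(center), spring_constant >= 0)
  structure(list(center = center, spring_constant = spring_constant), class = "bias_spec")
}

#' Simulate an overdamped Langevin trajectory
#'
#' @param potential a [potential_spec][potentials].
#' @param bias an optional [bias_spec()]; the total potential is
#'   `potential + bias`.
#' @param config a [langevin_config()] with `n_steps` set.
#' @return A `trajectory1d`: list with `times` (ps) and `positions` (nm) of
#'   equal length; identical `(inputs, seed)` give a bit-identical trajectory.
#' @examples
#' traj <- simulate_langevin(harmonic_potential(1000),
#'                           config = langevin_config(n_steps = 2000, seed = 7))
#' var(traj$positions)  # ~ k_B T / k
#' @export
simulate_langevin <- function(potential, bias = NULL, config) {
  stopifnot(inherits(potential, "potential_spec"), inherits(config, "langevin_config"))
  if (is.null(config$n_steps)) stop("config$n_steps must be set for simulate_langevin")
  bc <- 0; bk <- 0
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "bias_spec"))
    bc <- bias$center; bk <- bias$spring_constant
  }
  enc <- potential_for_core(potential)
  set.seed(config$seed)
  pos <- langevin_core(config$initial_position, as.integer(config$n_steps),
                       config$burn_in, config$stride, config$timestep,
                       config$diffusion_coeff, beta_of(config$temperature),
                       enc$id, enc$pars, enc$gz, enc$gf, bc, bk,
                       config$domain[1], config$domain[2])
  times <- (config$burn_in + config$stride * seq_along(pos)) * config$timestep
  structure(list(times = times, positions = pos), class = "trajectory1d")
}

#' Generate an umbrella-sampling dataset
#'
#' Runs one biased Langevin simulation per window center, each started at its
#' own center and seeded reproducibly from `(config$seed, window index)` via
#' [split_seed()]. The default protocol mirrors the umbrella geometry used
#' for matrix-to-water translocation: 60 windows spaced 0.2 nm with a
#' 1000 kJ mol^-1 nm^-2 spring.
#'
#' @param potential underlying [potential_spec][potentials].
#' @param window_centers sorted restraint centers, nm.
#' @param spring spring constant shared by all windows, kJ mol^-1 nm^-2.
#' @param config a [langevin_config()]; its `n_steps` is derived from
#'   `n_samples`, `burn_in` and `stride` below.
#' @param n_samples recorded samples per window.
#' @param burn_in equilibration steps discarded per window.
#' @param stride steps between recorded samples (decorrelation).
#' @return A [window_set()] whose `truth` attribute records the generating
#'   potential and protocol, so recovery tests need no bookkeeping.
#' @export
generate_umbrella_dataset <- function(potential, window_centers, spring = 1000,
                                      config = langevin_config(),
                                      n_samples = 5000L, burn_in = 10000L,
                                      stride = 1000L) {
  stopifnot(inherits(potential, "potential_spec"), n_samples >= 1)
  if (length(window_centers) == 0L) stop("window_centers must be non-empty")
  if (is.unsorted(window_centers)) stop("window_centers must be sorted")
  n_steps <- as.integer(burn_in + stride * n_samples)
  windows <- vector("list", length(window_centers))
  for (i in seq_along(window_centers)) {
    cfg_i <- config
    cfg_i$n_steps <- n_steps
    cfg_i$burn_in <- as.integer(burn_in)
    cfg_i$stride <- as.integer(stride)
    cfg_i$seed <- split_seed(config$seed, i)
    cfg_i$initial_position <- window_centers[i]
    traj <- simulate_langevin(potential, bias_spec(window_centers[i], spring), cfg_i)
    windows[[i]] <- umbrella_window(window_centers[i], spring, traj$positions)
  }
  ws <- window_set(windows, temperature = config$temperature)
  attr(ws, "truth") <- list(potential = potential, spring = spring,
                            n_samples = n_samples, seed = config$seed)
  ws
}

# inverse-CDF draw from the 1D Boltzmann density exp(-beta U) on [lo, hi];
# the CDF is accumulated on a fine uniform grid (trapezoid) and inverted by
# monotone interpolation -- deterministic given the seed, no rejection loop.
boltzmann_sample <- function(ufun, lo, hi, n, temperature, seed, n_grid = 4096L) {
  stopifnot(n >= 1, hi > lo)
  beta <- beta_of(temperature)
  z <- seq(lo, hi, length.out = n_grid)
  logw <- -beta * ufun(z)
  w <- exp(logw - max(logw))
  cw <- cumsum((w[-1] + w[-n_grid]) / 2 * diff(z))
  cdf <- c(0, cw / cw[n_grid - 1L])
  keep <- c(TRUE, diff(cdf) > 0)
  set.seed(seed)
  stats::approx(cdf[keep], z[keep], xout = stats::runif(n), rule = 2)$y
}

#' Sample a Boltzmann ensemble of a bonded term
#'
#' Draws `n` values from the equilibrium density exp(-V(x)/k_B T) of a bonded
#' potential by inverse-CDF sampling on a fine grid (no rejection loop, so
#' the draw count is exact and the output deterministic under the seed).
#' Domains: bonds on `equilibrium +/- 12 sd` intersected with (0, Inf);
#' angles on [0, 180] deg; dihedrals on (-180, 180] deg. Angle-like terms
#' are sampled in degrees, with the harmonic force constant interpreted in
#' kJ mol^-1 rad^-2.
#'
#' @param params a [bonded_params()].
#' @param n number of samples (> 0).
#' @param temperature K.
#' @param seed RNG seed.
#' @return Numeric samples (nm for bonds, degrees otherwise) with the
#'   generating parameters attached as attribute `truth`.
#' @export
sample_bonded_ensemble <- function(params, n, temperature = 310, seed = 1L) {
  stopifnot(inherits(params, "bonded_params"))
  if (n <= 0) stop("n must be positive")
  if (params$force_constant <= 0) stop("force_constant must be > 0")
  V <- bonded_energy_fun(params)
  if (params$kind == "bond") {
    sd0 <- sqrt(KB_KJ_MOL_K * temperature / params$force_constant)
    lo <- max(params$equilibrium_value - 12 * sd0, 1e-6)
    hi <- params$equilibrium_value + 12 * sd0
    x <- boltzmann_sample(V, lo, hi, n, temperature, seed)
  } else if (params$kind == "angle") {
    x <- boltzmann_sample(V, 0, 180, n, temperature, seed)
  } else {
    x <- boltzmann_sample(V, -180, 180, n, temperature, seed)
  }
  attr(x, "truth") <- params
  x
}

# V(x) in kJ/mol with x in the term's natural reporting units (nm or degrees)
bonded_energy_fun <- function(params) {
  k <- params$force_constant
  x0 <- params$equilibrium_value
  if (params$kind == "bond") {
    function(x) 0.5 * k * (x - x0)^2
  } else if (params$functional_form == "harmonic_cosine") {
    function(x) 0.5 * k * (cos(x * pi / 180) - cos(x0 * pi / 180))^2
  } else if (params$kind == "dihedral") {
    # harmonic in the wrapped deviation so the density is periodic at +/-180
    function(x) 0.5 * k * (((x - x0 + 180) %% 360 - 180) * pi / 180)^2
  } else {
    # harmonic in the angle itself; k in kJ/mol/rad^2, x in degrees
    function(x) 0.5 * k * ((x - x0) * pi / 180)^2
  }
}

#' Generate a power-law release curve
#'
#' Evaluates the Ritger-Peppas law M_t/M_inf = K t^n at the given times, adds
#' Gaussian noise of standard deviation `noise_sigma` (as a fraction of total
#' release) and clips to [0, 1]. At t = 0 the fraction is exactly 0.
#'
#' @param K rate constant, h^-n (> 0).
#' @param n diffusional exponent (> 0).
#' @param times sampling times, h (>= 0).
#' @param noise_sigma additive noise SD (>= 0).
#' @param seed RNG seed.
#' @return A [release_curve()] with the generating `(K, n)` in attribute
#'   `truth`.
#' @export
generate_release_curve <- function(K, n, times, noise_sigma = 0, seed = 1L) {
  stopifnot(K > 0, n > 0, all(times >= 0))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  f <- K * times^n
  if (noise_sigma > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(times), 0, noise_sigma)
  }
  f[times == 0] <- 0
  curve <- release_curve(times, pmin(pmax(f, 0), 1))
  attr(curve, "truth") <- list(K = K, n = n, noise_sigma = noise_sigma)
  curve
}

#' Generate a periodic particle configuration with planted clusters
#'
#' Places clusters of the requested sizes in an orthorhombic periodic box so
#' that the ground-truth partition under a contact cutoff between
#' `intra_spacing` and `inter_separation` is exactly `cluster_sizes`:
#' members of a cluster form a chain with consecutive spacing
#' `intra_spacing`, cluster centers sit on a cubic grid with pitch
#' `inter_separation + 2 r_max` (r_max the largest in-cluster radius), and an
#' optional global `offset` is applied modulo the box, which may put clusters
#' across the periodic boundary.
#'
#' @param cluster_sizes integer sizes of the planted clusters.
#' @param intra_spacing consecutive member distance within a cluster, nm.
#' @param inter_separation minimum surface-to-surface distance between
#'   clusters, nm (must exceed any cutoff used downstream).
#' @param box scalar or length-3 box edge lengths, nm.
#' @param seed RNG seed (member chain directions).
#' @param offset length-3 translation applied to every particle before
#'   wrapping, nm.
#' @return A [particle_config()] with the planted labels and sizes in
#'   attribute `truth`.
#' @export
generate_particle_config <- function(cluster_sizes, intra_spacing = 0.45,
                                     inter_separation = 5, box = 15, seed = 1L,
                                     offset = c(0, 0, 0)) {
  stopifnot(length(cluster_sizes) >= 1L, all(cluster_sizes >= 1),
            intra_spacing > 0, inter_separation > intra_spacing)
  box <- rep(as.numeric(box), length.out = 3L)
  n_cl <- length(cluster_sizes)
  # each cluster is a straight chain of length (size-1)*spacing, so its
  # bounding radius is exact; larger clusters are placed first
  ord <- order(cluster_sizes, decreasing = TRUE)
  radii <- (cluster_sizes - 1) * intra_spacing / 2
  set.seed(seed)
  # regular grid with pitch = separation + 2 r_max realizes the tightest
  # uniform packing (and wraps consistently under PBC, since m*pitch <= box);
  # when the radii are heterogeneous and the grid is too coarse, fall back to
  # greedy placement on a finer candidate grid with exact pairwise checks
  pitch <- inter_separation + 2 * max(radii)
  m_edge <- pmax(floor(box / pitch), 0L)
  centers <- matrix(NA_real_, n_cl, 3L)
  if (prod(m_edge) >= n_cl) {
    grid <- as.matrix(expand.grid(x = seq_len(m_edge[1]), y = seq_len(m_edge[2]),
                                  z = seq_len(m_edge[3])))
    centers[ord, ] <- sweep(grid - 0.5, 2L, pitch, "*")[seq_len(n_cl), , drop = FALSE]
  } else {
    cand_pitch <- inter_separation / 2
    n_edge <- max(floor(min(box) / cand_pitch), 1L)
    cand <- as.matrix(expand.grid(x = seq_len(n_edge), y = seq_len(n_edge),
                                  z = seq_len(n_edge))) * cand_pitch - cand_pitch / 2
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    for (rank in seq_len(n_cl)) {
      ci <- ord[rank]
      placed <- which(!is.na(centers[, 1]))
      ok <- FALSE
      for (s in seq_len(nrow(cand))) {
        need <- TRUE
        for (pj in placed) {
          d <- cand[s, ] - centers[pj, ]
          d <- d - box * round(d / box)
          if (sqrt(sum(d^2)) < inter_separation + radii[ci] + radii[pj]) { need <- FALSE; break }
        }
        if (need) {
          centers[ci, ] <- cand[s, ]
          cand <- cand[-s, , drop = FALSE]
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("cannot place %d clusters with separation %.2f nm in a %.1f x %.1f x %.1f nm box",
                     n_cl, inter_separation, box[1], box[2], box[3]))
      }
    }
  }
  pos <- matrix(0, sum(cluster_sizes), 3L)
  labels <- integer(sum(cluster_sizes))
  i <- 1L
  for (ci in seq_len(n_cl)) {
    sz <- cluster_sizes[ci]
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    chain <- outer(seq_len(sz) - (sz + 1) / 2, dir) * intra_spacing
    pos[i:(i + sz - 1L), ] <- sweep(chain, 2L, centers[ci, ], "+")
    labels[i:(i + sz - 1L)] <- ci
    i <- i + sz
  }
  pos <- sweep(pos, 2L, offset, "+") %% matrix(box, nrow(pos), 3L, byrow = TRUE)
  cfg <- particle_config(pos, box, periodic = TRUE)
  attr(cfg, "truth") <- list(labels = labels, sizes = sort(cluster_sizes, decreasing = TRUE))
  cfg
}

#' Generate multi-state alchemical samples on a lambda-scaled potential
#'
#' For each lambda in the schedule, draws samples from the Boltzmann density
#' of `u_fun(x, lambda)` by inverse-CDF sampling (per-state streams derived
#' from the master seed via [split_seed()]), then assembles the reduced
#' potential matrix u[k, n] = U_k(x_n)/k_B T over all states and samples --
#' the input the MBAR solver consumes.
#'
#' @param u_fun function `(x, lambda) -> kJ/mol`, vectorized in `x`.
#' @param lambdas coupling values, each in [0, 1].
#' @param n_per_state samples per state (scalar or vector).
#' @param temperature K.
#' @param seed master seed.
#' @param domain length-2 sampling domain, nm.
#' @return A [reduced_potential_matrix()] with the per-state samples attached
#'   as attribute `samples`.
#' @export
generate_alchemical_dataset <- function(u_fun, lambdas, n_per_state = 1000L,
                                        temperature = 300, seed = 1L,
                                        domain = c(-3, 3)) {
  K <- length(lambdas)
  stopifnot(K >= 2L)
  n_per_state <- rep(as.integer(n_per_state), length.out = K)
  samples <- vector("list", K)
  for (k in seq_len(K)) {
    samples[[k]] <- boltzmann_sample(function(x) u_fun(x, lambdas[k]),
                                     domain[1], domain[2], n_per_state[k],
                                     temperature, split_seed(seed, k))
  }
  x_all <- unlist(samples)
  beta <- beta_of(temperature)
  u <- matrix(0, K, length(x_all))
  for (k in seq_len(K)) u[k, ] <- beta * u_fun(x_all, lambdas[k])
  m <- reduced_potential_matrix(u, n_per_state, temperature)
  attr(m, "samples") <- samples
  attr(m, "truth") <- list(lambdas = lambdas, seed = seed)
  m
}
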