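# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: clustering by a plain O(n^2) union-find,
# partition functions by quadrature, reference densities by direct
# normalization.

# minimum-image single-linkage clustering by union-find
brute_force_clusters <- function(positions, box, cutoff, periodic = TRUE) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- positions[i, ] - positions[j, ]
      if (periodic) d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # canonical labels: smallest member index
  labels <- stats::ave(seq_len(n), roots, FUN = min)
  list(labels = as.integer(labels),
       sizes = sort(as.integer(table(labels)), decreasing = TRUE))
}

# log partition function of exp(-beta U) by adaptive quadrature
quadrature_logz <- function(ufun, lo, hi, temperature) {
  beta <- 1 / (0.008314462618 * temperature)
  log(stats::integrate(function(x) exp(-beta * ufun(x)), lo, hi,
                       rel.tol = 1e-10)$value)
}

# normalized Boltzmann density on a grid
quadrature_density <- function(ufun, grid, temperature) {
  beta <- 1 / (0.008314462618 * temperature)
  w <- exp(-beta * ufun(grid))
  w / (sum(w) * mean(diff(grid)))
}

# small umbrella dataset shared by several WHAM tests
make_double_well_windows <- function(n_samples = 2000, seed = 11,
                                     height = 10, half_sep = 4) {
  pot <- double_well_potential(height, half_sep)
  centers <- seq(-5.9, 5.9, by = 0.2)
  list(pot = pot,
       ws = generate_umbrella_dataset(pot, centers, 1000,
                                      langevin_config(seed = seed),
                                      n_samples = n_samples))
}

# RMSE between a PMF and the analytic potential after mean alignment,
# over the restrained range (between the outermost window centers; beyond
# them the profile is an extrapolated single-window tail)
pmf_rmse <- function(pmf, pot) {
  keep <- !is.na(pmf$free_energy)
  if (!is.null(pmf$restrained_range)) {
    keep <- keep & pmf$z_grid >= pmf$restrained_range[1] &
      pmf$z_grid <= pmf$restrained_range[2]
  }
  U <- potential_energy(pot, pmf$z_grid[keep])
  G <- pmf$free_energy[keep]
  sqrt(mean((G + mean(U - G) - U)^2))
}
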