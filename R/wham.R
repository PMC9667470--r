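#' Umbrella windows and window sets
#'
#' An `umbrella_window` holds the restraint geometry and the reaction
#' coordinate samples of one biased simulation; a `window_set` is the ordered
#' collection WHAM consumes, sharing one temperature.
#'
#' @param center restraint center, nm.
#' @param spring_constant kJ mol^-1 nm^-2 (>= 0).
#' @param samples reaction-coordinate values, nm (>= 1 sample).
#' @export
umbrella_window <- function(center, spring_constant, samples) {
  stopifnot(is.finite(center), spring_constant >= 0, length(samples) >= 1L,
            all(is.finite(samples)))
  structure(list(center = center, spring_constant = spring_constant,
                 samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' @rdname umbrella_window
#' @param windows list of `umbrella_window`, centers non-decreasing.
#' @param temperature shared temperature, K.
#' @export
window_set <- function(windows, temperature = 310) {
  stopifnot(length(windows) >= 1L, temperature > 0)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (is.unsorted(centers)) stop("window centers must be non-decreasing")
  structure(list(windows = windows, temperature = temperature), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  centers <- vapply(x$windows, `[[`, numeric(1), "center")
  ns <- vapply(x$windows, function(w) length(w$samples), integer(1))
  cat("<window_set> ", length(x$windows), " windows on [",
      signif(min(centers), 4), ", ", signif(max(centers), 4), "] nm, ",
      "T = ", x$temperature, " K, ", sum(ns), " samples\n", sep = "")
  invisible(x)
}

# histogram counts per window on a shared uniform grid; returns bin centers,
# counts matrix (bins x windows), window sizes
wham_histogram <- function(ws, bin_width, breaks = NULL) {
  all_samples <- unlist(lapply(ws$windows, `[[`, "samples"))
  if (is.null(breaks)) {
    # anchor bin centers at integer multiples of bin_width: a grid anchored at
    # the sample minimum makes the binning phase (and hence the discretization
    # error of the profile) a random function of the seed
    grid_range <- range(all_samples)
    k_lo <- floor(grid_range[1] / bin_width - 0.5)
    k_hi <- ceiling(grid_range[2] / bin_width + 0.5)
    breaks <- bin_width * (k_lo:k_hi + 0.5)
  }
  mids <- breaks[-length(breaks)] + bin_width / 2
  counts <- vapply(ws$windows, function(w) {
    s <- w$samples[w$samples >= breaks[1] & w$samples < breaks[length(breaks)]]
    tabulate(findInterval(s, breaks), nbins = length(mids))
  }, integer(length(mids)))
  list(mids = mids, counts = matrix(counts, nrow = length(mids)), breaks = breaks)
}

#' Reconstruct a free-energy profile by WHAM
#'
#' Iterates the standard weighted-histogram self-consistency over binned
#' window samples,
#' \deqn{p(z) \propto \frac{\sum_i n_i(z)}{\sum_j N_j e^{\beta(F_j - w_j(z))}},
#'       \qquad F_j = -k_B T \ln \sum_z p(z)\, e^{-\beta w_j(z)},}
#' until the largest change in any window offset F falls below `tol`, then
#' returns G(z) = -k_B T ln p(z) shifted so the reference region averages 0.
#' Bins with zero total counts are kept on the grid but flagged (`NA` free
#' energy), never interpolated.
#'
#' @param windows a [window_set()].
#' @param bin_width histogram bin width, nm.
#' @param tol convergence tolerance on max |delta F|, kJ/mol.
#' @param max_iter iteration cap; non-convergence raises an error of class
#'   `wham_convergence_error` carrying the F-change history.
#' @param reference_region length-2 interval of z defining G = 0; default is
#'   the outermost 10 percent of the sampled range on the solvent (upper z)
#'   side.
#' @param breaks optional fixed histogram breaks (used by the bootstrap to
#'   keep replicate grids aligned).
#' @return A `pmf_profile`: list with `z_grid`, `free_energy`, `stderr`
#'   (NA until bootstrapped), `reference_region`, `counts`, `f_offsets`,
#'   `iterations`, `temperature`.
#' @export
wham <- function(windows, bin_width = 0.05, tol = 1e-8, max_iter = 1e5,
                 reference_region = NULL, breaks = NULL) {
  stopifnot(inherits(windows, "window_set"), bin_width > 0, tol > 0)
  hist <- wham_histogram(windows, bin_width, breaks)
  mids <- hist$mids
  counts <- hist$counts
  n_win <- ncol(counts)
  N <- colSums(counts)
  c_z <- rowSums(counts)
  populated <- c_z > 0

  # window connectivity through shared populated bins
  if (n_win > 1L) {
    occ <- counts > 0
    adj <- crossprod(occ[populated, , drop = FALSE]) > 0
    comp <- connected_components(adj)
    if (max(comp) > 1L) {
      stop("disconnected window graph: windows split into ", max(comp),
           " groups with no shared populated bins; add intermediate windows")
    }
  }

  beta <- beta_of(windows$temperature)
  centers <- vapply(windows$windows, `[[`, numeric(1), "center")
  springs <- vapply(windows$windows, `[[`, numeric(1), "spring_constant")
  # B[z, j] = exp(-beta w_j(z_bin)); the standard bin-center evaluation.
  # w >= 0 so entries are in (0, 1].
  B <- exp(-beta * (0.5 * outer(mids, centers, "-")^2 %*% diag(springs, n_win)))

  # Newton minimization of the convex WHAM objective
  #   phi(f) = sum_z c_z ln sum_j N_j e^{f_j} B_zj - sum_j N_j f_j
  # whose stationarity conditions are the WHAM self-consistency equations;
  # f is the vector of beta * F_j with the first window as gauge (f_1 = 0).
  # Direct self-consistent iterations serve as the convergence certificate:
  # the loop ends only when a fixed-point sweep moves no offset by more
  # than tol.
  f <- numeric(n_win) # beta * F_j
  cpos <- c_z[populated]
  Bp <- B[populated, , drop = FALSE]
  sc_update <- function(f) {
    denom <- as.vector(Bp %*% (N * exp(f)))
    p <- cpos / denom
    p <- p / sum(p)
    f_new <- -log(as.vector(crossprod(Bp, p)))
    f_new - f_new[1]
  }
  phi <- function(f) {
    A <- exp(f) * N # per-window activity
    sum(cpos * log(as.vector(Bp %*% A))) - sum(N * f)
  }
  history <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    A <- exp(f) * N
    denom <- as.vector(Bp %*% A)
    R <- Bp * rep(A, each = nrow(Bp)) / denom # R[z, j] = a_zj / D_z
    g <- as.vector(crossprod(R, cpos)) - N
    # H_jk = sum_z c_z (delta_jk R_zj - R_zj R_zk)
    H <- -crossprod(R * sqrt(cpos))
    diag(H) <- diag(H) + as.vector(crossprod(R, cpos))
    keep <- 2:n_win
    if (n_win > 1L) {
      step <- tryCatch(solve(H[keep, keep, drop = FALSE] + diag(1e-10, n_win - 1L),
                             -g[keep]),
                       error = function(e) -g[keep] / pmax(diag(H)[keep], 1))
      lam <- 1
      phi0 <- phi(f)
      repeat {
        f_try <- f
        f_try[keep] <- f[keep] + lam * step
        if (phi(f_try) <= phi0 + 1e-12 * abs(phi0) || lam < 1e-6) break
        lam <- lam / 2
      }
      f <- f_try
    }
    f_sc <- sc_update(f)
    delta <- max(abs(f_sc - f))
    history <- c(history, delta)
    if (delta < beta * tol) { f <- f_sc; break }
    if (iter >= max_iter) {
      cond <- structure(class = c("wham_convergence_error", "error", "condition"),
                        list(message = sprintf(
                          "WHAM did not converge in %d iterations (last max |dF| = %.3g kJ/mol)",
                          iter, delta / beta),
                          call = sys.call(-1), history = history / beta))
      stop(cond)
    }
  }
  denom_full <- as.vector(B %*% (N * exp(f)))
  p <- ifelse(denom_full > 0 & c_z > 0, c_z / denom_full, 0)
  p <- p / sum(p)

  G <- rep(NA_real_, length(mids))
  G[populated] <- -log(p[populated]) / beta
  if (is.null(reference_region)) {
    zr <- range(mids[populated])
    reference_region <- c(zr[2] - 0.1 * diff(zr), zr[2])
  }
  ref <- populated & mids >= reference_region[1] & mids <= reference_region[2]
  if (!any(ref)) stop("reference region contains no populated bins")
  G <- G - mean(G[ref])

  structure(list(z_grid = mids, free_energy = G, stderr = rep(NA_real_, length(mids)),
                 reference_region = reference_region, counts = c_z,
                 f_offsets = f / beta, iterations = iter, breaks = hist$breaks,
                 restrained_range = range(centers),
                 temperature = windows$temperature, bin_width = bin_width,
                 f_history = history / beta),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  pop <- !is.na(x$free_energy)
  cat("<pmf_profile> ", sum(pop), " populated bins (", length(x$z_grid), " total), ",
      "G range [", signif(min(x$free_energy[pop]), 4), ", ",
      signif(max(x$free_energy[pop]), 4), "] kJ/mol, ",
      x$iterations, " WHAM iterations\n", sep = "")
  invisible(x)
}

# connected components of a logical adjacency matrix (small n; BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Histogram overlap between adjacent windows
#'
#' For each adjacent pair of windows, reports the histogram-intersection
#' fraction sum_z min(p_i(z), p_{i+1}(z)) of the normalized sample
#' histograms on a shared grid. Pairs below `threshold` are flagged; an
#' empty overlap is a flag, not an error.
#'
#' @param windows a [window_set()] with at least two windows.
#' @param bin_width nm.
#' @param threshold flag pairs whose overlap falls below this (default 0.03).
#' @return A data.frame with columns `window_a`, `window_b`, `overlap`,
#'   `flagged`.
#' @export
check_overlap <- function(windows, bin_width = 0.05, threshold = 0.03) {
  stopifnot(inherits(windows, "window_set"))
  if (length(windows$windows) < 2L) stop("need at least two windows")
  hist <- wham_histogram(windows, bin_width)
  P <- sweep(hist$counts, 2L, pmax(colSums(hist$counts), 1), "/")
  n_win <- ncol(P)
  ov <- vapply(seq_len(n_win - 1L), function(i) sum(pmin(P[, i], P[, i + 1L])), numeric(1))
  data.frame(window_a = seq_len(n_win - 1L), window_b = 2:n_win,
             overlap = ov, flagged = ov < threshold)
}

#' Bootstrap errors for a WHAM profile
#'
#' Resamples each window's samples with replacement (replicate streams
#' seeded from `seed` via [split_seed()]), re-runs WHAM on the original
#' histogram grid, and attaches the per-bin standard deviation across
#' replicates to the point-estimate profile. The replicate free-energy
#' matrix is kept (attribute `replicates`) so [extract_barrier()] can
#' propagate the uncertainty of derived barriers.
#'
#' @inheritParams wham
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed for the resampling.
#' @return The [wham()] profile with `stderr` filled in.
#' @export
bootstrap_pmf_error <- function(windows, n_boot = 32L, seed = 1L,
                                bin_width = 0.05, tol = 1e-8, max_iter = 1e5,
                                reference_region = NULL) {
  stopifnot(inherits(windows, "window_set"), n_boot >= 2L)
  base <- wham(windows, bin_width, tol, max_iter, reference_region)

  reps <- matrix(NA_real_, length(base$z_grid), n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(split_seed(seed, b))
    ws_b <- windows
    ws_b$windows <- lapply(windows$windows, function(w) {
      w$samples <- sample(w$samples, length(w$samples), replace = TRUE)
      w
    })
    prof_b <- tryCatch(
      wham(ws_b, bin_width, tol, max_iter, base$reference_region, breaks = base$breaks),
      wham_convergence_error = function(e) {
        stop("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      })
    reps[, b] <- prof_b$free_energy
  }
  # a bin may be empty in some replicates (NA there); its spread comes from
  # the replicates that populate it
  base$stderr <- apply(reps, 1L, stats::sd, na.rm = TRUE)
  attr(base, "replicates") <- reps
  base
}

#' Extract the translocation barrier from a profile
#'
#' The translocation barrier is the free energy of the preferred partition
#' location (the deepest populated bin, which may sit inside the matrix or
#' at the interface) relative to the mean over the aqueous reference region;
#' by this convention a bound compound has a negative barrier, and a larger
#' magnitude means slower release. If the profile carries bootstrap
#' replicates, the barrier's standard error is the SD of the same statistic
#' across replicates.
#'
#' @param pmf a `pmf_profile` from [wham()] or [bootstrap_pmf_error()].
#' @param reference_region length-2 z interval defining G = 0; default the
#'   profile's own. Must contain at least 3 populated bins.
#' @param min_counts minimum bin occupancy for the minimum search; bins with
#'   fewer samples (the extrapolated tails beyond the outermost restraints,
#'   where the reweighting is dominated by noise) are not candidate minima.
#'   The search is likewise restricted to the restrained range of the
#'   profile when known.
#' @return A `translocation_barrier`: list with `delta_g` (kJ/mol, <= 0 for
#'   a bound compound), `minimum_location` (nm), `reference_region`,
#'   `stderr`.
#' @export
extract_barrier <- function(pmf, reference_region = NULL, min_counts = 10L) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(reference_region)) reference_region <- pmf$reference_region
  pop <- !is.na(pmf$free_energy)
  ref <- pop & pmf$z_grid >= reference_region[1] & pmf$z_grid <= reference_region[2]
  if (sum(ref) < 3L) stop("reference region must contain at least 3 populated bins")
  search <- pop
  if (!is.null(pmf$counts)) search <- search & pmf$counts >= min_counts
  if (!is.null(pmf$restrained_range)) {
    search <- search & pmf$z_grid >= pmf$restrained_range[1] &
      pmf$z_grid <= pmf$restrained_range[2]
  }
  if (!any(search)) search <- pop
  barrier_of <- function(G) {
    Gref <- mean(G[ref])
    i_min <- which(search)[which.min(G[search])]
    c(delta = G[i_min] - Gref, loc = pmf$z_grid[i_min])
  }
  est <- barrier_of(pmf$free_energy)
  se <- NA_real_
  reps <- attr(pmf, "replicates")
  if (!is.null(reps)) {
    deltas <- apply(reps, 2L, function(G) {
      ok <- !is.na(G) & search
      mean_ref <- mean(G[ref & !is.na(G)])
      min(G[ok]) - mean_ref
    })
    se <- stats::sd(deltas)
  }
  structure(list(delta_g = unname(est["delta"]), minimum_location = unname(est["loc"]),
                 reference_region = reference_region, stderr = se),
            class = "translocation_barrier")
}

#' @export
print.translocation_barrier <- function(x, ...) {
  cat("<translocation_barrier> dG = ", signif(x$delta_g, 4), " kJ/mol",
      if (!is.na(x$stderr)) paste0(" +/- ", signif(x$stderr, 3)),
      " at z = ", signif(x$minimum_location, 4), " nm\n", sep = "")
  invisible(x)
}
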