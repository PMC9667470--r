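#' Lambda schedule for alchemical coupling
#'
#' Bookkeeping for the coupling path: `lj_only` is a single schedule that
#' scales the Lennard-Jones interaction (10 states of lambda = 0, 0.1, ...,
#' 1 by default, as used for uncharged coarse-grained solutes), while
#' `coulomb_then_lj` stacks two sub-schedules (electrostatics switched off
#' first, then dispersion; 20 states in total for charged solutes). Each
#' sub-schedule must contain both endpoints 0 and 1 and be strictly
#' increasing.
#'
#' @param lambdas numeric vector in [0, 1] (`lj_only`), or a list of two
#'   such vectors named `coulomb` and `lj` (`coulomb_then_lj`).
#' @param coupling_mode `"lj_only"` or `"coulomb_then_lj"`.
#' @return A `lambda_schedule` with a `n_states` field.
#' @export
lambda_schedule <- function(lambdas = seq(0, 1, by = 1 / 9),
                            coupling_mode = c("lj_only", "coulomb_then_lj")) {
  coupling_mode <- match.arg(coupling_mode)
  check_leg <- function(l, what) {
    if (any(l < 0) || any(l > 1)) stop(what, " lambdas must lie in [0, 1]")
    if (any(diff(l) <= 0)) stop(what, " lambdas must be strictly increasing")
    if (l[1] != 0 || l[length(l)] != 1) stop(what, " schedule must contain both endpoints 0 and 1")
    l
  }
  if (coupling_mode == "lj_only") {
    if (!is.numeric(lambdas)) stop("lj_only mode takes a numeric lambda vector")
    lambdas <- check_leg(lambdas, "lambda")
    n_states <- length(lambdas)
  } else {
    if (!is.list(lambdas) || !all(c("coulomb", "lj") %in% names(lambdas))) {
      stop("coulomb_then_lj mode takes list(coulomb = ..., lj = ...)")
    }
    lambdas <- list(coulomb = check_leg(lambdas$coulomb, "coulomb"),
                    lj = check_leg(lambdas$lj, "lj"))
    n_states <- length(lambdas$coulomb) + length(lambdas$lj)
  }
  structure(list(lambdas = lambdas, coupling_mode = coupling_mode,
                 n_states = n_states), class = "lambda_schedule")
}

#' Beutler soft-core Lennard-Jones potential
#'
#' \deqn{V(r;\lambda) = 4\epsilon\,\lambda^p \left[
#'   \frac{\sigma^{12}}{(\alpha\sigma^6(1-\lambda) + r^6)^2} -
#'   \frac{\sigma^6}{\alpha\sigma^6(1-\lambda) + r^6} \right]}
#' At lambda = 1 this is exactly the 12-6 Lennard-Jones potential; at
#' lambda = 0 the interaction is fully decoupled (V = 0); for any
#' lambda < 1 the potential is finite at r = 0, which is the point of the
#' soft core: no endpoint singularity when particles overlap.
#'
#' @param r separation, nm (vectorized, >= 0).
#' @param lam coupling parameter in [0, 1].
#' @param params a [softcore_params()].
#' @return Energies, kJ/mol.
#' @export
softcore_lj <- function(r, lam, params = softcore_params()) {
  stopifnot(inherits(params, "softcore_params"), lam >= 0, lam <= 1, all(r >= 0))
  if (lam == 0) return(rep(0, length(r)))
  s6 <- params$sigma^6
  denom <- params$alpha * s6 * (1 - lam) + r^6
  4 * params$epsilon * lam^params$lambda_power * (s6^2 / denom^2 - s6 / denom)
}

#' @rdname softcore_lj
#' @param alpha soft-core height parameter (>= 0); default 0.5.
#' @param lambda_power exponent p on lambda; default 1.
#' @param sigma LJ diameter, nm.
#' @param epsilon LJ well depth, kJ/mol (>= 0).
#' @export
softcore_params <- function(alpha = 0.5, lambda_power = 1L, sigma = 0.47,
                            epsilon = 2.0) {
  stopifnot(alpha >= 0, epsilon >= 0, sigma > 0, lambda_power >= 1)
  structure(list(alpha = alpha, lambda_power = as.integer(lambda_power),
                 sigma = sigma, epsilon = epsilon), class = "softcore_params")
}

#' Reduced potential matrix
#'
#' The MBAR input: dimensionless energies u[k, n] = U_k(x_n) / k_B T of all
#' N pooled samples evaluated in all K states, plus the number of samples
#' N_k drawn from each state.
#'
#' @param u K x N numeric matrix, all entries finite.
#' @param n_k integer vector of per-state sample counts; `sum(n_k)` must
#'   equal `ncol(u)`.
#' @param temperature K.
#' @export
reduced_potential_matrix <- function(u, n_k, temperature = 300) {
  u <- as.matrix(u)
  if (!all(is.finite(u))) stop("all reduced potential entries must be finite")
  if (length(n_k) != nrow(u)) stop("length(n_k) must equal the number of states (rows of u)")
  if (sum(n_k) != ncol(u)) stop("sum(n_k) must equal the number of samples (columns of u)")
  if (any(n_k < 0)) stop("n_k must be >= 0")
  if (sum(n_k > 0) < 2L) stop("need at least two states with samples")
  structure(list(u = u, n_k = as.integer(n_k), temperature = temperature),
            class = "reduced_potential_matrix")
}

#' Solve the MBAR equations
#'
#' Estimates the dimensionless free energies f_k of K thermodynamic states
#' from the pooled samples by the multistate Bennett acceptance ratio: the
#' self-consistency
#' \deqn{f_i = -\ln \sum_n \frac{e^{-u_{in}}}{\sum_k N_k e^{f_k - u_{kn}}}}
#' is solved by minimizing the equivalent convex objective with BFGS
#' (analytic gradient, log-sum-exp stabilized) followed by self-consistent
#' polish iterations until max |delta f| < `tol`. Uncertainties come from
#' the standard asymptotic covariance of the estimator, computed from the
#' weight matrix by SVD.
#'
#' @param u a [reduced_potential_matrix()].
#' @param tol convergence tolerance on max |delta f| (dimensionless);
#'   default 1e-10.
#' @param max_iter cap on polish iterations.
#' @return A `mbar_result`: list with `f` (reduced free energies, anchored
#'   at state 1 = 0), `covariance` (K x K, of f), `weights` (K x N mixture
#'   weight matrix), `iterations`, `temperature`.
#' @export
mbar_solve <- function(u, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(u, "reduced_potential_matrix"))
  U <- u$u
  N_k <- u$n_k
  K <- nrow(U); N <- ncol(U)
  sampled <- N_k > 0
  logN <- ifelse(sampled, log(N_k), -Inf)

  # pairwise overlap check among sampled states: a sampled state must share
  # appreciable configuration-space weight with at least one other
  # log denominator per sample given f
  log_denom <- function(f) logsumexp_cols(-U + (logN + f))
  # convex MBAR objective and gradient over sampled states (f[1] fixed at 0)
  obj <- function(fs) {
    f <- numeric(K); f[sampled] <- c(0, fs)
    sum(log_denom(f)) / N - sum(N_k[sampled] * f[sampled]) / N
  }
  grad <- function(fs) {
    f <- numeric(K); f[sampled] <- c(0, fs)
    ld <- log_denom(f)
    g <- vapply(which(sampled), function(k) {
      sum(exp(f[k] + logN[k] - U[k, ] - ld)) - N_k[k]
    }, numeric(1)) / N
    g[-1]
  }
  n_s <- sum(sampled)
  fs0 <- numeric(n_s - 1L)
  if (n_s > 1L) {
    opt <- stats::optim(fs0, obj, grad, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-14))
    fs0 <- opt$par
  }
  f <- numeric(K); f[sampled] <- c(0, fs0)

  # self-consistent polish to the requested tolerance, for all states
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- log_denom(f)
    f_new <- vapply(seq_len(K), function(i) -logsumexp(-U[i, ] - ld), numeric(1))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter >= max_iter) {
      warning(sprintf("MBAR polish stopped at max_iter = %d (max |delta f| = %.3g)",
                      max_iter, delta))
      break
    }
  }

  ld <- log_denom(f)
  # W[n, k] = exp(f_k - u_kn - log_denom_n); each column sums to 1 at the
  # solution (normalized mixture weights per state)
  W <- exp(t(-U + f) - ld)
  colnames(W) <- rownames(W) <- NULL

  # disconnected-state diagnostic via the state overlap matrix
  # O_ij = sum_n N_j W_ni W_nj restricted to sampled states
  if (n_s > 1L) {
    Ws <- W[, sampled, drop = FALSE]
    O <- crossprod(Ws) * rep(N_k[sampled], each = n_s)
    comp <- connected_components(O > 1e-10)
    if (max(comp) > 1L) {
      idx <- which(sampled)
      pair <- c(idx[which(comp == 1L)[1]], idx[which(comp == 2L)[1]])
      stop("non-overlapping states: state ", pair[1], " shares no samples' ",
           "configuration-space weight with state ", pair[2],
           "; the lambda schedule needs intermediate states")
    }
  }
  cov_f <- mbar_covariance(W, N_k)
  structure(list(f = f, covariance = cov_f, weights = t(W), iterations = iter,
                 temperature = u$temperature, n_k = N_k),
            class = "mbar_result")
}

# asymptotic covariance of the reduced free energies (SVD form):
# Theta = V S (I - S V' diag(N) V S)^+ S V', with W = U S V'
mbar_covariance <- function(W, N_k) {
  K <- ncol(W)
  sv <- svd(W)
  S <- diag(sv$d, K)
  V <- sv$v
  M <- diag(K) - S %*% t(V) %*% (N_k * V) %*% S
  Mi <- pseudo_inverse(M)
  Theta <- V %*% S %*% Mi %*% S %*% t(V)
  # covariance of f_k - f_1 differences is what callers use; return Theta
  (Theta + t(Theta)) / 2
}

pseudo_inverse <- function(M, rtol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > rtol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# stderr of f_j - f_i from an mbar_result
mbar_stderr_diff <- function(res, i, j) {
  v <- res$covariance[i, i] + res$covariance[j, j] - 2 * res$covariance[i, j]
  sqrt(max(v, 0))
}

#' @export
print.mbar_result <- function(x, ...) {
  cat("<mbar_result> ", length(x$f), " states, f range [",
      signif(min(x$f), 4), ", ", signif(max(x$f), 4), "] kT, ",
      x$iterations, " polish iterations\n", sep = "")
  invisible(x)
}

#' Solvation free energy from an alchemical dataset
#'
#' Runs MBAR over the schedule's states and returns the free-energy
#' difference between the fully coupled (lambda = 1, last state) and fully
#' decoupled (lambda = 0, first state) endpoints in kJ/mol.
#'
#' @param schedule a [lambda_schedule()]; its `n_states` must match the
#'   matrix.
#' @param u a [reduced_potential_matrix()] built over the schedule's states,
#'   ordered decoupled to coupled.
#' @param ... passed to [mbar_solve()].
#' @return A `free_energy_result`: list with `delta_g` (kJ/mol), `stderr`,
#'   `endpoints`, `temperature`.
#' @export
solvation_dg <- function(schedule, u, ...) {
  stopifnot(inherits(schedule, "lambda_schedule"), inherits(u, "reduced_potential_matrix"))
  if (schedule$n_states != nrow(u$u)) {
    stop("schedule has ", schedule$n_states, " states but the matrix has ", nrow(u$u))
  }
  res <- mbar_solve(u, ...)
  K <- length(res$f)
  kT <- KB_KJ_MOL_K * u$temperature
  free_energy_result(delta_g = (res$f[K] - res$f[1]) * kT,
                     stderr = mbar_stderr_diff(res, 1L, K) * kT,
                     endpoints = c("lambda=0", "lambda=1"),
                     temperature = u$temperature)
}

#' @rdname solvation_dg
#' @param delta_g free-energy difference, kJ/mol.
#' @param stderr standard error, kJ/mol (>= 0).
#' @param endpoints length-2 character labels.
#' @param temperature K.
#' @export
free_energy_result <- function(delta_g, stderr = NA_real_,
                               endpoints = c("A", "B"), temperature = 300) {
  if (!is.na(stderr) && stderr < 0) stop("stderr must be >= 0")
  structure(list(delta_g = delta_g, stderr = stderr, endpoints = endpoints,
                 temperature = temperature), class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat("<free_energy_result> dG(", x$endpoints[1], " -> ", x$endpoints[2], ") = ",
      signif(x$delta_g, 5), if (!is.na(x$stderr)) paste0(" +/- ", signif(x$stderr, 3)),
      " kJ/mol at ", x$temperature, " K\n", sep = "")
  invisible(x)
}

#' Transfer free energy between two solvents
#'
#' The free energy of moving a solute from solvent A to solvent B is the
#' difference of its solvation free energies, dG(A->B) = dG_solv(B) -
#' dG_solv(A); statistical errors add in quadrature. Both results must come
#' from the same temperature.
#'
#' @param dg_solv_in_a,dg_solv_in_b [free_energy_result][solvation_dg]
#'   objects for the same solute in solvents A and B.
#' @return A `free_energy_result` for the A -> B transfer.
#' @export
transfer_dg <- function(dg_solv_in_a, dg_solv_in_b) {
  stopifnot(inherits(dg_solv_in_a, "free_energy_result"),
            inherits(dg_solv_in_b, "free_energy_result"))
  if (abs(dg_solv_in_a$temperature - dg_solv_in_b$temperature) > 1e-9) {
    stop("temperature mismatch: ", dg_solv_in_a$temperature, " vs ",
         dg_solv_in_b$temperature, " K")
  }
  se <- if (is.na(dg_solv_in_a$stderr) || is.na(dg_solv_in_b$stderr)) NA_real_
        else sqrt(dg_solv_in_a$stderr^2 + dg_solv_in_b$stderr^2)
  free_energy_result(dg_solv_in_b$delta_g - dg_solv_in_a$delta_g, se,
                     endpoints = c("solvent A", "solvent B"),
                     temperature = dg_solv_in_a$temperature)
}

#' Octanol-water partition coefficient from a transfer free energy
#'
#' log P_ow = dG(O -> W) / (ln 10 * R * T) with R = k_B in kJ mol^-1 K^-1.
#' A positive cost of moving the solute from octanol into water means a
#' hydrophobic solute and a positive log P.
#'
#' @param dg_o_to_w octanol-to-water transfer free energy, kJ/mol (a number
#'   or a `free_energy_result`).
#' @param temperature K (taken from the result object when given one).
#' @return Dimensionless log P_ow.
#' @export
logp_from_transfer <- function(dg_o_to_w, temperature = 300) {
  if (inherits(dg_o_to_w, "free_energy_result")) {
    temperature <- dg_o_to_w$temperature
    dg_o_to_w <- dg_o_to_w$delta_g
  }
  stopifnot(temperature > 0)
  dg_o_to_w / (log(10) * KB_KJ_MOL_K * temperature)
}
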