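#' Bead mapping scheme
#'
#' Defines how groups of fine-grained atoms are collapsed to coarse-grained
#' beads: each bead is the mass-weighted center of its member atoms. Atom
#' indices are 1-based and must be disjoint across beads.
#'
#' @param beads a list; each element is `list(name =, atoms =, masses =)`
#'   with positive masses and as many masses as atoms.
#' @export
mapping_scheme <- function(beads) {
  stopifnot(length(beads) >= 1L)
  seen <- integer(0)
  for (b in beads) {
    stopifnot(is.character(b$name), length(b$atoms) >= 1L,
              length(b$atoms) == length(b$masses), all(b$masses > 0))
    if (any(b$atoms %in% seen)) stop("atom indices must be disjoint across beads")
    seen <- c(seen, b$atoms)
  }
  structure(list(beads = beads), class = "mapping_scheme")
}

#' Map a fine-grained trajectory to bead centers of mass
#'
#' Each bead's position in every frame is the mass-weighted mean of its
#' member atoms, the standard center-of-mass mapping used to convert an
#' atomistic trajectory into a coarse-grained one.
#'
#' @param fine_positions array `frames x atoms x 3`, nm.
#' @param mapping a [mapping_scheme()].
#' @return Array `frames x beads x 3`, nm, with bead names on the second
#'   dimension.
#' @export
map_trajectory <- function(fine_positions, mapping) {
  stopifnot(inherits(mapping, "mapping_scheme"), length(dim(fine_positions)) == 3L,
            dim(fine_positions)[3] == 3L)
  n_atoms <- dim(fine_positions)[2]
  n_frames <- dim(fine_positions)[1]
  n_beads <- length(mapping$beads)
  out <- array(NA_real_, c(n_frames, n_beads, 3L),
               dimnames = list(NULL, vapply(mapping$beads, `[[`, character(1), "name"), NULL))
  for (j in seq_len(n_beads)) {
    b <- mapping$beads[[j]]
    if (any(b$atoms < 1L) || any(b$atoms > n_atoms)) {
      stop("bead '", b$name, "' references atom indices outside 1..", n_atoms)
    }
    w <- b$masses / sum(b$masses)
    for (d in 1:3) {
      out[, j, d] <- fine_positions[, b$atoms, d, drop = FALSE][, , 1] %*% w
    }
  }
  out
}

# per-frame geometry of a bead tuple: distance (nm), angle or signed
# dihedral (degrees, atan2 convention)
tuple_values <- function(coarse, idx) {
  P <- function(i) array(coarse[, idx[i], , drop = FALSE], c(dim(coarse)[1], 3L))
  if (length(idx) == 2L) {
    v <- P(2) - P(1)
    sqrt(rowSums(v^2))
  } else if (length(idx) == 3L) {
    v1 <- P(1) - P(2); v2 <- P(3) - P(2)
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    cosang <- rowSums(v1 * v2) / (n1 * n2)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ang[n1 == 0 | n2 == 0] <- NA_real_
    ang
  } else {
    b1 <- P(2) - P(1); b2 <- P(3) - P(2); b3 <- P(4) - P(3)
    n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
                b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
                b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
    n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
                b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
                b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
    m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
                n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
                n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
    nb2 <- sqrt(rowSums(b2^2))
    x <- rowSums(n1 * n2)
    y <- rowSums(m1 * n2) / nb2
    dih <- atan2(y, x) * 180 / pi
    dih[nb2 == 0 | rowSums(n1^2) == 0 | rowSums(n2^2) == 0] <- NA_real_
    dih
  }
}

circular_mean_deg <- function(x) {
  a <- x * pi / 180
  atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
}

circular_sd_deg <- function(x) {
  a <- x * pi / 180
  R <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  sqrt(-2 * log(max(R, .Machine$double.eps))) * 180 / pi
}

#' Bonded distribution container
#'
#' Holds the raw per-frame values of one bonded term together with its
#' normalized histogram, mean and width. Dihedral statistics are circular
#' (values wrap at +/- 180 deg), so the mean and width come from the
#' resultant vector, not the arithmetic moments.
#'
#' @param kind `"bond"`, `"angle"` or `"dihedral"`.
#' @param values nm (bond) or degrees (angle/dihedral).
#' @param n_excluded frames dropped for degenerate geometry.
#' @param breaks optional histogram breaks (Freedman-Diaconis when `NULL`).
#' @export
bonded_distribution <- function(kind = c("bond", "angle", "dihedral"), values,
                                n_excluded = 0L, breaks = NULL) {
  kind <- match.arg(kind)
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2L)
  if (kind == "angle" && (any(values < 0) || any(values > 180))) {
    stop("angle values must lie in [0, 180] degrees")
  }
  if (kind == "dihedral") values <- ((values + 180) %% 360) - 180
  if (is.null(breaks)) breaks <- fd_breaks(values)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  circ <- kind == "dihedral"
  structure(list(kind = kind, values = values,
                 breaks = h$breaks, density = h$density,
                 mean = if (circ) circular_mean_deg(values) else mean(values),
                 width = if (circ) circular_sd_deg(values) else stats::sd(values),
                 n_excluded = as.integer(n_excluded)),
            class = "bonded_distribution")
}

fd_breaks <- function(x, min_bins = 16L) {
  n <- max(grDevices::nclass.FD(x), min_bins)
  r <- range(x)
  if (diff(r) == 0) r <- r + c(-1e-6, 1e-6)
  seq(r[1], r[2], length.out = n + 1L)
}

#' Extract bonded distributions from a coarse trajectory
#'
#' For every tuple in the topology, computes the per-frame geometric value
#' (distance for pairs; angle by arccos of the normalized dot product for
#' triplets; signed dihedral by the atan2 convention for quadruplets) and
#' its histogram. Frames with degenerate geometry (zero-length vectors) are
#' excluded and counted; a zero-width distribution is flagged with a
#' warning.
#'
#' @param coarse array `frames x beads x 3` from [map_trajectory()].
#' @param bonded_topology list of integer vectors of length 2, 3 or 4
#'   (bead indices).
#' @return A list of [bonded_distribution()] objects.
#' @export
extract_distributions <- function(coarse, bonded_topology) {
  stopifnot(length(dim(coarse)) == 3L, dim(coarse)[3] == 3L)
  lapply(bonded_topology, function(idx) {
    stopifnot(length(idx) %in% 2:4, all(idx >= 1L), all(idx <= dim(coarse)[2]))
    kind <- c("bond", "angle", "dihedral")[length(idx) - 1L]
    vals <- tuple_values(coarse, idx)
    n_bad <- sum(!is.finite(vals))
    vals <- vals[is.finite(vals)]
    if (length(vals) >= 2L && stats::sd(vals) == 0) {
      warning("zero-width ", kind, " distribution for tuple (",
              paste(idx, collapse = ", "), ")")
      vals <- vals + c(-1, 1) * 1e-9 # keep the container constructible
    }
    bonded_distribution(kind, vals, n_excluded = n_bad)
  })
}

#' Bonded interaction parameters
#'
#' @param kind `"bond"`, `"angle"` or `"dihedral"`.
#' @param equilibrium_value nm (bond) or degrees.
#' @param force_constant kJ mol^-1 nm^-2 for bonds; kJ mol^-1 rad^-2 for
#'   harmonic angles/dihedrals; kJ/mol for the harmonic-cosine form.
#' @param functional_form `"harmonic"` or `"harmonic_cosine"`.
#' @export
bonded_params <- function(kind = c("bond", "angle", "dihedral"),
                          equilibrium_value, force_constant,
                          functional_form = c("harmonic", "harmonic_cosine")) {
  kind <- match.arg(kind)
  functional_form <- match.arg(functional_form)
  if (force_constant <= 0) stop("force_constant must be > 0")
  if (kind == "bond" && functional_form != "harmonic") {
    stop("bonds use the harmonic form")
  }
  structure(list(kind = kind, equilibrium_value = equilibrium_value,
                 force_constant = force_constant, functional_form = functional_form),
            class = "bonded_params")
}

#' @export
print.bonded_params <- function(x, ...) {
  unit <- if (x$kind == "bond") "nm" else "deg"
  cat("<bonded_params> ", x$kind, " (", x$functional_form, "): eq = ",
      signif(x$equilibrium_value, 5), " ", unit, ", k = ",
      signif(x$force_constant, 5), "\n", sep = "")
  invisible(x)
}

#' Fit bonded parameters by Boltzmann inversion
#'
#' The equilibrium value is the distribution mean (circular mean for
#' dihedrals) and the force constant follows from equating the observed
#' variance to that of the model's Boltzmann distribution: for a harmonic
#' term, k = k_B T / var(x); for a harmonic-cosine term, k = k_B T /
#' var(cos theta). Angle-type variances are taken in radians, so harmonic
#' angle constants come out in kJ mol^-1 rad^-2.
#'
#' @param dist a [bonded_distribution()] with positive width.
#' @param form functional form to fit.
#' @param temperature K.
#' @return A [bonded_params()].
#' @export
fit_bonded <- function(dist, form = c("harmonic", "harmonic_cosine"),
                       temperature = 310) {
  stopifnot(inherits(dist, "bonded_distribution"))
  form <- match.arg(form)
  kT <- KB_KJ_MOL_K * temperature
  x <- dist$values
  if (dist$width <= 1e-12) {
    stop("zero-variance ", dist$kind,
         " distribution: replace this term by a constraint rather than a stiff spring")
  }
  if (dist$kind == "bond") {
    return(bonded_params("bond", mean(x), kT / stats::var(x), "harmonic"))
  }
  eq <- if (dist$kind == "dihedral") circular_mean_deg(x) else mean(x)
  if (form == "harmonic_cosine") {
    k <- kT / stats::var(cos(x * pi / 180))
  } else {
    if (dist$kind == "dihedral") {
      dev <- ((x - eq + 180) %% 360 - 180) * pi / 180
      k <- kT / mean(dev^2)
    } else {
      k <- kT / stats::var(x * pi / 180)
    }
  }
  bonded_params(dist$kind, eq, k, form)
}

# Jensen-Shannon divergence between two sample sets via shared histograms
js_divergence <- function(x, y, n_bins = 64L) {
  r <- range(c(x, y))
  if (diff(r) == 0) return(0)
  breaks <- seq(r[1] - 1e-12, r[2] + 1e-12, length.out = n_bins + 1L)
  p <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins) / length(x)
  q <- tabulate(findInterval(y, breaks, all.inside = TRUE), n_bins) / length(y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Iterative refinement of bonded parameters
#'
#' Mirrors the trial-and-error stage of coarse-grained parametrization, made
#' systematic: per iteration each term is re-sampled from its current
#' parameters, the force constant is rescaled by
#' `(width_current / width_target)^2` and the equilibrium value shifted by
#' the mean mismatch, until the Jensen-Shannon divergence between current
#' and target histograms drops below `tol`. If the mismatch increases twice
#' in a row the update is damped by half (recorded in the report) to guard
#' against oscillation.
#'
#' @param initial list of [bonded_params()], one per target.
#' @param targets list of [bonded_distribution()] objects.
#' @param max_iter iteration cap per term.
#' @param tol JSD threshold for convergence.
#' @param n_sample ensemble size drawn per iteration.
#' @param temperature K.
#' @param seed RNG seed for the per-iteration ensembles.
#' @param sampler function `(params, n, temperature, seed) -> samples`;
#'   defaults to [sample_bonded_ensemble()].
#' @return List with `params` (refined list) and `report` (data.frame of
#'   per-term mismatch before/after, iterations, convergence flag, damping
#'   events).
#' @export
refine_iteratively <- function(initial, targets, max_iter = 20L, tol = 5e-4,
                               n_sample = 20000L, temperature = 310, seed = 1L,
                               sampler = sample_bonded_ensemble) {
  stopifnot(length(initial) == length(targets))
  out <- vector("list", length(initial))
  rows <- vector("list", length(initial))
  for (t in seq_along(initial)) {
    par <- initial[[t]]
    target <- targets[[t]]
    mismatch_prev <- Inf
    rises <- 0L
    damp <- 1
    n_damped <- 0L
    mismatch0 <- NA_real_
    iter_used <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      cur <- sampler(par, n_sample, temperature, split_seed(seed, t * 1000L + it))
      mcur <- js_divergence(cur, target$values)
      if (it == 1L) mismatch0 <- mcur
      iter_used <- it
      if (mcur < tol) { converged <- TRUE; break }
      if (mcur > mismatch_prev) {
        rises <- rises + 1L
        if (rises >= 2L) { damp <- damp / 2; n_damped <- n_damped + 1L; rises <- 0L }
      } else rises <- 0L
      mismatch_prev <- mcur
      w_cur <- if (par$kind == "dihedral") circular_sd_deg(cur) else stats::sd(cur)
      m_cur <- if (par$kind == "dihedral") circular_mean_deg(cur) else mean(cur)
      ratio <- (w_cur / target$width)^2
      par$force_constant <- par$force_constant * ratio^damp
      shift <- target$mean - m_cur
      par$equilibrium_value <- par$equilibrium_value + damp * shift
    }
    final <- js_divergence(sampler(par, n_sample, temperature, split_seed(seed, t * 1000L)),
                           target$values)
    out[[t]] <- par
    rows[[t]] <- data.frame(term = t, kind = par$kind,
                            mismatch_before = mismatch0, mismatch_after = final,
                            iterations = iter_used, converged = converged || final < tol,
                            damping_events = n_damped)
  }
  list(params = out, report = do.call(rbind, rows))
}
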