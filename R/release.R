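#' Release curve container
#'
#' Fraction of drug released, M_t/M_inf, as a function of time.
#'
#' @param times hours, non-negative and increasing.
#' @param fraction_released values in [0, 1].
#' @param stderr optional per-point standard errors.
#' @export
release_curve <- function(times, fraction_released, stderr = NULL) {
  stopifnot(length(times) == length(fraction_released), all(times >= 0),
            !is.unsorted(times))
  if (any(fraction_released < 0 | fraction_released > 1)) {
    bad <- which(fraction_released < 0 | fraction_released > 1)[1]
    stop("fraction_released out of [0, 1] at row ", bad)
  }
  if (!is.null(stderr)) stopifnot(length(stderr) == length(times), all(stderr >= 0))
  structure(list(times = as.numeric(times),
                 fraction_released = as.numeric(fraction_released),
                 stderr = stderr),
            class = "release_curve")
}

#' Relative release rate from two translocation barriers
#'
#' Under the solubility-diffusion picture the release rate is proportional
#' to D exp(beta dG_t*); for two compounds with equal diffusion
#' coefficients the prefactor cancels and
#' \deqn{k_a / k_b = e^{\beta(\Delta G_a - \Delta G_b)}.}
#' A deeper (more negative) barrier therefore means a smaller rate. The
#' absolute rate carries an arbitrary prefactor and is exposed separately
#' as [absolute_rate()].
#'
#' @param dg_a,dg_b translocation barriers, kJ/mol (<= 0 by the package's
#'   convention).
#' @param temperature K.
#' @return Dimensionless ratio k_a / k_b.
#' @export
relative_rate <- function(dg_a, dg_b, temperature = 310) {
  stopifnot(dg_a <= 0, dg_b <= 0)
  exp(beta_of(temperature) * (dg_a - dg_b))
}

#' @rdname relative_rate
#' @param dg translocation barrier, kJ/mol.
#' @param diffusion_coeff nm^2/ps.
#' @return `absolute_rate`: D exp(beta dG), in units of D times an
#'   arbitrary prefactor (attribute `note`); only ratios of these are
#'   physically meaningful.
#' @export
absolute_rate <- function(dg, temperature = 310, diffusion_coeff = 0.01) {
  stopifnot(diffusion_coeff > 0)
  structure(diffusion_coeff * exp(beta_of(temperature) * dg),
            note = "arbitrary prefactor: only ratios are meaningful")
}

#' Rank compounds by translocation barrier
#'
#' Orders compounds fastest to slowest release: descending barrier (least
#' negative first), since a lower-magnitude barrier costs less to escape.
#' Ties are broken alphabetically and reported.
#'
#' @param barriers named numeric vector of barriers, kJ/mol.
#' @return Character vector of names, fastest first, with attribute `ties`
#'   listing tied groups (if any).
#' @export
rank_compounds <- function(barriers) {
  if (length(barriers) == 0L) stop("barriers must be non-empty")
  if (is.null(names(barriers)) || any(!nzchar(names(barriers)))) {
    stop("barriers must be named")
  }
  ord <- order(-barriers, names(barriers))
  ranked <- names(barriers)[ord]
  dup <- barriers[ord][duplicated(barriers[ord]) | duplicated(barriers[ord], fromLast = TRUE)]
  ties <- if (length(dup)) split(names(dup), dup) else list()
  structure(ranked, ties = ties)
}

#' Relative difference between two barriers
#'
#' 100 |dG_a - dG_b| / |dG_b|, in percent; the second argument is the
#' reference denominator by convention.
#'
#' @param dg_a,dg_b barriers, kJ/mol; `dg_b` must be non-zero.
#' @export
barrier_relative_difference <- function(dg_a, dg_b) {
  if (dg_b == 0) stop("reference barrier dg_b must be non-zero")
  100 * abs(dg_a - dg_b) / abs(dg_b)
}

#' Fit the Ritger-Peppas law to a release curve
#'
#' Fits M_t/M_inf = K t^n by nonlinear least squares, restricted to points
#' with fraction <= `max_fraction` (default 0.6, the standard validity
#' domain of the power law) and t > 0. The fit is initialized from a
#' log-log linear regression; when the curve carries per-point standard
#' errors the fit is inverse-variance weighted.
#'
#' @param curve a [release_curve()] with at least 3 usable points.
#' @param max_fraction upper release fraction included in the fit.
#' @return A `peppas_fit`: list with `K` (h^-n), `n`, `covariance` (2 x 2),
#'   `fit_range_max_fraction`, `n_points`.
#' @export
fit_peppas <- function(curve, max_fraction = 0.6) {
  stopifnot(inherits(curve, "release_curve"), max_fraction > 0)
  keep <- curve$times > 0 & curve$fraction_released > 0 &
    curve$fraction_released <= max_fraction
  if (sum(keep) < 3L) {
    stop("need at least 3 points with 0 < fraction <= ", max_fraction, " and t > 0")
  }
  t <- curve$times[keep]
  f <- curve$fraction_released[keep]
  if (any(!is.finite(t)) || any(!is.finite(f))) stop("non-finite inputs")
  init <- stats::lm(log(f) ~ log(t))
  start <- list(K = exp(unname(stats::coef(init)[1])),
                n = max(unname(stats::coef(init)[2]), 1e-3))
  w <- if (!is.null(curve$stderr)) {
    s <- curve$stderr[keep]
    if (all(s > 0)) 1 / s^2 else rep(1, length(t))
  } else rep(1, length(t))
  fit <- minpack.lm::nlsLM(f ~ K * t^n, start = start, weights = w,
                           lower = c(K = 1e-12, n = 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(list(K = unname(est["K"]), n = unname(est["n"]),
                 covariance = stats::vcov(fit),
                 fit_range_max_fraction = max_fraction,
                 n_points = length(t)),
            class = "peppas_fit")
}

#' @export
print.peppas_fit <- function(x, ...) {
  cat("<peppas_fit> K = ", signif(x$K, 4), " h^-n, n = ", signif(x$n, 4),
      " (", x$n_points, " points, fraction <= ", x$fit_range_max_fraction, ")\n", sep = "")
  invisible(x)
}

#' Predict a release curve from a Peppas fit
#'
#' @param fit a `peppas_fit` (or any list with `K` and `n`).
#' @param times hours (>= 0).
#' @return A [release_curve()] with K t^n clipped to [0, 1].
#' @export
predict_release <- function(fit, times) {
  stopifnot(all(times >= 0))
  f <- fit$K * times^fit$n
  f[times == 0] <- 0
  release_curve(times, pmin(pmax(f, 0), 1))
}
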