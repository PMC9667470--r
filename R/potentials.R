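#' Analytic one-dimensional potentials
#'
#' A `potential_spec` is the ground truth every estimator in the package is
#' tested against: an analytic 1D potential energy function U(z) with an
#' analytic first derivative. Energies are in kJ/mol, lengths in nm. Four
#' forms are supported:
#'
#' * `harmonic`: U = 1/2 k (z - center)^2
#' * `double_well`: U = h ((z/a)^2 - 1)^2, minima at +/- a, barrier h at 0
#' * `translocation`: a matrix-to-water profile (see
#'   [make_translocation_potential()])
#' * `tabulated`: natural cubic spline through (z, u) points with strictly
#'   increasing abscissa
#'
#' @param k force constant, kJ mol^-1 nm^-2.
#' @param center trap center, nm.
#' @name potentials
NULL

new_potential_spec <- function(form, params) {
  structure(list(form = form, params = params), class = "potential_spec")
}

#' @rdname potentials
#' @export
harmonic_potential <- function(k, center = 0) {
  stopifnot(k >= 0, is.finite(center))
  new_potential_spec("harmonic", list(k = k, center = center))
}

#' @rdname potentials
#' @param height barrier height h between the two minima, kJ/mol (> 0).
#' @param half_separation a, the distance of each minimum from the origin, nm.
#' @export
double_well_potential <- function(height, half_separation) {
  stopifnot(height > 0, half_separation > 0)
  new_potential_spec("double_well", list(h = height, a = half_separation))
}

#' @rdname potentials
#' @param z,u tabulated abscissa (strictly increasing, nm) and energies (kJ/mol).
#' @export
tabulated_potential <- function(z, u) {
  stopifnot(length(z) == length(u), length(z) >= 4L, all(is.finite(z)), all(is.finite(u)))
  if (any(diff(z) <= 0)) stop("tabulated potential requires a strictly increasing abscissa")
  new_potential_spec("tabulated", list(z = as.numeric(z), u = as.numeric(u)))
}

#' @rdname potentials
#' @export
flat_potential <- function() harmonic_potential(0, 0)

#' Matrix-to-water translocation profile
#'
#' Analytic stand-in for the free-energy landscape a hydrophobic compound
#' sees when moving from a poorly hydrated polymer matrix into bulk water:
#' a flat region at `well_depth` (< 0, kJ/mol) inside the matrix, a smooth
#' sigmoidal rise across the matrix-water interface, and a plateau at
#' `plateau_value` (default 0) in the solvent limit. The rise is a cubic
#' smoothstep over `interface_center +/- interface_width`, so the profile
#' and its derivative are continuous and the derivative vanishes on both
#' plateaus.
#'
#' @param well_depth depth of the matrix well relative to the solvent
#'   plateau, kJ/mol; must be <= 0.
#' @param well_center a position inside the matrix plateau, nm; must lie at
#'   or below `interface_center - interface_width`.
#' @param interface_center midpoint of the interfacial rise, nm.
#' @param interface_width half-width of the rise, nm (> 0).
#' @param plateau_value solvent-limit energy, kJ/mol (default 0).
#' @return A `potential_spec` of form `"translocation"`.
#' @examples
#' pot <- make_translocation_potential(-69.8, 2, 5, 1.5)
#' potential_energy(pot, c(0, 5, 10))
#' @export
make_translocation_potential <- function(well_depth, well_center,
                                         interface_center, interface_width,
                                         plateau_value = 0) {
  if (well_depth > 0) stop("well_depth must be <= 0 (a depth relative to the solvent plateau)")
  stopifnot(interface_width > 0)
  if (well_center > interface_center - interface_width) {
    stop("well_center must lie inside the matrix plateau, at or below interface_center - interface_width")
  }
  new_potential_spec("translocation", list(
    well_depth = well_depth, well_center = well_center,
    interface_center = interface_center, interface_width = interface_width,
    plateau_value = plateau_value
  ))
}

#' Evaluate a potential or its derivative
#'
#' @param pot a `potential_spec`.
#' @param z positions, nm (vectorized).
#' @return Energies in kJ/mol (`potential_energy`) or derivatives dU/dz in
#'   kJ mol^-1 nm^-1 (`potential_deriv`).
#' @export
potential_energy <- function(pot, z) {
  stopifnot(inherits(pot, "potential_spec"))
  p <- pot$params
  switch(pot$form,
    harmonic = 0.5 * p$k * (z - p$center)^2,
    double_well = p$h * ((z / p$a)^2 - 1)^2,
    translocation = {
      t <- (z - (p$interface_center - p$interface_width)) / (2 * p$interface_width)
      t <- pmin(pmax(t, 0), 1)
      s <- t * t * (3 - 2 * t)
      p$plateau_value + p$well_depth * (1 - s)
    },
    tabulated = tabulated_fun(pot)(z),
    stop("unknown potential form: ", pot$form)
  )
}

#' @rdname potential_energy
#' @export
potential_deriv <- function(pot, z) {
  stopifnot(inherits(pot, "potential_spec"))
  p <- pot$params
  switch(pot$form,
    harmonic = p$k * (z - p$center),
    double_well = 4 * p$h * z * ((z / p$a)^2 - 1) / p$a^2,
    translocation = {
      t <- (z - (p$interface_center - p$interface_width)) / (2 * p$interface_width)
      inside <- t > 0 & t < 1
      t <- pmin(pmax(t, 0), 1)
      ds <- ifelse(inside, 6 * t * (1 - t), 0)
      -p$well_depth * ds / (2 * p$interface_width)
    },
    tabulated = tabulated_fun(pot, deriv = 1L)(z),
    stop("unknown potential form: ", pot$form)
  )
}

# spline interpolant for the tabulated form (natural: linear extrapolation-free
# curvature at the ends keeps the derivative bounded)
tabulated_fun <- function(pot, deriv = 0L) {
  f <- stats::splinefun(pot$params$z, pot$params$u, method = "natural")
  function(z) f(z, deriv = deriv)
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$form, "\n")
  if (x$form != "tabulated") {
    cat(" ", paste(names(x$params), signif(unlist(x$params), 6), sep = " = ", collapse = ", "), "\n")
  } else {
    cat("  ", length(x$params$z), " tabulated points on [",
        min(x$params$z), ", ", max(x$params$z), "] nm\n", sep = "")
  }
  invisible(x)
}

# encode a potential for the compiled integrator: integer form id, a parameter
# vector, and (for tabulated) force values on a fine grid
potential_for_core <- function(pot) {
  p <- pot$params
  switch(pot$form,
    harmonic = list(id = 1L, pars = c(p$k, p$center), gz = numeric(0), gf = numeric(0)),
    double_well = list(id = 2L, pars = c(p$h, p$a), gz = numeric(0), gf = numeric(0)),
    translocation = list(
      id = 3L,
      pars = c(p$well_depth, p$interface_center, p$interface_width, p$plateau_value),
      gz = numeric(0), gf = numeric(0)
    ),
    tabulated = {
      zr <- range(p$z)
      gz <- seq(zr[1], zr[2], length.out = 4096L)
      list(id = 4L, pars = numeric(0), gz = gz, gf = tabulated_fun(pot, 1L)(gz))
    },
    stop("unknown potential form: ", pot$form)
  )
}
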