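#' Pupil-phase basis kernels
#'
#' The three basis phase functions from which the binary DOE is composed,
#' each evaluated in radians on the pupil lattice of an [pupil_grid()]:
#'
#' * `axicon_phase()`: radially linear cone,
#'   `pi * p1 * sqrt(u^2 + v^2)` with `(u, v)` in cycles/um.
#' * `defocus_phase()`: exact angular-spectrum propagation phase for an
#'   axial displacement `z_um`,
#'   `(2 pi n / lambda) * z * sqrt(1 - (lambda u / n)^2 - (lambda v / n)^2)`,
#'   set to zero beyond the propagating-wave circle (evanescent cutoff).
#' * `spherical_phase()`: primary (Seidel) spherical aberration,
#'   `2 pi * w * rho^4` with `w` in waves at the pupil edge and `rho` the
#'   NA-normalized pupil radius.
#'
#' All kernels are rotationally symmetric; axicon and spherical vanish at the
#' origin while defocus equals `2 pi n z / lambda` there (a piston that
#' carries the propagation distance).
#'
#' @param grid An [pupil_grid()].
#' @param p1 Axicon strength (dimensionless; 0 is the identity contribution).
#' @param z_um Axial displacement in um.
#' @param w Spherical aberration in waves at `rho = 1`.
#' @return A `grid_size x grid_size` numeric phase map (radians).
#' @examples
#' g <- pupil_grid(optical_config(grid_size = 64))
#' max(abs(axicon_phase(g, 0)))    # identity
#' @export
axicon_phase <- function(grid, p1) {
  stopifnot(inherits(grid, "edof_grid"))
  stopifnot_scalar(p1, "p1")
  pi * p1 * grid$rho * grid$cutoff_cpum
}

#' @rdname axicon_phase
#' @export
defocus_phase <- function(grid, z_um) {
  stopifnot(inherits(grid, "edof_grid"))
  stopifnot_scalar(z_um, "z_um")
  defocus_rate(grid) * z_um
}

# Defocus phase per micron of axial displacement (radians/um); zero outside
# the propagating-wave circle lambda * sqrt(u^2+v^2) / n > 1. Cached on the
# grid's environment-free list is not possible, so recomputed cheaply.
defocus_rate <- function(grid) {
  cfg <- grid$config
  f <- grid$rho * grid$cutoff_cpum
  arg <- 1 - (cfg$wavelength_um * f / cfg$n_medium)^2
  rate <- matrix(0, nrow(arg), ncol(arg))
  prop <- arg > 0
  rate[prop] <- 2 * pi * cfg$n_medium / cfg$wavelength_um * sqrt(arg[prop])
  rate
}

#' @rdname axicon_phase
#' @export
spherical_phase <- function(grid, w) {
  stopifnot(inherits(grid, "edof_grid"))
  stopifnot_scalar(w, "w")
  2 * pi * w * grid$rho^4
}

#' Native aberration model of the GRIN objective
#'
#' The on-axis aberration of the GRIN lens is dominated by primary spherical
#' aberration; the Zemax-characterized value for the design at hand is
#' `w040 = 29.4` waves at the pupil edge. Higher-order rotationally symmetric
#' Seidel terms can be supplied as powers of `rho` (e.g.
#' `higher_order = c("6" = 2)` adds `2 * 2 pi * rho^6` waves).
#'
#' @param w040 Primary spherical aberration in waves at `rho = 1`.
#' @param higher_order Named numeric vector: names are even powers of `rho`,
#'   values are waves at the pupil edge. Default empty.
#' @return An object of class `edof_aberration`.
#' @export
aberration_model <- function(w040 = 29.4, higher_order = numeric()) {
  stopifnot_scalar(w040, "w040")
  if (length(higher_order)) {
    if (is.null(names(higher_order)) || any(!nzchar(names(higher_order)))) {
      abort("`higher_order` must be a named vector (names = powers of rho).")
    }
  }
  structure(list(w040 = w040, higher_order = higher_order),
            class = "edof_aberration")
}

#' Evaluate the GRIN aberration phase on a pupil grid
#'
#' Returns the real-valued phase map (radians) of the native on-axis
#' aberration: `spherical_phase(grid, w040)` plus any higher-order terms.
#' Applied in the forward model as the unit-modulus factor `exp(1i * phase)`.
#'
#' @param model An [aberration_model()].
#' @param grid An [pupil_grid()].
#' @return Phase map (radians), zero at `rho = 0`.
#' @export
grin_aberration <- function(model, grid) {
  stopifnot(inherits(model, "edof_aberration"), inherits(grid, "edof_grid"))
  phase <- spherical_phase(grid, model$w040)
  for (nm in names(model$higher_order)) {
    p <- as.numeric(nm)
    if (!is.finite(p) || p <= 0) abort("higher_order powers must be positive numbers")
    phase <- phase + 2 * pi * model$higher_order[[nm]] * grid$rho^p
  }
  phase
}
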