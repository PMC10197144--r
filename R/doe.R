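#' Basis coefficients of a candidate DOE
#'
#' The three-element optimization vector of the designer: axicon strength,
#' defocus displacement (um) and spherical aberration (waves). The +1st
#' diffraction order of the resulting binary mask carries the composed phase
#' with these signs; the -1st order carries its conjugate.
#'
#' @param axicon Axicon kernel strength (dimensionless).
#' @param defocus_um Axial displacement of the defocus kernel, in um.
#' @param spherical_waves Spherical aberration in waves at the pupil edge.
#' @return An object of class `edof_coeffs`.
#' @examples
#' basis_coefficients(0, 129, 26.65)
#' @export
basis_coefficients <- function(axicon = 0, defocus_um = 0, spherical_waves = 0) {
  stopifnot_scalar(axicon, "axicon")
  stopifnot_scalar(defocus_um, "defocus_um")
  stopifnot_scalar(spherical_waves, "spherical_waves")
  structure(
    list(axicon = axicon, defocus_um = defocus_um,
         spherical_waves = spherical_waves),
    class = "edof_coeffs"
  )
}

#' @export
print.edof_coeffs <- function(x, ...) {
  cat(sprintf("<edof_coeffs> axicon %.4g, defocus %.4g um, spherical %.4g waves\n",
              x$axicon, x$defocus_um, x$spherical_waves))
  invisible(x)
}

#' @export
as.numeric.edof_coeffs <- function(x, ...) {
  c(axicon = x$axicon, defocus_um = x$defocus_um,
    spherical_waves = x$spherical_waves)
}

#' Compose the continuous (unwrapped) DOE phase
#'
#' Sum of the three basis kernels evaluated at the given coefficients:
#' `axicon_phase(p1) + defocus_phase(p2) + spherical_phase(p3)`.
#'
#' @param coeffs A [basis_coefficients()].
#' @param grid An [pupil_grid()].
#' @return Phase map in radians (not wrapped).
#' @export
compose_phase <- function(coeffs, grid) {
  stopifnot(inherits(coeffs, "edof_coeffs"), inherits(grid, "edof_grid"))
  axicon_phase(grid, coeffs$axicon) +
    defocus_phase(grid, coeffs$defocus_um) +
    spherical_phase(grid, coeffs$spherical_waves)
}

#' Wrap and binarize a continuous phase to a 0/pi mask
#'
#' The continuous phase is wrapped into `[0, 2*pi)` and thresholded at `pi`
#' with the half-open rule: wrapped values in `[0, pi)` map to 0, values in
#' `[pi, 2*pi)` map to `pi`. The rule is deterministic and idempotent
#' (`binarize_phase` of a mask's phase returns the mask).
#'
#' @param phase Numeric matrix of phase values (radians); must be finite.
#' @param coeffs Optional [basis_coefficients()] recorded as provenance.
#' @return An object of class `edof_mask`: list with `phase` (matrix of 0 and
#'   `pi`) and `coeffs`.
#' @export
binarize_phase <- function(phase, coeffs = NULL) {
  if (!is.matrix(phase) || !is.numeric(phase)) {
    abort("`phase` must be a numeric matrix.")
  }
  if (any(!is.finite(phase))) abort("`phase` must be finite everywhere.")
  wrapped <- phase %% (2 * pi)
  structure(
    list(phase = ifelse(wrapped >= pi, pi, 0), coeffs = coeffs),
    class = "edof_mask"
  )
}

#' @export
print.edof_mask <- function(x, ...) {
  cat(sprintf("<edof_mask> %d x %d, %.1f%% of samples at pi\n",
              nrow(x$phase), ncol(x$phase), 100 * mean(x$phase > 0)))
  if (!is.null(x$coeffs)) print(x$coeffs)
  invisible(x)
}

#' Complex pupil transmission of a binary mask
#'
#' `exp(1i * phase)` of a 0/pi mask: exactly +1 where the phase is 0 and -1
#' where it is pi. Returned as a real matrix of +/-1 (the field is purely
#' real); phase-only, so pupil-plane energy is unchanged.
#'
#' @param mask An [binarize_phase()] result.
#' @return Numeric matrix of +1 / -1.
#' @export
mask_transmission <- function(mask) {
  stopifnot(inherits(mask, "edof_mask"))
  ifelse(mask$phase >= pi, -1, 1)
}

#' Conjugate-phase field of a single diffraction order
#'
#' A binary 0/pi mask splits the transmitted field into diffraction orders;
#' the +1st and -1st orders carry conjugate versions of the underlying
#' continuous phase. `order_field()` returns `exp(1i * order * phase)` for
#' the composed continuous phase of `coeffs`, which isolates one focus of the
#' twin-foci design for analysis. The shared native GRIN aberration is *not*
#' included here; the forward model applies it to every order identically.
#'
#' @param coeffs A [basis_coefficients()].
#' @param order `+1` or `-1`.
#' @param grid An [pupil_grid()].
#' @return Complex matrix of unit modulus.
#' @export
order_field <- function(coeffs, order, grid) {
  if (!is.numeric(order) || length(order) != 1L || !(order %in% c(-1, 1))) {
    abort("`order` must be +1 or -1.")
  }
  exp(1i * order * compose_phase(coeffs, grid))
}

#' Radial ring boundaries of a rotationally symmetric binary mask
#'
#' Evaluates the mask's generating continuous phase on a dense 1-D radial
#' axis and reports the radii where the binarized value flips, i.e. the ring
#' boundaries a fabricated DOE would need to etch. Radii are reported both as
#' normalized pupil radius and in um on the physical pupil.
#'
#' @param coeffs A [basis_coefficients()].
#' @param grid An [pupil_grid()].
#' @param pupil_diameter_um Physical diameter of the pupil (clear aperture)
#'   in um; defaults to 1800 um, a GRIN-lens scale clear aperture. Only used
#'   to scale the reported radii.
#' @param n_samples Radial oversampling (default 20000).
#' @return A tibble with columns `ring_index`, `rho_inner`, `rho_outer`,
#'   `r_inner_um`, `r_outer_um`; one row per pi-valued ring.
#' @export
mask_ring_table <- function(coeffs, grid, pupil_diameter_um = 1800,
                            n_samples = 20000L) {
  stopifnot(inherits(coeffs, "edof_coeffs"), inherits(grid, "edof_grid"))
  cfg <- grid$config
  f <- seq(0, grid$cutoff_cpum, length.out = n_samples)
  rho <- f / grid$cutoff_cpum
  arg <- pmax(1 - (cfg$wavelength_um * f / cfg$n_medium)^2, 0)
  phase <- pi * coeffs$axicon * f +
    2 * pi * cfg$n_medium / cfg$wavelength_um * coeffs$defocus_um * sqrt(arg) +
    2 * pi * coeffs$spherical_waves * rho^4
  b <- (phase %% (2 * pi)) >= pi
  flips <- which(diff(b) != 0L)
  if (!length(flips)) {
    return(tibble(ring_index = integer(), rho_inner = numeric(),
                  rho_outer = numeric(), r_inner_um = numeric(),
                  r_outer_um = numeric()))
  }
  # boundaries bracket maximal runs of TRUE (pi-valued rings)
  starts <- flips[!b[flips]] + 1L
  ends <- flips[b[flips]]
  if (b[1]) starts <- c(1L, starts)
  if (b[length(b)]) ends <- c(ends, length(b))
  scale <- pupil_diameter_um / 2
  tibble(
    ring_index = seq_along(starts),
    rho_inner = rho[starts],
    rho_outer = rho[ends],
    r_inner_um = rho[starts] * scale,
    r_outer_um = rho[ends] * scale
  )
}

#' Export / import a binary mask
#'
#' Writes the 0/pi pattern as a lossless 1-bit-content PNG (pi rings white)
#' and, when the mask carries its generating coefficients, a CSV of radial
#' ring boundaries. `import_mask()` reads the PNG back to an `edof_mask`.
#'
#' @param mask An `edof_mask`.
#' @param path Output PNG path; the ring CSV (if written) replaces the
#'   extension with `_rings.csv`.
#' @param grid Optional [pupil_grid()]; required for the ring table.
#' @param pupil_diameter_um Physical pupil diameter for the ring table.
#' @return The PNG path, invisibly.
#' @export
export_mask <- function(mask, path, grid = NULL, pupil_diameter_um = 1800) {
  stopifnot(inherits(mask, "edof_mask"))
  png::writePNG(ifelse(mask$phase >= pi, 1, 0), path)
  if (!is.null(mask$coeffs) && !is.null(grid)) {
    rings <- mask_ring_table(mask$coeffs, grid, pupil_diameter_um)
    utils::write.csv(rings, sub("\\.png$", "_rings.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_mask
#' @export
import_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  binarize_phase(ifelse(img > 0.5, pi, 0))
}
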