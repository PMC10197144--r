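#' On-axis source object
#'
#' A proxy neuron: a centered uniform disk of the given diameter on the
#' object-space pixel lattice (`diameter_um = 0` gives a single-pixel
#' impulse). The amplitude map is normalized to unit total energy
#' (`sum(amplitude^2) == 1`).
#'
#' @param diameter_um Source diameter in um (>= 0); 5 um is the design's
#'   proxy-neuron size.
#' @param grid An [pupil_grid()] (fixes lattice size and pixel pitch).
#' @return An object of class `edof_source`: list with `amplitude` (matrix),
#'   `diameter_um`, `pixel_um`.
#' @export
make_source <- function(diameter_um, grid) {
  stopifnot(inherits(grid, "edof_grid"))
  stopifnot_scalar(diameter_um, "diameter_um")
  if (diameter_um < 0) abort("`diameter_um` must be >= 0.")
  n <- grid$config$grid_size
  dx <- grid$config$pixel_um
  if (diameter_um >= n * dx) {
    abort("Source diameter exceeds the simulated field of view.")
  }
  amp <- matrix(0, n, n)
  if (diameter_um == 0) {
    amp[n %/% 2 + 1, n %/% 2 + 1] <- 1
  } else {
    x <- centered_axis(n, dx)
    r2 <- outer(x^2, x^2, "+")
    amp[r2 <= (diameter_um / 2)^2] <- 1
  }
  amp <- amp / sqrt(sum(amp^2))
  structure(list(amplitude = amp, diameter_um = diameter_um, pixel_um = dx),
            class = "edof_source")
}

# Prepared pupil field: centered source spectrum x mask transmission x
# native-aberration phasor x aperture support. The slice loop multiplies in
# the per-depth defocus phasor and inverse-transforms.
prepare_pupil <- function(source, pupil_field, aberration, grid) {
  n <- grid$config$grid_size
  stopifnot(inherits(source, "edof_source"))
  if (!all(dim(source$amplitude) == n)) abort("source/grid size mismatch")
  S <- fftshift2(ft2(source$amplitude))
  M <- if (is.null(pupil_field)) {
    1
  } else if (inherits(pupil_field, "edof_mask")) {
    mask_transmission(pupil_field)
  } else if (is.matrix(pupil_field)) {
    pupil_field
  } else {
    abort("`pupil_field` must be NULL, an edof_mask or a matrix.")
  }
  A <- if (is.null(aberration)) {
    1
  } else if (inherits(aberration, "edof_aberration")) {
    exp(1i * grin_aberration(aberration, grid))
  } else if (is.matrix(aberration)) {
    exp(1i * aberration)
  } else {
    abort("`aberration` must be NULL, an aberration model or a phase matrix.")
  }
  if (is.matrix(M) && !all(dim(M) == n)) abort("pupil_field/grid size mismatch")
  if (is.matrix(A) && !all(dim(A) == n)) abort("aberration/grid size mismatch")
  S * M * A * grid$aperture
}

# Pupil field plus (for incoherent finite sources) the transform of the
# object's intensity pattern. A point source needs no convolution; the two
# model readings coincide there.
incoherent_inputs <- function(source, pupil_field, aberration, grid,
                              coherent) {
  stopifnot(inherits(source, "edof_source"))
  no_otf <- matrix(complex(real = numeric(0)), 0, 0)
  if (coherent || source$diameter_um == 0) {
    return(list(P = prepare_pupil(source, pupil_field, aberration, grid),
                OTF = no_otf))
  }
  impulse <- make_source(0, grid)
  obj <- source$amplitude^2
  obj <- obj / sum(obj)
  list(
    P = prepare_pupil(impulse, pupil_field, aberration, grid),
    OTF = stats::fft(ifftshift2(obj))
  )
}

#' Slice-wise forward model of the masked, aberrated miniscope
#'
#' For every depth `z` a point impulse's spectrum is multiplied by the pupil
#' mask transmission, the native-aberration phasor and the angular-spectrum
#' defocus phasor at `z`, inverse-transformed and squared to the intensity
#' point-spread function; fluorescence being incoherent, the finite source
#' then enters as a convolution of each intensity slice with the object's
#' intensity pattern (the default, `coherent = FALSE`). With
#' `coherent = TRUE` the source amplitude is placed inside the field
#' transform instead (coherent imaging of the object); the two coincide for
#' a point source. A scattering decay `exp(-(z - min(z)) / ls)` finally
#' scales each slice (depth measured from the shallowest simulated plane).
#' The model is linear shift invariant; transforms are orthonormal so that,
#' decay-free and with a unit-modulus pupil over the full support, per-slice
#' energy is conserved.
#'
#' @param source An [make_source()].
#' @param pupil_field Pupil transmission: an `edof_mask`, a numeric/complex
#'   matrix (e.g. an [order_field()]), or `NULL` for an open pupil.
#' @param aberration Native aberration: an [aberration_model()], a phase
#'   matrix in radians, or `NULL` for none.
#' @param depths_um Numeric vector of slice positions (um, strictly
#'   increasing, uniform step).
#' @param ls_um Scattering length in um; `Inf` disables the decay.
#' @param grid An [pupil_grid()].
#' @param keep_stack Keep the full 3-D intensity cube (memory heavy for large
#'   grids); with `FALSE` only per-slice summaries (axial profile, xz MIP,
#'   slice energies) are retained.
#' @param coherent Place the source amplitude inside the field transform
#'   instead of convolving intensities (default `FALSE`; see Details).
#' @return An `edof_stack`: list with `data` (x, y, z array or `NULL`),
#'   `xz_mip` (x-by-z matrix), `profile` (per-slice maximum), `energy`,
#'   `z_um`, `ls_um`, `decay_applied`, `pixel_um`.
#' @export
simulate_stack <- function(source, pupil_field = NULL, aberration = NULL,
                           depths_um, ls_um = Inf, grid, keep_stack = TRUE,
                           coherent = FALSE) {
  stopifnot(inherits(grid, "edof_grid"))
  if (length(depths_um) < 1L || is.unsorted(depths_um, strictly = TRUE)) {
    abort("`depths_um` must be strictly increasing.")
  }
  if (length(depths_um) > 2L) {
    steps <- diff(depths_um)
    if (max(abs(steps - steps[1])) > 1e-9 * max(abs(steps))) {
      abort("`depths_um` must be uniformly spaced.")
    }
  }
  if (!is.infinite(ls_um) && (!is.finite(ls_um) || ls_um <= 0)) {
    abort("`ls_um` must be positive (or Inf to disable decay).")
  }
  io <- incoherent_inputs(source, pupil_field, aberration, grid, coherent)
  K <- defocus_rate(grid)
  res <- cpp_propagate(io$P, K, as.numeric(depths_um), ls_um, keep_stack,
                       io$OTF)
  structure(
    list(
      data = if (keep_stack) res$stack else NULL,
      xz_mip = res$xz_mip,
      profile = as.numeric(res$profile),
      energy = as.numeric(res$energy),
      z_um = as.numeric(depths_um),
      ls_um = ls_um,
      decay_applied = is.finite(ls_um),
      pixel_um = grid$config$pixel_um
    ),
    class = "edof_stack"
  )
}

#' @export
print.edof_stack <- function(x, ...) {
  cat(sprintf(
    "<edof_stack> %s, %d depths [%g, %g] um, ls = %s um%s\n",
    if (is.null(x$data)) "profile-only" else
      paste(dim(x$data)[1:2], collapse = " x "),
    length(x$z_um), min(x$z_um), max(x$z_um),
    if (is.finite(x$ls_um)) format(x$ls_um) else "Inf",
    if (x$decay_applied) " (decay applied)" else ""
  ))
  invisible(x)
}

#' Per-slice maximum intensity along z
#'
#' The on-axis signal proxy used by the fitness function: the maximum
#' intensity of each slice as a function of depth.
#'
#' @param stack An [simulate_stack()] result.
#' @return A tibble with columns `z_um`, `intensity`.
#' @export
on_axis_profile <- function(stack) {
  stopifnot(inherits(stack, "edof_stack"))
  tibble(z_um = stack$z_um, intensity = stack$profile)
}

#' Construct an intensity stack from a plain array
#'
#' Wraps an existing non-negative 3-D array (e.g. read from disk or built
#' synthetically in tests) as an `edof_stack` so the characterization
#' operators apply to it.
#'
#' @param data Non-negative numeric array, dims (x, y, z).
#' @param z_um Slice positions, one per z plane, strictly increasing.
#' @param ls_um Scattering length the data embodies (`Inf` if none).
#' @param decay_applied Whether the decay factor is already in `data`.
#' @param pixel_um Lateral pixel size in um.
#' @return An `edof_stack`.
#' @export
as_stack <- function(data, z_um, ls_um = Inf, decay_applied = FALSE,
                     pixel_um = 0.375) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (x, y, z).")
  }
  if (length(z_um) != dim(data)[3]) abort("`z_um` length must match dim 3.")
  if (is.unsorted(z_um, strictly = TRUE)) abort("`z_um` must be increasing.")
  if (any(data < 0)) abort("intensities must be non-negative.")
  structure(
    list(
      data = data,
      xz_mip = apply(data, c(1, 3), max),
      profile = apply(data, 3, max),
      energy = apply(data, 3, sum),
      z_um = as.numeric(z_um),
      ls_um = ls_um,
      decay_applied = decay_applied,
      pixel_um = pixel_um
    ),
    class = "edof_stack"
  )
}
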