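#' Optical configuration of the miniscope simulation
#'
#' Collects the physical and sampling parameters of the Fourier-optics model:
#' the GRIN objective's numerical aperture, the system magnification and
#' sensor pixel (which together set the object-space pixel), the emission
#' wavelength, the immersion/tissue refractive index, and the pupil-plane and
#' axial sampling. Defaults are the published miniscope design values; the
#' wavelength defaults to 0.515 um (GFP emission, inside the 535/50 emission
#' band) and is freely configurable.
#'
#' @param na Numerical aperture of the objective (dimensionless). Must be
#'   strictly less than `n_medium`.
#' @param magnification System magnification (sensor plane / object plane).
#' @param sensor_pixel_um Sensor pixel pitch in um. The object-space pixel is
#'   `sensor_pixel_um / magnification` (0.375 um for the defaults).
#' @param wavelength_um Emission wavelength in um.
#' @param n_medium Refractive index of the object medium (tissue ~ 1.33).
#' @param grid_size Number of samples per side of the pupil lattice (>= 32).
#' @param depth_step_um Axial sampling step in um.
#' @param n_depths Number of simulated depth planes.
#' @param working_distance_um Nominal working distance in um (informational).
#'
#' @return An object of class `edof_config` (a named list).
#' @examples
#' cfg <- optical_config(grid_size = 256)
#' cfg$pixel_um
#' @export
optical_config <- function(na = 0.55,
                           magnification = 9.2,
                           sensor_pixel_um = 3.45,
                           wavelength_um = 0.515,
                           n_medium = 1.33,
                           grid_size = 1000L,
                           depth_step_um = 1,
                           n_depths = 100L,
                           working_distance_um = 230) {
  stopifnot_scalar(na, "na", positive = TRUE)
  stopifnot_scalar(magnification, "magnification", positive = TRUE)
  stopifnot_scalar(sensor_pixel_um, "sensor_pixel_um", positive = TRUE)
  stopifnot_scalar(wavelength_um, "wavelength_um", positive = TRUE)
  stopifnot_scalar(n_medium, "n_medium", positive = TRUE)
  stopifnot_scalar(depth_step_um, "depth_step_um", positive = TRUE)
  grid_size <- as.integer(grid_size)
  n_depths <- as.integer(n_depths)
  if (grid_size < 32L) abort("`grid_size` must be >= 32 (undersampled pupil).")
  if (n_depths < 1L) abort("`n_depths` must be >= 1.")
  if (na >= n_medium) {
    abort("`na` must be < `n_medium` (non-physical aperture).")
  }
  structure(
    list(
      na = na,
      magnification = magnification,
      sensor_pixel_um = sensor_pixel_um,
      wavelength_um = wavelength_um,
      n_medium = n_medium,
      grid_size = grid_size,
      depth_step_um = depth_step_um,
      n_depths = n_depths,
      working_distance_um = working_distance_um,
      pixel_um = sensor_pixel_um / magnification
    ),
    class = "edof_config"
  )
}

#' @export
print.edof_config <- function(x, ...) {
  cat("<edof_config>\n")
  cat(sprintf("  NA %.3g in n = %.4g, lambda = %.4g um\n",
              x$na, x$n_medium, x$wavelength_um))
  cat(sprintf("  magnification %.3g, sensor pixel %.4g um (object pixel %.4g um)\n",
              x$magnification, x$sensor_pixel_um, x$pixel_um))
  cat(sprintf("  pupil grid %d x %d, %d depth planes, step %.3g um\n",
              x$grid_size, x$grid_size, x$n_depths, x$depth_step_um))
  invisible(x)
}

#' Discrete pupil-plane coordinate system
#'
#' Builds the spatial-frequency lattice conjugate to the object-space pixel
#' lattice: `u`, `v` in cycles/um with zero frequency at index
#' `grid_size %/% 2 + 1`, the NA-normalized pupil radius
#' `rho = (lambda / NA) * sqrt(u^2 + v^2)` (1 exactly on the NA cutoff
#' circle), and the boolean aperture support `rho <= 1`.
#'
#' @param config An [optical_config()].
#' @return An object of class `edof_grid`: list with `u`, `v` (vectors),
#'   `rho`, `aperture` (matrices), `cutoff_cpum`, and the originating config.
#' @examples
#' g <- pupil_grid(optical_config(grid_size = 64))
#' g$cutoff_cpum            # NA / lambda
#' g$rho[33, 33]            # zero at the DC sample
#' @export
pupil_grid <- function(config) {
  stopifnot(inherits(config, "edof_config"))
  n <- config$grid_size
  df <- 1 / (n * config$pixel_um)
  u <- centered_axis(n, df)
  f2 <- outer(u^2, u^2, "+")
  cutoff <- config$na / config$wavelength_um
  if (max(u) < cutoff) {
    abort(paste0(
      "Pupil lattice does not reach the NA cutoff (", signif(cutoff, 5),
      " cycles/um); decrease the object pixel or increase `grid_size`."
    ))
  }
  rho <- sqrt(f2) / cutoff
  structure(
    list(
      u = u, v = u,
      rho = rho,
      aperture = rho <= 1,
      cutoff_cpum = cutoff,
      config = config
    ),
    class = "edof_grid"
  )
}

#' @export
print.edof_grid <- function(x, ...) {
  cat("<edof_grid>\n")
  cat(sprintf("  %d x %d, df = %.5g cycles/um, NA cutoff %.5g cycles/um\n",
              length(x$u), length(x$v), x$u[2] - x$u[1], x$cutoff_cpum))
  cat(sprintf("  aperture fraction %.3g\n", mean(x$aperture)))
  invisible(x)
}

#' Serialize / restore an optical configuration as YAML
#'
#' @param config An [optical_config()].
#' @param path File to write; with `NULL`, the YAML string is returned.
#' @return `config_to_yaml()` returns the path (or YAML string) invisibly;
#'   `config_from_yaml()` returns an [optical_config()].
#' @export
config_to_yaml <- function(config, path = NULL) {
  stopifnot(inherits(config, "edof_config"))
  keep <- c("na", "magnification", "sensor_pixel_um", "wavelength_um",
            "n_medium", "grid_size", "depth_step_um", "n_depths",
            "working_distance_um")
  txt <- yaml::as.yaml(config[keep])
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @param x Path to a YAML file or a YAML string.
#' @export
config_from_yaml <- function(x) {
  vals <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  known <- names(formals(optical_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    abort(paste0("Unknown optics keys: ", paste(extra, collapse = ", ")))
  }
  do.call(optical_config, vals)
}
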