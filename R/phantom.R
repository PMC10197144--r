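#' Mie scattering mean free path
#'
#' Geometric-optics scattering length of a suspension of spherical
#' scatterers: `ls = 2 d / (3 Phi Qs)` with `d` the mean scatterer diameter,
#' `Phi` the volume fraction and `Qs` the Mie scattering efficiency.
#'
#' @param d_um Mean scatterer diameter in um.
#' @param phi Volume fraction of scatterers (0 < phi < 1).
#' @param qs Scattering efficiency (see [mie_qs()]).
#' @return Scattering length in um.
#' @examples
#' scattering_length(1.1, 0.027 / 1.27, 0.292)
#' @export
scattering_length <- function(d_um, phi, qs) {
  stopifnot_scalar(d_um, "d_um", positive = TRUE)
  stopifnot_scalar(phi, "phi", positive = TRUE)
  stopifnot_scalar(qs, "qs", positive = TRUE)
  if (phi >= 1) abort("`phi` must be < 1.")
  2 * d_um / (3 * phi * qs)
}

#' Lorenz-Mie scattering efficiency of a homogeneous sphere
#'
#' Standard Lorenz-Mie series for a non-absorbing sphere in a host medium:
#' the size parameter uses the in-medium wavelength
#' (`x = pi d n_medium / lambda_vacuum`) and the relative index is
#' `m = n_particle / n_medium`. Riccati-Bessel functions are generated by
#' upward recurrence and the logarithmic derivative by downward recurrence
#' (the usual numerically stable combination);
#' `Qs = (2 / x^2) * sum (2n + 1) (|a_n|^2 + |b_n|^2)`.
#'
#' @param d_um Sphere diameter in um.
#' @param n_particle Refractive index of the sphere (e.g. polystyrene
#'   1.5979).
#' @param n_medium Refractive index of the host (e.g. cured resin 1.5403).
#' @param wavelength_um Vacuum wavelength in um (default 0.515).
#' @return The scattering efficiency `Qs` (dimensionless).
#' @examples
#' mie_qs(1.1, 1.5979, 1.5403, 0.515)
#' @export
mie_qs <- function(d_um, n_particle, n_medium, wavelength_um = 0.515) {
  stopifnot_scalar(d_um, "d_um", positive = TRUE)
  stopifnot_scalar(n_particle, "n_particle", positive = TRUE)
  stopifnot_scalar(n_medium, "n_medium", positive = TRUE)
  stopifnot_scalar(wavelength_um, "wavelength_um", positive = TRUE)
  x <- pi * d_um * n_medium / wavelength_um
  m <- n_particle / n_medium
  mie_qs_xm(m, x)
}

# Core series in terms of relative index m and size parameter x.
mie_qs_xm <- function(m, x) {
  if (x <= 0) abort("size parameter must be positive.")
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  # logarithmic derivative D_n(mx) by downward recurrence
  nstart <- max(nmax + 15L, ceiling(abs(m * x)) + 15L)
  D <- numeric(nstart + 1L)
  mx <- m * x
  for (n in nstart:1) {
    # D_{n-1}(mx) from D_n(mx); D[k] holds D_k with D_{nstart} = 0
    D[n] <- (n + 1) / mx - 1 / (D[n + 1L] + (n + 1) / mx)
  }
  # Riccati-Bessel psi, chi by upward recurrence (stable for these orders)
  psi <- numeric(nmax + 1L); chi <- numeric(nmax + 1L)
  psi0 <- cos(x); chi0 <- -sin(x) # order -1
  psi[1] <- sin(x); chi[1] <- cos(x) # order 0
  for (n in 1:nmax) {
    psi[n + 1L] <- (2 * n - 1) / x * psi[n] - (if (n == 1L) psi0 else psi[n - 1L])
    chi[n + 1L] <- (2 * n - 1) / x * chi[n] - (if (n == 1L) chi0 else chi[n - 1L])
  }
  qs <- 0
  for (n in 1:nmax) {
    psi_n <- psi[n + 1L]; psi_nm1 <- psi[n]
    chi_n <- chi[n + 1L]; chi_nm1 <- chi[n]
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a_n <- (da * psi_n - psi_nm1) / (da * xi_n - xi_nm1)
    b_n <- (db * psi_n - psi_nm1) / (db * xi_n - xi_nm1)
    qs <- qs + (2 * n + 1) * (Mod(a_n)^2 + Mod(b_n)^2)
  }
  if (!is.finite(qs)) abort("Mie series failed to converge.")
  2 / x^2 * qs
}

#' Contact-printing lithography resolution
#'
#' Smallest printable feature of proximity/contact photolithography,
#' `d = k * sqrt(lambda * h)` with `k ~ 2` for photolithography, `lambda`
#' the exposure wavelength and `h` the mask-resist separation.
#'
#' @param wavelength_um Exposure wavelength in um (e.g. 0.365 for i-line).
#' @param gap_um Separation (gap plus resist thickness) in um.
#' @param k Process constant (default 2).
#' @return Feature size in um.
#' @examples
#' contact_print_resolution(0.365, 50) # ~8.5 um
#' @export
contact_print_resolution <- function(wavelength_um, gap_um, k = 2) {
  stopifnot_scalar(wavelength_um, "wavelength_um", positive = TRUE)
  stopifnot_scalar(gap_um, "gap_um", positive = TRUE)
  stopifnot_scalar(k, "k")
  if (k < 0) abort("`k` must be >= 0.")
  k * sqrt(wavelength_um * gap_um)
}

#' Synthetic bead-phantom specification
#'
#' Parameters of the synthetic fluorescent-bead phantom emulating the
#' resin-embedded scattering samples: bead size and density, lateral and
#' axial extent, scattering length, background pedestal and noise model.
#' Defaults mirror the characterization phantom: 5-um beads at about
#' 2120 particles/mm^3 in a medium with a 100-um scattering length.
#'
#' @param bead_diameter_um Bead diameter in um.
#' @param density_per_mm3 Expected bead density (particles/mm^3).
#' @param fov_um Lateral extent of the simulated volume in um.
#' @param depth_range_um Length-2 axial interval in um.
#' @param ls_um Scattering length of the medium in um.
#' @param background_level Background pedestal as a fraction of the rendered
#'   peak signal.
#' @param noise One of `"none"` or `"poisson_gaussian"` (photon shot noise
#'   plus additive read noise).
#' @param read_noise_frac Read-noise sigma as a fraction of the rendered
#'   peak (used by `"poisson_gaussian"`).
#' @param peak_photons Expected photon count at the rendered peak (sets the
#'   shot-noise scale).
#' @param seed Integer seed recorded in the output and used for placement
#'   and noise.
#' @return An object of class `edof_phantom_spec`.
#' @export
phantom_spec <- function(bead_diameter_um = 5, density_per_mm3 = 2120,
                         fov_um = 600, depth_range_um = c(0, 100),
                         ls_um = 100, background_level = 0.1,
                         noise = c("none", "poisson_gaussian"),
                         read_noise_frac = 0.01, peak_photons = 5000,
                         seed = 1L) {
  noise <- match.arg(noise)
  stopifnot_scalar(bead_diameter_um, "bead_diameter_um", positive = TRUE)
  stopifnot_scalar(density_per_mm3, "density_per_mm3")
  if (density_per_mm3 < 0) abort("`density_per_mm3` must be >= 0.")
  stopifnot_scalar(fov_um, "fov_um", positive = TRUE)
  if (length(depth_range_um) != 2L || depth_range_um[2] <= depth_range_um[1]) {
    abort("`depth_range_um` must be an increasing length-2 interval.")
  }
  structure(
    list(bead_diameter_um = bead_diameter_um,
         density_per_mm3 = density_per_mm3, fov_um = fov_um,
         depth_range_um = as.numeric(depth_range_um), ls_um = ls_um,
         background_level = background_level, noise = noise,
         read_noise_frac = read_noise_frac, peak_photons = peak_photons,
         seed = as.integer(seed)),
    class = "edof_phantom_spec"
  )
}

#' Generate a labeled synthetic bead volume
#'
#' Draws a Poisson number of bead centers (expectation = density x volume)
#' uniformly in the slab, renders each as a solid sphere of the specified
#' diameter on the object-space lattice, and returns both the volume and the
#' ground-truth bead table. Fully reproducible from the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param pixel_um Lateral pixel size in um.
#' @param depth_step_um Axial step in um.
#' @return A list with `volume` (x, y, z array of 0/1 amplitudes), `beads`
#'   (tibble: bead, x_um, y_um, z_um, diameter_um), `z_um`, `pixel_um`,
#'   `seed`.
#' @export
generate_bead_volume <- function(spec, pixel_um = 0.375, depth_step_um = 1) {
  stopifnot(inherits(spec, "edof_phantom_spec"))
  nxy <- max(8L, round(spec$fov_um / pixel_um))
  z_um <- seq(spec$depth_range_um[1], spec$depth_range_um[2],
              by = depth_step_um)
  nz <- length(z_um)
  depth_um <- diff(spec$depth_range_um)
  vol_mm3 <- (spec$fov_um / 1000)^2 * (depth_um / 1000)
  bead_vol <- 4 / 3 * pi * (spec$bead_diameter_um / 2)^3
  if (spec$density_per_mm3 * bead_vol / 1e9 > 0.5) {
    abort("bead density implies > 50% volume occupancy.")
  }
  withr::with_seed(spec$seed, {
    n <- rpois(1, spec$density_per_mm3 * vol_mm3)
    beads <- tibble(
      bead = seq_len(n),
      x_um = runif(n, -spec$fov_um / 2, spec$fov_um / 2),
      y_um = runif(n, -spec$fov_um / 2, spec$fov_um / 2),
      z_um = runif(n, spec$depth_range_um[1], spec$depth_range_um[2]),
      diameter_um = spec$bead_diameter_um
    )
  })
  volume <- array(0, dim = c(nxy, nxy, nz))
  xs <- centered_axis(nxy, pixel_um)
  r <- spec$bead_diameter_um / 2
  for (i in seq_len(nrow(beads))) {
    zi <- which(abs(z_um - beads$z_um[i]) <= r)
    if (!length(zi)) zi <- which.min(abs(z_um - beads$z_um[i]))
    xi <- which(abs(xs - beads$x_um[i]) <= r)
    yi <- which(abs(xs - beads$y_um[i]) <= r)
    if (!length(xi) || !length(yi)) next
    for (zz in zi) {
      rz2 <- r^2 - (z_um[zz] - beads$z_um[i])^2
      if (rz2 < 0) next
      d2 <- outer((xs[xi] - beads$x_um[i])^2, (xs[yi] - beads$y_um[i])^2, "+")
      sl <- volume[xi, yi, zz]
      sl[d2 <= rz2] <- 1
      volume[xi, yi, zz] <- sl
    }
  }
  list(volume = volume, beads = beads, z_um = z_um, pixel_um = pixel_um,
       seed = spec$seed)
}

#' Render a single 2-D measurement of a bead volume
#'
#' The 2D-to-2D image formation: every z slice of the volume is convolved
#' with the PSF slice at that depth (scattering decay included via the PSF
#' stack) and the results are summed over depth; a background pedestal and
#' optional shot/read noise are then added per the spec. Convolutions are
#' circular FFT products on the shared lattice.
#'
#' The background pedestal, shot noise and read noise are expressed in
#' photons: by default the rendered peak maps to `spec$peak_photons`, the
#' pedestal is `background_level * peak_photons` and the read-noise sigma is
#' `read_noise_frac * peak_photons`. When comparing two optical
#' configurations imaging the same scene (e.g. masked versus open pupil),
#' pass the same `photon_scale` to both so they share one photon budget and
#' one camera noise floor instead of each being normalized to its own peak.
#'
#' @param bead_volume A [generate_bead_volume()] result.
#' @param psf_stack An `edof_stack` on the same lateral lattice whose `z_um`
#'   covers the volume's planes.
#' @param spec The [phantom_spec()] (for background and noise).
#' @param photon_scale Photons per unit of rendered intensity; `NULL` maps
#'   this image's own peak to `spec$peak_photons`.
#' @return A list with `image` (measurement in photons), `clean` (pre-noise,
#'   pre-pedestal signal in rendered-intensity units), `photon_scale`,
#'   `spec`.
#' @export
render_measurement <- function(bead_volume, psf_stack, spec,
                               photon_scale = NULL) {
  stopifnot(inherits(psf_stack, "edof_stack"),
            inherits(spec, "edof_phantom_spec"))
  if (is.null(psf_stack$data)) abort("PSF stack must keep its full cube.")
  nxy <- dim(bead_volume$volume)[1]
  if (!all(dim(psf_stack$data)[1:2] == nxy)) {
    abort("volume and PSF stack must share the lateral lattice.")
  }
  zmap <- match(round(bead_volume$z_um, 9), round(psf_stack$z_um, 9))
  if (anyNA(zmap)) abort("PSF stack does not cover the volume's z planes.")
  img <- matrix(0, nxy, nxy)
  for (k in seq_along(zmap)) {
    slice <- bead_volume$volume[, , k]
    if (!any(slice != 0)) next
    psf <- psf_stack$data[, , zmap[k]]
    img <- img + Re(stats::fft(stats::fft(slice) * stats::fft(ifftshift2(psf)),
                               inverse = TRUE)) / length(slice)
  }
  img[img < 0] <- 0
  clean <- img
  if (is.null(photon_scale)) {
    photon_scale <- if (max(img) > 0) spec$peak_photons / max(img) else 1
  }
  img <- img * photon_scale + spec$background_level * spec$peak_photons
  if (spec$noise == "poisson_gaussian") {
    withr::with_seed(spec$seed + 1L, {
      img <- rpois(length(img), lambda = as.numeric(img))
      img <- img + rnorm(length(img),
                         sd = spec$read_noise_frac * spec$peak_photons)
    })
    img <- matrix(pmax(img, 0), nxy, nxy)
  }
  list(image = img, clean = clean, photon_scale = photon_scale, spec = spec)
}
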