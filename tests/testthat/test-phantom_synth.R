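test_that("scattering length follows the 2d/(3 phi Qs) closure identity", {
  expect_equal(scattering_length(1.1, 0.02126, 0.2922) * 3 * 0.02126 * 0.2922 /
                 (2 * 1.1), 1, tolerance = 1e-12)
  # inverse proportionality in phi
  expect_equal(scattering_length(1.1, 0.04, 0.3),
               scattering_length(1.1, 0.02, 0.3) / 2, tolerance = 1e-12)
  # the published recipe: 0.27 mL of 10%-by-volume suspension per mL resin
  phi <- 0.027 / 1.27
  expect_equal(phi, 0.02126, tolerance = 1e-3)
  # with ls pinned at 100 um the implied efficiency
  qs_implied <- 2 * 1.1 / (3 * phi * 100)
  expect_equal(qs_implied, 0.345, tolerance = 0.01)
  expect_error(scattering_length(1.1, 1.2, 0.3), "phi")
  expect_error(scattering_length(-1, 0.1, 0.3), "d_um")
})

test_that("Mie efficiency reproduces reference values and behaves physically", {
  # canonical table case m = 1.5, x = 10 (frozen from an independent
  # Riccati-Bessel evaluation): Qsca = 2.882
  expect_equal(mie_qs(10 / pi, 1.5, 1, 1), 2.881999, tolerance = 1e-4)
  # the phantom's polystyrene-in-resin case at 0.515 um (frozen oracle)
  expect_equal(mie_qs(1.1, 1.5979, 1.5403, 0.515), 0.292202,
               tolerance = 1e-4)
  # index matching kills scattering
  expect_lt(mie_qs(1.1, 1.5403 + 1e-6, 1.5403, 0.515), 1e-8)
  # Rayleigh limit: (8/3) x^4 ((m^2-1)/(m^2+2))^2
  m <- 1.5; x <- 0.01
  expect_equal(mie_qs(x / pi, m, 1, 1) /
                 ((8 / 3) * x^4 * ((m^2 - 1) / (m^2 + 2))^2),
               1, tolerance = 1e-3)
  # smooth across the emission band: no resonant jumps > 20%
  qs <- vapply(seq(0.515, 0.535, 0.002), function(l) {
    mie_qs(1.1, 1.5979, 1.5403, l)
  }, numeric(1))
  expect_true(all(abs(diff(qs)) / qs[-length(qs)] < 0.2))
})

test_that("contact-printing resolution follows the square-root law", {
  expect_equal(contact_print_resolution(0.365, 50, 2), 2 * sqrt(18.25),
               tolerance = 1e-12)
  expect_equal(contact_print_resolution(0.365, 200, 2),
               2 * contact_print_resolution(0.365, 50, 2), tolerance = 1e-12)
  expect_equal(contact_print_resolution(0.365, 50, 0), 0)
  expect_error(contact_print_resolution(-0.365, 50), "wavelength_um")
})

test_that("bead volumes are seeded, Poisson-distributed and correctly rendered", {
  spec <- phantom_spec(bead_diameter_um = 5, density_per_mm3 = 0,
                       fov_um = 30, depth_range_um = c(0, 20), seed = 1)
  v0 <- generate_bead_volume(spec, pixel_um = 1, depth_step_um = 2)
  expect_identical(nrow(v0$beads), 0L)
  expect_equal(sum(v0$volume), 0)
  # same seed, same volume
  spec2 <- phantom_spec(bead_diameter_um = 3, density_per_mm3 = 2e5,
                        fov_um = 40, depth_range_um = c(0, 30), seed = 9)
  va <- generate_bead_volume(spec2, pixel_um = 1, depth_step_um = 1)
  vb <- generate_bead_volume(spec2, pixel_um = 1, depth_step_um = 1)
  expect_identical(va$volume, vb$volume)
  expect_identical(va$beads, vb$beads)
  expect_gt(nrow(va$beads), 0L)
  # rendered voxels are near each bead center
  b <- va$beads[1, ]
  ix <- round(b$x_um / 1) + 20 + 1
  expect_gt(sum(va$volume[max(1, ix - 2):min(40, ix + 2), , ]), 0)
  # Poisson statistics: published density over the characterization volume
  lam <- 2120 * 0.6 * 0.6 * 0.1
  counts <- vapply(1:60, function(s) {
    sp <- phantom_spec(bead_diameter_um = 5, density_per_mm3 = 2120,
                       fov_um = 600, depth_range_um = c(0, 100), seed = s)
    # coarse lattice: only the counts matter here
    nrow(generate_bead_volume(sp, pixel_um = 6, depth_step_um = 10)$beads)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 60) * 3)
  # chi-square sanity on the dispersion
  x2 <- sum((counts - lam)^2 / lam)
  p <- stats::pchisq(x2, df = 60)
  expect_gt(p, 0.01)
  expect_lt(p, 0.99)
  expect_error(
    generate_bead_volume(phantom_spec(bead_diameter_um = 50,
                                      density_per_mm3 = 1e6, fov_um = 100,
                                      depth_range_um = c(0, 100))),
    "occupancy"
  )
})

test_that("rendered measurements are linear in the bead configuration", {
  g <- small_grid(64L)
  src <- make_source(0, g)
  z <- seq(0, 4, 2)
  psf <- simulate_stack(src, NULL, NULL, z, Inf, g)
  spec <- phantom_spec(bead_diameter_um = 2, density_per_mm3 = 0,
                       fov_um = 64 * g$config$pixel_um,
                       depth_range_um = c(0, 4), background_level = 0,
                       seed = 5)
  mk_vol <- function(centers) {
    vol <- array(0, c(64, 64, 3))
    for (i in seq_len(nrow(centers))) {
      vol[centers[i, 1], centers[i, 2], centers[i, 3]] <- 1
    }
    list(volume = vol, beads = tibble::tibble(bead = seq_len(nrow(centers))),
         z_um = z, pixel_um = g$config$pixel_um, seed = 5)
  }
  r1 <- render_measurement(mk_vol(cbind(20, 20, 1)), psf, spec)
  r2 <- render_measurement(mk_vol(cbind(44, 40, 3)), psf, spec)
  r12 <- render_measurement(mk_vol(rbind(c(20, 20, 1), c(44, 40, 3))), psf,
                            spec)
  expect_equal(r12$clean, r1$clean + r2$clean, tolerance = 1e-9)
  # a single centered in-focus bead reproduces that PSF slice
  rc <- render_measurement(mk_vol(cbind(33, 33, 2)), psf, spec)
  expect_equal(rc$clean, psf$data[, , 2], tolerance = 1e-9)
  # flux conservation: total image equals per-slice PSF energy (pre-noise)
  expect_equal(sum(r1$clean), psf$energy[1], tolerance = 1e-6)
  # mismatched z planes are rejected
  bad <- mk_vol(cbind(20, 20, 1)); bad$z_um <- c(0, 2, 7)
  expect_error(render_measurement(bad, psf, spec), "cover")
})
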