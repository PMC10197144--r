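test_that("axial signal follows the xz-MIP line-profile recipe", {
  a <- array(0, c(8, 8, 5))
  a[3, 6, 2] <- 2 # single bright voxel
  st <- as_stack(a, 0:4)
  sig <- axial_signal(st)
  expect_equal(sig$intensity, c(0, 2, 0, 0, 0))
  # invariant to lateral translation of the whole stack
  b <- a[c(6:8, 1:5), c(4:8, 1:3), ]
  expect_equal(axial_signal(as_stack(b, 0:4))$intensity, sig$intensity)
  # separable stack: profile proportional to the axial factor
  g <- outer(exp(-(1:8 - 4)^2 / 4), exp(-(1:8 - 5)^2 / 6))
  h <- c(0.2, 1, 0.5, 0.8, 0.1)
  sep <- array(outer(as.numeric(g), h), c(8, 8, 5))
  expect_equal(axial_signal(as_stack(sep, 0:4))$intensity / max(g), h,
               tolerance = 1e-12)
})

test_that("fwhm is exact on closed forms and scale invariant", {
  # symmetric triangle of base 10 um sampled at 1 um: FWHM = 5 um
  tri <- c(0, 1:5, 4:0) / 5
  expect_equal(as.numeric(fwhm(tri, 1)), 5)
  # sampled Gaussian: 2 sqrt(2 log 2) sigma within one step
  zg <- seq(-50, 50, 1)
  gau <- exp(-zg^2 / (2 * 100))
  expect_lt(abs(as.numeric(fwhm(gau, 1)) - 2 * sqrt(2 * log(2)) * 10), 1)
  # scaling the profile leaves the width unchanged
  expect_equal(as.numeric(fwhm(37.5 * tri, 1)), as.numeric(fwhm(tri, 1)))
  # tibble input carries its own step
  expect_equal(as.numeric(fwhm(tibble::tibble(z_um = 2 * zg,
                                              intensity = gau))),
               2 * as.numeric(fwhm(gau, 1)), tolerance = 1e-9)
  # multimodal: width of the global peak only, against a dense crossing oracle
  z <- seq(0, 60, 1)
  prof <- exp(-(z - 15)^2 / (2 * 9)) + 0.6 * exp(-(z - 45)^2 / (2 * 36))
  zf <- seq(0, 60, 0.001)
  dense <- exp(-(zf - 15)^2 / (2 * 9)) + 0.6 * exp(-(zf - 45)^2 / (2 * 36))
  half <- max(dense) / 2
  above <- zf[dense >= half & abs(zf - 15) < 15]
  oracle <- max(above) - min(above)
  expect_lt(abs(as.numeric(fwhm(prof, 1)) - oracle), 0.1)
  # truncated profile flags one-sidedness
  expect_warning(w <- fwhm(c(1, 0.9, 0.7, 0.4, 0.2), 1), "one-sided")
  expect_true(attr(w, "one_sided"))
  expect_error(fwhm(rep(0, 5), 1), "positive maximum")
})

test_that("dof_measure sums per-focus widths for well-separated twin foci", {
  z <- seq(-150, 150, 1)
  p <- exp(-(z + 100)^2 / (2 * 25)) + 0.8 * exp(-(z - 50)^2 / (2 * 100))
  a <- array(rep(p, each = 1), c(1, 1, length(z)))
  st <- as_stack(a, z)
  one <- dof_measure(st, 1)
  expect_identical(one$n_foci_found, 1L)
  two <- dof_measure(st, 2)
  expect_identical(two$n_foci_found, 2L)
  w1 <- 2 * sqrt(2 * log(2)) * 5
  w2 <- 2 * sqrt(2 * log(2)) * 10
  expect_equal(two$fwhm_um, c(w1, w2), tolerance = 0.05)
  expect_equal(two$total_dof_um, sum(two$fwhm_um))
  expect_equal(two$focus_z_um, c(-100, 50), tolerance = 1e-9)
  expect_false(two$fell_back)
  # single-Gaussian profile: total equals the one width
  p1 <- exp(-z^2 / (2 * 64))
  st1 <- as_stack(array(p1, c(1, 1, length(z))), z)
  m1 <- dof_measure(st1, 1)
  expect_equal(m1$total_dof_um, m1$fwhm_um[1])
  # asking for two foci of a unimodal profile falls back with a flag
  m2 <- dof_measure(st1, 2)
  expect_true(m2$fell_back)
  expect_identical(m2$n_foci_found, 1L)
  # tidy/glance views
  expect_identical(nrow(tidy(two)), 2L)
  expect_named(glance(two), c("total_dof_um", "n_foci", "fell_back"))
})

test_that("overlapping twin peaks match isolated per-order re-simulation", {
  g <- small_grid(96L)
  src <- make_source(0, g)
  co <- basis_coefficients(0, 12, 0)
  z <- seq(-30, 30, 1)
  mask <- binarize_phase(compose_phase(co, g), co)
  both <- simulate_stack(src, mask, NULL, z, Inf, g)
  m <- dof_measure(both, 2)
  expect_identical(m$n_foci_found, 2L)
  # isolated orders as the oracle for each focus width
  for (k in 1:2) {
    ord <- if (m$focus_z_um[k] < 0) 1 else -1
    solo <- simulate_stack(src, order_field(co, ord, g), NULL, z, Inf, g,
                           keep_stack = FALSE)
    w_solo <- as.numeric(suppressWarnings(fwhm(on_axis_profile(solo))))
    expect_lt(abs(m$fwhm_um[k] - w_solo), 2)
  }
})

test_that("radially averaged MIP reproduces the Airy half-width for an ideal point source", {
  g <- small_grid(128L)
  src <- make_source(0, g)
  st <- simulate_stack(src, NULL, NULL, c(-1, 0, 1), Inf, g)
  rad <- radial_average_mip(st)
  expect_equal(rad$r_um[1], 0)
  mip <- apply(st$data, c(1, 2), max)
  expect_equal(rad$intensity[1], max(mip))
  # the radial profile starts at the peak, so the measured width is
  # one-sided; twice it is the full width
  w <- as.numeric(suppressWarnings(fwhm(rad$intensity, step_um = g$config$pixel_um)))
  airy_fwhm <- 0.5145 * g$config$wavelength_um / g$config$na
  expect_lt(abs(2 * w - airy_fwhm), g$config$pixel_um)
  # rotationally symmetric input (peaked at the center, where the radial
  # origin sits): radial profile reproduces a radial cut
  n <- 64L
  r <- sqrt(outer((1:n - 33)^2, (1:n - 33)^2, "+"))
  blob <- exp(-r^2 / (2 * 36))
  sym <- as_stack(array(blob, c(n, n, 1)), 0, pixel_um = 1)
  rp <- radial_average_mip(sym)
  cut <- blob[33, 33:48]
  expect_equal(rp$intensity[1:16], cut, tolerance = 0.05)
})

test_that("signal-to-background ratio matches analytic region means", {
  img <- matrix(1, 32, 32)
  expect_equal(sbr(img), 1)
  img2 <- matrix(1, 32, 32)
  sig <- matrix(FALSE, 32, 32); sig[10:14, 10:14] <- TRUE
  img2[sig] <- 2
  expect_equal(sbr(img2, sig, !sig), 2)
  # constructed bead image with a pedestal: ratio of means is analytic
  beads <- render_disks(64, cbind(c(20, 44), c(20, 40)), 7, value = 3)
  ped <- beads + 0.5
  mask <- beads > 0
  expect_equal(sbr(ped, mask, !mask), 3.5 / 0.5)
  # auto mode segments the same construction via Otsu
  expect_equal(sbr(ped), 7, tolerance = 1e-9)
  expect_error(sbr(ped, mask, mask), "disjoint")
  expect_error(sbr(ped, matrix(FALSE, 64, 64), !mask), "non-empty")
})
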