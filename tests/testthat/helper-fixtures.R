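# Shared fixtures: all small grids so the default run stays fast. The
# physical constants mirror the design configuration; only sampling is
# reduced.

small_config <- function(n = 64L, ...) {
  optical_config(grid_size = n, ...)
}

small_grid <- function(n = 64L, ...) pupil_grid(small_config(n, ...))

# A grid whose frequency lattice contains (0.3, 0.4) cycles/um exactly:
# df = 0.025 cycles/um. NA reduced so the cutoff fits on the lattice.
lattice_grid <- function() {
  pupil_grid(optical_config(na = 0.3, magnification = 1,
                            sensor_pixel_um = 0.625, grid_size = 64L))
}

# Reduced-size design problem for GA-level tests.
tiny_setup <- function(n = 64L, n_depths = 25L, depth_step = 4) {
  design_setup(optical_config(grid_size = n, n_depths = n_depths,
                              depth_step_um = depth_step))
}

# Direct (non-FFT) spatial convolution oracle with symmetric-reflection
# padding, matching apply_filter's boundary rule.
conv2_direct <- function(image, kernel) {
  e <- (nrow(kernel) - 1L) %/% 2L
  n <- nrow(image); m <- ncol(image)
  ri <- c(e:1, seq_len(n), n - (0:(e - 1L)))
  ci <- c(e:1, seq_len(m), m - (0:(e - 1L)))
  pad <- image[ri, ci]
  out <- matrix(0, n, m)
  k <- 2L * e + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i, j] <- sum(pad[i:(i + k - 1L), j:(j + k - 1L)] *
                         kernel[k:1, k:1])
    }
  }
  out
}

# Render disks of a given diameter (px) at integer centers on a blank image.
render_disks <- function(n, centers, diameter_px, value = 1) {
  img <- matrix(0, n, n)
  r <- diameter_px / 2
  for (i in seq_len(nrow(centers))) {
    xi <- pmax(1, floor(centers[i, 1] - r)):pmin(n, ceiling(centers[i, 1] + r))
    yi <- pmax(1, floor(centers[i, 2] - r)):pmin(n, ceiling(centers[i, 2] + r))
    d2 <- outer((xi - centers[i, 1])^2, (yi - centers[i, 2])^2, "+")
    sub <- img[xi, yi]
    sub[d2 <= r^2] <- value
    img[xi, yi] <- sub
  }
  img
}
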