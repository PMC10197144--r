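#' Canonical EDoF design problem
#'
#' Assembles the standard design setup used throughout the package: the
#' pupil grid and 5-um proxy-neuron source, the native GRIN aberration
#' (29.4 waves), the simulated depth window and the depth-coverage fitness.
#'
#' Axial geometry: z is the slice position relative to the nominal focal
#' plane, negative toward the objective (shallower in tissue). The fitness
#' target is an interval of `target_span_um` (default 80 um, the designed
#' first-order extension) centered one scattering length in front of the
#' nominal focus -- the scattering length sets the practical one-photon
#' imaging depth, so the design window tracks it. The simulated window is
#' `config$n_depths` planes of `config$depth_step_um` centered on the same
#' point; the twin -1st-order focus falls outside it, behind the nominal
#' plane, and is therefore not penalized.
#'
#' @param config An [optical_config()].
#' @param ls_um Scattering length of the target medium (um).
#' @param w040 Native spherical aberration of the GRIN lens (waves).
#' @param source_diameter_um Proxy-neuron diameter (um).
#' @param target_span_um Width of the fitness target interval (um).
#' @param alpha,threshold Passed to [fitness_spec()].
#' @return A list with `grid`, `source`, `aberration`, `depths_um`, `ls_um`,
#'   `spec` (the [fitness_spec()]), and `config`.
#' @export
design_setup <- function(config = optical_config(), ls_um = 100, w040 = 29.4,
                         source_diameter_um = 5, target_span_um = 80,
                         alpha = 4, threshold = 0.5) {
  stopifnot_scalar(ls_um, "ls_um", positive = TRUE)
  grid <- pupil_grid(config)
  center <- -ls_um
  depths <- center - (config$n_depths %/% 2) * config$depth_step_um +
    (seq_len(config$n_depths) - 1) * config$depth_step_um
  list(
    grid = grid,
    source = make_source(source_diameter_um, grid),
    aberration = aberration_model(w040),
    depths_um = depths,
    ls_um = ls_um,
    spec = fitness_spec(c(center - target_span_um / 2,
                          center + target_span_um / 2),
                        threshold = threshold, alpha = alpha),
    config = config
  )
}

#' Simulate and measure one diffraction order of a designed mask
#'
#' Builds the conjugate-phase order field of the coefficients, adds the
#' native aberration, runs the forward model over a window bracketing that
#' order's focus and reports the axial FWHM of its intensity profile.
#'
#' @param coeffs A [basis_coefficients()].
#' @param order `+1` or `-1`.
#' @param setup A [design_setup()].
#' @param depths_um Simulated planes; defaults to a window wide enough to
#'   bracket the order's focus (four target spans around the displaced
#'   focus).
#' @return A list with `fwhm_um`, `profile` (tibble `z_um`, `intensity`),
#'   `focus_z_um`.
#' @export
order_elongation <- function(coeffs, order, setup, depths_um = NULL) {
  stopifnot(inherits(coeffs, "edof_coeffs"))
  if (is.null(depths_um)) {
    # the order's paraxial focus sits at -order * defocus_um
    zc <- -order * coeffs$defocus_um
    half <- max(160, 2 * abs(diff(setup$spec$z_target)))
    depths_um <- seq(zc - half, zc + half, by = setup$config$depth_step_um)
  }
  field <- order_field(coeffs, order, setup$grid)
  stack <- simulate_stack(setup$source, field, setup$aberration, depths_um,
                          setup$ls_um, setup$grid, keep_stack = FALSE)
  sig <- axial_signal(stack)
  list(
    fwhm_um = as.numeric(suppressWarnings(fwhm(sig))),
    profile = sig,
    focus_z_um = sig$z_um[which.max(sig$intensity)]
  )
}

#' Detection recall of beads through a full synthetic experiment
#'
#' The desk-scale analogue of the bead-phantom experiment: generate a seeded
#' bead volume, image it through a PSF stack (2D-to-2D compression), filter
#' with the LoG kernel, extract particles, and match detections to the
#' ground truth within one bead diameter. Returns per-bead detection
#' outcomes joined with depth, from which recall-vs-depth summaries follow.
#'
#' @param bead_volume A [generate_bead_volume()] result.
#' @param psf_stack An `edof_stack` covering the volume's planes.
#' @param spec The [phantom_spec()] used for the volume.
#' @param sigma_px LoG sigma in pixels; default half the bead diameter in
#'   pixels.
#' @param min_diameter_px Minimum detectable particle diameter in pixels.
#' @param photon_scale Shared photon scale handed to [render_measurement()];
#'   `NULL` self-references this arm's peak.
#' @return A list: `detections` (tibble of extracted particles), `beads`
#'   (ground truth with a `detected` logical), `image` (the rendered
#'   measurement), `photon_scale`.
#' @export
pipeline_recall <- function(bead_volume, psf_stack, spec,
                            sigma_px = NULL, min_diameter_px = NULL,
                            photon_scale = NULL) {
  px <- bead_volume$pixel_um
  if (is.null(sigma_px)) sigma_px <- max(2, spec$bead_diameter_um / 2 / px)
  if (is.null(min_diameter_px)) {
    min_diameter_px <- max(2, 0.5 * spec$bead_diameter_um / px)
  }
  meas <- render_measurement(bead_volume, psf_stack, spec, photon_scale)
  filt <- apply_filter(meas$image, log_filter_spec(sigma_px))
  det <- extract_particles(filt, min_diameter_px)
  beads <- bead_volume$beads
  n <- dim(bead_volume$volume)[1]
  if (nrow(beads)) {
    bx <- beads$x_um / px + n %/% 2 + 1
    by <- beads$y_um / px + n %/% 2 + 1
    tol <- spec$bead_diameter_um / px
    # the rendering convolution is circular, so distances are toroidal
    wrap <- function(d) pmin(abs(d), n - abs(d))
    detected <- vapply(seq_len(nrow(beads)), function(i) {
      if (!nrow(det)) return(FALSE)
      any(wrap(det$x_px - bx[i])^2 + wrap(det$y_px - by[i])^2 <= tol^2)
    }, logical(1))
    beads <- dplyr::mutate(beads, detected = detected)
  } else {
    beads <- dplyr::mutate(beads, detected = logical(0))
  }
  list(detections = det, beads = beads, image = meas$image,
       photon_scale = meas$photon_scale)
}
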