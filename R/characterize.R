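#' Axial signal of an intensity stack
#'
#' Reslices the stack into xz perspectives, takes the maximum-intensity
#' projection over y, and extracts the z line profile through the lateral
#' (x) position of the global maximum. Invariant to lateral translation of
#' the whole stack.
#'
#' @param stack An [simulate_stack()] / [as_stack()] result.
#' @return A tibble with columns `z_um`, `intensity`.
#' @export
axial_signal <- function(stack) {
  stopifnot(inherits(stack, "edof_stack"))
  mip <- stack$xz_mip
  peak <- which(mip == max(mip), arr.ind = TRUE)[1, ]
  tibble(z_um = stack$z_um, intensity = mip[peak[1], ])
}

#' Full width at half maximum of a 1-D profile
#'
#' Width between the two half-maximum crossings bracketing the global peak,
#' with linear interpolation between samples. If the profile never falls
#' below half maximum on one side, the one-sided width is returned with a
#' warning and attribute `one_sided = TRUE`.
#'
#' @param profile Numeric vector of non-negative values (or a tibble with an
#'   `intensity` column as returned by [axial_signal()]).
#' @param step_um Sample spacing in um (ignored when `profile` is a tibble
#'   carrying `z_um`).
#' @return FWHM in um (scalar). Attribute `one_sided` flags truncation.
#' @examples
#' fwhm(c(0, 0.5, 1, 0.5, 0), step_um = 1) # triangle: half its base
#' @export
fwhm <- function(profile, step_um = 1) {
  if (is.data.frame(profile)) {
    step_um <- profile$z_um[2] - profile$z_um[1]
    profile <- profile$intensity
  }
  if (!is.numeric(profile) || max(profile) <= 0) {
    abort("`profile` must have a positive maximum.")
  }
  ipk <- which.max(profile)
  half <- profile[ipk] / 2
  n <- length(profile)
  one_sided <- FALSE
  # walk left from the peak to the first sample below half
  left <- ipk
  while (left > 1L && profile[left - 1L] >= half) left <- left - 1L
  if (left == 1L && profile[1L] >= half) {
    xl <- 1
    one_sided <- TRUE
  } else {
    lo <- left - 1L
    xl <- lo + (half - profile[lo]) / (profile[left] - profile[lo])
  }
  right <- ipk
  while (right < n && profile[right + 1L] >= half) right <- right + 1L
  if (right == n && profile[n] >= half) {
    xr <- n
    one_sided <- TRUE
  } else {
    hi <- right + 1L
    xr <- right + (half - profile[right]) / (profile[hi] - profile[right])
  }
  if (one_sided) {
    warn("profile does not fall below half maximum on one side; width is one-sided")
  }
  structure((xr - xl) * step_um, one_sided = one_sided)
}

# Local maxima of a profile: samples strictly greater than one neighbour and
# not smaller than the other (plateaus report their first sample).
local_peaks <- function(p) {
  n <- length(p)
  if (n < 3L) return(which.max(p))
  idx <- which(p[2:(n - 1)] >= p[1:(n - 2)] & p[2:(n - 1)] > p[3:n]) + 1L
  if (p[1] > p[2]) idx <- c(1L, idx)
  if (p[n] > p[n - 1]) idx <- c(idx, n)
  if (!length(idx)) idx <- which.max(p)
  idx
}

#' Depth-of-field measurement of an intensity stack
#'
#' Detects the `n_foci` highest well-separated peaks of the axial signal and
#' reports the per-focus axial FWHM plus their sum, the total depth of field
#' of a twin-foci design. A detected peak must be at least
#' `min_separation_steps` axial steps from a stronger one and retain at
#' least `min_rel_height` of the global maximum; if fewer qualifying peaks
#' than `n_foci` are found, single-focus mode is used with a flag (and an
#' error is raised when even one peak is absent). Each focus's FWHM is
#' measured against its own peak height, with crossings confined to the
#' valley-bounded segment around the peak.
#'
#' @param stack An `edof_stack`.
#' @param n_foci Expected number of foci (1 or 2).
#' @param min_separation_steps Minimum peak separation in axial steps.
#' @param min_rel_height Minimum peak height relative to the global maximum.
#' @return An object of class `edof_dof`: list with `fwhm_um` (one per
#'   focus), `focus_z_um`, `total_dof_um`, `n_foci_found`, `fell_back`.
#' @export
dof_measure <- function(stack, n_foci = 1L, min_separation_steps = 5L,
                        min_rel_height = 0.2) {
  stopifnot(inherits(stack, "edof_stack"))
  n_foci <- as.integer(n_foci)
  if (!n_foci %in% 1:2) abort("`n_foci` must be 1 or 2.")
  sig <- axial_signal(stack)
  p <- sig$intensity
  step <- if (length(sig$z_um) > 1) sig$z_um[2] - sig$z_um[1] else 1
  cand <- local_peaks(p)
  cand <- cand[p[cand] >= min_rel_height * max(p)]
  cand <- cand[order(-p[cand], cand)]
  picked <- integer()
  for (i in cand) {
    if (all(abs(i - picked) >= min_separation_steps)) picked <- c(picked, i)
    if (length(picked) == n_foci) break
  }
  fell_back <- FALSE
  if (length(picked) < n_foci) {
    if (!length(picked)) abort("No detectable peaks in the axial signal.")
    fell_back <- TRUE
  }
  picked <- sort(picked)
  widths <- numeric(length(picked))
  for (k in seq_along(picked)) {
    # confine to the valley-bounded segment between neighbouring picked peaks
    lo <- if (k == 1L) 1L else {
      seg <- picked[k - 1L]:picked[k]; seg[which.min(p[seg])]
    }
    hi <- if (k == length(picked)) length(p) else {
      seg <- picked[k]:picked[k + 1L]; seg[which.min(p[seg])]
    }
    widths[k] <- suppressWarnings(fwhm(p[lo:hi], step))
  }
  structure(
    list(fwhm_um = widths, focus_z_um = sig$z_um[picked],
         total_dof_um = sum(widths), n_foci_found = length(picked),
         fell_back = fell_back),
    class = "edof_dof"
  )
}

#' @export
print.edof_dof <- function(x, ...) {
  cat(sprintf("<edof_dof> %d focus/foci at z = %s um; FWHM %s um; total %.3g um\n",
              x$n_foci_found, paste(signif(x$focus_z_um, 4), collapse = ", "),
              paste(signif(x$fwhm_um, 4), collapse = ", "), x$total_dof_um))
  invisible(x)
}

#' @export
tidy.edof_dof <- function(x, ...) {
  tibble(focus = seq_along(x$fwhm_um), focus_z_um = x$focus_z_um,
         fwhm_um = as.numeric(x$fwhm_um))
}

#' @export
glance.edof_dof <- function(x, ...) {
  tibble(total_dof_um = x$total_dof_um, n_foci = x$n_foci_found,
         fell_back = x$fell_back)
}

#' Radially averaged lateral profile of the stack's MIP
#'
#' Maximum-intensity projection over the focal range along z, then the mean
#' over azimuth as a function of radius from the projection's peak, in
#' object-space um. Used to compare lateral resolution over the imaging
#' range.
#'
#' @param stack An `edof_stack` with the full cube retained.
#' @param z_range Optional length-2 interval (um) restricting the focal
#'   range; default all slices.
#' @return A tibble with columns `r_um`, `intensity` (bin width one pixel).
#' @export
radial_average_mip <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "edof_stack"))
  if (is.null(stack$data)) abort("needs the full stack (keep_stack = TRUE).")
  keep <- if (is.null(z_range)) {
    rep(TRUE, length(stack$z_um))
  } else {
    stack$z_um >= z_range[1] & stack$z_um <= z_range[2]
  }
  if (!any(keep)) abort("`z_range` selects no slices.")
  mip <- apply(stack$data[, , keep, drop = FALSE], c(1, 2), max)
  ctr <- which(mip == max(mip), arr.ind = TRUE)[1, ]
  nx <- nrow(mip); ny <- ncol(mip)
  r_px <- sqrt(outer((seq_len(nx) - ctr[1])^2, (seq_len(ny) - ctr[2])^2, "+"))
  bin <- round(r_px)
  prof <- tapply(as.numeric(mip), as.integer(bin), mean)
  tibble(
    r_um = as.numeric(names(prof)) * stack$pixel_um,
    intensity = as.numeric(prof)
  )
}

#' Signal-to-background ratio of a 2-D image
#'
#' Mean intensity over the signal region divided by the mean over the
#' background region. With `signal = NULL` the regions are segmented
#' automatically: signal = pixels above the Otsu threshold of the image,
#' background = the rest.
#'
#' @param image Numeric matrix.
#' @param signal,background Logical matrices (same shape) selecting disjoint,
#'   non-empty regions; both `NULL` for Otsu auto-segmentation.
#' @return The scalar ratio.
#' @export
sbr <- function(image, signal = NULL, background = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) abort("`image` must be a numeric matrix.")
  if (is.null(signal) != is.null(background)) {
    abort("supply both `signal` and `background`, or neither.")
  }
  if (is.null(signal)) {
    if (diff(range(image)) == 0) return(1) # uniform image: no contrast
    thr <- otsu_threshold(image)
    signal <- image > thr
    background <- !signal
  }
  if (!any(signal) || !any(background)) abort("regions must be non-empty.")
  if (any(signal & background)) abort("regions must be disjoint.")
  mean(image[signal]) / mean(image[background])
}
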