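#' Monitor geometry and pixel/degree conversion
#'
#' The display geometry of the stereoscope setup: a 36.5 x 27.4 degree
#' screen at 1600 x 1200 pixels viewed from 54 cm. Conversion uses the
#' linear small-angle convention `pixel_pitch = width_deg / width_px`
#' (0.0228 deg/px), which is the convention consistent with the stimulus
#' definitions (5 px = 0.11 deg at two decimals); a tangent-corrected pitch
#' is not.
#'
#' @param width_deg,width_px,height_deg,height_px,viewing_distance_cm
#'   Screen extent in degrees of visual angle and pixels, and the viewing
#'   distance.
#' @return A `monitor_geometry` object (list with the fields above plus
#'   `pixel_pitch_deg`).
#' @examples
#' px_to_deg(5)  # 0.114 -> prints as 0.11 at two decimals
#' @export
monitor_geometry <- function(width_deg = 36.5, width_px = 1600,
                             height_deg = 27.4, height_px = 1200,
                             viewing_distance_cm = 54) {
  if (width_deg <= 0 || width_px <= 0) {
    abort("Monitor extent must be positive.", class = "indecision_input_error")
  }
  structure(list(width_deg = width_deg, width_px = width_px,
                 height_deg = height_deg, height_px = height_px,
                 viewing_distance_cm = viewing_distance_cm,
                 pixel_pitch_deg = width_deg / width_px),
            class = "monitor_geometry")
}

#' @rdname monitor_geometry
#' @param pixels Signed pixel count(s).
#' @param geometry A [monitor_geometry()] object.
#' @export
px_to_deg <- function(pixels, geometry = monitor_geometry()) {
  pixels * geometry$pixel_pitch_deg
}

#' @rdname monitor_geometry
#' @param degrees Signed visual angle(s) in degrees.
#' @export
deg_to_px <- function(degrees, geometry = monitor_geometry()) {
  as.integer(round(degrees / geometry$pixel_pitch_deg))
}

#' Specification of the quantized depth-bump stimulus
#'
#' The bump's disparity falls from 0 at the center to `base_disparity_deg`
#' at the base following a cumulative Gaussian of the radial coordinate,
#' i.e. `d(r) = base * CDF((r - m) / sigma)` (the "1 - CDF" height profile
#' after normalisation to the [base, 0] disparity range). The mean radius
#' `m` is placed so that the *quantized* disparity (integer screen pixels,
#' magnitude-floor rule) is exactly zero over a flat top of the requested
#' diameter: `m = flat_top_radius - sigma * qnorm(pitch / |base|)`.
#'
#' @param flat_top_diameter_deg Diameter of the zero-disparity plateau,
#'   degrees. Default 2.26.
#' @param steepness_sigma_deg Steepness (sigma) of the cumulative Gaussian,
#'   degrees. Default 0.5.
#' @param base_disparity_deg Disparity at the base, degrees (negative =
#'   behind fixation). Default -0.5.
#' @param geometry A [monitor_geometry()] object.
#' @return A `bump_spec` object; field `cdf_mean_radius_deg` holds the
#'   derived mean radius.
#' @export
bump_spec <- function(flat_top_diameter_deg = 2.26, steepness_sigma_deg = 0.5,
                      base_disparity_deg = -0.5,
                      geometry = monitor_geometry()) {
  if (base_disparity_deg >= 0) {
    abort("`base_disparity_deg` must be negative (behind fixation).",
          class = "indecision_input_error")
  }
  if (steepness_sigma_deg <= 0) {
    abort("`steepness_sigma_deg` must be positive.",
          class = "indecision_input_error")
  }
  pitch <- geometry$pixel_pitch_deg
  m <- flat_top_diameter_deg / 2 -
    steepness_sigma_deg * qnorm(pitch / abs(base_disparity_deg))
  structure(list(flat_top_diameter_deg = flat_top_diameter_deg,
                 steepness_sigma_deg = steepness_sigma_deg,
                 base_disparity_deg = base_disparity_deg,
                 cdf_mean_radius_deg = m,
                 geometry = geometry),
            class = "bump_spec")
}

#' Radial disparity profile of the bump with pixel quantization
#'
#' Evaluates the continuous cumulative-Gaussian disparity and its
#' quantization to integer screen pixels. The default quantization rule is
#' the floor of the disparity magnitude (|-0.5 deg| = 21.9 px floors to 21,
#' so the bump decomposes into exactly 21 nonzero-disparity circles;
#' round-half-up would give 22).
#'
#' @param spec A [bump_spec()] object.
#' @param r_samples Nonnegative, sorted radial grid in degrees. Default: 0
#'   to `cdf_mean_radius + 4 sigma` at one-hundredth-pixel resolution.
#' @param quantization `"floor_magnitude"` (default) or `"round"`.
#' @return A tibble of class `disparity_profile` with columns `radius_deg`,
#'   `disparity_deg`, `disparity_px` (quantized integers <= 0). Attributes:
#'   `ring_levels` (sorted distinct nonzero quantized values) and `spec`.
#' @examples
#' prof <- bump_profile(bump_spec())
#' length(attr(prof, "ring_levels"))  # 21
#' @export
bump_profile <- function(spec = bump_spec(), r_samples = NULL,
                         quantization = c("floor_magnitude", "round")) {
  quantization <- match.arg(quantization)
  pitch <- spec$geometry$pixel_pitch_deg
  if (is.null(r_samples)) {
    r_max <- spec$cdf_mean_radius_deg + 4 * spec$steepness_sigma_deg
    r_samples <- seq(0, r_max, by = pitch / 100)
  }
  if (any(r_samples < 0) || is.unsorted(r_samples)) {
    abort("`r_samples` must be nonnegative and sorted.",
          class = "indecision_input_error")
  }
  d <- spec$base_disparity_deg *
    pnorm((r_samples - spec$cdf_mean_radius_deg) / spec$steepness_sigma_deg)
  mag_px <- abs(d) / pitch
  q <- switch(quantization,
              floor_magnitude = floor(mag_px),
              round = round(mag_px))
  d_px <- as.integer(sign(spec$base_disparity_deg) * q)
  out <- tibble(radius_deg = r_samples, disparity_deg = d,
                disparity_px = d_px)
  attr(out, "ring_levels") <- sort(setdiff(unique(d_px), 0L),
                                   decreasing = TRUE)
  attr(out, "spec") <- spec
  class(out) <- c("disparity_profile", class(out))
  out
}

#' Mean disparity of a radial region of the bump
#'
#' Averages the bump's disparity between two radii under a selectable
#' convention: `"radial_unweighted"` (mean of the continuous disparity over
#' the radial coordinate), `"area_weighted"` (continuous disparity weighted
#' by annulus area, i.e. by `r`), or `"ring_level_mean"` (unweighted mean
#' over the distinct quantized pixel levels present in the region,
#' including the zero level). The averaging convention is exposed because
#' the summary disparities of composite stimuli depend on it.
#'
#' @param profile A [bump_profile()] result.
#' @param inner_r,outer_r Region bounds in degrees, `inner_r < outer_r`.
#' @param weighting Averaging convention; see Details.
#' @return A list with `disparity_deg` (the mean) and `disparity_px` (its
#'   nearest-integer pixel equivalent).
#' @examples
#' prof <- bump_profile(bump_spec())
#' region_mean_disparity(prof, 1, 2)$disparity_px  # -5
#' @export
region_mean_disparity <- function(profile, inner_r, outer_r,
                                  weighting = c("radial_unweighted",
                                                "area_weighted",
                                                "ring_level_mean")) {
  weighting <- match.arg(weighting)
  if (inner_r >= outer_r) {
    abort("`inner_r` must be < `outer_r`.", class = "indecision_input_error")
  }
  sel <- profile$radius_deg >= inner_r & profile$radius_deg <= outer_r
  if (!any(sel)) {
    abort("Region contains no profile samples.",
          class = "indecision_input_error")
  }
  spec <- attr(profile, "spec")
  pitch <- spec$geometry$pixel_pitch_deg
  d_deg <- switch(weighting,
    radial_unweighted = mean(profile$disparity_deg[sel]),
    area_weighted = {
      w <- profile$radius_deg[sel]
      sum(profile$disparity_deg[sel] * w) / sum(w)
    },
    ring_level_mean = {
      levels_px <- unique(profile$disparity_px[sel])
      mean(levels_px) * pitch
    })
  list(disparity_deg = d_deg,
       disparity_px = as.integer(round(d_deg / pitch)))
}

#' @method autoplot disparity_profile
#' @export
autoplot.disparity_profile <- function(object, ...) {
  spec <- attr(object, "spec")
  pitch <- spec$geometry$pixel_pitch_deg
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radius_deg)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$disparity_deg,
                                    colour = "continuous")) +
    ggplot2::geom_step(ggplot2::aes(y = .data$disparity_px * pitch,
                                    colour = "quantized")) +
    ggplot2::labs(x = "Radius (deg)", y = "Disparity (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export a disparity profile as CSV
#'
#' @param profile A [bump_profile()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(
    tibble(radius_deg = profile$radius_deg,
           disparity_deg = profile$disparity_deg,
           disparity_px = profile$disparity_px),
    path)
  invisible(path)
}
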