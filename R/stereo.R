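#' Declarative stereo scene elements
#'
#' Constructors for the elements of a stereo stimulus scene. All positions
#' and sizes are in degrees of visual angle, contrasts in percent Michelson,
#' and disparities in degrees (negative = uncrossed, behind fixation).
#' Disparity is realised by shifting the element horizontally in the
#' right-eye image only, by the integer pixel count `deg_to_px(disparity)`
#' (no sub-pixel interpolation); the left-eye image is always at zero
#' disparity.
#'
#' `element_grating()` draws a sine-wave grating disc or annulus, optionally
#' cut into wedges by radial slots. `element_texture()` fills a disc/annulus
#' with the non-oriented filtered-noise texture. `element_dot_square()` is a
#' random-dot square (fixation lock). `element_bump()` draws a grating disc
#' whose disparity follows the quantized bump profile, rendered as
#' concentric circles each at its own integer-pixel disparity.
#'
#' @param center Element center `c(x, y)` in degrees.
#' @param outer_diameter_deg,inner_diameter_deg Annulus bounds (inner 0 for
#'   a disc).
#' @param orientation_deg Grating orientation (45 or 135 in the
#'   experiments).
#' @param sf_cyc_per_deg Spatial frequency. Default 2.
#' @param contrast_pct Michelson contrast, percent.
#' @param phase Grating phase, radians.
#' @param disparity_deg Element disparity.
#' @param n_slots,slot_width_deg Number and width of radial slots cutting
#'   the annulus into wedges (0 slots = full annulus).
#' @param side_deg Side length of a dot square.
#' @param density Fraction of white dots in a dot square.
#' @param spec A [bump_spec()] for `element_bump()`.
#' @param noise_rms Amplitude of the random luminance noise overlaid on the
#'   bump grating to strengthen the depth percept.
#' @return A list describing the element, for [render_stereo_pair()].
#' @name scene_elements
NULL

#' @rdname scene_elements
#' @export
element_grating <- function(center = c(0, 0), outer_diameter_deg = 2,
                            inner_diameter_deg = 0, orientation_deg = 45,
                            sf_cyc_per_deg = 2, contrast_pct = 30,
                            phase = 0, disparity_deg = 0,
                            n_slots = 0, slot_width_deg = 0.33) {
  list(type = "grating", center = center,
       outer_diameter_deg = outer_diameter_deg,
       inner_diameter_deg = inner_diameter_deg,
       orientation_deg = orientation_deg, sf_cyc_per_deg = sf_cyc_per_deg,
       contrast_pct = contrast_pct, phase = phase,
       disparity_deg = disparity_deg,
       n_slots = n_slots, slot_width_deg = slot_width_deg)
}

#' @rdname scene_elements
#' @export
element_texture <- function(center = c(0, 0), outer_diameter_deg = 8,
                            inner_diameter_deg = 0, sf_cyc_per_deg = 2,
                            contrast_pct = 80, disparity_deg = 0) {
  list(type = "texture", center = center,
       outer_diameter_deg = outer_diameter_deg,
       inner_diameter_deg = inner_diameter_deg,
       sf_cyc_per_deg = sf_cyc_per_deg, contrast_pct = contrast_pct,
       disparity_deg = disparity_deg)
}

#' @rdname scene_elements
#' @export
element_dot_square <- function(center, side_deg = 1.1, density = 0.5,
                               disparity_deg = 0) {
  list(type = "dot_square", center = center, side_deg = side_deg,
       density = density, disparity_deg = disparity_deg)
}

#' @rdname scene_elements
#' @export
element_bump <- function(center = c(0, 0), outer_diameter_deg = 8,
                         orientation_deg = 45, sf_cyc_per_deg = 2,
                         contrast_pct = 80, phase = 0, spec = bump_spec(),
                         noise_rms = 0.05) {
  list(type = "bump", center = center,
       outer_diameter_deg = outer_diameter_deg,
       orientation_deg = orientation_deg, sf_cyc_per_deg = sf_cyc_per_deg,
       contrast_pct = contrast_pct, phase = phase, spec = spec,
       noise_rms = noise_rms)
}

#' Render a stereo pair from a scene description
#'
#' Rasterises the scene twice: the left-eye image with every element at zero
#' disparity, the right-eye image with each element shifted horizontally by
#' its disparity rounded to integer pixels. Elements are painted in list
#' order (later elements on top) over a mid-gray (0.5) background.
#' Deterministic given the scene and `seed` (which drives dot patterns and
#' texture noise).
#'
#' @param elements A list of scene elements (see [scene_elements]).
#' @param geometry A [monitor_geometry()] object.
#' @param canvas_px Canvas size in pixels, `c(ny, nx)` or scalar; the canvas
#'   is centered on fixation.
#' @param seed Integer seed.
#' @return A list with matrices `left` and `right` (luminance in `[0, 1]`).
#' @examples
#' pair <- render_stereo_pair(list(element_grating()), canvas_px = 128)
#' identical(pair$left, pair$right)  # zero disparity
#' @export
render_stereo_pair <- function(elements, geometry = monitor_geometry(),
                               canvas_px = c(400, 400), seed = 1) {
  if (length(canvas_px) == 1L) canvas_px <- rep(canvas_px, 2)
  ny <- canvas_px[1]; nx <- canvas_px[2]
  pitch <- geometry$pixel_pitch_deg
  xs <- (seq_len(nx) - (nx + 1) / 2) * pitch
  ys <- (seq_len(ny) - (ny + 1) / 2) * pitch
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  half_x <- nx / 2 * pitch; half_y <- ny / 2 * pitch

  left <- matrix(0.5, ny, nx)
  right <- matrix(0.5, ny, nx)
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    max_shift <- if (el$type == "bump") {
      abs(el$spec$base_disparity_deg)
    } else {
      abs(deg_to_px(el$disparity_deg %||% 0, geometry) * pitch)
    }
    ext <- element_extent(el)
    if (abs(el$center[1]) + ext[1] + max_shift > half_x ||
        abs(el$center[2]) + ext[2] > half_y) {
      abort(sprintf("Element %d extends outside the canvas.", i),
            class = "indecision_input_error")
    }
    el_seed <- seed + 1000L * i
    left <- paint_element(left, el, X, Y, FALSE, geometry, el_seed)
    right <- paint_element(right, el, X, Y, TRUE, geometry, el_seed)
  }
  list(left = left, right = right)
}

element_extent <- function(el) {
  switch(el$type,
         dot_square = rep(el$side_deg / 2, 2),
         rep(el$outer_diameter_deg / 2, 2))
}

# paint one element onto img; disparity shifts apply to the right eye only
paint_element <- function(img, el, X, Y, right_eye, geometry, seed) {
  pitch <- geometry$pixel_pitch_deg
  shift_deg <- if (right_eye && el$type != "bump") {
    deg_to_px(el$disparity_deg %||% 0, geometry) * pitch
  } else 0
  xr <- X - el$center[1] - shift_deg
  yr <- Y - el$center[2]
  switch(el$type,
    grating = {
      mask <- annulus_mask(xr, yr, el$inner_diameter_deg / 2,
                           el$outer_diameter_deg / 2,
                           el$n_slots, el$slot_width_deg)
      img[mask] <- grating_pattern(xr, yr, el)[mask]
      img
    },
    texture = {
      mask <- annulus_mask(xr, yr, el$inner_diameter_deg / 2,
                           el$outer_diameter_deg / 2, 0, 0)
      tex <- make_nonoriented_texture(dim(img),
                                      sf_cyc_per_deg = el$sf_cyc_per_deg,
                                      target_contrast = el$contrast_pct,
                                      geometry = geometry, seed = seed)
      # shift the texture with the element so both eyes see the same patch
      if (shift_deg != 0) {
        s <- deg_to_px(shift_deg, geometry)
        tex <- tex[, shift_cols(ncol(tex), s), drop = FALSE]
      }
      img[mask] <- tex[mask]
      img
    },
    dot_square = {
      mask <- abs(xr) <= el$side_deg / 2 & abs(yr) <= el$side_deg / 2
      dots <- withr::with_seed(seed, {
        matrix(rbinom_matrix(dim(img), el$density), nrow(img))
      })
      if (shift_deg != 0) {
        s <- deg_to_px(shift_deg, geometry)
        dots <- dots[, shift_cols(ncol(dots), s), drop = FALSE]
      }
      img[mask] <- dots[mask]
      img
    },
    bump = {
      r_out <- el$outer_diameter_deg / 2
      prof <- bump_profile(el$spec, seq(0, r_out, by = pitch / 10))
      levels_px <- sort(unique(prof$disparity_px))  # most negative first
      noise <- if (el$noise_rms > 0) {
        withr::with_seed(seed, matrix(rnorm(length(img), 0, el$noise_rms),
                                      nrow(img)))
      }
      # paint far rings first, nearer rings (smaller |disparity|) on top;
      # each ring (circle at one quantized disparity) is displaced by its
      # own integer-pixel disparity in the right eye
      for (lev in levels_px) {
        rs <- prof$radius_deg[prof$disparity_px == lev]
        xq <- X - el$center[1] - (if (right_eye) lev * pitch else 0)
        rr <- sqrt(xq^2 + yr^2)
        mask <- rr >= min(rs) & rr <= max(rs)
        patq <- grating_pattern(xq, yr, el)
        if (!is.null(noise)) patq <- pmin(pmax(patq + noise, 0), 1)
        img[mask] <- patq[mask]
      }
      img
    },
    abort(paste0("Unknown element type: ", el$type),
          class = "indecision_input_error"))
}

annulus_mask <- function(xr, yr, r_in, r_out, n_slots, slot_width_deg) {
  rr <- sqrt(xr^2 + yr^2)
  mask <- rr >= r_in & rr <= r_out
  if (n_slots > 0) {
    phis <- seq(0, 2 * pi, length.out = n_slots + 1)[seq_len(n_slots)] +
      pi / n_slots
    for (phi in phis) {
      along <- xr * cos(phi) + yr * sin(phi)
      perp <- -xr * sin(phi) + yr * cos(phi)
      mask <- mask & !(along > 0 & abs(perp) <= slot_width_deg / 2)
    }
  }
  mask
}

grating_pattern <- function(xr, yr, el) {
  beta <- (el$orientation_deg + 90) * pi / 180  # modulation direction
  phase_arg <- 2 * pi * el$sf_cyc_per_deg *
    (xr * cos(beta) + yr * sin(beta)) + el$phase
  0.5 * (1 + el$contrast_pct / 100 * sin(phase_arg))
}

shift_cols <- function(n, s) {
  ((seq_len(n) - 1 - s) %% n) + 1
}

rbinom_matrix <- function(dims, density) {
  stats::rbinom(prod(dims), 1, density)
}
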