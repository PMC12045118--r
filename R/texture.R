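#' Non-oriented filtered-noise texture
#'
#' Synthesises the isotropic control texture used around the reference
#' grating: seeded Gaussian white noise filtered in the Fourier domain by a
#' bank of orientation-selective band-pass (log-Gabor style) filters whose
#' orientations are equally spaced over 0-180 degrees, summed, and rescaled
#' to a target Michelson contrast about mean luminance 0.5. With the
#' default 18 orientations the summed bank is nearly constant in angle, so
#' the texture carries the gratings' spatial-frequency content with no net
#' orientation. The spatial-frequency band is log-Gaussian with a 1-octave
#' bandwidth; orientation tuning is a wrapped Gaussian whose sd equals the
#' filter spacing.
#'
#' Contrast normalisation is an affine rescale placing the 0.1 and 99.9
#' luminance percentiles at the target Michelson range (robust to Gaussian
#' tails), followed by clipping to that range.
#'
#' @param size_px Image size, `c(ny, nx)` or a scalar. Default 256.
#' @param sf_cyc_per_deg Peak spatial frequency, cycles/degree. Default 2.
#' @param n_orientations Number of orientation bands (>= 1; >= 2 required
#'   for an approximately isotropic result). Default 18.
#' @param target_contrast Target Michelson contrast in percent, in (0, 100].
#' @param geometry A [monitor_geometry()] object (sets degrees per pixel).
#' @param ori_bw_deg Orientation tuning sd of each band, degrees. The
#'   default equals the 10-degree spacing of the 18-band bank, which keeps
#'   the summed bank's angular ripple negligible while a single band stays
#'   strongly oriented.
#' @param seed Integer seed; identical seeds give identical images.
#' @return A `size_px` matrix of luminances in `[0, 1]` with mean ~0.5.
#' @examples
#' tex <- make_nonoriented_texture(seed = 1)
#' michelson_contrast(tex)  # ~80
#' @export
make_nonoriented_texture <- function(size_px = c(256, 256),
                                     sf_cyc_per_deg = 2,
                                     n_orientations = 18,
                                     target_contrast = 80,
                                     geometry = monitor_geometry(),
                                     ori_bw_deg = 10,
                                     seed = 1) {
  if (length(size_px) == 1L) size_px <- rep(size_px, 2)
  if (any(size_px < 8)) {
    abort("`size_px` too small.", class = "indecision_input_error")
  }
  if (target_contrast <= 0 || target_contrast > 100) {
    abort("`target_contrast` must be in (0, 100].",
          class = "indecision_input_error")
  }
  if (n_orientations < 1) {
    abort("`n_orientations` must be >= 1.", class = "indecision_input_error")
  }
  ny <- size_px[1]; nx <- size_px[2]

  # frequency coordinates in cycles/pixel
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  FX <- matrix(fx, ny, nx, byrow = TRUE)
  FY <- matrix(fy, ny, nx)
  f <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX) %% pi            # orientation of the frequency vector

  f0 <- sf_cyc_per_deg * geometry$pixel_pitch_deg   # cycles/pixel
  # 1-octave FWHM log-Gaussian radial band
  sigma_logf <- 1 / (2 * sqrt(2 * log(2))) * log(2)
  radial <- exp(-(log(pmax(f, 1e-12) / f0))^2 / (2 * sigma_logf^2))
  radial[f == 0] <- 0

  thetas <- seq(0, pi, length.out = n_orientations + 1)[seq_len(n_orientations)]
  sigma_th <- ori_bw_deg * pi / 180
  angular <- 0
  for (th in thetas) {
    dth <- ang - th
    dth <- ((dth + pi / 2) %% pi) - pi / 2   # wrapped to [-pi/2, pi/2)
    angular <- angular + exp(-dth^2 / (2 * sigma_th^2))
  }
  H <- radial * angular

  img <- withr::with_seed(seed, {
    noise <- matrix(rnorm(ny * nx), ny, nx)
    Re(fft(fft(noise) * H, inverse = TRUE)) / (ny * nx)
  })

  c01 <- target_contrast / 100
  lo <- 0.5 * (1 - c01); hi <- 0.5 * (1 + c01)
  q <- quantile(img, c(0.001, 0.999), names = FALSE)
  img <- lo + (img - q[1]) / (q[2] - q[1]) * (hi - lo)
  pmin(pmax(img, lo), hi)
}

fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

#' Michelson contrast of a luminance image
#'
#' `(max - min) / (max + min)`, in percent.
#'
#' @param img Numeric matrix of luminances.
#' @return Scalar percent contrast.
#' @export
michelson_contrast <- function(img) {
  100 * (max(img) - min(img)) / (max(img) + min(img))
}

#' Orientation-energy distribution of an image
#'
#' Bins the Fourier power of the (mean-removed) image by orientation within
#' a band around a peak spatial frequency and reports per-bin energies and
#' their coefficient of variation. Before binning, each coefficient is
#' normalised by the mean power at its radial frequency, so the statistic
#' isolates orientation anisotropy from the (arbitrary) radial power
#' profile. An isotropic ("non-oriented") texture has a small CV; a
#' single-orientation texture a large one.
#'
#' @param img Luminance matrix.
#' @param n_bins Number of orientation bins over 0-180 deg. Default 18.
#' @param sf_cyc_per_deg Center of the frequency band inspected. Default 2.
#' @param geometry A [monitor_geometry()] object.
#' @return A list with `energy` (length-`n_bins` vector) and `cv`.
#' @export
orientation_energy <- function(img, n_bins = 18, sf_cyc_per_deg = 2,
                               geometry = monitor_geometry()) {
  ny <- nrow(img); nx <- ncol(img)
  P <- Mod(fft(img - mean(img)))^2
  FX <- matrix(fft_freq(nx), ny, nx, byrow = TRUE)
  FY <- matrix(fft_freq(ny), ny, nx)
  f <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX) %% pi
  f0 <- sf_cyc_per_deg * geometry$pixel_pitch_deg
  sel <- f >= f0 / 2 & f <= 2 * f0
  # remove the radial power profile: normalise by the mean power in thin
  # radial shells so every coefficient carries comparable weight
  r_px <- round(f[sel] * sqrt(nx * ny))
  shell_mean <- tapply(P[sel], r_px, mean)
  Pn <- P[sel] / shell_mean[as.character(r_px)]
  bins <- pmin(floor(ang[sel] / pi * n_bins) + 1L, n_bins)
  energy <- vapply(seq_len(n_bins),
                   function(b) mean(Pn[bins == b]), numeric(1))
  list(energy = energy, cv = sd(energy) / mean(energy))
}
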