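#' Sinusoidal reference grating
#'
#' Builds the reference pattern: a horizontal sinusoid
#' `p(x) = (1 - cos(2*pi*x/T))/2` spanning exactly two cycles, constant
#' along y. Column x = 0 is pure background (p = 0) and the crest (p = 1)
#' falls on a pixel centre. One pixel = one cone = 1/120 degree of visual
#' arc, so 120/sf cones per cycle; the standard frequencies use the
#' conventional cone counts \{30, 60, 110, 222\} for \{4, 2, 1, 0.5\}
#' cycles/degree.
#'
#' @param spatial_frequency grating frequency in cycles per degree.
#' @param ny vertical image size in cones (default 30).
#' @return an object of class `pvc_pattern` with fields `values`
#'   (Nx x Ny matrix in \[0,1\]), `spatial_frequency`, `cones_per_cycle`.
#' @examples
#' p <- make_grating(4)
#' dim(p$values)  # 60 30
#' @export
make_grating <- function(spatial_frequency, ny = 30) {
  stopifnot(spatial_frequency > 0, ny >= 1)
  standard <- c("4" = 30, "2" = 60, "1" = 110, "0.5" = 222)
  key <- as.character(spatial_frequency)
  cpc <- if (key %in% names(standard)) {
    unname(standard[key])
  } else {
    round(120 / spatial_frequency)
  }
  nx <- 2L * as.integer(cpc)
  x <- seq_len(nx) - 1
  p <- (1 - cos(2 * pi * x / cpc)) / 2
  structure(
    list(values = matrix(rep(p, ny), nx, ny),
         spatial_frequency = spatial_frequency,
         cones_per_cycle = as.integer(cpc)),
    class = "pvc_pattern"
  )
}

#' Eye optics parameters
#'
#' Human values: lens refractive index 1.406, focal length 21.3 mm, pupil
#' diameter 5 mm, and a pixel (cone) pitch of 1/120 degree of visual arc.
#' The diffraction-limited Airy pattern depends only on wavelength and pupil
#' diameter; refractive index and focal length are carried as metadata.
#'
#' @param refractive_index lens refractive index.
#' @param focal_length_mm focal length, mm.
#' @param pupil_diameter_mm pupil diameter, mm.
#' @param pixel_pitch_deg angular pixel pitch, degrees.
#' @param kernel_truncation PSF truncation radius in pixels.
#' @return an object of class `pvc_optics`.
#' @export
optics_model <- function(refractive_index = 1.406, focal_length_mm = 21.3,
                         pupil_diameter_mm = 5, pixel_pitch_deg = 1 / 120,
                         kernel_truncation = 9) {
  stopifnot(refractive_index > 0, focal_length_mm > 0,
            pupil_diameter_mm > 0, pixel_pitch_deg > 0,
            kernel_truncation >= 1)
  structure(
    list(refractive_index = refractive_index,
         focal_length_mm = focal_length_mm,
         pupil_diameter_mm = pupil_diameter_mm,
         pixel_pitch_deg = pixel_pitch_deg,
         kernel_truncation = as.integer(kernel_truncation)),
    class = "pvc_optics"
  )
}

#' Airy-disk point-spread function at one wavelength
#'
#' Circularly symmetric diffraction-limited intensity pattern
#' `(2 J1(x)/x)^2`, `x = pi d sin(theta) / lambda`, sampled at pixel
#' centres on the angular grid, truncated at `kernel_truncation` pixels and
#' normalised to sum 1. The kernel widens with wavelength (chromatic blur):
#' first zero at angle 1.22 lambda/d.
#'
#' @param lambda_nm wavelength in nm (must lie in \[300, 800\]).
#' @param optics an [optics_model()].
#' @return a square matrix of odd size `2*kernel_truncation + 1`.
#' @export
airy_psf <- function(lambda_nm, optics = optics_model()) {
  if (lambda_nm <= 0) stop("wavelength must be positive")
  if (lambda_nm < 300 || lambda_nm > 800) {
    stop("wavelength out of supported range [300, 800] nm")
  }
  k <- optics$kernel_truncation
  pitch_rad <- optics$pixel_pitch_deg * pi / 180
  d <- optics$pupil_diameter_mm * 1e-3
  lam <- lambda_nm * 1e-9
  off <- (-k):k
  r <- sqrt(outer(off^2, off^2, "+")) * pitch_rad
  x <- pi * d * sin(r) / lam
  v <- matrix(1, length(off), length(off))
  nz <- x > 0
  v[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
  v / sum(v)
}

#' Synthesize a 1/f (pink-noise) luminance-coefficient field
#'
#' Natural-scene luminance variation is emulated by a random-phase
#' Gaussian field whose amplitude spectrum falls as 1/f, synthesised in
#' the frequency domain, transformed to space, scaled to the requested RMS
#' contrast, floored to stay strictly positive, and renormalised to mean
#' exactly 1 so that luminance variation does not change mean image
#' intensity. The moderate-contrast Gaussian form emulates greyscale pixel
#' values of photographs of leafy scenes: camera pixel values are
#' gamma-compressed luminance, so their distribution is roughly symmetric
#' with mild contrast rather than heavy-tailed.
#'
#' @param nx,ny field dimensions in pixels (both >= 8).
#' @param seed integer seed; fields are bit-reproducible.
#' @param contrast target RMS contrast of the coefficients before the
#'   positivity floor.
#' @param lo lower positivity bound applied before mean renormalisation.
#' @return an object of class `pvc_lumfield` with fields `coefficients`
#'   (strictly positive Nx x Ny matrix with mean 1) and `seed`.
#' @export
synth_luminance_field <- function(nx, ny, seed, contrast = 0.3,
                                  lo = 0.05) {
  stopifnot(nx >= 8, ny >= 8, contrast > 0, lo > 0)
  z <- with_seed(seed, {
    wn <- matrix(stats::rnorm(nx * ny), nx, ny)
    fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
    fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
    f <- sqrt(outer(fx^2, fy^2, "+"))
    amp <- ifelse(f > 0, 1 / f, 0)
    Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (nx * ny)
  })
  z <- (z - mean(z)) / stats::sd(z)
  coef <- pmax(1 + contrast * z, lo)
  structure(list(coefficients = coef / mean(coef), seed = seed),
            class = "pvc_lumfield")
}

#' Fitted log-log slope of a field's radially averaged amplitude spectrum
#'
#' Diagnostic for [synth_luminance_field()]: computes the 2-D amplitude
#' spectrum, averages it in annular frequency bins, and least-squares fits
#' log-amplitude against log-frequency. A 1/f field has slope close to -1.
#'
#' @param field a matrix or a `pvc_lumfield`.
#' @param f_range frequency band (cycles/pixel) used for the fit.
#' @return the fitted slope (a single number).
#' @export
amplitude_spectrum_slope <- function(field, f_range = c(0.02, 0.4)) {
  m <- if (inherits(field, "pvc_lumfield")) field$coefficients else field
  nx <- nrow(m)
  ny <- ncol(m)
  a <- Mod(stats::fft(m - mean(m)))
  fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
  fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
  f <- sqrt(outer(fx^2, fy^2, "+"))
  keep <- f >= f_range[1] & f <= f_range[2]
  bins <- cut(log(f[keep]), breaks = 24)
  lf <- tapply(log(f[keep]), bins, mean)
  la <- tapply(log(a[keep]), bins, mean)
  ok <- is.finite(lf) & is.finite(la)
  unname(stats::coef(stats::lm(la[ok] ~ lf[ok]))[2])
}

#' Assemble a hyperspectral grating image
#'
#' Builds the Nx x Ny x Nlambda radiance stack for one target/background
#' spectrum pair, in pipeline order: (1) apply the illuminant to both
#' spectra; (2) per-pixel convex mixture weighted by the reference pattern,
#' `p*s_target + (1-p)*s_background`; (3) multiply each pixel's spectrum by
#' its luminance coefficient; (4) convolve each wavelength plane with its
#' Airy point-spread function (wrap-around boundary; the stimulus is
#' periodic in x).
#'
#' @param pattern a [make_grating()] reference pattern.
#' @param target,background [spectrum()] objects on a shared grid.
#' @param illuminant optional illuminant [spectrum()]; `NULL` means unit
#'   illuminant.
#' @param lum optional [synth_luminance_field()] with matching dimensions;
#'   `NULL` means coefficients all 1 (no luminance variation).
#' @param optics optional [optics_model()]; `NULL` skips chromatic blurring.
#' @return an object of class `pvc_image`: fields `values` (Nx x Ny x
#'   Nlambda array), `grid`, `pattern`, `label`.
#' @export
assemble_image <- function(pattern, target, background, illuminant = NULL,
                           lum = NULL, optics = NULL) {
  if (!same_grid(target$grid, background$grid)) {
    stop("target and background grids differ")
  }
  grid <- target$grid
  st <- target$values
  sb <- background$values
  if (!is.null(illuminant)) {
    if (!same_grid(illuminant$grid, grid)) stop("illuminant grid differs")
    st <- st * illuminant$values
    sb <- sb * illuminant$values
  }
  p <- pattern$values
  nx <- nrow(p)
  ny <- ncol(p)
  pv <- as.vector(p)
  # (npx x nlambda) layout; pixel index runs down x first
  m <- outer(pv, st) + outer(1 - pv, sb)
  if (!is.null(lum)) {
    cf <- lum$coefficients
    if (!all(dim(cf) == c(nx, ny))) {
      stop("luminance field dimensions do not match the pattern")
    }
    m <- m * as.vector(cf)
  }
  if (!is.null(optics)) {
    for (j in seq_len(grid$n)) {
      kern <- airy_psf(grid$values[j], optics)
      m[, j] <- as.vector(conv2_circular(matrix(m[, j], nx, ny), kern))
    }
  }
  structure(
    list(values = array(m, dim = c(nx, ny, grid$n)), grid = grid,
         pattern = pattern, label = target$label),
    class = "pvc_image"
  )
}

# npx x nlambda matrix view of a spectral image
image_matrix <- function(image) {
  d <- dim(image$values)
  matrix(image$values, d[1] * d[2], d[3])
}
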