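#' Random L/M cone mosaic
#'
#' Square-grid photoreceptor mosaic with independently, identically
#' distributed cone identities; each position is L with probability
#' `ratio`, otherwise M (locally random arrangement, default 1:1).
#'
#' @param nx,ny mosaic dimensions in cones.
#' @param ratio probability that a cone is L.
#' @param seed integer seed.
#' @return an object of class `pvc_mosaic` with fields `labels`
#'   (Nx x Ny character matrix over \{"M","L"\}), `ratio`, `seed`.
#' @export
make_mosaic <- function(nx, ny, ratio = 0.5, seed = 1) {
  stopifnot(nx >= 1, ny >= 1, ratio >= 0, ratio <= 1)
  labels <- with_seed(seed, {
    matrix(ifelse(stats::runif(nx * ny) < ratio, "L", "M"), nx, ny)
  })
  structure(list(labels = labels, ratio = ratio, seed = seed),
            class = "pvc_mosaic")
}

#' Govardovskii-type A1 visual pigment absorbance template
#'
#' Returns a function `psi(lambda, lmax)` giving the normalised absorbance
#' (peak 1) of an A1 visual pigment with peak at `lmax`, using the standard
#' alpha-band log-wavelength template plus the short-wave beta band. The
#' template is renormalised to exact peak 1 over a fine wavelength grid
#' before use.
#'
#' @return a function of `(lambda, lmax)`.
#' @export
pigment_template <- function() {
  alpha_beta <- function(lambda, lmax) {
    x <- lmax / lambda
    a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    s_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                      exp(-14.9 * (1.104 - x)) + 0.674)
    lm_beta <- 189 + 0.315 * lmax
    b_beta <- -40.5 + 0.195 * lmax
    s_beta <- 0.26 * exp(-((lambda - lm_beta) / b_beta)^2)
    s_alpha + s_beta
  }
  function(lambda, lmax) {
    fine <- seq(300, 800, by = 0.5)
    peak <- max(alpha_beta(fine, lmax))
    alpha_beta(lambda, lmax) / peak
  }
}

#' Combined ocular media optical density
#'
#' Combined lens plus macular pigment optical density on the wavelength
#' grid. `mode = "human"` is a smooth parametric approximation to standard
#' human values (an exponential lens edge, ~1.7 density at 400 nm falling
#' with a 40 nm constant, plus a Gaussian macular term of peak density 0.35
#' at 460 nm); `mode = "none"` gives zero density (full transmission),
#' useful for tests.
#'
#' @param grid a [wavelength_grid()].
#' @param mode `"human"` or `"none"`.
#' @return nonnegative numeric vector of densities on the grid.
#' @export
ocular_media <- function(grid = wavelength_grid(),
                         mode = c("human", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(rep(0, grid$n))
  lam <- grid$values
  lens <- 1.7 * exp(-(lam - 400) / 40)
  macular <- 0.35 * exp(-((lam - 460) / 35)^2)
  lens + macular
}

#' Cone spectral sensitivity for one peak wavelength
#'
#' Sensitivity through the ocular media:
#' `10^(-Delta(lambda)) * (1 - 10^(-D * psi(lambda, lmax)))`, i.e. media
#' transmission times pigment absorptance (absorbance converted with peak
#' optical density `D`). By default the curve is not rescaled to unit peak;
#' set `normalize = TRUE` to rescale.
#'
#' @param lmax peak absorbance wavelength, nm; must lie in \[440, 620\].
#' @param grid a [wavelength_grid()].
#' @param template a [pigment_template()] function.
#' @param media ocular media density vector on `grid` (see
#'   [ocular_media()]).
#' @param peak_density pigment peak optical density D for the
#'   absorbance-to-absorptance conversion.
#' @param normalize rescale the final curve to peak 1.
#' @return a [spectrum()] with role `"sensitivity"`.
#' @export
cone_fundamental <- function(lmax, grid = wavelength_grid(),
                             template = pigment_template(),
                             media = ocular_media(grid),
                             peak_density = 0.5, normalize = FALSE) {
  if (lmax < 440 || lmax > 620) {
    stop("lmax ", lmax, " nm outside template validity [440, 620]")
  }
  stopifnot(length(media) == grid$n, all(media >= 0))
  psi <- template(grid$values, lmax)
  sens <- 10^(-media) * (1 - 10^(-peak_density * psi))
  if (normalize) sens <- sens / max(sens)
  spectrum(sens, grid, role = "sensitivity",
           label = sprintf("lmax=%g", lmax))
}

#' Per-pixel spectral sensitivity mosaic
#'
#' Assigns the M or L cone fundamental to every mosaic position: pixel
#' (x,y) holds the M prototype when its label is M, otherwise the L
#' prototype. Stored compactly as the two prototype curves plus the label
#' mosaic.
#'
#' @param pair numeric length-2: `c(lmax_m, lmax_l)` in nm.
#' @param mosaic a [make_mosaic()].
#' @param grid a [wavelength_grid()].
#' @param template,media,peak_density see [cone_fundamental()].
#' @return an object of class `pvc_sensmosaic` with fields `m`, `l`
#'   (prototype sensitivity vectors), `pair`, `mosaic`, `grid`.
#' @export
build_sensitivity_mosaic <- function(pair, mosaic, grid = wavelength_grid(),
                                     template = pigment_template(),
                                     media = ocular_media(grid),
                                     peak_density = 0.5) {
  stopifnot(length(pair) == 2)
  m <- cone_fundamental(pair[1], grid, template, media, peak_density)
  l <- cone_fundamental(pair[2], grid, template, media, peak_density)
  structure(list(m = m$values, l = l$values, pair = pair,
                 mosaic = mosaic, grid = grid),
            class = "pvc_sensmosaic")
}

#' Quantal catch matrix
#'
#' Photon catch of every cone: the inner product over wavelength of the
#' pixel's incident radiance spectrum and that cone's spectral sensitivity.
#' Deterministic (no photon noise).
#'
#' @param image a [assemble_image()] spectral image.
#' @param sens a [build_sensitivity_mosaic()] with matching dimensions.
#' @return an Nx x Ny nonnegative matrix.
#' @export
quantal_catch <- function(image, sens) {
  d <- dim(image$values)
  if (!all(d[1:2] == dim(sens$mosaic$labels))) {
    stop("image and sensitivity mosaic dimensions differ")
  }
  if (d[3] != length(sens$m)) stop("spectral dimensions differ")
  pm <- image_matrix(image)
  qm <- pm %*% sens$m
  ql <- pm %*% sens$l
  is_l <- sens$mosaic$labels == "L"
  q <- ifelse(is_l, matrix(ql, d[1], d[2]), matrix(qm, d[1], d[2]))
  q
}

#' Difference-of-Gaussians receptive-field kernels
#'
#' Centre-surround kernels sampled at integer cone offsets across an
#' `nw` x `nw` window centred on one cone, with `W_OFF = -W_ON`. Defaults:
#' single-cone centre sigma 0.25 cones, surround sigma 1.66 cones,
#' surround weight 0.55, 9-cone window. Three constructions are provided:
#'
#' \describe{
#' \item{`"balanced"` (default)}{`W_ON = Nc/sum(Nc) - Ns/sum(Ns)`: both
#'   Gaussians normalised to unit integral, so the kernel has exactly zero
#'   DC response. This is the canonical centre-minus-local-mean opponent
#'   operator: the ON response is positive where the centre cone catches
#'   more than its neighbourhood and negative where it catches less, which
#'   is the behaviour the red-green channel requires (a cell is excited
#'   only when its centre is relatively "redder"/"greener" than the
#'   surround). `omega` is not used: a zero-DC kernel pins the integrated
#'   surround:centre weight at 1.}
#' \item{`"integral"`}{`W_ON = Nc/sum(Nc) - omega * Ns/sum(Ns)`: `omega` is
#'   the integrated surround:centre sensitivity ratio, the quantity
#'   physiological surveys of primate P cells report as ~0.55. The kernel
#'   retains a positive DC response of `1 - omega`.}
#' \item{`"none"`}{`W_ON = Nc - omega * Ns` with unnormalised (peak-1)
#'   Gaussians `N(0, s) = exp(-(dx^2 + dy^2)/(2 s^2))`: `omega` scales the
#'   surround peak amplitude. Centre value is `1 - omega` (0.45 at the
#'   defaults) but the integrated surround weight is then ~`omega *
#'   (sigma_s/sigma_c)^2` times the centre's, which strongly inverts the
#'   kernel's DC response.}
#' }
#'
#' The channel model uses `"balanced"`; the other forms are provided for
#' comparison and sensitivity analyses (see the methods vignette for why).
#'
#' @param sigma_c,sigma_s centre and surround Gaussian SDs, cones.
#' @param omega surround weight (interpretation depends on
#'   `normalization`).
#' @param nw odd window size, cones.
#' @param normalization kernel construction, see Details.
#' @return an object of class `pvc_rf` with fields `on`, `off`, `sigma_c`,
#'   `sigma_s`, `omega`, `nw`, `normalization`.
#' @export
make_receptive_fields <- function(sigma_c = 0.25, sigma_s = 1.66,
                                  omega = 0.55, nw = 9,
                                  normalization = c("balanced", "integral",
                                                    "none")) {
  normalization <- match.arg(normalization)
  stopifnot(nw %% 2 == 1, sigma_c > 0, sigma_s > 0)
  k <- (nw - 1) / 2
  off <- (-k):k
  r2 <- outer(off^2, off^2, "+")
  nc <- exp(-r2 / (2 * sigma_c^2))
  ns <- exp(-r2 / (2 * sigma_s^2))
  w_on <- switch(normalization,
    balanced = nc / sum(nc) - ns / sum(ns),
    integral = nc / sum(nc) - omega * ns / sum(ns),
    none = nc - omega * ns
  )
  structure(list(on = w_on, off = -w_on, sigma_c = sigma_c,
                 sigma_s = sigma_s, omega = omega, nw = as.integer(nw),
                 normalization = normalization),
            class = "pvc_rf")
}

#' Retinal ganglion cell response maps
#'
#' Convolves the quantal catch matrix with the ON and OFF
#' difference-of-Gaussians kernels ("valid" region only: the `nw - 1`
#' border pixels that incur edge artefacts are removed, split symmetrically).
#' The kernels are even-symmetric so convolution equals correlation.
#'
#' @param q quantal catch matrix.
#' @param rf a [make_receptive_fields()].
#' @return an object of class `pvc_rgc`: fields `on`, `off` (each
#'   (Nx-nw+1) x (Ny-nw+1)) with `off == -on`.
#' @export
rgc_responses <- function(q, rf = make_receptive_fields()) {
  g_on <- conv2_valid(q, rf$on)
  structure(list(on = g_on, off = -g_on, nw = rf$nw), class = "pvc_rgc")
}

#' Cone-type identifier masks
#'
#' Binary pointer matrices: `l[x,y] = 1` where the mosaic holds an L cone,
#' 0 otherwise, and `m = 1 - l`.
#'
#' @param mosaic a [make_mosaic()].
#' @return an object of class `pvc_masks` with fields `l` and `m`.
#' @export
identifier_masks <- function(mosaic) {
  l <- (mosaic$labels == "L") * 1
  structure(list(l = l, m = 1 - l), class = "pvc_masks")
}

#' Combine RGC responses into cortical input channels
#'
#' Red-green channel: `O = L * G_ON + M * G_OFF` (L-ON-centre plus
#' M-OFF-centre responses, elementwise mask weighting); luminance channel:
#' `O' = L * G_ON + M * G_ON = G_ON`. Masks are trimmed by the same
#' (nw-1)/2 margin as the response maps so all matrices align.
#'
#' @param g a [rgc_responses()] result.
#' @param masks a [identifier_masks()] result (untrimmed, mosaic-sized).
#' @return list with elements `red_green` and `luminance`, each a matrix of
#'   the trimmed response dimensions.
#' @export
integrate_channels <- function(g, masks) {
  margin <- (g$nw - 1) / 2
  lt <- trim_margin(masks$l, margin)
  mt <- trim_margin(masks$m, margin)
  if (!all(dim(lt) == dim(g$on))) {
    stop("mask and response dimensions do not align after trimming")
  }
  list(red_green = lt * g$on + mt * g$off, luminance = g$on)
}
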