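#' Wavelength sampling grid
#'
#' The spectral sampling grid shared by all spectra, images and cone
#' sensitivities. The default covers the primate visual range 400--700 nm at
#' 4 nm intervals, giving 76 samples.
#'
#' @param start,stop range in nm.
#' @param step sampling interval in nm.
#' @return an object of class `pvc_grid` with fields `start`, `stop`,
#'   `step`, `values` (the sampling positions) and `n`.
#' @examples
#' g <- wavelength_grid()
#' g$n   # 76
#' @export
wavelength_grid <- function(start = 400, stop = 700, step = 4) {
  stopifnot(start < stop, step > 0)
  values <- seq(start, stop, by = step)
  structure(
    list(start = start, stop = stop, step = step,
         values = values, n = length(values)),
    class = "pvc_grid"
  )
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$values, b$values))
}

#' Construct a spectrum on a wavelength grid
#'
#' @param values nonnegative numeric vector, one value per grid sample.
#'   Reflectances are dimensionless in \[0,1\]; illuminants and radiances are
#'   relative quanta.
#' @param grid a [wavelength_grid()].
#' @param role one of `"reflectance"`, `"illuminant"`, `"radiance"`,
#'   `"sensitivity"`.
#' @param label free-text label.
#' @param tol tolerance above 1 permitted for measured reflectances.
#' @return an object of class `pvc_spectrum`.
#' @export
spectrum <- function(values, grid = wavelength_grid(),
                     role = c("reflectance", "illuminant", "radiance",
                              "sensitivity"),
                     label = "", tol = 1e-6) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (length(values) != grid$n) {
    stop("spectrum length ", length(values), " does not match grid (",
         grid$n, " samples)")
  }
  if (any(values < 0)) stop("spectrum values must be nonnegative")
  if (role == "reflectance" && any(values > 1 + tol)) {
    stop("reflectance values exceed 1")
  }
  structure(list(values = values, grid = grid, role = role, label = label),
            class = "pvc_spectrum")
}

#' @export
print.pvc_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s' (%s), %d samples %g-%g nm, range [%.4g, %.4g]>\n",
              x$label, x$role, x$grid$n, x$grid$start, x$grid$stop,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Collection of spectra sharing one wavelength grid
#'
#' @param targets list of [spectrum()] objects (the target spectra, count Nf).
#' @param background optional single [spectrum()] used as the constant
#'   background (e.g. the mean mature leaf), or `NULL` for libraries where
#'   both grating phases are drawn from `targets` (Munsell-style pairing).
#' @param provenance free text describing the source.
#' @return an object of class `pvc_library`.
#' @export
spectral_library <- function(targets, background = NULL, provenance = "") {
  stopifnot(length(targets) >= 1)
  g <- targets[[1]]$grid
  for (s in targets) {
    if (!same_grid(s$grid, g)) stop("all spectra must share one grid")
  }
  if (!is.null(background) && !same_grid(background$grid, g)) {
    stop("background grid differs from target grid")
  }
  structure(list(targets = targets, background = background,
                 grid = g, n = length(targets), provenance = provenance),
            class = "pvc_library")
}

#' @export
print.pvc_library <- function(x, ...) {
  cat(sprintf("<spectral library: %d spectra on %d-sample grid%s%s>\n",
              x$n, x$grid$n,
              if (is.null(x$background)) "" else ", with background",
              if (nzchar(x$provenance)) paste0("; ", x$provenance) else ""))
  invisible(x)
}

# Linear resampling of (wl, values) onto the target grid; identity when the
# input is already on the grid. Negative measurements clip to 0.
resample_onto <- function(wl, values, grid) {
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (min(wl) > grid$start || max(wl) < grid$stop) {
    stop(sprintf("wavelength coverage [%g, %g] does not span [%g, %g] nm",
                 min(wl), max(wl), grid$start, grid$stop))
  }
  out <- stats::approx(wl, values, xout = grid$values)$y
  pmax(out, 0)
}

#' Read spectra from a delimited text file
#'
#' Expects a header row, a first column of wavelengths in nm and one or more
#' spectrum columns. Spectra are linearly resampled onto `grid` and
#' truncated to its range; negative values are clipped to 0.
#'
#' @param path file path (comma- or tab-delimited; inferred from content).
#' @param grid target [wavelength_grid()].
#' @param role role assigned to the spectra (see [spectrum()]).
#' @param tol reflectance tolerance above 1 (see [spectrum()]).
#' @return a [spectral_library()] with one target per value column.
#' @export
read_spectra <- function(path, grid = wavelength_grid(),
                         role = "reflectance", tol = 1e-2) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("need a wavelength column and >=1 spectrum column: ",
                         path)
  wl <- as.numeric(df[[1]])
  if (any(diff(wl) <= 0)) {
    stop("non-monotone wavelength column in ", path)
  }
  if (min(wl) > grid$start || max(wl) < grid$stop) {
    stop(sprintf(
      "%s: wavelength coverage [%g, %g] does not span [%g, %g] nm",
      path, min(wl), max(wl), grid$start, grid$stop))
  }
  targets <- lapply(seq_len(ncol(df) - 1) + 1, function(j) {
    v <- resample_onto(wl, as.numeric(df[[j]]), grid)
    if (role == "reflectance") v <- pmin(v, 1 + tol)
    spectrum(v, grid, role = role, label = names(df)[j], tol = tol)
  })
  spectral_library(targets, provenance = path)
}

#' Pointwise mean spectrum of a library
#'
#' Used to form the constant background from the set of mature-leaf spectra.
#'
#' @param library a [spectral_library()].
#' @return a [spectrum()] whose values are the arithmetic mean at each
#'   wavelength.
#' @export
mean_background <- function(library) {
  m <- rowMeans(vapply(library$targets, function(s) s$values,
                       numeric(library$grid$n)))
  spectrum(m, library$grid, role = library$targets[[1]]$role,
           label = "mean background")
}

#' Apply an illuminant to a reflectance spectrum
#'
#' Element-wise product of the reflectance and the illuminant, giving the
#' incident radiance spectrum.
#'
#' @param s a [spectrum()] (reflectance).
#' @param i a [spectrum()] (illuminant) on the same grid.
#' @return a radiance [spectrum()].
#' @export
apply_illuminant <- function(s, i) {
  if (!same_grid(s$grid, i$grid)) stop("spectrum and illuminant grids differ")
  spectrum(s$values * i$values, s$grid, role = "radiance", label = s$label)
}

#' Generate synthetic reflectance or illuminant spectra
#'
#' Reproducible generator for the spectral families used throughout the
#' package. All families produce smooth nonnegative curves on the grid.
#'
#' \describe{
#' \item{fruit}{Mostly long-pass (sigmoidal) red/orange/yellow reflectance
#'   edges with inflection wavelengths spread over ~500--640 nm, plus a
#'   minority of green-peaked and dark low-reflectance fruits.}
#' \item{leaf}{Chlorophyll-type curves: a green reflectance peak near 550 nm
#'   over a low pedestal with a small red-edge rise, low between-leaf
#'   variance.}
#' \item{munsell}{Smooth low-dimensional basis mixtures spanning diverse
#'   hues (flat, long-pass, green-peaked, short-peaked and descending
#'   components with random weights).}
#' \item{illuminant}{A broad smooth curve, green-biased as in forest shade
#'   light, normalised to mean 1.}
#' }
#'
#' @param family one of `"fruit"`, `"leaf"`, `"munsell"`, `"illuminant"`.
#' @param n number of spectra to generate.
#' @param seed integer seed; the same (family, n, seed, params) always
#'   yields an identical library.
#' @param grid target [wavelength_grid()].
#' @param params optional list of family parameters. For `fruit`:
#'   `frac_green` (default 0.2), `edge_range` (default c(500, 640)). For
#'   `leaf`: `peak_nm` (548), `peak_sd` (6). For `illuminant`: `green_bias`
#'   (default 0.35).
#' @return a [spectral_library()] (role `"illuminant"` for the illuminant
#'   family, `"reflectance"` otherwise).
#' @export
synth_spectra <- function(family = c("fruit", "leaf", "munsell", "illuminant"),
                          n = 1, seed = 1, grid = wavelength_grid(),
                          params = list()) {
  family <- match.arg(family)
  stopifnot(n >= 1)
  lam <- grid$values
  gen <- switch(family,
    fruit = function() synth_fruit(n, lam, params),
    leaf = function() synth_leaf(n, lam, params),
    munsell = function() synth_munsell(n, lam, params),
    illuminant = function() synth_illuminant(n, lam, params)
  )
  vals <- with_seed(seed, gen())
  role <- if (family == "illuminant") "illuminant" else "reflectance"
  targets <- lapply(seq_len(n), function(i) {
    spectrum(vals[, i], grid, role = role,
             label = sprintf("%s_%03d", family, i))
  })
  spectral_library(targets,
                   provenance = sprintf("synthetic %s (seed %d)", family, seed))
}

logistic <- function(x) 1 / (1 + exp(-x))

synth_fruit <- function(n, lam, params) {
  frac_green <- if (!is.null(params$frac_green)) params$frac_green else 0.2
  edge <- if (!is.null(params$edge_range)) params$edge_range else c(500, 640)
  vals <- matrix(0, length(lam), n)
  kind <- sample(c("edge", "green", "dark"), n, replace = TRUE,
                 prob = c(1 - frac_green, frac_green / 2, frac_green / 2))
  for (i in seq_len(n)) {
    if (kind[i] == "edge") {
      base <- stats::runif(1, 0.02, 0.08)
      amp <- stats::runif(1, 0.5, 0.9)
      l0 <- stats::runif(1, edge[1], edge[2])
      k <- stats::runif(1, 8, 25)
      v <- base + amp * logistic((lam - l0) / k)
    } else if (kind[i] == "green") {
      base <- stats::runif(1, 0.02, 0.08)
      h <- stats::runif(1, 0.10, 0.30)
      mu <- stats::runif(1, 520, 580)
      w <- stats::runif(1, 25, 45)
      v <- base + h * exp(-(lam - mu)^2 / (2 * w^2))
    } else {
      base <- stats::runif(1, 0.03, 0.08)
      slope <- stats::runif(1, -2e-4, 2e-4)
      v <- base + slope * (lam - 550)
    }
    vals[, i] <- pmin(pmax(v, 0), 1)
  }
  vals
}

synth_leaf <- function(n, lam, params) {
  peak <- if (!is.null(params$peak_nm)) params$peak_nm else 548
  psd <- if (!is.null(params$peak_sd)) params$peak_sd else 6
  vals <- matrix(0, length(lam), n)
  for (i in seq_len(n)) {
    pedestal <- pmax(stats::rnorm(1, 0.04, 0.005), 0.01)
    h <- pmax(stats::rnorm(1, 0.10, 0.015), 0.03)
    mu <- stats::rnorm(1, peak, psd)
    w <- pmax(stats::rnorm(1, 32, 3), 15)
    rededge <- stats::runif(1, 0.02, 0.05)
    v <- pedestal + h * exp(-(lam - mu)^2 / (2 * w^2)) +
      rededge * logistic((lam - 695) / 6)
    vals[, i] <- pmin(pmax(v, 0), 1)
  }
  vals
}

synth_munsell <- function(n, lam, params) {
  # hue-diverse chips: short-pass (blues), band-pass (greens/yellows) and
  # long-pass (oranges/reds) reflectance features at solid chroma, like a
  # hue circle sampled at medium value
  vals <- matrix(0, length(lam), n)
  kinds <- sample(c("long", "band", "short"), n, replace = TRUE)
  for (i in seq_len(n)) {
    base <- stats::runif(1, 0.04, 0.12)
    amp <- stats::runif(1, 0.30, 0.60)
    v <- base + amp * switch(kinds[i],
      long = logistic((lam - stats::runif(1, 540, 640)) /
                        stats::runif(1, 15, 30)),
      band = exp(-(lam - stats::runif(1, 470, 580))^2 /
                   (2 * stats::runif(1, 40, 80)^2)),
      short = 1 - logistic((lam - stats::runif(1, 440, 540)) /
                             stats::runif(1, 15, 30))
    )
    vals[, i] <- pmin(pmax(v, 0), 1)
  }
  vals
}

#' Scale target spectra to match a background's broadband intensity
#'
#' Rescales each target reflectance so that its broadband radiance under
#' the given illuminant equals the background's, up to a small log-normal
#' scatter — emulating stimulus sets in which targets and background are
#' highly similar in overall intensity so that discrimination must rely on
#' chromatic rather than intensity differences. Scaled reflectances are
#' clipped at 1.
#'
#' @param library a [spectral_library()] with a `background` spectrum.
#' @param illuminant illuminant [spectrum()] used to weight the match.
#' @param scatter standard deviation of the residual log-intensity
#'   difference.
#' @param seed integer seed for the scatter draws.
#' @return a new [spectral_library()] with rescaled targets.
#' @export
match_intensity <- function(library, illuminant, scatter = 0.08, seed = 1) {
  if (is.null(library$background)) {
    stop("library has no background spectrum to match against")
  }
  ib <- sum(library$background$values * illuminant$values)
  ks <- with_seed(seed, stats::rnorm(library$n, 0, scatter))
  targets <- lapply(seq_len(library$n), function(i) {
    s <- library$targets[[i]]
    k <- ib / sum(s$values * illuminant$values) * exp(ks[i])
    spectrum(pmin(s$values * k, 1), s$grid, role = s$role, label = s$label)
  })
  spectral_library(targets, background = library$background,
                   provenance = paste0(library$provenance,
                                       " (intensity-matched)"))
}

synth_illuminant <- function(n, lam, params) {
  bias <- if (!is.null(params$green_bias)) params$green_bias else 0.35
  vals <- matrix(0, length(lam), n)
  for (i in seq_len(n)) {
    mu <- stats::rnorm(1, 555, 8)
    w <- stats::rnorm(1, 80, 5)
    v <- (1 - bias + bias * exp(-(lam - mu)^2 / (2 * w^2))) *
      (0.75 + 0.25 * logistic((lam - 425) / 20))
    vals[, i] <- v / mean(v)
  }
  vals
}
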