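#' Min-max normalisation of a channel output
#'
#' Rescales a channel output matrix to \[0, 1\] before comparison with the
#' reference pattern. A constant matrix (degenerate output, e.g. from an
#' all-zero image) maps to all 0.5 so scoring remains finite mid-search.
#'
#' @param o channel output matrix.
#' @param eps range below which the output counts as constant.
#' @return matrix of the same dimensions with values in \[0, 1\].
#' @export
normalize_output <- function(o, eps = .Machine$double.eps * 4) {
  rng <- range(o)
  if (!is.finite(rng[1]) || !is.finite(rng[2])) stop("non-finite output")
  if (diff(rng) <= eps) {
    return(matrix(0.5, nrow(o), ncol(o)))
  }
  (o - rng[1]) / diff(rng)
}

#' Peak signal-to-noise ratio against the reference pattern
#'
#' `PSNR = 10 log10(peakval^2 / MSE)` in decibels, with `peakval = 1`.
#' A zero MSE (or a value above the ceiling) is capped.
#'
#' @param o_norm normalised channel output (see [normalize_output()]).
#' @param reference trimmed reference pattern matrix in \[0, 1\].
#' @param peakval peak signal value.
#' @param cap ceiling in dB for degenerate (zero-error) comparisons.
#' @return PSNR in dB.
#' @export
psnr <- function(o_norm, reference, peakval = 1, cap = 120) {
  if (!all(dim(o_norm) == dim(reference))) {
    stop("output and reference dimensions differ")
  }
  mse <- mean((o_norm - reference)^2)
  if (mse == 0) return(cap)
  min(10 * log10(peakval^2 / mse), cap)
}

#' Scene configuration for image building
#'
#' Bundles the stimulus settings shared by every image in one simulation.
#'
#' @param spatial_frequency grating frequency, cycles/degree.
#' @param ny vertical size, cones.
#' @param illuminant an illuminant [spectrum()] or `NULL` (unit illuminant).
#' @param lum_var include 1/f luminance variation?
#' @param contrast RMS contrast of the luminance coefficients.
#' @param optics an [optics_model()] or `NULL` to skip chromatic blur.
#' @return a list of class `pvc_scene` (includes the built `pattern`).
#' @export
scene_config <- function(spatial_frequency = 4, ny = 30, illuminant = NULL,
                         lum_var = TRUE, contrast = 0.3,
                         optics = optics_model()) {
  structure(
    list(pattern = make_grating(spatial_frequency, ny),
         spatial_frequency = spatial_frequency, ny = ny,
         illuminant = illuminant, lum_var = lum_var, contrast = contrast,
         optics = optics),
    class = "pvc_scene"
  )
}

#' Build the spectral-image set for one replicate
#'
#' For a library with a constant `background` (fruit vs mean-leaf mode) one
#' image is built per target spectrum. For a library without a background
#' (Munsell-style), each image draws two spectra from the library randomly
#' and without replacement; the redder of the two (longer reflectance
#' centroid wavelength) fills the grating crests and the other the troughs,
#' mirroring the fruit task in which the target class is the redder one (a
#' sign-balanced assignment would make the reference comparison blind to
#' chromatic structure, since the channel output for a swapped pair is the
#' inverted pattern). When luminance variation is on, a fresh 1/f field is
#' generated per image from the replicate's luminance stream.
#'
#' @param library a [spectral_library()].
#' @param scene a [scene_config()].
#' @param seed replicate seed; the luminance and spectrum-draw streams are
#'   derived from it (see [derive_seed()]).
#' @param n_images number of images; defaults to the number of targets.
#' @return list of [assemble_image()] objects.
#' @export
build_image_library <- function(library, scene, seed, n_images = NULL) {
  if (is.null(n_images)) n_images <- library$n
  munsell_mode <- is.null(library$background)
  if (munsell_mode && library$n < 2) {
    stop("random-pair mode needs at least two spectra")
  }
  draws <- if (munsell_mode) {
    lamv <- library$grid$values
    centroid <- vapply(library$targets, function(s) {
      sum(lamv * s$values) / sum(s$values)
    }, numeric(1))
    with_seed(derive_seed(seed, "spectra"), {
      lapply(seq_len(n_images), function(i) {
        ab <- sample.int(library$n, 2)
        if (centroid[ab[1]] < centroid[ab[2]]) ab <- rev(ab)
        ab
      })
    })
  } else {
    lapply(seq_len(n_images), function(i) {
      ((i - 1) %% library$n) + 1
    })
  }
  nx <- nrow(scene$pattern$values)
  ny <- ncol(scene$pattern$values)
  lapply(seq_len(n_images), function(i) {
    if (munsell_mode) {
      target <- library$targets[[draws[[i]][1]]]
      background <- library$targets[[draws[[i]][2]]]
    } else {
      target <- library$targets[[draws[[i]]]]
      background <- library$background
    }
    lum <- if (scene$lum_var) {
      synth_luminance_field(nx, ny, derive_seed(seed, "luminance", i),
                            contrast = scene$contrast)
    } else {
      NULL
    }
    assemble_image(scene$pattern, target, background,
                   illuminant = scene$illuminant, lum = lum,
                   optics = scene$optics)
  })
}

#' Score one peak-sensitivity pair
#'
#' Runs the full retinal pipeline (quantal catch, DoG opponent processing,
#' channel integration) on every image and returns the mean PSNR between
#' the normalised channel output and the trimmed reference pattern, in dB.
#'
#' @param pair `c(lmax_m, lmax_l)` in nm.
#' @param images list of spectral images (see [build_image_library()]), all
#'   sharing one pattern.
#' @param mosaic a [make_mosaic()] of matching dimensions.
#' @param channel `"red_green"` or `"luminance"`.
#' @param grid a [wavelength_grid()].
#' @param template,media,peak_density see [cone_fundamental()].
#' @param rf a [make_receptive_fields()].
#' @param cap PSNR ceiling, dB.
#' @return mean PSNR (z score) in dB.
#' @export
score_pair <- function(pair, images, mosaic,
                       channel = c("red_green", "luminance"),
                       grid = wavelength_grid(),
                       template = pigment_template(),
                       media = ocular_media(grid), peak_density = 0.5,
                       rf = make_receptive_fields(), cap = 120) {
  channel <- match.arg(channel)
  sens <- build_sensitivity_mosaic(pair, mosaic, grid, template, media,
                                   peak_density)
  masks <- identifier_masks(mosaic)
  ref <- trim_margin(images[[1]]$pattern$values, (rf$nw - 1) / 2)
  scores <- vapply(images, function(im) {
    q <- quantal_catch(im, sens)
    g <- rgc_responses(q, rf)
    o <- integrate_channels(g, masks)[[channel]]
    psnr(normalize_output(o), ref, cap = cap)
  }, numeric(1))
  mean(scores)
}

#' Enumerate a constrained search grid of peak-sensitivity pairs
#'
#' All (lmax_m, lmax_l) combinations, by default filtered to
#' `lmax_l >= lmax_m` (the L pigment peaks at the longer wavelength).
#'
#' @param lmax_m candidate M peaks, nm.
#' @param lmax_l candidate L peaks, nm (may be a single fixed value).
#' @param constraint apply `lmax_l >= lmax_m`?
#' @return data.frame with columns `lmax_m`, `lmax_l`.
#' @export
search_grid <- function(lmax_m, lmax_l, constraint = TRUE) {
  pairs <- expand.grid(lmax_m = lmax_m, lmax_l = lmax_l,
                       KEEP.OUT.ATTRS = FALSE)
  if (constraint) pairs <- pairs[pairs$lmax_l >= pairs$lmax_m, ]
  if (nrow(pairs) == 0) stop("empty search grid after applying constraint")
  rownames(pairs) <- NULL
  pairs
}

#' Exhaustive search over peak-sensitivity pairs
#'
#' For every replicate seed: draw a fresh random mosaic, build the image
#' set (with fresh per-image luminance fields when luminance variation is
#' on), score every pair in the grid, and record the best pair. Ties at the
#' top are broken toward the shortest wavelength and flagged.
#'
#' Internally the quantal catches for all distinct peak wavelengths are
#' computed once per image as a single matrix product, so the cost grows
#' with the number of pairs only through the receptive-field convolution.
#'
#' @param pairs a [search_grid()] data.frame.
#' @param library a [spectral_library()].
#' @param scene a [scene_config()].
#' @param seeds integer vector of replicate seeds.
#' @param channel `"red_green"` or `"luminance"`.
#' @param n_images images per replicate (default: number of targets).
#' @param grid,template,media,peak_density,rf,cap see [score_pair()].
#' @param progress print per-replicate progress to stderr?
#' @return an object of class `pvc_search`; see [summary.pvc_search()].
#' @export
exhaustive_search <- function(pairs, library, scene, seeds,
                              channel = c("red_green", "luminance"),
                              n_images = NULL, grid = wavelength_grid(),
                              template = pigment_template(),
                              media = ocular_media(grid),
                              peak_density = 0.5,
                              rf = make_receptive_fields(), cap = 120,
                              progress = FALSE) {
  channel <- match.arg(channel)
  stopifnot(nrow(pairs) >= 1, length(seeds) >= 1)
  lams <- sort(unique(c(pairs$lmax_m, pairs$lmax_l)))
  sens_mat <- vapply(lams, function(lm) {
    cone_fundamental(lm, grid, template, media, peak_density)$values
  }, numeric(grid$n))
  im_idx <- match(pairs$lmax_m, lams)
  il_idx <- match(pairs$lmax_l, lams)
  margin <- (rf$nw - 1) / 2
  ref <- trim_margin(scene$pattern$values, margin)
  nx <- nrow(scene$pattern$values)
  ny <- ncol(scene$pattern$values)
  npair <- nrow(pairs)
  z <- matrix(0, npair, length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    mosaic <- make_mosaic(nx, ny, seed = derive_seed(seed, "mosaic"))
    masks <- identifier_masks(mosaic)
    diffmask <- trim_margin(masks$l - masks$m, margin)
    is_l <- as.vector(mosaic$labels == "L")
    images <- build_image_library(library, scene, seed, n_images)
    acc <- numeric(npair)
    for (im in images) {
      catches <- image_matrix(im) %*% sens_mat  # npx x n_lams
      for (j in seq_len(npair)) {
        q <- catches[, im_idx[j]]
        if (im_idx[j] != il_idx[j]) q[is_l] <- catches[is_l, il_idx[j]]
        g_on <- conv2_valid(matrix(q, nx, ny), rf$on)
        o <- if (channel == "red_green") diffmask * g_on else g_on
        acc[j] <- acc[j] + psnr(normalize_output(o), ref, cap = cap)
      }
    }
    z[, si] <- acc / length(images)
    if (progress) {
      message(sprintf("replicate %d/%d done (seed %d)",
                      si, length(seeds), seed))
    }
  }
  argmax <- do.call(rbind, lapply(seq_along(seeds), function(si) {
    best <- best_pair(pairs, z[, si])
    data.frame(seed = seeds[si], lmax_m = best$lmax_m,
               lmax_l = best$lmax_l, z = best$z, tie = best$tie)
  }))
  structure(
    list(pairs = pairs, z = z, z_mean = rowMeans(z), seeds = seeds,
         channel = channel, argmax = argmax,
         spatial_frequency = scene$spatial_frequency,
         n_images = if (is.null(n_images)) library$n else n_images),
    class = "pvc_search"
  )
}

# tie-break: highest z, then shortest lmax_m, then shortest lmax_l
best_pair <- function(pairs, zvec) {
  top <- which(zvec == max(zvec))
  tie <- length(top) > 1
  ord <- order(pairs$lmax_m[top], pairs$lmax_l[top])
  k <- top[ord[1]]
  list(lmax_m = pairs$lmax_m[k], lmax_l = pairs$lmax_l[k],
       z = zvec[k], tie = tie)
}

#' Replicate statistics of the optimal M peak
#'
#' Mean, standard deviation and normal-approximation 95% confidence
#' interval (mean +/- 1.96 sd/sqrt(n)) of the per-replicate optimal
#' `lmax_m`.
#'
#' @param surface a `pvc_search` object, or a numeric vector of
#'   per-replicate optima.
#' @param level confidence level.
#' @return data.frame with columns `mean`, `sd`, `ci_lo`, `ci_hi`, `n`,
#'   `ties`.
#' @export
aggregate_optima <- function(surface, level = 0.95) {
  if (inherits(surface, "pvc_search")) {
    x <- surface$argmax$lmax_m
    ties <- sum(surface$argmax$tie)
  } else {
    x <- as.numeric(surface)
    ties <- 0L
  }
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else 0
  zq <- stats::qnorm(1 - (1 - level) / 2)
  half <- zq * s / sqrt(n)
  data.frame(mean = m, sd = s, ci_lo = m - half, ci_hi = m + half,
             n = n, ties = ties)
}

#' Compare per-replicate optima between two conditions
#'
#' Two-sample t-test (Welch by default) on per-replicate optimal `lmax_m`
#' values, e.g. between the highest and lowest spatial frequencies.
#'
#' @param optima_a,optima_b numeric vectors of per-replicate optima.
#' @param method `"welch"` (unequal variances) or `"pooled"`.
#' @return an object of class `htest` (see [stats::t.test()]).
#' @export
compare_frequencies <- function(optima_a, optima_b,
                                method = c("welch", "pooled")) {
  method <- match.arg(method)
  stats::t.test(optima_a, optima_b, var.equal = (method == "pooled"))
}

#' @export
print.pvc_search <- function(x, ...) {
  cat(sprintf("<performance surface: %s channel, %d pairs x %d replicates, %g cpd>\n",
              x$channel, nrow(x$pairs), length(x$seeds),
              x$spatial_frequency))
  b <- best_pair(x$pairs, x$z_mean)
  cat(sprintf("  best mean z: %.3f dB at (lmax_m = %g, lmax_l = %g)\n",
              b$z, b$lmax_m, b$lmax_l))
  invisible(x)
}

#' Summarise an exhaustive search
#'
#' @param object a `pvc_search`.
#' @param ... unused.
#' @return list with the best mean-z pair, per-replicate optimum table and
#'   the aggregate statistics of the optimal M peak.
#' @export
summary.pvc_search <- function(object, ...) {
  out <- list(best = best_pair(object$pairs, object$z_mean),
              argmax = object$argmax,
              optima = aggregate_optima(object),
              channel = object$channel,
              spatial_frequency = object$spatial_frequency)
  class(out) <- "summary.pvc_search"
  out
}

#' @export
print.summary.pvc_search <- function(x, ...) {
  cat(sprintf("Exhaustive search (%s channel, %g cpd)\n", x$channel,
              x$spatial_frequency))
  cat(sprintf("  best mean-z pair: lmax_m = %g nm, lmax_l = %g nm (z = %.3f dB)\n",
              x$best$lmax_m, x$best$lmax_l, x$best$z))
  o <- x$optima
  cat(sprintf("  optimal lmax_m over %d replicates: %.2f nm (sd %.2f, 95%% CI [%.2f, %.2f])\n",
              o$n, o$mean, o$sd, o$ci_lo, o$ci_hi))
  if (o$ties > 0) cat(sprintf("  note: %d replicate(s) had tied optima\n", o$ties))
  invisible(x)
}

#' @export
coef.pvc_search <- function(object, ...) {
  b <- best_pair(object$pairs, object$z_mean)
  c(lmax_m = b$lmax_m, lmax_l = b$lmax_l)
}

#' Plot a performance surface
#'
#' For a two-dimensional grid, an image map of mean z over
#' (lmax_m, lmax_l); for a fixed-L search, the mean z curve against lmax_m
#' with the per-replicate optimum marked.
#'
#' @param x a `pvc_search`.
#' @param ... passed to the underlying base graphics call.
#' @export
plot.pvc_search <- function(x, ...) {
  ms <- sort(unique(x$pairs$lmax_m))
  ls <- sort(unique(x$pairs$lmax_l))
  if (length(ls) > 1) {
    zmat <- matrix(NA_real_, length(ms), length(ls))
    zmat[cbind(match(x$pairs$lmax_m, ms), match(x$pairs$lmax_l, ls))] <-
      x$z_mean
    graphics::image(ms, ls, zmat, col = grDevices::hcl.colors(64, "Blue-Red"),
                    xlab = expression(lambda[max]^M ~ "(nm)"),
                    ylab = expression(lambda[max]^L ~ "(nm)"),
                    main = sprintf("mean z (dB), %s channel", x$channel), ...)
    b <- best_pair(x$pairs, x$z_mean)
    graphics::points(b$lmax_m, b$lmax_l, pch = 17, cex = 1.4)
  } else {
    graphics::plot(ms, x$z_mean[order(x$pairs$lmax_m)], type = "b",
                   xlab = expression(lambda[max]^M ~ "(nm)"),
                   ylab = "mean z (dB)",
                   main = sprintf("%s channel, lmax_l = %g nm",
                                  x$channel, ls), ...)
    graphics::abline(v = mean(x$argmax$lmax_m), lty = 2)
  }
  invisible(x)
}

#' Write a performance surface as long-format CSV
#'
#' Columns: `lmax_m`, `lmax_l`, `seed`, `channel`, `z`.
#'
#' @param surface a `pvc_search`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_surface_csv <- function(surface, path) {
  rows <- do.call(rbind, lapply(seq_along(surface$seeds), function(si) {
    data.frame(lmax_m = surface$pairs$lmax_m,
               lmax_l = surface$pairs$lmax_l,
               seed = surface$seeds[si],
               channel = surface$channel,
               z = surface$z[, si])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
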