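#' Configuration for one of the four standard simulation sets
#'
#' The four named experiments and their full-scale defaults:
#'
#' | experiment       | lmax_m grid    | lmax_l        | step | lum. var. | reps |
#' |------------------|----------------|---------------|------|-----------|------|
#' | `varied_spectra` | 490--560       | 490--560      | 10   | yes       | 50   |
#' | `lw_limit`       | 490--598       | 490--598      | 4    | yes       | 50   |
#' | `optimal_m`      | 515--535       | fixed 562     | 1    | yes       | 100  |
#' | `lum_var`        | 440--560       | fixed 562     | 10   | no        | 100  |
#'
#' `varied_spectra` uses a diverse-hue (Munsell-like) library with random
#' pairing; the others use fruit targets against the mean-leaf background.
#' The two-peak grids apply the constraint `lmax_l >= lmax_m`. By default a
#' reduced-scale profile is used (10 replicates, 100 synthetic fruit
#' spectra) so a full set runs in minutes; pass `full_scale = TRUE` for the
#' full replicate counts and library sizes.
#'
#' @param experiment experiment name (see table).
#' @param reps replicates (differently seeded mosaics); `NULL` = profile
#'   default.
#' @param spatial_frequencies grating frequencies, cycles/degree.
#' @param master_seed integer seed from which all replicate, mosaic,
#'   luminance and spectrum-draw seeds are derived.
#' @param full_scale use the full-scale profile?
#' @param n_targets,n_leaves synthetic library sizes (ignored when
#'   `spectra_path` is given); `NULL` = profile default.
#' @param spectra_path optional path to a delimited file of measured target
#'   reflectances (see [read_spectra()]); for fruit/leaf experiments
#'   `leaves_path` must then also be given.
#' @param leaves_path optional path to measured leaf reflectances.
#' @param illuminant_path optional path to a measured illuminant; default
#'   is the synthetic green-biased forest illuminant.
#' @param channels channels to score; `optimal_m` defaults to both.
#' @param contrast luminance-coefficient log-contrast (see
#'   [synth_luminance_field()]).
#' @param intensity_match rescale synthetic fruit targets so their
#'   broadband radiance matches the leaf background (see
#'   [match_intensity()]); emulates stimulus sets whose target and
#'   background classes are highly similar in intensity.
#' @return a list of class `pvc_config`.
#' @export
experiment_config <- function(experiment = c("varied_spectra", "lw_limit",
                                             "optimal_m", "lum_var"),
                              reps = NULL,
                              spatial_frequencies = c(4, 2, 1, 0.5),
                              master_seed = 1, full_scale = FALSE,
                              n_targets = NULL, n_leaves = NULL,
                              spectra_path = NULL, leaves_path = NULL,
                              illuminant_path = NULL,
                              channels = NULL, contrast = 0.3,
                              intensity_match = TRUE) {
  experiment <- match.arg(experiment)
  defaults <- switch(experiment,
    varied_spectra = list(lmax_m = seq(490, 560, 10),
                          lmax_l = seq(490, 560, 10),
                          lum_var = TRUE, dataset = "munsell",
                          reps_full = 50),
    lw_limit = list(lmax_m = seq(490, 598, 4),
                    lmax_l = seq(490, 598, 4),
                    lum_var = TRUE, dataset = "fruit_leaf", reps_full = 50),
    optimal_m = list(lmax_m = seq(515, 535, 1), lmax_l = 562,
                     lum_var = TRUE, dataset = "fruit_leaf",
                     reps_full = 100),
    lum_var = list(lmax_m = seq(440, 562, 10), lmax_l = 562,
                   lum_var = FALSE, dataset = "fruit_leaf",
                   reps_full = 100)
  )
  if (is.null(reps)) reps <- if (full_scale) defaults$reps_full else 10
  if (is.null(n_targets)) n_targets <- if (full_scale) 1139 else 100
  if (is.null(n_leaves)) n_leaves <- 409
  if (is.null(channels)) {
    channels <- if (experiment == "optimal_m") {
      c("red_green", "luminance")
    } else {
      "red_green"
    }
  }
  structure(
    list(experiment = experiment, lmax_m = defaults$lmax_m,
         lmax_l = defaults$lmax_l, lum_var = defaults$lum_var,
         dataset = defaults$dataset, reps = reps,
         spatial_frequencies = spatial_frequencies,
         master_seed = master_seed, full_scale = full_scale,
         n_targets = n_targets, n_leaves = n_leaves,
         spectra_path = spectra_path, leaves_path = leaves_path,
         illuminant_path = illuminant_path, channels = channels,
         contrast = contrast, intensity_match = intensity_match),
    class = "pvc_config"
  )
}

# Resolve the spectral library and illuminant a config asks for.
config_library <- function(config, grid = wavelength_grid()) {
  seed <- derive_seed(config$master_seed, "spectra")
  if (!is.null(config$spectra_path)) {
    if (!file.exists(config$spectra_path)) {
      stop("spectra file not found: ", config$spectra_path,
           " (expected delimited text: wavelength column + spectra columns)")
    }
    targets <- read_spectra(config$spectra_path, grid)
    if (config$dataset == "fruit_leaf") {
      if (is.null(config$leaves_path) || !file.exists(config$leaves_path)) {
        stop("fruit/leaf experiments need leaves_path ",
             "(delimited text: wavelength column + leaf spectra columns)")
      }
      leaves <- read_spectra(config$leaves_path, grid)
      library <- spectral_library(targets$targets,
                                  background = mean_background(leaves),
                                  provenance = config$spectra_path)
    } else {
      library <- targets
    }
  } else if (config$dataset == "munsell") {
    library <- synth_spectra("munsell", n = config$n_targets, seed = seed,
                             grid = grid)
  } else {
    fruit <- synth_spectra("fruit", n = config$n_targets, seed = seed,
                           grid = grid)
    leaves <- synth_spectra("leaf", n = config$n_leaves,
                            seed = derive_seed(config$master_seed,
                                               "spectra", 1), grid = grid)
    library <- spectral_library(fruit$targets,
                                background = mean_background(leaves),
                                provenance = fruit$provenance)
  }
  illuminant <- if (!is.null(config$illuminant_path)) {
    if (!file.exists(config$illuminant_path)) {
      stop("illuminant file not found: ", config$illuminant_path)
    }
    lib <- read_spectra(config$illuminant_path, grid, role = "illuminant")
    lib$targets[[1]]
  } else {
    synth_spectra("illuminant", n = 1,
                  seed = derive_seed(config$master_seed, "spectra", 2),
                  grid = grid)$targets[[1]]
  }
  if (!is.null(library$background) && isTRUE(config$intensity_match)) {
    library <- match_intensity(library, illuminant,
                               seed = derive_seed(config$master_seed,
                                                  "spectra", 3))
  }
  list(library = library, illuminant = illuminant)
}

#' Run one full simulation set
#'
#' For each spatial frequency: build the grating, build the image set per
#' replicate (with fresh mosaics, and fresh luminance fields when luminance
#' variation is on), score every pair in the grid, and aggregate the
#' per-replicate optima. A two-sample t-test compares the optima at the
#' highest and lowest spatial frequencies. Fully reproducible from
#' `master_seed`.
#'
#' @param config an [experiment_config()].
#' @param progress print progress to stderr?
#' @return an object of class `pvc_run`: config echo, per-frequency (and
#'   per-channel) `pvc_search` surfaces, an optima table, the t-test, the
#'   seed ledger and elapsed time.
#' @export
run_experiment <- function(config, progress = FALSE) {
  t0 <- Sys.time()
  grid <- wavelength_grid()
  dat <- config_library(config, grid)
  pairs <- search_grid(config$lmax_m, config$lmax_l)
  seeds <- vapply(seq_len(config$reps), function(r) {
    derive_seed(config$master_seed, "replicate", r)
  }, integer(1))
  surfaces <- list()
  optima <- NULL
  for (sf in config$spatial_frequencies) {
    scene <- scene_config(spatial_frequency = sf,
                          illuminant = dat$illuminant,
                          lum_var = config$lum_var,
                          contrast = config$contrast)
    for (ch in config$channels) {
      if (progress) {
        message(sprintf("experiment %s: %g cpd, %s channel, %d pairs x %d reps",
                        config$experiment, sf, ch, nrow(pairs),
                        length(seeds)))
      }
      s <- exhaustive_search(pairs, dat$library, scene, seeds, channel = ch,
                             grid = grid, progress = progress)
      key <- sprintf("sf%g_%s", sf, ch)
      surfaces[[key]] <- s
      st <- aggregate_optima(s)
      optima <- rbind(optima, cbind(
        data.frame(spatial_frequency = sf, channel = ch), st))
    }
  }
  rg <- optima[optima$channel == "red_green", ]
  ttest <- NULL
  if (length(config$spatial_frequencies) >= 2) {
    hi <- sprintf("sf%g_red_green", max(config$spatial_frequencies))
    lo <- sprintf("sf%g_red_green", min(config$spatial_frequencies))
    if (!is.null(surfaces[[hi]]) && !is.null(surfaces[[lo]])) {
      ttest <- compare_frequencies(surfaces[[hi]]$argmax$lmax_m,
                                   surfaces[[lo]]$argmax$lmax_m)
    }
  }
  structure(
    list(config = config, surfaces = surfaces, optima = optima,
         t_test = ttest,
         seed_ledger = data.frame(replicate = seq_along(seeds),
                                  seed = seeds),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "pvc_run"
  )
}

#' @export
print.pvc_run <- function(x, ...) {
  cat(sprintf("<experiment '%s': %d replicates, %s cpd, %.1f s>\n",
              x$config$experiment, x$config$reps,
              paste(x$config$spatial_frequencies, collapse = "/"),
              x$elapsed_s))
  print(x$optima, row.names = FALSE)
  if (!is.null(x$t_test)) {
    cat(sprintf("highest vs lowest frequency: t = %.3f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  }
  invisible(x)
}

#' Write a run result to CSV + JSON
#'
#' Writes every performance surface in long format to
#' `<stem>_surface.csv` and a JSON summary (config, optima, t-test) to
#' `<stem>_summary.json`.
#'
#' @param run a [run_experiment()] result.
#' @param stem output path stem.
#' @return paths of the files written, invisibly.
#' @export
write_run <- function(run, stem) {
  rows <- do.call(rbind, lapply(names(run$surfaces), function(key) {
    s <- run$surfaces[[key]]
    do.call(rbind, lapply(seq_along(s$seeds), function(si) {
      data.frame(spatial_frequency = s$spatial_frequency,
                 channel = s$channel,
                 lmax_m = s$pairs$lmax_m, lmax_l = s$pairs$lmax_l,
                 seed = s$seeds[si], z = s$z[, si])
    }))
  }))
  csv <- paste0(stem, "_surface.csv")
  jsn <- paste0(stem, "_summary.json")
  utils::write.csv(rows, csv, row.names = FALSE)
  summ <- list(
    config = run$config[c("experiment", "reps", "spatial_frequencies",
                          "master_seed", "full_scale", "n_targets",
                          "lum_var", "channels")],
    optima = run$optima,
    t_test = if (is.null(run$t_test)) NULL else
      list(statistic = unname(run$t_test$statistic),
           p_value = run$t_test$p.value),
    elapsed_s = run$elapsed_s
  )
  jsonlite::write_json(summ, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, jsn))
}
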