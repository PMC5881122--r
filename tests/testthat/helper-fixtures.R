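# Shared fixtures, built once per test run. Everything is generated in code;
# no data files.

GRID <- wavelength_grid()
ILLUM <- synth_spectra("illuminant", n = 1, seed = 42)$targets[[1]]
LEAVES <- synth_spectra("leaf", n = 60, seed = 12)
MEAN_LEAF <- mean_background(LEAVES)
FRUIT <- synth_spectra("fruit", n = 30, seed = 11)
FRUIT_LIB <- match_intensity(
  spectral_library(FRUIT$targets, background = MEAN_LEAF),
  ILLUM, seed = 7
)

# Brute-force quantal catch: explicit triple loop over x, y, lambda.
oracle_quantal_catch <- function(image, sens) {
  d <- dim(image$values)
  q <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      cvec <- if (sens$mosaic$labels[x, y] == "L") sens$l else sens$m
      acc <- 0
      for (k in seq_len(d[3])) acc <- acc + image$values[x, y, k] * cvec[k]
      q[x, y] <- acc
    }
  }
  q
}

# Brute-force DoG response at a single interior pixel (1-based, centre
# coordinates in the untrimmed image).
oracle_dog_at <- function(q, kernel, x, y) {
  k <- (nrow(kernel) - 1) / 2
  acc <- 0
  for (dx in -k:k) {
    for (dy in -k:k) {
      acc <- acc + kernel[dx + k + 1, dy + k + 1] * q[x + dx, y + dy]
    }
  }
  acc
}

# Independent radially binned amplitude-spectrum slope (distinct code path
# from amplitude_spectrum_slope: per-pixel log-log regression, no binning).
oracle_spectrum_slope <- function(m, f_range = c(0.02, 0.4)) {
  nx <- nrow(m)
  ny <- ncol(m)
  a <- Mod(stats::fft(m - mean(m)))
  fx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1) / nx
  fy <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1) / ny
  f <- sqrt(outer(fx^2, fy^2, "+"))
  keep <- f >= f_range[1] & f <= f_range[2] & a > 0
  unname(stats::coef(stats::lm(log(a[keep]) ~ log(f[keep])))[2])
}

# Small spectra file on disk for reader tests.
write_spectra_file <- function(wl, mat, path, sep = ",") {
  df <- data.frame(wavelength = wl)
  for (j in seq_len(ncol(mat))) df[[paste0("s", j)]] <- mat[, j]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
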