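#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus a named stream (and optional
#' index) to a new integer seed, so that independent sources of randomness
#' (mosaic layout, luminance fields, spectrum draws, replicates) can be
#' varied one at a time. All derived seeds stay below 2^31.
#'
#' @param master integer master seed.
#' @param stream character stream name, one of `"mosaic"`, `"luminance"`,
#'   `"spectra"`, `"replicate"`, `"image"`.
#' @param index nonnegative integer sub-index within the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream = "replicate", index = 0L) {
  codes <- c(mosaic = 1, luminance = 2, spectra = 3, replicate = 4, image = 5)
  if (!stream %in% names(codes)) {
    stop("unknown seed stream: ", stream)
  }
  m <- as.double(master) %% 2147483647
  s <- (m * 69069 + codes[[stream]] * 1000003 + as.double(index) * 10007) %%
    2147483629
  as.integer(s + 1)
}

# Run code with a temporary RNG state; restores .Random.seed afterwards so
# generator calls do not perturb the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Valid-region 2-D convolution of matrix `x` with an odd-sized symmetric
# kernel `k` (correlation == convolution for the kernels used here).
# Output dims: (nrow(x)-nk+1) x (ncol(x)-nk+1).
conv2_valid <- function(x, k) {
  nk <- nrow(k)
  stopifnot(nk == ncol(k), nk %% 2 == 1)
  nx <- nrow(x)
  ny <- ncol(x)
  if (nx < nk || ny < nk) {
    stop("input (", nx, "x", ny, ") smaller than kernel window (", nk, ")")
  }
  ox <- nx - nk + 1
  oy <- ny - nk + 1
  out <- matrix(0, ox, oy)
  for (i in seq_len(nk)) {
    for (j in seq_len(nk)) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * x[i:(i + ox - 1), j:(j + oy - 1), drop = FALSE]
      }
    }
  }
  out
}

# Circular (wrap-around) 2-D convolution via FFT. The kernel is centred:
# element (0,0) of the kernel lands on the pixel itself. Kernel may be
# larger than the image; excess wraps (modular accumulation).
conv2_circular <- function(x, k) {
  nx <- nrow(x)
  ny <- ncol(x)
  kc <- (dim(k) + 1) / 2
  kpad <- matrix(0, nx, ny)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      ii <- ((i - kc[1]) %% nx) + 1
      jj <- ((j - kc[2]) %% ny) + 1
      kpad[ii, jj] <- kpad[ii, jj] + k[i, j]
    }
  }
  Re(stats::fft(stats::fft(x) * stats::fft(kpad), inverse = TRUE)) / (nx * ny)
}

# Symmetric border trim: drop `margin` rows/cols on every side.
trim_margin <- function(x, margin) {
  if (margin == 0) return(x)
  nx <- nrow(x)
  ny <- ncol(x)
  if (nx <= 2 * margin || ny <= 2 * margin) {
    stop("matrix too small to trim ", margin, " pixels per side")
  }
  x[(margin + 1):(nx - margin), (margin + 1):(ny - margin), drop = FALSE]
}
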