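# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: morphology by explicit set translation, optics
# by direct Rayleigh-Sommerfeld point summation and the paraxial
# Gaussian-beam closed form.

# --- brute-force binary morphology (set translation) ---------------------

se_cells <- function(se) {
  idx <- which(se$footprint, arr.ind = TRUE)
  cbind(idx[, 1L] - se$origin[1L], idx[, 2L] - se$origin[2L])
}

brute_erode <- function(f, se) {
  cells <- se_cells(se)
  out <- matrix(FALSE, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(f))) {
      ok <- TRUE
      for (k in seq_len(nrow(cells))) {
        r <- i + cells[k, 1L]; c <- j + cells[k, 2L]
        if (r < 1L || r > nrow(f) || c < 1L || c > ncol(f) || !f[r, c]) {
          ok <- FALSE
          break
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

brute_dilate <- function(f, se) {
  # reflected element about the origin: out(e) true iff any f(e - g)
  cells <- se_cells(se)
  out <- matrix(FALSE, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(f))) {
      hit <- FALSE
      for (k in seq_len(nrow(cells))) {
        r <- i - cells[k, 1L]; c <- j - cells[k, 2L]
        if (r >= 1L && r <= nrow(f) && c >= 1L && c <= ncol(f) && f[r, c]) {
          hit <- TRUE
          break
        }
      }
      out[i, j] <- hit
    }
  }
  out
}

brute_open <- function(f, se) brute_dilate(brute_erode(f, se), se)
brute_close <- function(f, se) brute_erode(brute_dilate(f, se), se)
brute_oc <- function(f, s1, s2) brute_close(brute_open(f, s1), s2)
brute_co <- function(f, s1, s2) brute_open(brute_close(f, s1), s2)

random_mask <- function(n = 32L, p = 0.5) matrix(runif(n * n) < p, n, n)

# --- direct Rayleigh-Sommerfeld axial intensity for an aperture ----------

# First RS solution evaluated at the on-axis point behind the grid centre,
# using Babinet's principle for a plane wave through 1 - disk:
# U = exp(ikz) - sum_{disk px} (z / (i lambda)) exp(ikr) / r^2 dA
rs_axial_intensity <- function(blocked, pitch, wavelength, z,
                               center = dim(blocked) / 2) {
  k <- 2 * pi / wavelength
  idx <- which(blocked, arr.ind = TRUE)
  dx <- (idx[, 1L] - center[1L]) * pitch
  dy <- (idx[, 2L] - center[2L]) * pitch
  r <- sqrt(z^2 + dx^2 + dy^2)
  integ <- sum((z / (1i * wavelength)) * exp(1i * k * r) / r^2) * pitch^2
  Mod(exp(1i * k * z) - integ)^2
}

# --- paraxial Gaussian-beam closed form ----------------------------------

# u0 = exp(-r^2 / w0^2) propagated a distance z; relative field without
# the plane-phase factor exp(ikz).
gaussian_beam_field <- function(r2, w0, wavelength, z) {
  q <- 1 + 1i * z * wavelength / (pi * w0^2)
  (1 / q) * exp(-r2 / (w0^2 * q))
}

# --- shared fixtures -----------------------------------------------------

band_limited_field <- function(n = 64L, pitch = 5.86e-6,
                               wavelength = 500e-9, seed = 1L,
                               keep_frac = 0.25) {
  set.seed(seed)
  v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  g <- frequency_grid(c(n, n), pitch)
  V <- stats::fft(v)
  V[g$f2 > (keep_frac / (2 * pitch))^2] <- 0
  complex_field(stats::fft(V, inverse = TRUE) / length(V), pitch,
                wavelength)
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

test_scene <- function(shape = 200L, seed = 3L, ...) {
  sim_scene(shape = c(shape, shape), pad_shape = 2L * c(shape, shape),
            seed = seed, ...)
}
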