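#' Logarithmic frequency grid for the wavelet transform
#'
#' Frequencies ascending from `f_min` in steps of `2^(1/voices)`, not
#' exceeding `f_max`. The default covers the five physiological bands
#' (0.005--2 Hz) at 12 voices per octave (~104 frequencies), which
#' places 16 grid points inside the neurovascular band IV.
#'
#' @param f_min,f_max Frequency range, Hz.
#' @param voices Voices per octave.
#' @return An object of class `frequency_grid` (list with `frequency`,
#'   `voices`, `range`).
#' @export
frequency_grid <- function(f_min = 0.005, f_max = 2, voices = 12) {
  if (f_min <= 0 || f_max <= f_min) abort("Need 0 < f_min < f_max.")
  n_oct <- log2(f_max / f_min)
  j <- 0:floor(n_oct * voices + 1e-9)
  structure(
    list(frequency = f_min * 2^(j / voices), voices = voices,
         range = c(f_min, f_max)),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat("<frequency_grid> ", length(x$frequency), " frequencies, ",
      signif(min(x$frequency), 4), "-", signif(max(x$frequency), 4),
      " Hz at ", x$voices, " voices/octave\n", sep = "")
  invisible(x)
}

# Fourier factor of the analytic Morlet wavelet: the period/scale
# ratio, so scale = 1 / (fourier_factor^-1 ... ) i.e.
# s = (omega0 + sqrt(2 + omega0^2)) / (4 pi f).
morlet_scale <- function(f, omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)
}

#' Continuous wavelet transform with the analytic Morlet wavelet
#'
#' Computes complex Morlet coefficients on a logarithmic frequency
#' grid by frequency-domain multiplication (zero-padded so circular
#' wrap-around is negligible at every scale), together with a
#' cone-of-influence validity mask that excludes, at each frequency,
#' the edge samples within one e-folding span (`sqrt(2) * scale`) of
#' either end of the record.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate, Hz.
#' @param grid A [frequency_grid()].
#' @param omega0 Dimensionless Morlet central frequency (default 6).
#' @return A `wavelet_spectrum`: list with `coef` (frequencies x
#'   samples, complex), `frequency`, `scale` (s), `coi_valid` (logical
#'   matrix), `fully_masked` (frequencies with no valid sample), `fs`,
#'   `omega0`.
#' @export
morlet_cwt <- function(x, fs, grid = frequency_grid(), omega0 = 6) {
  n <- length(x)
  if (n == 0) abort("Empty series.")
  if (anyNA(x)) abort("Series contains missing values.")
  freq <- grid$frequency
  scales <- morlet_scale(freq, omega0)
  dt <- 1 / fs

  pad_need <- n + ceiling(7 * max(scales) / dt)
  m <- 2^ceiling(log2(pad_need))
  xhat <- fft(c(x, rep(0, m - n)))
  k <- 0:(m - 1)
  w_k <- 2 * pi * ifelse(k <= m / 2, k, k - m) / (m * dt)
  pos <- w_k > 0

  coef <- matrix(0i, length(freq), n)
  for (i in seq_along(freq)) {
    s <- scales[i]
    psihat <- numeric(m)
    psihat[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-(s * w_k[pos] - omega0)^2 / 2)
    coef[i, ] <- (fft(xhat * psihat, inverse = TRUE) / m)[seq_len(n)]
  }

  t <- (seq_len(n) - 1) * dt
  efold <- sqrt(2) * scales
  coi_valid <- outer(efold, t, function(e, tt) tt >= e) &
    outer(efold, rev(t), function(e, tt) tt >= e)
  fully_masked <- rowSums(coi_valid) == 0

  structure(
    list(coef = coef, frequency = freq, scale = scales,
         coi_valid = coi_valid, fully_masked = fully_masked,
         fs = fs, omega0 = omega0, n = n),
    class = "wavelet_spectrum"
  )
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat("<wavelet_spectrum> ", length(x$frequency), " frequencies x ",
      x$n, " samples (fs ", x$fs, " Hz, omega0 ", x$omega0, "); ",
      sum(x$fully_masked), " frequencies fully outside the COI\n", sep = "")
  invisible(x)
}

check_compatible <- function(s1, s2) {
  if (!identical(s1$frequency, s2$frequency) || s1$fs != s2$fs ||
      s1$n != s2$n || s1$omega0 != s2$omega0) {
    abort("Wavelet spectra have mismatched grids; recompute on a common grid.")
  }
}

#' Wavelet power spectrum
#'
#' Time-averaged squared coefficient magnitude per frequency,
#' restricted to COI-valid samples.
#'
#' @param s A `wavelet_spectrum`.
#' @return Tibble with `frequency`, `power`, `n_valid`.
#' @export
wavelet_power <- function(s) {
  nf <- length(s$frequency)
  power <- rep(NA_real_, nf)
  nv <- integer(nf)
  for (i in seq_len(nf)) {
    v <- s$coi_valid[i, ]
    nv[i] <- sum(v)
    if (nv[i] > 0) power[i] <- mean(Mod(s$coef[i, v])^2)
  }
  tibble::tibble(frequency = s$frequency, power = power, n_valid = nv)
}
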