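# Shared fixtures, built in code at test time.

# A short two-trial paradigm (600 s total) used across pipeline tests.
quick_paradigm <- function() {
  build_paradigm(n_trials = 2, task_s = 225, rest_s = 60, lead_in_s = 30)
}

# Band-IV-covering wavelet grid (fast: no sub-band-IV scales).
band4_grid <- function() frequency_grid(0.02, 0.05, 12)

# One synthetic subject through the optical forward model.
quick_recording <- function(seed = 1, kappa = 0.9, systemic = TRUE,
                            noise = TRUE, fs = 10,
                            paradigm = quick_paradigm()) {
  prof <- group_profile(
    "trained", 1,
    coupling = coupling_spec("CPFC-SMA", kappa),
    noise = if (noise) {
      c(cardiac = 0.02, respiratory = 0.01, myogenic = 0.005,
        endothelial = 0.005, white = 0.05)
    } else {
      c(cardiac = 0, respiratory = 0, myogenic = 0, endothelial = 0,
        white = 0)
    }
  )
  hbo <- simulate_region_hbo(paradigm, prof, fs = fs, seed = seed)
  sys_amp <- if (systemic) prof$noise[1:4] else
    c(cardiac = 0, respiratory = 0, myogenic = 0, endothelial = 0)
  forward_optics(hbo, systemic = sys_amp, seed = seed + 1,
                 subject_id = sprintf("sub%03d", seed))
}

# Region-level band-IV WPCO for one pair of series.
band4_wpco <- function(x, y, fs) {
  prof <- coherence_profile(x, y, fs = fs, grid = band4_grid())
  band_average(prof, "IV")$wpco
}

# Direct time-domain Morlet convolution: the brute-force oracle the
# FFT implementation is checked against.
direct_morlet <- function(x, fs, freq, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freq)
  out <- matrix(0i, length(freq), n)
  m <- seq_len(n)
  for (i in seq_along(freq)) {
    s <- scales[i]
    for (nn in seq_len(n)) {
      eta <- (m - nn) * dt / s
      psi_conj <- pi^(-0.25) * exp(-1i * omega0 * eta) * exp(-eta^2 / 2)
      out[i, nn] <- sqrt(dt / s) * sum(x * psi_conj)
    }
  }
  out
}

# Hotelling's T^2 for two groups, and its Wilks/F transforms: the
# independent oracle for the two-group MANOVA.
hotelling_t2 <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  d <- colMeans(X1) - colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S, d))
  n <- n1 + n2
  list(
    t2 = t2,
    lambda = 1 / (1 + t2 / (n - 2)),
    f = t2 * (n - p - 1) / (p * (n - 2)),
    df1 = p, df2 = n - p - 1
  )
}
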