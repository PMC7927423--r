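#' Specify ground-truth inter-regional coupling
#'
#' Defines, for one or more of the ten unordered region pairs, the
#' strength and phase lag of the shared band-limited oscillator that
#' the synthetic generator plants between the two regions. Coupling
#' strength `kappa` is the amplitude fraction of the source region's
#' oscillator mixed into the target region; the magnitude-squared
#' coherence of the two ground-truth band components is then `kappa^2`.
#'
#' @param pair Character vector of pair labels, e.g. `"CPFC-SMA"`
#'   (region order within the label is normalised).
#' @param kappa Coupling strength in `[0, 1]`, recycled.
#' @param phase_lag Phase lag in radians applied to the shared
#'   component in the second region, recycled.
#' @param band Frequency band of the shared oscillator: a band label
#'   (default `"IV"`, 0.02--0.05 Hz) or `c(low, high)` in Hz.
#' @return A tibble with one row per pair (class `coupling_spec`);
#'   pairs not listed default to `kappa = 0` (independent oscillators).
#' @export
#' @examples
#' coupling_spec("CPFC-SMA", kappa = 0.9)
coupling_spec <- function(pair = character(), kappa = numeric(),
                          phase_lag = 0, band = "IV") {
  band <- resolve_band(band)
  if (length(pair) == 0) {
    out <- tibble::tibble(
      pair = character(), kappa = numeric(), phase_lag = numeric(),
      f_low = numeric(), f_high = numeric()
    )
    return(tibble::new_tibble(out, class = "coupling_spec"))
  }
  parts <- strsplit(pair, "-", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("Pair labels must be of the form \"REGION-REGION\".")
  }
  a <- vapply(parts, `[`, "", 1)
  b <- vapply(parts, `[`, "", 2)
  if (!all(a %in% REGION_ORDER) || !all(b %in% REGION_ORDER)) {
    abort(paste0(
      "Unknown region in coupling pair; regions are ",
      paste(REGION_ORDER, collapse = ", "), "."
    ))
  }
  if (any(a == b)) abort("A coupling pair must name two distinct regions.")
  if (any(kappa < 0 | kappa > 1)) abort("`kappa` must lie in [0, 1].")
  canon <- canonical_pair(a, b)
  if (anyDuplicated(canon)) abort("Duplicate coupling pair.")
  out <- tibble::tibble(
    pair = canon,
    kappa = rep_len(as.numeric(kappa), length(canon)),
    phase_lag = rep_len(as.numeric(phase_lag), length(canon)),
    f_low = band[1], f_high = band[2]
  )
  tibble::new_tibble(out, class = "coupling_spec")
}

#' Define a subject-group generating profile
#'
#' Bundles the parameters under which synthetic subjects of one cohort
#' group are generated: group size, trials per session, ground-truth
#' coupling, evoked response amplitude, and noise/systemic component
#' amplitudes.
#'
#' @param name Group label: one of `"expert"`, `"novice"`, `"trained"`,
#'   `"control"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_trials Task trials per session (surgeon cohorts performed
#'   5, the control group 3).
#' @param coupling A [coupling_spec()].
#' @param hrf_amplitude Peak evoked HbO response, micromolar.
#' @param osc_amplitude Standard deviation of each region's spontaneous
#'   band-IV oscillator, micromolar.
#' @param noise Named numeric vector of component amplitudes:
#'   `cardiac`, `respiratory`, `myogenic`, `endothelial` (systemic
#'   optical-density oscillation amplitudes, dimensionless OD) and
#'   `white` (white measurement noise on HbO, micromolar).
#' @return A list of class `group_profile`.
#' @export
#' @examples
#' group_profile("expert", n_subjects = 8,
#'               coupling = coupling_spec("CPFC-SMA", kappa = 0.3))
group_profile <- function(name, n_subjects, n_trials = if (name == "control") 3 else 5,
                          coupling = coupling_spec(),
                          hrf_amplitude = 1,
                          osc_amplitude = 0.3,
                          noise = c(cardiac = 0.02, respiratory = 0.01,
                                    myogenic = 0.005, endothelial = 0.005,
                                    white = 0.05)) {
  if (!name %in% c("expert", "novice", "trained", "control")) {
    abort("Group name must be one of expert, novice, trained, control.")
  }
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  need <- c("cardiac", "respiratory", "myogenic", "endothelial", "white")
  full <- c(cardiac = 0.02, respiratory = 0.01, myogenic = 0.005,
            endothelial = 0.005, white = 0.05)
  full[names(noise)] <- noise
  if (any(full < 0)) abort("Noise amplitudes must be non-negative.")
  structure(
    list(
      name = name,
      n_subjects = as.integer(n_subjects),
      n_trials = as.integer(n_trials),
      coupling = coupling,
      hrf_amplitude = hrf_amplitude,
      osc_amplitude = osc_amplitude,
      noise = full[need]
    ),
    class = "group_profile"
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (response peak at 6 s, undershoot peaking
#' at 16 s, undershoot ratio 1/6), normalised to unit peak.
#'
#' @param t Time since stimulus onset, seconds (vector).
#' @return HRF values at `t` (unit peak).
#' @export
hrf_double_gamma <- function(t) {
  # gamma-shape pdfs peak at (shape - 1): shape 7 -> 6 s peak,
  # shape 17 -> 16 s undershoot
  dg <- function(tt) {
    ifelse(tt <= 0, 0,
           tt^6 * exp(-tt) / gamma(7) - (1 / 6) * tt^16 * exp(-tt) / gamma(17))
  }
  tg <- seq(0, 32, by = 0.01)
  dg(t) / max(dg(tg))
}

# Band-limited Gaussian noise of unit variance, synthesised in the
# frequency domain so that all spectral power lies strictly inside
# [f_low, f_high). Uses the current RNG state.
narrowband_noise <- function(n, fs, f_low, f_high) {
  freq <- (0:(n - 1)) * fs / n
  half <- seq(2, floor(n / 2) + 1)           # positive-frequency bins
  in_band <- freq[half] >= f_low & freq[half] < f_high
  if (!any(in_band)) {
    abort("No frequency bin inside the oscillator band; series too short.")
  }
  z <- complex(real = rnorm(sum(in_band)), imaginary = rnorm(sum(in_band)))
  spec <- complex(length.out = n)
  spec[half[in_band]] <- z
  neg <- n - half[in_band] + 2
  keep <- neg <= n & neg > floor(n / 2) + 1
  spec[neg[keep]] <- Conj(z[keep])
  x <- Re(fft(spec, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

# Apply a constant phase lag to every positive-frequency component of
# x (a narrowband series); the result lags x by `phi` radians.
phase_shift <- function(x, phi) {
  n <- length(x)
  spec <- fft(x)
  k <- 0:(n - 1)
  sgn <- ifelse(k == 0 | (n %% 2 == 0 & k == n / 2), 0,
                ifelse(k <= n / 2, 1, -1))
  x_out <- Re(fft(spec * exp(-1i * phi * sgn), inverse = TRUE)) / n
  x_out
}

#' Simulate region-level HbO time series with known coupling
#'
#' Generates, for each of the five cortical regions, a
#' concentration-change series composed of (i) the task boxcar
#' convolved with the canonical double-gamma HRF, (ii) a band-limited
#' spontaneous oscillator (band IV by default) whose inter-regional
#' sharing is controlled by the profile's [coupling_spec()], and (iii)
#' independent white noise. For a coupled pair the second region's band
#' component is `kappa` times the first region's oscillator
#' (phase-lagged) plus `sqrt(1 - kappa^2)` of its own independent
#' oscillator, so ground-truth band coherence is `kappa^2`.
#'
#' @param paradigm A [build_paradigm()] result.
#' @param profile A [group_profile()].
#' @param fs Sampling rate, Hz (>= 4 so that the cardiac band is
#'   resolvable downstream).
#' @param seed Integer seed; output is deterministic given
#'   (paradigm, profile, fs, seed).
#' @return A tibble (class `region_series`) with columns `time` and one
#'   HbO series (micromolar) per region, with attributes `fs`,
#'   `paradigm`, and `ground_truth` (a list holding the evoked
#'   component and the per-region oscillator matrix).
#' @export
simulate_region_hbo <- function(paradigm, profile, fs = 10, seed = 1) {
  if (fs < 4) abort("`fs` must be at least 4 Hz.")
  if (!inherits(profile, "group_profile")) abort("`profile` must be a group_profile.")
  cp <- profile$coupling
  if (nrow(cp) > 0) {
    regs <- unique(unlist(strsplit(cp$pair, "-", fixed = TRUE)))
    if (!all(regs %in% REGIONS)) abort("Coupling spec names an undefined region.")
  }
  set.seed(as.integer(seed))
  n <- round(session_duration(paradigm) * fs)
  t <- (seq_len(n) - 1) / fs

  box <- task_boxcar(paradigm, fs)
  h <- hrf_double_gamma(seq(0, 32, by = 1 / fs))
  evoked <- convolve_causal(box, h)
  if (max(evoked) > 0) evoked <- profile$hrf_amplitude * evoked / max(evoked)

  # independent base oscillators, then mix per coupling row
  band <- if (nrow(cp) > 0) c(cp$f_low[1], cp$f_high[1]) else resolve_band("IV")
  osc <- sapply(REGIONS, function(r) narrowband_noise(n, fs, band[1], band[2]))
  if (nrow(cp) > 0) {
    for (i in seq_len(nrow(cp))) {
      ab <- strsplit(cp$pair[i], "-", fixed = TRUE)[[1]]
      k <- cp$kappa[i]
      shared <- phase_shift(osc[, ab[1]], cp$phase_lag[i])
      osc[, ab[2]] <- k * shared + sqrt(1 - k^2) * osc[, ab[2]]
    }
  }
  osc_scaled <- profile$osc_amplitude * osc

  white <- matrix(rnorm(n * length(REGIONS), sd = profile$noise[["white"]]),
                  nrow = n)
  values <- sweep(osc_scaled + white, 1, evoked, `+`)
  colnames(values) <- REGIONS

  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(out, time = t, .before = 1)
  out <- tibble::new_tibble(out, class = "region_series")
  attr(out, "fs") <- fs
  attr(out, "paradigm") <- paradigm
  attr(out, "ground_truth") <- list(evoked = evoked, oscillator = osc_scaled)
  out
}

# Causal FIR convolution truncated to the input length.
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")
  out[seq_len(n)]
}

#' @export
print.region_series <- function(x, ...) {
  cat("<region_series> ", nrow(x), " samples at ", attr(x, "fs"),
      " Hz; regions: ", paste(setdiff(names(x), "time"), collapse = ", "),
      "\n", sep = "")
  NextMethod()
}
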