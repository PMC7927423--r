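# Extinction coefficients for HbO2 / Hb at the two laser lines,
# converted from the standard compiled molar (base-10, cm^-1 M^-1)
# values 276 / 2051.96 (690 nm) and 974 / 693.04 (830 nm) to
# natural-log units per micromolar per millimetre.
EXTINCTION <- {
  to_e <- log(10) * 1e-6 / 10   # base-10 cm^-1 M^-1  ->  ln, uM^-1 mm^-1
  m <- rbind(
    `690` = c(hbo = 276, hbr = 2051.96),
    `830` = c(hbo = 974, hbr = 693.04)
  ) * to_e
  m
}

WAVELENGTHS <- c(690, 830)

# One representative systemic oscillation frequency per physiological
# band (I cardiac, II respiratory, III myogenic, V endothelial), Hz.
SYSTEMIC_FREQS <- c(cardiac = 1, respiratory = 0.25,
                    myogenic = 0.1, endothelial = 0.01)

# dB reference: intensity level = 20 log10(mean intensity / 1e-6
# detector units), so the unit source intensity I0 = 1 sits at 120 dB,
# inside the 80-140 dB retention window. A module convention.
DB_REFERENCE <- 1e-6

intensity_db <- function(x) 20 * log10(mean(x) / DB_REFERENCE)

#' Default optode montage
#'
#' A probe layout with 8 sources, each paired with two long-separation
#' detectors (30--40 mm, cortex-sensitive) and one short-separation
#' detector (8 mm, scalp-sensitive). The 16 long channels cover the
#' five cortical regions (LPFC, CPFC x 4, RPFC, LMM1, SMA x 3 each
#' except CPFC).
#'
#' @return A tibble with columns `channel`, `source_id`, `detector_id`,
#'   `separation_mm`, `region`, `class`.
#' @export
default_geometry <- function() {
  long_regions <- c("LPFC", "LPFC", "LPFC", "CPFC", "CPFC", "CPFC", "CPFC",
                    "RPFC", "RPFC", "RPFC", "LMM1", "LMM1", "LMM1",
                    "SMA", "SMA", "SMA")
  long_sources <- rep(1:8, each = 2)
  long <- tibble::tibble(
    channel = seq_len(16),
    source_id = long_sources,
    detector_id = seq_len(16),
    separation_mm = 30 + (seq_len(16) * 3) %% 11,
    region = long_regions,
    class = "long"
  )
  short <- tibble::tibble(
    channel = 16 + 1:8,
    source_id = 1:8,
    detector_id = 16 + 1:8,
    separation_mm = 8,
    region = "none",
    class = "short"
  )
  dplyr::bind_rows(long, short)
}

validate_geometry <- function(geometry) {
  long <- geometry[geometry$class == "long", ]
  short <- geometry[geometry$class == "short", ]
  if (any(long$separation_mm < 30 | long$separation_mm > 40)) {
    abort("Long channels must have separations in [30, 40] mm.")
  }
  if (any(short$separation_mm != 8)) {
    abort("Short channels must have an 8 mm separation.")
  }
  if (!all(REGIONS %in% long$region)) {
    abort("Every region needs at least one long channel.")
  }
  if (!setequal(unique(long$source_id), short$source_id) ||
      anyDuplicated(short$source_id)) {
    abort("Every source must carry exactly one short channel.")
  }
  invisible(geometry)
}

#' Project region HbO/HbR onto measured channel intensities
#'
#' The optical forward model: per channel and wavelength, the
#' modified Beer--Lambert optical density
#' `OD(t) = (eps_HbO * dHbO + eps_HbR * dHbR) * d * PPF + systemic`,
#' and measured intensity `I = I0 * exp(-OD)`. Long channels see the
#' concentration changes of their region; short (8 mm) channels see
#' only the systemic terms, which are shared (up to a per-source gain)
#' with the long channels of the same source. Systemic physiology is
#' modelled as one sinusoid per band -- cardiac ~1 Hz, respiratory
#' ~0.25 Hz, myogenic ~0.1 Hz, endothelial ~0.01 Hz -- with seeded
#' random phases.
#'
#' @param hbo A `region_series` from [simulate_region_hbo()] (micromolar).
#' @param geometry Montage tibble, see [default_geometry()].
#' @param systemic Named amplitudes (OD units) for `cardiac`,
#'   `respiratory`, `myogenic`, `endothelial`; defaults all zero.
#' @param hbr Optional `region_series` of HbR; defaults to `-hbo/3`.
#' @param ppf Partial path-length factors, named by wavelength
#'   (defaults 6.4 at 690 nm, 5.8 at 830 nm).
#' @param i0 Source intensity in detector units (> 0, default 1).
#' @param seed Integer seed for systemic phases and gains.
#' @param subject_id,group Metadata carried on the recording.
#' @return A `nirs_recording`: list with `geometry`, `fs`, `paradigm`,
#'   `intensity` (samples x channel-wavelength matrix, all positive),
#'   `wavelengths`, metadata and `provenance`.
#' @export
forward_optics <- function(hbo, geometry = default_geometry(),
                           systemic = c(cardiac = 0, respiratory = 0,
                                        myogenic = 0, endothelial = 0),
                           hbr = NULL,
                           ppf = c(`690` = 6.4, `830` = 5.8),
                           i0 = 1, seed = 1,
                           subject_id = "sub01", group = NA_character_) {
  validate_geometry(geometry)
  if (i0 <= 0) abort("`i0` must be positive.")
  sys_amp <- c(cardiac = 0, respiratory = 0, myogenic = 0, endothelial = 0)
  sys_amp[names(systemic)] <- systemic
  if (any(sys_amp < 0)) abort("Systemic amplitudes must be non-negative.")
  fs <- attr(hbo, "fs")
  n <- nrow(hbo)
  t <- hbo$time
  hbo_m <- as.matrix(hbo[REGIONS])
  hbr_m <- if (is.null(hbr)) -hbo_m / 3 else as.matrix(hbr[REGIONS])

  set.seed(as.integer(seed))
  phases <- runif(length(SYSTEMIC_FREQS), 0, 2 * pi)
  systemic_wave <- numeric(n)
  for (i in seq_along(SYSTEMIC_FREQS)) {
    systemic_wave <- systemic_wave +
      sys_amp[[names(SYSTEMIC_FREQS)[i]]] *
        sin(2 * pi * SYSTEMIC_FREQS[[i]] * t + phases[i])
  }
  src <- sort(unique(geometry$source_id))
  gain <- stats::setNames(runif(length(src), 0.7, 1.3), src)

  ncol_out <- nrow(geometry) * 2
  intensity <- matrix(NA_real_, n, ncol_out)
  cn <- character(ncol_out)
  k <- 0L
  for (i in seq_len(nrow(geometry))) {
    ch <- geometry[i, ]
    g <- gain[[as.character(ch$source_id)]]
    for (wl in WAVELENGTHS) {
      k <- k + 1L
      od <- g * systemic_wave
      if (ch$class == "long") {
        e <- EXTINCTION[as.character(wl), ]
        od <- od + (e[["hbo"]] * hbo_m[, ch$region] +
                    e[["hbr"]] * hbr_m[, ch$region]) *
          ch$separation_mm * ppf[[as.character(wl)]]
      }
      intensity[, k] <- i0 * exp(-od)
      cn[k] <- paste0("ch", ch$channel, "_", wl)
    }
  }
  colnames(intensity) <- cn

  structure(
    list(
      geometry = geometry,
      fs = fs,
      paradigm = attr(hbo, "paradigm"),
      wavelengths = WAVELENGTHS,
      intensity = intensity,
      subject_id = subject_id,
      group = group,
      seed = as.integer(seed),
      artifacts = NULL,
      provenance = list(
        ppf = ppf, i0 = i0, systemic = sys_amp,
        ground_truth = attr(hbo, "ground_truth")
      )
    ),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("<nirs_recording> subject ", x$subject_id,
      if (!is.na(x$group)) paste0(" (", x$group, ")"),
      ": ", nrow(x$intensity), " samples at ", x$fs, " Hz, ",
      nrow(x$geometry), " channels x 2 wavelengths\n", sep = "")
  invisible(x)
}

intensity_column <- function(rec, channel, wl) {
  rec$intensity[, paste0("ch", channel, "_", wl)]
}

#' Inject global motion artifacts into a recording
#'
#' Adds transient spikes (Gaussian bumps in optical density, ~1 s) and
#' step baseline shifts at seeded random times. Motion is global: each
#' event hits every channel simultaneously, with a per-channel
#' amplitude jitter. Ground-truth event times are recorded in the
#' returned recording's `artifacts` table.
#'
#' @param rec A `nirs_recording`.
#' @param n_spikes,n_shifts Event counts (>= 0).
#' @param spike_amplitude OD amplitude of spikes (default 0.5).
#' @param shift_amplitude OD amplitude of baseline steps (default 0.2).
#' @param spike_width_s Gaussian spike standard deviation, seconds.
#' @param seed Integer seed.
#' @return The recording with artifacts applied and annotated; with
#'   both counts zero the input is returned unchanged.
#' @export
inject_artifacts <- function(rec, n_spikes = 0, n_shifts = 0,
                             spike_amplitude = 0.5, shift_amplitude = 0.2,
                             spike_width_s = 1, seed = 1) {
  if (n_spikes < 0 || n_shifts < 0) abort("Artifact counts must be >= 0.")
  if (n_spikes == 0 && n_shifts == 0) return(rec)
  set.seed(as.integer(seed))
  n <- nrow(rec$intensity)
  t <- (seq_len(n) - 1) / rec$fs
  dur <- t[n]
  events <- list()
  od_art <- numeric(n)
  if (n_spikes > 0) {
    times <- sort(runif(n_spikes, 0.05 * dur, 0.95 * dur))
    for (tt in times) {
      od_art <- od_art + spike_amplitude * exp(-(t - tt)^2 / (2 * spike_width_s^2))
    }
    events[[length(events) + 1]] <- tibble::tibble(
      type = "spike", time = times, duration = 2 * spike_width_s,
      amplitude = spike_amplitude
    )
  }
  if (n_shifts > 0) {
    times <- sort(runif(n_shifts, 0.05 * dur, 0.95 * dur))
    for (tt in times) {
      od_art <- od_art + shift_amplitude * sign(rnorm(1)) * (t >= tt)
    }
    events[[length(events) + 1]] <- tibble::tibble(
      type = "shift", time = times, duration = NA_real_,
      amplitude = shift_amplitude
    )
  }
  jitter <- runif(ncol(rec$intensity), 0.6, 1.4)
  rec$intensity <- rec$intensity * exp(-outer(od_art, jitter))
  rec$artifacts <- dplyr::bind_rows(events)
  rec$provenance$artifact_seed <- as.integer(seed)
  rec
}
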