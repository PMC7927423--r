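#' Per-frequency wavelet coherence (WCO)
#'
#' The normalised magnitude of the time-averaged wavelet
#' cross-spectrum:
#' `WCO(f) = |mean(w1 w2*)|^2 / (P1(f) P2(f))` with
#' `P_i(f) = mean(|w_i|^2)`, all time averages running over the
#' jointly COI-valid samples at each frequency. Bounded in `[0, 1]` by
#' the Cauchy--Schwarz inequality; exactly 1 for a series against
#' itself. Frequencies with no jointly valid sample are returned as
#' missing, never as silent zeros.
#'
#' @param s1,s2 `wavelet_spectrum` objects on one grid.
#' @return Tibble with `frequency`, `wco`, `n_valid`.
#' @export
wco_profile <- function(s1, s2) {
  check_compatible(s1, s2)
  nf <- length(s1$frequency)
  wco <- rep(NA_real_, nf)
  nv <- integer(nf)
  for (i in seq_len(nf)) {
    v <- s1$coi_valid[i, ] & s2$coi_valid[i, ]
    nv[i] <- sum(v)
    if (nv[i] == 0) next
    w1 <- s1$coef[i, v]
    w2 <- s2$coef[i, v]
    cross <- mean(w1 * Conj(w2))
    p1 <- mean(Mod(w1)^2)
    p2 <- mean(Mod(w2)^2)
    if (p1 == 0 || p2 == 0) next
    wco[i] <- Mod(cross)^2 / (p1 * p2)
  }
  tibble::tibble(frequency = s1$frequency, wco = wco, n_valid = nv)
}

#' Per-frequency wavelet phase coherence (WPCO)
#'
#' The resultant length of the instantaneous phase-difference
#' distribution: with `dphi(f, t) = arg w1 - arg w2`,
#' `WPCO(f) = sqrt(mean(cos dphi)^2 + mean(sin dphi)^2)`, the averages
#' running over the jointly COI-valid samples. Equals 1 when the phase
#' difference is constant in time, and is amplitude-invariant.
#'
#' @inheritParams wco_profile
#' @return Tibble with `frequency`, `wpco`, `n_valid`.
#' @export
wpco_profile <- function(s1, s2) {
  check_compatible(s1, s2)
  nf <- length(s1$frequency)
  wpco <- rep(NA_real_, nf)
  nv <- integer(nf)
  for (i in seq_len(nf)) {
    v <- s1$coi_valid[i, ] & s2$coi_valid[i, ]
    nv[i] <- sum(v)
    if (nv[i] == 0) next
    dphi <- Arg(s1$coef[i, v]) - Arg(s2$coef[i, v])
    wpco[i] <- sqrt(mean(cos(dphi))^2 + mean(sin(dphi))^2)
  }
  tibble::tibble(frequency = s1$frequency, wpco = wpco, n_valid = nv)
}

#' Joint WCO/WPCO profile for a pair of series or spectra
#'
#' @param x,y Numeric series (with `fs` supplied) or precomputed
#'   `wavelet_spectrum` objects.
#' @param fs Sampling rate, Hz (ignored for spectra).
#' @param grid A [frequency_grid()].
#' @param omega0 Morlet central frequency.
#' @param pair Optional pair label carried on the result.
#' @return A `coherence_profile` tibble: `frequency`, `wco`, `wpco`,
#'   `n_valid`, plus per-series time-averaged power `p1`, `p2`.
#' @export
coherence_profile <- function(x, y, fs = NULL, grid = frequency_grid(),
                              omega0 = 6, pair = NULL) {
  s1 <- if (inherits(x, "wavelet_spectrum")) x else {
    if (is.null(fs)) abort("Supply `fs` for numeric input.")
    morlet_cwt(x, fs, grid, omega0)
  }
  s2 <- if (inherits(y, "wavelet_spectrum")) y else {
    if (is.null(fs)) abort("Supply `fs` for numeric input.")
    morlet_cwt(y, fs, grid, omega0)
  }
  a <- wco_profile(s1, s2)
  b <- wpco_profile(s1, s2)
  out <- tibble::tibble(
    frequency = a$frequency, wco = a$wco, wpco = b$wpco,
    n_valid = a$n_valid,
    p1 = wavelet_power(s1)$power, p2 = wavelet_power(s2)$power
  )
  out <- tibble::new_tibble(out, class = "coherence_profile")
  attr(out, "pair") <- pair
  out
}

#' Band-averaged coherence
#'
#' Unweighted mean of the per-frequency metrics over the grid
#' frequencies `f` with `f_low <= f < f_high`. A band containing grid
#' frequencies but only missing (fully COI-masked) values yields
#' missing values, never silent zeros.
#'
#' @param profile A `coherence_profile` (or any tibble with
#'   `frequency` and metric columns `wco`/`wpco`).
#' @param band Band label (`"I"`..`"V"`) or `c(low, high)` in Hz;
#'   default the neurovascular band `"IV"` (0.02--0.05 Hz).
#' @return One-row tibble with `band_low`, `band_high`, `wco`, `wpco`,
#'   `n_freq` (non-missing grid frequencies used).
#' @export
band_average <- function(profile, band = "IV") {
  b <- resolve_band(band)
  idx <- profile$frequency >= b[1] & profile$frequency < b[2]
  if (!any(idx)) {
    abort(sprintf("No grid frequency inside band [%g, %g) Hz.", b[1], b[2]))
  }
  sub <- profile[idx, ]
  ok <- !is.na(sub$wco)
  tibble::tibble(
    band_low = b[1], band_high = b[2],
    wco = if (any(ok)) mean(sub$wco[ok]) else NA_real_,
    wpco = if (any(!is.na(sub$wpco))) mean(sub$wpco, na.rm = TRUE) else NA_real_,
    n_freq = sum(ok)
  )
}

#' Band-averaged coherence for all ten region pairs
#'
#' Computes one Morlet transform per region, then WCO and WPCO for
#' each of the ten unordered region pairs, band-averaged (default:
#' neurovascular band IV), in the fixed reporting order LPFC-CPFC,
#' LPFC-RPFC, LPFC-SMA, LPFC-LMM1, CPFC-RPFC, CPFC-SMA, CPFC-LMM1,
#' RPFC-SMA, RPFC-LMM1, SMA-LMM1.
#'
#' @param regions A `region_series` tibble (five regions).
#' @param band Band label or `c(low, high)` Hz; default `"IV"`.
#' @param grid A [frequency_grid()]; defaults to the full 0.005--2 Hz
#'   grid. For band-restricted studies a narrower grid covering the
#'   band is sufficient and faster.
#' @param omega0 Morlet central frequency.
#' @return A `pair_connectivity` tibble: `pair`, `region_a`,
#'   `region_b`, `wco`, `wpco`, `n_freq`, carrying `subject_id` and
#'   `group` attributes from the input.
#' @export
pairwise_connectivity <- function(regions, band = "IV",
                                  grid = frequency_grid(), omega0 = 6) {
  missing_regions <- setdiff(REGIONS, names(regions))
  if (length(missing_regions) > 0) {
    abort(paste0("Missing region series: ",
                 paste(missing_regions, collapse = ", ")))
  }
  fs <- attr(regions, "fs")
  specs <- lapply(stats::setNames(REGIONS, REGIONS),
                  function(r) morlet_cwt(regions[[r]], fs, grid, omega0))
  pairs <- region_pairs()
  rows <- purrr::pmap(pairs, function(region_a, region_b, pair) {
    prof <- coherence_profile(specs[[region_a]], specs[[region_b]],
                              pair = pair)
    ba <- band_average(prof, band)
    tibble::tibble(pair = pair, region_a = region_a, region_b = region_b,
                   wco = ba$wco, wpco = ba$wpco, n_freq = ba$n_freq)
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::new_tibble(out, class = "pair_connectivity")
  attr(out, "subject_id") <- attr(regions, "subject_id")
  attr(out, "group") <- attr(regions, "group")
  attr(out, "band") <- resolve_band(band)
  out
}

# Gaussian time smoothing of each spectrum row at its own scale, with
# edge renormalisation; used only by the visualization map.
smooth_rows <- function(mat, scales, fs, factor = 1) {
  out <- mat
  n <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    sd_samp <- scales[i] * fs * factor
    half <- max(1L, ceiling(3 * sd_samp))
    kern <- exp(-(seq(-half, half))^2 / (2 * sd_samp^2))
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), mat[i, ], rep(0, half))
    ones <- c(rep(0, half), rep(1, n), rep(0, half))
    num <- stats::filter(padded, kern, sides = 2)
    den <- stats::filter(ones, kern, sides = 2)
    out[i, ] <- (num / den)[(half + 1):(half + n)]
  }
  out
}

#' Time-frequency coherence map (visualization)
#'
#' Locally smoothed wavelet coherence in time and scale, for plotting
#' only (no statistic consumes it). Without smoothing the pointwise
#' magnitude-squared coherence of any pair is identically 1 (each
#' time-frequency atom has a single amplitude and phase, so the
#' pointwise cross-spectrum ratio is degenerate); smoothing over the
#' wavelet scale in time and over adjacent scales restores contrast.
#'
#' @param s1,s2 `wavelet_spectrum` objects on one grid.
#' @param time_factor Gaussian time-smoothing width as a multiple of
#'   the scale (default 1).
#' @param scale_window Boxcar width (rows) for scale smoothing
#'   (default 3).
#' @return A `coherence_map`: list with `coherence` (frequencies x
#'   samples, in `[0,1]`, NA outside the COI), `frequency`, `time`.
#' @export
timefreq_coherence_map <- function(s1, s2, time_factor = 1, scale_window = 3) {
  check_compatible(s1, s2)
  cross <- s1$coef * Conj(s2$coef)
  p1 <- Mod(s1$coef)^2
  p2 <- Mod(s2$coef)^2
  sm <- function(m) {
    re <- smooth_rows(Re(m), s1$scale, s1$fs, time_factor)
    if (is.complex(m)) {
      im <- smooth_rows(Im(m), s1$scale, s1$fs, time_factor)
      m2 <- complex(real = re, imaginary = im)
      dim(m2) <- dim(m)
    } else {
      m2 <- re
    }
    # boxcar over adjacent scales
    nf <- nrow(m2)
    half <- floor(scale_window / 2)
    out <- m2
    for (i in seq_len(nf)) {
      rows <- max(1, i - half):min(nf, i + half)
      out[i, ] <- colMeans(m2[rows, , drop = FALSE])
    }
    out
  }
  s12 <- sm(cross)
  sp1 <- sm(p1)
  sp2 <- sm(p2)
  coh <- Mod(s12)^2 / (sp1 * sp2)
  coh <- pmin(pmax(coh, 0), 1)
  dim(coh) <- dim(cross)
  coh[!(s1$coi_valid & s2$coi_valid)] <- NA_real_
  structure(
    list(coherence = coh, frequency = s1$frequency,
         time = (seq_len(s1$n) - 1) / s1$fs),
    class = "coherence_map"
  )
}

#' Assemble a cohort connectivity table
#'
#' Binds per-subject [pairwise_connectivity()] tables into one long
#' tibble with subject and group columns.
#'
#' @param tables List of `pair_connectivity` tibbles.
#' @return Long tibble: `subject_id`, `group`, `pair`, `wco`, `wpco`.
#' @export
bind_connectivity <- function(tables) {
  dplyr::bind_rows(lapply(tables, function(tb) {
    tibble::add_column(
      tb[, c("pair", "wco", "wpco")],
      subject_id = attr(tb, "subject_id") %||% NA_character_,
      group = attr(tb, "group") %||% NA_character_,
      .before = 1
    )
  }))
}

#' Widen a connectivity table for the statistics layer
#'
#' @param long Long connectivity tibble from [bind_connectivity()].
#' @param metric `"wpco"` or `"wco"`.
#' @return Wide tibble: `subject_id`, `group`, one column per pair.
#' @export
pivot_connectivity <- function(long, metric = c("wpco", "wco")) {
  metric <- match.arg(metric)
  long |>
    dplyr::select("subject_id", "group", "pair", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "pair", values_from = dplyr::all_of(metric))
}
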