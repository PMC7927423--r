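#' Prune channels by intensity level
#'
#' Flags channels whose mean intensity level falls outside the
#' retention window at either wavelength. The level is
#' `20 log10(mean intensity / 1e-6 detector units)` (a module
#' convention for the dB scale; the unit source intensity sits at
#' 120 dB).
#'
#' @param rec A `nirs_recording`.
#' @param low_db,high_db Retention window bounds (defaults 80, 140).
#' @return The recording with a logical `kept` column on its geometry
#'   and the mask recorded in `provenance$prune`.
#' @export
prune_channels <- function(rec, low_db = 80, high_db = 140) {
  if (low_db >= high_db) abort("`low_db` must be below `high_db`.")
  geom <- rec$geometry
  kept <- logical(nrow(geom))
  level <- matrix(NA_real_, nrow(geom), 2,
                  dimnames = list(NULL, as.character(WAVELENGTHS)))
  for (i in seq_len(nrow(geom))) {
    lv <- vapply(WAVELENGTHS, function(wl) {
      intensity_db(intensity_column(rec, geom$channel[i], wl))
    }, 0)
    level[i, ] <- lv
    kept[i] <- all(lv >= low_db & lv <= high_db)
  }
  if (!any(kept)) {
    abort(sprintf(
      "All channels pruned by the [%g, %g] dB window.", low_db, high_db
    ))
  }
  geom$kept <- kept
  rec$geometry <- geom
  rec$provenance$prune <- list(
    low_db = low_db, high_db = high_db,
    level = tibble::tibble(channel = geom$channel,
                           db_690 = level[, 1], db_830 = level[, 2],
                           kept = kept)
  )
  rec
}

kept_geometry <- function(rec) {
  g <- rec$geometry
  if (!"kept" %in% names(g)) g$kept <- TRUE
  g[g$kept, ]
}

#' Convert raw intensities to optical density changes
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, so each
#' OD series is zero-mean in the log domain and invariant to constant
#' channel gain.
#'
#' @param rec A `nirs_recording`, optionally pruned with
#'   [prune_channels()].
#' @return An `od_series`: list with `values` (samples x kept
#'   channel-wavelength matrix), `geometry` (kept channels), `fs`,
#'   `paradigm`, `provenance`.
#' @export
intensity_to_od <- function(rec) {
  geom <- kept_geometry(rec)
  cols <- as.vector(t(outer(geom$channel, WAVELENGTHS,
                            function(ch, wl) paste0("ch", ch, "_", wl))))
  values <- matrix(NA_real_, nrow(rec$intensity), length(cols),
                   dimnames = list(NULL, cols))
  for (cl in cols) {
    x <- rec$intensity[, cl]
    if (any(x <= 0)) {
      abort(paste0("Non-positive intensity sample in channel ", cl, "."))
    }
    values[, cl] <- -log(x / mean(x))
  }
  structure(
    list(values = values, geometry = geom, fs = rec$fs,
         paradigm = rec$paradigm, subject_id = rec$subject_id,
         group = rec$group,
         provenance = c(rec$provenance, list(od = "log-ratio about channel mean"))),
    class = "od_series"
  )
}

#' Remove leading principal components (motion correction)
#'
#' Large motion events load coherently on all channels, so the leading
#' principal component(s) of the multichannel OD matrix capture them;
#' those components are projected out.
#'
#' @param od An `od_series`.
#' @param n_components Number of leading components to remove
#'   (default 1; 0 is a no-op).
#' @return The corrected `od_series`.
#' @export
pca_motion_correct <- function(od, n_components = 1) {
  if (n_components < 0) abort("`n_components` must be >= 0.")
  if (n_components == 0) {
    od$provenance$pca <- list(n_components = 0L)
    return(od)
  }
  if (n_components >= ncol(od$values)) {
    abort("`n_components` must be smaller than the number of kept channel series.")
  }
  sv <- svd(od$values, nu = n_components, nv = n_components)
  k <- seq_len(n_components)
  od$values <- od$values -
    sv$u[, k, drop = FALSE] %*% (sv$d[k] * t(sv$v[, k, drop = FALSE]))
  od$provenance$pca <- list(
    n_components = as.integer(n_components),
    variance_removed = sum(sv$d[k]^2) / sum(sv$d^2)
  )
  od
}

#' Invert the modified Beer--Lambert law
#'
#' Per channel, solves the 2x2 system
#' `OD(lambda) / (d * PPF(lambda)) = E %*% c(dHbO, dHbR)` for the
#' hemoglobin concentration changes, with `E` the extinction matrix,
#' `d` the source-detector separation and wavelength-specific partial
#' path-length factors.
#'
#' @param od An `od_series`.
#' @param ppf_690,ppf_830 Partial path-length factors (defaults 6.4
#'   and 5.8).
#' @return A `conc_series`: list with `hbo`, `hbr` (samples x kept
#'   channel matrices, micromolar; long and short channels), plus
#'   geometry and provenance.
#' @export
od_to_concentration <- function(od, ppf_690 = 6.4, ppf_830 = 5.8) {
  E <- EXTINCTION
  if (abs(det(E)) < 1e-12 * prod(diag(E))) {
    abort("Extinction matrix is singular; check wavelength configuration.")
  }
  Einv <- solve(E)
  geom <- od$geometry
  n <- nrow(od$values)
  hbo <- hbr <- matrix(NA_real_, n, nrow(geom),
                       dimnames = list(NULL, paste0("ch", geom$channel)))
  for (i in seq_len(nrow(geom))) {
    d <- geom$separation_mm[i]
    od690 <- od$values[, paste0("ch", geom$channel[i], "_690")] / (d * ppf_690)
    od830 <- od$values[, paste0("ch", geom$channel[i], "_830")] / (d * ppf_830)
    conc <- Einv %*% rbind(od690, od830)
    hbo[, i] <- conc[1, ]
    hbr[, i] <- conc[2, ]
  }
  structure(
    list(hbo = hbo, hbr = hbr, geometry = geom, fs = od$fs,
         paradigm = od$paradigm, subject_id = od$subject_id,
         group = od$group,
         provenance = c(od$provenance,
                        list(ppf = c(`690` = ppf_690, `830` = ppf_830)))),
    class = "conc_series"
  )
}

# Design-matrix cache so cohort runs sharing one paradigm/basis reuse
# a single QR decomposition.
.design_cache <- new.env(parent = emptyenv())

ss_design <- function(paradigm, fs, n, basis_sd, basis_spacing, drift_order) {
  onsets <- task_onsets(paradigm)
  key <- paste(round(onsets, 6), collapse = ",")
  key <- paste(key, fs, n, basis_sd, basis_spacing, drift_order, sep = "|")
  hit <- .design_cache[[key]]
  if (!is.null(hit)) return(hit)

  t <- (seq_len(n) - 1) / fs
  task_dur <- max(paradigm$duration[paradigm$condition == "task"])
  window <- task_dur + 16
  centers <- seq(0, window, by = basis_spacing)
  task <- matrix(0, n, length(centers))
  for (j in seq_along(centers)) {
    for (on in onsets) {
      task[, j] <- task[, j] +
        exp(-(t - on - centers[j])^2 / (2 * basis_sd^2))
    }
  }
  tt <- (t - mean(t)) / (max(t) / 2)
  drift <- sapply(0:drift_order, function(k) tt^k)
  S <- cbind(task, drift)
  colnames(S) <- c(paste0("g", seq_along(centers)),
                   paste0("drift", 0:drift_order))
  qrS <- qr(S)
  out <- list(
    S = S, qr = qrS,
    Q = qr.Q(qrS), R = qr.R(qrS), pivot = qrS$pivot,
    centers = centers, basis_sd = basis_sd,
    task_cols = seq_along(centers),
    drift_cols = length(centers) + 1 + 0:drift_order,
    window = window
  )
  .design_cache[[key]] <- out
  out
}

#' Short-separation GLM with a Gaussian temporal basis
#'
#' Fits, per long channel, an ordinary-least-squares model of the HbO
#' series on (a) task regressors formed by a consecutive sequence of
#' Gaussian functions over the peristimulus window placed at each task
#' onset, (b) polynomial drift terms, and (c) the HbO series of the
#' channel's same-source short-separation channel (the systemic
#' nuisance). Returns the per-channel HRF estimate and the cortical
#' series: measurement minus drift minus the short-channel fit, with
#' the task structure retained.
#'
#' @param conc A `conc_series`.
#' @param basis_sd Gaussian basis standard deviation, seconds
#'   (default 1).
#' @param basis_spacing Spacing of basis centres, seconds (default 1).
#'   The peristimulus window is `[0, task duration + 16 s]`.
#' @param drift_order Polynomial drift order (default 3).
#' @return A `nirs_glm`: list with `cortical` and `task_fit` (samples
#'   x long-channel matrices), `hrf` (tibble: `tau` x channel), `beta`,
#'   `short_coef`, `residuals`, geometry and provenance.
#' @export
glm_short_separation <- function(conc, basis_sd = 1, basis_spacing = 1,
                                 drift_order = 3) {
  geom <- conc$geometry
  long <- geom[geom$class == "long", ]
  short <- geom[geom$class == "short", ]
  if (nrow(long) == 0) abort("No long channels available for the GLM.")
  if (sum(conc$paradigm$condition == "task") < 1) {
    abort("The paradigm must contain at least one task block.")
  }
  n <- nrow(conc$hbo)
  des <- ss_design(conc$paradigm, conc$fs, n, basis_sd, basis_spacing,
                   drift_order)
  qrS <- des$qr
  if (qrS$rank < ncol(des$S)) {
    bad <- colnames(des$S)[qrS$pivot[(qrS$rank + 1):ncol(des$S)]]
    abort(paste0("Rank-deficient GLM design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  fs <- conc$fs
  tau <- seq(0, des$window, by = 1 / fs)
  basis_tau <- sapply(des$centers,
                      function(cc) exp(-(tau - cc)^2 / (2 * basis_sd^2)))

  ch_names <- paste0("ch", long$channel)
  # each long channel pairs with the short channel sharing its source
  short_map <- integer(nrow(long))
  for (i in seq_len(nrow(long))) {
    s_idx <- which(short$source_id == long$source_id[i])
    if (length(s_idx) == 0) {
      abort(paste0("Long channel ", long$channel[i],
                   " has no surviving short channel on source ",
                   long$source_id[i], "."))
    }
    short_map[i] <- s_idx[1]
  }

  # batched OLS: project the shared design out of all responses and
  # all short-channel regressors at once, then solve the augmented
  # system channel-wise in closed form
  Q <- des$Q
  Y <- conc$hbo[, paste0("ch", long$channel), drop = FALSE]
  U <- conc$hbo[, paste0("ch", short$channel), drop = FALSE]
  QtY <- crossprod(Q, Y)
  QtU <- crossprod(Q, U)
  Y_p <- Y - Q %*% QtY
  U_p <- U - Q %*% QtU
  u_ss <- colSums(U_p^2)
  gamma <- colSums(U_p[, short_map, drop = FALSE] * Y_p) /
    ifelse(u_ss[short_map] > 0, u_ss[short_map], 1)
  gamma[u_ss[short_map] == 0] <- 0

  rhs <- QtY - sweep(QtU[, short_map, drop = FALSE], 2, gamma, `*`)
  beta <- backsolve(des$R, rhs)
  beta[des$pivot, ] <- beta
  rownames(beta) <- colnames(des$S)
  colnames(beta) <- ch_names

  U_fit <- sweep(U[, short_map, drop = FALSE], 2, gamma, `*`)
  drift_fit <- des$S[, des$drift_cols, drop = FALSE] %*%
    beta[des$drift_cols, , drop = FALSE]
  task_fit <- des$S[, des$task_cols, drop = FALSE] %*%
    beta[des$task_cols, , drop = FALSE]
  cortical <- Y - drift_fit - U_fit
  residuals <- Y_p - sweep(U_p[, short_map, drop = FALSE], 2, gamma, `*`)
  hrf <- basis_tau %*% beta[des$task_cols, , drop = FALSE]
  short_coef <- stats::setNames(gamma, ch_names)
  colnames(cortical) <- colnames(task_fit) <- colnames(residuals) <-
    colnames(hrf) <- ch_names

  structure(
    list(cortical = cortical, task_fit = task_fit, residuals = residuals,
         hrf = tibble::as_tibble(as.data.frame(hrf)) |>
           tibble::add_column(tau = tau, .before = 1),
         beta = beta, short_coef = short_coef,
         design = des$S, geometry = long, fs = fs, paradigm = conc$paradigm,
         subject_id = conc$subject_id, group = conc$group,
         provenance = c(conc$provenance, list(
           glm = list(basis_sd = basis_sd, basis_spacing = basis_spacing,
                      drift_order = drift_order)
         ))),
    class = "nirs_glm"
  )
}

#' Aggregate cortical channel series into region series
#'
#' @param fit A `nirs_glm`.
#' @param output `"cortical"` (default): measurement minus drift minus
#'   short-channel fit; `"hrf"`: the reconstructed task component only.
#' @return A `region_series` tibble (`time` plus the five regions).
#' @export
extract_region_series <- function(fit, output = c("cortical", "hrf")) {
  output <- match.arg(output)
  src <- if (output == "cortical") fit$cortical else fit$task_fit
  geom <- fit$geometry
  n <- nrow(src)
  vals <- matrix(NA_real_, n, length(REGIONS), dimnames = list(NULL, REGIONS))
  for (r in REGIONS) {
    idx <- which(geom$region == r)
    if (length(idx) == 0) {
      abort(paste0("Region ", r, " has no surviving long channel."))
    }
    vals[, r] <- rowMeans(src[, idx, drop = FALSE])
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- tibble::add_column(out, time = (seq_len(n) - 1) / fit$fs, .before = 1)
  out <- tibble::new_tibble(out, class = "region_series")
  attr(out, "fs") <- fit$fs
  attr(out, "paradigm") <- fit$paradigm
  attr(out, "subject_id") <- fit$subject_id
  attr(out, "group") <- fit$group
  attr(out, "provenance") <- fit$provenance
  out
}

#' Full preprocessing chain: raw recording to region HbO
#'
#' Pruning, optical density, PCA motion correction, Beer--Lambert
#' inversion, short-separation GLM, region aggregation — in that
#' order, with no temporal filtering anywhere so the full frequency
#' band is preserved for coherence analysis.
#'
#' @param rec A `nirs_recording`.
#' @param low_db,high_db Pruning window (dB).
#' @param pca_components Leading principal components to remove
#'   (default 1; use 0 when no motion correction is wanted).
#' @param ppf_690,ppf_830 Partial path-length factors.
#' @param basis_sd,basis_spacing,drift_order GLM settings, see
#'   [glm_short_separation()].
#' @param output Passed to [extract_region_series()].
#' @return A `region_series` tibble.
#' @export
preprocess_recording <- function(rec, low_db = 80, high_db = 140,
                                 pca_components = 1,
                                 ppf_690 = 6.4, ppf_830 = 5.8,
                                 basis_sd = 1, basis_spacing = 1,
                                 drift_order = 3,
                                 output = "cortical") {
  rec |>
    prune_channels(low_db = low_db, high_db = high_db) |>
    intensity_to_od() |>
    pca_motion_correct(n_components = pca_components) |>
    od_to_concentration(ppf_690 = ppf_690, ppf_830 = ppf_830) |>
    glm_short_separation(basis_sd = basis_sd, basis_spacing = basis_spacing,
                         drift_order = drift_order) |>
    extract_region_series(output = output)
}
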