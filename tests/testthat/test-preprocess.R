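test_that("channels outside the dB window are pruned, in-range kept", {
  rec <- quick_recording(seed = 1)
  pruned <- prune_channels(rec)
  expect_true(all(pruned$geometry$kept))  # defaults sit at ~120 dB

  # plant k channels out of range (+30 dB and -50 dB)
  k_ids <- c(2, 9, 20)
  for (ch in k_ids[1:2]) {
    for (wl in c(690, 830)) {
      cl <- paste0("ch", ch, "_", wl)
      rec$intensity[, cl] <- rec$intensity[, cl] * 10^(30 / 20)
    }
  }
  cl <- paste0("ch", k_ids[3], "_690")
  rec$intensity[, cl] <- rec$intensity[, cl] * 10^(-50 / 20)
  pruned <- prune_channels(rec)
  expect_equal(sum(!pruned$geometry$kept), 3)
  expect_setequal(pruned$geometry$channel[!pruned$geometry$kept], k_ids)

  expect_error(prune_channels(rec, low_db = 119, high_db = 121),
               NA)  # most channels still inside
  expect_error(prune_channels(rec, low_db = 200, high_db = 300),
               "pruned")
})

test_that("optical density is the mean-referenced log ratio", {
  rec <- quick_recording(seed = 2, systemic = FALSE, noise = FALSE)
  od <- intensity_to_od(rec)
  # channel means are zero by construction... of the log-ratio
  expect_lt(max(abs(colMeans(exp(-od$values)) - 1)), 1e-9)

  # algebraic oracle: I = I0 exp(-x) => OD = x - log-mean correction
  n <- 500
  x <- sin(seq_len(n) / 20) * 0.1
  rec2 <- rec
  rec2$intensity <- rec2$intensity[seq_len(n), ]
  rec2$intensity[, "ch1_690"] <- 2.5 * exp(-x)
  od2 <- intensity_to_od(rec2)
  got <- od2$values[, "ch1_690"]
  expect_lt(max(abs((got - mean(got)) - (x - mean(x)))), 1e-10)

  # gain invariance: doubling all samples leaves OD unchanged
  rec3 <- rec
  rec3$intensity[, "ch3_830"] <- 2 * rec3$intensity[, "ch3_830"]
  od3 <- intensity_to_od(rec3)
  expect_equal(od3$values[, "ch3_830"], od$values[, "ch3_830"],
               tolerance = 1e-12)

  rec$intensity[5, "ch1_690"] <- -1
  expect_error(intensity_to_od(rec), "ch1_690")
})

test_that("PCA stage removes exactly the leading components", {
  rec <- quick_recording(seed = 3)
  od <- intensity_to_od(rec)
  expect_identical(pca_motion_correct(od, 0)$values, od$values)

  # rank-1 input is annihilated by removing one component
  od1 <- od
  u <- rnorm(nrow(od$values))
  v <- rnorm(ncol(od$values))
  od1$values <- outer(u, v)
  corrected <- pca_motion_correct(od1, 1)
  expect_lt(norm(corrected$values, "F"), 1e-8 * norm(od1$values, "F"))

  expect_error(pca_motion_correct(od, ncol(od$values)), "smaller")
})

test_that("Beer-Lambert inversion is linear and PPF-scaled", {
  rec <- quick_recording(seed = 4, systemic = FALSE, noise = FALSE)
  od <- intensity_to_od(rec)
  od0 <- od
  od0$values[] <- 0
  conc0 <- od_to_concentration(od0)
  expect_true(all(conc0$hbo == 0) && all(conc0$hbr == 0))

  conc <- od_to_concentration(od)
  conc_half <- od_to_concentration(od, ppf_690 = 3.2, ppf_830 = 2.9)
  expect_equal(conc_half$hbo, 2 * conc$hbo, tolerance = 1e-12)
  expect_equal(conc_half$hbr, 2 * conc$hbr, tolerance = 1e-12)
})

test_that("short-separation regression recovers the nuisance coefficient", {
  par <- build_paradigm(1, task_s = 30, rest_s = 15, lead_in_s = 15)
  geom <- default_geometry()
  fs <- 4
  n <- round(session_duration(par) * fs)
  t <- (seq_len(n) - 1) / fs
  gammas <- vapply(1:20, function(s) {
    set.seed(s)
    hbo <- matrix(0, n, nrow(geom),
                  dimnames = list(NULL, paste0("ch", geom$channel)))
    shorts <- geom$channel[geom$class == "short"]
    for (sc in shorts) {
      hbo[, paste0("ch", sc)] <- sin(2 * pi * 0.25 * t + runif(1, 0, 6)) +
        0.3 * rnorm(n)
    }
    for (i in which(geom$class == "long")) {
      sc <- geom$channel[geom$class == "short" &
                           geom$source_id == geom$source_id[i]]
      hbo[, paste0("ch", geom$channel[i])] <-
        1.0 * hbo[, paste0("ch", sc)] + 0.2 * rnorm(n)
    }
    conc <- structure(
      list(hbo = hbo, hbr = -hbo / 3, geometry = geom, fs = fs,
           paradigm = par, provenance = list()),
      class = "conc_series"
    )
    fit <- glm_short_separation(conc)
    mean(fit$short_coef)
  }, 0)
  expect_lt(abs(mean(gammas) - 1), 0.05)
})

test_that("the Gaussian-basis GLM recovers the block response shape", {
  par <- quick_paradigm()
  prof <- group_profile("trained", 1, osc_amplitude = 0,
                        noise = c(white = 0))
  hbo <- simulate_region_hbo(par, prof, fs = 10, seed = 6)
  rec <- forward_optics(hbo, seed = 7)
  rs_fit <- rec |>
    prune_channels() |>
    intensity_to_od() |>
    pca_motion_correct(0) |>
    od_to_concentration() |>
    glm_short_separation()
  tau <- rs_fit$hrf$tau
  h <- hrf_double_gamma(seq(0, 32, by = 0.1))
  box1 <- as.numeric(seq(0, 241, by = 0.1) < 225)
  truth <- stats::convolve(box1, rev(h), type = "open")[seq_along(box1)]
  truth <- stats::approx(seq(0, 241, by = 0.1), truth, xout = tau)$y
  for (ch in c("ch1", "ch8", "ch16")) {
    expect_gt(cor(rs_fit$hrf[[ch]], truth), 0.95)
  }
})

test_that("GLM residuals are orthogonal to every design column", {
  rec <- quick_recording(seed = 8)
  fit <- rec |>
    prune_channels() |>
    intensity_to_od() |>
    pca_motion_correct(1) |>
    od_to_concentration() |>
    glm_short_separation()
  X <- fit$design
  for (j in seq_len(ncol(fit$residuals))) {
    r <- fit$residuals[, j]
    dots <- abs(crossprod(X, r)) / (sqrt(colSums(X^2)) * sqrt(sum(r^2)))
    expect_lt(max(dots), 1e-8)
  }
})

test_that("region aggregation averages surviving channels", {
  par <- quick_paradigm()
  n <- 50
  x <- rnorm(n)
  geom <- tibble::tibble(
    channel = 1:6,
    source_id = 1:6, detector_id = 1:6, separation_mm = 35,
    region = c("LPFC", "CPFC", "RPFC", "LMM1", "SMA", "SMA"),
    class = "long"
  )
  cortical <- cbind(x, 2 * x, 3 * x, 4 * x, x, -x)
  colnames(cortical) <- paste0("ch", 1:6)
  fit <- structure(
    list(cortical = cortical, task_fit = cortical, geometry = geom,
         fs = 10, paradigm = par, provenance = list()),
    class = "nirs_glm"
  )
  rs <- extract_region_series(fit)
  expect_equal(rs$LPFC, x)              # single channel passthrough
  expect_equal(rs$SMA, rep(0, n))       # x and -x cancel

  fit$geometry <- geom[-5:-6, ]
  fit$cortical <- cortical[, 1:4]
  expect_error(extract_region_series(fit), "SMA")
})

test_that("channel gain scaling never reaches downstream results", {
  rec <- quick_recording(seed = 9)
  rec2 <- rec
  rec2$intensity[, "ch5_690"] <- 7.7 * rec2$intensity[, "ch5_690"]
  rec2$intensity[, "ch5_830"] <- 0.3 * rec2$intensity[, "ch5_830"]
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec2)
  for (r in c("LPFC", "CPFC", "RPFC", "LMM1", "SMA")) {
    expect_equal(a[[r]], b[[r]], tolerance = 1e-10)
  }
})

test_that("noiseless subjects round-trip the whole chain", {
  par <- quick_paradigm()
  prof <- group_profile("trained", 1,
                        coupling = coupling_spec("CPFC-SMA", 0.9),
                        noise = c(white = 0))
  hbo <- simulate_region_hbo(par, prof, fs = 10, seed = 10)
  rec <- forward_optics(hbo, seed = 11)
  rs <- preprocess_recording(rec, pca_components = 0)
  for (r in c("LPFC", "CPFC", "RPFC", "LMM1", "SMA")) {
    expect_gt(cor(rs[[r]], hbo[[r]]), 0.99)
  }
})
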