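test_that("self-coherence is exactly one at every valid frequency", {
  set.seed(7)
  x <- rnorm(1024)
  s <- morlet_cwt(x, 10)
  wco <- wco_profile(s, s)
  wpco <- wpco_profile(s, s)
  valid <- wco$n_valid > 0
  expect_true(any(valid))
  expect_lt(max(abs(wco$wco[valid] - 1)), 1e-12)
  expect_lt(max(abs(wpco$wpco[valid] - 1)), 1e-12)
  expect_true(all(is.na(wco$wco[!valid])))
})

test_that("independent noise shows low band-IV coherence on long records", {
  # 4096 samples at 1 Hz: many independent band-IV wavelet atoms
  means <- vapply(1:20, function(s) {
    set.seed(s)
    prof <- coherence_profile(rnorm(4096), rnorm(4096), fs = 1,
                              grid = frequency_grid(0.01, 0.1, 8))
    band_average(prof, "IV")$wco
  }, 0)
  expect_lt(mean(means), 0.3)
})

test_that("a shared tone in noise is detected as near-unit coherence", {
  set.seed(11)
  fs <- 1
  t <- (0:4095) / fs
  tone <- sin(2 * pi * 0.03 * t)
  snr_sd <- sqrt(var(tone) / 10)
  x <- tone + rnorm(length(t), sd = snr_sd)
  y <- tone + rnorm(length(t), sd = snr_sd)
  prof <- coherence_profile(x, y, fs = fs)
  i <- which.min(abs(prof$frequency - 0.03))
  expect_gt(prof$wco[i], 0.9)
  expect_gt(prof$wpco[i], 0.9)
})

test_that("a constant phase offset preserves unit phase coherence", {
  fs <- 2
  t <- (0:2047) / fs
  x <- sin(2 * pi * 0.05 * t)
  y <- sin(2 * pi * 0.05 * t + pi / 4)
  prof <- coherence_profile(x, y, fs = fs)
  i <- which.min(abs(prof$frequency - 0.05))
  expect_gt(prof$wpco[i], 0.999)
})

test_that("uniform random phases obey the 1/M null expectation", {
  # closed form: with M i.i.d. uniform phase differences,
  # E[WPCO^2] = 1/M
  M <- 64
  fake_spec <- function(theta) {
    coef <- matrix(exp(1i * theta), 1, M)
    structure(list(coef = coef, frequency = 0.1, scale = 1,
                   coi_valid = matrix(TRUE, 1, M),
                   fully_masked = FALSE, fs = 1, omega0 = 6, n = M),
              class = "wavelet_spectrum")
  }
  set.seed(5)
  sq <- replicate(4000, {
    s1 <- fake_spec(runif(M, 0, 2 * pi))
    s2 <- fake_spec(rep(0, M))
    wpco_profile(s1, s2)$wpco^2
  })
  expect_equal(mean(sq), 1 / M, tolerance = 0.1)
})

test_that("band averaging is the plain mean over in-band grid points", {
  prof <- tibble::tibble(
    frequency = c(0.01, 0.025, 0.04, 0.06),
    wco = c(0.9, 0.2, 0.8, 0.5),
    wpco = c(0.9, 0.2, 0.8, 0.5)
  )
  ba <- band_average(prof, "IV")
  expect_equal(ba$wco, 0.5)
  expect_equal(ba$wpco, 0.5)
  expect_equal(ba$n_freq, 2)

  # enumeration oracle on a random profile
  set.seed(2)
  prof2 <- tibble::tibble(
    frequency = sort(runif(40, 0.001, 0.2)),
    wco = runif(40), wpco = runif(40)
  )
  idx <- prof2$frequency >= 0.02 & prof2$frequency < 0.05
  expect_equal(band_average(prof2, "IV")$wco, mean(prof2$wco[idx]),
               tolerance = 1e-12)
  expect_error(band_average(prof, c(0.3, 0.4)), "band")

  # a band whose grid points are all COI-masked is missing, not zero
  prof3 <- tibble::tibble(frequency = c(0.03, 0.04),
                          wco = c(NA_real_, NA_real_),
                          wpco = c(NA_real_, NA_real_))
  ba3 <- band_average(prof3, "IV")
  expect_true(is.na(ba3$wco))
})

test_that("coherence is bounded, symmetric, and amplitude-invariant", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(700)
    y <- as.numeric(stats::filter(rnorm(700), rep(1 / 4, 4), sides = 1))
    y[is.na(y)] <- 0
    g <- frequency_grid(0.02, 1, 8)
    p_xy <- coherence_profile(x, y, fs = 5, grid = g)
    p_yx <- coherence_profile(y, x, fs = 5, grid = g)
    ok <- !is.na(p_xy$wco)
    expect_true(all(p_xy$wco[ok] >= 0 & p_xy$wco[ok] <= 1))
    expect_true(all(p_xy$wpco[ok] >= 0 & p_xy$wpco[ok] <= 1))
    expect_equal(p_xy$wco, p_yx$wco, tolerance = 1e-12)
    expect_equal(p_xy$wpco, p_yx$wpco, tolerance = 1e-12)
    p_scaled <- coherence_profile(3.7 * x, 0.2 * y, fs = 5, grid = g)
    expect_equal(p_scaled$wco, p_xy$wco, tolerance = 1e-10)
    expect_equal(p_scaled$wpco, p_xy$wpco, tolerance = 1e-10)
  }
})

test_that("pairwise connectivity reports the ten canonical pairs", {
  par <- quick_paradigm()
  prof <- group_profile("trained", 1,
                        coupling = coupling_spec("CPFC-SMA", 0.7))
  rs <- simulate_region_hbo(par, prof, fs = 10, seed = 13)
  tab <- pairwise_connectivity(rs, band = "IV", grid = band4_grid())
  expect_equal(nrow(tab), 10)
  expect_equal(tab$pair, region_pairs()$pair)
  expect_true(all(tab$wco >= 0 & tab$wco <= 1))

  # identical series in all regions: every pair fully coherent
  rs2 <- rs
  for (r in c("CPFC", "RPFC", "LMM1", "SMA")) rs2[[r]] <- rs2$LPFC
  tab2 <- pairwise_connectivity(rs2, band = "IV", grid = band4_grid())
  expect_equal(tab2$wco, rep(1, 10), tolerance = 1e-9)
  expect_equal(tab2$wpco, rep(1, 10), tolerance = 1e-9)

  # swapping two region labels relabels rows without changing values
  rs3 <- rs
  rs3$LPFC <- rs$RPFC
  rs3$RPFC <- rs$LPFC
  tab3 <- pairwise_connectivity(rs3, band = "IV", grid = band4_grid())
  expect_equal(tab3$wco[tab3$pair == "LPFC-SMA"],
               tab$wco[tab$pair == "RPFC-SMA"], tolerance = 1e-12)
  expect_equal(tab3$wpco[tab3$pair == "LPFC-CPFC"],
               tab$wpco[tab$pair == "CPFC-RPFC"], tolerance = 1e-12)
})

test_that("the smoothed time-frequency map stays in bounds", {
  set.seed(17)
  fs <- 2
  g <- frequency_grid(0.05, 0.5, 6)
  x <- rnorm(600)
  s1 <- morlet_cwt(x, fs, g)
  m_self <- timefreq_coherence_map(s1, s1)
  inside <- !is.na(m_self$coherence)
  expect_true(any(inside))
  expect_true(all(abs(m_self$coherence[inside] - 1) < 1e-6))
  for (rep in 1:5) {
    s2 <- morlet_cwt(rnorm(600), fs, g)
    m <- timefreq_coherence_map(s1, s2)
    v <- m$coherence[!is.na(m$coherence)]
    expect_true(all(v >= 0 & v <= 1))
  }
})
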