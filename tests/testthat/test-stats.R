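make_wide <- function(n1 = 6, n2 = 6, shift = 0, p = 3, seed = 1) {
  set.seed(seed)
  g <- rep(c("expert", "novice"), c(n1, n2))
  out <- tibble::tibble(subject_id = sprintf("s%02d", seq_along(g)),
                        group = g)
  for (j in seq_len(p)) {
    out[[paste0("dv", j)]] <- rnorm(n1 + n2) + shift * (g == "novice")
  }
  out
}

test_that("Shapiro-Wilk holds its nominal type-I rate on Gaussian data", {
  set.seed(42)
  reject <- replicate(200, {
    d <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                        dv1 = rnorm(100))
    chk <- check_assumptions(d, alpha = 0.01)
    any(chk$shapiro$p_value < 0.01)
  })
  # 2 tests per replicate at alpha 0.01: expect ~2% of replicates
  expect_lte(mean(reject), 0.08)
})

test_that("Levene p-values are uniform under equal variances", {
  set.seed(43)
  ps <- replicate(200, {
    d <- tibble::tibble(group = rep(c("a", "b"), each = 20),
                        dv1 = rnorm(40))
    chk <- check_assumptions(d)
    chk$levene$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("constant cells are reported untestable, not fatal", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                      dv1 = c(rep(1, 5), rnorm(5)))
  chk <- check_assumptions(d)
  expect_true(chk$shapiro$untestable[chk$shapiro$group == "a"])
  expect_false(chk$shapiro$untestable[chk$shapiro$group == "b"])
})

test_that("MANOVA collapses to the Hotelling T^2 oracle for two groups", {
  # printed toy values: 2 DVs, 4 + 4 subjects
  X1 <- matrix(c(1.2, 0.8, 1.9, 1.4,
                 2.1, 1.7, 2.8, 2.2), ncol = 2)
  X2 <- matrix(c(2.0, 2.6, 1.8, 2.9,
                 3.1, 3.9, 2.7, 4.0), ncol = 2)
  d <- tibble::tibble(
    group = rep(c("g1", "g2"), each = 4),
    dv1 = c(X1[, 1], X2[, 1]),
    dv2 = c(X1[, 2], X2[, 2])
  )
  fit <- manova_wilks(d)
  oracle <- hotelling_t2(X1, X2)
  expect_equal(fit$wilks, oracle$lambda, tolerance = 1e-10)
  expect_equal(fit$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(fit$df1, oracle$df1)
  expect_equal(fit$df2, oracle$df2)

  # cross-check against the standard linear-model MANOVA machinery
  ref <- summary(stats::manova(cbind(dv1, dv2) ~ group, data = d),
                 test = "Wilks")
  expect_equal(fit$wilks, ref$stats[1, "Wilks"], tolerance = 1e-10)
  expect_equal(fit$statistic, ref$stats[1, "approx F"], tolerance = 1e-10)
})

test_that("MANOVA is invariant to subject order and null when means agree", {
  d <- make_wide(n1 = 8, n2 = 8, shift = 0.8, seed = 3)
  fit <- manova_wilks(d)
  d2 <- d[sample(nrow(d)), ]
  fit2 <- manova_wilks(d2)
  expect_equal(fit$wilks, fit2$wilks, tolerance = 1e-12)
  expect_equal(fit$p_value, fit2$p_value, tolerance = 1e-12)

  # identical group mean vectors: H = 0, Lambda = 1, F = 0
  base <- make_wide(n1 = 5, n2 = 5, seed = 4)
  dup <- base
  dup$group <- "expert"
  dup2 <- base
  dup2$group <- "novice"
  dd <- dplyr::bind_rows(dup, dup2)
  dd$subject_id <- sprintf("s%02d", seq_len(nrow(dd)))
  fit0 <- manova_wilks(dd)
  expect_equal(fit0$wilks, 1, tolerance = 1e-12)
  expect_equal(fit0$statistic, 0, tolerance = 1e-12)

  expect_error(manova_wilks(make_wide(n1 = 2, n2 = 2, p = 5)),
               "Too few subjects")
})

test_that("partial eta squared matches the explicit SS decomposition", {
  d <- tibble::tibble(group = c("a", "a", "b", "b"),
                      dv1 = c(0, 0, 1, 1),
                      dv2 = c(1, 2, 1, 2))
  eta <- partial_eta_squared(d)
  expect_equal(eta$eta_squared[eta$dv == "dv1"], 1)
  expect_equal(eta$eta_squared[eta$dv == "dv2"], 0)

  d2 <- make_wide(n1 = 7, n2 = 5, shift = 0.5, p = 2, seed = 9)
  eta2 <- partial_eta_squared(d2)
  g <- factor(d2$group)
  for (dv in c("dv1", "dv2")) {
    y <- d2[[dv]]
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    expect_equal(eta2$eta_squared[eta2$dv == dv], ssb / (ssb + ssw),
                 tolerance = 1e-12)
  }

  # MANOVA diagonal decomposition agrees
  fit <- manova_wilks(d2)
  expect_equal(fit$eta_squared$eta_squared, eta2$eta_squared,
               tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exhaustive relabeling enumeration", {
  res <- mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)

  # brute-force oracle: all C(8,4) = 70 labelings of a no-ties sample
  set.seed(6)
  z <- sample(rnorm(8))
  x <- z[1:4]; y <- z[5:8]
  u_stat <- function(a, b) {
    sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(8, 4)
  u_null <- apply(labelings, 2, function(idx) u_stat(z[idx], z[-idx]))
  mu <- 4 * 4 / 2
  p_oracle <- mean(abs(u_null - mu) >= abs(u_obs - mu))
  res2 <- mann_whitney_two_tailed(x, y)
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-12)

  # agreement with the standard implementation on fresh data
  xx <- rnorm(9); yy <- rnorm(5)
  ref <- stats::wilcox.test(xx, yy, exact = TRUE)
  got <- mann_whitney_two_tailed(xx, yy)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney symmetry and degenerate cases", {
  x <- c(0.1, 0.7, 1.3, 2.2)
  y <- c(0.4, 0.9, 3.1)
  a <- mann_whitney_two_tailed(x, y)
  b <- mann_whitney_two_tailed(y, x)
  expect_equal(a$U, length(x) * length(y) - b$U)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  same <- mann_whitney_two_tailed(1:4, 1:4)
  expect_equal(same$U, 8)
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney_two_tailed(numeric(0), 1:3), "Empty")
})

test_that("Bonferroni adjustment caps and scales correctly", {
  out <- bonferroni_adjust(c(0.001, rep(0.5, 9)), alpha = 0.05)
  expect_equal(out$p_adjusted[1], 0.01)
  expect_equal(out$p_adjusted[2], 1)
  expect_true(out$significant[1])
  expect_false(out$significant[2])
  single <- bonferroni_adjust(0.04)
  expect_equal(single$p_adjusted, 0.04)
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("power analysis reproduces the standard reference value", {
  est <- power_two_sample_t(d = 0.5, alpha = 0.05, power = 0.80)
  expect_equal(est$n_per_group, 64L)
  # agreement with the closed-form noncentral machinery
  ref <- stats::power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                             power = 0.80)
  expect_equal(est$n_per_group, as.integer(ceiling(ref$n)))

  # monotonicity: larger effects need no more subjects
  n_small <- power_two_sample_t(d = 1.0)$n_per_group
  n_large <- power_two_sample_t(d = 2.0)$n_per_group
  expect_lte(n_large, n_small)

  # pilot effect sizes of the surgical-training design are tiny-n
  big <- power_two_sample_t(d = 5.67, alpha = 0.05, power = 0.80)
  expect_lte(big$n_per_group, 4)
  expect_gte(big$achieved_power, 0.80)

  expect_error(power_two_sample_t(d = -1), "positive")
  expect_error(power_two_sample_t(d = 0.5, alpha = 1.5), "alpha")
})
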