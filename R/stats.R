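resolve_dvs <- function(data, group_col, dv_cols = NULL) {
  if (is.null(dv_cols)) {
    dv_cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], group_col)
  }
  if (length(dv_cols) == 0) abort("No numeric dependent variables found.")
  if (anyNA(data[dv_cols])) {
    abort("Missing cells in the dependent variables; complete cases required.")
  }
  dv_cols
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro--Wilk normality per dependent variable within each group,
#' and Levene's test (mean-centred) of variance homogeneity across
#' groups, for every dependent variable. Constant-valued cells are
#' reported as untestable rather than failing.
#'
#' @param data Wide tibble: one row per subject, a group column, one
#'   numeric column per dependent variable.
#' @param group_col Name of the group column (default `"group"`).
#' @param dv_cols Dependent-variable columns; default all numeric
#'   columns except the group.
#' @param alpha Flagging level (default 0.01).
#' @return List of class `assumption_checks`: `shapiro` (tibble: dv,
#'   group, statistic, p_value, untestable), `levene` (tibble: dv,
#'   statistic, df1, df2, p_value), `alpha`, `violations`.
#' @export
check_assumptions <- function(data, group_col = "group", dv_cols = NULL,
                              alpha = 0.01) {
  dv_cols <- resolve_dvs(data, group_col, dv_cols)
  g <- factor(data[[group_col]])
  if (any(table(g) < 3)) abort("Each group needs at least 3 subjects.")
  sw <- list()
  lv <- list()
  for (dv in dv_cols) {
    y <- data[[dv]]
    for (lev in levels(g)) {
      yi <- y[g == lev]
      res <- tryCatch(shapiro.test(yi), error = function(e) NULL)
      sw[[paste(dv, lev)]] <- tibble::tibble(
        dv = dv, group = lev,
        statistic = if (is.null(res)) NA_real_ else unname(res$statistic),
        p_value = if (is.null(res)) NA_real_ else res$p.value,
        untestable = is.null(res)
      )
    }
    lt <- tryCatch(
      car::leveneTest(y ~ g, center = mean),
      error = function(e) NULL
    )
    lv[[dv]] <- tibble::tibble(
      dv = dv,
      statistic = if (is.null(lt)) NA_real_ else lt$`F value`[1],
      df1 = if (is.null(lt)) NA_real_ else lt$Df[1],
      df2 = if (is.null(lt)) NA_real_ else lt$Df[2],
      p_value = if (is.null(lt)) NA_real_ else lt$`Pr(>F)`[1]
    )
  }
  shapiro <- dplyr::bind_rows(sw)
  levene <- dplyr::bind_rows(lv)
  violations <- dplyr::bind_rows(
    shapiro |>
      dplyr::filter(!.data$untestable, .data$p_value < alpha) |>
      dplyr::transmute(dv = .data$dv, test = "shapiro", group = .data$group),
    levene |>
      dplyr::filter(!is.na(.data$p_value), .data$p_value < alpha) |>
      dplyr::transmute(dv = .data$dv, test = "levene", group = NA_character_)
  )
  structure(list(shapiro = shapiro, levene = levene, alpha = alpha,
                 violations = violations),
            class = "assumption_checks")
}

#' @export
print.assumption_checks <- function(x, ...) {
  cat("<assumption_checks> alpha =", x$alpha, "\n")
  nv <- nrow(x$violations)
  if (nv == 0) cat("No violations flagged.\n")
  else {
    cat(nv, "violation(s):\n")
    print(x$violations)
  }
  invisible(x)
}

#' One-way MANOVA with Wilks' lambda
#'
#' Computes the between-group (H) and within-group (E) SSCP matrices,
#' Wilks' `Lambda = det(E) / det(E + H)`, Rao's F approximation (exact
#' for two groups), and the per-variable partial eta squared effect
#' sizes.
#'
#' @inheritParams check_assumptions
#' @return A `nirs_manova` object: `wilks`, `statistic` (F), `df1`,
#'   `df2`, `p_value`, `eta_squared` (tibble), `n`, `n_groups`,
#'   `dv_cols`.
#' @export
manova_wilks <- function(data, group_col = "group", dv_cols = NULL) {
  dv_cols <- resolve_dvs(data, group_col, dv_cols)
  g <- factor(data[[group_col]])
  Y <- as.matrix(data[dv_cols])
  n <- nrow(Y)
  p <- ncol(Y)
  k <- nlevels(g)
  if (k < 2) abort("At least two groups are required.")
  if (any(table(g) < 2)) abort("Each group needs at least 2 subjects.")
  if (n <= p + k - 1) {
    abort(paste0(
      "Too few subjects (", n, ") for ", p, " dependent variables and ",
      k, " groups; the within-group SSCP would be singular. ",
      "Reduce the number of dependent variables."
    ))
  }
  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    mi <- colMeans(Yi)
    H <- H + nrow(Yi) * tcrossprod(mi - grand)
    C <- sweep(Yi, 2, mi)
    E <- E + crossprod(C)
  }
  detE <- det(E)
  detEH <- det(E + H)
  if (!is.finite(detE) || detE <= 0 || detEH <= 0) {
    abort("Singular within-group SSCP; reduce the dependent variables.")
  }
  lambda <- detE / detEH

  q <- k - 1
  v <- n - k
  tden <- p^2 + q^2 - 5
  tt <- if (tden > 0) sqrt((p^2 * q^2 - 4) / tden) else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / df1)
  pval <- pf(Fstat, df1, df2, lower.tail = FALSE)

  hd <- unname(diag(H))
  ed <- unname(diag(E))
  eta <- tibble::tibble(
    dv = dv_cols,
    ss_between = hd,
    ss_within = ed,
    eta_squared = ifelse(hd + ed > 0, hd / (hd + ed), NA_real_)
  )
  structure(
    list(wilks = lambda, statistic = Fstat, df1 = df1, df2 = df2,
         p_value = pval, eta_squared = eta, n = n, n_groups = k,
         dv_cols = dv_cols, H = H, E = E),
    class = "nirs_manova"
  )
}

#' @export
print.nirs_manova <- function(x, ...) {
  cat(sprintf(
    "<nirs_manova> Wilks' Lambda = %.4f, F(%g, %g) = %.3f, p = %.4g (n = %d, %d groups)\n",
    x$wilks, x$df1, x$df2, x$statistic, x$p_value, x$n, x$n_groups
  ))
  invisible(x)
}

#' @method tidy nirs_manova
#' @export
tidy.nirs_manova <- function(x, ...) x$eta_squared

#' @method glance nirs_manova
#' @export
glance.nirs_manova <- function(x, ...) {
  tibble::tibble(wilks = x$wilks, statistic = x$statistic,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value,
                 n = x$n, n_groups = x$n_groups)
}

#' Per-variable partial eta squared
#'
#' One-way ANOVA decomposition per dependent variable:
#' `eta^2 = SS_between / (SS_between + SS_within)`. Variables with
#' zero total sum of squares are flagged as undefined.
#'
#' @inheritParams check_assumptions
#' @return Tibble: `dv`, `ss_between`, `ss_within`, `eta_squared`.
#' @export
partial_eta_squared <- function(data, group_col = "group", dv_cols = NULL) {
  dv_cols <- resolve_dvs(data, group_col, dv_cols)
  g <- factor(data[[group_col]])
  rows <- lapply(dv_cols, function(dv) {
    y <- data[[dv]]
    fit <- stats::aov(y ~ g)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    tot <- sum(ss)
    tibble::tibble(
      dv = dv, ss_between = ss[1], ss_within = ss[2],
      eta_squared = if (tot > 0) ss[1] / tot else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Two-tailed Mann--Whitney U test
#'
#' Rank-sum U with midranks for ties. The two-tailed p-value is exact
#' (null distribution enumeration) whenever there are no ties and both
#' samples have at most 50 observations; otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return A `mw_test` object: `U` (for the first sample), `p_value`,
#'   `method`, `n1`, `n2`, and group summaries (mean, sd).
#' @export
#' @examples
#' mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
mann_whitney_two_tailed <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Empty sample.")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= 50 && n2 <= 50) {
    method <- "exact"
    if (U > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    method <- "normal approximation (tie-corrected)"
    ntot <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((ntot + 1) - sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0 || U == mu) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(
    list(U = U, p_value = p, method = method, n1 = n1, n2 = n2,
         summary = tibble::tibble(
           sample = c("x", "y"), n = c(n1, n2),
           mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y))
         )),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, two-tailed p = %.4g (%s; n = %d vs %d)\n",
              x$U, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, method = x$method,
                 n1 = x$n1, n2 = x$n2,
                 mean_x = x$summary$mean[1], sd_x = x$summary$sd[1],
                 mean_y = x$summary$mean[2], sd_y = x$summary$sd[2])
}

#' Bonferroni correction
#'
#' @param p Vector of p-values.
#' @param alpha Decision level (default 0.05).
#' @return Tibble: `p`, `p_adjusted` (`min(1, m * p)`), `significant`
#'   (`p_adjusted < alpha`).
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  adj <- p.adjust(p, method = "bonferroni")
  tibble::tibble(p = p, p_adjusted = adj, significant = adj < alpha)
}

#' A priori power analysis for a two-sample t-test
#'
#' Smallest integer per-group n such that the two-sided two-sample
#' t-test at level `alpha` reaches the target power against a
#' standardised effect size `d` (noncentral-t power with
#' noncentrality `d * sqrt(n / 2)` on `2n - 2` df).
#'
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search cap (error if the target is unattainable below
#'   it).
#' @return A `power_estimate`: `d`, `alpha`, `power_target`,
#'   `n_per_group`, `achieved_power`.
#' @export
#' @examples
#' power_two_sample_t(d = 0.5)          # 64 per group
#' power_two_sample_t(d = 5.67, alpha = 0.05, power = 0.80)
power_two_sample_t <- function(d, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (d <= 0) abort("`d` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1).")
  pow_at <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  }
  n <- 2
  while (pow_at(n) < power) {
    n <- n + 1
    if (n > n_max) abort("Target power unattainable within `n_max`.")
  }
  structure(
    list(d = d, alpha = alpha, power_target = power,
         n_per_group = as.integer(n), achieved_power = pow_at(n)),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "<power_estimate> d = %g, alpha = %g, target power = %g -> n = %d per group (power %.3f)\n",
    x$d, x$alpha, x$power_target, x$n_per_group, x$achieved_power
  ))
  invisible(x)
}

#' @method tidy power_estimate
#' @export
tidy.power_estimate <- function(x, ...) {
  tibble::tibble(d = x$d, alpha = x$alpha, power_target = x$power_target,
                 n_per_group = x$n_per_group,
                 achieved_power = x$achieved_power)
}
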