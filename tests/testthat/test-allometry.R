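test_that("log10 transform is elementwise, propagates missing values and rejects non-positive cells", {
  ch <- cohort(data.frame(specimen_id = c("a", "b", "c"),
                          cbl = c(100, 88.7, 150),
                          v_mal = c(10, NA, 12)))
  m <- log10_transform(ch, c("cbl", "v_mal"))
  expect_equal(m["a", "cbl"], 2)
  expect_equal(m["b", "cbl"], log10(88.7))
  expect_true(is.na(m["b", "v_mal"]))
  bad <- ch
  bad$v_mal[1] <- -1
  expect_error(log10_transform(bad, "v_mal"), "v_mal.*'a'")
})

test_that("pearson matrix reproduces hand-computed and perfect correlations", {
  ch <- cohort(data.frame(
    specimen_id = letters[1:5],
    cbl = 10^(1:5),
    msw = 10^(1:5) / 2,               # cephalic index constant
    v_cav = 10^c(1, 3, 2, 5, 4),      # hand example: r = 0.8
    v_mal = 10^(2 * (1:5)),           # exact y = 2x: r = 1
    v_inc = 10^(-(1:5) + 6),          # exact y = -x + 6: r = -1
    v_stp = c(0.5, 0.6, NA, NA, NA)   # only 2 complete pairs: undefined
  ))
  r <- pearson_matrix(ch, ear_traits = c("v_cav", "v_mal", "v_inc", "v_stp"),
                      skull_vars = c("cbl", "msw"))
  expect_equal(r["cbl", "v_cav"], 0.8, tolerance = 1e-12)
  expect_equal(r["cbl", "v_mal"], 1, tolerance = 1e-12)
  expect_equal(r["cbl", "v_inc"], -1, tolerance = 1e-12)
  expect_true(is.na(r["cbl", "v_stp"]))
  expect_equal(attr(r, "n")["cbl", "v_stp"], 2)
  expect_equal(attr(r, "n")["cbl", "v_cav"], 5)
})

test_that("projected specimens never enter correlations", {
  ch <- random_cohort(seed = 6)          # last specimen is projected
  r_all <- pearson_matrix(ch, ear_traits = "v_cav", skull_vars = "cbl")
  dropped <- ch[ch$role == "fit", , drop = FALSE]
  class(dropped) <- class(ch)
  r_fit <- pearson_matrix(dropped, ear_traits = "v_cav", skull_vars = "cbl")
  expect_equal(r_all[1, 1], r_fit[1, 1], tolerance = 1e-15)
})

test_that("the 5-point worked fit gives the hand-computed coefficients and test", {
  f <- fit_loglog(1:5, c(1, 3, 2, 5, 4), expected = 3)
  expect_equal(f$slope, 0.8)
  expect_equal(f$intercept, 0.6)
  expect_equal(f$r2, 0.64)
  expect_equal(f$se_slope, sqrt(0.12), tolerance = 1e-9)
  expect_equal(f$t_stat, (0.8 - 3) / sqrt(0.12), tolerance = 1e-9)
  expect_equal(f$p_value, 2 * pt((0.8 - 3) / sqrt(0.12), df = 3),
               tolerance = 1e-9)
  expect_equal(round(f$p_value, 5), 0.0079)
  # residuals of an OLS fit with intercept sum to zero
  expect_equal(unname(f$residuals), c(-0.4, 0.8, -1.0, 1.2, -0.6))
  expect_equal(f$sd_resid, sqrt(3.6 / 4), tolerance = 1e-12)
})

test_that("closed-form OLS agrees with the QR-based lm oracle on 100 random datasets", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- rnorm(n, mean = runif(1, -2, 2) + runif(1, -3, 3) * x,
               sd = runif(1, 0.01, 2))
    f <- fit_loglog(x, y, expected = 3)
    o <- lm(y ~ x)
    so <- summary(o)
    expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-9)
    expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-9)
    expect_equal(f$r2, so$r.squared, tolerance = 1e-9)
    expect_equal(f$se_slope, so$coefficients[2, 2], tolerance = 1e-9)
    expect_equal(unname(f$residuals), unname(resid(o)), tolerance = 1e-9)
    # internal consistency invariants
    expect_equal(f$r2, f$r^2, tolerance = 1e-12)
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-12)
    expect_lt(abs(sum(f$residuals)), 1e-9)
    z <- standardized_residuals(f)$z
    if (f$sd_resid > 0) expect_equal(sd(z), 1, tolerance = 1e-9)
  }
})

test_that("degenerate designs and exact fits are handled as the continuous limit", {
  # exact isometry: slope equals expectation, zero residuals -> p = 1
  x <- c(1, 2, 3, 4)
  f <- fit_loglog(x, 3 * x + 1, expected = 3)
  expect_equal(f$slope, 3)
  expect_equal(f$r2, 1)
  expect_true(is.na(f$t_stat))
  expect_equal(f$p_value, 1)
  expect_equal(standardized_residuals(f)$z, rep(0, 4))
  # exact fit with slope away from expectation -> p = 0
  g <- fit_loglog(x, 2 * x, expected = 3)
  expect_equal(g$p_value, 0)
  expect_error(fit_loglog(c(1, 1, 1), c(1, 2, 3), expected = 3),
               "constant")
  expect_error(fit_loglog(1:2, 1:2, expected = 1), "at least 3")
})

test_that("standardized residuals flag |z| > 2 and respect the (n-1) denominator", {
  set.seed(9)
  x <- 1:10
  y <- 0.5 * x + rnorm(10, sd = 0.1)
  y[4] <- y[4] + 2                       # planted deviation
  f <- fit_loglog(x, y, expected = 1)
  z <- standardized_residuals(f)
  expect_equal(z$z, unname(f$residuals) / sd(f$residuals))
  expect_true(z$outlier[4])
  expect_equal(sum(z$outlier), 1)
})

test_that("held-out projection uses the fit's residual SD and warns off-range", {
  f <- fit_loglog(1:5, c(1, 3, 2, 5, 4), expected = 3)
  # a point exactly on the line
  expect_equal(project_specimen(f, 3, 0.6 + 0.8 * 3), 0)
  # a point one residual-SD above the line
  y0 <- (0.6 + 0.8 * 6) + f$sd_resid
  expect_warning(z <- project_specimen(f, 6, y0), "outside")
  expect_equal(z, 1, tolerance = 1e-12)
  # inside the 20% margin: no warning
  expect_no_warning(project_specimen(f, 5.5, 5))
  # zero residual variance -> undefined
  g <- fit_loglog(1:4, 2 * (1:4), expected = 2)
  expect_warning(zz <- project_specimen(g, 2, 4), "undefined")
  expect_true(is.na(zz))
})

test_that("natural-unit prediction follows the fitted power law", {
  ident <- fit_loglog(c(1, 2, 3), c(1, 2, 3), expected = 1)
  expect_equal(predict_trait(ident, 7), 7, tolerance = 1e-12)
  # cavity-volume power law evaluated at the largest skull in the study
  x <- c(1.9, 2.1, 2.4)
  f <- fit_loglog(x, -1.424 + 2.077 * x, expected = 3)
  expect_equal(predict_trait(f, 240), 10^(-1.424 + 2.077 * log10(240)),
               tolerance = 1e-6)
  # monotone increasing in cbl for positive slope
  cbls <- seq(80, 260, by = 20)
  expect_true(all(diff(predict_trait(f, cbls)) > 0))
  expect_error(predict_trait(f, -1), "> 0")
})

test_that("per-trait casewise deletion: a missing trait only affects its own fit", {
  ch <- random_cohort(seed = 12)
  ch$v_mal[2] <- NA
  fits <- fit_cohort(ch)
  n_fit <- sum(ch$role == "fit")
  expect_equal(fits$v_mal$n, n_fit - sum(is.na(fit_specimens(ch)$v_mal)))
  expect_equal(fits$v_cav$n, n_fit)
  expect_equal(fits$v_cav$expected_slope, 3)
  expect_equal(fits$a_tm$expected_slope, 2)
  tab <- summary(fits)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$trait, ear_traits())
})

test_that("expected isometric slopes follow the trait class", {
  expect_equal(unname(expected_slope(c("v_cav", "a_tm", "malleus_length"))),
               c(3, 2, 1))
})
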