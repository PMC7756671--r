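# Environmental driver regressions and class-binned fitting.

test_that("a noiseless water-table relation is recovered exactly", {
  wt <- seq(-40, 20, by = 2)
  dat <- data.frame(wt = wt, ch4 = 14.95 * wt + 616.09)
  m <- fit_driver_model(dat, "ch4", "wt")
  expect_equal(unname(m$coefficients["wt"]), 14.95, tolerance = 1e-10)
  expect_equal(m$intercept, 616.09, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  # predictions reproduce the inputs
  expect_equal(predict(m, dat), dat$ch4, tolerance = 1e-10)
  expect_equal(predict(m, data.frame(wt = 0)), 616.09, tolerance = 1e-10)
})

test_that("a noisy log-offset bivariate model is recovered within 3 SE", {
  set.seed(21)
  n <- 1e4
  dat <- data.frame(co2 = runif(n, 10, 80), wfps = runif(n, 40, 100))
  eta <- 0.03 * dat$co2 + 0.01 * dat$wfps + 0.63 + rnorm(n, 0, 0.3)
  dat$n2o <- exp(eta) - 4
  m <- fit_driver_model(dat, "n2o", c("co2", "wfps"), transform = "ln_offset")
  expect_lt(abs(m$coefficients["co2"] - 0.03) / m$coef_se["co2"], 3)
  expect_lt(abs(m$coefficients["wfps"] - 0.01) / m$coef_se["wfps"], 3)
  expect_lt(abs(m$intercept - 0.63) / m$intercept_se, 3)
  expect_equal(m$n, n)
})

test_that("OLS output matches the normal-equations oracle", {
  set.seed(22)
  for (i in 1:5) {
    n <- 30
    dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    dat$y <- 2 + 1.5 * dat$x1 - 0.7 * dat$x2 + rnorm(n)
    m <- fit_driver_model(dat, "y", c("x1", "x2"))
    X <- cbind(1, dat$x1, dat$x2)
    beta <- solve(t(X) %*% X, t(X) %*% dat$y)
    resid <- dat$y - X %*% beta
    sigma2 <- sum(resid^2) / (n - 3)
    ses <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
    expect_equal(unname(coef(m)), as.vector(beta), tolerance = 1e-10)
    expect_equal(unname(c(m$intercept_se, m$coef_se)), ses, tolerance = 1e-10)
  }
})

test_that("degenerate responses and designs are handled", {
  dat <- data.frame(x = 1:10, y = rep(5, 10))
  m <- fit_driver_model(dat, "y", "x")
  expect_equal(m$r2, 0)
  expect_equal(unname(m$coefficients["x"]), 0, tolerance = 1e-12)
  # collinear terms
  dat$x2 <- 2 * dat$x
  expect_error(fit_driver_model(dat, "y", c("x", "x2")), "collinear")
  # offset violation names the offending rows
  bad <- data.frame(x = 1:5, y = c(1, 2, -5, 3, 4))
  expect_error(fit_driver_model(bad, "y", "x", transform = "ln_offset"),
               "rows")
})

test_that("log-offset back-transform round trips and has its fixed point", {
  x <- seq(0, 10, by = 0.5)
  dat <- data.frame(x = x, y = exp(0.2 * x + 0.5) - 4)
  m <- fit_driver_model(dat, "y", "x", transform = "ln_offset")
  expect_equal(predict(m, dat), dat$y, tolerance = 1e-8)
  # eta = ln 4 maps to zero flux
  m0 <- driver_model(c(x = 0), log(4), transform = "ln_offset")
  expect_equal(predict(m0, data.frame(x = 3)), 0, tolerance = 1e-12)
})

test_that("exponential and quadratic forms evaluate correctly", {
  x <- seq(-30, 10, by = 1)
  dat <- data.frame(wt = x, y = exp(0.05 * x + 6))
  m <- fit_driver_model(dat, "y", "wt", form = "exponential")
  expect_equal(unname(m$coefficients["wt"]), 0.05, tolerance = 1e-10)
  expect_equal(predict(m, data.frame(wt = 0)), exp(6), tolerance = 1e-8)
  # positive slope: predictions increase with the water table
  expect_true(all(diff(predict(m, dat)) > 0))

  w <- seq(30, 90, by = 2)
  datq <- data.frame(wfps = w, y = -0.02 * (w - 55)^2 + 12)
  mq <- fit_driver_model(datq, "y", "wfps", form = "quadratic")
  vertex <- -mq$coefficients["wfps"] / (2 * mq$coefficients["wfps^2"])
  expect_equal(unname(vertex), 55, tolerance = 1e-8)
})

test_that("R2 never decreases when a term is added", {
  set.seed(23)
  for (i in 1:5) {
    dat <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
    dat$y <- dat$x1 + rnorm(40)
    r1 <- fit_driver_model(dat, "y", "x1")$r2
    r2 <- fit_driver_model(dat, "y", c("x1", "x2"))$r2
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("binned fits agree with unbinned fits for linear truths", {
  set.seed(24)
  n <- 5000
  dat <- data.frame(wfps = runif(n, 0, 100))
  dat$y <- 2 * dat$wfps + 10 + rnorm(n, 0, 5)
  unbinned <- fit_driver_model(dat, "y", "wfps")
  binned <- bin_and_fit(dat, "y", "wfps", width = 2)
  expect_equal(unname(binned$model$coefficients["wfps"]),
               unname(unbinned$coefficients["wfps"]), tolerance = 0.01)
  expect_error(bin_and_fit(dat, "y", "wfps", width = 200), "3 non-empty")
})

test_that("a quadratic WFPS optimum is located from binned monthly data", {
  set.seed(25)
  n <- 2000
  dat <- data.frame(wfps = runif(n, 20, 95))
  dat$y <- -0.01 * (dat$wfps - 55)^2 + 8 + rnorm(n, 0, 3)
  bf <- bin_and_fit(dat, "y", "wfps", width = 10, form = "quadratic")
  vertex <- -bf$model$coefficients["wfps"] /
    (2 * bf$model$coefficients["wfps^2"])
  expect_lt(abs(vertex - 55), 20)  # within two 10% classes of the optimum
  expect_gte(nrow(bf$bins), 3)
})

test_that("the bundled catalog round-trips through driver_model", {
  cat_df <- driver_catalog()
  expect_equal(nrow(cat_df), 30)
  m30 <- catalog_model(30)
  expect_equal(unname(m30$coefficients["wt"]), 14.95)
  expect_equal(m30$intercept, 616.09)
  expect_identical(m30$transform, "identity")
  m15 <- catalog_model(15)
  expect_identical(m15$transform, "ln_offset")
  expect_equal(unname(m15$coefficients[c("co2", "wfps")]), c(0.03, 0.01))
  # intercept-only evaluation of the log-offset model
  expect_equal(predict(m15, data.frame(co2 = 0, wfps = 0)),
               exp(0.63) - 4, tolerance = 1e-12)
})
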