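# Monthly means, annual trapezoid budgets, site-scale weighting,
# multi-year summaries and interval comparison.

test_that("monthly means follow the replicate arithmetic", {
  m <- monthly_mean(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$se, 1 / sqrt(3))  # sd 1 over sqrt(n)
  expect_equal(m$n, 3L)

  same <- monthly_mean(rep(4.2, 9))
  expect_equal(same$mean, 4.2)
  expect_equal(same$se, 0)

  gap <- monthly_mean(c(1:8, NA))
  expect_equal(gap$n, 8L)
  expect_equal(gap$mean, mean(1:8))
  expect_warning(all_na <- monthly_mean(c(NA_real_, NA_real_)), "missing")
  expect_true(is.na(all_na$mean))
})

test_that("the vectorised table path matches per-group monthly_mean", {
  set.seed(8)
  df <- expand.grid(site = c("A", "B"), status = "live",
                    microtopography = c("hummock", "hollow"),
                    date = as.Date("2015-04-15") + c(0, 30, 61),
                    rep = 1:9, stringsAsFactors = FALSE)
  df$flux <- rnorm(nrow(df), 500, 200)
  df$flux[sample(nrow(df), 10)] <- NA
  got <- monthly_means(df)
  key <- interaction(df[c("site", "status", "microtopography", "date")],
                     drop = TRUE)
  for (i in sample(nrow(got), 8)) {
    rows <- df$site == got$site[i] & df$microtopography ==
      got$microtopography[i] & df$date == got$date[i]
    want <- monthly_mean(df$flux[rows])
    expect_equal(got$mean[i], want$mean)
    expect_equal(got$se[i], want$se)
    expect_equal(got$n[i], want$n)
  }
})

test_that("annual integration reproduces closed-form integrals", {
  ws <- as.Date("2016-04-01")  # a 365-day window (no Feb 29 inside)
  # constant flux: 365 * f / 1000 exactly
  d <- seq(ws, by = "month", length.out = 12)
  b <- annual_cumulative(d, rep(10, 12), window_start = ws)
  expect_equal(b$cumulative, 365 * 10 / 1000)
  # two dates at the window edges: a single trapezoid
  b2 <- annual_cumulative(c(ws, ws + 365), c(4, 8), window_start = ws)
  expect_equal(b2$cumulative, 365 * (4 + 8) / 2 / 1000)
  # sinusoid over evenly spaced months vs the analytic integral
  days <- as.numeric(d - ws)
  f <- 100 + 50 * sin(2 * pi * days / 365)
  b3 <- annual_cumulative(d, f, window_start = ws)
  analytic <- (100 * 365 + 50 * 365 / (2 * pi) *
                 (1 - cos(2 * pi))) / 1000  # = 36.5
  expect_equal(b3$cumulative, analytic, tolerance = 0.02)
})

test_that("trapezoid weights match independent basis-vector integration", {
  # oracle: integrate each unit basis vector with approx() + trapezoid sums
  ws <- as.Date("2016-04-01")
  set.seed(3)
  d <- sort(ws + sample(-20:380, 13))
  trapz_oracle <- function(dates, values, s, e) {
    knots <- sort(unique(c(s, dates[dates > s & dates < e], e)))
    yk <- approx(as.numeric(dates), values, xout = as.numeric(knots),
                 rule = 2)$y
    sum(diff(as.numeric(knots)) * (yk[-1] + yk[-length(yk)]) / 2)
  }
  f <- runif(13, 0, 100)
  b <- annual_cumulative(d, f, window_start = ws)
  expect_equal(b$cumulative * 1000, trapz_oracle(d, f, ws, ws + 365),
               tolerance = 1e-10)
  w_oracle <- vapply(1:13, function(i) {
    ei <- numeric(13); ei[i] <- 1
    trapz_oracle(d, ei, ws, ws + 365)
  }, numeric(1))
  expect_equal(b$weights, w_oracle, tolerance = 1e-10)
})

test_that("annual integration is linear and sign-preserving", {
  ws <- as.Date("2016-04-01")
  d <- seq(ws - 10, by = "5 weeks", length.out = 12)
  set.seed(4)
  f1 <- runif(12, 0, 50); f2 <- runif(12, 0, 50)
  a1 <- annual_cumulative(d, f1, window_start = ws)$cumulative
  a2 <- annual_cumulative(d, f2, window_start = ws)$cumulative
  a12 <- annual_cumulative(d, f1 + f2, window_start = ws)$cumulative
  expect_equal(a12, a1 + a2, tolerance = 1e-10)
  expect_gte(a1, 0)
  expect_error(annual_cumulative(d[1], 1, window_start = ws), "at least 2")
  expect_error(annual_cumulative(d, f1, window_start = ws,
                                 window_end = ws + 200), "365 or 366")
})

test_that("SE propagation through the trapezoid agrees with simulation", {
  ws <- as.Date("2016-04-01")
  d <- seq(ws, by = "month", length.out = 12)
  mu <- rep(100, 12); se <- rep(10, 12)
  b <- annual_cumulative(d, mu, se, window_start = ws)
  set.seed(11)
  sims <- replicate(3000, {
    annual_cumulative(d, rnorm(12, mu, se), window_start = ws)$cumulative
  })
  expect_equal(b$se, sd(sims), tolerance = 0.05)
})

test_that("area weighting reproduces the convexity identity and errors", {
  w <- c(a = 0.3, b = 0.7)
  expect_equal(site_scale(c(a = 5, b = 5), w)$mean, 5)
  # permutation invariance and bounds
  v <- c(a = 2, b = 10)
  expect_equal(site_scale(v, w)$mean, site_scale(rev(v), rev(w))$mean)
  expect_true(site_scale(v, w)$mean >= min(v) && site_scale(v, w)$mean <= max(v))
  expect_error(site_scale(c(a = 1, b = 2), c(a = 1)), "weights")
  expect_error(site_scale(c(a = 1, b = 2), c(a = 0.4, b = 0.4)), "sum to 1")
  # Gaussian propagation of stratum SEs
  s <- site_scale(v, w, ses = c(a = 1, b = 2))
  expect_equal(s$se, sqrt(0.3^2 * 1 + 0.7^2 * 4))
})

test_that("multi-year summaries give mean and SD/sqrt(N)", {
  s <- multi_year_summary(c(319.4, 212.0, 145.3))
  expect_equal(round_half_up(s$mean), 225.6)
  expect_equal(round_half_up(s$se), 50.7)
  s2 <- multi_year_summary(c(0.5, 2.6, 0.9))
  expect_equal(round_half_up(s2$mean), 1.3)
  expect_equal(round_half_up(s2$se), 0.6)
  s3 <- multi_year_summary(rep(7, 3))
  expect_equal(s3$mean, 7)
  expect_equal(s3$se, 0)
  expect_true(is.na(multi_year_summary(5)$se))
})

test_that("interval overlap decides significance", {
  expect_identical(compare_intervals(1.3, 0.6, 0.5, 0.1), "different")
  expect_identical(compare_intervals(1.0, 0.5, 1.5, 0.1), "not_different")
  # touching endpoints: closed intervals overlap
  expect_identical(compare_intervals(1.0, 0.5, 2.0, 0.5), "not_different")
})
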