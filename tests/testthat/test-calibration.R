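test_that("IntCal-dialect parser interpolates, sorts, and rejects bad input", {
  cv <- read_cal_curve(toy_curve_lines, resolution = 1)
  expect_length(cv$grid, 201L)
  expect_equal(cv$mu[cv$grid == 50], 140)        # linear interpolation midpoint
  expect_equal(cv$mu[cv$grid == 150], 235)
  expect_equal(cv$sigma[cv$grid == 200], 12)

  # decreasing rows are accepted and re-sorted to an identical result
  cv_rev <- read_cal_curve(rev(toy_curve_lines[-1]), resolution = 1)
  expect_equal(cv_rev$grid, cv$grid)
  expect_equal(cv_rev$mu, cv$mu)

  # whitespace dialect and extra columns
  cv_ws <- read_cal_curve(c("0 100 10 999", "100 180 10 999", "200 290 12 999"),
                          resolution = 1)
  expect_equal(cv_ws$mu, cv$mu)

  expect_error(read_cal_curve(c("0,100", "100,180"), resolution = 1),
               "at least 3 columns")
  expect_error(read_cal_curve(c("0,100,10", "0,105,10", "200,290,12"),
                              resolution = 1), "duplicate")
  expect_error(read_cal_curve(c("0,100,10", "100,180,0", "200,290,12"),
                              resolution = 1), "positive")
})

test_that("radiocarbon calibration on the identity curve is the measurement Gaussian", {
  cv <- make_curve("identity", range = c(3000, 7000), resolution = 1)
  d <- geochron_date(5000, 50)
  dens <- calibrate_radiocarbon(d, cv)
  expect_equal(sum(dens$p), 1, tolerance = 1e-9)
  expect_true(all(dens$p >= 0))
  expect_equal(density_quantile(dens, 0.5), 5000)
  # closed-form Normal quantiles within one grid step
  for (q in c(0.05, 0.3173, 0.5, 0.6827, 0.95)) {
    expect_within(density_quantile(dens, q),
                  round(5000 + qnorm(1 - q) * 50), 1)
  }
})

test_that("asymmetric errors give a two-piece density matching the closed form", {
  cv <- make_curve("identity", range = c(0, 3000), resolution = 1)
  d <- geochron_date(1200, error_minus = 110, error_plus = 70)
  dens <- calibrate_radiocarbon(d, cv)
  # mass below the mode is sigma_minus / (sigma_minus + sigma_plus)
  expect_equal(sum(dens$p[dens$grid < 1200]), 110 / 180, tolerance = 0.01)
  med <- density_quantile(dens, 0.5)
  expect_lt(med, 1200)
  # closed-form two-piece median: CDF(x) = (2 s- / (s- + s+)) Phi((x-m)/s-)
  med_expected <- 1200 + 110 * qnorm(0.5 * 180 / 220)
  expect_within(med, round(med_expected), 1)
})

test_that("calendar densities sit on the cal BP axis and renormalize on truncation", {
  cv <- make_curve("identity", range = c(0, 55000), resolution = 5)
  tl <- geochron_date(25000, 2000, kind = "calendar")
  dens <- calendar_density(tl, cv)
  expect_within(density_quantile(dens, 0.5), 25000, 5)
  # pre-calibrated radiocarbon treated as calendar
  pc <- geochron_date(9500, 120, kind = "calendar")
  expect_within(density_quantile(calendar_density(pc, cv), 0.5), 9500, 5)
  # truncated tail: quantiles match the closed-form truncated Normal
  tr <- geochron_date(54000, 3000, kind = "calendar")
  dt <- calendar_density(tr, cv)
  expect_equal(sum(dt$p), 1, tolerance = 1e-9)
  mass_hi <- (pnorm(55000, 54000, 3000) - pnorm(50000, 54000, 3000)) /
             (pnorm(55000, 54000, 3000) - pnorm(0, 54000, 3000))
  expect_equal(sum(dt$p[dt$grid >= 50000]), mass_hi, tolerance = 0.005)
})

test_that("density_quantile follows the from-the-old-end convention", {
  g <- 1000:2000
  unif <- neochron:::new_cal_density(g, rep(1, length(g)))
  expect_equal(density_quantile(unif, 0.5), 1500)
  g2 <- 0:1000
  unif2 <- neochron:::new_cal_density(g2, rep(1, length(g2)))
  expect_equal(density_quantile(unif2, 0.3173), 683)
  # smaller from-old fraction = older age, for arbitrary densities
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(101)
    d <- neochron:::new_cal_density(seq(0, 1000, 10), p)
    qs <- density_quantile(d, c(0.1, 0.3, 0.5, 0.7, 0.9))
    expect_true(all(diff(qs) <= 0))
  }
  expect_error(density_quantile(unif, 0), "strictly inside")
  expect_error(density_quantile(unif, 1), "strictly inside")
})

test_that("summarize_control reports median and 5/95 from-old limits", {
  cv <- make_curve("identity", range = c(4000, 6000), resolution = 1)
  d <- geochron_date(5000, 50, lab_id = "LAB-1")
  ctl <- summarize_control(calibrate_radiocarbon(d, cv), d)
  expect_within(ctl$age, 5000, 1)
  expect_within(ctl$agelimitolder, 5082, 1)
  expect_within(ctl$agelimityounger, 4918, 1)
  expect_true(ctl$agelimityounger <= ctl$age && ctl$age <= ctl$agelimitolder)
  expect_identical(ctl$labnumber, "LAB-1")
})

test_that("quantiles on a wiggly curve match a 10x finer-grid CDF oracle", {
  mkdens <- function(res) {
    cv <- make_curve("wiggly", range = c(2000, 8000), resolution = res,
                     amplitude = 40, period = 700, sigma = 10)
    calibrate_radiocarbon(geochron_date(5000, 60), cv)
  }
  coarse <- mkdens(1)
  fine <- mkdens(0.1)
  # independent oracle: raw cumulative sum on the fine grid, no interpolation
  fine_q <- function(q) {
    cum <- cumsum(rev(fine$p))
    rev(fine$grid)[which(cum >= q)[1]]
  }
  for (q in c(0.05, 0.5, 0.95))
    expect_within(density_quantile(coarse, q), fine_q(q), 1)
})

test_that("calibration medians are monotone in the measured 14C age", {
  cv <- make_curve("linear", range = c(0, 12000), resolution = 5,
                   a = 100, b = 1.1, sigma = 15)
  meds <- vapply(seq(2000, 9000, by = 500), function(x)
    density_quantile(calibrate_radiocarbon(geochron_date(x, 80), cv), 0.5),
    numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("unusable dates are refused by the calibrators", {
  cv <- make_curve("identity", range = c(0, 1000), resolution = 1)
  expect_error(calibrate_radiocarbon(
    geochron_date(31500, 0, single_sided = TRUE), cv), "single-sided")
  expect_error(calibrate_radiocarbon(geochron_date(500, 0), cv),
               "missing or zero")
  expect_error(calibrate_radiocarbon(geochron_date(54000, 50), cv),
               "out of range")
  expect_error(calendar_density(geochron_date(500, NA, kind = "calendar"), cv),
               "missing or zero")
  expect_error(calibrate_radiocarbon(geochron_date(500, 50, kind = "calendar"), cv),
               "expects a radiocarbon")
})
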