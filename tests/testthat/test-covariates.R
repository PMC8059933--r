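test_that("season is a pure function of month with five dry months", {
  expect_equal(season_of(as.Date("2005-07-15")), "dry")
  expect_equal(season_of(as.Date("2005-12-01")), "wet")
  ## boundary: May 31 wet, June 1 dry; Oct 31 dry, Nov 1 wet
  expect_equal(season_of(as.Date(c("2005-05-31", "2005-06-01",
                                   "2005-10-31", "2005-11-01"))),
               c("wet", "dry", "dry", "wet"))
  months <- seq(as.Date("2004-01-15"), by = "month", length.out = 12)
  expect_equal(sum(season_of(months) == "dry"), 5L)
})

test_that("3-month rainfall anomaly matches brute-force sums", {
  ## identical record every year: anomaly 0
  w <- toy_weather(2003:2005, rain = function(d) {
    md <- as.integer(format(d, "%d")) + 3 * as.integer(format(d, "%m"))
    (md %% 7) / 3
  })
  ## query window (May-July) avoids the leap day, so the record really is
  ## identical across years over the window
  a <- rainfall_anomaly_3mo(w, as.Date("2004-08-01"))
  expect_lt(abs(a), 1e-9)

  ## brute force on an arbitrary record
  set.seed(1)
  w2 <- toy_weather(2003:2005, rain = function(d) stats::rexp(length(d), 1))
  qd <- as.Date("2004-09-15")
  win <- function(end_year) {
    dd <- as.Date(sprintf("%d-09-15", end_year))
    sum(w2$rain_mm[w2$date >= dd - 90 & w2$date <= dd - 1])
  }
  expected <- win(2004) - mean(c(win(2003), win(2004), win(2005)))
  expect_equal(rainfall_anomaly_3mo(w2, qd), expected, tolerance = 1e-12)

  ## linearity: +1 mm/day in the focal window only
  w3 <- w2
  focal <- w3$date >= qd - 90 & w3$date <= qd - 1
  w3$rain_mm[focal] <- w3$rain_mm[focal] + 1
  ## the long-term mean also includes the focal year
  expect_equal(rainfall_anomaly_3mo(w3, qd) - rainfall_anomaly_3mo(w2, qd),
               90 * (1 - 1 / 3), tolerance = 1e-10)
})

test_that("annual rainfall anomaly handles truncated years", {
  set.seed(2)
  w <- toy_weather(2003:2006, rain = function(d) stats::rexp(length(d), 2))
  s <- as.Date("2004-03-01"); e <- as.Date("2004-08-17")  # truncated span
  span <- function(y) {
    sy <- as.Date(sprintf("%d-03-01", y))
    sum(w$rain_mm[w$date >= sy & w$date <= sy + as.numeric(e - s)])
  }
  expected <- span(2004) - mean(sapply(2003:2006, span))
  expect_equal(annual_rainfall_anomaly(w, s, e), expected, tolerance = 1e-12)

  ## +100 mm dumped into the focal span only -> positive anomaly
  w4 <- w
  day1 <- which(w4$date == s)
  w4$rain_mm[day1] <- w4$rain_mm[day1] + 100
  d <- annual_rainfall_anomaly(w4, s, e) - annual_rainfall_anomaly(w, s, e)
  expect_equal(d, 100 * (1 - 1 / 4), tolerance = 1e-10)
})

test_that("30-day temperature mean follows the stated missing-day rule", {
  w <- toy_weather(2004, tmax = 30)
  expect_equal(mean_max_temp_30d(w, as.Date("2004-06-30")), 30)

  ## linear ramp, hand-computed mean over the 30 days ending at the date
  w2 <- toy_weather(2004)
  w2$tmax_c <- seq_len(nrow(w2))
  qd <- as.Date("2004-03-15")
  i <- which(w2$date == qd)
  expect_equal(mean_max_temp_30d(w2, qd), mean(w2$tmax_c[(i - 29):i]))

  ## 4 missing days -> mean of the 26 remaining; 6 missing -> NA
  w3 <- w2
  w3$tmax_c[(i - 10):(i - 7)] <- NA
  expect_equal(mean_max_temp_30d(w3, qd),
               mean(w3$tmax_c[(i - 29):i], na.rm = TRUE))
  w3$tmax_c[(i - 6):(i - 5)] <- NA
  expect_true(is.na(mean_max_temp_30d(w3, qd)))
})

test_that("reproductive state recodes the first four days of lactation", {
  states <- data.frame(state = c("cycling", "pregnant", "lactating"),
                       start_age = c(6.0, 6.5, 6.5 + 178 / 365.25),
                       end_age = c(6.5, 6.5 + 178 / 365.25, 9))
  part <- 6.5 + 178 / 365.25       # parturition day
  expect_equal(reproductive_state_at(states, part), "pregnant")
  expect_equal(reproductive_state_at(states, part + 3.5 / 365.25), "pregnant")
  expect_equal(reproductive_state_at(states, part + 4.5 / 365.25), "lactating")
  expect_equal(reproductive_state_at(states, 6.2), "cycling")
  expect_true(is.na(reproductive_state_at(states, 5.0)))
})

test_that("design matrix encodes dummies and z-scores as specified", {
  set.seed(3)
  n <- 40
  smp <- data.frame(
    id = rep(c("A", "B"), each = n / 2),
    age = runif(n, 5, 20),
    reproductive_state = "cycling",
    season = "dry",
    rain_anom_3mo = rnorm(n), tmax_30d = rnorm(n, 30),
    group_size = sample(10:60, n, TRUE), rank = runif(n),
    is_alpha = FALSE,
    time_to_extraction = runif(n, 1, 40),
    time_to_assay = runif(n, 10, 300),
    log_fgc = rnorm(n, 4))
  d <- build_fgc_design(smp)
  ## all-cycling, dry-season, non-alpha: dummy columns all zero
  expect_true(all(d$X[, c("pregnant", "lactating", "wet_season",
                          "is_alpha")] == 0))
  ## z-scored columns have mean 0, sd 1
  for (cl in c("rain_anom_3mo", "tmax_30d", "group_size", "group_size_sq",
               "rank", "time_to_extraction", "time_to_assay")) {
    expect_lt(abs(mean(d$X[, cl])), 1e-10)
    expect_equal(sd(d$X[, cl]), 1, tolerance = 1e-10)
  }
  ## group size squared is squared first, then scaled by its own moments
  gs2 <- smp$group_size^2
  expect_equal(d$X[, "group_size_sq"], (gs2 - mean(gs2)) / sd(gs2),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## age stays in years
  expect_equal(d$X[, "age"], smp$age, ignore_attr = TRUE)
  ## stored constants reproduce the same scaling on new data
  d2 <- build_fgc_design(smp, zconst = d$zconst)
  expect_equal(d2$X, d$X)
})
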