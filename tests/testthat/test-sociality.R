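mk_members <- function() {
  data.frame(id = c("f1", "f2", "f3", "m1"),
             sex = c("F", "F", "F", "M"),
             group = "G1",
             start_date = as.Date("2004-01-01"),
             end_date = as.Date("2004-12-31"))
}

test_that("dyadic rates divide counts by co-residence days, both directions", {
  mem <- mk_members()
  g <- data.frame(date = rep(as.Date("2004-03-01"), 10),
                  giver = c(rep("f1", 6), rep("f2", 4)),
                  receiver = c(rep("f2", 6), rep("f1", 4)))
  dy <- dyadic_rates(g, mem, "f1", as.Date("2004-01-01"),
                     as.Date("2004-07-18"))   # 200 days inclusive
  r <- dy[dy$partner == "f2", ]
  expect_equal(r$grooming_count, 10L)
  expect_equal(r$coresidence_days, 200)
  expect_equal(r$daily_rate, 0.05)

  ## swapping giver and receiver leaves the rate unchanged
  g_sw <- data.frame(date = g$date, giver = g$receiver, receiver = g$giver)
  dy_sw <- dyadic_rates(g_sw, mem, "f1", as.Date("2004-01-01"),
                        as.Date("2004-07-18"))
  expect_equal(dy_sw$daily_rate, dy$daily_rate)

  ## juvenile partners (absent from the adult members table) are excluded
  g_juv <- rbind(g, data.frame(date = as.Date("2004-03-02"),
                               giver = "f1", receiver = "juv9"))
  dy_j <- dyadic_rates(g_juv, mem, "f1", as.Date("2004-01-01"),
                       as.Date("2004-07-18"))
  expect_false("juv9" %in% dy_j$partner)
  expect_equal(dy_j[dy_j$partner == "f2", "grooming_count"], 10L)
})

test_that("observer effort is the stated triple quotient", {
  mem <- mk_members()
  ## 100 days, 500 focal samples in the group, constant 3 adult females
  fc <- data.frame(group = "G1",
                   date = seq(as.Date("2004-02-01"), by = "day", length.out = 100),
                   n_focal = 5)
  eff <- observer_effort(fc, mem, "G1", as.Date("2004-02-01"),
                         as.Date("2004-05-10"))
  expect_equal(eff, 500 / 3 / 100)
  ## doubling focal samples doubles effort
  fc2 <- fc; fc2$n_focal <- 10
  expect_equal(observer_effort(fc2, mem, "G1", as.Date("2004-02-01"),
                               as.Date("2004-05-10")), 2 * eff)
  ## 3-day toy with varying female counts, brute force
  mem3 <- mk_members()
  mem3$end_date[mem3$id == "f3"] <- as.Date("2004-06-01")
  days <- seq(as.Date("2004-05-31"), as.Date("2004-06-02"), "day")
  fc3 <- data.frame(group = "G1", date = days, n_focal = c(4, 2, 6))
  got <- observer_effort(fc3, mem3, "G1", days[1], days[3])
  expect_equal(got, 12 / mean(c(3, 3, 2)) / 3)
})

test_that("bond residuals are OLS residuals of log rate on log effort", {
  dy <- data.frame(grooming_count = c(5L, 9L, 2L, 7L),
                   daily_rate = c(0.05, 0.09, 0.02, 0.07),
                   effort = c(0.5, 0.8, 0.3, 0.6))
  out <- bond_residuals(dy)
  fit <- lm(log(daily_rate) ~ log(effort), data = dy)
  expect_equal(out$residual, unname(residuals(fit)), tolerance = 1e-10)
  expect_lt(abs(sum(out$residual)), 1e-10)   # OLS with intercept

  ## exact log-log linear data -> all residuals zero
  dy2 <- data.frame(grooming_count = rep(1L, 4),
                    effort = c(0.2, 0.4, 0.6, 0.9))
  dy2$daily_rate <- 0.1 * dy2$effort^1.7
  expect_lt(max(abs(bond_residuals(dy2)$residual)), 1e-10)

  ## zero-count dyads get no residual and do not enter the fit
  dy3 <- rbind(dy, data.frame(grooming_count = 0L, daily_rate = 0,
                              effort = 0.4))
  out3 <- bond_residuals(dy3)
  expect_true(is.na(out3$residual[5]))
  expect_equal(out3$residual[1:4], out$residual, tolerance = 1e-12)

  ## identical efforts: slope undefined, centred log rates with warning
  dy4 <- dy; dy4$effort <- 0.5
  expect_warning(out4 <- bond_residuals(dy4), "identical")
  expect_equal(out4$residual, log(dy4$daily_rate) - mean(log(dy4$daily_rate)))
})

test_that("DSI takes the mean of the top three bonds, fewer if scarce", {
  expect_equal(dsi(c(1.0, 0.5, 0.2, -0.3)), (1.0 + 0.5 + 0.2) / 3)
  expect_equal(dsi(c(0.4, 0.2)), 0.3)
  expect_true(is.na(dsi(numeric(0))))
  expect_true(is.na(dsi(c(NA_real_, NA_real_))))
})

test_that("missing DSI values are imputed with age-class means", {
  tab <- data.frame(id = c("a", "b", "c", "d"),
                    age_class = c(7, 7, 7, 9),
                    dsi_f = c(0.10, 0.14, NA, 0.5),
                    dsi_m = c(0.2, 0.1, 0.3, 0.4))
  out <- impute_missing_dsi(tab)
  expect_equal(out$dsi_f[3], 0.12)
  expect_equal(sum(out$dsi_f_imputed), 1L)
  expect_false(any(out$dsi_m_imputed))
  expect_equal(out$dsi_m, tab$dsi_m)   # no missing -> unchanged
  ## age class with no observed values falls back to the global mean
  tab2 <- tab; tab2$dsi_f[4] <- NA
  expect_warning(out2 <- impute_missing_dsi(tab2), "global mean")
  expect_equal(out2$dsi_f[4], mean(c(0.10, 0.14)))
})

test_that("doubling every dyad's effort leaves residuals unchanged", {
  set.seed(8)
  n <- 30
  dy <- data.frame(grooming_count = rpois(n, 4) + 1L,
                   effort = runif(n, 0.2, 1))
  dy$daily_rate <- 0.05 * dy$effort * exp(rnorm(n, 0, 0.3))
  r1 <- bond_residuals(dy)$residual
  dy2 <- dy; dy2$effort <- dy$effort * 2
  r2 <- bond_residuals(dy2)$residual
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("the full DSI pipeline runs and is giver/receiver symmetric", {
  s <- small_sim()
  beh <- simulate_behavior(s$cohort)
  fem <- s$cohort$females[1:6, ]
  fem$exit_age <- pmin(fem$censor_age, fem$entry_age + 3)
  tab <- suppressWarnings(
    dsi_table(beh$grooming, beh$focal_counts, s$cohort$members, fem))
  expect_true(all(c("dsi_f", "dsi_m", "dsi_f_imputed") %in% names(tab)))
  expect_true(all(is.finite(tab$dsi_f)))
  ## relabel giver/receiver wholesale: DSI unchanged
  g2 <- beh$grooming
  names(g2)[2:3] <- c("receiver", "giver")
  tab2 <- suppressWarnings(
    dsi_table(g2, beh$focal_counts, s$cohort$members, fem))
  expect_equal(tab2$dsi_f, tab$dsi_f, tolerance = 1e-12)
  expect_equal(tab2$dsi_m, tab$dsi_m, tolerance = 1e-12)
})
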