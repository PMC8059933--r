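test_that("degenerate noise-free data reproduce least squares exactly", {
  cfg <- sim_config(n_females = 12L, obs_window_years = 6, seed = 3L,
                    n_groups = 2L,
                    Sigma_b = matrix(0, 2, 2), sigma2 = 0)
  co <- simulate_cohort(cfg)
  fg <- suppressWarnings(simulate_fgc(co))
  ols <- qr.solve(fg$design$X, fg$design$y)
  expect_equal(unname(ols), unname(fg$beta_true), tolerance = 1e-8)
  ## with vanishing truth, the fitted random-effect SDs shrink toward 0
  fit <- suppressMessages(fit_lmm(fg$design))
  expect_lt(sqrt(fit$Sigma_b[1, 1]), 0.05)
  expect_lt(sqrt(fit$Sigma_b[2, 2]), 0.05)
  expect_equal(unname(fit$beta), unname(fg$beta_true), tolerance = 1e-4)
})

test_that("a singular design is rejected with the offending column named", {
  s <- small_sim()
  d <- s$fgc$design
  d$X <- cbind(d$X, rank_copy = d$X[, "rank"])
  expect_error(fit_lmm(d), "rank_copy|rank")
})

test_that("the LMM recovers the generator's coefficients", {
  cfg <- sim_config(n_females = 150L, seed = 21L)
  co <- simulate_cohort(cfg)
  fg <- suppressWarnings(simulate_fgc(co))
  fit <- fit_lmm(fg$design)
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))
  z <- (fit$beta - fg$beta_true) / se
  ## every coefficient within 4 standard errors, most within 2
  expect_true(all(abs(z) < 4))
  expect_gt(mean(abs(z) < 2), 0.8)
  expect_equal(fit$sigma2, cfg$sigma2, tolerance = 0.05)
})

test_that("Nakagawa R2 reduces to exact ratios on known components", {
  ## toy fit object with hand-chosen variance components
  fake_design <- list(X = cbind(intercept = 1, age = c(1, 2, 3, 4)),
                      age = c(1, 2, 3, 4))
  fake_fit <- list(beta = c(intercept = 0, age = 1),
                   Sigma_b = diag(c(2, 0)), sigma2 = 3,
                   design = fake_design)
  vf <- var(c(1, 2, 3, 4))
  r2 <- r2_nakagawa(fake_fit)
  expect_equal(unname(r2["marginal"]), vf / (vf + 2 + 3))
  expect_equal(unname(r2["conditional"]), (vf + 2) / (vf + 2 + 3))
  ## no random effects and vanishing noise: marginal -> 1
  fake_fit$Sigma_b <- diag(c(0, 0)); fake_fit$sigma2 <- 1e-12
  expect_equal(unname(r2_nakagawa(fake_fit)["marginal"]), 1, tolerance = 1e-9)
})

test_that("trajectory evaluation matches direct arithmetic and integrals", {
  path <- list(a0 = 5L,
               rows = matrix(c(1, 0, 0.5,
                               1, 0, -0.2,
                               1, 0, 0.1), 3, byrow = TRUE,
                             dimnames = list(NULL, c("intercept", "age", "x"))),
               entry = 5, end = 8)
  ## pad the rows out to the full design width
  full <- matrix(0, 3, length(gcjoint:::design_columns()),
                 dimnames = list(NULL, gcjoint:::design_columns()))
  full[, "intercept"] <- 1
  full[, "rank"] <- path$rows[, "x"]
  path$rows <- full
  beta <- setNames(numeric(ncol(full)), colnames(full))
  beta["intercept"] <- 4; beta["age"] <- 0.1; beta["rank"] <- 2
  b <- c(0.3, -0.02)
  tr <- make_trajectory(beta, b, path)
  ## brute-force dot product at t = 6.25 (year row 2)
  expect_equal(tr$value(6.25), 4 + 2 * (-0.2) + 0.3 + (0.1 - 0.02) * 6.25)
  ## linearity in age within a year
  expect_equal(tr$value(6.6) - tr$value(6.2), (0.1 - 0.02) * 0.4)
  expect_equal(tr$deriv(7.3), 0.1 - 0.02)
  ## closed-form integral vs high-resolution trapezoid, segment by segment
  ## (the trajectory may jump at birthdays, so integrate within years)
  trap <- sum(sapply(list(c(5, 6), c(6, 7), c(7, 8)), function(seg) {
    g <- seq(seg[1], seg[2], length.out = 20001)
    g[length(g)] <- seg[2] - 1e-12      # stay inside the year
    sum((tr$value(g[-1]) + tr$value(g[-length(g)])) / 2) * diff(g[1:2])
  }))
  expect_equal(tr$integral(5, 8), trap, tolerance = 1e-8)
  ## additivity over adjacent intervals
  expect_equal(tr$integral(5, 6.3) + tr$integral(6.3, 8), tr$integral(5, 8),
               tolerance = 1e-10)
})

test_that("predict_m falls back to the population level for unknown females", {
  s <- small_sim()
  fit <- fit_lmm(s$fgc$design)
  pth <- s$fgc$xpath[[1]]
  known <- rownames(fit$b)[1]
  m1 <- predict_m(fit, known, c(7.2, 7.9), pth)
  expect_length(m1, 2L)
  expect_warning(m0 <- predict_m(fit, "GHOST", 7.2, pth), "population")
  expect_true(isTRUE(attr(m0, "population_level")))
  tr <- make_trajectory(fit$beta, c(0, 0), pth)
  expect_equal(as.numeric(m0), tr$value(7.2))
})
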