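test_that("invalid configurations are rejected with named fields", {
  expect_error(sim_config(n_females = 0), "n_females")
  expect_error(sim_config(sampling_rate = -1), "sampling_rate")
  expect_error(sim_config(Sigma_b = matrix(c(1, 2, 2, 1), 2)), "Sigma_b")
  expect_error(sim_config(beta = c(intercept = 4)), "beta")
})

test_that("cohorts respect entry bounds and are seed-reproducible", {
  cfg <- sim_config(n_females = 1L, seed = 1L)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$females), 1L)
  expect_gte(co$females$entry_age, 5)
  expect_gt(co$females$censor_age, co$females$entry_age)

  s <- small_sim()
  co1 <- simulate_cohort(s$cfg)
  co2 <- simulate_cohort(s$cfg)
  expect_identical(co1, co2)
  fg1 <- suppressWarnings(simulate_fgc(co1))
  fg2 <- suppressWarnings(simulate_fgc(co2))
  expect_identical(fg1$samples, fg2$samples)
  ## reproductive-state intervals partition the adult timeline
  for (f in co1$females$id[1:5]) {
    iv <- co1$repro[co1$repro$id == f, ]
    expect_true(all(abs(iv$start_age[-1] - iv$end_age[-nrow(iv)]) < 1e-9))
  }
})

test_that("noise-free limit reproduces the fixed linear predictor exactly", {
  cfg <- sim_config(n_females = 8L, obs_window_years = 6, seed = 3L,
                    Sigma_b = matrix(0, 2, 2), sigma2 = 0)
  co <- simulate_cohort(cfg)
  fg <- suppressWarnings(simulate_fgc(co))
  eta <- drop(fg$design$X %*% fg$beta_true)
  expect_equal(fg$samples$log_fgc, eta, tolerance = 1e-12)
})

test_that("the generator meets its variance budget", {
  ## components sum to the published total
  cfg <- sim_config()
  expect_equal(cfg$var_fixed + cfg$var_random + cfg$sigma2, 0.199,
               tolerance = 1e-3)
  ## empirical components from a large simulation match within 5%
  big <- sim_config(n_females = 620L, seed = 9L)
  co <- simulate_cohort(big)
  fg <- suppressWarnings(simulate_fgc(co))
  expect_gt(nrow(fg$samples), 50000)
  eta <- drop(fg$design$X %*% fg$beta_true)
  expect_lt(abs(var(eta) - 0.0275) / 0.0275, 1e-6)   # calibrated exactly
  re <- fg$b_true[fg$design$id, 1] + fg$b_true[fg$design$id, 2] * fg$design$age
  expect_lt(abs(var(re) - 0.0149) / 0.0149, 0.05)
  resid <- fg$samples$log_fgc - eta - re
  expect_lt(abs(var(resid) - 0.1566) / 0.1566, 0.05)
  expect_lt(abs(var(fg$samples$log_fgc) - 0.199) / 0.199, 0.05)
})

test_that("per-female-year sample counts match the published median", {
  set.seed(101)
  cnt <- draw_sample_counts(1634L, 7.5)
  expect_true(all(cnt >= 1L))
  expect_equal(median(cnt), 7)
})

test_that("death times invert the constant hazard exactly", {
  ## alpha = 0, Gompertz b = 0: exit - entry ~ Exp(a), censored at window end
  cfg <- sim_config(n_females = 2000L, obs_window_years = 10,
                    sampling_rate = 1, seed = 13L,
                    baseline = c(a = 0.1, b = 0),
                    gamma = c(dsi_f = 0, dsi_m = 0, rain_anom = 0),
                    assoc = assoc_spec("none"))
  co <- simulate_cohort(cfg)
  fg <- suppressWarnings(simulate_fgc(co))
  sv <- simulate_survival(co, fg)
  r <- sv$records
  tt <- r$exit_age - r$entry_age
  ## KS test against Exp(0.1) on uncensored spells (censoring at a fixed
  ## horizon is independent of the death draw, so the conditional law of
  ## uncensored spells is a truncated exponential; compare via the
  ## probability-integral transform on each female's own horizon)
  horiz <- co$females$censor_age - co$females$entry_age
  died <- r$event == 1
  u <- pexp(tt[died], 0.1) / pexp(horiz[died], 0.1)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## Kaplan-Meier stays inside the exponential's 95% bands
  km <- survival::survfit(survival::Surv(tt, r$event) ~ 1)
  inside <- exp(-0.1 * km$time) >= km$lower & exp(-0.1 * km$time) <= km$upper
  expect_gt(mean(inside), 0.95)

  ## null association: no correlation between trajectory level and death age
  rho <- cor(fg$b_true[r$id, 1], r$exit_age, method = "spearman")
  expect_lt(abs(rho), 0.05)
})

test_that("a positive value association lowers survival of high-fGC females", {
  cfg <- sim_config(n_females = 600L, obs_window_years = 15, sampling_rate = 1,
                    seed = 17L, var_random = 0.16, sd_slope = 0.001,
                    assoc = assoc_spec("value", 1.0))
  co <- simulate_cohort(cfg)
  fg <- suppressWarnings(simulate_fgc(co))
  sv <- simulate_survival(co, fg)
  r <- sv$records
  hi <- fg$b_true[r$id, 1] > median(fg$b_true[r$id, 1])
  ## higher-trajectory half dies earlier (compare death ages among deaths)
  expect_lt(median(r$exit_age[hi & r$event == 1]),
            median(r$exit_age[!hi & r$event == 1]))
  expect_gt(mean(r$event[hi]), mean(r$event[!hi]))
})

test_that("behavioral tables are deterministic and respect the hierarchy", {
  s <- small_sim()
  b1 <- simulate_behavior(s$cohort)
  b2 <- simulate_behavior(s$cohort)
  expect_identical(b1, b2)
  ## zero upset probability: monthly winners always rank above losers
  b0 <- simulate_behavior(s$cohort, upset_prob = 0)
  ab <- setNames(s$cohort$females$ability, s$cohort$females$id)
  expect_true(all(ab[b0$agonism$winner] > ab[b0$agonism$loser]))
  ## and the inferred order equals the latent order in a one-month slice
  g <- s$cohort$females$group[1]
  ids <- s$cohort$females$id[s$cohort$females$group == g]
  mo <- format(as.Date(b0$agonism$date), "%Y-%m")
  busy <- names(sort(table(mo[b0$agonism$winner %in% ids]), decreasing = TRUE))[1]
  ag <- b0$agonism[mo == busy & b0$agonism$winner %in% ids &
                     b0$agonism$loser %in% ids, ]
  present <- union(ag$winner, ag$loser)
  rk <- proportional_ranks(ag, present)
  ## the inferred order is consistent with every observed interaction
  ## (pairs never observed together are unconstrained)
  pos <- setNames(rk$order, rk$id)
  expect_true(all(pos[ag$winner] < pos[ag$loser]))
})
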