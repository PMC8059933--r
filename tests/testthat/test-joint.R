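flat_path <- function(const = 2, entry = 5, end = 12) {
  cols <- gcjoint:::design_columns()
  rows <- matrix(0, end - entry, length(cols),
                 dimnames = list(NULL, cols))
  rows[, "intercept"] <- 1
  list(a0 = as.integer(entry), rows = rows, entry = entry, end = end)
}

const_beta <- function(intercept = 2, age = 0) {
  b <- setNames(numeric(length(gcjoint:::design_columns())),
                gcjoint:::design_columns())
  b["intercept"] <- intercept; b["age"] <- age
  b
}

test_that("association terms follow their defining formulas", {
  tr <- make_trajectory(const_beta(intercept = 2), c(0, 0), flat_path())
  ## constant m = 2 on [5, t], auc: rectangle 2 * (t - 5)
  expect_equal(association_term(tr, c(6, 9.5), assoc_spec("auc", 1)),
               2 * (c(6, 9.5) - 5))
  ## linear m: slope mode returns the constant slope exactly
  tr2 <- make_trajectory(const_beta(2, 0.3), c(0, 0.1), flat_path())
  expect_equal(association_term(tr2, c(6, 8), assoc_spec("slope", 1)),
               rep(0.4, 2))
  expect_equal(association_term(tr2, 7, assoc_spec("value", 2)),
               2 * tr2$value(7))
  expect_equal(association_term(tr2, 7, assoc_spec("none")), 0)
  expect_error(association_term(tr, 4.5, assoc_spec("auc", 1)), "entry")

  ## piecewise toy trajectory: auc vs 10,000-point trapezoid
  path <- flat_path()
  path$rows[, "rank"] <- seq(-0.5, 0.7, length.out = nrow(path$rows))
  beta <- const_beta(2, 0.05); beta["rank"] <- 1.3
  tr3 <- make_trajectory(beta, c(0.2, -0.01), path)
  for (tt in c(7.4, 11.2)) {
    brk <- c(5, seq(6, floor(tt)), tt)
    trap <- sum(sapply(seq_len(length(brk) - 1), function(k) {
      g <- seq(brk[k], brk[k + 1], length.out = 10001)
      g[length(g)] <- brk[k + 1] - 1e-12
      sum((tr3$value(g[-1]) + tr3$value(g[-length(g)])) / 2) * diff(g[1:2])
    }))
    expect_equal(association_term(tr3, tt, assoc_spec("auc", 1)), trap,
                 tolerance = 1e-7)
  }
})

test_that("log hazard assembles baseline, covariates and association", {
  tr <- make_trajectory(const_beta(2, 0.1), c(0.1, 0), flat_path())
  w <- matrix(rnorm(21), 7, 3)
  rec <- list(entry_age = 5.2, exit_age = 11.5, a0 = 5L, w = w)
  params <- list(log_h0 = function(t) log(0.05) + 0.1 * (t - 5),
                 gamma = c(-0.2, 0.1, 0.3), assoc = assoc_spec("none"))
  ## gamma = 0, alpha = 0 -> log h0 exactly
  p0 <- params; p0$gamma <- c(0, 0, 0)
  expect_equal(log_hazard(c(6, 9.9), rec, tr, p0),
               p0$log_h0(c(6, 9.9)))
  ## piecewise-constant yearly covariates: jump at a birthday is gamma' dw
  eps <- 1e-9
  jump <- log_hazard(8 + eps, rec, tr, params) -
    log_hazard(8 - eps, rec, tr, params)
  expect_equal(jump, drop((w[4, ] - w[3, ]) %*% params$gamma),
               tolerance = 1e-6)
  expect_error(log_hazard(4, rec, tr, params), "outside")
})

test_that("cumulative hazard matches closed forms and is additive", {
  tr <- make_trajectory(const_beta(0, 0), c(0, 0), flat_path())
  rec <- list(entry_age = 5, exit_age = 12, a0 = 5L, w = matrix(0, 7, 3))
  ## constant hazard c over 3 years -> 3c
  cpar <- list(log_h0 = function(t) rep(log(0.2), length(t)),
               gamma = c(0, 0, 0), assoc = assoc_spec("none"))
  expect_equal(cumulative_hazard(rec, tr, cpar, 6, 9), 0.6,
               tolerance = 1e-10)
  ## Gompertz closed form (a/b)(e^{b t2} - e^{b t1}), ages from 0 reference
  a <- 0.03; bb <- 0.15
  gpar <- list(log_h0 = function(t) log(a) + bb * t,
               gamma = c(0, 0, 0), assoc = assoc_spec("none"))
  closed <- a / bb * (exp(bb * 11.2) - exp(bb * 5.4))
  expect_equal(cumulative_hazard(rec, tr, gpar, 5.4, 11.2), closed,
               tolerance = 1e-8 * closed)
  ## additivity to tight tolerance
  H1 <- cumulative_hazard(rec, tr, gpar, 5, 7.3)
  H2 <- cumulative_hazard(rec, tr, gpar, 7.3, 11.9)
  expect_equal(H1 + H2, cumulative_hazard(rec, tr, gpar, 5, 11.9),
               tolerance = 1e-10)
})

test_that("survival probabilities are proper and monotone", {
  tr <- make_trajectory(const_beta(1, 0.02), c(0.2, 0), flat_path())
  rec <- list(entry_age = 5, exit_age = 12, a0 = 5L, w = matrix(0.3, 7, 3))
  params <- list(log_h0 = function(t) log(0.04) + 0.1 * (t - 5),
                 gamma = c(-0.2, 0.1, 0.05), assoc = assoc_spec("value", 0.3))
  S <- sapply(seq(5, 12, 0.5), function(t)
    exp(-cumulative_hazard(rec, tr, params, 5, t)))
  expect_true(all(S > 0 & S <= 1))
  expect_true(all(diff(S) <= 1e-12))
})

test_that("proportional-hazards contract: shifting m scales all hazards", {
  path <- flat_path()
  beta <- const_beta(2, 0.05)
  rec <- list(entry_age = 5, exit_age = 12, a0 = 5L,
              w = matrix(rnorm(21), 7, 3))
  params <- list(log_h0 = function(t) log(0.05) + 0.05 * t,
                 gamma = c(0.1, -0.2, 0.3), assoc = assoc_spec("value", 0.7))
  tr_lo <- make_trajectory(beta, c(0, 0), path)
  beta_hi <- beta; beta_hi["intercept"] <- beta["intercept"] + 0.9
  tr_hi <- make_trajectory(beta_hi, c(0, 0), path)
  tt <- c(5.7, 8.2, 11.4)
  expect_equal(log_hazard(tt, rec, tr_hi, params) -
                 log_hazard(tt, rec, tr_lo, params),
               rep(0.7 * 0.9, 3), tolerance = 1e-10)
})

test_that("the joint log posterior matches the brute-force oracle", {
  tiny <- tiny_jm_data()
  jd <- tiny$jd
  set.seed(31)
  params <- list(
    beta = tiny$fgc$beta_true + rnorm(jd$p, 0, 0.02),
    sigma2 = 0.14,
    Sigma_b = matrix(c(0.015, 1e-4, 1e-4, 1e-5), 2),
    b = cbind(rnorm(3, 0, 0.1), rnorm(3, 0, 0.003)),
    gamma = c(-0.2, -0.1, 0.08),
    omega = rnorm(ncol(jd$Bq), -3, 0.3),
    alpha = 0.4)
  for (mode in c("none", "value", "slope", "auc")) {
    ## an AUC feature is two orders of magnitude larger than the current
    ## value, so a realistically small coefficient keeps hazards sane
    params$alpha <- if (mode == "auc") 0.01 else 0.4
    got <- joint_log_posterior(params, jd, assoc = mode)
    want <- oracle_log_posterior(params, jd, mode)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("with alpha = 0 the posterior separates into its two submodels", {
  tiny <- tiny_jm_data()
  jd <- tiny$jd
  set.seed(32)
  params <- list(beta = tiny$fgc$beta_true, sigma2 = 0.15,
                 Sigma_b = diag(c(0.013, 1e-5)),
                 b = cbind(rnorm(3, 0, 0.1), 0),
                 gamma = c(-0.1, 0, 0.1),
                 omega = rnorm(ncol(jd$Bq), -3, 0.2), alpha = 0)
  full <- joint_log_posterior(params, jd, assoc = "value")
  long_part <- gcjoint:::.jm_loglik_long(jd, params$beta, params$sigma2,
                                         params$b) +
    gcjoint:::.jm_loglik_b(params$b, params$Sigma_b)
  am <- gcjoint:::.assoc_mats(jd, "none")
  surv_part <- gcjoint:::.jm_surv_parts(jd, am, params$beta, params$gamma,
                                        params$omega, 0, params$b)$ll
  prior <- gcjoint:::.jm_prior(gcjm_priors(jd), params$beta, params$sigma2,
                               params$Sigma_b, params$gamma, params$omega,
                               0)
  expect_equal(full, long_part + surv_part + prior, tolerance = 1e-8)
})

test_that("a single censored female under constant hazard gives -c * span", {
  tiny <- tiny_jm_data()
  jd <- tiny$jd
  i <- which(jd$delta == 0)[1]
  expect_false(is.na(i))   # the seeded tiny cohort has a censored female
  cc <- 0.07
  omega <- rep(log(cc), ncol(jd$Bq))   # basis sums to 1
  am <- gcjoint:::.assoc_mats(jd, "none")
  parts <- gcjoint:::.jm_surv_parts(jd, am, tiny$fgc$beta_true,
                                    c(0, 0, 0), omega, 0,
                                    matrix(0, jd$nf, 2))
  span <- jd$surv$exit_age[i] - jd$surv$entry_age[i]
  expect_equal(unname(parts$H[i]), cc * span, tolerance = 1e-8)
  expect_equal(unname(jd$delta[i] * parts$logh_T[i] - parts$H[i]),
               -cc * span, tolerance = 1e-8)
})
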