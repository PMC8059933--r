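# Independent straight-line oracle for the joint log posterior: assembled
# term by term (per female, per sample, per year segment) from the model
# definition, sharing only the raw inputs and the quadrature order with
# the implementation under test.

oracle_log_posterior <- function(params, jd, mode, nodes = 15L) {
  pr <- gcjm_priors(jd)
  beta <- params$beta; s2 <- params$sigma2; Sb <- params$Sigma_b
  b <- params$b; gam <- params$gamma; om <- params$omega; al <- params$alpha

  ## priors, written out one by one
  sds <- sqrt(diag(Sb)); rho <- Sb[1, 2] / prod(sds)
  lp <- 0
  for (j in seq_along(beta))
    lp <- lp + dnorm(beta[j], pr$beta_mean[j], pr$beta_sd[j], log = TRUE)
  for (g in gam) lp <- lp + dnorm(g, 0, pr$gamma_sd, log = TRUE)
  for (o in om) lp <- lp + dnorm(o, 0, pr$omega_sd, log = TRUE)
  lp <- lp + dnorm(al, 0, pr$alpha_sd, log = TRUE)
  lp <- lp + dnorm(sqrt(s2), 0, pr$sigma_scale, log = TRUE) + log(2)
  lp <- lp + dnorm(sds[1], 0, pr$sd_b_scale[1], log = TRUE) + log(2)
  lp <- lp + dnorm(sds[2], 0, pr$sd_b_scale[2], log = TRUE) + log(2)
  lp <- lp + dunif(rho, -1, 1, log = TRUE)

  Si <- solve(Sb)
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  for (i in seq_len(jd$nf)) {
    idf <- jd$ids[i]
    sel <- which(as.integer(jd$idx) == i)
    ## longitudinal: y_ij ~ N(x_ij beta + b0 + b1 age_ij, s2)
    for (j in sel) {
      mu <- sum(jd$X[j, ] * beta) + b[i, 1] + b[i, 2] * jd$age[j]
      lp <- lp + dnorm(jd$y[j], mu, sqrt(s2), log = TRUE)
    }
    ## random effects
    lp <- lp - log(2 * pi) - 0.5 * log(det(Sb)) -
      0.5 * drop(b[i, ] %*% Si %*% b[i, ])
    ## survival with delayed entry
    pth <- jd$xpath[[idf]]
    entry <- jd$surv$entry_age[i]; exit <- jd$surv$exit_age[i]
    wz_i <- function(t) {
      rows <- which(jd$wpath$id == idf)
      k <- rows[which.min(abs(jd$wpath$age_class[rows] -
                                pmin(floor(t), floor(exit - 1e-9))))]
      w <- unlist(jd$wpath[k, c("dsi_f", "dsi_m", "rain_anom")])
      (w - jd$wconst$mean) / jd$wconst$sd
    }
    m_of <- function(t) {
      r <- pth$rows[min(max(floor(t) - pth$a0 + 1, 1), nrow(pth$rows)), ]
      r[jd$age_col] <- t
      sum(r * beta) + b[i, 1] + b[i, 2] * t
    }
    auc_of <- function(t) {       # integral of m from jd$auc_from to t
      brk <- unique(c(jd$auc_from,
                      Filter(function(x) x > jd$auc_from & x < t,
                             seq(ceiling(jd$auc_from), floor(t))), t))
      tot <- 0
      for (k in seq_len(length(brk) - 1)) {
        mid <- (brk[k] + brk[k + 1]) / 2
        tot <- tot + m_of(mid) * (brk[k + 1] - brk[k])  # exact: m linear
      }
      tot
    }
    feat <- function(t) switch(mode, none = 0, value = m_of(t),
                               slope = beta[jd$age_col] + b[i, 2],
                               auc = auc_of(t))
    logh <- function(t)
      sum(jd$basis(t)[1, ] * om) + sum(wz_i(t) * gam) + al * feat(t)
    ## event term
    if (jd$surv$event[i] == 1) lp <- lp + logh(exit)
    ## cumulative hazard, year segment by year segment
    cuts <- seq(ceiling(entry), floor(exit))
    brk <- unique(c(entry, cuts[cuts > entry & cuts < exit], exit))
    for (k in seq_len(length(brk) - 1)) {
      half <- (brk[k + 1] - brk[k]) / 2
      mid2 <- (brk[k + 1] + brk[k]) / 2
      for (q in seq_along(gl$x))
        lp <- lp - half * gl$w[q] * exp(logh(half * gl$x[q] + mid2))
    }
  }
  lp
}
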