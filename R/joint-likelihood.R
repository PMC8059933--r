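#' Association term f(alpha, M_i(t))
#'
#' The feature of the individual trajectory history that enters the log
#' hazard: `alpha * m_i(t)` (current value), `alpha * m_i'(t)` (current
#' slope), or `alpha * integral of m_i from entry age to t` (cumulative
#' area under the curve; the trajectory is undefined before adult entry,
#' so the lower limit is the entry age). Mode `"none"` contributes 0.
#'
#' @param traj a [make_trajectory()] object.
#' @param t evaluation ages (must be `>= traj$entry`).
#' @param spec an [assoc_spec()].
#' @return numeric vector of association-term values.
#' @export
association_term <- function(traj, t, spec) {
  stopifnot(inherits(traj, "gc_trajectory"), inherits(spec, "assoc_spec"))
  if (any(t < traj$entry - 1e-12))
    stop("association_term: t precedes the trajectory's entry age")
  switch(spec$mode,
         none = rep(0, length(t)),
         value = spec$alpha * traj$value(t),
         slope = spec$alpha * traj$deriv(t),
         auc = spec$alpha * traj$integral(traj$entry, t))
}

#' Log hazard of death at age t
#'
#' `log h_i(t) = log h0(t) + gamma' w_i(t) + f(alpha, M_i(t))`, with the
#' yearly survival covariates `w_i` piecewise constant within years of
#' life (they step at birthdays).
#'
#' @param t evaluation ages within `[entry, exit]`.
#' @param record list with `entry_age`, `exit_age`, `a0` (first covered
#'   age class) and `w` (matrix of yearly covariates, one row per age
#'   class from `a0`, z-scored).
#' @param traj the female's [make_trajectory()] object.
#' @param params list with `log_h0` (vectorized function of age), `gamma`
#'   and `assoc` (an [assoc_spec()]).
#' @return numeric vector of log hazards.
#' @export
log_hazard <- function(t, record, traj, params) {
  if (any(t < record$entry_age - 1e-9 | t > record$exit_age + 1e-9))
    stop("log_hazard: t outside [entry, exit]")
  k <- pmin(pmax(floor(t) - record$a0 + 1, 1L), nrow(record$w))
  if (anyNA(record$w[k, ]))
    stop("log_hazard: missing survival covariates at age ", t[which(is.na(
      rowSums(record$w[k, , drop = FALSE])))[1]])
  params$log_h0(t) + drop(record$w[k, , drop = FALSE] %*% params$gamma) +
    association_term(traj, t, params$assoc)
}

#' Cumulative hazard by per-year Gauss-Legendre quadrature
#'
#' Integrates the hazard from `t0` to `t1` with a fixed-order
#' Gauss-Legendre rule applied separately within each year-of-life
#' segment (the integrand is smooth within a year and may jump at
#' birthdays). Exact additivity over adjacent intervals holds by
#' construction.
#'
#' @inheritParams log_hazard
#' @param t0,t1 integration limits (ages, `t1 > t0 >= entry`).
#' @param nodes quadrature nodes per year segment.
#' @return scalar cumulative hazard.
#' @export
cumulative_hazard <- function(record, traj, params, t0, t1, nodes = 15L) {
  if (t1 <= t0) return(0)
  segs <- year_segments(t0, t1)
  H <- 0
  for (k in seq_len(nrow(segs))) {
    g <- gl_segment(segs[k, 1], segs[k, 2], nodes)
    h <- exp(log_hazard(g$x, record, traj, params))
    if (any(!is.finite(h)))
      stop("non-finite hazard integrand near age ",
           signif(g$x[which(!is.finite(h))[1]], 5))
    H <- H + sum(g$w * h)
  }
  H
}

## ---------------------------------------------------------------------------
## Vectorized likelihood internals shared by joint_log_posterior() and the
## sampler. `am` is the .assoc_mats() list for the chosen mode.

.jm_loglik_long <- function(data, beta, sigma2, b) {
  mu <- drop(data$X %*% beta) + b[data$idx, 1] + b[data$idx, 2] * data$age
  sum(stats::dnorm(data$y, mu, sqrt(sigma2), log = TRUE))
}

.jm_surv_parts <- function(data, am, beta, gamma, omega, alpha, b) {
  feat_q <- drop(am$G %*% beta) + b[data$fq, 1] * am$D[, 1] +
    b[data$fq, 2] * am$D[, 2]
  logh_q <- drop(data$Bq %*% omega) + drop(data$Wq %*% gamma) + alpha * feat_q
  H <- rowsum(data$wq * exp(logh_q), data$fq, reorder = TRUE)
  feat_T <- drop(am$G_T %*% beta) + b[, 1] * am$D_T[, 1] + b[, 2] * am$D_T[, 2]
  logh_T <- drop(data$B_T %*% omega) + drop(data$W_T %*% gamma) + alpha * feat_T
  list(H = drop(H), logh_T = logh_T,
       ll = sum(data$delta * logh_T) - sum(H))
}

.jm_loglik_b <- function(b, Sigma_b) {
  Si <- solve(Sigma_b)
  ld <- determinant(Sigma_b, logarithm = TRUE)$modulus
  -0.5 * nrow(b) * (2 * log(2 * pi) + as.numeric(ld)) -
    0.5 * sum((b %*% Si) * b)
}

.jm_prior <- function(pr, beta, sigma2, Sigma_b, gamma, omega, alpha) {
  sds <- sqrt(diag(Sigma_b))
  rho <- Sigma_b[1, 2] / prod(sds)
  if (abs(rho) >= 1 || any(sds <= 0) || sigma2 <= 0) return(-Inf)
  sum(stats::dnorm(beta, pr$beta_mean, pr$beta_sd, log = TRUE)) +
    sum(stats::dnorm(gamma, 0, pr$gamma_sd, log = TRUE)) +
    sum(stats::dnorm(omega, 0, pr$omega_sd, log = TRUE)) +
    stats::dnorm(alpha, 0, pr$alpha_sd, log = TRUE) +
    ## half-normal priors on the three scale parameters
    stats::dnorm(sqrt(sigma2), 0, pr$sigma_scale, log = TRUE) + log(2) +
    stats::dnorm(sds[1], 0, pr$sd_b_scale[1], log = TRUE) + log(2) +
    stats::dnorm(sds[2], 0, pr$sd_b_scale[2], log = TRUE) + log(2) +
    stats::dunif(rho, -1, 1, log = TRUE)
}

#' Default weakly informative prior scales
#' @param data a `gcjm_data` bundle.
#' @return list of prior hyperparameters, scaled by the response spread.
#' @export
gcjm_priors <- function(data) {
  sdy <- stats::sd(data$y); my <- mean(data$y)
  p <- data$p
  beta_mean <- rep(0, p); beta_sd <- rep(2.5 * sdy, p)
  beta_mean[1] <- my; beta_sd[1] <- 5 * sdy
  list(beta_mean = beta_mean, beta_sd = beta_sd,
       gamma_sd = 2.5, omega_sd = 20, alpha_sd = 2.5,
       sigma_scale = 2 * sdy, sd_b_scale = c(sdy, sdy / 5))
}

#' Joint log posterior density
#'
#' The sum of the longitudinal Gaussian log likelihood, the survival log
#' likelihood with delayed entry (event indicator times log hazard at
#' exit, minus the cumulative hazard from entry to exit), the
#' random-effect log density, and the log priors. All parameters are on
#' their natural scale.
#'
#' @param params list with `beta`, `sigma2`, `Sigma_b`, `b` (females x 2
#'   matrix), `gamma`, `omega` (spline coefficients of the log baseline
#'   hazard) and `alpha`.
#' @param data a `gcjm_data` bundle.
#' @param assoc association mode (string) or [assoc_spec()]; the `alpha`
#'   in `params` is used.
#' @param priors prior scales, default [gcjm_priors()].
#' @return finite scalar log posterior (or `-Inf` outside the support).
#' @export
joint_log_posterior <- function(params, data, assoc = "none",
                                priors = gcjm_priors(data)) {
  mode <- if (inherits(assoc, "assoc_spec")) assoc$mode else assoc
  am <- .assoc_mats(data, mode)
  lp <- .jm_prior(priors, params$beta, params$sigma2, params$Sigma_b,
                  params$gamma, params$omega, params$alpha)
  if (!is.finite(lp)) return(-Inf)
  lp + .jm_loglik_long(data, params$beta, params$sigma2, params$b) +
    .jm_surv_parts(data, am, params$beta, params$gamma, params$omega,
                   params$alpha, params$b)$ll +
    .jm_loglik_b(params$b, params$Sigma_b)
}
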