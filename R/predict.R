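#' Percentile trajectory specification for a hypothetical female
#'
#' Builds the log-fGC history of a hypothetical individual who sits at a
#' fixed empirical percentile of the population in every age class: one
#' pseudo-observation per age class, placed at the age-class midpoint,
#' from adult entry to the last observed age `t0`. All other covariates
#' are held at their age-specific means (z-score zero) and categorical
#' covariates at their reference levels (cycling, dry season, not alpha).
#'
#' @param samples data frame with `age` and `log_fgc` (e.g. the samples
#'   table of [simulate_fgc()] or any observed dataset).
#' @param percentile percentile in (0, 100), e.g. 90 or 10.
#' @param t0 last observed age (conditioning age), default 14.
#' @param entry adult entry age, default 5.
#' @return An object of class `"trajectory_spec"`: list with `ages`
#'   (class midpoints), `values` (per-class percentiles), `percentile`,
#'   `t0`, `entry`.
#' @export
percentile_trajectory <- function(samples, percentile, t0 = 14, entry = 5) {
  stopifnot(percentile > 0, percentile < 100, t0 > entry)
  classes <- seq(floor(entry), ceiling(t0) - 1L)
  vals <- rep(NA_real_, length(classes))
  for (k in seq_along(classes)) {
    y <- samples$log_fgc[samples$age >= classes[k] &
                           samples$age < classes[k] + 1]
    if (length(y) > 0)
      vals[k] <- as.numeric(stats::quantile(y, percentile / 100, type = 7))
  }
  if (anyNA(vals)) {
    warning("empty age class(es) interpolated from neighbours")
    vals <- stats::approx(classes[!is.na(vals)], vals[!is.na(vals)],
                          xout = classes, rule = 2)$y
  }
  structure(list(ages = classes + 0.5, values = vals,
                 percentile = percentile, t0 = t0, entry = entry),
            class = "trajectory_spec")
}

#' Dynamic conditional survival prediction for a hypothetical female
#'
#' For each posterior draw, the hypothetical individual's random effects
#' are drawn from their exact Gaussian conditional distribution given the
#' specification's pseudo-observations (one per age class, with residual
#' variance from the same draw), and the conditional survival function
#' `S(t | t0) = exp(-integral of the hazard from t0 to t)` is evaluated on
#' the age grid with the same per-segment Gauss-Legendre quadrature used
#' in fitting. Pointwise medians and 90 percent intervals are reported
#' across draws. Survival covariates sit at their population means
#' (z-score zero).
#'
#' @param fit a [gcjm()] fit.
#' @param spec a [percentile_trajectory()] specification.
#' @param age_grid increasing grid starting at `spec$t0`.
#' @param ndraws number of posterior draws to use (subsampled evenly).
#' @param b_draws optional matrix (`ndraws` x 2) of fixed random effects,
#'   bypassing the conditional draw (used for consistency checks).
#' @return An object of class `"survival_curve"`: data frame with `age`,
#'   `median`, `lo90`, `hi90`; attributes `t0` and `draws` (the full
#'   draws-by-grid matrix).
#' @export
conditional_survival <- function(fit, spec,
                                 age_grid = seq(spec$t0, 27, by = 0.25),
                                 ndraws = 200, b_draws = NULL) {
  stopifnot(inherits(fit, "gcjm"), inherits(spec, "trajectory_spec"))
  if (abs(age_grid[1] - spec$t0) > 1e-9)
    stop("age_grid must start at the conditioning age t0")
  dr <- as.matrix(fit)
  p <- fit$data$p
  use <- unique(round(seq(1, nrow(dr), length.out = min(ndraws, nrow(dr)))))
  dr <- dr[use, , drop = FALSE]
  a_col <- fit$data$age_col
  om_ix <- grep("^omega", colnames(dr))
  entry <- spec$entry

  ## quadrature nodes inside each grid interval (hazard smooth there)
  nseg <- length(age_grid) - 1L
  g <- gl_rule(7L)
  lo <- age_grid[-length(age_grid)]; hi <- age_grid[-1]
  tq <- as.vector(outer(g$x, (hi - lo) / 2) +
                    matrix((lo + hi) / 2, 7L, nseg, byrow = TRUE))
  wq <- as.vector(outer(g$w, (hi - lo) / 2))
  segi <- rep(seq_len(nseg), each = 7L)
  Bq <- unclass(fit$data$basis(tq))

  S <- matrix(NA_real_, nrow(dr), length(age_grid))
  for (s in seq_len(nrow(dr))) {
    beta <- dr[s, seq_len(p)]
    sigma2 <- dr[s, "sigma2"]
    sds <- dr[s, c("sd_b0", "sd_b1")]; rho <- dr[s, "rho_b"]
    Sigma <- diag(sds^2); Sigma[1, 2] <- Sigma[2, 1] <- rho * prod(sds)
    omega <- dr[s, om_ix]; alpha <- dr[s, "alpha"]
    ## trajectory at reference covariates: m(t) = c0 + c1 t + b0 + b1 t
    c0 <- beta[1]; c1 <- beta[a_col]
    if (is.null(b_draws)) {
      Z <- cbind(1, spec$ages)
      Qm <- crossprod(Z) / sigma2 + solve(Sigma)
      rz <- spec$values - (c0 + c1 * spec$ages)
      U <- chol(Qm)
      mu_b <- backsolve(U, forwardsolve(t(U), crossprod(Z, rz) / sigma2))
      b <- drop(mu_b + backsolve(U, stats::rnorm(2)))
    } else b <- b_draws[s, ]
    m0 <- c0 + b[1]; m1 <- c1 + b[2]       # m(t) = m0 + m1 t
    feat <- switch(fit$assoc,
                   none = rep(0, length(tq)),
                   value = m0 + m1 * tq,
                   slope = rep(m1, length(tq)),
                   auc = m0 * (tq - entry) + m1 * (tq^2 - entry^2) / 2)
    logh <- drop(Bq %*% omega) + alpha * feat
    Hseg <- drop(rowsum(wq * exp(logh), segi, reorder = TRUE))
    S[s, ] <- exp(-c(0, cumsum(Hseg)))
  }
  qs <- apply(S, 2, stats::quantile, probs = c(0.5, 0.05, 0.95))
  out <- data.frame(age = age_grid, median = qs[1, ],
                    lo90 = qs[2, ], hi90 = qs[3, ])
  attr(out, "t0") <- spec$t0
  attr(out, "draws") <- S
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' @rdname conditional_survival
#' @param object a `gcjm` fit.
#' @param ... passed on to [conditional_survival()].
#' @export
predict.gcjm <- function(object, spec, ...) {
  conditional_survival(object, spec, ...)
}

#' Age at which the median conditional survival curve crosses 0.5
#'
#' Linear interpolation between the bracketing grid ages; `NA` if the
#' curve never reaches 0.5 within the grid.
#'
#' @param curve a [conditional_survival()] result.
#' @return scalar age (years) or `NA`.
#' @export
median_survival_age <- function(curve) {
  m <- curve$median
  k <- which(m <= 0.5)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(curve$age[1])
  a0 <- curve$age[k - 1]; a1 <- curve$age[k]
  m0 <- m[k - 1]; m1 <- m[k]
  a0 + (0.5 - m0) / (m1 - m0) * (a1 - a0)
}

#' @export
plot.survival_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add)
    graphics::plot(x$age, x$median, type = "n", ylim = c(0, 1),
                   xlab = "age (years)",
                   ylab = sprintf("S(t | t0 = %.0f)", attr(x, "t0")), ...)
  graphics::polygon(c(x$age, rev(x$age)), c(x$lo90, rev(x$hi90)),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(x$age, x$median, col = col, lwd = 2)
  invisible(x)
}
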