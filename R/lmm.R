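#' Fit the longitudinal linear mixed submodel of log fGC
#'
#' Fits `log fGC ~ fixed covariates + (1 + age | female)` by restricted
#' maximum likelihood (through \pkg{lme4}): every covariate of the design
#' enters as a fixed effect, and each female carries a random intercept
#' and a random slope of age, so her baseline log fGC follows an
#' individual-specific linear trajectory after adjustment for the fixed
#' covariates. This standalone fit supplies variance-explained summaries
#' ([r2_nakagawa()]), starting values for the joint model, and per-female
#' conditional modes (BLUPs) of the random effects.
#'
#' @param design an `fgc_design` from [build_fgc_design()] with a response.
#' @return An object of class `"fgc_lmm"`: list with `beta`, `Sigma_b`
#'   (2x2 random-effect covariance), `sigma2`, `b` (per-female
#'   intercept/slope matrix), `zconst`, `fit` (the underlying `lmerMod`)
#'   and `design`.
#' @export
fit_lmm <- function(design) {
  stopifnot(inherits(design, "fgc_design"), !is.null(design$y))
  X <- design$X
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(y = design$y, id = design$id, age = design$age)
  fit <- lme4::lmer(
    y ~ 0 + X + (1 + age | id), data = df,
    control = lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                                calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  names(beta) <- colnames(X)
  vc <- lme4::VarCorr(fit)
  Sigma_b <- matrix(as.numeric(vc$id), 2, 2)
  re <- lme4::ranef(fit)$id
  b <- as.matrix(re)[levels(design$id), , drop = FALSE]
  colnames(b) <- c("intercept", "slope")
  structure(list(beta = beta, Sigma_b = Sigma_b,
                 sigma2 = stats::sigma(fit)^2, b = b,
                 zconst = design$zconst, fit = fit, design = design),
            class = "fgc_lmm")
}

#' @export
print.fgc_lmm <- function(x, ...) {
  cat("Longitudinal submodel of log fGC (linear mixed model)\n")
  cat(sprintf("  %d samples, %d females\n",
              length(x$design$y), nrow(x$b)))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  cat(sprintf("  random effects: sd(intercept) = %.4f, sd(age slope) = %.4f, corr = %.2f\n",
              sqrt(x$Sigma_b[1, 1]), sqrt(x$Sigma_b[2, 2]),
              stats::cov2cor(x$Sigma_b)[1, 2]))
  cat(sprintf("  residual variance = %.4f\n", x$sigma2))
  r2 <- r2_nakagawa(x)
  cat(sprintf("  R2 (marginal / conditional) = %.3f / %.3f\n",
              r2[["marginal"]], r2[["conditional"]]))
  invisible(x)
}

#' Marginal and conditional variance explained (Nakagawa decomposition)
#'
#' Marginal R2 is the variance of the fixed-effect predictor over the
#' total (fixed + random + residual) variance; conditional R2 adds the
#' random-effect variance to the numerator. The random-effect variance for
#' the intercept + age-slope structure is the average over observations of
#' `z' Sigma_b z` with `z = (1, age)`.
#'
#' @param fit an `fgc_lmm` (or any list with `beta`, `Sigma_b`, `sigma2`).
#' @param design the design to evaluate on (defaults to the fitted one).
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(fit, design = fit$design) {
  var_f <- stats::var(drop(design$X %*% fit$beta[colnames(design$X)]))
  Z <- cbind(1, design$age)
  var_r <- mean(rowSums((Z %*% fit$Sigma_b) * Z))
  tot <- var_f + var_r + fit$sigma2
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Evaluate an individual's underlying trajectory m_i(t)
#'
#' The noise-free linear predictor `X_i(t) beta + Z_i(t) b_i` at the given
#' ages, using the female's yearly covariate path. For a female absent
#' from the fit the population-level prediction (`b_i = 0`) is returned
#' with attribute `population_level = TRUE` and a warning.
#'
#' @param fit an `fgc_lmm` (or any object with `beta` and `b`).
#' @param female female id.
#' @param t ages (years) at which to evaluate.
#' @param path the female's yearly covariate path (one element of
#'   [trajectory_paths()]).
#' @return numeric vector of trajectory values; see also
#'   [make_trajectory()] for derivative and integral queries.
#' @export
predict_m <- function(fit, female, t, path) {
  b <- if (female %in% rownames(fit$b)) fit$b[female, ] else {
    warning("female '", female, "' not in fit; population-level prediction")
    c(0, 0)
  }
  traj <- make_trajectory(fit$beta, b, path)
  out <- traj$value(t)
  if (!(female %in% rownames(fit$b))) attr(out, "population_level") <- TRUE
  out
}
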