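#' Configuration for the synthetic-cohort generator
#'
#' Builds and validates the parameter set that drives all synthetic-data
#' operations ([simulate_cohort()], [simulate_fgc()], [simulate_behavior()],
#' [simulate_survival()]). Defaults emulate the design of a long-term study
#' of wild female baboons: 242 adult females observed over a 19.5-year
#' window with staggered entry and right censoring, sparse irregular fecal
#' glucocorticoid (fGC) sampling (about 7.5 expected samples per
#' female-year), and mortality whose hazard depends on the true underlying
#' log-fGC trajectory.
#'
#' The default variance budget for log fGC partitions a total variance of
#' 0.199 (so that one unit of log fGC equals 2.24 standard deviations) into
#' a fixed-effect component (0.0275), a summed random intercept + age-slope
#' component evaluated at a reference adult age (0.0149), and residual
#' noise (0.1566); these imply marginal and conditional variance-explained
#' ratios of about 0.138 and 0.213.
#'
#' @param n_females number of adult females in the cohort.
#' @param obs_window_years length of the observation window in years.
#' @param entry_age_min minimum adult entry age in years.
#' @param sampling_rate expected fGC samples per female-year (zero-truncated
#'   Poisson rate).
#' @param beta named fixed-effect coefficients on the design scale (dummy
#'   codes for reproductive state, wet season and alpha status; z-scores for
#'   the continuous covariates; age in years). When `calibrate_fixed` is
#'   `TRUE` the non-intercept part is rescaled so its realised sample
#'   variance equals `var_fixed`; the realised coefficients are returned by
#'   [simulate_fgc()].
#' @param var_fixed target variance of the fixed linear predictor.
#' @param var_random summed marginal variance of the random intercept +
#'   age-slope at `ref_age`. Used to derive `Sigma_b` when that is `NULL`.
#' @param sd_slope standard deviation of the individual age slope
#'   (log-fGC units per year).
#' @param rho_b correlation between random intercept and slope.
#' @param Sigma_b optional explicit 2x2 random-effect covariance matrix,
#'   overriding `var_random`/`sd_slope`/`rho_b`.
#' @param ref_age adult age (years) at which the summed random-effect
#'   variance is anchored.
#' @param sigma2 residual variance of log fGC.
#' @param baseline Gompertz baseline-hazard parameters `c(a, b)`:
#'   `h0(t) = a * exp(b * (t - entry_age_min))`. The default gives a median
#'   adult age at death near 18 years.
#' @param gamma coefficients of the yearly survival covariates
#'   (DSI-F, DSI-M, annual rainfall anomaly), on the z-score scale.
#' @param assoc association structure linking trajectory and hazard; see
#'   [assoc_spec()].
#' @param n_groups number of social groups.
#' @param calibrate_fixed rescale the fixed predictor to hit `var_fixed`
#'   exactly in-sample (default `TRUE`).
#' @param seed integer seed governing all randomness.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [assoc_spec()], [simulate_cohort()]
#' @export
sim_config <- function(n_females = 242L,
                       obs_window_years = 19.5,
                       entry_age_min = 5.0,
                       sampling_rate = 7.5,
                       beta = default_sim_beta(),
                       var_fixed = 0.0275,
                       var_random = 0.0149,
                       sd_slope = 0.003,
                       rho_b = 0,
                       Sigma_b = NULL,
                       ref_age = 11.5,
                       sigma2 = 0.1566,
                       baseline = c(a = 0.022, b = 0.12),
                       gamma = c(dsi_f = -0.25, dsi_m = -0.15,
                                 rain_anom = -0.10),
                       assoc = assoc_spec("none"),
                       n_groups = 5L,
                       calibrate_fixed = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_females = as.integer(n_females),
    obs_window_years = obs_window_years,
    entry_age_min = entry_age_min,
    sampling_rate = sampling_rate,
    beta = beta,
    var_fixed = var_fixed,
    var_random = var_random,
    sd_slope = sd_slope,
    rho_b = rho_b,
    ref_age = ref_age,
    sigma2 = sigma2,
    baseline = baseline,
    gamma = gamma,
    assoc = assoc,
    n_groups = as.integer(n_groups),
    calibrate_fixed = isTRUE(calibrate_fixed),
    origin = as.Date("2000-01-01"),
    seed = as.integer(seed)
  )
  if (is.null(Sigma_b)) {
    v_slope <- sd_slope^2
    cov_is <- rho_b * sd_slope * sqrt(max(var_random, 1e-12))
    v_int <- var_random - ref_age^2 * v_slope - 2 * ref_age * cov_is
    if (v_int < 0)
      stop("sim_config: var_random too small for sd_slope at ref_age ",
           "(field 'var_random')", call. = FALSE)
    Sigma_b <- matrix(c(v_int, cov_is, cov_is, v_slope), 2, 2)
  }
  cfg$Sigma_b <- Sigma_b
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Association structure between trajectory and hazard
#'
#' @param mode one of `"value"` (current value of the trajectory),
#'   `"slope"` (current derivative), `"auc"` (cumulative area under the
#'   trajectory since adult entry), or `"none"`.
#' @param alpha association coefficient on the log hazard; forced to 0 for
#'   `mode = "none"`.
#' @return An object of class `"assoc_spec"`.
#' @export
assoc_spec <- function(mode = c("none", "value", "slope", "auc"),
                       alpha = 0) {
  mode <- match.arg(mode)
  if (mode == "none") alpha <- 0
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  structure(list(mode = mode, alpha = alpha), class = "assoc_spec")
}

#' Default fixed-effect coefficients of the synthetic log-fGC model
#'
#' Signs follow the field's expectations: higher fGC when pregnant, in the
#' wet season, at high temperature and in very small or large groups; lower
#' at high rank. Magnitudes are starting values that [simulate_fgc()]
#' rescales to meet the configured fixed-effect variance.
#' @return named numeric vector (design-scale coefficients).
#' @export
default_sim_beta <- function() {
  c(intercept = 4.0, age = 0.010,
    pregnant = 0.20, lactating = 0.05,
    wet_season = 0.08, is_alpha = 0.06,
    rain_anom_3mo = -0.05, tmax_30d = 0.06,
    group_size = 0.03, group_size_sq = 0.03,
    rank = -0.04, time_to_extraction = 0.03, time_to_assay = 0.02)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("sim_config: invalid field '%s': %s", field, msg),
         call. = FALSE)
  if (cfg$n_females < 1L) fail("n_females", "must be >= 1")
  if (cfg$obs_window_years <= 0) fail("obs_window_years", "must be > 0")
  if (cfg$entry_age_min < 0) fail("entry_age_min", "must be >= 0")
  if (cfg$sampling_rate <= 0) fail("sampling_rate", "must be > 0")
  if (cfg$sigma2 < 0) fail("sigma2", "must be >= 0")
  if (cfg$var_fixed < 0) fail("var_fixed", "must be >= 0")
  ev <- eigen(cfg$Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) fail("Sigma_b", "must be positive semi-definite")
  if (!all(c("a", "b") %in% names(cfg$baseline)))
    fail("baseline", "needs named components 'a' and 'b'")
  if (cfg$baseline[["a"]] <= 0) fail("baseline", "Gompertz 'a' must be > 0")
  if (!inherits(cfg$assoc, "assoc_spec")) fail("assoc", "use assoc_spec()")
  req <- c("intercept", "age", "pregnant", "lactating", "wet_season",
           "is_alpha", "rain_anom_3mo", "tmax_30d", "group_size",
           "group_size_sq", "rank", "time_to_extraction", "time_to_assay")
  if (!all(req %in% names(cfg$beta)))
    fail("beta", paste("missing coefficients:",
                       paste(setdiff(req, names(cfg$beta)), collapse = ", ")))
  invisible(cfg)
}
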