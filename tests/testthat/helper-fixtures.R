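# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

## small cohort + samples + survival, reused across test files
small_sim <- function() {
  if (is.null(.fx$small)) {
    cfg <- sim_config(n_females = 30L, obs_window_years = 12,
                      seed = 42L, assoc = assoc_spec("none"))
    co <- simulate_cohort(cfg)
    fg <- suppressWarnings(simulate_fgc(co))
    sv <- simulate_survival(co, fg)
    .fx$small <- list(cfg = cfg, cohort = co, fgc = fg, surv = sv)
  }
  .fx$small
}

## tiny 3-female joint data bundle for oracle checks
tiny_jm_data <- function() {
  if (is.null(.fx$tiny)) {
    cfg <- sim_config(n_females = 3L, obs_window_years = 8,
                      sampling_rate = 4, seed = 7L)
    co <- simulate_cohort(cfg)
    fg <- suppressWarnings(simulate_fgc(co))
    sv <- simulate_survival(co, fg)
    .fx$tiny <- list(cfg = cfg, cohort = co, fgc = fg, surv = sv,
                     jd = gcjm_data_from_sim(fg, sv))
  }
  .fx$tiny
}

## a fitted joint model on a small auc cohort (shared by prediction tests)
fitted_auc_model <- function() {
  if (is.null(.fx$fit_auc)) {
    cfg <- sim_config(n_females = 120L, seed = 11L,
                      assoc = assoc_spec("auc", 0.115))
    co <- simulate_cohort(cfg)
    fg <- suppressWarnings(simulate_fgc(co))
    sv <- simulate_survival(co, fg)
    jd <- gcjm_data_from_sim(fg, sv)
    fit <- suppressWarnings(
      gcjm(jd, assoc = "auc",
           control = jm_control(chains = 2, iter = 700, warmup = 350,
                                seed = 11L)))
    .fx$fit_auc <- list(cfg = cfg, cohort = co, fgc = fg, surv = sv,
                        jd = jd, fit = fit)
  }
  .fx$fit_auc
}

## daily weather record spanning whole years, constant or custom rain
toy_weather <- function(years = 2003:2005, rain = NULL, tmax = 30) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  data.frame(date = dates,
             rain_mm = if (is.null(rain)) rep(1, length(dates))
                       else rain(dates),
             tmax_c = rep(tmax, length.out = length(dates)))
}

## a synthetic gcjm fit object with constant-hazard posterior draws, for
## closed-form checks of the prediction machinery
constant_hazard_fit <- function(log_c = log(0.08), n_draws = 60L) {
  tiny <- tiny_jm_data()
  jd <- tiny$jd
  p <- jd$p
  nm <- c(paste0("beta[", colnames(jd$X), "]"),
          "sigma2", "sd_b0", "sd_b1", "rho_b",
          paste0("gamma[", c("dsi_f", "dsi_m", "rain_anom"), "]"),
          paste0("omega[", seq_len(ncol(jd$Bq)), "]"), "alpha", "lp")
  dr <- matrix(0, n_draws, length(nm), dimnames = list(NULL, nm))
  dr[, "beta[intercept]"] <- 4
  dr[, "sigma2"] <- 0.15
  dr[, "sd_b0"] <- 1e-4; dr[, "sd_b1"] <- 1e-6
  dr[, grep("^omega", nm)] <- log_c   # basis sums to 1: log h0 == log_c
  structure(list(chains = list(list(draws = dr,
                                    b_draws = array(0, c(n_draws, jd$nf, 2)),
                                    accept = c(b = 1))),
                 data = jd, assoc = "none",
                 control = jm_control(chains = 1, iter = 2 * n_draws,
                                      warmup = n_draws),
                 failed = FALSE),
            class = "gcjm")
}
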