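#' True trajectory functions of a simulated cohort
#'
#' @param fgc an `fgc_sim` from [simulate_fgc()].
#' @return named list of [make_trajectory()] objects built from the
#'   generator's realised coefficients and random effects (the "truth").
#' @export
true_trajectories <- function(fgc) {
  stopifnot(inherits(fgc, "fgc_sim"))
  ids <- names(fgc$xpath)
  stats::setNames(lapply(ids, function(f)
    make_trajectory(fgc$beta_true, fgc$b_true[f, ], fgc$xpath[[f]])), ids)
}

#' Simulate death times from a trajectory-dependent hazard
#'
#' Draws each female's death time by inverse-transform sampling from the
#' hazard
#' `h_i(t) = a exp(b (t - entry_min)) * exp(gamma' w_i(t) + f_c(alpha, M_i(t)))`,
#' where `w_i(t)` are yearly time-varying covariates (latent sociality
#' indices DSI-F and DSI-M plus the annual rainfall anomaly, z-scored
#' across female-years) and `f_c` is the configured association feature of
#' the true trajectory, centred at the population-mean trajectory so that
#' the Gompertz baseline retains its scale. The cumulative hazard is
#' integrated by the same per-year Gauss-Legendre quadrature the joint
#' model uses, and the equation `H(T) = -log(U)` is solved by root
#' finding. Exit is the earlier of death and censoring.
#'
#' @param cohort a `gc_cohort`.
#' @param fgc the matching `fgc_sim`.
#' @param config the [sim_config()] (defaults to the cohort's).
#' @return An object of class `"surv_sim"`: list with `records` (id,
#'   entry_age, exit_age, event), `wpath` (per female-year covariates, raw
#'   and z-scored), `wconst` (z constants), and the config echo.
#' @export
simulate_survival <- function(cohort, fgc, config = cohort$config) {
  stopifnot(inherits(cohort, "gc_cohort"), inherits(fgc, "fgc_sim"))
  set.seed(child_seed(config$seed, 3L))
  fem <- cohort$females
  trajs <- true_trajectories(fgc)
  beta_age <- fgc$beta_true[["age"]]
  etabar0 <- mean(drop(fgc$design$X %*% fgc$beta_true) -
                    beta_age * fgc$design$age)

  ## --- yearly survival covariates ----------------------------------------
  wrange <- range(cohort$weather$date)
  wp <- do.call(rbind, lapply(seq_len(nrow(fem)), function(i) {
    pth <- fgc$xpath[[fem$id[i]]]
    yrs <- seq(pth$a0, length.out = nrow(pth$rows))
    s <- pmax(age_to_date(fem$birthdate[i], yrs), wrange[1])
    e <- pmin(age_to_date(fem$birthdate[i], yrs + 1) - 1, wrange[2])
    e <- pmax(e, s)
    data.frame(id = fem$id[i], age_class = yrs,
               dsi_f = 0.7 * fem$sociality[i] + stats::rnorm(length(yrs), 0, 0.5),
               dsi_m = 0.5 * fem$sociality[i] + stats::rnorm(length(yrs), 0, 0.6),
               rain_anom = annual_rainfall_anomaly(cohort$weather, s, e))
  }))
  wconst <- list(mean = colMeans(wp[, c("dsi_f", "dsi_m", "rain_anom")]),
                 sd = apply(wp[, c("dsi_f", "dsi_m", "rain_anom")], 2, stats::sd))
  for (v in c("dsi_f", "dsi_m", "rain_anom"))
    wp[[paste0(v, "_z")]] <- (wp[[v]] - wconst$mean[[v]]) / wconst$sd[[v]]

  gam <- config$gamma
  alpha <- config$assoc$alpha
  mode <- config$assoc$mode
  a_g <- config$baseline[["a"]]; b_g <- config$baseline[["b"]]
  e_min <- config$entry_age_min

  records <- vector("list", nrow(fem))
  for (i in seq_len(nrow(fem))) {
    idf <- fem$id[i]
    traj <- trajs[[idf]]
    entry <- fem$entry_age[i]; censor <- fem$censor_age[i]
    wz <- as.matrix(wp[wp$id == idf, c("dsi_f_z", "dsi_m_z", "rain_anom_z")])
    a0 <- fgc$xpath[[idf]]$a0
    feat <- function(t) {
      switch(mode,
             none = 0,
             value = traj$value(t) - (etabar0 + beta_age * t),
             slope = traj$deriv(t) - beta_age,
             auc = traj$integral(e_min, t) -
               (etabar0 * (t - e_min) + beta_age * (t^2 - e_min^2) / 2))
    }
    loghaz <- function(t) {
      k <- pmin(pmax(floor(t) - a0 + 1, 1L), nrow(wz))
      lh <- log(a_g) + b_g * (t - e_min) + drop(wz[k, , drop = FALSE] %*% gam) +
        alpha * vapply(t, feat, 0)
      if (any(!is.finite(lh)))
        stop("non-finite hazard for female ", idf, " at age ",
             signif(t[which(!is.finite(lh))[1]], 5))
      lh
    }
    E <- stats::rexp(1)
    segs <- year_segments(entry, censor)
    Hcum <- 0; death <- NA_real_
    for (k in seq_len(nrow(segs))) {
      q <- gl_segment(segs[k, 1], segs[k, 2])
      Hseg <- sum(q$w * exp(loghaz(q$x)))
      if (Hcum + Hseg >= E) {
        f_root <- function(u) {
          qq <- gl_segment(segs[k, 1], u)
          Hcum + sum(qq$w * exp(loghaz(qq$x))) - E
        }
        death <- stats::uniroot(f_root, c(segs[k, 1] + 1e-9, segs[k, 2]),
                                tol = 1e-8)$root
        break
      }
      Hcum <- Hcum + Hseg
    }
    event <- !is.na(death)
    records[[i]] <- data.frame(id = idf, entry_age = entry,
                               exit_age = if (event) death else censor,
                               event = as.integer(event))
  }
  records <- do.call(rbind, records)
  ## truncate the covariate path at exit
  wp <- wp[wp$age_class < records$exit_age[match(wp$id, records$id)], ]
  structure(list(records = records, wpath = wp, wconst = wconst,
                 config = config),
            class = "surv_sim")
}
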