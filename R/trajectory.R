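#' Yearly trajectory covariate paths
#'
#' Builds, for each female, the yearly design-matrix path used to evaluate
#' her underlying (noise-free) log-fGC trajectory `m_i(t)` at arbitrary
#' adult ages: one row per year of life covering `[entry, censor]`, in the
#' column order of [build_fgc_design()]. Within a year all covariates are
#' constant except age, which enters continuously (the `age` column is
#' stored as 0 and supplied at evaluation time). Seasonal, reproductive
#' and weather covariates are averaged over a monthly grid within the
#' year; group size and latent rank are taken at mid-year; the storage
#' covariates sit at their sample means (z-score 0).
#'
#' @param cohort a `gc_cohort`.
#' @param zconst z-scoring constants from the sample design (so the path
#'   is on the same scale as the fitted coefficients).
#' @return named list (by female id) of lists with `a0` (first year-start
#'   age, integer), `rows` (matrix, years x design columns), `entry`,
#'   `end` (ages).
#' @export
trajectory_paths <- function(cohort, zconst) {
  fem <- cohort$females
  cols <- design_columns()
  zc_cols <- names(zconst$mean)
  out <- vector("list", nrow(fem))
  names(out) <- fem$id
  wrange <- range(cohort$weather$date)
  for (i in seq_len(nrow(fem))) {
    entry <- fem$entry_age[i]; end <- fem$censor_age[i]
    a0 <- floor(entry)
    yrs <- seq(a0, ceiling(end) - 1L)
    rows <- matrix(0, length(yrs), length(cols),
                   dimnames = list(NULL, cols))
    repro_i <- cohort$repro[cohort$repro$id == fem$id[i], ]
    ny <- length(yrs)
    ## one monthly grid for all years of this female at once
    grid_age <- rep(yrs, each = 12) + (seq_len(12) - 0.5) / 12
    grid_date <- age_to_date(fem$birthdate[i], grid_age)
    grid_date <- pmin(pmax(grid_date, wrange[1] + 91), wrange[2])
    st <- reproductive_state_at(repro_i, pmin(pmax(grid_age, entry), end))
    byyear <- function(v) rowMeans(matrix(v, ny, 12, byrow = TRUE),
                                   na.rm = TRUE)
    rain_y <- byyear(rainfall_anomaly_3mo(cohort$weather, grid_date))
    tmax_y <- byyear(mean_max_temp_30d(cohort$weather, grid_date))
    preg_y <- byyear(st == "pregnant")
    lact_y <- byyear(st == "lactating")
    wet_y <- byyear(season_of(grid_date) == "wet")
    mid_date <- pmin(pmax(age_to_date(fem$birthdate[i], yrs + 0.5),
                          wrange[1]), wrange[2])
    gr <- .group_rank_covariates(cohort, rep(i, ny), mid_date)
    raw <- cbind(rain_anom_3mo = rain_y, tmax_30d = tmax_y,
                 group_size = gr$group_size,
                 group_size_sq = gr$group_size^2, rank = gr$rank,
                 time_to_extraction = zconst$mean[["time_to_extraction"]],
                 time_to_assay = zconst$mean[["time_to_assay"]])
    z <- sweep(sweep(raw[, zc_cols, drop = FALSE], 2, zconst$mean[zc_cols]),
               2, zconst$sd[zc_cols], "/")
    rows[] <- cbind(intercept = 1, age = 0, pregnant = preg_y,
                    lactating = lact_y, wet_season = wet_y,
                    is_alpha = as.numeric(gr$is_alpha), z)[, cols]
    out[[i]] <- list(a0 = a0, rows = rows, entry = entry, end = end)
  }
  out
}

#' Individual trajectory function m_i(t)
#'
#' Packages one female's fitted (or true) linear trajectory as an object
#' supporting value, derivative and exact integral queries. Within each
#' year of life the trajectory is linear in age (yearly covariates are
#' piecewise constant); the integral is the piecewise closed form, exact
#' and additive over adjacent intervals.
#'
#' @param beta fixed-effect vector (design-column order).
#' @param b length-2 individual random effect `(intercept, slope)`.
#' @param path one element of [trajectory_paths()].
#' @return An object of class `"gc_trajectory"` with functions
#'   `value(t)`, `deriv(t)` and `integral(t0, t1)` (all vectorized).
#' @export
make_trajectory <- function(beta, b, path) {
  beta <- beta[design_columns()]
  consts <- drop(path$rows %*% beta) + b[1]
  slope <- beta[["age"]] + b[2]
  a0 <- path$a0
  nseg <- length(consts)
  seg_of <- function(t) pmin(pmax(floor(t) - a0 + 1, 1L), nseg)
  value <- function(t) consts[seg_of(t)] + slope * t
  deriv <- function(t) rep(slope, length(t))
  ## exact integral of the piecewise-linear trajectory from t0 to t1
  integral <- function(t0, t1) {
    n <- max(length(t0), length(t1))
    t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
    vapply(seq_len(n), function(j) {
      sgn <- 1
      a <- t0[j]; bb <- t1[j]
      if (bb < a) { tmp <- a; a <- bb; bb <- tmp; sgn <- -1 }
      ints <- if (ceiling(a) <= floor(bb)) seq(ceiling(a), floor(bb))
              else numeric(0)
      brk <- unique(c(a, ints[ints > a & ints < bb], bb))
      if (length(brk) < 2L) return(0)
      lo <- brk[-length(brk)]; hi <- brk[-1]
      mid <- (lo + hi) / 2
      sgn * sum((consts[seg_of(mid)] + slope * mid) * (hi - lo))
    }, 0)
  }
  structure(list(value = value, deriv = deriv, integral = integral,
                 entry = path$entry, end = path$end,
                 consts = consts, slope = slope, a0 = a0),
            class = "gc_trajectory")
}
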