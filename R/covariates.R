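#' Season of a date
#'
#' The study system has a single long dry season: June through October.
#' November through May is the wet season. Season is a pure function of the
#' calendar month.
#'
#' @param date a `Date` vector.
#' @return character vector, `"dry"` or `"wet"`.
#' @export
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 6L & m <= 10L, "dry", "wet")
}

## Internal: index of a date in a contiguous daily record; NA outside.
.day_index <- function(record_dates, dates) {
  i <- as.integer(as.numeric(dates) - as.numeric(record_dates[1L])) + 1L
  i[i < 1L | i > length(record_dates)] <- NA_integer_
  i
}

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

## Internal: calendar month-day index on a 365-day scale (Feb 29 -> Feb 28)
## and its inverse for a given year. Numeric day arithmetic for speed.
.calendar_md <- function(dates) {
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1L
  year <- lt$year + 1900L
  list(md = doy - as.integer(.is_leap(year) & doy > 59L), year = year)
}

.md_date_num <- function(md, y) {
  jan1 <- as.numeric(as.Date(paste0(y, "-01-01")))
  jan1 + md - 1 + as.integer(.is_leap(y) & md >= 60L)
}

.check_daily <- function(weather, value_col) {
  stopifnot(is.data.frame(weather), "date" %in% names(weather),
            value_col %in% names(weather))
  d <- as.Date(weather$date)
  if (nrow(weather) > 1L && any(diff(d) != 1L))
    stop("daily weather record must be contiguous (one row per day)")
  d
}

#' Three-month rainfall anomaly
#'
#' Total rainfall over the 90 days ending the day before each query date,
#' minus the long-term mean of the same calendar window across all years of
#' the daily record (the focal year included).
#'
#' @param weather data frame with columns `date` and `rain_mm` (one row per
#'   day, contiguous).
#' @param dates query dates.
#' @return numeric vector (mm); `NA` with a warning where the 90-day focal
#'   window is not covered by the record.
#' @export
rainfall_anomaly_3mo <- function(weather, dates) {
  d <- .check_daily(weather, "rain_mm")
  cs <- c(0, cumsum(weather$rain_mm))
  d0 <- as.numeric(d[1L]); nd <- length(d)
  win_sum <- function(qn) {          # qn: numeric dates (query day itself)
    i <- as.integer(qn - d0) + 1L
    lo <- i - 90L
    out <- rep(NA_real_, length(qn))
    ok <- !is.na(i) & i <= nd & lo >= 1L
    out[ok] <- cs[i[ok]] - cs[lo[ok]]
    out
  }
  dates <- as.Date(dates)
  focal <- win_sum(as.numeric(dates))
  if (anyNA(focal))
    warning(sum(is.na(focal)), " date(s) lack 90-day rainfall coverage; NA returned")
  years <- sort(unique(as.POSIXlt(d)$year + 1900L))
  md <- .calendar_md(dates)$md
  acc <- matrix(NA_real_, length(dates), length(years))
  for (k in seq_along(years))
    acc[, k] <- win_sum(.md_date_num(md, years[k]))
  ltm <- rowMeans(acc, na.rm = TRUE)
  ltm[rowSums(!is.na(acc)) < 1L] <- NA_real_
  focal - ltm
}

#' Annual rainfall anomaly over a (possibly truncated) year of life
#'
#' Total rainfall between `start` and `end` (inclusive), minus the
#' long-term mean total over the same calendar span across all years of
#' the record. Spans truncated by death or censoring are compared against
#' the same truncated calendar span in other years.
#'
#' @param weather daily record with `date` and `rain_mm`.
#' @param start,end `Date` vectors delimiting each interval (`end >= start`).
#' @return numeric vector (mm), `NA` with warning when uncovered.
#' @export
annual_rainfall_anomaly <- function(weather, start, end) {
  d <- .check_daily(weather, "rain_mm")
  cs <- c(0, cumsum(weather$rain_mm))
  d0 <- as.numeric(d[1L]); nd <- length(d)
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(length(start) == length(end), all(end >= start))
  span_sum <- function(sn, en) {
    i0 <- as.integer(sn - d0) + 1L; i1 <- as.integer(en - d0) + 1L
    out <- rep(NA_real_, length(sn))
    ok <- i0 >= 1L & i1 <= nd
    out[ok] <- cs[i1[ok] + 1L] - cs[i0[ok]]
    out
  }
  focal <- span_sum(as.numeric(start), as.numeric(end))
  if (anyNA(focal))
    warning(sum(is.na(focal)), " interval(s) not covered by the rainfall record")
  len <- as.numeric(end - start)
  years <- sort(unique(as.POSIXlt(d)$year + 1900L))
  md <- .calendar_md(start)$md
  acc <- matrix(NA_real_, length(start), length(years))
  for (k in seq_along(years)) {
    s_k <- .md_date_num(md, years[k])
    acc[, k] <- span_sum(s_k, s_k + len)
  }
  ltm <- rowMeans(acc, na.rm = TRUE)
  ltm[rowSums(!is.na(acc)) < 1L] <- NA_real_
  focal - ltm
}

#' Mean daily maximum temperature over the preceding 30 days
#'
#' Arithmetic mean of daily maximum temperature over the 30 days ending at
#' and including each query date. Up to 5 missing days are tolerated (the
#' mean is then taken over the available days); more than 5 missing days
#' yield `NA`.
#'
#' @param weather daily record with `date` and `tmax_c` (may contain `NA`).
#' @param dates query dates.
#' @return numeric vector (degrees C).
#' @export
mean_max_temp_30d <- function(weather, dates) {
  d <- .check_daily(weather, "tmax_c")
  v <- weather$tmax_c
  ok <- !is.na(v)
  cs <- c(0, cumsum(ifelse(ok, v, 0)))
  cn <- c(0L, cumsum(as.integer(ok)))
  i <- .day_index(d, as.Date(dates))
  lo <- i - 30L
  out <- rep(NA_real_, length(i))
  valid <- !is.na(i) & lo >= 0L
  s <- cs[i[valid] + 1L] - cs[lo[valid] + 1L]
  n <- cn[i[valid] + 1L] - cn[lo[valid] + 1L]
  m <- ifelse(n >= 25L, s / n, NA_real_)
  out[valid] <- m
  out
}

#' Reproductive state at a given age, with the early-lactation recode
#'
#' Looks up a female's reproductive-state interval table at an age and
#' recodes the day of parturition plus the three following days (the first
#' four days of lactation) as `"pregnant"`, reflecting the lag with which
#' excreted hormone metabolites track circulating levels around birth.
#'
#' @param states data frame with columns `state`
#'   (`cycling`/`pregnant`/`lactating`), `start_age`, `end_age` (decimal
#'   years; half-open intervals `[start, end)` partitioning the timeline).
#' @param age numeric vector of query ages.
#' @return character vector of states, `NA` outside the known intervals.
#' @export
reproductive_state_at <- function(states, age) {
  stopifnot(all(c("state", "start_age", "end_age") %in% names(states)))
  out <- rep(NA_character_, length(age))
  for (k in seq_len(nrow(states))) {
    in_k <- age >= states$start_age[k] & age < states$end_age[k]
    out[in_k] <- states$state[k]
    if (states$state[k] == "lactating") {
      recode <- in_k & age < states$start_age[k] + 4 / 365.25
      out[recode] <- "pregnant"
    }
  }
  out
}

#' Z-score helper that stores its constants
#' @noRd
.zscore <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Column order of the longitudinal fixed-effect design
#' @noRd
design_columns <- function() {
  c("intercept", "age", "pregnant", "lactating", "wet_season", "is_alpha",
    "rain_anom_3mo", "tmax_30d", "group_size", "group_size_sq", "rank",
    "time_to_extraction", "time_to_assay")
}

#' Build the fixed-effect design matrix of the longitudinal submodel
#'
#' Takes a table of fGC samples carrying their covariate snapshot and
#' assembles the design used by [fit_lmm()] and [gcjm()]: an intercept; age
#' in years (unstandardized, shared with the random slope); dummy codes for
#' pregnant and lactating (reference cycling), wet season (reference dry)
#' and alpha status; and z-scored continuous covariates (3-month rainfall
#' anomaly, 30-day maximum temperature, group size, group size squared,
#' proportional dominance rank, time to extraction, time to assay). Group
#' size squared is squared first and z-scored by its own mean and standard
#' deviation. Z-scoring constants are stored for reuse at prediction time.
#'
#' @param samples data frame with columns `id`, `age`,
#'   `reproductive_state`, `season`, `rain_anom_3mo`, `tmax_30d`,
#'   `group_size`, `rank`, `is_alpha`, `time_to_extraction`,
#'   `time_to_assay`, and optionally `log_fgc` (the response).
#' @param zconst optional list of previously stored z-scoring constants
#'   (as returned in the output) to apply instead of recomputing.
#' @return An object of class `"fgc_design"`: list with elements `X`
#'   (design matrix), `y` (response or `NULL`), `id` (factor), `age`,
#'   `zconst`, and `n_dropped` (rows removed for unresolvable covariates).
#' @export
build_fgc_design <- function(samples, zconst = NULL) {
  need <- c("id", "age", "reproductive_state", "season", "rain_anom_3mo",
            "tmax_30d", "group_size", "rank", "is_alpha",
            "time_to_extraction", "time_to_assay")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("samples table lacks columns: ", paste(miss, collapse = ", "))
  cont_raw <- cbind(rain_anom_3mo = samples$rain_anom_3mo,
                    tmax_30d = samples$tmax_30d,
                    group_size = as.numeric(samples$group_size),
                    group_size_sq = as.numeric(samples$group_size)^2,
                    rank = samples$rank,
                    time_to_extraction = as.numeric(samples$time_to_extraction),
                    time_to_assay = as.numeric(samples$time_to_assay))
  keep <- stats::complete.cases(cont_raw) & !is.na(samples$age) &
    !is.na(samples$reproductive_state) & !is.na(samples$season)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("build_fgc_design: dropped ", n_dropped,
            " sample(s) with unresolvable covariates")
  samples <- samples[keep, , drop = FALSE]
  cont_raw <- cont_raw[keep, , drop = FALSE]
  if (is.null(zconst)) {
    zs <- apply(cont_raw, 2L, .zscore, simplify = FALSE)
    zconst <- list(mean = vapply(zs, `[[`, 0, "mean"),
                   sd = vapply(zs, `[[`, 0, "sd"))
  }
  Zc <- sweep(sweep(cont_raw, 2L, zconst$mean[colnames(cont_raw)]),
              2L, zconst$sd[colnames(cont_raw)], "/")
  X <- cbind(intercept = 1,
             age = samples$age,
             pregnant = as.numeric(samples$reproductive_state == "pregnant"),
             lactating = as.numeric(samples$reproductive_state == "lactating"),
             wet_season = as.numeric(samples$season == "wet"),
             is_alpha = as.numeric(samples$is_alpha > 0),
             Zc)
  X <- X[, design_columns(), drop = FALSE]
  structure(list(X = X,
                 y = samples$log_fgc %||% NULL,
                 id = factor(samples$id),
                 age = samples$age,
                 zconst = zconst,
                 n_dropped = n_dropped),
            class = "fgc_design")
}
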