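#' Dyadic daily grooming rates for one female-year
#'
#' For a focal female and one year of her life (birthday to birthday,
#' possibly right-truncated), returns one record per adult partner that
#' co-resided with her in the same group during the window: the number of
#' grooming events between them in either direction, the number of
#' co-residence days, and the daily grooming rate (events per co-residence
#' day). Grooming with juveniles is excluded by construction: only partners
#' present in the adult `members` table are considered.
#'
#' @param grooming data frame of events with columns `date`, `giver`,
#'   `receiver`.
#' @param members adult residency table with columns `id`, `sex`
#'   (`"F"`/`"M"`), `group`, `start_date`, `end_date` (one interval per
#'   animal).
#' @param focal focal female id.
#' @param start,end `Date` bounds of the female-year window (inclusive).
#' @return data frame of class rows: `partner`, `partner_sex`,
#'   `grooming_count`, `coresidence_days`, `daily_rate`. Dyads with zero
#'   co-residence days are skipped.
#' @export
dyadic_rates <- function(grooming, members, focal, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  me <- members[members$id == focal, ]
  if (nrow(me) != 1L) stop("focal female not found in members table")
  others <- members[members$id != focal & members$group == me$group, ]
  s <- pmax(as.Date(others$start_date), as.Date(me$start_date), start)
  e <- pmin(as.Date(others$end_date), as.Date(me$end_date), end)
  cores <- as.numeric(e - s) + 1
  keep <- cores > 0
  others <- others[keep, ]; s <- s[keep]; e <- e[keep]; cores <- cores[keep]
  if (nrow(others) == 0L)
    return(data.frame(partner = character(), partner_sex = character(),
                      grooming_count = integer(), coresidence_days = numeric(),
                      daily_rate = numeric(),
                      cores_start = as.Date(character()),
                      cores_end = as.Date(character())))
  gd <- as.Date(grooming$date)
  inv <- (grooming$giver == focal | grooming$receiver == focal)
  g <- grooming[inv, , drop = FALSE]; gd <- gd[inv]
  partner_of <- ifelse(g$giver == focal, g$receiver, g$giver)
  cnt <- integer(nrow(others))
  for (k in seq_len(nrow(others)))
    cnt[k] <- sum(partner_of == others$id[k] & gd >= s[k] & gd <= e[k])
  data.frame(partner = others$id, partner_sex = others$sex,
             grooming_count = cnt, coresidence_days = cores,
             daily_rate = cnt / cores,
             cores_start = s, cores_end = e, row.names = NULL)
}

#' Observer effort for a dyad's co-residence days
#'
#' The number of focal samples on adult females collected during the given
#' days, divided by the mean number of adult females in the group during
#' those days, divided by the number of days.
#'
#' @param focal_counts data frame with `group`, `date`, `n_focal`.
#' @param members adult residency table (see [dyadic_rates()]).
#' @param group group id.
#' @param start,end `Date` bounds of the dyad's co-residence interval.
#' @return scalar effort; `NA` if no adult females were present on any day.
#' @export
observer_effort <- function(focal_counts, members, group, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  days <- seq(start, end, by = "day")
  fc <- focal_counts[focal_counts$group == group, ]
  n_samples <- sum(fc$n_focal[as.Date(fc$date) >= start & as.Date(fc$date) <= end])
  fem <- members[members$sex == "F" & members$group == group, ]
  if (nrow(fem) == 0L) return(NA_real_)
  counts <- vapply(days, function(d)
    sum(as.Date(fem$start_date) <= d & as.Date(fem$end_date) >= d), 0L)
  mean_f <- mean(counts)
  if (mean_f == 0) return(NA_real_)
  n_samples / mean_f / length(days)
}

#' Effort-corrected dyadic bond strengths
#'
#' Ordinary least-squares residuals of log daily grooming rate on log
#' observer effort, pooled over all dyads supplied (the population's dyads
#' for one female-year window). Dyads that were never observed grooming
#' (`grooming_count == 0`) are excluded from the regression and receive no
#' residual (`NA`): a bond strength is defined only for observed grooming
#' partners.
#'
#' @param dyads data frame with `grooming_count`, `daily_rate`, `effort`.
#' @return the input with a `residual` column appended.
#' @export
bond_residuals <- function(dyads) {
  stopifnot(all(c("grooming_count", "daily_rate", "effort") %in% names(dyads)))
  res <- rep(NA_real_, nrow(dyads))
  use <- dyads$grooming_count >= 1L & !is.na(dyads$effort) & dyads$effort > 0
  if (sum(use) >= 2L) {
    lr <- log(dyads$daily_rate[use])
    le <- log(dyads$effort[use])
    if (stats::var(le) < 1e-12) {
      warning("all observer-effort values identical; slope set to 0")
      res[use] <- lr - mean(lr)
    } else {
      fit <- stats::lm.fit(cbind(1, le), lr)
      res[use] <- fit$residuals
    }
  } else if (sum(use) == 1L) {
    res[use] <- 0
  }
  dyads$residual <- res
  dyads
}

#' Dyadic sociality index: mean strength of the top three bonds
#'
#' Mean of the three largest bond-strength residuals among a female's
#' partners of a given sex in one year of life; with fewer than three
#' partners, the mean of however many she had; with none, `NA` (missing, to
#' be imputed downstream).
#'
#' @param residuals numeric vector of bond strengths for one female-year
#'   and partner sex (`NA`s ignored).
#' @return scalar DSI value or `NA`.
#' @export
dsi <- function(residuals) {
  r <- sort(residuals[!is.na(residuals)], decreasing = TRUE)
  if (length(r) == 0L) return(NA_real_)
  mean(r[seq_len(min(3L, length(r)))])
}

#' Impute missing DSI values by age-class means
#'
#' Missing `dsi_f`/`dsi_m` entries are replaced by the mean of the
#' non-missing values of females in the same age class (integer year of
#' life); age classes with no observed values fall back to the global mean
#' with a warning.
#'
#' @param dsi_table data frame with `age_class` and the columns named in
#'   `cols`.
#' @param cols columns to impute.
#' @return the table with imputed values and logical `<col>_imputed` flags.
#' @export
impute_missing_dsi <- function(dsi_table, cols = c("dsi_f", "dsi_m")) {
  if (nrow(dsi_table) == 0L) stop("empty DSI table")
  for (cl in cols) {
    v <- dsi_table[[cl]]
    miss <- is.na(v)
    dsi_table[[paste0(cl, "_imputed")]] <- miss
    if (!any(miss)) next
    if (all(miss)) stop("column '", cl, "' has no observed values")
    cls_mean <- tapply(v[!miss], dsi_table$age_class[!miss], mean)
    fill <- cls_mean[as.character(dsi_table$age_class[miss])]
    if (anyNA(fill)) {
      warning("age class(es) without observed ", cl,
              "; global mean used for ", sum(is.na(fill)), " value(s)")
      fill[is.na(fill)] <- mean(v[!miss])
    }
    v[miss] <- fill
    dsi_table[[cl]] <- v
  }
  dsi_table
}

#' Per-female-year DSI table from raw behavioral records
#'
#' Runs the full sociality pipeline: for each female-year of life, daily
#' grooming rates for all of the population's dyads over that window,
#' observer-effort correction by pooled log-log regression, and the
#' female's DSI with female (DSI-F) and male (DSI-M) partners, followed by
#' age-class-mean imputation of missing values.
#'
#' @param grooming,focal_counts,members see [dyadic_rates()] and
#'   [observer_effort()].
#' @param females data frame with `id`, `birthdate`, `entry_age`,
#'   `exit_age` delimiting each female's adult observation span.
#' @param exclude_windows optional data frame (`group`, `start`, `end`) of
#'   low-observation periods; grooming and effort inside them are dropped.
#' @return data frame: `id`, `year_of_life`, `age_class`, `dsi_f`, `dsi_m`
#'   plus imputation flags.
#' @export
dsi_table <- function(grooming, focal_counts, members, females,
                      exclude_windows = NULL) {
  if (!is.null(exclude_windows) && nrow(exclude_windows)) {
    drop_g <- rep(FALSE, nrow(grooming))
    drop_f <- rep(FALSE, nrow(focal_counts))
    for (k in seq_len(nrow(exclude_windows))) {
      w <- exclude_windows[k, ]
      drop_g <- drop_g | (as.Date(grooming$date) >= as.Date(w$start) &
                            as.Date(grooming$date) <= as.Date(w$end))
      drop_f <- drop_f | (focal_counts$group == w$group &
                            as.Date(focal_counts$date) >= as.Date(w$start) &
                            as.Date(focal_counts$date) <= as.Date(w$end))
    }
    grooming <- grooming[!drop_g, , drop = FALSE]
    focal_counts <- focal_counts[!drop_f, , drop = FALSE]
  }
  effort_cache <- new.env(parent = emptyenv())
  cached_effort <- function(grp, s, e) {
    key <- paste(grp, s, e, sep = "|")
    if (is.null(effort_cache[[key]]))
      effort_cache[[key]] <- observer_effort(focal_counts, members, grp, s, e)
    effort_cache[[key]]
  }
  all_f <- members$id[members$sex == "F"]
  grp_of <- stats::setNames(members$group, members$id)
  ## pooled dyad table over one window: dyads of every adult female in the
  ## population, female-female pairs counted once
  pooled_window <- function(s, e) {
    parts <- lapply(all_f, function(fid) {
      dy <- dyadic_rates(grooming, members, fid, s, e)
      if (nrow(dy)) dy$focal <- fid
      dy
    })
    dy <- do.call(rbind, parts[vapply(parts, nrow, 0L) > 0])
    if (is.null(dy) || nrow(dy) == 0L) return(dy)
    key <- ifelse(dy$partner_sex == "F",
                  paste(pmin(dy$focal, dy$partner), pmax(dy$focal, dy$partner)),
                  paste(dy$focal, dy$partner))
    reg <- dy[!duplicated(key), , drop = FALSE]
    reg$effort <- vapply(seq_len(nrow(reg)), function(k)
      cached_effort(grp_of[[reg$focal[k]]], reg$cores_start[k], reg$cores_end[k]),
      0)
    reg <- bond_residuals(reg)
    dy$residual <- reg$residual[match(key, key[!duplicated(key)])]
    dy
  }
  out <- list()
  for (i in seq_len(nrow(females))) {
    f <- females[i, ]
    birth <- as.Date(f$birthdate)
    yrs <- seq(floor(f$entry_age), ceiling(f$exit_age) - 1L)
    for (a in yrs) {
      s <- max(age_to_date(birth, a), age_to_date(birth, f$entry_age))
      e <- min(age_to_date(birth, a + 1) - 1, age_to_date(birth, f$exit_age))
      if (e < s) next
      dy <- pooled_window(s, e)
      mine <- if (!is.null(dy) && nrow(dy)) dy[dy$focal == f$id, ] else NULL
      out[[length(out) + 1L]] <- data.frame(
        id = f$id, year_of_life = a + 1L, age_class = a,
        dsi_f = if (!is.null(mine) && nrow(mine))
          dsi(mine$residual[mine$partner_sex == "F"]) else NA_real_,
        dsi_m = if (!is.null(mine) && nrow(mine))
          dsi(mine$residual[mine$partner_sex == "M"]) else NA_real_)
    }
  }
  impute_missing_dsi(do.call(rbind, out))
}
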