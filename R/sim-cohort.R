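#' Simulate a study cohort: females, weather, rosters, reproductive states
#'
#' Generates the observational frame that the downstream modules consume:
#' adult females with staggered entry into a fixed observation window and
#' right censoring at its end; a contiguous daily weather record (seasonal
#' rainfall with a November-May wet season, and daily maximum temperature);
#' group assignments with a latent dominance ability per female and a pool
#' of co-resident adult males; and a semi-Markov reproductive-state path
#' per female (cycling, then 178 days pregnant, then about a year
#' lactating, then cycling again).
#'
#' Females either are already adult when the window opens (entering at a
#' uniformly drawn adult age) or reach adulthood during the window and
#' enter at the minimum adult age. Death times are not drawn here; see
#' [simulate_survival()].
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"gc_cohort"`: list with `females`,
#'   `males`, `weather`, `repro` (state intervals), `members` (adult
#'   residency table for the behavioral modules) and the `config` echo.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 1L))
  W <- config$obs_window_years
  origin <- config$origin
  n <- config$n_females

  ## --- females: staggered entry, censoring at window end -----------------
  present_at_start <- stats::runif(n) < 0.35
  entry_time <- ifelse(present_at_start, 0,
                       stats::runif(n, 0, max(W - 0.5, 0.1)))
  entry_age <- ifelse(present_at_start,
                      stats::runif(n, config$entry_age_min,
                                   config$entry_age_min + 13),
                      config$entry_age_min)
  censor_age <- entry_age + (W - entry_time)
  id <- sprintf("F%03d", seq_len(n))
  birthdate <- origin + round((entry_time - entry_age) * 365.25)
  group <- sprintf("G%d", 1L + (seq_len(n) - 1L) %% config$n_groups)
  females <- data.frame(id = id, group = group, birthdate = birthdate,
                        entry_age = entry_age, censor_age = censor_age,
                        entry_date = age_to_date(birthdate, entry_age),
                        censor_date = age_to_date(birthdate, censor_age),
                        ability = stats::rnorm(n),
                        sociality = stats::rnorm(n),
                        row.names = NULL)

  ## --- daily weather ------------------------------------------------------
  dates <- seq(origin, origin + ceiling(W * 365.25), by = "day")
  wet <- season_of(dates) == "wet"
  p_rain <- ifelse(wet, 0.30, 0.06)
  mu_rain <- ifelse(wet, 5, 2)
  rain <- ifelse(stats::runif(length(dates)) < p_rain,
                 stats::rexp(length(dates), 1 / mu_rain), 0)
  doy <- as.integer(format(dates, "%j"))
  tmax <- 30 + 3 * cos(2 * pi * (doy - 45) / 365.25) +
    stats::rnorm(length(dates), 0, 1.5)
  weather <- data.frame(date = dates, rain_mm = rain, tmax_c = tmax)

  ## --- adult males with single residency intervals ------------------------
  males <- do.call(rbind, lapply(unique(group), function(g) {
    nf <- sum(group == g)
    nm <- max(3L, round(0.8 * nf))
    start <- origin + round(stats::runif(nm, -1, W - 0.5) * 365.25)
    dur <- pmax(1, stats::rexp(nm, 1 / 5))
    data.frame(id = sprintf("M_%s_%02d", g, seq_len(nm)), group = g,
               start_date = pmax(start, origin),
               end_date = pmin(start + round(dur * 365.25),
                               origin + round(W * 365.25)))
  }))

  ## --- reproductive-state paths (semi-Markov) -----------------------------
  repro <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- .simulate_repro_path(entry_age[i], censor_age[i] + 2)
    cbind(id = id[i], p)
  }))

  members <- rbind(
    data.frame(id = females$id, sex = "F", group = females$group,
               start_date = females$entry_date, end_date = females$censor_date),
    data.frame(id = males$id, sex = "M", group = males$group,
               start_date = males$start_date, end_date = males$end_date))

  structure(list(females = females, males = males, weather = weather,
                 repro = repro, members = members, config = config),
            class = "gc_cohort")
}

## Semi-Markov reproductive path over [entry, end_age] (ages in years).
## Durations: cycling ~ Gamma(shape 2, mean 120 d), pregnancy 178 d,
## lactation ~ Normal(365, 30) d. Entry state drawn from the
## stationary distribution implied by the mean durations.
.simulate_repro_path <- function(entry_age, end_age) {
  durs <- c(cycling = 120, pregnant = 178, lactating = 365) / 365.25
  states <- character(); starts <- numeric(); ends <- numeric()
  draw_dur <- function(st)
    switch(st,
           cycling = stats::rgamma(1, shape = 2, scale = 60) / 365.25,
           pregnant = 178 / 365.25,
           lactating = max(stats::rnorm(1, 365, 30), 200) / 365.25)
  st <- sample(names(durs), 1, prob = durs / sum(durs))
  ## start partway through the entry state
  t <- entry_age - stats::runif(1) * draw_dur(st)
  nxt <- c(cycling = "pregnant", pregnant = "lactating",
           lactating = "cycling")
  while (t < end_age) {
    d <- draw_dur(st)
    states <- c(states, st); starts <- c(starts, t); ends <- c(ends, t + d)
    t <- t + d
    st <- nxt[[st]]
  }
  out <- data.frame(state = states, start_age = starts, end_age = ends)
  out$start_age[1] <- min(out$start_age[1], entry_age)
  out
}
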