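#' Simulate grooming, observer effort and agonistic interactions
#'
#' Generates the behavioral event tables consumed by the sociality and
#' dominance-rank modules. Dyadic grooming counts follow a dyad-specific
#' latent affinity (partly driven by each animal's latent sociality), with
#' observed counts scaled by observer effort, so the effort-correction
#' regression in [bond_residuals()] has a real signal to remove. Focal
#' sample counts are Poisson per group-day with a constant observer team.
#' Decided agonistic outcomes follow the latent linear hierarchy (the
#' females' `ability` scores) with a small upset probability.
#'
#' @param cohort a `gc_cohort`.
#' @param config the [sim_config()] (defaults to the cohort's).
#' @param base_rate baseline grooming events per dyad per co-residence day
#'   at unit effort.
#' @param focal_per_day mean focal samples per group per day.
#' @param agonism_rate mean monthly decided interactions per female-female
#'   dyad.
#' @param upset_prob probability that the lower-ability female wins.
#' @return list with `grooming` (date, giver, receiver), `focal_counts`
#'   (group, date, n_focal) and `agonism` (date, winner, loser).
#' @export
simulate_behavior <- function(cohort, config = cohort$config,
                              base_rate = 0.005, focal_per_day = 6,
                              agonism_rate = 0.5, upset_prob = 0.05) {
  stopifnot(inherits(cohort, "gc_cohort"))
  set.seed(child_seed(config$seed, 4L))
  mem <- cohort$members
  fem <- cohort$females
  soc <- c(stats::setNames(fem$sociality, fem$id),
           stats::setNames(stats::rnorm(nrow(cohort$males)), cohort$males$id))

  ## --- focal effort -------------------------------------------------------
  days <- seq(min(as.Date(mem$start_date)), max(as.Date(mem$end_date)), "day")
  focal_counts <- do.call(rbind, lapply(unique(mem$group), function(g)
    data.frame(group = g, date = days,
               n_focal = stats::rpois(length(days), focal_per_day))))

  ## --- grooming -----------------------------------------------------------
  groom <- list()
  for (g in unique(mem$group)) {
    mg <- mem[mem$group == g, ]
    fg <- mg[mg$sex == "F", ]
    nf_bar <- max(mean(as.numeric(as.Date(fg$end_date) - as.Date(fg$start_date)) > 0) *
                    nrow(fg) / 2, 1)
    eff_day <- focal_per_day / nf_bar     # effort per co-residence day
    idx <- which(mg$sex == "F")
    for (a in idx) {
      partners <- seq_len(nrow(mg))
      partners <- partners[partners > a | mg$sex[partners] == "M"]
      for (b2 in partners) {
        if (b2 == a) next
        s <- max(as.Date(mg$start_date[a]), as.Date(mg$start_date[b2]))
        e <- min(as.Date(mg$end_date[a]), as.Date(mg$end_date[b2]))
        co <- as.numeric(e - s) + 1
        if (co <= 0) next
        aff <- exp(0.4 * (soc[[mg$id[a]]] + soc[[mg$id[b2]]]) +
                     stats::rnorm(1, 0, 0.7))
        n <- stats::rpois(1, base_rate * aff * eff_day * co)
        if (n == 0) next
        d <- s + sample.int(co, n, replace = TRUE) - 1L
        swap <- stats::runif(n) < 0.5
        groom[[length(groom) + 1L]] <- data.frame(
          date = d,
          giver = ifelse(swap, mg$id[a], mg$id[b2]),
          receiver = ifelse(swap, mg$id[b2], mg$id[a]))
      }
    }
  }
  grooming <- if (length(groom)) do.call(rbind, groom) else
    data.frame(date = as.Date(character()), giver = character(),
               receiver = character())

  ## --- agonism ------------------------------------------------------------
  months <- seq(as.Date(format(min(days), "%Y-%m-01")), max(days), "month")
  ag <- list()
  for (g in unique(fem$group)) {
    fg <- fem[fem$group == g, ]
    for (m in seq_along(months)) {
      mo <- months[m]
      present <- fg[fg$entry_date <= mo + 27 & fg$censor_date >= mo, ]
      if (nrow(present) < 2L) next
      pr <- utils::combn(nrow(present), 2)
      n_int <- stats::rpois(ncol(pr), agonism_rate)
      for (k in which(n_int > 0)) {
        i <- pr[1, k]; j <- pr[2, k]
        hi <- if (present$ability[i] >= present$ability[j]) i else j
        lo <- if (hi == i) j else i
        up <- stats::runif(n_int[k]) < upset_prob
        ag[[length(ag) + 1L]] <- data.frame(
          date = mo + 14,
          winner = ifelse(up, present$id[lo], present$id[hi]),
          loser = ifelse(up, present$id[hi], present$id[lo]))
      }
    }
  }
  agonism <- if (length(ag)) do.call(rbind, ag) else
    data.frame(date = as.Date(character()), winner = character(),
               loser = character())
  list(grooming = grooming, focal_counts = focal_counts, agonism = agonism)
}
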