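#' Proportional dominance ranks from decided agonistic interactions
#'
#' Orders the adult females of one group-month by an
#' inconsistency-minimizing linear hierarchy inferred from the matrix of
#' decided agonistic outcomes, then expresses each female's rank as the
#' proportion of other adult females she dominates (1 = alpha, 0 =
#' lowest). The ordering minimizes, lexicographically, (i) the number of
#' dominance relations directed up the hierarchy and (ii) the total
#' strength of those inconsistencies — the classic I&SI criterion.
#' Exhaustive search over all orderings is used for up to 8 females;
#' larger groups use a pairwise-swap descent from the win-proportion
#' ordering.
#'
#' @param agonism data frame of decided interactions with columns `winner`
#'   and `loser` (ids). Undecided interactions must be removed upstream.
#' @param females character vector of adult female ids present (the
#'   roster); females without interactions are still ranked (placed by the
#'   descent, at the bottom in the absence of information).
#' @return data frame with columns `id`, `order` (1 = top), `rank`
#'   (proportion dominated) and `is_alpha`.
#' @export
proportional_ranks <- function(agonism, females) {
  females <- unique(as.character(females))
  n <- length(females)
  if (n == 0L) stop("no females on the roster")
  if (n == 1L) {
    warning("single female in group: rank defined as 1")
    return(data.frame(id = females, order = 1L, rank = 1, is_alpha = TRUE))
  }
  W <- matrix(0L, n, n, dimnames = list(females, females))
  if (nrow(agonism) > 0) {
    keep <- agonism$winner %in% females & agonism$loser %in% females
    a <- agonism[keep, , drop = FALSE]
    if (nrow(a) > 0) {
      tab <- table(factor(a$winner, levels = females),
                   factor(a$loser, levels = females))
      W <- W + unclass(tab)
    }
  }
  ord <- if (n <= 8L) .order_exhaustive(W) else .order_descent(W)
  pos <- match(seq_len(n), ord)      # pos[i] = position of female i
  data.frame(id = females,
             order = pos,
             rank = (n - pos) / (n - 1),
             is_alpha = pos == 1L,
             row.names = NULL)
}

## Inconsistency score of an ordering: (count, strength) of pairs where the
## lower-positioned female beats the higher-positioned one more often.
.isi_score <- function(W, ord) {
  n <- length(ord)
  Wo <- W[ord, ord, drop = FALSE]
  up <- t(Wo)[upper.tri(Wo)]   # wins directed up the hierarchy, by pair
  dn <- Wo[upper.tri(Wo)]
  inc <- up > dn
  c(sum(inc), sum((up - dn)[inc]))
}

.order_exhaustive <- function(W) {
  n <- nrow(W)
  perms <- .permutations(n)
  best <- NULL; best_score <- c(Inf, Inf)
  for (k in seq_len(nrow(perms))) {
    sc <- .isi_score(W, perms[k, ])
    if (sc[1] < best_score[1] ||
        (sc[1] == best_score[1] && sc[2] < best_score[2])) {
      best <- perms[k, ]; best_score <- sc
    }
  }
  best
}

.order_descent <- function(W) {
  n <- nrow(W)
  wins <- rowSums(W); losses <- colSums(W)
  prop <- (wins + 0.5) / (wins + losses + 1)
  ord <- order(prop, decreasing = TRUE)
  best_score <- .isi_score(W, ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      cand <- ord; cand[c(i, j)] <- cand[c(j, i)]
      sc <- .isi_score(W, cand)
      if (sc[1] < best_score[1] ||
          (sc[1] == best_score[1] && sc[2] < best_score[2])) {
        ord <- cand; best_score <- sc; improved <- TRUE
      }
    }
  }
  ord
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, ] <- cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Monthly rank series with carry-forward for empty months
#'
#' Convenience wrapper applying [proportional_ranks()] month by month
#' within a group; months with no decided interactions inherit the previous
#' month's ranks (or are missing if there is no previous month).
#'
#' @param agonism data frame with `winner`, `loser`, `date`.
#' @param rosters data frame with `month` (first-of-month `Date`), `id`.
#' @return data frame with `month`, `id`, `rank`, `is_alpha`.
#' @export
monthly_ranks <- function(agonism, rosters) {
  months <- sort(unique(rosters$month))
  prev <- NULL
  out <- vector("list", length(months))
  ag_month <- as.Date(format(as.Date(agonism$date), "%Y-%m-01"))
  for (k in seq_along(months)) {
    ids <- rosters$id[rosters$month == months[k]]
    a <- agonism[ag_month == months[k], , drop = FALSE]
    if (nrow(a) == 0L) {
      rk <- if (!is.null(prev)) prev[prev$id %in% ids, c("id", "rank", "is_alpha")]
            else data.frame(id = character(), rank = numeric(), is_alpha = logical())
    } else {
      rk <- proportional_ranks(a, ids)[, c("id", "rank", "is_alpha")]
      prev <- rk
    }
    if (nrow(rk)) out[[k]] <- cbind(month = months[k], rk)
  }
  do.call(rbind, out)
}
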