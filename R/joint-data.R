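#' Assemble the data bundle for the joint model
#'
#' Precomputes everything the joint likelihood needs: the longitudinal
#' design; the survival records with left truncation at entry age; the
#' cubic B-spline basis of the log baseline hazard (two internal knots at
#' the 33rd/67th percentiles of observed event ages by default); the
#' yearly survival covariates, z-scored across female-years; and
#' fixed-order Gauss-Legendre quadrature nodes laid out per year-of-life
#' segment (the integrand is smooth within a year and may jump at
#' birthdays, where the yearly covariates step).
#'
#' At every quadrature node and at each exit time the association feature
#' is linear in `(beta, b_i)`; the assembled matrices represent the
#' feature as `G %*% beta + rowSums(D * b)` for each of the three
#' association structures (current value, current slope, cumulative
#' area-under-the-curve from entry age).
#'
#' @param design an `fgc_design` (with response) for the longitudinal part.
#' @param surv data frame with `id`, `entry_age`, `exit_age`, `event`.
#' @param wpath data frame with `id`, `age_class`, `dsi_f`, `dsi_m`,
#'   `rain_anom` (raw scale; z-scored here).
#' @param xpath yearly trajectory design paths ([trajectory_paths()]).
#' @param knots optional internal knot ages for the baseline spline.
#' @param quad_nodes Gauss-Legendre nodes per year segment.
#' @return An object of class `"gcjm_data"`.
#' @export
gcjm_data <- function(design, surv, wpath, xpath, knots = NULL,
                      quad_nodes = 15L, auc_from = NULL) {
  stopifnot(inherits(design, "fgc_design"), !is.null(design$y))
  ids <- levels(design$id)
  if (!setequal(ids, surv$id))
    stop("longitudinal and survival records cover different females")
  surv <- surv[match(ids, surv$id), ]
  if (any(surv$exit_age <= surv$entry_age))
    stop("exit_age must exceed entry_age for every female")
  nf <- length(ids)
  p <- ncol(design$X)
  ## cumulative (AUC) association integrates from the common adult-onset
  ## age: for females entering observation later, the first observed
  ## year's covariates are carried back over the unobserved adult span
  auc_from <- auc_from %||% min(surv$entry_age)

  ## --- baseline-hazard spline basis --------------------------------------
  ev_ages <- surv$exit_age[surv$event == 1]
  if (is.null(knots)) {
    qs <- if (length(ev_ages) >= 2) stats::quantile(ev_ages, c(1, 2) / 3)
          else stats::quantile(surv$exit_age, c(1, 2) / 3)
    knots <- as.numeric(qs)
  }
  bknots <- c(min(surv$entry_age), max(surv$exit_age) + 1e-8)
  basis <- function(t) splines::bs(pmin(pmax(t, bknots[1]), bknots[2]),
                                   knots = knots, degree = 3L,
                                   Boundary.knots = bknots, intercept = TRUE)

  ## --- yearly survival covariates, z-scored ------------------------------
  wcols <- c("dsi_f", "dsi_m", "rain_anom")
  wconst <- list(mean = colMeans(wpath[, wcols]),
                 sd = apply(wpath[, wcols], 2, stats::sd))
  wz <- sweep(sweep(as.matrix(wpath[, wcols]), 2, wconst$mean),
              2, wconst$sd, "/")
  wkey <- paste(wpath$id, wpath$age_class)

  age_col <- match("age", design_columns())
  ## design-path row for female i at year a, with integral helpers
  lookup_w <- function(id, yr) {
    k <- match(paste(id, yr), wkey)
    if (anyNA(k)) {
      ## clamp to the female's nearest covered year
      for (j in which(is.na(k))) {
        cand <- which(wpath$id == id)
        if (!length(cand)) stop("no survival covariates for female ", id)
        k[j] <- cand[which.min(abs(wpath$age_class[cand] - yr[j]))]
      }
    }
    wz[k, , drop = FALSE]
  }

  per_f <- vector("list", nf)
  for (i in seq_len(nf)) {
    idf <- ids[i]
    pth <- xpath[[idf]]
    if (is.null(pth)) stop("no trajectory path for female ", idf)
    segs <- year_segments(surv$entry_age[i], surv$exit_age[i])
    nseg <- nrow(segs)
    tq <- numeric(0); wq <- numeric(0)
    for (k in seq_len(nseg)) {
      g <- gl_segment(segs[k, 1], segs[k, 2], quad_nodes)
      tq <- c(tq, g$x); wq <- c(wq, g$w)
    }
    yr_row <- function(t) pmin(pmax(floor(t) - pth$a0 + 1, 1L),
                               nrow(pth$rows))
    A <- pth$rows[yr_row(tq), , drop = FALSE]; A[, age_col] <- tq
    ## cumulative integral of the path design from auc_from to each node
    entry <- surv$entry_age[i]
    seg_lo <- segs[, 1]
    base_rows <- pth$rows[yr_row((segs[, 1] + segs[, 2]) / 2), , drop = FALSE]
    seg_len <- segs[, 2] - segs[, 1]
    seg_int <- base_rows * seg_len
    seg_int[, age_col] <- (segs[, 2]^2 - segs[, 1]^2) / 2
    pre <- pth$rows[1L, ] * (entry - auc_from)
    pre[age_col] <- (entry^2 - auc_from^2) / 2
    cum0 <- rbind(0, apply(seg_int, 2, cumsum))[seq_len(nseg), , drop = FALSE]
    cum0 <- sweep(cum0, 2L, pre, "+")
    segidx <- rep(seq_len(nseg), each = quad_nodes)
    AI <- cum0[segidx, , drop = FALSE] +
      base_rows[segidx, , drop = FALSE] * (tq - seg_lo[segidx])
    AI[, age_col] <- cum0[segidx, age_col] +
      (tq^2 - seg_lo[segidx]^2) / 2
    Tt <- surv$exit_age[i]
    A_T <- pth$rows[yr_row(Tt), , drop = FALSE]; A_T[, age_col] <- Tt
    AI_T <- cum0[nseg, ] + base_rows[nseg, ] * (Tt - seg_lo[nseg])
    AI_T[age_col] <- cum0[nseg, age_col] + (Tt^2 - seg_lo[nseg]^2) / 2
    per_f[[i]] <- list(
      tq = tq, wq = wq, A = A, AI = AI, A_T = A_T, AI_T = AI_T,
      Wq = lookup_w(idf, floor(tq)),
      W_T = lookup_w(idf, min(floor(Tt), floor(surv$exit_age[i] - 1e-9))))
  }
  fq <- rep(seq_len(nf), vapply(per_f, function(z) length(z$tq), 0L))
  tq <- unlist(lapply(per_f, `[[`, "tq"))
  structure(list(
    y = design$y, X = design$X, idx = as.integer(design$id),
    age = design$age, zconst = design$zconst,
    ids = ids, surv = surv, nf = nf, p = p,
    knots = knots, bknots = bknots, basis = basis,
    wconst = wconst, wpath = wpath,
    fq = fq, tq = tq, wq = unlist(lapply(per_f, `[[`, "wq")),
    Bq = unclass(basis(tq)),
    B_T = unclass(basis(surv$exit_age)),
    Wq = do.call(rbind, lapply(per_f, `[[`, "Wq")),
    W_T = do.call(rbind, lapply(per_f, `[[`, "W_T")),
    Aq = do.call(rbind, lapply(per_f, `[[`, "A")),
    AIq = do.call(rbind, lapply(per_f, `[[`, "AI")),
    A_T = do.call(rbind, lapply(per_f, `[[`, "A_T")),
    AI_T = do.call(rbind, lapply(per_f, `[[`, "AI_T")),
    delta = surv$event,
    age_col = age_col,
    auc_from = auc_from,
    xpath = xpath),
    class = "gcjm_data")
}

## Association feature matrices for a mode: list(G, D, G_T, D_T) such that
## feature = G beta + rowSums(D * b[fq, ]) at nodes, same at exit times.
.assoc_mats <- function(data, mode) {
  p <- data$p; nq <- length(data$tq); nf <- data$nf
  a0 <- data$auc_from
  switch(mode,
    none = list(G = matrix(0, nq, p), D = matrix(0, nq, 2),
                G_T = matrix(0, nf, p), D_T = matrix(0, nf, 2)),
    value = list(G = data$Aq, D = cbind(1, data$tq),
                 G_T = data$A_T, D_T = cbind(1, data$surv$exit_age)),
    slope = {
      e <- matrix(0, nq, p); e[, data$age_col] <- 1
      eT <- matrix(0, nf, p); eT[, data$age_col] <- 1
      list(G = e, D = cbind(0, rep(1, nq)),
           G_T = eT, D_T = cbind(0, rep(1, nf)))
    },
    auc = list(G = data$AIq,
               D = cbind(data$tq - a0, (data$tq^2 - a0^2) / 2),
               G_T = data$AI_T,
               D_T = cbind(data$surv$exit_age - a0,
                           (data$surv$exit_age^2 - a0^2) / 2)),
    stop("unknown association mode: ", mode))
}

#' Assemble joint-model data directly from simulation objects
#'
#' @param fgc an `fgc_sim`; @param surv_sim a `surv_sim`.
#' @param ... passed to [gcjm_data()].
#' @return a `gcjm_data` bundle restricted to the simulated exit times.
#' @export
gcjm_data_from_sim <- function(fgc, surv_sim, ...) {
  recs <- surv_sim$records
  des <- fgc$design
  ## drop samples collected after the (possibly earlier) simulated exit
  exit <- recs$exit_age[match(as.character(des$id), recs$id)]
  keep <- des$age <= exit
  des2 <- des
  des2$X <- des$X[keep, , drop = FALSE]
  des2$y <- des$y[keep]
  des2$id <- factor(as.character(des$id)[keep], levels = levels(des$id))
  des2$age <- des$age[keep]
  ## a female whose death precedes her first sample keeps her first sample
  lost <- setdiff(levels(des$id), unique(as.character(des2$id)))
  if (length(lost)) {
    add <- match(lost, as.character(des$id))
    des2$X <- rbind(des2$X, des$X[add, , drop = FALSE])
    des2$y <- c(des2$y, des$y[add])
    des2$id <- factor(c(as.character(des2$id), lost), levels = levels(des$id))
    des2$age <- c(des2$age, des$age[add])
    recs$exit_age[match(lost, recs$id)] <-
      pmax(recs$exit_age[match(lost, recs$id)], des$age[add] + 1e-6)
  }
  wp <- surv_sim$wpath
  gcjm_data(des2, recs,
            data.frame(id = wp$id, age_class = wp$age_class,
                       dsi_f = wp$dsi_f, dsi_m = wp$dsi_m,
                       rain_anom = wp$rain_anom),
            fgc$xpath, ...)
}
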