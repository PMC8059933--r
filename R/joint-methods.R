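#' Combined posterior draws
#' @param x a `gcjm` fit.
#' @param ... unused.
#' @return matrix of posterior draws (all chains stacked).
#' @export
as.matrix.gcjm <- function(x, ...) {
  do.call(rbind, lapply(x$chains, `[[`, "draws"))
}

#' @export
coef.gcjm <- function(object, ...) {
  colMeans(as.matrix(object))
}

#' @export
print.gcjm <- function(x, ...) {
  cat("Joint model of log fGC and adult survival\n")
  cat(sprintf("  association: %s\n", x$assoc))
  cat(sprintf("  %d females (%d deaths), %d fGC samples\n",
              x$data$nf, sum(x$data$delta), length(x$data$y)))
  cat(sprintf("  %d chain(s) x %d iterations (%d warmup); %.1f s\n",
              x$control$chains, x$control$iter, x$control$warmup, x$time))
  if (isTRUE(x$failed)) cat("  WARNING: convergence flags raised\n")
  dr <- as.matrix(x)
  show <- grep("^(gamma|alpha)", colnames(dr), value = TRUE)
  if (x$assoc == "none") show <- setdiff(show, "alpha")
  est <- colMeans(dr[, show, drop = FALSE])
  ci <- apply(dr[, show, drop = FALSE], 2, stats::quantile,
              probs = c(0.05, 0.95))
  for (nmk in show)
    cat(sprintf("  %-18s %8.3f  [%.3f, %.3f]\n", nmk, est[nmk],
                ci[1, nmk], ci[2, nmk]))
  invisible(x)
}

#' Posterior summary table with nested credible intervals
#'
#' One row per scalar parameter: posterior mean, SD, central 50/75/90
#' percent credible intervals, and convergence diagnostics.
#'
#' @param object a `gcjm` fit.
#' @param ... unused.
#' @return data frame of class `"summary.gcjm"`.
#' @export
summary.gcjm <- function(object, ...) {
  dr <- as.matrix(object)
  dg <- diagnostics(object)
  qs <- t(apply(dr, 2, stats::quantile,
                probs = c(0.25, 0.75, 0.125, 0.875, 0.05, 0.95)))
  out <- data.frame(parameter = colnames(dr),
                    mean = colMeans(dr), sd = apply(dr, 2, stats::sd),
                    lo50 = qs[, 1], hi50 = qs[, 2],
                    lo75 = qs[, 3], hi75 = qs[, 4],
                    lo90 = qs[, 5], hi90 = qs[, 6],
                    rhat = dg$rhat[colnames(dr)],
                    ess = dg$ess[colnames(dr)],
                    row.names = NULL)
  class(out) <- c("summary.gcjm", "data.frame")
  out
}

#' @export
print.summary.gcjm <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.gcjm <- function(object, ...) {
  dr <- as.matrix(object)
  beta <- colMeans(dr)[seq_len(object$data$p)]
  bmean <- apply(do.call(abind_1, lapply(object$chains, `[[`, "b_draws")),
                 c(2, 3), mean)
  d <- object$data
  d$y - drop(d$X %*% beta) - bmean[d$idx, 1] - bmean[d$idx, 2] * d$age
}

## minimal 3-d array bind along dim 1
abind_1 <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.array(xs[[1]]))
    xs <- xs[[1]]
  n1 <- vapply(xs, function(a) dim(a)[1], 0L)
  out <- array(NA_real_, c(sum(n1), dim(xs[[1]])[2], dim(xs[[1]])[3]))
  at <- 0L
  for (a in xs) { out[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
  out
}

#' Posterior mean random effects
#' @param object a `gcjm` fit; @param ... unused.
#' @return females x 2 matrix of posterior-mean intercepts and slopes.
#' @export
ranef_gcjm <- function(object, ...) {
  bm <- apply(abind_1(lapply(object$chains, `[[`, "b_draws")), c(2, 3), mean)
  dimnames(bm) <- list(object$data$ids, c("intercept", "slope"))
  bm
}

#' Trace or interval plots for a joint-model fit
#'
#' @param x a `gcjm` fit.
#' @param type `"intervals"` (posterior means with nested 50/75/90
#'   credible bars, survival submodel parameters) or `"trace"`.
#' @param pars parameters to show (default: survival coefficients and
#'   association).
#' @param ... unused.
#' @export
plot.gcjm <- function(x, type = c("intervals", "trace"), pars = NULL, ...) {
  type <- match.arg(type)
  dr <- as.matrix(x)
  if (is.null(pars)) {
    pars <- grep("^(gamma|alpha)", colnames(dr), value = TRUE)
    if (x$assoc == "none") pars <- setdiff(pars, "alpha")
  }
  if (type == "trace") {
    old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    n_keep <- x$control$iter - x$control$warmup
    for (pp in pars) {
      graphics::matplot(matrix(dr[, pp], n_keep), type = "l", lty = 1,
                        ylab = pp, xlab = "")
    }
  } else {
    s <- summary(x)
    s <- s[s$parameter %in% pars, ]
    yy <- rev(seq_len(nrow(s)))
    graphics::plot(s$mean, yy, xlim = range(s$lo90, s$hi90), pch = 16,
                   yaxt = "n", ylab = "", xlab = "posterior estimate")
    graphics::axis(2, at = yy, labels = s$parameter, las = 1)
    graphics::segments(s$lo90, yy, s$hi90, yy, lwd = 1)
    graphics::segments(s$lo75, yy, s$hi75, yy, lwd = 2.5)
    graphics::segments(s$lo50, yy, s$hi50, yy, lwd = 4)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}
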