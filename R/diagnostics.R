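#' Convergence diagnostics: split-Rhat, effective sample size, MCSE
#'
#' Split-chain potential scale reduction (each chain halved), effective
#' sample size from chain-averaged autocorrelations with Geyer's
#' initial-positive-sequence truncation, and the Monte Carlo standard
#' error `sd / sqrt(ESS)`, for every scalar parameter. With a single
#' chain Rhat is still computed from the two half-chains but a warning is
#' issued.
#'
#' @param fit a `gcjm` fit (or list of chains with `draws` matrices).
#' @return data frame with `parameter`, `rhat`, `ess`, `mcse` and a
#'   `pass` flag (`rhat < 1.01`).
#' @export
diagnostics <- function(fit) {
  chains <- lapply(fit$chains, `[[`, "draws")
  if (length(chains) < 2L)
    warning("single chain: Rhat computed from split halves only")
  pars <- colnames(chains[[1]])
  n <- nrow(chains[[1]])
  half <- floor(n / 2)
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1L]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1L]] <- ch[(n - half + 1):n, , drop = FALSE]
  }
  m <- length(splits); nn <- half
  rhat <- ess <- mcse <- stats::setNames(rep(NA_real_, length(pars)), pars)
  for (pp in pars) {
    x <- vapply(splits, function(s) s[, pp], numeric(nn))  # nn x m
    mu <- colMeans(x); vv <- apply(x, 2, stats::var)
    W <- mean(vv); B <- nn * stats::var(mu)
    varp <- (nn - 1) / nn * W + B / nn
    rhat[pp] <- if (W > 1e-300) sqrt(varp / W) else 1
    ## chain-averaged autocorrelation, Geyer initial positive sequence
    max_lag <- min(nn - 2L, 200L)
    if (W > 1e-300 && max_lag > 2) {
      ac <- rowMeans(vapply(seq_len(m), function(j)
        stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1] * vv[j], numeric(max_lag + 1L)))
      rho <- 1 - (W - ac[-1]) / varp
      ## sum over pairs while their sum stays positive
      tau <- 1
      k <- 1
      while (k + 1 <= length(rho)) {
        pair <- rho[k] + rho[k + 1]
        if (!is.finite(pair) || pair < 0) break
        tau <- tau + 2 * pair
        k <- k + 2
      }
      ess[pp] <- max(m * nn / tau, 1)
    } else ess[pp] <- m * nn
    mcse[pp] <- stats::sd(c(x)) / sqrt(ess[pp])
  }
  data.frame(parameter = pars, rhat = rhat, ess = ess, mcse = mcse,
             pass = rhat < 1.01, row.names = NULL)
}
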