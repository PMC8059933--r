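# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seeds so every sub-generator can be reseeded
## independently from one global integer seed. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 48271 + 1103 * stream) %% 2147483629) + 1L
}

## One draw per row from N(mu, Sigma); eigen-based so singular (even zero)
## covariance matrices are handled.
rmvn <- function(n, mu, Sigma) {
  k <- length(mu)
  e <- eigen(Sigma, symmetric = TRUE)
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(stats::rnorm(n * k), n, k) %*% L
  sweep(z, 2L, mu, "+")
}

## Gauss-Legendre nodes/weights on [-1, 1], cached.
gl_rule <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      g <- pracma::gaussLegendre(n, -1, 1)
      cache[[key]] <<- list(x = g$x, w = g$w)
    }
    cache[[key]]
  }
})

## Map a GL rule onto the segment [a, b].
gl_segment <- function(a, b, n = 15L) {
  r <- gl_rule(n)
  list(x = (a + b) / 2 + (b - a) / 2 * r$x, w = (b - a) / 2 * r$w)
}

## Year-of-life segment boundaries for ages in [entry, exit]: cut at
## birthdays (integer ages), dropping zero-length pieces.
year_segments <- function(entry, exit) {
  stopifnot(exit > entry)
  cuts <- seq(ceiling(entry), floor(exit))
  brk <- unique(c(entry, cuts[cuts > entry & cuts < exit], exit))
  cbind(lo = brk[-length(brk)], hi = brk[-1])
}

## ISO date helpers: decimal age <-> date given a birthdate.
age_to_date <- function(birth, age) birth + round(age * 365.25)
date_to_age <- function(birth, date) as.numeric(date - birth) / 365.25
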