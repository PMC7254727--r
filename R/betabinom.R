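## Vectorised beta-binomial density and upper tail. No installed package
## provides these vectorised over (x, size, alpha, beta), and the error model
## is exercised over millions of cells, so they are implemented here.

#' Beta-binomial probability mass
#'
#' Density of the beta-binomial distribution: `X ~ Bin(size, p)` with
#' `p ~ Beta(alpha, beta)`.
#'
#' @param x number of alternative reads (vectorised)
#' @param size read coverage
#' @param alpha,beta beta shape parameters (> 0)
#' @param log return log density?
#' @return numeric vector of probabilities
#' @export
dbetabinom <- function(x, size, alpha, beta, log = FALSE) {
  n <- max(length(x), length(size), length(alpha), length(beta))
  x <- rep_len(x, n); size <- rep_len(size, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  ld <- lchoose(size, x) + lbeta(x + alpha, size - x + beta) -
    lbeta(alpha, beta)
  ld[x < 0 | x > size | x != floor(x)] <- -Inf
  if (log) ld else exp(ld)
}

#' Beta-binomial upper-tail probability P(X >= x)
#'
#' Upper tail of the beta-binomial, used as the per-site error-model p-value:
#' the probability of observing at least the given number of alternative
#' reads under the fitted error distribution. Fully vectorised; the tail is
#' accumulated by direct summation of the mass function.
#'
#' @inheritParams dbetabinom
#' @return numeric vector of tail probabilities in `[0, 1]`
#' @export
pbetabinomUpper <- function(x, size, alpha, beta) {
  n <- max(length(x), length(size), length(alpha), length(beta))
  x <- rep_len(x, n); size <- rep_len(size, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  out <- numeric(n)
  out[x <= 0] <- 1
  out[x > size] <- 0
  todo <- which(x > 0 & x <= size)
  if (!length(todo)) return(out)
  ## sum whichever tail is shorter, one vectorised density evaluation per
  ## offset over the still-active cells
  sumTail <- function(start, stop, sz, a, b) {
    acc <- numeric(length(start))
    active <- seq_along(start)
    off <- 0L
    repeat {
      kk <- start[active] + off
      active <- active[kk <= stop[active]]
      if (!length(active)) break
      acc[active] <- acc[active] +
        dbetabinom(start[active] + off, sz[active], a[active], b[active])
      off <- off + 1L
    }
    acc
  }
  xs <- x[todo]; sz <- size[todo]; a <- alpha[todo]; b <- beta[todo]
  lower <- xs - 1 < sz - xs         # fewer terms in P(X <= x-1)
  if (any(lower)) {
    i <- which(lower)
    out[todo[i]] <- pmax(0, 1 - sumTail(rep(0L, length(i)), xs[i] - 1,
                                        sz[i], a[i], b[i]))
  }
  if (any(!lower)) {
    i <- which(!lower)
    out[todo[i]] <- pmin(1, sumTail(xs[i], sz[i], sz[i], a[i], b[i]))
  }
  out
}

#' Random beta-binomial deviates
#'
#' @param n number of deviates
#' @inheritParams dbetabinom
#' @return integer vector of counts
#' @export
rbetabinom <- function(n, size, alpha, beta) {
  p <- stats::rbeta(n, alpha, beta)
  stats::rbinom(n, size = rep_len(size, n), prob = p)
}
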