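#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) \eqn{\hat R} comparing between- and within-chain
#' variance for one scalar parameter:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n\,W + B/n}{W}}}
#' with `W` the mean within-chain variance and `B/n` the variance of the
#' chain means. Values near 1 indicate the chains have mixed.
#'
#' @param chains A list of numeric vectors (one per chain, equal length) or
#'   a matrix with one column per chain; >= 2 chains of >= 2 draws.
#' @return The scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L) {
    stop("need >= 2 chains", call. = FALSE)
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L || n < 2L) {
    stop("chains must have equal length >= 2", call. = FALSE)
  }
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) stop("zero within-chain variance", call. = FALSE)
  B_over_n <- var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of a single chain with the mean of
#' a late window: \eqn{z = (\bar x_{first} - \bar x_{last}) /
#' \sqrt{se^2_{first} + se^2_{last}}}. For a stationary chain z is
#' approximately standard normal; `|z| < 2` is reported as a pass. A chain
#' with zero variance in both windows is degenerate and reported as a pass
#' with `z = NA`.
#'
#' @param x Numeric draws from one chain.
#' @param first,last Fractions of the chain used for the early and late
#'   windows (defaults 0.1 and 0.5).
#' @return List with elements `z` and `pass`.
#' @export
geweke <- function(x, first = 0.1, last = 0.5) {
  n <- length(x)
  n1 <- floor(n * first)
  n2 <- floor(n * last)
  if (n1 < 1L || n2 < 1L || n1 + n2 > n) {
    stop("window fractions leave an empty or overlapping window",
         call. = FALSE)
  }
  x1 <- x[seq_len(n1)]
  x2 <- x[seq.int(n - n2 + 1L, n)]
  se2 <- var(x1) / n1 + var(x2) / n2
  if (se2 == 0) {
    if (mean(x1) == mean(x2)) return(list(z = NA_real_, pass = TRUE))
    return(list(z = Inf * sign(mean(x1) - mean(x2)), pass = FALSE))
  }
  z <- (mean(x1) - mean(x2)) / sqrt(se2)
  list(z = z, pass = abs(z) < 2)
}
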