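#' Discrete attention-time distributions
#'
#' The number of chain steps spent attending to one attribute before the
#' next switch is a discrete random variable with support on the positive
#' integers \{1, 2, ...\} (a zero-length attention episode is meaningless).
#' Five families are available:
#'
#' \describe{
#'   \item{deterministic}{point mass at \code{n0} steps; variance 0.}
#'   \item{geometric}{\eqn{P(T = n) = (1-r)^{n-1} r}; mean \eqn{1/r},
#'     variance \eqn{(1-r)/r^2}.  The memoryless case: attention may switch
#'     at any moment with constant hazard \code{r}.}
#'   \item{uniform}{equally likely on \eqn{\{N-M, \ldots, N+M\}} with
#'     \eqn{P = 1/(2M+1)}; mean \eqn{N}, variance \eqn{M(M+1)/3}.  Varying
#'     \code{M} interpolates between the deterministic (\code{M = 0}) and
#'     high-variance regimes.}
#'   \item{poisson}{a Poisson(\eqn{\lambda}) count shifted up by one step so
#'     the support starts at 1; mean \eqn{\lambda + 1}, variance
#'     \eqn{\lambda}.}
#'   \item{binomial}{a Binomial(\code{size}, \code{prob}) count shifted up
#'     by one step; mean \code{size * prob + 1}, variance
#'     \code{size * prob * (1 - prob)}.}
#' }
#'
#' Instead of natural parameters, every kind accepts \code{mean = } a target
#' expected number of steps, convenient for sweeps that match expectations
#' across kinds: deterministic uses \code{n0 = round(mean)}, geometric
#' \code{r = 1/mean}, uniform \code{N = round(mean)} with \code{M}
#' controlled by \code{spread} (\code{"half"}: \code{M = N/2};
#' \code{"full"}: \code{M = N - 1}), poisson \code{lambda = mean - 1}, and
#' binomial \code{prob = 1/2}, \code{size = round(2 * (mean - 1))}.
#'
#' @param kind One of \code{"deterministic"}, \code{"geometric"},
#'   \code{"uniform"}, \code{"poisson"}, \code{"binomial"}.
#' @param ... Kind-specific parameters: \code{n0} (deterministic); \code{r}
#'   (geometric); \code{N}, \code{M} (uniform); \code{lambda} (poisson);
#'   \code{size}, \code{prob} (binomial).
#' @param mean Target mean number of steps (alternative parameterization).
#' @param spread For \code{kind = "uniform"} with \code{mean}: \code{"half"}
#'   (\eqn{M = \lfloor N/2 \rfloor}) or \code{"full"} (\eqn{M = N - 1}).
#'
#' @return An object of class \code{"attention_dist"}.
#' @examples
#' attention_time("geometric", r = 1 / 300)
#' attention_time("uniform", mean = 300, spread = "full")
#' @export
attention_time <- function(kind = c("deterministic", "geometric", "uniform",
                                    "poisson", "binomial"),
                           ..., mean = NULL, spread = c("half", "full")) {
  kind <- match.arg(kind)
  pars <- list(...)
  bad_par <- function(msg) stop(sprintf("attention_time(\"%s\"): %s",
                                        kind, msg), call. = FALSE)
  if (!is.null(mean)) {
    if (!is.numeric(mean) || length(mean) != 1L || mean < 1)
      bad_par("`mean` must be a number >= 1")
    pars <- switch(kind,
      deterministic = list(n0 = max(1L, as.integer(round(mean)))),
      geometric     = list(r = 1 / mean),
      uniform       = {
        N <- max(1L, as.integer(round(mean)))
        M <- switch(match.arg(spread),
                    half = N %/% 2L,
                    full = N - 1L)
        list(N = N, M = M)
      },
      poisson       = list(lambda = mean - 1),
      binomial      = list(size = max(1L, as.integer(round(2 * (mean - 1)))),
                           prob = 0.5))
    if (kind == "poisson" && pars$lambda <= 0)
      bad_par("`mean` must exceed 1 for a shifted poisson")
  }
  switch(kind,
    deterministic = {
      n0 <- pars$n0
      if (is.null(n0) || n0 < 1 || n0 != round(n0))
        bad_par("`n0` must be a positive integer")
      pars <- list(n0 = as.integer(n0))
    },
    geometric = {
      r <- pars$r
      if (is.null(r) || !is.numeric(r) || r <= 0 || r > 1)
        bad_par("`r` must lie in (0, 1]")
      pars <- list(r = r)
    },
    uniform = {
      N <- pars$N; M <- pars$M
      if (is.null(N) || N < 1 || N != round(N))
        bad_par("`N` must be a positive integer")
      if (is.null(M) || M < 0 || M > N - 1 || M != round(M))
        bad_par("`M` must be an integer in 0..N-1")
      pars <- list(N = as.integer(N), M = as.integer(M))
    },
    poisson = {
      lambda <- pars$lambda
      if (is.null(lambda) || !is.numeric(lambda) || lambda <= 0)
        bad_par("`lambda` must be positive")
      pars <- list(lambda = lambda)
    },
    binomial = {
      size <- pars$size; prob <- pars$prob
      if (is.null(size) || size < 1 || size != round(size))
        bad_par("`size` must be a positive integer")
      if (is.null(prob) || prob <= 0 || prob >= 1)
        bad_par("`prob` must lie in (0, 1)")
      pars <- list(size = as.integer(size), prob = prob)
    })
  structure(c(list(kind = kind), pars), class = "attention_dist")
}

#' @export
print.attention_dist <- function(x, ...) {
  p <- x[setdiff(names(x), "kind")]
  mom <- at_moments(x)
  cat(sprintf("<attention_dist> %s(%s): mean %g steps, variance %g\n",
              x$kind,
              paste(sprintf("%s = %g", names(p), unlist(p)), collapse = ", "),
              mom$mean, mom$variance))
  invisible(x)
}

#' Probability mass function of an attention-time distribution
#'
#' @param dist An \code{\link{attention_time}} object.
#' @param n Vector of step counts (positive integers; values outside the
#'   support return 0).
#' @return \eqn{P(T_{at} = n)}, vectorized over \code{n}.
#' @export
at_pmf <- function(dist, n) {
  stopifnot(inherits(dist, "attention_dist"))
  n <- as.numeric(n)
  out <- numeric(length(n))
  ok <- n >= 1 & n == round(n)
  if (any(ok)) {
    nn <- n[ok]
    out[ok] <- switch(dist$kind,
      deterministic = as.numeric(nn == dist$n0),
      geometric     = stats::dgeom(nn - 1, prob = dist$r),
      uniform       = ifelse(nn >= dist$N - dist$M & nn <= dist$N + dist$M,
                             1 / (2 * dist$M + 1), 0),
      poisson       = stats::dpois(nn - 1, lambda = dist$lambda),
      binomial      = stats::dbinom(nn - 1, size = dist$size,
                                    prob = dist$prob))
  }
  out
}

#' Cumulative distribution function of an attention-time distribution
#'
#' @inheritParams at_pmf
#' @param n Vector of nonnegative integers; \code{at_cdf(dist, 0)} is 0
#'   because the support starts at 1.
#' @return \eqn{P(T_{at} \le n)}, vectorized over \code{n}.
#' @export
at_cdf <- function(dist, n) {
  stopifnot(inherits(dist, "attention_dist"))
  n <- floor(as.numeric(n))
  out <- numeric(length(n))
  pos <- n >= 1
  if (any(pos)) {
    nn <- n[pos]
    out[pos] <- switch(dist$kind,
      deterministic = as.numeric(nn >= dist$n0),
      geometric     = stats::pgeom(nn - 1, prob = dist$r),
      uniform       = pmin(1, pmax(0, (pmin(nn, dist$N + dist$M) -
                                       (dist$N - dist$M) + 1)) /
                                  (2 * dist$M + 1)),
      poisson       = stats::ppois(nn - 1, lambda = dist$lambda),
      binomial      = stats::pbinom(nn - 1, size = dist$size,
                                    prob = dist$prob))
  }
  out
}

#' Closed-form mean and variance of an attention-time distribution
#'
#' @inheritParams at_pmf
#' @return A list with components \code{mean} (steps) and \code{variance}
#'   (steps squared).
#' @export
at_moments <- function(dist) {
  stopifnot(inherits(dist, "attention_dist"))
  switch(dist$kind,
    deterministic = list(mean = dist$n0, variance = 0),
    geometric     = list(mean = 1 / dist$r,
                         variance = (1 - dist$r) / dist$r^2),
    uniform       = list(mean = dist$N,
                         variance = dist$M * (dist$M + 1) / 3),
    poisson       = list(mean = dist$lambda + 1, variance = dist$lambda),
    binomial      = list(mean = dist$size * dist$prob + 1,
                         variance = dist$size * dist$prob * (1 - dist$prob)))
}

#' Truncation point for series over an attention-time distribution
#'
#' Smallest \code{N_max} with \eqn{1 - F(N_{max}) \le} \code{tol}; the
#' matrix series for the schedule operators are cut off there.
#'
#' @inheritParams at_pmf
#' @param tol Tail mass tolerance in (0, 1); default \code{1e-12}.
#' @return A positive integer.
#' @export
at_truncation_bound <- function(dist, tol = 1e-12) {
  stopifnot(inherits(dist, "attention_dist"), tol > 0, tol < 1)
  switch(dist$kind,
    deterministic = dist$n0,
    uniform       = dist$N + dist$M,
    geometric     = max(1L, as.integer(ceiling(log(tol) / log1p(-dist$r)))),
    poisson       = {
      n <- stats::qpois(tol, lambda = dist$lambda, lower.tail = FALSE) + 1L
      while (stats::ppois(n - 1, dist$lambda, lower.tail = FALSE) > tol)
        n <- n + 1L
      n
    },
    binomial      = {
      n <- stats::qbinom(tol, size = dist$size, prob = dist$prob,
                         lower.tail = FALSE) + 1L
      while (n <= dist$size + 1L &&
             stats::pbinom(n - 1, dist$size, dist$prob,
                           lower.tail = FALSE) > tol)
        n <- n + 1L
      min(n, dist$size + 1L)
    })
}

#' Sample attention times
#'
#' Draws from the distribution using the current RNG state (so results are
#' reproducible under \code{set.seed}).
#'
#' @inheritParams at_pmf
#' @param n Number of draws.
#' @return An integer vector of step counts.
#' @export
at_sample <- function(dist, n) {
  stopifnot(inherits(dist, "attention_dist"))
  switch(dist$kind,
    deterministic = rep.int(dist$n0, n),
    geometric     = stats::rgeom(n, prob = dist$r) + 1L,
    uniform       = sample.int(2L * dist$M + 1L, n, replace = TRUE) +
                    (dist$N - dist$M - 1L),
    poisson       = stats::rpois(n, lambda = dist$lambda) + 1L,
    binomial      = stats::rbinom(n, size = dist$size, prob = dist$prob) + 1L)
}
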