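#' Attribute parameters for the evidence-accumulation process
#'
#' One attribute contributes evidence through an Ornstein-Uhlenbeck process
#' \eqn{dX(t) = (\delta - \gamma X(t))\,dt + \sigma\,dW(t)}.  The drift
#' \eqn{\delta} is the expected evidence gain per unit time (positive values
#' favour alternative A), the decay \eqn{\gamma} pulls the state back towards
#' \eqn{\delta/\gamma}, and \eqn{\sigma} scales the noise.  Setting
#' \eqn{\gamma = 0} gives a Wiener process with drift.
#'
#' @param delta Drift rate (evidence units per unit time).
#' @param gamma Decay rate (per unit time); 0 for a pure drift-diffusion
#'   process.
#' @param sigma Diffusion coefficient (evidence units per square-root unit
#'   time).  Must be positive; defaults to 1, the conventional scaling.
#'
#' @return An object of class \code{"maas_attribute"}.
#' @examples
#' attribute_params(delta = 0.2, gamma = 0.03)
#' @export
attribute_params <- function(delta, gamma = 0, sigma = 1) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  structure(list(delta = delta, gamma = gamma, sigma = sigma),
            class = "maas_attribute")
}

#' @export
print.maas_attribute <- function(x, ...) {
  cat(sprintf("<maas_attribute> delta = %g, gamma = %g, sigma = %g\n",
              x$delta, x$gamma, x$sigma))
  invisible(x)
}

as_attribute_list <- function(attrs) {
  if (inherits(attrs, "maas_attribute")) attrs <- list(attrs)
  if (!is.list(attrs) || !all(vapply(attrs, inherits, logical(1),
                                     "maas_attribute")))
    stop("`attrs` must be an attribute_params() object or a list of them",
         call. = FALSE)
  attrs
}

#' Discretize the evidence state space
#'
#' Replaces the continuous evidence interval \eqn{[-\theta_B, \theta_A]} by a
#' regular grid with evidence step \eqn{\Delta = \sigma\sqrt{\tau}}, where
#' \eqn{\tau} is the time step.  This scaling keeps the one-step variance of
#' the discrete walk equal to \eqn{\sigma^2 \tau} so the chain converges to
#' the diffusion as \eqn{\tau \to 0}.  The grid has \eqn{m_A} states above
#' and \eqn{m_B} states below zero plus the two absorbing thresholds, for
#' \eqn{m = m_A + m_B + 1} states in total; the \eqn{m - 2} interior
#' (transient) states are ordered from low to high evidence,
#' \eqn{(-m_B + 1)\Delta, \ldots, (m_A - 1)\Delta}.
#'
#' @param theta_A Upper threshold magnitude (choose A at \eqn{+\theta_A}).
#' @param theta_B Lower threshold magnitude (choose B at \eqn{-\theta_B});
#'   defaults to \code{theta_A} (symmetric thresholds).
#' @param sigma Diffusion coefficient used for the grid spacing.
#' @param tau Time step (time units per chain step).
#'
#' @return An object of class \code{"maas_discretization"} with fields
#'   \code{delta_x}, \code{m_A}, \code{m_B}, \code{m}, \code{tau} and
#'   \code{states} (evidence values of the transient states).
#'
#' @details If a threshold is not an integer multiple of \code{delta_x} the
#'   grid index is rounded and a warning reports the effective thresholds
#'   \eqn{m_A\Delta} and \eqn{-m_B\Delta} actually used.
#'
#' @examples
#' # the standard configuration: 81 states
#' build_discretization(theta_A = 10, sigma = 1, tau = 1 / 16)
#' @export
build_discretization <- function(theta_A, theta_B = theta_A, sigma = 1, tau) {
  for (nm in c("theta_A", "theta_B", "sigma", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a positive finite number", nm),
           call. = FALSE)
  }
  delta_x <- sigma * sqrt(tau)
  m_A <- as.integer(round(theta_A / delta_x))
  m_B <- as.integer(round(theta_B / delta_x))
  if (m_A < 1L || m_B < 1L)
    stop("thresholds must be at least one evidence step away from the start",
         call. = FALSE)
  off_A <- abs(theta_A - m_A * delta_x)
  off_B <- abs(theta_B - m_B * delta_x)
  if (off_A > 1e-9 || off_B > 1e-9)
    warning(sprintf(paste0(
      "thresholds are not on the evidence grid; using effective thresholds ",
      "+%g / -%g (requested +%g / -%g)"),
      m_A * delta_x, m_B * delta_x, theta_A, theta_B), call. = FALSE)
  m <- m_A + m_B + 1L
  structure(list(
    theta_A = theta_A, theta_B = theta_B, sigma = sigma, tau = tau,
    delta_x = delta_x, m_A = m_A, m_B = m_B, m = m,
    states = (seq_len(m - 2L) - m_B) * delta_x
  ), class = "maas_discretization")
}

#' @export
print.maas_discretization <- function(x, ...) {
  cat(sprintf(
    "<maas_discretization> m = %d states (m_A = %d, m_B = %d), tau = %g, delta_x = %g\n",
    x$m, x$m_A, x$m_B, x$tau, x$delta_x))
  invisible(x)
}

#' One-step transition probabilities at an interior state
#'
#' The birth-death chain moves one evidence step up with probability
#' \eqn{p_{up} = \tfrac12\bigl(1 + (\delta - \gamma x)\sqrt{\tau}/\sigma\bigr)}
#' and one step down with probability \eqn{1 - p_{up}}; there is no staying
#' probability.  The local drift \eqn{\delta - \gamma x} is evaluated at the
#' current evidence value \eqn{x}.
#'
#' @param attr An \code{\link{attribute_params}} object.
#' @param disc A \code{\link{build_discretization}} object.
#' @param x Evidence value(s) at interior grid points.
#'
#' @return A list with numeric vectors \code{p_down} and \code{p_up}.
#' @examples
#' disc <- build_discretization(10, tau = 1 / 16)
#' transition_probabilities(attribute_params(0.2, 0.03), disc, x = 0)
#' @export
transition_probabilities <- function(attr, disc, x) {
  stopifnot(inherits(attr, "maas_attribute"),
            inherits(disc, "maas_discretization"))
  bias <- (attr$delta - attr$gamma * x) * sqrt(disc$tau) / attr$sigma
  bad <- which(abs(bias) > 1)
  if (length(bad))
    stop(sprintf(paste0(
      "unstable discretization: |delta - gamma*x|*sqrt(tau)/sigma = %.4g > 1 ",
      "at state x = %g for attribute (delta = %g, gamma = %g); ",
      "reduce tau or the drift/decay magnitudes"),
      abs(bias[bad[1]]), x[bad[1]], attr$delta, attr$gamma), call. = FALSE)
  p_up <- 0.5 * (1 + bias)
  list(p_down = 1 - p_up, p_up = p_up)
}

#' Assemble the absorbing-chain transition blocks for one attribute
#'
#' Writes the chain's transition matrix in canonical form and returns the
#' two blocks that matter for first-passage quantities: \code{Q}, the
#' \eqn{(m-2)\times(m-2)} tridiagonal substochastic matrix over transient
#' states (zero diagonal, rows ordered low to high evidence), and \code{R},
#' the \eqn{(m-2)\times 2} matrix of one-step absorption probabilities with
#' column order \code{c("B", "A")}.  Only the two boundary-adjacent rows of
#' \code{R} are nonzero.
#'
#' @inheritParams transition_probabilities
#' @return An object of class \code{"maas_blocks"} with elements \code{Q},
#'   \code{R}, \code{p_up} (per transient state) and the originating
#'   \code{attr} and \code{disc}.
#' @examples
#' disc <- build_discretization(10, tau = 1 / 16)
#' blk <- build_transition_blocks(attribute_params(0.2, 0.03), disc)
#' range(rowSums(blk$Q) + rowSums(blk$R))  # rows conserve probability
#' @export
build_transition_blocks <- function(attr, disc) {
  S <- disc$m - 2L
  tp <- transition_probabilities(attr, disc, disc$states)
  Q <- matrix(0, S, S)
  if (S > 1L) {
    Q[cbind(seq_len(S - 1L), seq_len(S - 1L) + 1L)] <- tp$p_up[-S]
    Q[cbind(seq_len(S - 1L) + 1L, seq_len(S - 1L))] <- tp$p_down[-1L]
  }
  R <- matrix(0, S, 2L, dimnames = list(NULL, c("B", "A")))
  R[1L, "B"] <- tp$p_down[1L]
  R[S, "A"] <- tp$p_up[S]
  structure(list(Q = Q, R = R, p_up = tp$p_up, attr = attr, disc = disc),
            class = "maas_blocks")
}

#' @export
print.maas_blocks <- function(x, ...) {
  cat(sprintf(
    "<maas_blocks> %d transient states, attribute delta = %g, gamma = %g\n",
    nrow(x$Q), x$attr$delta, x$attr$gamma))
  invisible(x)
}

#' Initial distribution over transient states
#'
#' By default a point mass at the transient state closest to evidence 0
#' (the unbiased start halfway between the thresholds).  A biased start can
#' be given either as an evidence value or as a full probability vector over
#' the \eqn{m - 2} transient states.
#'
#' @param disc A \code{\link{build_discretization}} object.
#' @param at Evidence value at which to place a point mass (default 0).
#' @param probs Optional full probability vector of length \code{m - 2};
#'   overrides \code{at}.
#'
#' @return A numeric probability vector of length \code{m - 2}.
#' @export
initial_state <- function(disc, at = 0, probs = NULL) {
  stopifnot(inherits(disc, "maas_discretization"))
  S <- disc$m - 2L
  if (!is.null(probs)) {
    probs <- as.numeric(probs)
    if (length(probs) != S)
      stop(sprintf("`probs` must have length m - 2 = %d", S), call. = FALSE)
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-10)
      stop("`probs` must be nonnegative and sum to 1", call. = FALSE)
    return(probs)
  }
  if (at <= -disc$m_B * disc$delta_x || at >= disc$m_A * disc$delta_x)
    stop("starting evidence must lie strictly between the thresholds",
         call. = FALSE)
  Z <- numeric(S)
  Z[which.min(abs(disc$states - at))] <- 1
  Z
}

#' Dump the transition blocks as dense text matrices
#'
#' Debug helper: writes \code{Q} and \code{R} as whitespace-separated dense
#' matrices to a text file for external inspection.
#'
#' @param blocks A \code{\link{build_transition_blocks}} object.
#' @param file Path to write to.
#' @return The file path, invisibly.
#' @export
dump_transition_blocks <- function(blocks, file) {
  stopifnot(inherits(blocks, "maas_blocks"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# Q %d x %d", nrow(blocks$Q), ncol(blocks$Q)), con)
  utils::write.table(blocks$Q, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("# R %d x 2 (columns B, A)", nrow(blocks$R)), con)
  utils::write.table(blocks$R, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
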