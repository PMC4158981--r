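#' Schedule operators for one attribute under a random attention time
#'
#' For transient block \code{Q}, absorption block \code{R} and a discrete
#' attention-time distribution with pmf \eqn{p_n} and cdf \eqn{f_n}, the
#' four operators that summarize one attention episode are
#' \deqn{V = \Bigl[\sum_{i \ge 0} (1 - f_i)\, Q^i\Bigr] R, \qquad
#'       W = \Bigl[\sum_{i \ge 0} (1 - f_i)(i + 1)\, Q^i\Bigr] R,}
#' \deqn{B = \sum_{n \ge 1} p_n\, Q^n, \qquad
#'       C = \sum_{n \ge 1} p_n\, n\, Q^n.}
#' Row \code{x} of \code{V} holds the probabilities of being absorbed at
#' (B, A) during the episode when it starts in transient state \code{x};
#' \code{W} carries the corresponding step-weighted sums used for mean
#' response times; \code{B} propagates the surviving (defective) state
#' distribution to the end of the episode; and \code{C} is its
#' duration-weighted companion, which books the episode length onto
#' decisions made in later episodes.
#'
#' The series are accumulated jointly with one matrix product per term and
#' truncated at \code{\link{at_truncation_bound}(dist, tol)}.  For the
#' geometric distribution closed forms via linear solves are used instead
#' (\code{method = "auto"}):
#' \eqn{V = (I - (1-r)Q)^{-1} R},
#' \eqn{W = (I - (1-r)Q)^{-2} R},
#' \eqn{B = r Q (I - (1-r)Q)^{-1}},
#' \eqn{C = r Q (I - (1-r)Q)^{-2}}.
#'
#' @param blocks A \code{\link{build_transition_blocks}} object.
#' @param dist An \code{\link{attention_time}} object.
#' @param tol Tail-mass truncation tolerance for the series.
#' @param method \code{"auto"} (closed form when available, currently the
#'   geometric case), \code{"series"} (always the truncated series) or
#'   \code{"closed"} (closed form, geometric only).
#'
#' @return \code{schedule_operators} returns a list with matrices \code{V},
#'   \code{W} (\eqn{(m-2) \times 2}, columns B, A) and \code{B}, \code{C}
#'   (\eqn{(m-2) \times (m-2)}).  The single-operator wrappers return the
#'   corresponding matrix.
#' @examples
#' disc <- build_discretization(2, tau = 1 / 4)
#' blk <- build_transition_blocks(attribute_params(0.1), disc)
#' ops <- schedule_operators(blk, attention_time("geometric", r = 0.2))
#' rowSums(ops$V) + rowSums(ops$B)  # episode conserves probability
#' @export
schedule_operators <- function(blocks, dist, tol = 1e-12,
                               method = c("auto", "series", "closed")) {
  stopifnot(inherits(blocks, "maas_blocks"),
            inherits(dist, "attention_dist"))
  method <- match.arg(method)
  if (method == "closed" && dist$kind != "geometric")
    stop("closed-form operators are only available for the geometric kind",
         call. = FALSE)
  if (method == "auto" && dist$kind == "geometric") method <- "closed"

  Q <- blocks$Q; R <- blocks$R
  S <- nrow(Q)
  if (method == "closed") {
    r <- dist$r
    A <- diag(S) - (1 - r) * Q
    V1 <- solve(A, R)           # (I-(1-r)Q)^{-1} R
    W  <- solve(A, V1)          # (I-(1-r)Q)^{-2} R
    B1 <- r * (Q %*% solve(A))  # r Q (I-(1-r)Q)^{-1}
    C1 <- r * (Q %*% solve(A, solve(A)))
    out <- list(V = V1, W = W, B = B1, C = C1)
  } else {
    N_max <- at_truncation_bound(dist, tol)
    surv <- 1 - at_cdf(dist, 0:(N_max - 1L))     # 1 - f_i, i = 0..N_max-1
    pm <- at_pmf(dist, seq_len(N_max))           # p_n, n = 1..N_max
    SV <- matrix(0, S, S); SW <- SV; SB <- SV; SC <- SV
    X <- diag(S)                                 # Q^i, starting at i = 0
    for (i in 0:N_max) {
      if (i < N_max) {
        s <- surv[i + 1L]
        if (s > 0) {
          SV <- SV + s * X
          SW <- SW + s * (i + 1) * X
        }
      }
      if (i >= 1L && pm[i] > 0) {
        SB <- SB + pm[i] * X
        SC <- SC + pm[i] * i * X
      }
      if (i < N_max) X <- X %*% Q
    }
    out <- list(V = SV %*% R, W = SW %*% R, B = SB, C = SC)
  }
  colnames(out$V) <- colnames(out$W) <- c("B", "A")
  out
}

#' @rdname schedule_operators
#' @export
compute_V <- function(blocks, dist, tol = 1e-12,
                      method = c("auto", "series", "closed")) {
  schedule_operators(blocks, dist, tol, method)$V
}

#' @rdname schedule_operators
#' @export
compute_W <- function(blocks, dist, tol = 1e-12,
                      method = c("auto", "series", "closed")) {
  schedule_operators(blocks, dist, tol, method)$W
}

#' @rdname schedule_operators
#' @export
compute_B <- function(blocks, dist, tol = 1e-12,
                      method = c("auto", "series", "closed")) {
  schedule_operators(blocks, dist, tol, method)$B
}

#' @rdname schedule_operators
#' @export
compute_C <- function(blocks, dist, tol = 1e-12,
                      method = c("auto", "series", "closed")) {
  schedule_operators(blocks, dist, tol, method)$C
}

#' Decision operators for an unbounded final attention episode
#'
#' When the last attribute is attended until a threshold is reached,
#' absorption is certain and the episode operators reduce to the classical
#' fundamental-matrix forms \eqn{V = (I - Q)^{-1} R} and
#' \eqn{W = (I - Q)^{-2} R}, computed by linear solves.
#'
#' @param blocks A \code{\link{build_transition_blocks}} object.
#' @return A list with matrices \code{V} (rows sum to 1) and \code{W}.
#' @export
infinite_horizon_VW <- function(blocks) {
  stopifnot(inherits(blocks, "maas_blocks"))
  A <- diag(nrow(blocks$Q)) - blocks$Q
  V <- solve(A, blocks$R)
  W <- solve(A, V)
  colnames(V) <- colnames(W) <- c("B", "A")
  list(V = V, W = W)
}

choice_result <- function(p_B, p_A, et_B, et_A, tau, horizon, tol = 1e-12) {
  p_A <- unname(p_A); p_B <- unname(p_B)
  et_A <- unname(et_A); et_B <- unname(et_B)
  p_0 <- 1 - p_A - p_B
  if (horizon == "infinite") p_0 <- max(0, min(p_0, 1))
  structure(list(
    p_A = p_A, p_B = p_B, p_0 = p_0,
    ET_A = if (p_A > 0) tau * et_A / p_A else NA_real_,
    ET_B = if (p_B > 0) tau * et_B / p_B else NA_real_,
    et_A = et_A, et_B = et_B,
    tau = tau, horizon = horizon
  ), class = "maas_result")
}

#' @export
print.maas_result <- function(x, ...) {
  cat(sprintf(
    "<maas_result> p_A = %.6f, p_B = %.6f, p_0 = %.3g | ET_A = %s, ET_B = %s (%s horizon)\n",
    x$p_A, x$p_B, x$p_0,
    ifelse(is.na(x$ET_A), "undefined", sprintf("%.4f", x$ET_A)),
    ifelse(is.na(x$ET_B), "undefined", sprintf("%.4f", x$ET_B)),
    x$horizon))
  invisible(x)
}

#' @export
as.data.frame.maas_result <- function(x, ...) {
  data.frame(p_A = x$p_A, p_B = x$p_B, p_0 = x$p_0,
             ET_A = x$ET_A, ET_B = x$ET_B)
}

#' Choice probabilities and mean response times, deterministic schedule
#'
#' Solves the piecewise chain for a fully fixed schedule: during stage
#' \code{l} the defective state distribution is advanced with the attended
#' attribute's \code{Q}, and the probability mass absorbed at each step
#' \code{i} (counted globally from the start) is accumulated into the choice
#' probabilities and, weighted by \code{i}, into the response-time sums.
#' An infinite final stage uses the fundamental-matrix solves of
#' \code{\link{infinite_horizon_VW}} instead of stepping.
#'
#' Mean response times are conditional on the choice:
#' \eqn{ET_X = \tau \cdot et_X / p_X}; they are reported as \code{NA} when
#' the corresponding choice has probability 0.
#'
#' @param sched A fully fixed \code{\link{time_order_schedule}} (integer
#'   order and durations).
#' @param attrs List of \code{\link{attribute_params}}, indexed by the
#'   attribute numbers used in the schedule.
#' @param disc A \code{\link{build_discretization}} object.
#' @param Z Initial distribution over transient states (default: point mass
#'   at evidence 0).
#'
#' @return A \code{maas_result}: \code{p_A}, \code{p_B}, \code{p_0} (no
#'   decision by the final time; 0 for infinite horizons), \code{ET_A},
#'   \code{ET_B} in time units, and the unnormalized step-weighted sums
#'   \code{et_A}, \code{et_B}.
#' @examples
#' disc <- build_discretization(10, tau = 1 / 16)
#' attrs <- list(attribute_params(0.2, 0.03), attribute_params(0.04, 0.003))
#' sched <- time_order_schedule(order = c(1, 2), times = c(300, 1),
#'                              horizon = "infinite")
#' solve_deterministic(sched, attrs, disc)
#' @export
solve_deterministic <- function(sched, attrs, disc,
                                Z = initial_state(disc)) {
  stopifnot(inherits(sched, "maas_schedule"),
            inherits(disc, "maas_discretization"))
  if (!schedule_is_fixed(sched))
    stop("`sched` has random components; use solve_random() or sample_schedule()",
         call. = FALSE)
  attrs <- as_attribute_list(attrs)
  ord <- sched$order$fixed
  dur <- sched$times$fixed
  if (max(ord) > length(attrs))
    stop("schedule refers to more attributes than supplied", call. = FALSE)
  blocks <- lapply(attrs, build_transition_blocks, disc = disc)

  z <- matrix(Z, nrow = 1)           # defective distribution, row vector
  pAB <- c(B = 0, A = 0)
  et  <- c(B = 0, A = 0)
  offset <- 0                        # global steps completed before stage l
  L <- sched$L
  for (l in seq_len(L)) {
    blk <- blocks[[ord[l]]]
    if (l == L && sched$horizon == "infinite") {
      vw <- infinite_horizon_VW(blk)
      pv <- z %*% vw$V
      pAB <- pAB + drop(pv)
      et  <- et + offset * drop(pv) + drop(z %*% vw$W)
      z <- matrix(0, 1, ncol(blk$Q))
    } else {
      for (j in seq_len(dur[l])) {
        absorbed <- z %*% blk$R
        pAB <- pAB + drop(absorbed)
        et  <- et + (offset + j) * drop(absorbed)
        z <- z %*% blk$Q
      }
      offset <- offset + dur[l]
    }
  }
  choice_result(pAB["B"], pAB["A"], et["B"], et["A"],
                tau = disc$tau, horizon = sched$horizon)
}

#' Choice probabilities and mean response times, random schedule
#'
#' Evaluates a random (or semi-random) time-and-order schedule exactly, by
#' the nested block recursion over the per-attribute episode operators
#' \code{V, W, B, C} of \code{\link{schedule_operators}}.  Working backwards
#' from the final stage, the decision operators conditional on entering
#' stage \code{l} with attribute \code{k'} are
#' \deqn{G_l(k') = V_{k'} + B_{k'} \sum_k d^{(l)}_{k'k}\, G_{l+1}(k),}
#' \deqn{H_l(k') = W_{k'} + C_{k'} \sum_k d^{(l)}_{k'k}\, G_{l+1}(k)
#'                 + B_{k'} \sum_k d^{(l)}_{k'k}\, H_{l+1}(k),}
#' with \eqn{G_L = V}, \eqn{H_L = W} (infinite-horizon operators when the
#' final stage is unbounded).  \eqn{Z' G_1(k_1)} gives the (B, A) choice
#' probabilities for initial attribute \eqn{k_1} and \eqn{Z' H_1(k_1)} the
#' step-weighted sums.
#'
#' A fixed attribute order is handled as the semi-random special case
#' (degenerate order transitions along the given sequence, with per-stage
#' operators).  Fixed integer durations are treated as point-mass attention
#' times, so \code{solve_random} on a fully fixed schedule reproduces
#' \code{\link{solve_deterministic}}.
#'
#' @inheritParams solve_deterministic
#' @param sched A \code{\link{time_order_schedule}}; any mix of fixed and
#'   random components.
#' @param tol Series truncation tolerance passed to
#'   \code{\link{schedule_operators}}.
#'
#' @return A list of class \code{"maas_random_result"}:
#'   \describe{
#'     \item{per_initial}{data frame, one row per initial attribute, with
#'       \code{initial_attribute}, \code{p_A}, \code{p_B}, \code{p_0},
#'       \code{ET_A}, \code{ET_B}, \code{et_A}, \code{et_B}.}
#'     \item{aggregate}{\code{maas_result} mixing the initial attributes by
#'       the schedule's initial distribution.}
#'   }
#' @export
solve_random <- function(sched, attrs, disc, Z = initial_state(disc),
                         tol = 1e-12) {
  stopifnot(inherits(sched, "maas_schedule"),
            inherits(disc, "maas_discretization"))
  attrs <- as_attribute_list(attrs)
  K <- length(attrs)
  L <- sched$L
  blocks <- lapply(attrs, build_transition_blocks, disc = disc)
  S <- disc$m - 2L

  fixed_order <- sched$order$fixed
  if (is.null(fixed_order)) {
    init_p <- normalize_init(sched$order$init, K)
    for (msg in validate_schedule(sched, K))
      if (!startsWith(msg, "warning:")) stop(msg, call. = FALSE)
  } else {
    if (max(fixed_order) > K)
      stop("schedule refers to more attributes than supplied", call. = FALSE)
    init_p <- numeric(K); init_p[fixed_order[1]] <- 1
  }

  # Episode operators for stage l, attribute k.  Cached per
  # (attribute, distribution) pair; point-mass stand-ins for fixed times.
  cache <- new.env(parent = emptyenv())
  ops_for <- function(l, k) {
    if (!is.null(sched$times$fixed))
      d <- attention_time("deterministic", n0 = sched$times$fixed[l])
    else
      d <- stage_time_dist(sched, l, k)
    key <- paste(k, d$kind, paste(unlist(d[-1]), collapse = "_"), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- schedule_operators(blocks[[k]], d, tol = tol)
    cache[[key]]
  }
  final_vw <- function(k) {
    if (sched$horizon == "infinite") infinite_horizon_VW(blocks[[k]])
    else ops_for(L, k)[c("V", "W")]
  }

  # Backward recursion over stages.  G[[k]], H[[k]] are (m-2) x 2.
  if (is.null(fixed_order)) {
    G <- lapply(seq_len(K), function(k) final_vw(k)$V)
    H <- lapply(seq_len(K), function(k) final_vw(k)$W)
    for (l in rev(seq_len(L - 1L))) {
      D <- order_matrix(sched$order$D, l)
      Gn <- vector("list", K); Hn <- vector("list", K)
      for (kp in seq_len(K)) {
        op <- ops_for(l, kp)
        sumG <- matrix(0, S, 2L); sumH <- matrix(0, S, 2L)
        for (k in seq_len(K)) {
          d <- D[kp, k]
          if (d > 0) {
            sumG <- sumG + d * G[[k]]
            sumH <- sumH + d * H[[k]]
          }
        }
        Gn[[kp]] <- op$V + op$B %*% sumG
        Hn[[kp]] <- op$W + op$C %*% sumG + op$B %*% sumH
      }
      G <- Gn; H <- Hn
    }
    per_idx <- seq_len(K)
    Gtop <- G; Htop <- H
  } else {
    # semi-random: one operator chain along the fixed sequence
    k <- fixed_order[L]
    Gcur <- final_vw(k)$V
    Hcur <- final_vw(k)$W
    for (l in rev(seq_len(L - 1L))) {
      kp <- fixed_order[l]
      op <- ops_for(l, kp)
      Hcur <- op$W + op$C %*% Gcur + op$B %*% Hcur
      Gcur <- op$V + op$B %*% Gcur
    }
    per_idx <- fixed_order[1]
    Gtop <- vector("list", K)
    Htop <- vector("list", K)
    Gtop[[per_idx]] <- Gcur
    Htop[[per_idx]] <- Hcur
  }

  zrow <- matrix(Z, nrow = 1)
  rows <- lapply(per_idx, function(k1) {
    p <- drop(zrow %*% Gtop[[k1]])
    e <- drop(zrow %*% Htop[[k1]])
    res <- choice_result(p[1], p[2], e[1], e[2],
                         tau = disc$tau, horizon = sched$horizon)
    cbind(data.frame(initial_attribute = k1), as.data.frame(res),
          data.frame(et_A = res$et_A, et_B = res$et_B))
  })
  per_initial <- do.call(rbind, rows)

  w <- init_p[per_idx]
  agg <- choice_result(
    sum(w * per_initial$p_B), sum(w * per_initial$p_A),
    sum(w * per_initial$et_B), sum(w * per_initial$et_A),
    tau = disc$tau, horizon = sched$horizon)

  structure(list(per_initial = per_initial, aggregate = agg,
                 initial_distribution = init_p),
            class = "maas_random_result")
}

#' @export
print.maas_random_result <- function(x, ...) {
  cat("<maas_random_result>\n")
  print(x$per_initial, row.names = FALSE)
  cat("aggregate: ")
  print(x$aggregate)
  invisible(x)
}
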