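#' Monte Carlo simulation of the attention-switching chain
#'
#' Simulates the discrete birth-death walk itself (the same process the
#' solvers analyze, not a rediscretized diffusion), so solver and simulator
#' target the identical chain and agree up to Monte Carlo error.  Per
#' trial: a fixed schedule realization is drawn (order via the Markov order
#' model, durations independently per stage from the stage attribute's
#' attention-time distribution), the start state is drawn from \code{Z},
#' and the walk steps with the attended attribute's transition
#' probabilities until absorption or the final time.  Schedule sampling and
#' walk stepping consume one seeded RNG stream in that order, so a seed
#' fixes the full result.
#'
#' @inheritParams solve_deterministic
#' @param sched A \code{\link{time_order_schedule}} (fixed or random
#'   components in any mix).
#' @param n_trials Number of simulated decision trials.
#' @param seed Integer seed (required, for reproducibility).
#' @param max_steps Per-trial safety cap on total steps for unbounded final
#'   stages; trials hitting the cap are scored as no-decision and counted
#'   in \code{truncated}.
#'
#' @return An object of class \code{"maas_sim"} with fields
#'   \code{n_trials}, \code{counts} (named: A, B, none),
#'   \code{rt_samples_A}, \code{rt_samples_B} (decision times in time
#'   units), \code{choice} and \code{rt} per trial, \code{orders} and
#'   \code{durations} (realized schedules), \code{empirical} (estimates
#'   \code{p_A}, \code{p_B}, \code{p_0}, \code{ET_A}, \code{ET_B} with
#'   standard errors \code{se_*}), \code{seed} and \code{truncated}.
#' @examples
#' disc <- build_discretization(2, tau = 1 / 4)
#' sched <- time_order_schedule(order = 1, times = 1, horizon = "infinite")
#' sim <- simulate_trials(sched, attribute_params(0), disc,
#'                        n_trials = 1000, seed = 1)
#' sim$empirical$p_A
#' @export
simulate_trials <- function(sched, attrs, disc, Z = initial_state(disc),
                            n_trials, seed, max_steps = 1e7) {
  stopifnot(inherits(sched, "maas_schedule"),
            inherits(disc, "maas_discretization"),
            n_trials >= 1)
  attrs <- as_attribute_list(attrs)
  K <- length(attrs)
  L <- sched$L
  set.seed(seed)

  # per-attribute up-move probabilities on the transient grid
  p_up <- vapply(attrs, function(a)
    transition_probabilities(a, disc, disc$states)$p_up,
    numeric(disc$m - 2L))
  p_up <- matrix(p_up, ncol = K)

  # realized orders ------------------------------------------------------
  if (!is.null(sched$order$fixed)) {
    orders <- matrix(sched$order$fixed, n_trials, L, byrow = TRUE)
  } else {
    init_p <- normalize_init(sched$order$init, K)
    orders <- matrix(0L, n_trials, L)
    orders[, 1] <- sample.int(K, n_trials, replace = TRUE, prob = init_p)
    for (l in seq_len(L - 1L)) {
      D <- order_matrix(sched$order$D, l)
      for (kp in seq_len(K)) {
        idx <- which(orders[, l] == kp)
        if (length(idx))
          orders[idx, l + 1L] <- sample.int(K, length(idx), replace = TRUE,
                                            prob = D[kp, ])
      }
    }
  }

  # realized durations ---------------------------------------------------
  if (!is.null(sched$times$fixed)) {
    durations <- matrix(sched$times$fixed, n_trials, L, byrow = TRUE)
  } else {
    durations <- matrix(0L, n_trials, L)
    for (l in seq_len(L)) {
      if (l == L && sched$horizon == "infinite") next
      for (k in seq_len(K)) {
        idx <- which(orders[, l] == k)
        if (length(idx))
          durations[idx, l] <- at_sample(stage_time_dist(sched, l, k),
                                         length(idx))
      }
    }
  }
  if (sched$horizon == "infinite") durations[, L] <- NA_integer_

  start <- sample.int(disc$m - 2L, n_trials, replace = TRUE, prob = Z)
  res <- walk_trials_cpp(orders, durations, p_up, start, max_steps)

  choice <- factor(res$choice, levels = c(1, -1, 0),
                   labels = c("A", "B", "none"))
  rt <- res$steps * disc$tau
  truncated <- sum(sched$horizon == "infinite" & res$choice == 0L)
  if (truncated > 0)
    warning(sprintf("%d trial(s) hit the %g-step cap and were scored as no-decision",
                    truncated, max_steps), call. = FALSE)

  counts <- c(A = sum(choice == "A"), B = sum(choice == "B"),
              none = sum(choice == "none"))
  rt_A <- rt[choice == "A"]
  rt_B <- rt[choice == "B"]
  p_hat <- counts / n_trials
  se_p <- sqrt(p_hat * (1 - p_hat) / n_trials)
  se_mean <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
             else NA_real_
  empirical <- list(
    p_A = unname(p_hat["A"]), p_B = unname(p_hat["B"]),
    p_0 = unname(p_hat["none"]),
    ET_A = if (length(rt_A)) mean(rt_A) else NA_real_,
    ET_B = if (length(rt_B)) mean(rt_B) else NA_real_,
    se_p_A = unname(se_p["A"]), se_p_B = unname(se_p["B"]),
    se_p_0 = unname(se_p["none"]),
    se_ET_A = se_mean(rt_A), se_ET_B = se_mean(rt_B))

  structure(list(
    n_trials = n_trials, counts = counts,
    rt_samples_A = rt_A, rt_samples_B = rt_B,
    choice = choice, rt = rt,
    orders = orders, durations = durations,
    empirical = empirical, seed = seed, truncated = truncated,
    tau = disc$tau, horizon = sched$horizon
  ), class = "maas_sim")
}

#' @export
print.maas_sim <- function(x, ...) {
  e <- x$empirical
  cat(sprintf(
    "<maas_sim> %d trials (seed %d): p_A = %.4f (SE %.4f), p_B = %.4f, p_0 = %.4f\n",
    x$n_trials, x$seed, e$p_A, e$se_p_A, e$p_B, e$p_0))
  cat(sprintf("           ET_A = %.3f (SE %.3g), ET_B = %.3f (SE %.3g)\n",
              e$ET_A, e$se_ET_A, e$ET_B, e$se_ET_B))
  invisible(x)
}

#' Empirical response-time quantiles from a simulation
#'
#' @param result A \code{\link{simulate_trials}} object.
#' @param probs Quantile levels in [0, 1].
#' @return A data frame with columns \code{prob}, \code{A}, \code{B};
#'   quantiles for an empty side are \code{NA}.
#' @export
empirical_rt_quantiles <- function(result, probs = c(0.1, 0.25, 0.5,
                                                     0.75, 0.9)) {
  stopifnot(inherits(result, "maas_sim"))
  qf <- function(x) if (length(x)) stats::quantile(x, probs, names = FALSE)
        else rep(NA_real_, length(probs))
  data.frame(prob = probs, A = qf(result$rt_samples_A),
             B = qf(result$rt_samples_B))
}

#' Export simulated trials as CSV
#'
#' One row per trial: trial index, choice (A/B/none), decision time, the
#' realized attribute order and the realized stage durations.
#'
#' @param result A \code{\link{simulate_trials}} object.
#' @param file Path of the CSV file to write.
#' @return The file path, invisibly.
#' @export
export_trials_csv <- function(result, file) {
  stopifnot(inherits(result, "maas_sim"))
  df <- data.frame(
    trial = seq_len(result$n_trials),
    choice = as.character(result$choice),
    rt = result$rt,
    order = apply(result$orders, 1, paste, collapse = "-"),
    durations = apply(result$durations, 1, function(d)
      paste(ifelse(is.na(d), "inf", d), collapse = "-")))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
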