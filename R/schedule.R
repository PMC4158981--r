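#' Time-and-order schedules for attention switching
#'
#' A schedule specifies which attribute is attended during each of \code{L}
#' consecutive stages and for how many chain steps.  Both components may be
#' fixed or random:
#'
#' \itemize{
#'   \item \strong{order}: a fixed integer sequence \code{k_1, ..., k_L}, or
#'     a Markov chain given by an initial distribution over attributes plus
#'     a list of K x K order-transition matrices \code{D[[l]]} whose entry
#'     \code{(k', k)} is the probability that attention switches from
#'     attribute \code{k'} to \code{k} at the l-th switch.  If fewer than
#'     \code{L - 1} matrices are supplied the last one is recycled
#'     (stationary switching).
#'   \item \strong{times}: fixed integer stage durations (chain steps), a
#'     single \code{\link{attention_time}} distribution shared by all
#'     attributes, or a list of K distributions keyed by attribute.
#'     \code{stage_overrides} can replace the distribution for individual
#'     stages.
#' }
#'
#' With \code{horizon = "infinite"} the final stage lasts until a threshold
#' is reached (no-decision probability 0); its time specification is
#' ignored.  With \code{horizon = "finite"} the process may run out of time,
#' leaving a no-decision probability \eqn{p_0 > 0}.
#'
#' @param order Integer vector of length \code{L} (fixed order), or a list
#'   with elements \code{init} (attribute index or probability vector over
#'   attributes) and \code{D} (list of order-transition matrices).
#' @param times Integer vector of length \code{L}, one
#'   \code{\link{attention_time}} object, or a list of K of them (indexed by
#'   attribute).
#' @param horizon \code{"finite"} or \code{"infinite"} (final stage).
#' @param L Number of stages; inferred from \code{order} when that is a
#'   fixed sequence.
#' @param stage_overrides Optional named list mapping stage index (as a
#'   name, e.g. \code{"2"}) to an \code{\link{attention_time}} object that
#'   replaces the attribute-keyed distribution for that stage.
#'
#' @return An object of class \code{"maas_schedule"}.
#' @examples
#' # fixed order (1, 2), first stage 300 steps, second until absorption
#' time_order_schedule(order = c(1, 2), times = c(300, 1),
#'                     horizon = "infinite")
#' # random order over 3 attributes, geometric times with mean 300
#' D <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE)
#' time_order_schedule(order = list(init = 1, D = list(D)),
#'                     times = attention_time("geometric", mean = 300),
#'                     horizon = "infinite", L = 3)
#' @export
time_order_schedule <- function(order, times, horizon = c("finite",
                                                          "infinite"),
                                L = NULL, stage_overrides = NULL) {
  horizon <- match.arg(horizon)
  if (is.numeric(order)) {
    order <- as.integer(order)
    if (any(order < 1L)) stop("attribute indices must be >= 1",
                              call. = FALSE)
    if (is.null(L)) L <- length(order)
    if (L != length(order))
      stop("`L` disagrees with the length of the fixed order",
           call. = FALSE)
    order_spec <- list(fixed = order)
  } else if (is.list(order) && !is.null(order$init) && !is.null(order$D)) {
    if (is.null(L)) stop("`L` must be given for a random order",
                         call. = FALSE)
    D <- order$D
    if (is.matrix(D)) D <- list(D)
    init <- order$init
    order_spec <- list(init = init, D = D)
  } else {
    stop("`order` must be an integer vector or list(init = , D = )",
         call. = FALSE)
  }
  L <- as.integer(L)
  if (L < 1L) stop("`L` must be at least 1", call. = FALSE)

  if (is.numeric(times)) {
    times <- as.integer(times)
    if (length(times) == 1L) times <- rep.int(times, L)
    if (length(times) != L)
      stop("fixed `times` must have length L", call. = FALSE)
    if (any(times < 1L))
      stop("fixed stage durations must be >= 1 step", call. = FALSE)
    time_spec <- list(fixed = times)
  } else if (inherits(times, "attention_dist")) {
    time_spec <- list(by_attribute = list(times), shared = TRUE)
  } else if (is.list(times) &&
             all(vapply(times, inherits, logical(1), "attention_dist"))) {
    time_spec <- list(by_attribute = times, shared = FALSE)
  } else {
    stop(paste0("`times` must be integer durations, an attention_time ",
                "object, or a list of attention_time objects"),
         call. = FALSE)
  }
  if (!is.null(stage_overrides)) {
    if (is.null(names(stage_overrides)) ||
        !all(vapply(stage_overrides, inherits, logical(1),
                    "attention_dist")))
      stop("`stage_overrides` must be a named list of attention_time objects",
           call. = FALSE)
  }
  structure(list(order = order_spec, times = time_spec, horizon = horizon,
                 L = L, stage_overrides = stage_overrides),
            class = "maas_schedule")
}

#' @export
print.maas_schedule <- function(x, ...) {
  ord <- if (!is.null(x$order$fixed))
    paste0("fixed (", paste(x$order$fixed, collapse = ", "), ")")
  else "random (Markov order transitions)"
  tm <- if (!is.null(x$times$fixed))
    paste0("fixed steps (", paste(x$times$fixed, collapse = ", "), ")")
  else if (isTRUE(x$times$shared))
    paste0("random, shared ", x$times$by_attribute[[1]]$kind)
  else "random, per attribute"
  cat(sprintf("<maas_schedule> L = %d stages, order %s, times %s, %s horizon\n",
              x$L, ord, tm, x$horizon))
  invisible(x)
}

schedule_is_fixed <- function(sched) {
  !is.null(sched$order$fixed) && !is.null(sched$times$fixed)
}

# Distribution governing the duration of stage `l` when attribute `k` is
# attended; stage overrides take precedence over attribute keying.
stage_time_dist <- function(sched, l, k) {
  if (!is.null(sched$stage_overrides)) {
    ov <- sched$stage_overrides[[as.character(l)]]
    if (!is.null(ov)) return(ov)
  }
  ba <- sched$times$by_attribute
  if (isTRUE(sched$times$shared)) return(ba[[1]])
  if (k > length(ba))
    stop(sprintf("no attention-time distribution for attribute %d", k),
         call. = FALSE)
  ba[[k]]
}

normalize_init <- function(init, K) {
  if (length(init) == 1L) {
    k1 <- as.integer(init)
    if (k1 < 1L || k1 > K)
      stop("initial attribute index out of range", call. = FALSE)
    p <- numeric(K); p[k1] <- 1
    return(p)
  }
  p <- as.numeric(init)
  if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-10)
    stop("initial attribute distribution must be a probability vector over K attributes",
         call. = FALSE)
  p
}

# D matrix for switch l (1-based switch index, l in 1..L-1), recycling the
# last matrix when fewer than L-1 were supplied.
order_matrix <- function(D_list, l) {
  D_list[[min(l, length(D_list))]]
}

#' Enumerate attribute order sequences and their probabilities
#'
#' Expands the Markov order model into the full set of attribute sequences
#' with nonzero probability.  The probability of a sequence is the initial
#' probability of \code{k_1} times the product of the order-transition
#' entries along the path.
#'
#' @param D_list List of K x K order-transition matrices (recycled if
#'   shorter than \code{L - 1}).
#' @param init Initial attribute index or probability vector over the K
#'   attributes.
#' @param L Number of stages.
#'
#' @return A data frame with a list-column \code{sequence} (integer vectors
#'   of length \code{L}) and a numeric column \code{probability}, summing
#'   to 1.
#' @examples
#' D1 <- matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE)
#' D2 <- matrix(c(0, 1, 0, 1, 0, 0, 3/4, 1/4, 0), 3, byrow = TRUE)
#' enumerate_order_sequences(list(D1, D2), init = 1, L = 3)
#' @export
enumerate_order_sequences <- function(D_list, init, L) {
  if (is.matrix(D_list)) D_list <- list(D_list)
  K <- nrow(D_list[[1]])
  for (D in D_list) {
    if (!is.matrix(D) || nrow(D) != K || ncol(D) != K)
      stop("all order-transition matrices must be K x K with a common K",
           call. = FALSE)
    if (any(D < 0) || any(abs(rowSums(D) - 1) > 1e-12))
      stop("order-transition matrix rows must be nonnegative and sum to 1",
           call. = FALSE)
  }
  L <- as.integer(L)
  init_p <- normalize_init(init, K)
  seqs <- list(); probs <- numeric(0)
  recurse <- function(path, prob) {
    l <- length(path)
    if (l == L) {
      seqs[[length(seqs) + 1L]] <<- path
      probs[length(probs) + 1L] <<- prob
      return(invisible())
    }
    row <- if (l == 0L) init_p else order_matrix(D_list, l)[path[l], ]
    for (k in which(row > 0)) recurse(c(path, k), prob * row[k])
  }
  recurse(integer(0), 1)
  data.frame(
    sequence = I(seqs),
    probability = probs,
    label = vapply(seqs, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Draw one fixed realization of a (partially) random schedule
#'
#' Samples the attribute order from the Markov order model and the stage
#' durations independently from the stage-appropriate attention-time
#' distributions.  Fixed components pass through unchanged.  An
#' infinite-horizon final stage keeps duration \code{NA}.
#'
#' @param sched A \code{\link{time_order_schedule}} object.
#' @param K Number of attributes (needed when the order is random).
#' @param seed Optional integer seed; when supplied the draw is a pure
#'   function of it.
#'
#' @return A list with integer vectors \code{order} and \code{durations}
#'   (the latter \code{NA} for an infinite final stage).
#' @export
sample_schedule <- function(sched, K = NULL, seed = NULL) {
  stopifnot(inherits(sched, "maas_schedule"))
  if (!is.null(seed)) set.seed(seed)
  L <- sched$L
  if (!is.null(sched$order$fixed)) {
    ord <- sched$order$fixed
  } else {
    if (is.null(K)) K <- nrow(sched$order$D[[1]])
    init_p <- normalize_init(sched$order$init, K)
    ord <- integer(L)
    ord[1] <- sample.int(K, 1L, prob = init_p)
    for (l in seq_len(L - 1L)) {
      row <- order_matrix(sched$order$D, l)[ord[l], ]
      ord[l + 1L] <- sample.int(K, 1L, prob = row)
    }
  }
  if (!is.null(sched$times$fixed)) {
    dur <- sched$times$fixed
  } else {
    dur <- vapply(seq_len(L), function(l)
      as.integer(at_sample(stage_time_dist(sched, l, ord[l]), 1L)),
      integer(1))
  }
  if (sched$horizon == "infinite") dur[L] <- NA_integer_
  list(order = ord, durations = dur)
}

#' Validate a schedule against an attribute set
#'
#' Reporting operation: returns character diagnostics rather than stopping,
#' so configuration files can be linted before a run.
#'
#' @param sched A \code{\link{time_order_schedule}} object.
#' @param K Number of attributes available.
#' @return A character vector of messages, empty when the schedule is clean.
#'   Messages starting with \code{"warning:"} are advisory.
#' @export
validate_schedule <- function(sched, K) {
  stopifnot(inherits(sched, "maas_schedule"))
  out <- character(0)
  if (!is.null(sched$order$fixed)) {
    bad <- which(sched$order$fixed > K | sched$order$fixed < 1L)
    if (length(bad))
      out <- c(out, sprintf("attribute index out of range 1..%d at stage %s",
                            K, paste(bad, collapse = ", ")))
  } else {
    D_list <- sched$order$D
    if (length(D_list) > max(1L, sched$L - 1L))
      out <- c(out, sprintf(
        "warning: %d order matrices supplied but only %d switches occur",
        length(D_list), sched$L - 1L))
    for (j in seq_along(D_list)) {
      D <- D_list[[j]]
      if (!is.matrix(D) || nrow(D) != K || ncol(D) != K) {
        out <- c(out, sprintf("order matrix %d is not %d x %d", j, K, K))
        next
      }
      if (any(D < 0))
        out <- c(out, sprintf("order matrix %d has negative entries", j))
      rs <- rowSums(D)
      bad <- which(abs(rs - 1) > 1e-12)
      if (length(bad))
        out <- c(out, sprintf(
          "order matrix %d: row %d sums to %.6g, expected 1", j, bad[1],
          rs[bad[1]]))
      dg <- which(diag(D) > 0)
      if (length(dg))
        out <- c(out, sprintf(
          "warning: order matrix %d has no-switch probability %.3g on the diagonal (attribute %d)",
          j, diag(D)[dg[1]], dg[1]))
    }
  }
  if (is.null(sched$times$fixed) && !isTRUE(sched$times$shared) &&
      length(sched$times$by_attribute) < K)
    out <- c(out, sprintf(
      "only %d attention-time distributions supplied for %d attributes",
      length(sched$times$by_attribute), K))
  out
}
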