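# Independent oracles and small fixtures used across the test files.

# Gambler's-ruin absorption probability at the upper boundary for a
# constant-drift birth-death chain: start `j` steps above the lower
# boundary, boundaries `n` steps apart, up-move probability `p`.
gamblers_ruin_up <- function(p, j, n) {
  q <- 1 - p
  if (abs(p - q) < 1e-15) return(j / n)
  r <- q / p
  (1 - r^j) / (1 - r^n)
}

# Continuous two-boundary Wiener first-passage probability of hitting +a
# before -b from 0, drift mu, diffusion sigma.
wiener_upper_prob <- function(mu, a, b, sigma = 1) {
  if (mu == 0) return(b / (a + b))
  k <- 2 * mu / sigma^2
  (1 - exp(k * b)) / (exp(-k * a) - exp(k * b))
}

# Exhaustive trajectory enumeration for a fixed schedule on a small chain:
# walks every +/-1 path, multiplying step probabilities, and accumulates
# absorption probabilities and step-weighted sums.  Independent of the
# solver's matrix algebra.  `p_up_by_attr` is an (m-2) x K matrix; `order`
# and `durations` give the fixed schedule (total steps must stay small).
enumerate_paths <- function(p_up_by_attr, order, durations, start_state) {
  S <- nrow(p_up_by_attr)
  n_total <- sum(durations)
  stage_of_step <- rep(seq_along(order), durations)
  acc <- new.env()
  acc$p_A <- 0; acc$p_B <- 0; acc$p_0 <- 0
  acc$et_A <- 0; acc$et_B <- 0
  recurse <- function(s, step, prob) {
    if (step == n_total) {
      acc$p_0 <- acc$p_0 + prob
      return(invisible())
    }
    k <- order[stage_of_step[step + 1L]]
    pu <- p_up_by_attr[s, k]
    for (mv in c(1L, -1L)) {
      pr <- prob * if (mv == 1L) pu else 1 - pu
      if (pr == 0) next
      s2 <- s + mv
      if (s2 > S) {
        acc$p_A <- acc$p_A + pr
        acc$et_A <- acc$et_A + pr * (step + 1L)
      } else if (s2 < 1L) {
        acc$p_B <- acc$p_B + pr
        acc$et_B <- acc$et_B + pr * (step + 1L)
      } else {
        recurse(s2, step + 1L, pr)
      }
    }
  }
  recurse(start_state, 0L, 1)
  as.list(acc)
}

# Brute-force series evaluation of the episode operators by direct
# summation with explicit dense matrix powers.
brute_operators <- function(Q, R, pmf_fun, cdf_fun, N_max) {
  S <- nrow(Q)
  V <- matrix(0, S, 2); W <- matrix(0, S, 2)
  B <- matrix(0, S, S); C <- matrix(0, S, S)
  Qi <- diag(S)
  for (i in 0:N_max) {
    surv <- 1 - cdf_fun(i)
    V <- V + surv * Qi %*% R
    W <- W + surv * (i + 1) * Qi %*% R
    if (i >= 1) {
      B <- B + pmf_fun(i) * Qi
      C <- C + pmf_fun(i) * i * Qi
    }
    Qi <- Qi %*% Q
  }
  list(V = V, W = W, B = B, C = C)
}

# Fixtures ------------------------------------------------------------------

# the standard 81-state configuration
disc81 <- function() build_discretization(10, sigma = 1, tau = 1 / 16)

# a small chain for brute-force comparisons
disc_small <- function(theta = 2, tau = 1 / 4)
  build_discretization(theta, sigma = 1, tau = tau)

# the two-attribute sets behind the simulation experiments
attrs_strong_then_weak <- function()          # strong A first, weak A second
  list(attribute_params(0.2, 0.03), attribute_params(0.04, 0.003))
attrs_b_then_strong <- function()             # favours B first, strong A second
  list(attribute_params(-0.1, 0), attribute_params(0.2, 0.03))
attrs_three <- function()                     # weak A, B, strong A
  list(attribute_params(0.04, 0.003), attribute_params(-0.1, 0),
       attribute_params(0.2, 0.03))

# the three-attribute order-transition worked example
order_example <- function() {
  list(
    D1 = matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, byrow = TRUE),
    D2 = matrix(c(0, 1, 0, 1, 0, 0, 3 / 4, 1 / 4, 0), 3, byrow = TRUE))
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |diff| = %.3g (tol %.3g)",
                              max(abs(actual - expected)), tol))
}
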