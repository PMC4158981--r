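# Episode operators --------------------------------------------------------

test_that("single-step and point-mass attention times give the expected operators", {
  d <- disc_small()
  blk <- build_transition_blocks(attribute_params(0.1, 0.02), d)
  one <- attention_time("deterministic", n0 = 1)
  expect_equal(compute_V(blk, one), blk$R, ignore_attr = TRUE)
  expect_equal(compute_W(blk, one), blk$R, ignore_attr = TRUE)
  expect_equal(compute_B(blk, one), blk$Q)
  expect_equal(compute_C(blk, one), blk$Q)

  n0 <- 5L
  d5 <- attention_time("deterministic", n0 = n0)
  Qp <- diag(nrow(blk$Q)); Vexp <- 0 * blk$R; Wexp <- Vexp
  for (i in 0:(n0 - 1)) {
    Vexp <- Vexp + Qp %*% blk$R
    Wexp <- Wexp + (i + 1) * Qp %*% blk$R
    Qp <- Qp %*% blk$Q
  }
  expect_close(compute_V(blk, d5), Vexp, 1e-14)
  expect_close(compute_W(blk, d5), Wexp, 1e-14)
  expect_close(compute_B(blk, d5), Qp, 1e-14)            # Q^n0
  expect_close(compute_C(blk, d5), n0 * Qp, 1e-14)       # n0 Q^n0
})

test_that("geometric closed forms equal the truncated series", {
  d <- disc_small(theta = 3)
  blk <- build_transition_blocks(attribute_params(0.15, 0.01), d)
  S <- nrow(blk$Q)
  for (r in c(0.5, 0.1)) {
    g <- attention_time("geometric", r = r)
    A <- diag(S) - (1 - r) * blk$Q
    expect_close(compute_V(blk, g, method = "series"),
                 solve(A, blk$R), 1e-10)
    expect_close(compute_W(blk, g, method = "series"),
                 solve(A, solve(A, blk$R)), 1e-10)
    expect_close(compute_B(blk, g, method = "series"),
                 r * blk$Q %*% solve(A), 1e-10)
    expect_close(compute_C(blk, g, method = "series"),
                 r * blk$Q %*% solve(A, solve(A)), 1e-10)
    # and "auto" dispatches to the closed form
    expect_close(compute_V(blk, g), solve(A, blk$R), 1e-12)
  }
})

test_that("series operators match a brute-force summation for every kind", {
  d <- disc_small()
  blk <- build_transition_blocks(attribute_params(-0.05, 0.03), d)
  for (dist in list(attention_time("uniform", N = 12, M = 5),
                    attention_time("poisson", lambda = 8),
                    attention_time("binomial", size = 20, prob = 0.4),
                    attention_time("geometric", r = 0.5))) {
    N_max <- at_truncation_bound(dist, 1e-14)
    oracle <- brute_operators(blk$Q, blk$R,
                              function(n) at_pmf(dist, n),
                              function(n) at_cdf(dist, n), N_max)
    ops <- schedule_operators(blk, dist, tol = 1e-14, method = "series")
    expect_close(ops$V, oracle$V, 1e-12)
    expect_close(ops$W, oracle$W, 1e-12)
    expect_close(ops$B, oracle$B, 1e-12)
    expect_close(ops$C, oracle$C, 1e-12)
    expect_true(all(rowSums(ops$B) <= 1 + 1e-12))
  }
})

test_that("infinite-horizon operators give certain absorption", {
  d <- disc81()
  blk <- build_transition_blocks(attribute_params(0, 0), d)
  vw <- infinite_horizon_VW(blk)
  expect_close(rowSums(vw$V), 1, 1e-10)
  # symmetric driftless chain from the centre: 50/50
  Z <- initial_state(d)
  expect_close(drop(Z %*% vw$V), c(0.5, 0.5), 1e-12)

  blk2 <- build_transition_blocks(attribute_params(0.2, 0), d)
  V2 <- infinite_horizon_VW(blk2)$V
  p <- 0.525
  expect_close(drop(Z %*% V2)[2],
               gamblers_ruin_up(p, d$m_B, d$m_A + d$m_B), 1e-10)
})

# Deterministic schedules ---------------------------------------------------

test_that("single unbounded stage reduces to first-passage quantities", {
  d <- disc81()
  sched <- time_order_schedule(order = 1, times = 1, horizon = "infinite")
  sym <- solve_deterministic(sched, attribute_params(0, 0), d)
  expect_close(sym$p_A, 0.5, 1e-12)
  expect_close(sym$p_B, 0.5, 1e-12)
  expect_equal(sym$ET_A, sym$ET_B, tolerance = 1e-10)
  expect_close(sym$p_0, 0, 1e-12)

  drift <- solve_deterministic(sched, attribute_params(0.2, 0), d)
  expect_close(drift$p_A, gamblers_ruin_up(0.525, 40, 80), 1e-10)
})

test_that("deterministic solves match exhaustive path enumeration", {
  d <- disc_small(theta = 1, tau = 1 / 9)  # m = 7, 5 transient states
  attrs <- list(attribute_params(0.3, 0.1), attribute_params(-0.2, 0))
  p_up <- vapply(attrs, function(a)
    transition_probabilities(a, d, d$states)$p_up, numeric(d$m - 2L))
  for (case in list(list(order = c(1L, 2L), dur = c(4L, 6L)),
                    list(order = c(2L, 1L, 2L), dur = c(3L, 4L, 5L)),
                    list(order = 1L, dur = 10L))) {
    oracle <- enumerate_paths(p_up, case$order, case$dur, start_state = 3L)
    sched <- time_order_schedule(order = case$order, times = case$dur,
                                 horizon = "finite")
    got <- solve_deterministic(sched, attrs, d)
    expect_close(got$p_A, oracle$p_A, 1e-12)
    expect_close(got$p_B, oracle$p_B, 1e-12)
    expect_close(got$p_0, oracle$p_0, 1e-12)
    expect_close(got$et_A, oracle$et_A, 1e-12)
    expect_close(got$et_B, oracle$et_B, 1e-12)
  }
})

test_that("finite horizons leave no-decision mass and conserve probability", {
  d <- disc81()
  attrs <- attrs_strong_then_weak()
  sched <- time_order_schedule(order = c(1, 2), times = c(50, 50),
                               horizon = "finite")
  r <- solve_deterministic(sched, attrs, d)
  expect_close(r$p_A + r$p_B + r$p_0, 1, 1e-10)
  expect_gt(r$p_0, 0)
  # ET undefined (not zero) when a side has no probability: force it with
  # an immediate-absorption-free tiny horizon from the centre
  short <- time_order_schedule(order = 1, times = 3, horizon = "finite")
  r2 <- solve_deterministic(short, attrs[[1]], d)
  expect_true(is.na(r2$ET_A) && is.na(r2$ET_B))
  expect_equal(r2$p_0, 1)
})

test_that("both attributes favouring A keeps p_A above one half", {
  d <- disc81()
  attrs <- attrs_strong_then_weak()
  for (n1 in c(10L, 160L, 1600L, 8000L)) {
    sched <- time_order_schedule(order = c(1, 2), times = c(n1, 1),
                                 horizon = "infinite")
    expect_gt(solve_deterministic(sched, attrs, d)$p_A, 0.5)
  }
})

# Random schedules ----------------------------------------------------------

test_that("L = 1 random solve equals Z'V for each attribute", {
  d <- disc_small(theta = 3)
  attrs <- list(attribute_params(0.1, 0), attribute_params(-0.1, 0.02))
  Z <- initial_state(d)
  g <- attention_time("geometric", r = 0.2)
  for (k in 1:2) {
    sched <- time_order_schedule(order = k, times = g, horizon = "finite")
    got <- solve_random(sched, attrs, d)$aggregate
    blk <- build_transition_blocks(attrs[[k]], d)
    pv <- drop(Z %*% compute_V(blk, g))
    expect_close(c(got$p_B, got$p_A), pv, 1e-12)
  }
})

test_that("random solver reduces exactly to the deterministic solver", {
  d <- disc81()
  cases <- list(
    list(attrs = attrs_strong_then_weak(), order = c(1, 2), horizon = "infinite"),
    list(attrs = attrs_strong_then_weak(), order = c(2, 1), horizon = "infinite"),
    list(attrs = attrs_strong_then_weak(), order = c(1, 2), horizon = "finite"),
    list(attrs = attrs_b_then_strong(),    order = c(1, 2), horizon = "infinite"),
    list(attrs = attrs_b_then_strong(),    order = c(1, 2), horizon = "finite"),
    list(attrs = attrs_b_then_strong(),    order = c(2, 1), horizon = "infinite"),
    list(attrs = attrs_three(),            order = c(1, 2, 3), horizon = "infinite"),
    list(attrs = attrs_three(),            order = c(3, 1, 2), horizon = "infinite"))
  for (cs in cases) {
    times <- rep(120L, length(cs$order))
    sched <- time_order_schedule(order = cs$order, times = times,
                                 horizon = cs$horizon)
    det <- solve_deterministic(sched, cs$attrs, d)
    rnd <- solve_random(sched, cs$attrs, d)$aggregate
    for (q in c("p_A", "p_B", "p_0", "et_A", "et_B"))
      expect_close(rnd[[q]], det[[q]], 1e-12)
  }
})

test_that("random orders equal the sequence-probability mixture of fixed orders", {
  d <- disc_small(theta = 3)
  attrs <- list(attribute_params(0.2, 0.05), attribute_params(-0.1, 0),
                attribute_params(0.05, 0))
  ex <- order_example()
  n0 <- 8L
  sched <- time_order_schedule(
    order = list(init = 1, D = list(ex$D1, ex$D2)),
    times = attention_time("deterministic", n0 = n0),
    horizon = "finite", L = 3)
  got <- solve_random(sched, attrs, d)$aggregate

  e <- enumerate_order_sequences(list(ex$D1, ex$D2), init = 1, L = 3)
  mix <- c(p_A = 0, p_B = 0, et_A = 0, et_B = 0)
  for (i in seq_len(nrow(e))) {
    fx <- time_order_schedule(order = e$sequence[[i]], times = rep(n0, 3),
                              horizon = "finite")
    r <- solve_deterministic(fx, attrs, d)
    w <- e$probability[i]
    mix <- mix + w * c(r$p_A, r$p_B, r$et_A, r$et_B)
  }
  expect_close(got$p_A, mix["p_A"], 1e-12)
  expect_close(got$p_B, mix["p_B"], 1e-12)
  expect_close(got$et_A, mix["et_A"], 1e-12)
  expect_close(got$et_B, mix["et_B"], 1e-12)
})

test_that("per-initial-attribute results aggregate by the initial distribution", {
  d <- disc_small(theta = 3)
  attrs <- list(attribute_params(0.2, 0), attribute_params(-0.2, 0))
  D <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  sched <- time_order_schedule(
    order = list(init = c(0.3, 0.7), D = list(D)),
    times = attention_time("geometric", r = 0.1),
    horizon = "infinite", L = 2)
  res <- solve_random(sched, attrs, d)
  expect_equal(nrow(res$per_initial), 2L)
  expect_close(res$aggregate$p_A,
               sum(c(0.3, 0.7) * res$per_initial$p_A), 1e-12)
})

# Invariants ----------------------------------------------------------------

test_that("probability is conserved across randomized configurations", {
  set.seed(42)
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    tau <- sample(c(1 / 4, 1 / 9, 1 / 16), 1)
    theta <- sample(2:4, 1)
    d <- build_discretization(theta, sigma = 1, tau = tau)
    K <- sample(1:3, 1)
    attrs <- replicate(K, attribute_params(stats::runif(1, -0.3, 0.3),
                                           stats::runif(1, 0, 0.05)),
                       simplify = FALSE)
    L <- sample(1:3, 1)
    ord <- sample.int(K, L, replace = TRUE)
    horizon <- sample(c("finite", "infinite"), 1)
    dist <- switch(sample(1:3, 1),
                   attention_time("geometric", r = stats::runif(1, .05, .9)),
                   attention_time("uniform", N = sample(3:20, 1), M = 2L),
                   attention_time("poisson", lambda = stats::runif(1, 1, 15)))
    sched <- time_order_schedule(order = ord, times = dist,
                                 horizon = horizon)
    r <- solve_random(sched, attrs, d)$aggregate
    expect_close(r$p_A + r$p_B + r$p_0, 1, 1e-10)
    if (horizon == "infinite") expect_lte(r$p_0, 1e-10)
  }
})

test_that("negating every drift swaps the A and B predictions", {
  d <- disc81()
  attrs <- attrs_strong_then_weak()
  neg <- lapply(attrs, function(a) attribute_params(-a$delta, a$gamma,
                                                    a$sigma))
  for (horizon in c("infinite", "finite")) {
    sched <- time_order_schedule(
      order = c(1, 2), times = attention_time("geometric", mean = 100),
      horizon = horizon)
    r1 <- solve_random(sched, attrs, d)$aggregate
    r2 <- solve_random(sched, neg, d)$aggregate
    expect_close(r1$p_A, r2$p_B, 1e-10)
    expect_close(r1$p_B, r2$p_A, 1e-10)
    expect_close(r1$et_A, r2$et_B, 1e-10)
    expect_close(r1$et_B, r2$et_A, 1e-10)
  }
})

test_that("stage overrides replace the attribute-keyed distribution", {
  d <- disc_small(theta = 3)
  attrs <- list(attribute_params(0.1, 0))
  base <- attention_time("geometric", r = 0.5)
  over <- attention_time("deterministic", n0 = 20)
  s_over <- time_order_schedule(order = c(1, 1), times = base,
                                horizon = "finite",
                                stage_overrides = list("2" = over))
  s_expl <- time_order_schedule(order = c(1, 1),
                                times = list(base),
                                horizon = "finite")
  r_over <- solve_random(s_over, attrs, d)$aggregate
  r_expl <- solve_random(s_expl, attrs, d)$aggregate
  expect_false(isTRUE(all.equal(r_over$p_A, r_expl$p_A)))
})
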