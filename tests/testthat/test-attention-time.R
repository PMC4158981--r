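test_that("pmf values match the defining formulas", {
  g <- attention_time("geometric", r = 0.5)
  expect_equal(at_pmf(g, 1:3), c(0.5, 0.25, 0.125))

  u <- attention_time("uniform", N = 300, M = 150)
  expect_equal(at_pmf(u, c(149, 150, 300, 450, 451)),
               c(0, 1, 1, 1, 0) / 301)

  d <- attention_time("deterministic", n0 = 7)
  expect_equal(at_pmf(d, 1:8), c(rep(0, 6), 1, 0))

  # support starts at 1 for every kind
  for (dist in list(g, u, d, attention_time("poisson", lambda = 3),
                    attention_time("binomial", size = 10, prob = 0.3)))
    expect_equal(at_pmf(dist, 0), 0)
})

test_that("cdf accumulates the pmf and starts at zero", {
  g <- attention_time("geometric", r = 0.5)
  expect_equal(at_cdf(g, 2), 0.75)
  d7 <- attention_time("deterministic", n0 = 7)
  expect_equal(at_cdf(d7, c(6, 7)), c(0, 1))

  for (dist in list(g, d7,
                    attention_time("uniform", N = 20, M = 7),
                    attention_time("poisson", lambda = 5),
                    attention_time("binomial", size = 12, prob = 0.4))) {
    expect_equal(at_cdf(dist, 0), 0)
    n <- 1:60
    expect_close(at_cdf(dist, n) - at_cdf(dist, n - 1), at_pmf(dist, n),
                 1e-12)
    expect_true(all(diff(at_cdf(dist, n)) >= 0))
  }
})

test_that("closed-form moments match numerically summed moments", {
  expect_equal(at_moments(attention_time("geometric", r = 0.1)),
               list(mean = 10, variance = 90))
  expect_equal(at_moments(attention_time("uniform", N = 300, M = 299)),
               list(mean = 300, variance = 29900))
  expect_equal(at_moments(attention_time("deterministic", n0 = 5))$variance,
               0)

  for (dist in list(attention_time("geometric", r = 0.2),
                    attention_time("uniform", N = 30, M = 12),
                    attention_time("poisson", lambda = 11),
                    attention_time("binomial", size = 40, prob = 0.35),
                    attention_time("deterministic", n0 = 9))) {
    n <- seq_len(at_truncation_bound(dist, 1e-14))
    p <- at_pmf(dist, n)
    mom <- at_moments(dist)
    expect_close(sum(p * n), mom$mean, 1e-9)
    expect_close(sum(p * (n - mom$mean)^2), mom$variance, 1e-9)
  }
})

test_that("truncation bounds cover the stated tail mass", {
  expect_equal(at_truncation_bound(attention_time("deterministic", n0 = 7),
                                   1e-3), 7L)
  u <- attention_time("uniform", N = 300, M = 150)
  expect_lte(at_truncation_bound(u, 1e-12), 450L)
  expect_equal(at_truncation_bound(attention_time("geometric", r = 0.5),
                                   1e-12), 40L)
  for (dist in list(attention_time("poisson", lambda = 299),
                    attention_time("binomial", size = 598, prob = 0.5),
                    attention_time("geometric", r = 1 / 300))) {
    nb <- at_truncation_bound(dist, 1e-12)
    expect_lte(1 - at_cdf(dist, nb), 1e-12)
    expect_gt(1 - at_cdf(dist, nb - 1L), 1e-12)
  }
})

test_that("mean parameterization matches the requested expectation", {
  for (kind in c("deterministic", "geometric", "poisson", "binomial")) {
    dist <- attention_time(kind, mean = 300)
    expect_equal(at_moments(dist)$mean, 300)
  }
  expect_equal(at_moments(attention_time("uniform", mean = 300,
                                         spread = "full")),
               list(mean = 300, variance = 29900))
  expect_equal(attention_time("uniform", mean = 300, spread = "half")$M,
               150L)
})

test_that("variance ordering at matched mean follows the kinds' spread", {
  v <- vapply(list(attention_time("geometric", mean = 300),
                   attention_time("uniform", mean = 300, spread = "full"),
                   attention_time("uniform", mean = 300, spread = "half"),
                   attention_time("poisson", mean = 300),
                   attention_time("binomial", mean = 300)),
              function(d) at_moments(d)$variance, numeric(1))
  expect_true(all(diff(v[1:4]) < 0))  # geometric > unif(full) > unif(half) > poisson
  expect_lt(v[5], v[3])               # binomial below both uniforms
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(attention_time("geometric", r = 0), "\\(0, 1\\]")
  expect_error(attention_time("uniform", N = 10, M = 10), "0..N-1")
  expect_error(attention_time("deterministic", n0 = 0), "positive integer")
  expect_error(attention_time("poisson", lambda = -1), "positive")
  expect_error(attention_time("binomial", size = 5, prob = 1), "\\(0, 1\\)")
  expect_error(attention_time("poisson", mean = 1), "exceed 1")
})

test_that("sampling is seed-reproducible and hits the right mean", {
  for (dist in list(attention_time("geometric", mean = 50),
                    attention_time("uniform", mean = 50, spread = "half"),
                    attention_time("poisson", mean = 50),
                    attention_time("binomial", mean = 50))) {
    set.seed(7); x1 <- at_sample(dist, 2000)
    set.seed(7); x2 <- at_sample(dist, 2000)
    expect_identical(x1, x2)
    expect_true(all(x1 >= 1))
    se <- sqrt(at_moments(dist)$variance / 2000)
    expect_lt(abs(mean(x1) - 50), 4 * se + 1e-9)
  }
})
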