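test_that("Student t test matches the pooled-variance textbook formula", {
  # identical groups: no difference
  res <- students_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # independent oracle: direct pooled-variance computation
  a <- c(0, 0, 1); b <- c(1, 1, 2)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(abs(t_oracle), df = 4, lower.tail = FALSE)
  res <- students_t_test(a, b)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)

  # swapping groups negates t, preserves p
  rev <- students_t_test(b, a)
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)

  expect_error(students_t_test(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(students_t_test(1, c(1, 2)), "2 finite values")
})

test_that("Storey q-values reduce to BH with pi0 = 1 and estimate pi0 on uniform p", {
  expect_equal(storey_qvalues(rep(1, 5))$q_values, rep(1, 5))

  withr::with_seed(42, {
    for (i in 1:5) {
      p <- runif(50)^seq(0.5, 2, length.out = 50)
      expect_equal(storey_qvalues(p, pi0 = 1)$q_values,
                   p.adjust(p, "BH"), tolerance = 1e-12)
    }
    p <- runif(100)
    est <- storey_qvalues(p)
    expect_gt(est$pi0_estimate, 0.75)
    expect_lte(est$pi0_estimate, 1)
    # monotone in p (ties allowed from the cummin step) and q bounded
    expect_true(all(diff(est$q_values[order(p)]) >= 0))
    expect_true(all(est$q_values <= 1 & est$q_values >= 0))
  })

  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("Spearman rho matches the rank-difference formula and its symmetries", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  # d^2 sum = 8 over n = 8: rho = 1 - 6*8/(8*63)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  expect_equal(spearman_rho(1:8, y), 1 - 6 * 8 / (8 * 63), tolerance = 1e-12)
  expect_equal(spearman_rho(1:8, rev(y)), -(1 - 6 * 8 / (8 * 63)),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- rnorm(10); z <- rnorm(10)
      r <- spearman_rho(x, z)
      expect_equal(spearman_rho(exp(x), z), r, tolerance = 1e-12)
      expect_equal(spearman_rho(x, z^3 + 2 * z), r, tolerance = 1e-12)
    }
  })
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("Fisher z clips at 0.99 and is odd and increasing", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(1), atanh(0.99))
  expect_equal(fisher_z(-1), -atanh(0.99))
  expect_equal(fisher_z(0.5), atanh(0.5))
  grid <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-grid), -fisher_z(grid))
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_true(all(abs(fisher_z(seq(-1, 1, by = 0.05))) <= atanh(0.99) + 1e-12))
  expect_error(fisher_z(1.2), "exceed 1")
})

test_that("normal threshold and tail p reproduce published cutoffs and invert each other", {
  th <- normal_threshold(0.158, 0.05)
  expect_equal(th$cutoff, 0.3097, tolerance = 1e-4)
  expect_equal(th$cutoff_2dp, 0.31)
  th <- normal_threshold(0.428, 0.10)
  expect_equal(th$cutoff, 0.704, tolerance = 1e-3)
  expect_equal(th$cutoff_2dp, 0.70)
  expect_lt(normal_threshold(3, 0.999999)$cutoff, 1e-4)

  expect_equal(signif(normal_tail_p(0.98, list(mean = 0, sd = 0.308)), 2),
               1.5e-3)
  expect_equal(normal_tail_p(0, list(mean = 0, sd = 1)), 1)
  expect_equal(normal_tail_p(1.96 * 0.3, list(mean = 0, sd = 0.3)), 0.05,
               tolerance = 1e-3)
  # mutual inverses over a grid of (sd, alpha)
  for (s in c(0.1, 0.428, 2)) for (a in c(0.01, 0.05, 0.5)) {
    expect_equal(
      normal_tail_p(normal_threshold(s, a)$cutoff, list(mean = 0, sd = s)),
      a, tolerance = 1e-10)
  }
  expect_error(normal_tail_p(1, list(mean = 0, sd = 0)), "positive")
})

test_that("Fisher exact enrichment matches brute-force hypergeometric enumeration", {
  res <- fisher_exact_enrichment(10, 4, 100, 10)
  expect_equal(res$enrichment_factor, 4)
  oracle <- sum(dhyper(4:10, 10, 90, 10))
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # exhaustive enumeration oracle on small backgrounds
  withr::with_seed(3, {
    for (i in 1:20) {
      N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
      x <- sample(0:min(n, K), 1)
      brute <- sum(vapply(x:min(n, K), function(i)
        choose(K, i) * choose(N - K, n - i) / choose(N, n), 0))
      expect_equal(fisher_exact_enrichment(n, x, N, K)$p, brute,
                   tolerance = 1e-9)
    }
  })

  res <- fisher_exact_enrichment(20, 5, 20, 5)  # selection = background
  expect_equal(res$enrichment_factor, 1)
  expect_equal(res$p, 1)
  res <- fisher_exact_enrichment(10, 0, 100, 10)
  expect_equal(res$enrichment_factor, 0)
  expect_equal(res$p, 1)
  expect_true(is.na(fisher_exact_enrichment(10, 0, 100, 0)$enrichment_factor))
})

test_that("Tukey biweight location is robust, equivariant, and exact for symmetric input", {
  expect_equal(tukey_biweight_location(c(-1, 0, 1)), 0)
  expect_lt(abs(tukey_biweight_location(c(0, 0, 0, 0, 10))), 0.01)
  expect_equal(tukey_biweight_location(3.7), 3.7)
  withr::with_seed(9, {
    x <- rnorm(50)
    for (shift in c(-2, 0.3, 10))
      expect_equal(tukey_biweight_location(x + shift),
                   tukey_biweight_location(x) + shift, tolerance = 1e-6)
  })
  expect_error(tukey_biweight_location(NA_real_), "finite")
})

test_that("null summary recomputes moments from samples and validates input", {
  withr::with_seed(2, x <- rnorm(100))
  ns <- null_summary(x, keep_samples = TRUE)
  expect_equal(ns$mean, mean(x))
  expect_equal(ns$sd, sd(x))
  expect_equal(ns$n_iterations, 100)
  expect_equal(mean(ns$samples), ns$mean)
  expect_error(null_summary(mean = 0, sd = -1), "nonnegative")
})
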