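test_that("stem estimator matches its closed form and inverts exactly", {
  expect_equal(stem_rate(10, 10, 0)$r_hat, log(10) / 10)
  expect_equal(stem_rate(1, 5, 0.3)$r_hat, 0)  # single survivor
  r <- stem_rate(20, 5, 0.9)$r_hat
  expect_equal(r, log(2.9) / 5)
  expect_equal(expected_stem_diversity(r, 0.9, 5), 20, tolerance = 1e-12)
})

test_that("crown estimator reduces correctly at its special points", {
  # two-taxon degeneracy: exactly zero at every extinction fraction
  for (eps in c(0, 0.5, 0.9)) expect_identical(crown_rate(2, 7, eps)$r_hat, 0)
  expect_equal(crown_rate(8, 10, 0)$r_hat, log(4) / 10)
  expect_equal(crown_rate(2.01, 10, 0)$r_hat, log(1.005) / 10)
  # vectorised over the epsilon grid
  expect_equal(nrow(crown_rate(10, 5, c(0, 0.5, 0.9))), 3L)
})

test_that("two-taxon adjustment bumps exactly 2 and is idempotent", {
  expect_equal(two_taxon_adjustment(c(2, 3, 2.01, 1)), c(2.01, 3, 2.01, 1))
  expect_error(two_taxon_adjustment(0.5), "clade size")
})

test_that("estimator domain errors identify the offending field", {
  expect_error(stem_rate(10, -1, 0), "'t'")
  expect_error(stem_rate(0.5, 5, 0), "'n'")
  expect_error(stem_rate(10, 5, 1), "epsilon")
  expect_error(crown_rate(1.5, 5, 0), "two_taxon_adjustment")
  expect_error(geometric_law(-0.1, 0, 5), "declining-diversity")
  expect_error(geometric_law(0.1, 1, 5), "epsilon")
})

test_that("geometric law hits its closed-form anchors", {
  expect_equal(geometric_law(log(2), 0, 1)$beta, 0.5)
  expect_equal(geometric_law(0.2, 0.5, 10)$beta, (exp(2) - 1) / (exp(2) - 0.5))
  law0 <- geometric_law(0.3, 0.5, 0)
  expect_equal(law0$beta, 0)
  expect_equal(law0$alpha, 0)
  # series regime: beta ~ r t/(1-eps) as r t -> 0
  expect_equal(geometric_law(1e-9, 0.5, 1e-5)$beta, 1e-14 / 0.5, tolerance = 1e-6)
})

test_that("expected diversities hit their limits and anchors", {
  expect_equal(expected_stem_diversity(log(10) / 10, 0, 10), 10)
  expect_equal(expected_stem_diversity(log(2), 0.5, 1), 3)
  expect_equal(expected_stem_diversity(0, 0.5, 12), 1)
  expect_equal(expected_crown_diversity(log(4) / 10, 0, 10), 8)
  expect_equal(expected_crown_diversity(0, 0.7, 30), 2)
})

test_that("rate estimation round-trips expected diversity on the full grid", {
  for (n in grid_n) for (t in grid_t) for (eps in grid_eps) {
    r_c <- crown_rate(n, t, eps)$r_hat
    expect_equal(expected_crown_diversity(r_c, eps, t), n, tolerance = 1e-9)
    r_s <- stem_rate(n, t, eps)$r_hat
    expect_equal(expected_stem_diversity(r_s, eps, t), n, tolerance = 1e-9)
  }
})

test_that("crown estimator is continuous in epsilon at zero", {
  for (n in grid_n) for (t in grid_t)
    expect_lt(abs(crown_rate(n, t, 1e-8)$r_hat - (log(n) - log(2)) / t), 1e-6)
})

test_that("rates are monotone in clade size, age and extinction fraction", {
  ns <- c(3, 5, 10, 50, 200)
  ts <- c(2, 5, 10, 20)
  for (eps in c(0, 0.5, 0.9)) {
    for (t in ts) {
      expect_true(all(diff(crown_rate(ns, t, eps)$r_hat) > 0))
      expect_true(all(diff(stem_rate(ns, t, eps)$r_hat) > 0))
    }
    for (n in ns) {
      expect_true(all(diff(crown_rate(n, ts, eps)$r_hat) < 0))
      expect_true(all(diff(stem_rate(n, ts, eps)$r_hat) < 0))
    }
  }
  # non-increasing in epsilon at fixed (n, t)
  for (n in ns) {
    expect_true(all(diff(crown_rate(n, 10, c(0, 0.5, 0.9))$r_hat) <= 0))
    expect_true(all(diff(stem_rate(n, 10, c(0, 0.5, 0.9))$r_hat) <= 0))
  }
})

test_that("tail probabilities match their anchors and the brute-force convolution", {
  expect_equal(prob_geq_stem(1, 0.3, 0.5, 7), 1)
  expect_equal(prob_geq_stem(4, log(2), 0, 1), 0.125)
  expect_equal(prob_geq_crown(2, 0.3, 0.9, 4), 1)
  expect_equal(prob_geq_crown(4, log(2), 0, 1), 0.5)
  expect_error(prob_geq_stem(2.5, 0.3, 0, 5), "integer")
  expect_error(prob_geq_crown(1, 0.3, 0, 5), ">= 2")
  for (beta in c(0.3, 0.5, 0.9)) {
    t_beta <- 1; r <- -log(1 - beta)  # eps = 0 gives beta = 1 - e^{-rt}
    for (n in c(2, 3, 7, 25))
      expect_equal(prob_geq_crown(n, r, 0, t_beta),
                   brute_crown_tail(n, beta), tolerance = 1e-9)
  }
})

test_that("crown size law conserves probability and tails are decreasing in n", {
  beta <- geometric_law(0.25, 0.5, 8)$beta
  k <- 2:20000
  expect_equal(sum((k - 1) * (1 - beta)^2 * beta^(k - 2)), 1, tolerance = 1e-9)
  # tail formula equals 1 minus the partial sum below n
  for (n in c(3, 10, 40)) {
    partial <- sum((2:(n - 1) - 1) * (1 - beta)^2 * beta^(2:(n - 1) - 2))
    expect_equal(prob_geq_crown(n, 0.25, 0.5, 8), 1 - partial, tolerance = 1e-9)
  }
  tails <- prob_geq_crown(2:30, 0.25, 0.5, 8)
  expect_true(all(diff(tails) < 0))
})

test_that("diversity limits invert the stem tail in closed form", {
  env <- diversity_limits(log(2), 0, times = 1, conf = 0.95, basis = "stem")
  expect_equal(env$lower, 1 + log(0.975) / log(0.5), tolerance = 1e-9)
  expect_equal(env$upper, 1 + log(0.025) / log(0.5), tolerance = 1e-9)
})

test_that("envelopes nest with confidence, bound the expectation, and respect floors", {
  times <- c(0, 1, 5, 10, 20)
  for (eps in c(0, 0.5, 0.9)) for (basis in c("crown", "stem")) {
    e95 <- diversity_limits(0.2, eps, times, conf = 0.95, basis = basis)
    e99 <- diversity_limits(0.2, eps, times, conf = 0.99, basis = basis)
    expect_true(all(e95$lower <= e95$upper))
    expect_true(all(e99$lower <= e95$lower))
    expect_true(all(e99$upper >= e95$upper))
    expect_true(all(e95$lower >= if (basis == "crown") 2 else 1))
    expectation <- if (basis == "crown") expected_crown_diversity(0.2, eps, times)
                   else expected_stem_diversity(0.2, eps, times)
    expect_true(all(e95$lower <= expectation & expectation <= e95$upper))
  }
  expect_error(diversity_limits(0.2, 0, numeric(0)), "times")
  expect_error(diversity_limits(0.2, 0, 1:3, conf = 1.2), "conf")
})

test_that("continuous crown bounds invert the tail they were solved from", {
  for (t in c(2, 10, 30)) {
    env <- diversity_limits(0.205, 0, times = t, conf = 0.95, basis = "crown")
    beta <- geometric_law(0.205, 0, t)$beta
    tail_at <- function(n) beta^(n - 2) * ((n - 1) - (n - 2) * beta)
    expect_equal(tail_at(env$lower), 0.975, tolerance = 1e-7)
    expect_equal(tail_at(env$upper), 0.025, tolerance = 1e-7)
  }
})

test_that("bd_params derives r and epsilon and rejects the critical process", {
  p <- bd_params(0.3, 0.15)
  expect_equal(p$r, 0.15)
  expect_equal(p$epsilon, 0.5)
  expect_error(bd_params(0.3, 0.3), "epsilon")
  expect_error(bd_params(0, 0), "lambda")
})
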