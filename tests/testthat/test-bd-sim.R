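test_that("identical seed and scenario reproduce the result sequence exactly", {
  scn <- sim_scenario(0.3, 0.1, horizon = 10, condition = "stem_survival", seed = 99)
  a <- simulate_clade(scn)
  b <- simulate_clade(scn)
  expect_identical(a$extant_count, b$extant_count)
  expect_identical(a$crown_age, b$crown_age)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  ea <- simulate_ensemble(scn, 50)
  eb <- simulate_ensemble(scn, 50)
  expect_identical(ea$counts, eb$counts)
})

test_that("scenario validation rejects malformed pulses and rates", {
  expect_error(sim_scenario(-0.1, 0, horizon = 10), "lambda")
  expect_error(sim_scenario(0.2, 0, horizon = 0), "horizon")
  expect_error(sim_scenario(0.2, 0, horizon = 10,
                            pulses = data.frame(older_ma = 12, younger_ma = 5, mu = 1)),
               "within")
  expect_error(sim_scenario(0.2, 0, horizon = 10,
                            pulses = data.frame(older_ma = c(8, 6), younger_ma = c(5, 3),
                                                mu = c(1, 1))),
               "overlap")
})

test_that("pure-birth ensemble mean tracks e^(lambda t)", {
  ens <- simulate_ensemble(sim_scenario(0.2, 0, horizon = 10, seed = 11), 4000)
  se <- sqrt(ens$summary$var / 4000)
  expect_lt(abs(ens$summary$mean - exp(2)), 2 * se)
})

test_that("stem-conditioned mean matches the survival-conditioned expectation", {
  ens <- simulate_ensemble(sim_scenario(0.3, 0.15, horizon = 10,
                                        condition = "stem_survival", seed = 12),
                           4000, probe_sizes = c(2, 5, 10))
  se <- sqrt(ens$summary$var / 4000)
  expect_lt(abs(ens$summary$mean - expected_stem_diversity(0.15, 0.5, 10)), 2 * se)
  theory <- prob_geq_stem(c(2, 5, 10), 0.15, 0.5, 10)
  binom_se <- sqrt(theory * (1 - theory) / 4000)
  expect_true(all(abs(ens$summary$tail - theory) < 3 * binom_se))
})

test_that("unconditioned extinction frequency matches alpha", {
  ens <- simulate_ensemble(sim_scenario(0.3, 0.15, horizon = 10, seed = 14), 4000)
  alpha <- geometric_law(0.15, 0.5, 10)$alpha
  se <- sqrt(alpha * (1 - alpha) / 4000)
  expect_lt(abs(mean(ens$counts == 0) - alpha), 3 * se)
})

test_that("stem-conditioned clade sizes fit the geometric law (chi-square GOF)", {
  reps <- 5000
  ens <- simulate_ensemble(sim_scenario(0.3, 0.15, horizon = 5,
                                        condition = "stem_survival", seed = 15), reps)
  beta <- geometric_law(0.15, 0.5, 5)$beta
  bins <- 1:9
  p <- (1 - beta) * beta^(bins - 1)
  p <- c(p, 1 - sum(p))  # 10+
  obs <- c(tabulate(pmin(ens$counts, 10), nbins = 10)[1:9],
           sum(ens$counts >= 10))
  stat <- sum((obs - reps * p)^2 / (reps * p))
  expect_gt(stats::pchisq(stat, df = length(p) - 1, lower.tail = FALSE), 0.001)
})

test_that("higher turnover inflates clade-size variance at equal net rate", {
  v0 <- simulate_ensemble(sim_scenario(0.15, 0, horizon = 10,
                                       condition = "stem_survival", seed = 16), 1500)
  v9 <- simulate_ensemble(sim_scenario(1.5, 1.35, horizon = 10,
                                       condition = "stem_survival", seed = 16), 1500)
  expect_gt(v9$summary$var, v0$summary$var)
})

test_that("survivor trees are ultrametric with tip count matching extant_count", {
  for (seed in 1:5) {
    res <- simulate_clade(sim_scenario(0.4, 0.2, horizon = 8,
                                       condition = "crown_survival", seed = seed))
    if (is.null(res$tree)) next
    expect_identical(length(res$tree$tip.label), res$extant_count)
    depth <- ape::node.depth.edgelength(res$tree)
    tip_depth <- depth[seq_along(res$tree$tip.label)]
    expect_lt(diff(range(tip_depth)), 1e-9)
  }
})

test_that("crown age and tree height agree across modules", {
  res <- simulate_clade(sim_scenario(0.5, 0.1, horizon = 10,
                                     condition = "crown_survival", seed = 31))
  expect_false(is.null(res$tree))  # crown conditioning guarantees >= 2 tips
  tr <- read_chronogram(text = paste0(ape::write.tree(res$tree)))
  expect_equal(mrca_age(tr, tr$tip.label), res$crown_age, tolerance = 1e-8)
  expect_lte(res$crown_age, res$stem_age)
})

test_that("single replicate with two survivors has gap = horizon - crown age", {
  scn <- sim_scenario(0.25, 0.2, horizon = 10, condition = "stem_survival", seed = 8)
  found <- FALSE
  for (i in 1:50) {
    res <- simulate_clade(sim_scenario(0.25, 0.2, horizon = 10,
                                       condition = "stem_survival", seed = i))
    if (res$extant_count == 2) {
      gaps <- res$stem_age - res$crown_age
      expect_equal(gaps, 10 - res$crown_age)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("mean stem-crown gap grows with extinction-pulse intensity", {
  gap_means <- vapply(c(0, 0.2, 0.4), function(m) {
    scn <- sim_scenario(0.3, 0, horizon = 10,
                        pulses = data.frame(older_ma = 7, younger_ma = 5, mu = m),
                        condition = "stem_survival", seed = 21)
    mean(stem_crown_gap_distribution(scn, 800))
  }, numeric(1))
  expect_true(all(diff(gap_means) > 0))
})

test_that("unattainable conditioning fails loudly at the rejection cap", {
  scn <- sim_scenario(0.05, 5, horizon = 10, condition = "crown_survival",
                      seed = 3, max_rejections = 10)
  expect_error(simulate_clade(scn), "max_rejections")
})

test_that("reps = 1 summary equals the single draw", {
  ens <- simulate_ensemble(sim_scenario(0.3, 0, horizon = 6, seed = 77), 1)
  expect_identical(ens$summary$mean, as.numeric(ens$counts))
  expect_identical(ens$summary$var, 0)
})
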