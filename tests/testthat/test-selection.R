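test_that("standard-curve quantification inverts the amplification model", {
  sc <- standard_curve(slope = -3.3219, intercept = 38)
  expect_equal(sc$efficiency, 1, tolerance = 1e-4)

  # Ct equal to the intercept corresponds to a single copy
  m <- data.frame(sample_id = "a", Ct = 38, replicate = 1)
  expect_equal(quantify(m, sc)$copies, 1, tolerance = 1e-6)

  # at 100% efficiency one cycle is one doubling
  m2 <- data.frame(sample_id = c("hi", "lo"), Ct = c(20, 21), replicate = 1)
  q2 <- quantify(m2, sc)
  expect_equal(q2$copies[q2$sample_id == "hi"] / q2$copies[q2$sample_id == "lo"],
               2, tolerance = 1e-3)

  # noiseless dilution series in the 95-98% efficiency band: exact recovery
  for (eff in c(0.95, 0.96, 0.98)) {
    d <- sy_generate("qpcr_dilution", seed = 5, efficiency = eff, ct_sd = 0)
    q <- quantify(d$data, standard_curve(d$truth$slope, d$truth$intercept))
    truth <- tapply(d$data$true_copies, d$data$sample_id, unique)
    expect_true(all(abs(q$copies / truth[q$sample_id] - 1) < 0.05))
  }

  # out-of-range Ct is flagged, not dropped
  sc_r <- standard_curve(-3.4, 38, ct_range = c(10, 30))
  qf <- quantify(data.frame(sample_id = "x", Ct = 35, replicate = 1), sc_r)
  expect_true(qf$out_of_range)
  expect_error(quantify(data.frame(sample_id = "x", Ct = -1), sc),
               "positive")
})

test_that("a fitted standard curve recovers slope, intercept and efficiency", {
  d <- sy_generate("qpcr_dilution", seed = 8, ct_sd = 0)
  sc <- fit_standard_curve(d$data$Ct, d$data$true_copies)
  expect_equal(sc$slope, d$truth$slope, tolerance = 1e-9)
  expect_equal(sc$efficiency, 0.96, tolerance = 1e-9)
  expect_warning(standard_curve(-5, 38), "efficiency")
})

test_that("enrichment folds are ratios of copies with propagated error", {
  ef <- enrichment_fold(1.7e5, 1.0e3)
  expect_equal(ef$fold, 170)
  expect_false(ef$lower_bound)
  expect_equal(enrichment_fold(500, 500)$fold, 1)
  # scale invariance
  expect_equal(enrichment_fold(3.3e7, 1.5e5)$fold,
               enrichment_fold(3.3e2, 1.5e0)$fold)
  # undetectable background becomes a flagged lower bound
  lb <- enrichment_fold(1e5, 0)
  expect_true(lb$lower_bound)
  expect_true(is.finite(lb$fold))

  # Monte-Carlo: with 10% CV triplicates the estimate lies within 2
  # propagated SDs of the truth in at least 95% of runs
  set.seed(99)
  true_fold <- 170
  hits <- replicate(1000, {
    t_rep <- 1.7e5 * (1 + rnorm(3, 0, 0.1))
    b_rep <- 1.0e3 * (1 + rnorm(3, 0, 0.1))
    ef <- enrichment_fold(mean(t_rep), mean(b_rep), sd(t_rep), sd(b_rep))
    abs(ef$fold - true_fold) <= 2 * ef$fold_sd
  })
  expect_gte(mean(hits), 0.95)
})

test_that("expected_unique matches exact enumeration and its own inverse", {
  expect_equal(expected_unique(1, 50), 1)
  expect_equal(expected_unique(0, 50), 0)
  # exact oracle via Stirling-number distribution of the distinct count
  for (D in c(2, 3, 5, 10)) {
    for (n in c(1, 2, 5, 10)) {
      expect_equal(expected_unique(n, D), exact_expected_unique(n, D),
                   tolerance = 1e-10, info = sprintf("n=%d D=%d", n, D))
    }
  }
  # monotone in n, bounded by min(n, D)
  eu <- expected_unique(0:200, 25)
  expect_true(all(diff(eu) > 0))
  expect_true(all(eu <= pmin(0:200, 25) + 1e-9))
  # n -> Inf limit is D
  expect_equal(expected_unique(1e9, 25), 25, tolerance = 1e-9)
  # simulation agreement at n=48, D=100
  set.seed(17)
  sim <- replicate(10000, length(unique(sample.int(100, 48, replace = TRUE))))
  se <- sd(sim) / sqrt(length(sim))
  expect_lt(abs(mean(sim) - expected_unique(48, 100)), 4 * se)
  # inverse: diversity estimate round-trips
  u <- expected_unique(48, 300)
  expect_equal(estimate_diversity(u, 48), 300, tolerance = 1e-6)
  expect_identical(estimate_diversity(48, 48), Inf)
  # the uniqueness statistic regime: 40 unique of 48 sequenced
  expect_gt(estimate_diversity(40, 48), 48)
})

test_that("cascade diversity is monotone in sampling depth and infection rate", {
  lo <- cascade_diversity(infection_rate = 0.02)
  hi <- cascade_diversity(infection_rate = 0.05)
  expect_lt(lo$steps$diversity[4], hi$steps$diversity[4])
  # full infection loses essentially nothing at that step
  full <- cascade_diversity(infection_rate = 1)
  expect_equal(full$steps$diversity[4] / full$steps$diversity[3], 1,
               tolerance = 1e-3)
  # round-1 output diversity never exceeds the displayed diversity
  expect_lte(lo$steps$diversity[2], lo$steps$diversity[1])
  # at the stated magnitudes the recovery of the initial display round is
  # the cascade's bottleneck
  expect_identical(lo$bottleneck, "round1_recovery")
  expect_error(cascade_diversity(infection_rate = 0), "infection_rate")
})

test_that("cascade expectations agree with stochastic simulation at small scale", {
  set.seed(23)
  D0 <- 500; n_display <- 2000; n_recover <- 80
  sim <- replicate(400, {
    displayed <- sample.int(D0, n_display, replace = TRUE)
    recovered <- sample(displayed, n_recover)
    c(length(unique(displayed)), length(unique(recovered)))
  })
  model <- cascade_diversity(pool_diversity = D0, displayed = n_display,
                             round1_output = n_recover,
                             phage_library_size = 1e7, eluted_phages = 1e8,
                             infection_rate = 1)
  expect_equal(model$steps$diversity[1], mean(sim[1, ]), tolerance = 0.02)
  expect_equal(model$steps$diversity[2], mean(sim[2, ]), tolerance = 0.05)
})

test_that("ELISA hit calling separates true hits at the default threshold", {
  # signal equal to background is never a hit above threshold 1
  calls <- elisa_call(signal = c(0.5, 0.5), background = c(0.5, 0.5),
                      threshold_ratio = 1.5)
  expect_false(any(calls$hit))
  # threshold 1 calls every well
  expect_true(all(elisa_call(c(0.2, 0.9), c(0.2, 0.3),
                             threshold_ratio = 1)$hit))
  # synthetic plate: 60% true hits at 5x signal recovered at threshold 3
  d <- sy_generate("elisa_plate", seed = 31)
  calls <- elisa_call(d$data$signal, d$data$background)
  expect_identical(calls$hit, d$data$true_hit)
  expect_equal(attr(calls, "fraction_positive"), mean(d$data$true_hit))
  # near-zero background uses the floor and is flagged
  fl <- elisa_call(0.5, 0.001)
  expect_true(fl$flagged)
  expect_equal(fl$ratio, 0.5 / 0.01)
})
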