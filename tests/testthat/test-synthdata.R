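test_that("generate_population draws from the stated age-SL law", {
  pop <- generate_population(population_params(n = 10000), seed = 1)
  expect_equal(nrow(pop), 10000)
  expect_true(all(pop$age >= 20 & pop$age <= 60))

  # degenerate scatter: every fish exactly on the line
  p0 <- population_params(n = 200, sigma = 0)
  pop0 <- generate_population(p0, seed = 2)
  expect_equal(pop0$sl, p0$beta0 + p0$beta1 * pop0$age)

  # Monte-Carlo check of the conditional mean at age 30
  p <- population_params(n = 50000, age_range = c(10, 50), beta0 = 10,
                         beta1 = 1, sigma = 2)
  big <- generate_population(p, seed = 3)
  bin <- big$sl[big$age == 30]
  expect_lt(abs(mean(bin) - 40), 3 * 2 / sqrt(length(bin)))
})

test_that("population parameters are validated", {
  expect_error(population_params(n = 0), "positive")
  expect_error(population_params(beta1 = -1), "positive")
  expect_error(population_params(sigma = -1), "non-negative")
  expect_error(population_params(age_range = c(30, 30)), "non-degenerate")
  expect_error(population_params(beta0 = NaN), "finite")
})

test_that("cohort mixtures produce multi-modal age structure", {
  p <- population_params(n = 5000, age_range = c(10, 70),
                         cohorts = list(mean = c(25, 55), sd = c(3, 3),
                                        prop = c(0.5, 0.5)))
  pop <- generate_population(p, seed = 4)
  # essentially nothing in the trough between the modes
  expect_lt(mean(pop$age >= 38 & pop$age <= 42), 0.02)
  expect_gt(mean(pop$age < 40), 0.4)
  expect_gt(mean(pop$age > 40), 0.4)
})

test_that("net sampling reproduces retention bias", {
  pop <- generate_population(population_params(n = 20000), seed = 5)

  # non-selective net: a plain random sample, no length bias
  srs <- sample_net_catch(pop, NULL, 2000, seed = 6)
  expect_equal(nrow(srs), 2000)
  expect_lt(abs(mean(srs$sl) - mean(pop$sl)), 4 * sd(pop$sl) / sqrt(2000))

  # retention midpoint at the population mean: netted fish run long;
  # oracle is the retention-weighted population mean
  rc <- retention_curve(l50 = mean(pop$sl), delta = 4)
  net <- sample_net_catch(pop, rc, 2000, seed = 7)
  w_mean <- weighted.mean(pop$sl, retention_prob(pop$sl, rc))
  expect_gt(mean(net$sl), mean(pop$sl))
  expect_lt(abs(mean(net$sl) - w_mean), 4 * sd(pop$sl) / sqrt(2000))

  # nothing retained when l50 sits far above every fish
  expect_warning(
    short <- sample_net_catch(pop, retention_curve(l50 = 500, delta = 0.5),
                              50, seed = 8),
    "retained")
  expect_lt(nrow(short), 50)
})

test_that("consumed sampling follows the selection spec", {
  params <- population_params(n = 20000)
  pop <- generate_population(params, seed = 9)

  # random predation: consumed age-SL slope matches the population slope
  cons_r <- sample_consumed(pop, selection_spec("random"), 500, seed = 10)
  fit <- lm(sl ~ age, data = cons_r)
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(coef(fit)["age"] - params$beta1), 3 * se)

  # strong size selection: consumed mean below the weighted-mean oracle band
  spec_s <- selection_spec("size", half = mean(pop$sl) - 5, width = 2)
  cons_s <- sample_consumed(pop, spec_s, 500, seed = 11)
  w <- plogis((spec_s$half - pop$sl) / spec_s$width)
  oracle_mean <- weighted.mean(pop$sl, w)
  expect_lt(mean(cons_s$sl), mean(pop$sl))
  expect_lt(abs(mean(cons_s$sl) - oracle_mean), 4 * sd(pop$sl) / sqrt(500))

  # growth selection: residuals pulled down, age distribution untouched
  spec_g <- selection_spec("growth", half = -2, width = 2)
  cons_g <- sample_consumed(pop, spec_g, 200, params = params, seed = 12)
  resid <- cons_g$sl - (params$beta0 + params$beta1 * cons_g$age)
  expect_lt(mean(resid), 0)
  ks <- suppressWarnings(ks.test(cons_g$age, pop$age))
  expect_gt(ks$p.value, 0.01)
})

test_that("consumed sampling requires usable weights", {
  pop <- generate_population(population_params(n = 100), seed = 13)
  expect_error(sample_consumed(pop, selection_spec("growth", 0, 1), 10),
               "params")
})

test_that("otolith generation respects the daily-increment model", {
  fish <- data.frame(id = 1:5, age = c(30, 45, 22, 60, 30),
                     sl = c(28, 45, 19, 61, 31))
  og <- otolith_growth_params()
  oto <- generate_otoliths(fish, og, noise_sd = 0)
  expect_equal(nrow(oto), 10)  # left + right per fish
  expect_equal(oto$n_increments[oto$fish_id == 1][1], 28L)

  # zero noise: sides identical, radius exactly proportional
  left <- oto[oto$side == "left", ]; right <- oto[oto$side == "right", ]
  expect_equal(left$radius, right$radius)
  expect_equal(left$radius, 10 + 10 * (fish$sl - 3))

  # round trip through the matching calibration recovers the true SL
  expect_equal(reconstruct_sl_from_radius(left$radius, calibration()),
               fish$sl, tolerance = 1e-12)

  expect_error(generate_otoliths(data.frame(id = 1, age = 1, sl = 5), og),
               "hatch_age")
})

test_that("generation is byte-identical under a fixed seed", {
  s1 <- simulate_survey(seed = 99)
  s2 <- simulate_survey(seed = 99)
  expect_identical(s1$fish, s2$fish)
  expect_identical(s1$otoliths, s2$otoliths)
  expect_identical(s1$squid, s2$squid)
})

test_that("random predation converges to the population mean over replicates", {
  params <- population_params(n = 5000)
  pop <- generate_population(params, seed = 14)
  n <- 50
  set.seed(15)
  diffs <- replicate(100, {
    mean(sample_consumed(pop, selection_spec("random"), n)$sl) - mean(pop$sl)
  })
  expect_lt(abs(mean(diffs)), 3 * params$sigma / sqrt(100 * n))
})

test_that("pooled size selection across two age ranges mimics growth selection", {
  # two narrow hatch cohorts, each size-selected about its own length range:
  # the pooled consumed line sits parallel below the population line
  set.seed(16)
  pa <- population_params(n = 5000, age_range = c(20, 23))
  pb <- population_params(n = 5000, age_range = c(50, 53))
  A <- generate_population(pa); B <- generate_population(pb)
  cons <- rbind(
    sample_consumed(A, selection_spec("size", mean(A$sl) - 2, 2), 100),
    sample_consumed(B, selection_spec("size", mean(B$sl) - 2, 2), 100))
  fit <- lm(sl ~ age, data = cons)
  expect_lt(abs(coef(fit)["age"] - pa$beta1), 0.1)      # slope preserved
  expect_lt(coef(fit)["(Intercept)"], pa$beta0 - 0.5)   # shifted down
})
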