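test_that("population fitting reduces to OLS without a retention curve", {
  set.seed(41)
  netted <- data.frame(age = sample(20:60, 80, TRUE))
  netted$sl <- -5 + 1.1 * netted$age + rnorm(80, 0, 3)
  pop <- fit_population(netted, retention = NULL)
  ols <- lm(sl ~ age, data = netted)
  expect_equal(pop$beta0, unname(coef(ols)[1]))
  expect_equal(pop$beta1, unname(coef(ols)[2]))
  expect_error(fit_population(netted[1:3, ]), "at least 5")
  expect_error(fit_population(data.frame(age = rep(30, 10),
                                         sl = rnorm(10, 28, 1))),
               "singular")
})

test_that("retention weighting recovers the true slope under mild net bias", {
  params <- population_params(n = 4000)
  rc <- retention_curve()                      # mild bias at the small tail
  set.seed(42)
  est <- numeric(200)
  for (i in 1:200) {
    pop <- generate_population(params)
    est[i] <- fit_population(sample_net_catch(pop, rc, 100), rc)$beta1
  }
  # unbiased recovery: estimates within 2 sampling SEs of the truth in >=90%
  # of replicates (the sampling SE is the replicate SD itself; analytic
  # weighted-regression SEs are not valid when weights depend on the
  # response)
  expect_lt(abs(mean(est) - params$beta1), 3 * sd(est) / sqrt(200))
  expect_gte(mean(abs(est - params$beta1) < 2 * sd(est)), 0.9)
})

test_that("weighting beats ignoring a strong net bias", {
  params <- population_params(n = 4000)
  rc <- retention_curve(l50 = 38, delta = 4)   # bites well into the SL range
  set.seed(43)
  err_w <- err_u <- numeric(200)
  for (i in 1:200) {
    pop <- generate_population(params)
    net <- suppressWarnings(sample_net_catch(pop, rc, 100))
    err_w[i] <- abs(fit_population(net, rc)$beta1 - params$beta1)
    err_u[i] <- abs(fit_population(net, NULL)$beta1 - params$beta1)
  }
  expect_lt(mean(err_w), mean(err_u))
})

test_that("the random-model likelihood equals its closed form", {
  pop <- default_pop_model()
  set.seed(43)
  cons <- simulate_from_population(pop, 30)
  ll <- selection_loglik("random", NULL, pop, cons)
  manual <- sum(log(pop$age_weights[match(cons$age, pop$ages)])) +
    sum(dnorm(cons$sl, pop$beta0 + pop$beta1 * cons$age, pop$sigma, log = TRUE))
  expect_equal(ll, manual, tolerance = 1e-12)
})

test_that("flat selection weights collapse to the random model", {
  pop <- default_pop_model()
  set.seed(44)
  cons <- simulate_from_population(pop, 25)
  ll0 <- selection_loglik("random", NULL, pop, cons)
  for (kind in c("size", "growth")) {
    ll <- selection_loglik(kind, c(0, 1e6), pop, cons)
    expect_equal(ll, ll0, tolerance = 1e-3)
  }
})

test_that("growth-model likelihood is invariant to residual-preserving shifts", {
  pop <- population_model(-5, 1.1, 3, 10:70)  # uniform age support
  set.seed(45)
  cons <- data.frame(age = sample(30:40, 20, TRUE))
  cons$sl <- -5 + 1.1 * cons$age + rnorm(20, -1, 2)
  shifted <- data.frame(age = cons$age + 5, sl = cons$sl + 1.1 * 5)
  th <- c(-1.5, 2)
  expect_equal(selection_loglik("growth", th, pop, cons),
               selection_loglik("growth", th, pop, shifted),
               tolerance = 1e-9)
})

test_that("ages outside the population support yield zero density", {
  pop <- default_pop_model(ages = 20:40)
  cons <- data.frame(age = c(25, 90), sl = c(25, 90))
  expect_warning(ll <- selection_loglik("random", NULL, pop, cons), "support")
  expect_identical(ll, -Inf)
})

test_that("the AIC identity holds for every fit", {
  pop <- default_pop_model()
  set.seed(46)
  cons <- simulate_from_population(pop, 30)
  for (kind in c("random", "size", "growth")) {
    f <- fit_selection(kind, pop, cons)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-6)
    expect_gte(f$loglik, selection_loglik("random", NULL, pop, cons) - 1e-9)
  }
})

test_that("selection fits recover generating parameters in distribution", {
  params <- population_params(n = 10000)
  pop <- default_pop_model()
  spec <- selection_spec("growth", half = -2, width = 2)
  set.seed(47)
  theta <- t(replicate(100, {
    p <- generate_population(params)
    cons <- sample_consumed(p, spec, 100, params = params)
    fit_selection("growth", pop, cons)$theta
  }))
  # the MLE is centred on the truth; the width is individually well
  # identified, the half-point trades off against it along a ridge
  expect_lt(abs(median(theta[, 1]) - (-2)), 1)       # half within +/-50%
  expect_lt(abs(median(theta[, 2]) - 2), 1)          # width within +/-50%
  expect_gte(mean(theta[, 2] > 1 & theta[, 2] < 3), 0.8)
})

test_that("the bootstrap LRT is reproducible and bounded", {
  pop <- default_pop_model()
  set.seed(48)
  cons <- simulate_from_population(pop, 40)
  b1 <- bootstrap_lrt(pop, cons, "growth", B = 100, seed = 5)
  b2 <- bootstrap_lrt(pop, cons, "growth", B = 100, seed = 5)
  expect_equal(b1$p, b2$p)
  expect_gt(b1$p, 0)
  expect_lte(b1$p, 1)
  expect_gte(b1$lr_obs, -1e-9)
  expect_error(bootstrap_lrt(pop, cons, "growth", B = 10), "at least 100")
})

test_that("model selection is consistent under the generating model", {
  params <- population_params(n = 5000)
  pop <- default_pop_model()
  set.seed(49)
  # under random predation the AIC penalty protects the null
  sel_r <- replicate(100, {
    cons <- simulate_from_population(pop, 30)
    compare_models(pop, cons, B = 0)$selected
  })
  expect_gte(mean(sel_r == "random"), 0.85)

  # under growth selection in a single cohort the growth model wins
  spec <- selection_spec("growth", half = -2, width = 2)
  sel_g <- replicate(30, {
    p <- generate_population(params)
    cons <- sample_consumed(p, spec, 100, params = params)
    compare_models(pop, cons, B = 0)$selected
  })
  expect_gt(mean(sel_g == "growth"), 0.5)
})

test_that("comparison tables carry the AIC ranking and tie-breaks", {
  pop <- default_pop_model()
  set.seed(50)
  cons <- simulate_from_population(pop, 30)
  cmp <- compare_models(pop, cons, scope = "site:test", B = 0)
  aics <- c(cmp$fits$random$aic, cmp$fits$size$aic, cmp$fits$growth$aic)
  expect_equal(min(aics),
               cmp$fits[[cmp$selected]]$aic)
  expect_equal(cmp$table$scope, "site:test")
  expect_equal(cmp$table$n_consumed, 30)
})
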