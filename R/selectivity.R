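# Selectivity inference. The original population is modelled as a discrete
# age distribution f0(a) (retention-weighted, kernel-smoothed netted ages)
# with SL | age ~ Normal(beta0 + beta1 * a, sigma^2). A predation model
# multiplies that density by a selection weight w(a, l; theta) and
# renormalises:
#   f_c(a, l) = f0(a) phi(l; beta0 + beta1 a, sigma) w(a, l; theta) / Z(theta)
# with w = 1 (random), a decreasing logistic in l (size) or in the residual
# l - (beta0 + beta1 a) (growth). The three models are fitted to the consumed
# sample by maximum likelihood and compared by AIC and a parametric-bootstrap
# likelihood-ratio test against the random model.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Discretised-Gaussian kernel smoothing of a weighted integer-age sample.
# bandwidth 0 returns the pure empirical (point-mass) distribution.
make_age_support <- function(ages, weights, bandwidth = 2) {
  stopifnot(length(ages) == length(weights), all(weights >= 0))
  if (bandwidth <= 0) {
    grid <- sort(unique(ages))
    w <- vapply(grid, function(a) sum(weights[ages == a]), 0)
  } else {
    pad <- ceiling(3 * bandwidth)
    grid <- seq(floor(min(ages)) - pad, ceiling(max(ages)) + pad)
    w <- colSums(weights * outer(ages, grid, function(a, g)
      stats::dnorm(g, a, bandwidth)))
  }
  list(ages = grid, weights = w / sum(w))
}

# Quadrature grids reused by every likelihood evaluation for this population:
# an SL grid carrying the age-mixture density sum_a f0(a) phi(l; mu_a, sigma)
# (size model) and a residual grid carrying phi(r; 0, sigma) (growth model).
# Trapezoidal integration on a uniform grid is spectrally accurate here
# because the integrands vanish with all derivatives at the boundaries.
make_grids <- function(beta0, beta1, sigma, ages, age_weights,
                       step_frac = 1 / 8, pad = 8.5) {
  mu <- beta0 + beta1 * ages
  step <- sigma * step_frac
  lgrid <- seq(min(mu) - pad * sigma, max(mu) + pad * sigma, by = step)
  mix <- as.numeric(age_weights %*% outer(mu, lgrid, function(m, l)
    stats::dnorm(l, m, sigma)))
  rgrid <- seq(-pad * sigma, pad * sigma, by = step)
  list(step = step, lgrid = lgrid, log_mix = log(mix),
       rgrid = rgrid, log_phir = stats::dnorm(rgrid, 0, sigma, log = TRUE))
}

#' Construct a population model directly
#'
#' The inferred original-population law: a linear mean age-SL relation with
#' Gaussian residuals and a discrete age distribution. Usually produced by
#' [fit_population()]; this constructor is for simulations with known truth.
#'
#' @param beta0,beta1 Intercept (mm) and slope (mm/day) of the mean age-SL
#'   line; `beta1 > 0`.
#' @param sigma Residual SD of SL given age (mm); positive.
#' @param ages Integer support of the age distribution (days).
#' @param age_weights Probabilities on `ages`; normalised internally.
#' @return An object of class `"population_model"`.
#' @export
population_model <- function(beta0, beta1, sigma, ages,
                             age_weights = rep(1, length(ages))) {
  stopifnot(is.finite(beta0), is.finite(beta1), sigma > 0,
            length(ages) == length(age_weights), all(age_weights >= 0),
            sum(age_weights) > 0)
  age_weights <- age_weights / sum(age_weights)
  m <- structure(
    list(beta0 = beta0, beta1 = beta1, sigma = sigma,
         ages = ages, age_weights = age_weights, n_netted = NA_integer_),
    class = "population_model"
  )
  m$grids <- make_grids(beta0, beta1, sigma, ages, age_weights)
  m
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model (original age-SL law)\n")
  cat(sprintf("  mean SL = %.3f + %.3f * age,  sigma = %.3f mm\n",
              x$beta0, x$beta1, x$sigma))
  cat(sprintf("  age support: %d-%d dph (%d points)\n",
              min(x$ages), max(x$ages), length(x$ages)))
  if (!is.na(x$n_netted))
    cat(sprintf("  fitted from %d netted records\n", x$n_netted))
  invisible(x)
}

#' Infer the original population from the net sample
#'
#' Weighted least squares of SL on age with weights `1 / retention(SL)`
#' undoes the net's length bias: fish that the net under-samples count more.
#' The residual SD is the weighted residual variance (with a two-parameter
#' degrees-of-freedom correction), and the age distribution is the
#' retention-weighted empirical distribution of netted ages, smoothed by a
#' discretised Gaussian kernel so that consumed ages falling between observed
#' netted ages retain positive density. With `retention = NULL` the fit
#' reduces to ordinary least squares.
#'
#' @param netted A data frame of netted fish with columns `age` and `sl`;
#'   at least 5 rows.
#' @param retention A [retention_curve()] or `NULL`.
#' @param age_bandwidth Kernel bandwidth for the age support, in days;
#'   0 keeps the raw empirical distribution.
#' @return A `"population_model"`.
#' @export
fit_population <- function(netted, retention = NULL, age_bandwidth = 2) {
  stopifnot(is.data.frame(netted), all(c("age", "sl") %in% names(netted)))
  if (nrow(netted) < 5) stop("need at least 5 netted records")
  if (length(unique(netted$age)) < 2)
    stop("all netted ages identical: age-SL regression is singular")
  w <- 1 / retention_prob(netted$sl, retention)
  fit <- stats::lm(sl ~ age, data = netted, weights = w)
  res <- stats::residuals(fit)
  n <- nrow(netted)
  sigma <- sqrt(sum(w * res^2) / sum(w) * n / (n - 2))
  sup <- make_age_support(netted$age, w, age_bandwidth)
  m <- population_model(unname(stats::coef(fit)[1]),
                        unname(stats::coef(fit)[2]),
                        sigma, sup$ages, sup$weights)
  m$n_netted <- n
  m
}

#' Sample from the fitted null (random-predation) density
#'
#' Draws ages from the population age distribution and lengths from the
#' conditional normal; used by the parametric bootstrap.
#'
#' @param pop A `"population_model"`.
#' @param n Sample size.
#' @return A data frame with columns `age` and `sl`.
#' @export
simulate_from_population <- function(pop, n) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  a <- sample(pop$ages, n, replace = TRUE, prob = pop$age_weights)
  data.frame(age = a,
             sl = stats::rnorm(n, pop$beta0 + pop$beta1 * a, pop$sigma))
}

# Precomputed per-dataset context so repeated likelihood evaluations inside
# the optimiser and the bootstrap avoid re-deriving data-dependent terms.
loglik_context <- function(kind, pop, consumed) {
  idx <- match(consumed$age, pop$ages)
  if (anyNA(idx)) return(NULL)
  mu <- pop$beta0 + pop$beta1 * consumed$age
  ll0 <- sum(log(pop$age_weights[idx])) +
    sum(stats::dnorm(consumed$sl, mu, pop$sigma, log = TRUE))
  g <- pop$grids
  if (kind == "size") {
    list(ll0 = ll0, x = consumed$sl, gx = g$lgrid, gdens = g$log_mix,
         lstep = log(g$step), n = nrow(consumed))
  } else {
    list(ll0 = ll0, x = consumed$sl - mu, gx = g$rgrid, gdens = g$log_phir,
         lstep = log(g$step), n = nrow(consumed))
  }
}

loglik_eval <- function(ctx, half, width) {
  lw <- stats::plogis((half - ctx$x) / width, log.p = TRUE)
  lwg <- stats::plogis((half - ctx$gx) / width, log.p = TRUE)
  logZ <- ctx$lstep + logsumexp(lwg + ctx$gdens)
  ctx$ll0 + sum(lw) - ctx$n * logZ
}

#' Log-likelihood of a predation model for a consumed sample
#'
#' Evaluates `sum log f_c(a_i, l_i)` under the selected predation kind. The
#' normalising constant `Z(theta)` is computed by summing over the discrete
#' age support and trapezoidal quadrature over SL on a precomputed grid
#' spanning the mean line +/- 8.5 residual SDs; all terms are handled in the
#' log domain. For the growth model the selection weight depends only on the
#' residual, so a single residual-grid integral serves every age.
#'
#' @param kind `"random"`, `"size"` or `"growth"`.
#' @param theta Numeric `c(half, width)` for size/growth (`width > 0`);
#'   ignored for random.
#' @param pop A `"population_model"`.
#' @param consumed A data frame of consumed fish with columns `age`, `sl`.
#' @return The log-likelihood in nats (`-Inf` if a consumed age lies outside
#'   the population age support).
#' @export
selection_loglik <- function(kind = c("random", "size", "growth"),
                             theta = NULL, pop, consumed) {
  kind <- match.arg(kind)
  stopifnot(inherits(pop, "population_model"),
            is.data.frame(consumed), nrow(consumed) >= 1)
  idx <- match(consumed$age, pop$ages)
  if (anyNA(idx)) {
    warning("consumed age outside the population age support; density is 0")
    return(-Inf)
  }
  mu <- pop$beta0 + pop$beta1 * consumed$age
  ll0 <- sum(log(pop$age_weights[idx])) +
    sum(stats::dnorm(consumed$sl, mu, pop$sigma, log = TRUE))
  if (kind == "random") return(ll0)
  stopifnot(length(theta) == 2, is.finite(theta[1]), theta[2] > 0)
  loglik_eval(loglik_context(kind, pop, consumed), theta[1], theta[2])
}

#' AIC from a log-likelihood and parameter count
#'
#' `AIC = 2k - 2 lnL`. The random model has no free selection parameters
#' (k = 0, population parameters are plug-in), so its AIC is `-2 lnL`; the
#' size and growth models each add two (half-point and width, k = 2).
#'
#' @param loglik Log-likelihood in nats.
#' @param k Number of free selection parameters (0 or 2).
#' @return The AIC.
#' @examples
#' selection_aic(-41.456, 0)  # 82.912
#' @export
selection_aic <- function(loglik, k) 2 * k - 2 * loglik

# Dispersed optimiser starts: half-points at quantiles of the observed SL
# (or residual), widths around the population sigma, plus a near-flat start
# from which the weight is effectively constant (the random limit).
start_grid <- function(x, sigma, n_starts) {
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  s <- sigma
  starts <- rbind(
    c(q[2], log(s)), c(q[3], log(0.5 * s)), c(q[1], log(2 * s)),
    c(q[3], log(2 * s)), c(q[1], log(0.5 * s)), c(q[2], log(0.3 * s)),
    c(max(x) + 6 * s, log(4 * s))
  )
  starts[seq_len(min(nrow(starts), max(n_starts, 2))), , drop = FALSE]
}

#' Fit one predation model by maximum likelihood
#'
#' For the size and growth models, the half-point and (log-)width are
#' optimised by Nelder-Mead from several dispersed starts; the best local
#' optimum is kept, making the fit deterministic given the data and start
#' grid. The random model has nothing to optimise.
#'
#' @param kind `"random"`, `"size"` or `"growth"`.
#' @param pop A `"population_model"`.
#' @param consumed Consumed-fish data frame (`age`, `sl`); at least 5 rows
#'   for the two-parameter models.
#' @param n_starts Number of optimiser starts (default 6 dispersed starts
#'   plus a near-flat one; at least 2 are always used).
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param width_min Lower bound on the logistic width (mm); defaults to half
#'   the population residual SD. A width below that is indistinguishable from
#'   a knife-edge threshold at the data's resolution, and an unbounded width
#'   admits a degenerate truncation optimum (the weight collapsing to a step
#'   just beyond the largest observation) that inflates the likelihood of
#'   every selective model even under random predation.
#' @return An object of class `"selection_fit"`: `kind`, `theta`
#'   (`c(half, width)` or `NULL`), `loglik`, `k`, `aic`, `n`, `convergence`.
#' @export
fit_selection <- function(kind = c("random", "size", "growth"), pop, consumed,
                          n_starts = 7, reltol = 1e-9, width_min = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(pop, "population_model"), is.data.frame(consumed))
  ctx <- loglik_context(if (kind == "random") "size" else kind, pop, consumed)
  if (is.null(ctx)) {
    warning("consumed age outside the population age support; density is 0")
    ctx <- list(ll0 = -Inf, n = nrow(consumed))
  }
  ll_rand <- ctx$ll0
  if (kind == "random") {
    return(structure(list(kind = kind, theta = NULL, loglik = ll_rand, k = 0L,
                          aic = selection_aic(ll_rand, 0), n = nrow(consumed),
                          convergence = 0L),
                     class = "selection_fit"))
  }
  if (nrow(consumed) < 5)
    stop("two-parameter selection fits need at least 5 consumed records")
  if (!is.finite(ll_rand)) stop("consumed ages outside the age support")
  if (is.null(width_min)) width_min <- 0.5 * pop$sigma
  obj <- function(par) {
    ll <- loglik_eval(ctx, par[1], width_min + exp(par[2]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- start_grid(ctx$x, pop$sigma, n_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("selection fit failed to converge from all starts")
  ll <- -best$value
  # nested in the random model (flat-weight limit): never report less
  theta <- c(best$par[1], width_min + exp(best$par[2]))
  if (ll < ll_rand) {
    ll <- ll_rand
    theta <- c(max(consumed$sl) + 20 * pop$sigma, 4 * pop$sigma)
  }
  structure(list(kind = kind, theta = theta, loglik = ll, k = 2L,
                 aic = selection_aic(ll, 2), n = nrow(consumed),
                 convergence = best$convergence),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("Selection fit: %s model (n = %d)\n", x$kind, x$n))
  if (!is.null(x$theta))
    cat(sprintf("  half-point = %.3f mm, width = %.3f mm\n",
                x$theta[1], x$theta[2]))
  cat(sprintf("  lnL = %.3f,  k = %d,  AIC = %.3f\n", x$loglik, x$k, x$aic))
  if (!is.null(x$boot_p))
    cat(sprintf("  bootstrap p vs random = %.4f\n", x$boot_p))
  invisible(x)
}

#' Parametric-bootstrap likelihood-ratio test against random predation
#'
#' Tests a selective model against the random-predation null. The observed
#' statistic is `LR = 2 (lnL_alt - lnL_random)` at the alternative's MLE.
#' `B` samples of the consumed-sample size are drawn from the fitted null
#' density, the alternative is refitted to each, and the p-value is
#' `(1 + #(LR_b >= LR_obs)) / (B + 1)` (never exactly zero). Iterations whose
#' refit fails are dropped and counted, with a warning if more than 1% drop.
#'
#' @param pop A `"population_model"`.
#' @param consumed Consumed-fish data frame.
#' @param alt_kind `"size"` or `"growth"`.
#' @param B Number of bootstrap iterations (default 2000; at least 100).
#' @param seed Optional integer seed.
#' @param n_starts_boot Optimiser starts used inside the bootstrap refits
#'   (fewer than for the reported fit, for speed).
#' @return A list of class `"bootstrap_lrt"`: `p`, `lr_obs`, `B_used`,
#'   `n_dropped`, `alt_fit`.
#' @export
bootstrap_lrt <- function(pop, consumed, alt_kind = c("size", "growth"),
                          B = 2000, seed = NULL, n_starts_boot = 3) {
  alt_kind <- match.arg(alt_kind)
  if (B < 100) stop("use at least 100 bootstrap iterations")
  if (!is.null(seed)) set.seed(seed)
  alt_fit <- fit_selection(alt_kind, pop, consumed)
  ll_rand <- selection_loglik("random", NULL, pop, consumed)
  lr_obs <- 2 * (alt_fit$loglik - ll_rand)
  n <- nrow(consumed)
  lr_boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    sim <- simulate_from_population(pop, n)
    lr_boot[b] <- tryCatch({
      fb <- fit_selection(alt_kind, pop, sim, n_starts = n_starts_boot,
                          reltol = 1e-7)
      2 * (fb$loglik - selection_loglik("random", NULL, pop, sim))
    }, error = function(e) NA_real_)
  }
  dropped <- sum(is.na(lr_boot))
  if (dropped > 0.01 * B)
    warning(sprintf("%d of %d bootstrap refits failed", dropped, B))
  ok <- lr_boot[!is.na(lr_boot)]
  structure(list(p = (1 + sum(ok >= lr_obs)) / (length(ok) + 1),
                 lr_obs = lr_obs, B_used = length(ok), n_dropped = dropped,
                 alt_fit = alt_fit),
            class = "bootstrap_lrt")
}

#' @export
print.bootstrap_lrt <- function(x, ...) {
  cat(sprintf("Bootstrap LRT (%s vs random): LR = %.3f, p = %.4f (B = %d)\n",
              x$alt_fit$kind, x$lr_obs, x$p, x$B_used))
  invisible(x)
}

sig_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Fit and compare the three predation models
#'
#' Fits the random, size-selective and growth-selective models to one
#' consumed sample, optionally runs the bootstrap likelihood-ratio test for
#' the two selective models, and selects the model with the lowest AIC (ties
#' broken toward fewer parameters, then random < size < growth order).
#'
#' @param pop A `"population_model"`.
#' @param consumed Consumed-fish data frame (`age`, `sl`).
#' @param scope Label for the comparison (`"site"`, `"year"`, `"all"`, or a
#'   free label carried into the report).
#' @param B Bootstrap iterations; `0` skips the bootstrap.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"model_comparison"` with the three
#'   `"selection_fit"`s (bootstrap p attached), the selected kind, and a
#'   one-row summary data frame `$table`.
#' @export
compare_models <- function(pop, consumed, scope = "site", B = 2000,
                           seed = NULL) {
  kinds <- c("random", "size", "growth")
  fits <- lapply(kinds, fit_selection, pop = pop, consumed = consumed)
  names(fits) <- kinds
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (k in c("size", "growth"))
      fits[[k]]$boot_p <- bootstrap_lrt(pop, consumed, k, B = B)$p
  }
  aics <- vapply(fits, `[[`, 0, "aic")
  ks <- vapply(fits, `[[`, 0L, "k")
  ord <- order(aics, ks, match(kinds, kinds))
  selected <- kinds[ord[1]]
  tab <- data.frame(
    scope = scope, n_consumed = nrow(consumed),
    lnl_random = fits$random$loglik, lnl_size = fits$size$loglik,
    lnl_growth = fits$growth$loglik,
    aic_random = fits$random$aic, aic_size = fits$size$aic,
    aic_growth = fits$growth$aic,
    p_size = if (B > 0) fits$size$boot_p else NA_real_,
    p_growth = if (B > 0) fits$growth$boot_p else NA_real_,
    selected = selected
  )
  structure(list(scope = scope, fits = fits, selected = selected,
                 table = tab),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  t <- x$table
  cat(sprintf("Predation-model comparison [%s], n = %d consumed\n",
              t$scope, t$n_consumed))
  star <- function(p) if (is.na(p)) "" else sig_stars(p)
  cat(sprintf("  random : lnL = %8.3f  AIC = %8.3f\n",
              t$lnl_random, t$aic_random))
  cat(sprintf("  size   : lnL = %8.3f  AIC = %8.3f %s\n",
              t$lnl_size, t$aic_size, star(t$p_size)))
  cat(sprintf("  growth : lnL = %8.3f  AIC = %8.3f %s\n",
              t$lnl_growth, t$aic_growth, star(t$p_growth)))
  cat(sprintf("  selected (min AIC): %s\n", x$selected))
  invisible(x)
}
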