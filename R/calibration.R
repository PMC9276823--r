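#' Otolith and body-size calibration
#'
#' Bundles the linear otolith-radius to standard-length (SL) mapping, the
#' allometric SL-weight relationship and the biological-intercept anchor used
#' throughout reconstruction. The radius-SL relation is `SL = c0 + c1 * R`
#' (mm, um) and the allometry is `W = p * SL^q` (g, mm). The hatch anchor is
#' the point at which the first daily increment is deposited: by default
#' 2 days post-hatch at about 3 mm body length.
#'
#' Calibration parameters are survey-specific and are normally fitted from a
#' reference table of fish with both otolith and body measurements (ordinary
#' least squares for radius-SL, log-log regression for SL-weight); see
#' [fit_calibration()]. The defaults here describe a small carangid juvenile
#' (roughly 10 um of post-rostral radius per mm of SL, condition such that a
#' 50 mm fish weighs about 2.5 g) and are intended for simulation.
#'
#' @param c0,c1 Intercept (mm) and slope (mm/um) of the radius-to-SL line;
#'   `c1` must be positive.
#' @param p,q Allometric coefficient (g) and exponent of `W = p * SL^q`; both
#'   must be positive.
#' @param hatch_sl Body length at first increment deposition (mm).
#' @param hatch_age Age at first increment deposition (days post-hatch).
#' @param hatch_radius Otolith radius at first increment deposition (um).
#' @return An object of class `"calibration"`.
#' @examples
#' cal <- calibration()
#' sl_to_weight(50, cal)
#' @export
calibration <- function(c0 = 2, c1 = 0.1, p = 2e-5, q = 3,
                        hatch_sl = 3, hatch_age = 2, hatch_radius = 10) {
  stopifnot(is.finite(c0), is.finite(c1), is.finite(p), is.finite(q),
            is.finite(hatch_sl), is.finite(hatch_age), is.finite(hatch_radius))
  if (c1 <= 0) stop("radius-SL slope `c1` must be positive")
  if (p <= 0 || q <= 0) stop("allometric parameters `p` and `q` must be positive")
  if (hatch_sl <= 0 || hatch_radius <= 0 || hatch_age < 0)
    stop("hatch anchor must have positive length and radius, non-negative age")
  structure(
    list(c0 = c0, c1 = c1, p = p, q = q,
         hatch_sl = hatch_sl, hatch_age = hatch_age,
         hatch_radius = hatch_radius),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("Otolith/body calibration\n")
  cat(sprintf("  radius -> SL : SL = %.4g + %.4g * R   (mm, um)\n", x$c0, x$c1))
  cat(sprintf("  allometry    : W  = %.4g * SL^%.4g    (g, mm)\n", x$p, x$q))
  cat(sprintf("  hatch anchor : %.3g mm, %g dph, %.3g um\n",
              x$hatch_sl, x$hatch_age, x$hatch_radius))
  invisible(x)
}

#' Fit calibration parameters from a reference table
#'
#' Ordinary least squares of SL on otolith radius and log-log regression of
#' weight on SL, applied to a reference sample of fish measured for both body
#' and otolith dimensions.
#'
#' @param ref A data frame with columns `sl` (mm), `radius` (um) and
#'   optionally `weight` (g).
#' @param hatch_sl,hatch_age,hatch_radius Hatch anchor, as in [calibration()].
#' @return A `"calibration"` object.
#' @export
fit_calibration <- function(ref, hatch_sl = 3, hatch_age = 2, hatch_radius = 10) {
  stopifnot(is.data.frame(ref), all(c("sl", "radius") %in% names(ref)))
  if (nrow(ref) < 3) stop("need at least 3 reference fish")
  f1 <- stats::lm(sl ~ radius, data = ref)
  c0 <- unname(stats::coef(f1)[1]); c1 <- unname(stats::coef(f1)[2])
  if (!is.null(ref$weight)) {
    f2 <- stats::lm(log(weight) ~ log(sl), data = ref)
    q <- unname(stats::coef(f2)[2]); p <- exp(unname(stats::coef(f2)[1]))
  } else {
    p <- 2e-5; q <- 3
  }
  calibration(c0 = c0, c1 = c1, p = p, q = q, hatch_sl = hatch_sl,
              hatch_age = hatch_age, hatch_radius = hatch_radius)
}

#' Logistic net-retention curve
#'
#' Probability that a fish of length `l` is retained by the sampling net,
#' `r(l) = 1 / (1 + exp(-(l - l50) / delta))`: strictly increasing in `l`,
#' 0.5 at `l50`. Small fish slip through the mesh, so the net sample
#' over-represents long individuals; `retention_prob()` supplies the weights
#' used by [fit_population()] to undo that bias.
#'
#' @param l50 Length at 50% retention (mm).
#' @param delta Logistic width (mm); must be positive.
#' @return An object of class `"retention_curve"`.
#' @examples
#' rc <- retention_curve(25, 3)
#' retention_prob(c(20, 25, 40), rc)
#' @export
retention_curve <- function(l50 = 25, delta = 3) {
  stopifnot(is.finite(l50), is.finite(delta))
  if (delta <= 0) stop("retention width `delta` must be positive")
  structure(list(l50 = l50, delta = delta), class = "retention_curve")
}

#' @rdname retention_curve
#' @param sl Vector of standard lengths (mm).
#' @param curve A `"retention_curve"`, or `NULL` for a non-selective net
#'   (retention identically 1).
#' @export
retention_prob <- function(sl, curve) {
  if (is.null(curve)) return(rep(1, length(sl)))
  stopifnot(inherits(curve, "retention_curve"))
  stats::plogis((sl - curve$l50) / curve$delta)
}

#' @export
print.retention_curve <- function(x, ...) {
  cat(sprintf("Logistic net retention: l50 = %g mm, width = %g mm\n",
              x$l50, x$delta))
  invisible(x)
}

#' Predation-selection specification
#'
#' Describes how a predator samples the prey population. `kind = "random"`
#' gives every individual equal weight; `"size"` down-weights long fish by a
#' decreasing logistic in SL; `"growth"` down-weights fast growers by a
#' decreasing logistic in the age-standardised length residual
#' `SL - (beta0 + beta1 * age)`, so slow growers (negative residual) are
#' preferred independent of age.
#'
#' @param kind One of `"random"`, `"size"`, `"growth"`.
#' @param half Half-selection point: SL (mm) for `"size"`, residual SL (mm)
#'   for `"growth"`. Ignored for `"random"`.
#' @param width Logistic width (mm), positive. Ignored for `"random"`.
#' @return An object of class `"selection_spec"`.
#' @export
selection_spec <- function(kind = c("random", "size", "growth"),
                           half = NA_real_, width = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "random") {
    stopifnot(is.finite(half), is.finite(width))
    if (width <= 0) stop("selection `width` must be positive")
  }
  structure(list(kind = kind, half = half, width = width),
            class = "selection_spec")
}

#' Gastric evacuation line
#'
#' Linear decline of the digestion ratio (stomach weight as a percentage of
#' the reconstructed prey weight) with time since ingestion,
#' `DR = slope * t + intercept` with `t` in minutes. The default coefficients
#' are an empirical squid evacuation line measured at 17 degrees C
#' (slope -0.176 %/min, intercept 59.462 %); both are configurable because
#' evacuation rate varies with temperature and species.
#'
#' @param slope Evacuation slope (% per minute); must be negative.
#' @param intercept DR at ingestion time (%).
#' @return An object of class `"evacuation_model"`.
#' @export
evacuation_model <- function(slope = -0.176, intercept = 59.462) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (slope >= 0) stop("evacuation `slope` must be negative")
  structure(list(slope = slope, intercept = intercept),
            class = "evacuation_model")
}

#' Otolith growth parameters for simulation
#'
#' Controls how synthetic otoliths are derived from body size: radius grows
#' proportionally with SL above the hatch anchor,
#' `R = hatch_radius + radius_per_mm * (SL - hatch_sl)`, and one increment is
#' deposited per day starting at `hatch_age` days post-hatch.
#'
#' @param hatch_radius Radius at first increment (um).
#' @param radius_per_mm Radius gained per mm of SL (um/mm).
#' @param hatch_sl Length at first increment (mm).
#' @param hatch_age Age at first increment (days post-hatch).
#' @return An object of class `"otolith_growth_params"`.
#' @export
otolith_growth_params <- function(hatch_radius = 10, radius_per_mm = 10,
                                  hatch_sl = 3, hatch_age = 2) {
  stopifnot(hatch_radius > 0, radius_per_mm > 0, hatch_sl > 0, hatch_age >= 0)
  structure(list(hatch_radius = hatch_radius, radius_per_mm = radius_per_mm,
                 hatch_sl = hatch_sl, hatch_age = hatch_age),
            class = "otolith_growth_params")
}

#' Population parameters for simulation
#'
#' The original prey population before predation and net sampling: ages on
#' `age_range` (uniform, or a mixture of Gaussian hatch cohorts), mean length
#' linear in age, `SL | age ~ Normal(beta0 + beta1 * age, sigma^2)`, weight by
#' allometry. Defaults describe a juvenile population spanning roughly
#' 17-75 mm over 20-60 days post-hatch.
#'
#' @param n Number of individuals; positive.
#' @param age_range Integer age range in days post-hatch, length 2,
#'   non-degenerate.
#' @param beta0 SL intercept (mm).
#' @param beta1 Growth slope (mm/day); positive.
#' @param sigma Residual SD of SL given age (mm); non-negative.
#' @param cohorts Optional Gaussian age-cohort mixture: a list with numeric
#'   vectors `mean`, `sd` and `prop` (proportions summing to 1). When given,
#'   ages are drawn from the mixture, rounded to days and clamped to
#'   `age_range`, emulating multi-modal hatch-date structure.
#' @return An object of class `"population_params"`.
#' @export
population_params <- function(n = 10000, age_range = c(20, 60),
                              beta0 = -5, beta1 = 1.1, sigma = 3,
                              cohorts = NULL) {
  stopifnot(length(age_range) == 2)
  if (!all(is.finite(c(n, age_range, beta0, beta1, sigma))))
    stop("population parameters must be finite")
  if (n <= 0) stop("`n` must be positive")
  if (beta1 <= 0) stop("growth slope `beta1` must be positive")
  if (sigma < 0) stop("residual SD `sigma` must be non-negative")
  if (age_range[2] <= age_range[1]) stop("`age_range` must be non-degenerate")
  if (!is.null(cohorts)) {
    stopifnot(is.list(cohorts),
              all(c("mean", "sd", "prop") %in% names(cohorts)),
              length(cohorts$mean) == length(cohorts$sd),
              length(cohorts$mean) == length(cohorts$prop))
    if (abs(sum(cohorts$prop) - 1) > 1e-8)
      stop("cohort proportions must sum to 1")
  }
  structure(list(n = as.integer(n), age_range = age_range, beta0 = beta0,
                 beta1 = beta1, sigma = sigma, cohorts = cohorts),
            class = "population_params")
}
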