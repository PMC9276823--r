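# Feeding-habit metrics: digestion state and timing, occurrence rates,
# predator-prey mass ratios, and covariate regressions.

#' Digestion ratio of a stomach
#'
#' The digestion ratio (DR) is the wet weight of the predator's stomach
#' expressed as a percentage of the reconstructed wet weight of the prey it
#' contains, `DR = 100 * stomach / prey`. It is only meaningful when the
#' stomach contains the focal prey species alone; mixed-prey stomachs should
#' be excluded upstream. A missing stomach weight yields `NA` (some survey
#' years did not weigh stomachs).
#'
#' @param stomach_weight Stomach wet weight (g); `NA` allowed.
#' @param prey_weight_total Summed reconstructed prey wet weight (g); must be
#'   positive.
#' @return DR in percent.
#' @examples
#' digestion_ratio(1, 2)  # 50
#' @export
digestion_ratio <- function(stomach_weight, prey_weight_total) {
  if (any(prey_weight_total <= 0, na.rm = TRUE))
    stop("total prey weight must be positive")
  100 * stomach_weight / prey_weight_total
}

#' Invert the gastric evacuation line to a digestion duration
#'
#' Given the evacuation line `DR = slope * t + intercept`, the time since
#' ingestion is `t = (intercept - DR) / (-slope)` minutes. A DR above the
#' intercept means the prey is fresher than the line can represent; the
#' duration is clamped to 0 and flagged. With `convention = "digested"` the
#' input is interpreted as the percentage already digested and `100 - DR`
#' enters the line instead.
#'
#' @param dr Digestion ratio (%), non-negative; `NA` propagates.
#' @param model An [evacuation_model()].
#' @param convention `"remaining"` (default: DR is stomach weight relative to
#'   prey weight) or `"digested"`.
#' @return A data frame with `duration` (minutes) and logical `fresh`
#'   (TRUE when DR exceeded the intercept and the duration was clamped).
#' @examples
#' digestion_duration(24.262)$duration  # 200 minutes under the default line
#' @export
digestion_duration <- function(dr, model = evacuation_model(),
                               convention = c("remaining", "digested")) {
  stopifnot(inherits(model, "evacuation_model"))
  convention <- match.arg(convention)
  if (any(dr < 0, na.rm = TRUE)) stop("DR must be non-negative")
  if (convention == "digested") dr <- 100 - dr
  t <- (model$intercept - dr) / (-model$slope)
  fresh <- !is.na(t) & t < 0
  t[fresh] <- 0
  data.frame(duration = t, fresh = fresh)
}

#' Clock time of predation
#'
#' Subtracts the digestion duration from the capture time (the tow midpoint),
#' wrapping across midnight: a fish caught at 06:29 with a 330-minute
#' digestion history was eaten at 00:59.
#'
#' @param capture_time Character vector `"HH:MM"` (24 h clock).
#' @param duration Minutes since predation; non-negative.
#' @return Character vector `"HH:MM"` of predation times.
#' @export
time_at_predation <- function(capture_time, duration) {
  if (any(duration < 0, na.rm = TRUE)) stop("duration must be non-negative")
  parts <- regmatches(capture_time,
                      regexec("^([0-9]{1,2}):([0-9]{2})", capture_time))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad & !is.na(capture_time))) stop("capture times must be 'HH:MM'")
  mins <- vapply(parts, function(p)
    if (length(p) == 3L) as.numeric(p[2]) * 60 + as.numeric(p[3]) else NA_real_, 0)
  at <- (mins - duration) %% (24 * 60)
  ifelse(is.na(at), NA_character_,
         sprintf("%02d:%02d", floor(at / 60), round(at %% 60)))
}

#' Occurrence rate of the focal prey
#'
#' Percentage of analysed predator stomachs that contained the focal prey,
#' reported to one decimal place.
#'
#' @param n_with_prey Number of stomachs containing the prey.
#' @param n_stomachs Total analysed stomachs; positive.
#' @return Occurrence rate in percent.
#' @examples
#' occurrence_rate(4, 50)   # 8.0
#' occurrence_rate(6, 23)   # 26.1
#' @export
occurrence_rate <- function(n_with_prey, n_stomachs) {
  if (any(n_stomachs <= 0)) stop("need at least one analysed stomach")
  if (any(n_with_prey < 0) || any(n_with_prey > n_stomachs))
    stop("`n_with_prey` must lie in [0, n_stomachs]")
  round(100 * n_with_prey / n_stomachs, 1)
}

#' Predator-prey mass ratio
#'
#' Predator wet weight divided by the (reconstructed) wet weight of an
#' individual prey. Scale-invariant: rescaling both masses by a common factor
#' leaves the ratio unchanged.
#'
#' @param predator_weight,prey_weight Wet weights (g); both positive.
#' @return The mass ratio.
#' @export
ppmr <- function(predator_weight, prey_weight) {
  if (any(predator_weight <= 0) || any(prey_weight <= 0))
    stop("weights must be positive")
  predator_weight / prey_weight
}

#' Build the predation-event table
#'
#' Joins reconstructed prey individuals to their host predators and computes,
#' per stomach, the digestion ratio, duration and predation time, and per
#' prey, the PPMR. Stomachs with missing weight keep `NA` digestion fields
#' and are flagged.
#'
#' @param prey A data frame of consumed prey with columns `host_id`, `sl`
#'   (mm) and optionally `weight` (g, reconstructed if absent).
#' @param squid A data frame of predators with columns `squid_id`, `ml`,
#'   `weight`, `stomach_weight`, `capture_time`, `lunar`.
#' @param calib A [calibration()] (used when prey weight must be
#'   reconstructed from SL).
#' @param evac An [evacuation_model()].
#' @return A data frame with one row per prey individual: host and prey
#'   identifiers, weights, `dr`, `duration`, `fresh`, `time_at_predation`,
#'   `ppmr`, `lunar`, `ml`.
#' @export
build_events <- function(prey, squid, calib = calibration(),
                         evac = evacuation_model()) {
  stopifnot(is.data.frame(prey), is.data.frame(squid),
            all(c("host_id", "sl") %in% names(prey)),
            all(c("squid_id", "ml", "weight") %in% names(squid)))
  if (is.null(prey$weight)) prey$weight <- sl_to_weight(prey$sl, calib)
  idx <- match(prey$host_id, squid$squid_id)
  if (anyNA(idx)) stop("prey host_id not found among squid records")
  totals <- tapply(prey$weight, prey$host_id, sum)
  stow <- if (is.null(squid$stomach_weight)) rep(NA_real_, nrow(squid)) else squid$stomach_weight
  dr_host <- digestion_ratio(stow[match(names(totals), squid$squid_id)],
                             as.numeric(totals))
  names(dr_host) <- names(totals)
  dr <- dr_host[prey$host_id]
  dur <- digestion_duration(ifelse(is.na(dr), 0, dr), evac)
  dur$duration[is.na(dr)] <- NA_real_
  dur$fresh[is.na(dr)] <- NA
  ct <- if (is.null(squid$capture_time)) NA_character_ else squid$capture_time[idx]
  data.frame(
    host_id = prey$host_id,
    site = if (is.null(squid$site)) NA_character_ else squid$site[idx],
    ml = squid$ml[idx],
    predator_weight = squid$weight[idx],
    prey_sl = prey$sl,
    prey_weight = prey$weight,
    dr = as.numeric(dr),
    duration = dur$duration,
    fresh = dur$fresh,
    time_at_predation = time_at_predation(ct, ifelse(is.na(dur$duration), 0, dur$duration)),
    ppmr = ppmr(squid$weight[idx], prey$weight),
    lunar = if (is.null(squid$lunar)) NA_real_ else squid$lunar[idx],
    row.names = NULL
  )
}

#' Regress feeding metrics on a covariate
#'
#' Ordinary least squares of prey wet weight and log10 PPMR on a covariate
#' (lunar illumination or predator mantle length), with a two-sided test of
#' the slope.
#'
#' @param events An event table from [build_events()] (needs `prey_weight`,
#'   `ppmr` and the covariate column).
#' @param covariate `"lunar"` or `"ml"`.
#' @return A data frame with one row per response (`prey_weight`,
#'   `log10_ppmr`): slope, intercept, `r_squared`, `p_value`, `n`.
#' @export
feeding_regressions <- function(events, covariate = c("lunar", "ml")) {
  covariate <- match.arg(covariate)
  x <- events[[covariate]]
  keep <- is.finite(x)
  if (sum(keep) < 3) stop("need at least 3 events with a finite covariate")
  if (stats::sd(x[keep]) == 0) stop("covariate is constant; slope undefined")
  fit_one <- function(y, label) {
    ok <- keep & is.finite(y)
    if (stats::sd(y[ok]) == 0) {
      # constant response: zero slope, nothing to test
      return(data.frame(response = label, covariate = covariate, slope = 0,
                        intercept = y[ok][1], r_squared = 0, p_value = 1,
                        n = sum(ok)))
    }
    m <- stats::lm(y[ok] ~ x[ok])
    s <- summary(m)
    data.frame(response = label, covariate = covariate,
               slope = unname(stats::coef(m)[2]),
               intercept = unname(stats::coef(m)[1]),
               r_squared = s$r.squared,
               p_value = s$coefficients[2, 4],
               n = sum(ok))
  }
  rbind(fit_one(events$prey_weight, "prey_weight"),
        fit_one(log10(events$ppmr), "log10_ppmr"))
}
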