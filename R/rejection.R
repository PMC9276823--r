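# Head-rejection screening: squids may reject the head of prey that are
# large relative to their own mass (PPMR below about 13.2), which would
# deplete large prey from stomach samples and mimic size-selective predation.
# Sites showing that signature are excluded from selectivity fitting.

#' Site-level SL threshold for potential head rejection
#'
#' Divides each predator's wet weight by the critical mass ratio (13.2),
#' converts the resulting prey mass to SL through the inverse allometry, and
#' averages over predators at the site. Prey longer than this threshold are
#' "unpalatable": their heads may be rejected rather than swallowed.
#'
#' @param squid_weights Predator wet weights (g) at the site; positive.
#' @param calib A [calibration()] supplying the SL-weight allometry.
#' @param critical_ppmr Mass ratio below which head rejection is expected.
#' @return Threshold SL in mm.
#' @export
threshold_sl <- function(squid_weights, calib = calibration(),
                         critical_ppmr = 13.2) {
  if (length(squid_weights) == 0) stop("need at least one squid weight")
  if (any(squid_weights <= 0)) stop("squid weights must be positive")
  mean(weight_to_sl(squid_weights / critical_ppmr, calib))
}

#' Upper bound on the expected unpalatable proportion under rejection
#'
#' If a predator feeds randomly on a population containing `alpha` %
#' unpalatable individuals and rejects their heads with probability 60-100%,
#' the proportion of unpalatable individuals whose otoliths reach the stomach
#' is between 0 and
#' \deqn{U(\alpha) = 0.4 \alpha \cdot 100 / (100 - 0.6 \alpha)}
#' percent. `U` is increasing in `alpha` and never exceeds `alpha`.
#'
#' @param alpha Percentage of unpalatable individuals in the population
#'   (netted sample), in \[0, 100\].
#' @return Upper bound in percent.
#' @examples
#' round(expected_rejection_bound(74.4), 1)  # 53.8
#' @export
expected_rejection_bound <- function(alpha) {
  if (any(alpha < 0) || any(alpha > 100))
    stop("`alpha` must lie in [0, 100]")
  0.4 * alpha * 100 / (100 - 0.6 * alpha)
}

#' Screen one site for head-rejection bias
#'
#' Computes the unpalatable proportions among netted (`alpha_n`) and consumed
#' (`alpha_c`) juveniles, using strict inequality `SL > threshold`, and flags
#' the site when `alpha_n > 5` % and `alpha_c` falls below the rejection
#' bound `U(alpha_n)`: a depleted unpalatable fraction in the stomachs is
#' then consistent with head rejection, and the site must be excluded from
#' selectivity fitting. An empty consumed set gives `alpha_c = 0` and the
#' screen is still evaluated.
#'
#' @param netted_sl SLs (mm) of netted juveniles; non-empty.
#' @param consumed_sl SLs (mm) of consumed juveniles; may be empty.
#' @param threshold Site threshold SL (mm) from [threshold_sl()].
#' @param site Optional site label carried through to the report.
#' @return A one-row data frame: `site`, `threshold_sl`, `alpha_n`,
#'   `alpha_c`, `expected_upper`, `flagged`.
#' @export
screen_site <- function(netted_sl, consumed_sl, threshold, site = NA) {
  if (length(netted_sl) == 0) stop("need a non-empty netted sample")
  alpha_n <- 100 * mean(netted_sl > threshold)
  alpha_c <- if (length(consumed_sl)) 100 * mean(consumed_sl > threshold) else 0
  upper <- expected_rejection_bound(alpha_n)
  data.frame(site = site, threshold_sl = threshold,
             alpha_n = alpha_n, alpha_c = alpha_c,
             expected_upper = upper,
             flagged = alpha_n > 5 && alpha_c < upper)
}

#' Screen every site in a survey
#'
#' Applies [threshold_sl()] and [screen_site()] per site of a fish/squid
#' table pair.
#'
#' @param fish Fish records with columns `site`, `sl`, `source`
#'   (`"netted"`/`"consumed"`).
#' @param squid Squid records with columns `site`, `weight`.
#' @param calib A [calibration()].
#' @return A data frame with one row per site (the screen report).
#' @export
screen_sites <- function(fish, squid, calib = calibration()) {
  stopifnot(all(c("site", "sl", "source") %in% names(fish)),
            all(c("site", "weight") %in% names(squid)))
  out <- lapply(unique(fish$site), function(st) {
    f <- fish[fish$site == st, ]
    sw <- squid$weight[squid$site == st]
    if (!length(sw)) return(NULL)
    screen_site(f$sl[f$source == "netted"], f$sl[f$source == "consumed"],
                threshold_sl(sw, calib), site = st)
  })
  do.call(rbind, out)
}
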