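# Otolith processing: ageing, radius->length->mass reconstruction,
# biological-intercept back-calculation, left/right pairing.

#' Estimate age from an otolith increment count
#'
#' Daily increments begin to form at the hatch anchor age (2 days post-hatch
#' by default), so age in days equals the increment count plus that anchor.
#'
#' @param n_increments Non-negative integer vector of increment counts.
#' @param hatch_age Age at first increment deposition (days).
#' @return Integer ages in days post-hatch.
#' @examples
#' estimate_age(28)  # 30 dph
#' @export
estimate_age <- function(n_increments, hatch_age = 2) {
  if (any(!is.finite(n_increments)) || any(n_increments < 0))
    stop("increment counts must be non-negative")
  as.integer(n_increments + hatch_age)
}

#' Reconstruct standard length from otolith radius
#'
#' Applies the linear radius-SL calibration `SL = c0 + c1 * R`. Used for
#' consumed fish, whose body length cannot be measured directly.
#'
#' @param radius Otolith radius (um), positive.
#' @param calib A [calibration()].
#' @return Standard length (mm).
#' @export
reconstruct_sl_from_radius <- function(radius, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (any(!is.finite(radius)) || any(radius < 0))
    stop("otolith radii must be non-negative")
  sl <- calib$c0 + calib$c1 * radius
  if (any(sl <= 0))
    stop("reconstructed SL is non-positive: radius-SL calibration mismatch")
  sl
}

#' Allometric length-weight conversions
#'
#' `sl_to_weight()` applies `W = p * SL^q`; `weight_to_sl()` inverts it,
#' `SL = (W / p)^(1/q)`. The two are exact inverses on the positive domain.
#'
#' @param sl Standard length (mm), positive.
#' @param weight Wet weight (g), positive.
#' @param calib A [calibration()].
#' @return Weight in g, or SL in mm.
#' @export
sl_to_weight <- function(sl, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (any(sl <= 0)) stop("SL must be positive")
  calib$p * sl^calib$q
}

#' @rdname sl_to_weight
#' @export
weight_to_sl <- function(weight, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (any(weight <= 0)) stop("weight must be positive")
  (weight / calib$p)^(1 / calib$q)
}

#' Biological-intercept back-calculation of length at age
#'
#' Reconstructs the SL-at-age series of one fish from its otolith increment
#' widths, anchoring the otolith-size to body-size relation at the hatch
#' point (`hatch_radius`, `hatch_sl`) and at capture
#' (`radius_capture`, `sl_capture`):
#' \deqn{SL(a) = SL_h + (R(a) - R_h) (SL_c - SL_h) / (R_c - R_h)}
#' where `R(a)` is the hatch radius plus the cumulative increment widths laid
#' down through age `a`. Increment widths whose cumulative sum disagrees with
#' `radius_capture - hatch_radius` by at most 1% are rescaled proportionally
#' so the series ends exactly at the measured length; a larger mismatch
#' triggers a warning. If `widths` is `NULL`, equal widths are assumed from
#' the radius and count (logged as a data-quality note).
#'
#' @param radius_capture Otolith radius at capture (um); must exceed the
#'   hatch radius.
#' @param sl_capture SL at capture (mm), measured (netted) or reconstructed
#'   from the radius (consumed); must exceed the hatch SL.
#' @param widths Numeric vector of per-increment widths (um), or `NULL`.
#' @param n_increments Increment count, required when `widths` is `NULL`.
#' @param calib A [calibration()] providing the hatch anchor.
#' @return A data frame with columns `age` (days, from the hatch age to the
#'   capture age) and `sl` (mm); the first row is the hatch anchor.
#' @examples
#' bc <- back_calculate_sl(110, 43, widths = rep(10, 10),
#'                         calib = calibration(hatch_radius = 10, hatch_sl = 3))
#' tail(bc, 1)$sl  # equals the capture SL
#' @export
back_calculate_sl <- function(radius_capture, sl_capture, widths = NULL,
                              n_increments = NULL, calib = calibration()) {
  stopifnot(inherits(calib, "calibration"))
  if (radius_capture <= calib$hatch_radius)
    stop("capture radius must exceed the hatch radius (degenerate fish)")
  if (sl_capture <= calib$hatch_sl)
    stop("capture SL must exceed the hatch SL")
  if (is.null(widths)) {
    if (is.null(n_increments) || n_increments < 1)
      stop("need `widths` or a positive `n_increments`")
    message("no increment widths supplied; assuming equal widths")
    widths <- rep((radius_capture - calib$hatch_radius) / n_increments,
                  n_increments)
  }
  if (any(widths < 0)) stop("increment widths must be non-negative")
  total <- sum(widths)
  target <- radius_capture - calib$hatch_radius
  if (abs(total - target) > 0.01 * radius_capture)
    warning(sprintf(
      "cumulative increment widths (%.3g um) disagree with capture radius by >1%%",
      total))
  widths <- widths * (target / total)  # anchor the series at capture exactly
  or <- calib$hatch_radius + c(0, cumsum(widths))
  sl <- calib$hatch_sl + (or - calib$hatch_radius) *
    (sl_capture - calib$hatch_sl) / (radius_capture - calib$hatch_radius)
  data.frame(age = calib$hatch_age + seq_along(or) - 1L, sl = sl)
}

# Optimal left-right matching within one stomach: maximise the number of
# pairs with |dSL| below the threshold, break ties by minimal total |dSL|.
# Exhaustive recursion; stomachs hold at most a handful of prey.
match_sides <- function(d, thr) {
  nl <- nrow(d); nr <- ncol(d)
  best <- list(pairs = -1L, cost = Inf, assign = rep(NA_integer_, nl))
  recurse <- function(i, used, assign, npairs, cost) {
    if (i > nl) {
      if (npairs > best$pairs ||
          (npairs == best$pairs && cost < best$cost))
        best <<- list(pairs = npairs, cost = cost, assign = assign)
      return(invisible())
    }
    recurse(i + 1L, used, assign, npairs, cost)  # leave left i unpaired
    for (j in seq_len(nr)) {
      if (!used[j] && d[i, j] < thr) {
        used[j] <- TRUE; assign[i] <- j
        recurse(i + 1L, used, assign, npairs + 1L, cost + d[i, j])
        used[j] <- FALSE; assign[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, nr), rep(NA_integer_, nl), 0L, 0)
  best$assign
}

#' Pair left and right otoliths from one stomach into individuals
#'
#' Multiple otoliths recovered from a stomach must be grouped into prey
#' individuals. A left and a right otolith are taken to come from the same
#' fish when their reconstructed lengths differ by less than `threshold`
#' (2 mm). When several candidate matchings satisfy the rule, the assignment
#' maximising the number of pairs and minimising the total length difference
#' is used, so the result is deterministic and independent of input order.
#' Unmatched otoliths become singleton individuals. Each individual's SL is
#' taken from its left otolith where available, otherwise from the right.
#'
#' @param reads A data frame of otolith reads from one stomach with columns
#'   `side` (`"left"`/`"right"`) and `radius` (um), plus any id columns.
#' @param calib A [calibration()] for radius-SL reconstruction.
#' @param threshold Maximum |SL difference| (mm) for a pair; default 2.
#' @return `reads` with added columns `sl_est` (per-read reconstructed SL),
#'   `individual` (integer label within the stomach) and `sl` (the
#'   individual's SL, from the left side when present).
#' @export
pair_otoliths <- function(reads, calib = calibration(), threshold = 2) {
  stopifnot(is.data.frame(reads), all(c("side", "radius") %in% names(reads)))
  if (!all(reads$side %in% c("left", "right")))
    stop("otolith `side` must be 'left' or 'right'")
  reads$sl_est <- reconstruct_sl_from_radius(reads$radius, calib)
  li <- which(reads$side == "left"); ri <- which(reads$side == "right")
  reads$individual <- NA_integer_
  if (length(li) && length(ri)) {
    d <- abs(outer(reads$sl_est[li], reads$sl_est[ri], "-"))
    assign <- match_sides(d, threshold)
    k <- 0L
    for (i in seq_along(li)) {
      if (!is.na(assign[i])) {
        k <- k + 1L
        reads$individual[c(li[i], ri[assign[i]])] <- k
      }
    }
  }
  singles <- which(is.na(reads$individual))
  if (length(singles))
    reads$individual[singles] <- max(0L, reads$individual, na.rm = TRUE) +
      seq_along(singles)
  # individual's SL: left read if present, else right
  sl_of <- vapply(split(seq_len(nrow(reads)), reads$individual), function(ix) {
    lft <- ix[reads$side[ix] == "left"]
    reads$sl_est[if (length(lft)) lft[1] else ix[1]]
  }, 0)
  reads$sl <- sl_of[as.character(reads$individual)]
  reads
}
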