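# Synthetic survey generator: known-truth populations, net samples, consumed
# samples, otolith series and predator records for end-to-end validation.

#' Generate an original prey population
#'
#' Draws individuals with integer ages on the configured range (uniform by
#' default, or a Gaussian cohort mixture), lengths from the linear age-SL law
#' with Gaussian residuals, and weights from the allometric calibration.
#'
#' @param params A [population_params()] object.
#' @param calib A [calibration()] used for the SL-weight allometry.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `id`, `age` (days), `sl` (mm),
#'   `weight` (g).
#' @examples
#' pop <- generate_population(population_params(n = 100), seed = 1)
#' head(pop)
#' @export
generate_population <- function(params = population_params(),
                                calib = calibration(), seed = NULL) {
  stopifnot(inherits(params, "population_params"),
            inherits(calib, "calibration"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  ages <- if (is.null(params$cohorts)) {
    sample(seq(params$age_range[1], params$age_range[2]), n, replace = TRUE)
  } else {
    comp <- sample(length(params$cohorts$prop), n, replace = TRUE,
                   prob = params$cohorts$prop)
    a <- round(stats::rnorm(n, params$cohorts$mean[comp],
                            params$cohorts$sd[comp]))
    pmin(pmax(a, params$age_range[1]), params$age_range[2])
  }
  sl <- params$beta0 + params$beta1 * ages +
    stats::rnorm(n, 0, params$sigma)
  sl <- pmax(sl, calib$hatch_sl)  # physical floor: no fish below hatch size
  data.frame(id = seq_len(n), age = as.integer(ages), sl = sl,
             weight = sl_to_weight(sl, calib))
}

#' Draw a net sample from a population
#'
#' Each individual is retained independently with probability given by the
#' logistic retention curve; `n` fish are then drawn without replacement from
#' the retained set. Because retention increases with length, the net sample
#' over-represents long fish relative to the population.
#'
#' @param population A population data frame from [generate_population()].
#' @param retention A [retention_curve()], or `NULL` for a non-selective net.
#' @param n Sample size requested; if fewer fish are retained, all retained
#'   fish are returned with a warning.
#' @param seed Optional integer seed.
#' @return A data frame of fish records with `source = "netted"`.
#' @export
sample_net_catch <- function(population, retention, n, seed = NULL) {
  stopifnot(is.data.frame(population), n >= 0, n <= nrow(population))
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(population)) < retention_prob(population$sl, retention)
  retained <- population[keep, , drop = FALSE]
  if (nrow(retained) < n) {
    warning(sprintf("only %d of the requested %d fish were retained by the net",
                    nrow(retained), n))
    out <- retained
  } else {
    out <- retained[sample(nrow(retained), n), , drop = FALSE]
  }
  out$source <- rep("netted", nrow(out))
  rownames(out) <- NULL
  out
}

# Relative predation weight for each individual under a selection spec.
selection_weights <- function(population, spec, beta0, beta1) {
  switch(spec$kind,
    random = rep(1, nrow(population)),
    size   = stats::plogis((spec$half - population$sl) / spec$width),
    growth = {
      resid <- population$sl - (beta0 + beta1 * population$age)
      stats::plogis((spec$half - resid) / spec$width)
    }
  )
}

#' Draw a consumed (predated) sample from a population
#'
#' Individuals are sampled without replacement with probability proportional
#' to the predation weight of the selection spec: uniform (`random`),
#' decreasing logistic in SL (`size`), or decreasing logistic in the
#' age-standardised residual SL (`growth`). Growth selection therefore prefers
#' slow growers while leaving the age distribution untouched.
#'
#' @param population A population data frame from [generate_population()].
#' @param spec A [selection_spec()].
#' @param n Number of consumed fish; at least 1.
#' @param params The [population_params()] that generated the population
#'   (supplies the true age-SL line for the growth residual). Required for
#'   `kind = "growth"`.
#' @param seed Optional integer seed.
#' @return A data frame of fish records with `source = "consumed"`.
#' @export
sample_consumed <- function(population, spec, n, params = NULL, seed = NULL) {
  stopifnot(is.data.frame(population), inherits(spec, "selection_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (spec$kind == "growth" && is.null(params))
    stop("growth selection needs `params` for the population age-SL line")
  w <- selection_weights(population, spec,
                         if (is.null(params)) 0 else params$beta0,
                         if (is.null(params)) 0 else params$beta1)
  if (all(w == 0)) stop("all predation weights are zero under this spec")
  out <- population[sample(nrow(population), n, prob = w), , drop = FALSE]
  out$source <- rep("consumed", nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate otolith reads for a set of fish
#'
#' Emits one left and one right otolith per fish. The increment count is
#' `age - hatch_age` (one increment per day from the hatch anchor); the
#' capture radius follows the proportional radius-SL law plus additive
#' Gaussian measurement noise (independently per side, so left and right
#' differ only by noise). Increment widths are equal, consistent with the
#' linear mean growth of the generator. Radii that would fall below the hatch
#' radius are clipped there.
#'
#' @param fish A fish data frame (columns `id`, `age`, `sl`).
#' @param og An [otolith_growth_params()] object.
#' @param noise_sd Measurement noise SD in um, or the string `"relative"` for
#'   the default 1% of each radius.
#' @param seed Optional integer seed.
#' @return A data frame with one row per otolith: `fish_id`, `side`,
#'   `radius`, `n_increments` and a list column `widths` of per-increment
#'   widths (um).
#' @export
generate_otoliths <- function(fish, og = otolith_growth_params(),
                              noise_sd = "relative", seed = NULL) {
  stopifnot(is.data.frame(fish), inherits(og, "otolith_growth_params"))
  if (any(fish$age < og$hatch_age))
    stop("all fish must be at least hatch_age days old")
  if (!is.null(seed)) set.seed(seed)
  base <- og$hatch_radius + og$radius_per_mm * (fish$sl - og$hatch_sl)
  sd_um <- if (identical(noise_sd, "relative")) 0.01 * base else noise_sd
  one_side <- function(side) {
    r <- base + stats::rnorm(nrow(fish), 0, sd_um)
    clipped <- r < og$hatch_radius
    if (any(clipped)) {
      message(sprintf("%d otolith radii clipped at the hatch radius", sum(clipped)))
      r[clipped] <- og$hatch_radius
    }
    ninc <- as.integer(fish$age - og$hatch_age)
    data.frame(fish_id = fish$id, side = side, radius = r,
               n_increments = ninc,
               widths = I(lapply(seq_along(r), function(i) {
                 if (ninc[i] == 0) numeric(0)
                 else rep((r[i] - og$hatch_radius) / ninc[i], ninc[i])
               })))
  }
  out <- rbind(one_side("left"), one_side("right"))
  out <- out[order(out$fish_id, out$side), ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete predation survey
#'
#' Generates, for each configured site, an original population, a net sample,
#' a consumed sample distributed across predator stomachs, otolith reads for
#' every sampled fish, and predator (squid) records with mantle length,
#' weight, stomach weight consistent with the evacuation line, capture time
#' and lunar illumination. Ground-truth population parameters are carried in
#' the attributes so downstream estimates can be checked against them.
#'
#' @param sites A data frame describing sites: columns `site`, `year`, and
#'   optionally `lunar` (% illumination), `capture_time` ("HH:MM"),
#'   `n_netted`, `n_consumed`, `n_squid`. Missing columns get defaults.
#' @param params A [population_params()] shared by all sites.
#' @param spec A [selection_spec()] for the predation process.
#' @param retention A [retention_curve()] or `NULL`.
#' @param calib A [calibration()].
#' @param og An [otolith_growth_params()].
#' @param evac An [evacuation_model()] used to make stomach weights
#'   consistent with a random digestion time.
#' @param otolith_noise Passed to [generate_otoliths()].
#' @param seed Integer seed; the whole survey is reproducible given it.
#' @return A list of data frames `fish`, `otoliths`, `squid`, `sites`, with
#'   attribute `truth` recording the generator parameters.
#' @export
simulate_survey <- function(sites = data.frame(site = "St.01", year = 2008),
                            params = population_params(),
                            spec = selection_spec("growth", half = -2, width = 2),
                            retention = retention_curve(),
                            calib = calibration(),
                            og = otolith_growth_params(),
                            evac = evacuation_model(),
                            otolith_noise = "relative",
                            seed = 1) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1, "site" %in% names(sites))
  set.seed(seed)
  defaults <- list(lunar = NA_real_, capture_time = "06:30",
                   n_netted = 50, n_consumed = 10, n_squid = 25)
  for (nm in names(defaults))
    if (is.null(sites[[nm]])) sites[[nm]] <- defaults[[nm]]
  sites$lunar[is.na(sites$lunar)] <- round(stats::runif(sum(is.na(sites$lunar)), 0, 100), 1)
  if (is.null(sites$year)) sites$year <- 2008L

  fish_all <- list(); oto_all <- list(); squid_all <- list()
  for (i in seq_len(nrow(sites))) {
    st <- sites$site[i]
    pop <- generate_population(params, calib)
    netted <- sample_net_catch(pop, retention, sites$n_netted[i])
    consumed <- sample_consumed(pop, spec, sites$n_consumed[i], params = params)
    netted$site <- st; consumed$site <- st
    netted$year <- sites$year[i]; consumed$year <- sites$year[i]

    # squid: mantle length 58-160 mm, weight roughly cubic in ML
    nsq <- sites$n_squid[i]
    ml <- stats::runif(nsq, 58, 160)
    sqw <- 3e-5 * ml^3 * exp(stats::rnorm(nsq, 0, 0.15))
    squid <- data.frame(squid_id = sprintf("%s-SQ%02d", st, seq_len(nsq)),
                        site = st, year = sites$year[i], ml = ml,
                        weight = sqw,
                        capture_time = sites$capture_time[i],
                        lunar = sites$lunar[i])

    # scatter consumed fish over the first ceiling(n_consumed/2) stomachs
    hosts <- sample(ceiling(sites$n_consumed[i] / 2),
                    sites$n_consumed[i], replace = TRUE)
    consumed$host_id <- squid$squid_id[hosts]
    netted$host_id <- NA_character_

    # stomach weight = digested fraction of the total consumed prey weight
    prey_w <- tapply(consumed$weight, consumed$host_id, sum)
    dr <- pmax(evac$intercept + evac$slope * stats::runif(nsq, 30, 300), 0)
    squid$stomach_weight <- 0
    squid$stomach_weight[match(names(prey_w), squid$squid_id)] <-
      as.numeric(prey_w) * dr[match(names(prey_w), squid$squid_id)] / 100

    fish <- rbind(netted, consumed)
    # unique ids across sites (population ids can repeat between samples)
    fish$fish_id <- sprintf("%s-F%04d", st, seq_len(nrow(fish)))
    oto <- generate_otoliths(data.frame(id = seq_len(nrow(fish)),
                                        age = fish$age, sl = fish$sl),
                             og, noise_sd = otolith_noise)
    oto$fish_id <- fish$fish_id[oto$fish_id]
    oto$host_id <- fish$host_id[match(oto$fish_id, fish$fish_id)]
    oto$site <- st
    oto$year <- sites$year[i]
    fish$id <- NULL
    fish_all[[i]] <- fish; oto_all[[i]] <- oto; squid_all[[i]] <- squid
  }
  out <- list(fish = do.call(rbind, fish_all),
              otoliths = do.call(rbind, oto_all),
              squid = do.call(rbind, squid_all),
              sites = sites)
  attr(out, "truth") <- list(params = params, spec = spec,
                             retention = retention, calib = calib, og = og,
                             evac = evac, seed = seed)
  out
}

#' Write a simulated survey to CSV files
#'
#' Emits `fish.csv`, `otoliths.csv`, `squid.csv` and `sites.csv` into `dir`.
#' Otolith increment-width lists are serialised as semicolon-separated values.
#'
#' @param survey A list from [simulate_survey()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_survey_csv <- function(survey, dir) {
  stopifnot(is.list(survey),
            all(c("fish", "otoliths", "squid", "sites") %in% names(survey)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  oto <- survey$otoliths
  oto$widths <- vapply(oto$widths, function(w) paste(signif(w, 8), collapse = ";"), "")
  paths <- c(fish = file.path(dir, "fish.csv"),
             otoliths = file.path(dir, "otoliths.csv"),
             squid = file.path(dir, "squid.csv"),
             sites = file.path(dir, "sites.csv"))
  utils::write.csv(survey$fish, paths["fish"], row.names = FALSE)
  utils::write.csv(oto, paths["otoliths"], row.names = FALSE)
  utils::write.csv(survey$squid, paths["squid"], row.names = FALSE)
  utils::write.csv(survey$sites, paths["sites"], row.names = FALSE)
  invisible(paths)
}
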