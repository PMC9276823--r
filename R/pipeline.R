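# Orchestration: YAML configuration, CSV I/O, schema validation, and the
# end-to-end otolith -> feeding -> rejection -> selectivity -> cohorts run.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], optionally
#' merged with overrides read from a YAML file by [read_config()]. Units:
#' lengths mm, masses g, radii um, ages integer days, times "HH:MM".
#'
#' @param data_dir Directory holding `fish.csv`, `otoliths.csv`, `squid.csv`,
#'   `sites.csv`.
#' @param out_dir Output directory for the report bundle.
#' @return A nested list of settings.
#' @export
default_config <- function(data_dir = ".", out_dir = "results") {
  list(
    paths = list(fish = file.path(data_dir, "fish.csv"),
                 otoliths = file.path(data_dir, "otoliths.csv"),
                 squid = file.path(data_dir, "squid.csv"),
                 sites = file.path(data_dir, "sites.csv")),
    calibration = list(c0 = 2, c1 = 0.1, p = 2e-5, q = 3,
                       hatch_sl = 3, hatch_age = 2, hatch_radius = 10),
    evacuation = list(slope = -0.176, intercept = 59.462),
    retention = list(l50 = 25, delta = 3),
    selection = list(B = 2000, seed = 1),
    cohorts = list(),        # named list: year -> k
    pairing_threshold = 2,   # mm
    age_bandwidth = 2,       # days
    out_dir = out_dir
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the YAML override the defaults; everything else keeps
#' its default. A `retention: ~` entry disables net-bias weighting.
#'
#' @param path Path to a YAML file.
#' @param data_dir,out_dir Defaults passed to [default_config()].
#' @return A configuration list.
#' @export
read_config <- function(path, data_dir = dirname(path), out_dir = "results") {
  cfg <- default_config(data_dir, out_dir)
  usr <- yaml::read_yaml(path)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  if ("retention" %in% names(usr) && is.null(usr$retention)) cfg$retention <- NULL
  merge_in(cfg, usr[!vapply(usr, is.null, TRUE)])
}

cfg_calibration <- function(cfg) do.call(calibration, cfg$calibration)
cfg_retention <- function(cfg)
  if (is.null(cfg$retention)) NULL else do.call(retention_curve, cfg$retention)
cfg_evacuation <- function(cfg) do.call(evacuation_model, cfg$evacuation)

#' Read an otolith CSV
#'
#' Expects columns `fish_id` (or `id`), `side`, `radius`, `n_increments` and
#' optionally `widths` (semicolon-separated um values) and `host_id`/`site`.
#'
#' @param path CSV path.
#' @return A data frame with `widths` parsed into a list column.
#' @export
read_otoliths_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$fish_id) && !is.null(d$id)) d$fish_id <- d$id
  if (!is.null(d$widths) && is.character(d$widths)) {
    d$widths <- I(lapply(strsplit(d$widths, ";", fixed = TRUE), as.numeric))
  }
  d
}

#' Validate the survey tables
#'
#' Column-presence, type and range checks on the four input tables. Issues
#' are aggregated rather than failing on the first; each names the table,
#' row and column concerned.
#'
#' @param paths Named list/vector with entries `fish`, `otoliths`, `squid`,
#'   `sites` (missing entries are skipped).
#' @return A data frame of issues (`table`, `row`, `column`, `severity`,
#'   `message`); zero rows when everything is well-formed.
#' @export
validate_tables <- function(paths) {
  issues <- list()
  add <- function(tab, row, col, sev, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      table = tab, row = row, column = col, severity = sev, message = msg)
  need <- function(d, tab, cols) {
    miss <- setdiff(cols, names(d))
    for (m in miss) add(tab, NA, m, "error", "required column missing")
    length(miss) == 0
  }
  rng <- function(d, tab, col, test, msg) {
    bad <- which(!test(d[[col]]))
    for (r in bad) add(tab, r, col, "error", msg)
  }
  if (!is.null(paths$fish) && file.exists(paths$fish)) {
    d <- utils::read.csv(paths$fish)
    if (need(d, "fish", c("fish_id", "site", "sl", "source"))) {
      rng(d, "fish", "sl", function(x) is.finite(x) & x > 0, "SL must be positive")
      rng(d, "fish", "source", function(x) x %in% c("netted", "consumed"),
          "source must be 'netted' or 'consumed'")
    }
  }
  if (!is.null(paths$otoliths) && file.exists(paths$otoliths)) {
    d <- read_otoliths_csv(paths$otoliths)
    if (need(d, "otoliths", c("fish_id", "side", "radius", "n_increments"))) {
      rng(d, "otoliths", "side", function(x) x %in% c("left", "right"),
          "side must be 'left' or 'right'")
      rng(d, "otoliths", "radius", function(x) is.finite(x) & x > 0,
          "radius must be positive")
      if (!is.null(d$widths)) {
        tot <- vapply(d$widths, sum, 0)
        bad <- which(tot > d$radius * 1.01)
        for (r in bad) add("otoliths", r, "widths", "warning",
                           "cumulative widths exceed capture radius by >1%")
      }
    }
  }
  if (!is.null(paths$squid) && file.exists(paths$squid)) {
    d <- utils::read.csv(paths$squid)
    if (need(d, "squid", c("squid_id", "site", "ml", "weight"))) {
      rng(d, "squid", "ml", function(x) is.finite(x) & x > 0, "ML must be positive")
      rng(d, "squid", "weight", function(x) is.finite(x) & x > 0,
          "weight must be positive")
      if (!is.null(d$lunar))
        rng(d, "squid", "lunar",
            function(x) is.na(x) | (x >= 0 & x <= 100),
            "lunar illumination must lie in [0, 100]")
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(table = character(), row = integer(), column = character(),
                  severity = character(), message = character())
}

# Reconstruct individual fish (netted and consumed) from the fish and
# otolith tables: age from increment counts, consumed SL from paired
# otoliths, back-calculated trajectory per individual (left otolith).
reconstruct_individuals <- function(fish, otoliths, calib, pairing_threshold) {
  fish$age <- NA_integer_
  records <- list(); series <- list()
  # netted fish: measured SL, ages from their left otolith
  netted <- fish[fish$source == "netted", , drop = FALSE]
  for (i in seq_len(nrow(netted))) {
    oto <- otoliths[otoliths$fish_id == netted$fish_id[i], , drop = FALSE]
    lft <- oto[oto$side == "left", , drop = FALSE]
    if (!nrow(lft)) lft <- oto
    if (!nrow(lft)) next
    age <- estimate_age(lft$n_increments[1], calib$hatch_age)
    rec <- data.frame(fish_id = netted$fish_id[i], site = netted$site[i],
                      year = if (is.null(netted$year)) NA else netted$year[i],
                      source = "netted", age = age, sl = netted$sl[i],
                      weight = sl_to_weight(netted$sl[i], calib),
                      host_id = NA_character_)
    records[[length(records) + 1]] <- rec
    series[[rec$fish_id]] <- back_calculate_sl(
      lft$radius[1], netted$sl[i], widths = lft$widths[[1]], calib = calib)
  }
  # consumed fish: pair otoliths within each stomach, reconstruct SL
  stomach <- otoliths[!is.na(otoliths$host_id) & otoliths$host_id != "", ,
                      drop = FALSE]
  for (h in unique(stomach$host_id)) {
    reads <- pair_otoliths(stomach[stomach$host_id == h, , drop = FALSE],
                           calib, threshold = pairing_threshold)
    for (ind in unique(reads$individual)) {
      rr <- reads[reads$individual == ind, , drop = FALSE]
      use <- rr[match("left", rr$side), , drop = FALSE]
      if (is.na(use$side[1])) use <- rr[1, , drop = FALSE]
      age <- estimate_age(use$n_increments[1], calib$hatch_age)
      id <- sprintf("%s-I%02d", h, ind)
      rec <- data.frame(fish_id = id,
                        site = if (is.null(use$site)) NA else use$site[1],
                        year = if (is.null(use$year)) NA else use$year[1],
                        source = "consumed", age = age, sl = use$sl[1],
                        weight = sl_to_weight(use$sl[1], calib), host_id = h)
      records[[length(records) + 1]] <- rec
      series[[id]] <- back_calculate_sl(
        use$radius[1], use$sl[1], widths = use$widths[[1]], calib = calib)
    }
  }
  list(records = do.call(rbind, records), series = series)
}

#' Run the full inference pipeline
#'
#' Executes, in order: table validation, otolith reconstruction (ageing,
#' pairing, back-calculation), feeding metrics (events table), the
#' head-rejection screen, selectivity model comparison for each site, each
#' year and all data pooled (rejection-flagged sites excluded from pooled
#' scopes), and cohort-wise growth-trajectory comparisons. Writes
#' `events.csv`, `screen.csv`, `fits.csv`, `trajectories.csv` and
#' `run_log.txt` into the configured output directory.
#'
#' @param config A configuration list from [default_config()] /
#'   [read_config()], or a path to a YAML file.
#' @return Invisibly, a list with all intermediate and final objects:
#'   `individuals`, `events`, `screen`, `fits` (data frame),
#'   `comparisons` (list of `"model_comparison"`), `trajectory_tests`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  calib <- cfg_calibration(cfg)
  evac <- cfg_evacuation(cfg)
  retention <- cfg_retention(cfg)

  issues <- validate_tables(cfg$paths)
  if (any(issues$severity == "error")) {
    print(issues[issues$severity == "error", ])
    stop("input validation failed; see the issues above")
  }

  fish <- utils::read.csv(cfg$paths$fish, stringsAsFactors = FALSE)
  otoliths <- read_otoliths_csv(cfg$paths$otoliths)
  squid <- utils::read.csv(cfg$paths$squid, stringsAsFactors = FALSE)

  rec <- reconstruct_individuals(fish, otoliths, calib, cfg$pairing_threshold)
  ind <- rec$records

  consumed_all <- ind[ind$source == "consumed", , drop = FALSE]
  events <- build_events(
    data.frame(host_id = consumed_all$host_id, sl = consumed_all$sl,
               weight = consumed_all$weight),
    squid, calib, evac)

  screen <- screen_sites(ind, squid, calib)
  flagged <- screen$site[screen$flagged]

  # selectivity at three spatiotemporal scopes
  seed0 <- cfg$selection$seed
  B <- cfg$selection$B
  comparisons <- list(); si <- 0L
  scope_sets <- list()
  for (st in setdiff(unique(ind$site), flagged))
    scope_sets[[paste0("site:", st)]] <- ind$site == st
  if (!is.null(ind$year) && !all(is.na(ind$year))) {
    for (yr in unique(ind$year))
      scope_sets[[paste0("year:", yr)]] <-
        ind$year == yr & !(ind$site %in% flagged)
    scope_sets[["all"]] <- !(ind$site %in% flagged)
  }
  for (nm in names(scope_sets)) {
    sel <- scope_sets[[nm]]
    sel[is.na(sel)] <- FALSE
    netted <- ind[sel & ind$source == "netted", ]
    consumed <- ind[sel & ind$source == "consumed", ]
    si <- si + 1L
    if (nrow(netted) < 5 || nrow(consumed) < 5) next
    pop <- fit_population(netted, retention, cfg$age_bandwidth)
    comparisons[[nm]] <- compare_models(pop, consumed, scope = nm, B = B,
                                        seed = seed0 + si)
  }
  fits <- do.call(rbind, lapply(comparisons, `[[`, "table"))

  # cohort-wise trajectory comparisons per year
  traj_tests <- list(); traj_rows <- list()
  years <- if (is.null(ind$year)) character(0) else unique(stats::na.omit(ind$year))
  for (yr in years) {
    sub <- ind[!is.na(ind$year) & ind$year == yr & !(ind$site %in% flagged), ]
    if (nrow(sub) < 6) next
    k <- cfg$cohorts[[as.character(yr)]]
    if (is.null(k)) k <- 1
    sub$cohort <- assign_cohorts(sub$age, sub$sl, k)
    for (co in sort(unique(sub$cohort))) {
      ids <- sub$fish_id[sub$cohort == co]
      mat <- trajectory_matrix(rec$series[ids])
      grp <- sub$source[sub$cohort == co]
      traj_rows[[length(traj_rows) + 1]] <- do.call(rbind, lapply(
        seq_along(ids), function(i) {
          s <- rec$series[[ids[i]]]
          data.frame(fish_id = ids[i], year = yr, group = grp[i], cohort = co,
                     age = s$age, sl_backcalc = s$sl)
        }))
      if (min(table(grp)) >= 3 && length(unique(grp)) == 2) {
        traj_tests[[sprintf("%s-cohort%d", yr, co)]] <-
          tryCatch(compare_trajectories(mat, grp), error = function(e) NULL)
      }
    }
  }
  trajectories <- if (length(traj_rows)) do.call(rbind, traj_rows) else NULL

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(screen, file.path(out_dir, "screen.csv"), row.names = FALSE)
  if (!is.null(fits))
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  if (!is.null(trajectories))
    utils::write.csv(trajectories, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
  writeLines(c(
    sprintf("predselect %s | R %s", as.character(utils::packageVersion("predselect")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d, bootstrap B: %d", seed0, B),
    sprintf("retention: %s", if (is.null(retention)) "none (unweighted)"
            else sprintf("l50 = %g mm, delta = %g mm", retention$l50, retention$delta)),
    sprintf("age-support kernel bandwidth: %g days", cfg$age_bandwidth),
    sprintf("pairing threshold: %g mm", cfg$pairing_threshold),
    sprintf("flagged sites (head rejection): %s",
            if (length(flagged)) paste(flagged, collapse = ", ") else "none")
  ), file.path(out_dir, "run_log.txt"))

  invisible(list(individuals = ind, series = rec$series, events = events,
                 screen = screen, fits = fits, comparisons = comparisons,
                 trajectory_tests = traj_tests, trajectories = trajectories,
                 issues = issues))
}
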