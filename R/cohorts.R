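# Hatch-cohort assignment and growth-trajectory comparison between consumed
# and netted juveniles.

#' Assign hatch cohorts by Ward clustering
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances of the
#' standardised age and SL) splits a multi-modal age-SL cloud into hatch
#' cohorts. Labels are ordered young to old by mean age and are invariant to
#' the input row order.
#'
#' @param age,sl Numeric vectors (days, mm) of equal length.
#' @param k Number of cohorts, `1 <= k <= n`.
#' @return Integer cohort labels in `1:k`, 1 = youngest.
#' @export
assign_cohorts <- function(age, sl, k) {
  stopifnot(length(age) == length(sl), k >= 1)
  n <- length(age)
  if (k > n) stop("`k` cannot exceed the number of records")
  if (k == 1) return(rep(1L, n))
  x <- scale(cbind(age, sl))
  x[is.nan(x)] <- 0  # constant column: no information, drop from distance
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  mean_age <- tapply(age, raw, mean)
  relabel <- match(raw, as.integer(names(sort(mean_age))))
  as.integer(relabel)
}

#' Build a back-calculated growth-trajectory matrix
#'
#' Evaluates each individual's back-calculated SL-at-age series at fixed age
#' intervals (5 days), producing a wide individuals-by-ages matrix. Ages
#' beyond an individual's capture age are `NA`. Series are interpolated
#' linearly between daily back-calculated points.
#'
#' @param series A named list of per-individual back-calculation data frames
#'   (from [back_calculate_sl()]), each with columns `age`, `sl`.
#' @param interval Age spacing in days (default 5).
#' @return A numeric matrix, rows = individuals (named), columns = ages
#'   (named by age in days).
#' @export
trajectory_matrix <- function(series, interval = 5) {
  stopifnot(is.list(series), length(series) >= 1)
  max_age <- max(vapply(series, function(s) max(s$age), 0))
  min_age <- min(vapply(series, function(s) min(s$age), 0))
  grid <- seq(interval * ceiling(min_age / interval),
              interval * floor(max_age / interval), by = interval)
  out <- t(vapply(series, function(s) {
    stats::approx(s$age, s$sl, xout = grid, rule = 1)$y
  }, numeric(length(grid))))
  colnames(out) <- grid
  rownames(out) <- names(series)
  out
}

#' Compare growth trajectories between groups
#'
#' One-way MANOVA (Wilks' lambda with its F approximation) on the vector of
#' back-calculated SLs over the common age window of the two groups, followed
#' by post-hoc univariate F tests per age column. The common window is the
#' set of ages at which every retained individual has a value. If there are
#' too many age columns for the available error degrees of freedom, the
#' window is coarsened (every other column dropped) with a warning.
#'
#' @param mat A trajectory matrix from [trajectory_matrix()].
#' @param groups Factor-like vector of group labels (length `nrow(mat)`),
#'   two levels, at least 3 individuals each.
#' @param alpha Significance level for flagging ages (default 0.05).
#' @return A list of class `"trajectory_comparison"`: `wilks`, `F`, `df`,
#'   `p_value`, and `per_age` (data frame with age, group means, F, p,
#'   significance).
#' @export
compare_trajectories <- function(mat, groups, alpha = 0.05) {
  stopifnot(is.matrix(mat), nrow(mat) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are compared")
  if (any(table(groups) < 3)) stop("need at least 3 individuals per group")
  complete <- colSums(is.na(mat)) == 0
  if (!any(complete)) stop("no common age window across individuals")
  m <- mat[, complete, drop = FALSE]
  n <- nrow(m); g <- 2L
  resid_rank <- function(mm) {
    e <- mm - apply(mm, 2, stats::ave, groups)
    qr(e)$rank
  }
  while (ncol(m) > 1 &&
         (ncol(m) > n - g - 1 || resid_rank(m) < ncol(m))) {
    warning("age columns exceed the usable error rank; coarsening the age window")
    m <- m[, seq(1, ncol(m), by = 2), drop = FALSE]
  }
  ages <- as.numeric(colnames(m))
  if (ncol(m) == 1) {
    a <- stats::anova(stats::lm(m[, 1] ~ groups))
    wl <- NA_real_; Fv <- a$`F value`[1]; df <- a$Df; pv <- a$`Pr(>F)`[1]
  } else {
    fit <- stats::manova(m ~ groups)
    s <- summary(fit, test = "Wilks")$stats
    wl <- s[1, "Wilks"]; Fv <- s[1, "approx F"]
    df <- c(s[1, "num Df"], s[1, "den Df"]); pv <- s[1, "Pr(>F)"]
  }
  per_age <- do.call(rbind, lapply(seq_along(ages), function(j) {
    a <- stats::anova(stats::lm(m[, j] ~ groups))
    mm <- tapply(m[, j], groups, mean)
    data.frame(age = ages[j], mean_1 = mm[1], mean_2 = mm[2],
               F = a$`F value`[1], p_value = a$`Pr(>F)`[1],
               significant = a$`Pr(>F)`[1] < alpha, row.names = NULL)
  }))
  structure(list(wilks = wl, F = Fv, df = df, p_value = pv,
                 groups = levels(groups), per_age = per_age, alpha = alpha),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf("Growth-trajectory comparison: %s vs %s\n",
              x$groups[1], x$groups[2]))
  if (is.finite(x$wilks))
    cat(sprintf("  Wilks' lambda = %.4f, F = %.3f (df %g, %g), p = %.4g\n",
                x$wilks, x$F, x$df[1], x$df[2], x$p_value))
  else
    cat(sprintf("  single-age F = %.3f, p = %.4g\n", x$F, x$p_value))
  sig <- x$per_age$age[x$per_age$significant]
  cat(sprintf("  ages differing at alpha = %g: %s\n", x$alpha,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}
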