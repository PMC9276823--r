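# Shared fixtures and small oracles, all built in code.

default_pop_model <- function(ages = 20:60)
  population_model(-5, 1.1, 3, ages)

# adjusted Rand index between two labelings (closed-form contingency oracle)
adjusted_rand <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  si <- sum(choose(rowSums(t), 2)); sj <- sum(choose(colSums(t), 2))
  sij <- sum(choose(t, 2)); e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# independent brute-force left/right matcher: enumerate all injective
# assignments of lefts to rights, maximise pairs then minimise total |dSL|
brute_force_pairs <- function(left_sl, right_sl, thr = 2) {
  nl <- length(left_sl); nr <- length(right_sl)
  best <- list(pairs = -1, cost = Inf, assign = rep(NA_integer_, nl))
  options_for <- function(i) c(NA_integer_, seq_len(nr))
  grid <- do.call(expand.grid, rep(list(options_for(1)), nl))
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(unlist(grid[g, ]))
    used <- asg[!is.na(asg)]
    if (anyDuplicated(used)) next
    d <- abs(left_sl - right_sl[asg])
    if (any(!is.na(asg) & !(d < thr))) next
    npair <- sum(!is.na(asg)); cost <- sum(d, na.rm = TRUE)
    if (npair > best$pairs || (npair == best$pairs && cost < best$cost))
      best <- list(pairs = npair, cost = cost, assign = asg)
  }
  best
}

# radius giving a target reconstructed SL under the default calibration
radius_for_sl <- function(sl, calib = calibration()) (sl - calib$c0) / calib$c1
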