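test_that("age is the increment count plus the hatch age", {
  expect_identical(estimate_age(28), 30L)
  expect_identical(estimate_age(0), 2L)
  expect_identical(estimate_age(43), 45L)
  expect_error(estimate_age(-1), "non-negative")
})

test_that("biological-intercept back-calculation interpolates between anchors", {
  cal <- calibration()  # hatch: 10 um, 3 mm, 2 dph

  # equal widths, capture (110 um, 43 mm): radius 60 um is reached at age 22
  # and maps to 3 + 50 * 40 / 100 = 23 mm
  bc <- back_calculate_sl(110, 43, widths = rep(2.5, 40), calib = cal)
  expect_equal(bc$sl[bc$age == 22], 23)

  # endpoint identity and hatch anchor
  expect_equal(bc$sl[nrow(bc)], 43)
  expect_equal(bc$sl[1], 3)
  expect_equal(bc$age[1], 2)
  expect_equal(bc$age[nrow(bc)], 42)

  # monotone non-decreasing for non-negative widths
  expect_true(all(diff(bc$sl) >= 0))

  expect_error(back_calculate_sl(5, 43, widths = rep(1, 10), calib = cal),
               "hatch radius")
  expect_error(back_calculate_sl(110, 2, widths = rep(1, 10), calib = cal),
               "hatch SL")
})

test_that("equal widths are assumed when only a count is given", {
  cal <- calibration()
  expect_message(
    bc <- back_calculate_sl(110, 43, n_increments = 40, calib = cal),
    "equal widths")
  expect_equal(bc$sl[bc$age == 22], 23)
})

test_that("width/radius mismatch beyond 1% warns but still anchors at capture", {
  cal <- calibration()
  expect_warning(
    bc <- back_calculate_sl(110, 43, widths = rep(3, 40), calib = cal),
    "disagree")
  expect_equal(bc$sl[nrow(bc)], 43)
})

test_that("radius-to-SL and allometry behave as exact inverse mappings", {
  cal <- calibration()
  expect_equal(reconstruct_sl_from_radius(0, cal), cal$c0)
  expect_equal(weight_to_sl(sl_to_weight(50, cal), cal), 50, tolerance = 1e-9)
  expect_error(sl_to_weight(-1, cal), "positive")
  expect_error(weight_to_sl(0, cal), "positive")
  expect_error(reconstruct_sl_from_radius(-5, cal), "non-negative")

  # synthetic fish, noise-free otolith: reconstruction recovers the truth
  fish <- data.frame(id = 1:20, age = sample(20:60, 20, TRUE))
  fish$sl <- -5 + 1.1 * fish$age
  oto <- generate_otoliths(fish, otolith_growth_params(), noise_sd = 0)
  lft <- oto[oto$side == "left", ]
  expect_equal(reconstruct_sl_from_radius(lft$radius, cal), fish$sl,
               tolerance = 1e-6)
})

test_that("otolith pairing follows the 2-mm rule", {
  cal <- calibration()
  mk <- function(sl, side) data.frame(side = side, radius = radius_for_sl(sl))

  # |d| = 1.5 < 2: one individual, SL from the left read
  r <- pair_otoliths(rbind(mk(40, "left"), mk(41.5, "right")), cal)
  expect_equal(length(unique(r$individual)), 1L)
  expect_equal(unique(r$sl), 40)

  # |d| = 2.5 >= 2: two singletons
  r <- pair_otoliths(rbind(mk(40, "left"), mk(42.5, "right")), cal)
  expect_equal(length(unique(r$individual)), 2L)

  # optimal assignment: (40.0, 40.9) and (44.0, 43.5)
  reads <- rbind(mk(40, "left"), mk(44, "left"),
                 mk(43.5, "right"), mk(40.9, "right"))
  r <- pair_otoliths(reads, cal)
  ind_of <- function(sl) r$individual[abs(r$sl_est - sl) < 1e-6]
  expect_equal(ind_of(40), ind_of(40.9))
  expect_equal(ind_of(44), ind_of(43.5))
  expect_false(ind_of(40) == ind_of(44))
})

test_that("pairing matches a brute-force matcher and is order-invariant", {
  cal <- calibration()
  set.seed(21)
  for (rep in 1:20) {
    nl <- sample(0:4, 1); nr <- sample(1:4, 1)
    sls <- runif(nl + nr, 20, 60)
    reads <- data.frame(side = c(rep("left", nl), rep("right", nr)),
                        radius = radius_for_sl(sls))
    r <- pair_otoliths(reads, cal)

    # every read assigned exactly once; no same-side pairs
    expect_false(anyNA(r$individual))
    for (ind in unique(r$individual)) {
      sides <- r$side[r$individual == ind]
      expect_lte(length(sides), 2L)
      expect_equal(length(sides), length(unique(sides)))
    }

    # same number of pairs and total |dSL| as exhaustive enumeration
    if (nl > 0) {
      bf <- brute_force_pairs(sls[seq_len(nl)], sls[nl + seq_len(nr)])
      got_pairs <- sum(table(r$individual) == 2)
      expect_equal(got_pairs, bf$pairs)
      if (got_pairs > 0) {
        cost <- sum(vapply(unique(r$individual), function(ind) {
          s <- r$sl_est[r$individual == ind]
          if (length(s) == 2) abs(diff(s)) else 0
        }, 0))
        expect_equal(cost, bf$cost, tolerance = 1e-9)
      }
    }

    # permutation invariance (pair structure, not labels)
    perm <- sample(nrow(reads))
    r2 <- pair_otoliths(reads[perm, ], cal)
    key <- function(rr) {
      g <- split(round(rr$sl_est, 9), rr$individual)
      unname(sort(vapply(g, function(v) paste(sort(v), collapse = "|"), "")))
    }
    expect_equal(key(r), key(r2))
  }
})
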