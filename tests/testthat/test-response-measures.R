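test_that("inhibition converts to clamped viability", {
  expect_equal(inhibition_to_viability(c(0, 100, -200, 200, 50)),
               c(1, 0, 1, 0, 0.5))
  expect_error(inhibition_to_viability(NaN), "finite")
})

test_that("noiseless 3PL data is recovered to high precision", {
  x <- c(0.01, 0.05, 0.2, 0.5, 2, 10)
  truth <- list(b = 1.2, c = 0.1, e = 0.5)
  fit <- fit_3pl(x, curve_eval_3pl(truth$b, truth$c, truth$e, x))
  expect_s3_class(fit, "curve_fit_3pl")
  expect_lt(abs(fit$b - truth$b), 1e-6)
  expect_lt(abs(fit$c - truth$c), 1e-6)
  expect_lt(abs(fit$e - truth$e), 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(tidy(fit)$term, c("b", "c", "e"))
})

test_that("fits are rejected for too few points and gated on RMSE", {
  x <- c(0.1, 1, 10, 100)
  r <- fit_3pl(x, curve_eval_3pl(1, 0, 1, x))
  expect_true(is_rejected(r))
  expect_equal(r$reason, "min_points")

  # incoherent data: forced past the gate vs gated
  set.seed(1)
  xs <- rep(c(0.01, 0.1, 1, 10, 100), 4)
  vs <- rep(c(0, 1), 10)
  gated <- fit_3pl(xs, vs)
  expect_true(is_rejected(gated))
  expect_equal(gated$reason, "rmse_gate")
  expect_gt(gated$rmse, 0.3)
  kept <- fit_3pl(xs, vs, rmse_max = Inf)
  expect_s3_class(kept, "curve_fit_3pl")
})

test_that("constant viabilities produce a degenerate flat fit", {
  fit <- fit_3pl(c(0.1, 0.5, 1, 5, 10), rep(1, 5))
  expect_s3_class(fit, "curve_fit_3pl")
  expect_true(fit$degenerate)
  expect_equal(fit$c, 1)
  expect_lt(fit$rmse, 1e-9)
  expect_equal(as.numeric(cmax_viability(fit, 100)), 1, tolerance = 1e-6)
})

test_that("curve evaluation honours the logistic closed forms", {
  fit <- fit_3pl(c(0.05, 0.2, 1, 5, 20, 80),
                 curve_eval_3pl(1.5, 0.2, 1.3, c(0.05, 0.2, 1, 5, 20, 80)))
  expect_equal(curve_eval(fit, fit$e), fit$c + (1 - fit$c) / 2, tolerance = 1e-9)
  expect_equal(curve_eval(fit, 0), 1)
  expect_equal(curve_eval_3pl(1, 0, 1, 1), 0.5)
  # strictly decreasing for b > 0
  xs <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(curve_eval(fit, xs)) < 0))
})

test_that("IC-level inversion matches the bisection oracle and flags undefined levels", {
  f1 <- structure(list(b = 1, c = 0, e = 2, rmse = 0, n_points = 5,
                       degenerate = FALSE, concs = c(0.1, 1, 2, 5, 10),
                       viabilities = rep(0.5, 5)), class = "curve_fit_3pl")
  expect_equal(ic_level(f1, 50), 2)

  f2 <- f1; f2$c <- 0.6
  expect_true(is.na(ic_level(f2, 50)))

  f3 <- f1; f3$c <- 0.25; f3$b <- 2; f3$e <- 1
  expect_equal(ic_level(f3, 50), bisect_ic(f3, 0.5), tolerance = 1e-9)

  # property: wherever defined, the curve passes through the target viability
  set.seed(99)
  for (i in 1:25) {
    f <- f1
    f$b <- runif(1, 0.3, 3); f$c <- runif(1, 0, 0.9); f$e <- 10^runif(1, -2, 2)
    lvl <- runif(1, 5, 95)
    x <- ic_level(f, lvl)
    v_star <- (100 - lvl) / 100
    if (f$c >= v_star) {
      expect_true(is.na(x))
    } else {
      expect_lt(abs(curve_eval(f, x) - v_star), 1e-9)
      expect_equal(x, bisect_ic(f, v_star), tolerance = 1e-7)
    }
  }
})

test_that("CMax viability evaluates the curve at CMax and flags extrapolation", {
  x <- c(0.1, 0.5, 1, 2, 4)
  fit <- fit_3pl(x, curve_eval_3pl(1, 0, 2, x))
  cv <- cmax_viability(fit, 2)
  expect_equal(as.numeric(cv), 0.5, tolerance = 1e-6)
  expect_false(attr(cv, "extrapolated"))
  expect_true(attr(cmax_viability(fit, 50), "extrapolated"))
  expect_error(cmax_viability(fit, -1), "positive")
})

test_that("dose-response matrices gain zero margins and flag missing cells", {
  doses_a <- c(0.5, 1, 2); doses_b <- c(0.2, 0.6, 1.8)
  grid <- tidyr::expand_grid(a = doses_a, b = doses_b)
  entries <- dplyr::bind_rows(
    screen_tbl("CL1", "A", "B", grid$a, grid$b, 40),
    screen_tbl("CL1", "A", NA, doses_a, 0, 20),
    screen_tbl("CL1", "B", NA, doses_b, 0, 10)
  )
  attr(entries, "conc_scale") <- "raw_uM"
  m <- assemble_matrix(entries)
  expect_equal(dim(m$viability), c(4, 4))
  expect_equal(m$row_concs, c(0, doses_a))
  expect_equal(m$viability[1, 1], 1)
  expect_false(any(m$missing))
  expect_equal(m$viability[2, 3], inhibition_to_viability(40))

  # drop drug B monotherapies: zero-column cells missing except the control
  no_b <- entries[!(is.na(entries$drug_col) & entries$drug_row == "B"), ]
  attr(no_b, "conc_scale") <- "raw_uM"
  m2 <- assemble_matrix(no_b)
  expect_true(all(m2$missing[1, -1]))
  expect_equal(m2$viability[1, 1], 1)

  # conflicting duplicates are a consistency error
  dup <- dplyr::bind_rows(entries, screen_tbl("CL1", "A", "B", 0.5, 0.2, 90))
  attr(dup, "conc_scale") <- "raw_uM"
  expect_error(assemble_matrix(dup), "conflicting")
})

test_that("combination CMax viability handles flat and separable surfaces exactly", {
  z <- matrix(0.4, 4, 4); z[1, 1] <- 1
  # constant interior: min of interpolated field is the constant
  m_const <- make_drm(c(0, 1, 2, 3), c(0, 1, 2, 3), matrix(0.4, 4, 4))
  expect_equal(as.numeric(combination_cmax_viability(m_const, 2.5, 2.5)), 0.4)

  # separable decreasing surface: minimum sits at the CMax corner
  va <- c(1, 0.8, 0.5, 0.3); vb <- c(1, 0.7, 0.4, 0.2)
  m_sep <- make_drm(c(0, 1, 2, 3), c(0, 1, 2, 3), outer(va, vb))
  got <- combination_cmax_viability(m_sep, 3, 3)
  expect_equal(as.numeric(got), 0.3 * 0.2)
  expect_false(attr(got, "clamped"))

  # clamping: CMax beyond screened range clamps to the grid edge
  got2 <- combination_cmax_viability(m_sep, 10, 10)
  expect_equal(as.numeric(got2), 0.3 * 0.2)
  expect_true(attr(got2, "clamped"))
  expect_error(combination_cmax_viability(m_sep, 10, 10, clamp = FALSE), "screened")

  # missing cells inside the box are refused
  z3 <- outer(va, vb); z3[2, 2] <- NA
  m_miss <- make_drm(c(0, 1, 2, 3), c(0, 1, 2, 3), z3)
  expect_error(combination_cmax_viability(m_miss, 3, 3), "missing")
})

test_that("an interior synergy pocket is found by the grid minimum", {
  rc <- c(0, 0.5, 1, 2, 4)
  cc <- c(0, 0.5, 1, 2, 4)
  z <- outer(c(1, 0.9, 0.8, 0.7, 0.6), c(1, 0.9, 0.8, 0.7, 0.6))
  z[3, 3] <- 0.1  # pocket well below the corner value 0.36
  m <- make_drm(rc, cc, z)
  got <- combination_cmax_viability(m, 4, 4)
  oracle <- bilinear_min_oracle(m, 4, 4, 1000)
  expect_lt(as.numeric(got), 0.36)
  expect_lt(abs(as.numeric(got) - oracle), adjacent_cell_bound(m))
})

test_that("enlarging the CMax box never increases the minimum", {
  set.seed(123)
  for (i in 1:10) {
    m <- random_drm()
    small <- combination_cmax_viability(m, max(m$row_concs) / 2, max(m$col_concs) / 2)
    large <- combination_cmax_viability(m, max(m$row_concs), max(m$col_concs))
    # monotone up to the lattice resolution of the two grids
    expect_lte(as.numeric(large), as.numeric(small) + adjacent_cell_bound(m) / 25)
  }
})

test_that("curve RMSE reports summarize accepted and gated fits", {
  x <- c(0.05, 0.2, 1, 5, 20)
  good <- lapply(c(0.5, 1, 2), function(e) fit_3pl(x, curve_eval_3pl(1, 0.1, e, x)))
  rep1 <- curve_rmse_report(good)
  expect_equal(rep1$frac_below_threshold, 1)
  expect_lt(rep1$mean_rmse, 1e-8)

  set.seed(2)
  bad <- fit_3pl(rep(x, 4), rep(c(0, 1), 10))
  rep2 <- curve_rmse_report(c(good, list(bad)))
  expect_equal(rep2$n_fits, 4L)
  expect_equal(rep2$n_rejected, 1L)
  expect_equal(rep2$frac_below_threshold, 0.75)

  rejected_only <- list(structure(list(reason = "min_points", n_points = 3),
                                  class = "curve_rejection"))
  rep3 <- curve_rmse_report(rejected_only)
  expect_equal(rep3$n_fits, 0L)
  expect_true(is.na(rep3$mean_rmse))
})

test_that("reconstructed measures recover ground truth on a noiseless world", {
  w <- tiny_world(seed = 41, noise_sd = 0, n_cells = 6, n_drugs = 5,
                  n_combinations = 5)
  raw <- preprocess_screen(w$screen, drug_min_entries = 1, log1p_concs = FALSE)
  meas <- reconstruct_measures(raw, w$cmax)
  truth <- ground_truth_measures(w)
  j <- dplyr::inner_join(meas, truth, by = c("cell_line", "treatment", "type", "measure"),
                         suffix = c("_rec", "_true"))
  j <- j[!is.na(j$value_true) & !is.na(j$value_rec), ]
  expect_gt(nrow(j), 50)
  cm_rows <- j$measure == "cmax_viability"
  expect_lt(max(abs(j$value_rec[cm_rows] - j$value_true[cm_rows])), 1e-4)
  ic_rows <- j$measure == "ic50"
  expect_lt(max(abs(j$value_rec[ic_rows] / j$value_true[ic_rows] - 1)), 1e-4)
  cc_rows <- j$measure == "combination_cmax_viability"
  # matrix-based measure: exact up to the interpolation grid resolution
  expect_lt(stats::quantile(abs(j$value_rec[cc_rows] - j$value_true[cc_rows]), 0.9), 0.02)
})
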