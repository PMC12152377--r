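#' Convert relative inhibition to relative viability
#'
#' Viability is `(100 - inhibition) / 100`, clamped to \[0, 1\]. An untreated
#' control (inhibition 0) has viability 1; full inhibition (100) has
#' viability 0; inhibitions outside \[0, 100\] are clamped after conversion.
#'
#' @param inhibition Numeric vector of relative inhibitions.
#' @return Numeric vector of viabilities in \[0, 1\].
#' @export
inhibition_to_viability <- function(inhibition) {
  if (!all(is.finite(inhibition))) abort("inhibition values must be finite")
  clamp((100 - inhibition) / 100, 0, 1)
}

#' Fit a three-parameter logistic dose-response curve
#'
#' Fits `f(x) = c + (1 - c) / (1 + exp(b * (log(x) - log(e))))` by bound-
#' constrained nonlinear least squares: `c` in \[0, 1\] is the lower
#' asymptote, `b > 0` the slope (the curve decreases from 1 toward `c`), and
#' `e > 0` the inflection concentration in micromolar. Three starts are
#' tried (`c0` at the minimum viability and at 0 with `b0 = 1` and `e0` the
#' geometric mean concentration, plus one steeper start) and the best
#' converged solution kept.
#'
#' A fit is rejected — returning a `curve_rejection` instead — when fewer
#' than `min_points` dose-response points are available, when no start
#' converges, or when the fit RMSE exceeds `rmse_max` (0.3 is the
#' conventional satisfactory-quality gate). Near-constant viabilities are
#' fit as a flat curve (`c` at the mean level) and flagged `degenerate`.
#'
#' @param concs Strictly positive concentrations, micromolar.
#' @param viabilities Relative viabilities in \[0, 1\], same length.
#' @param min_points Minimum number of points required (default 5).
#' @param rmse_max Maximum admissible RMSE in viability units (default 0.3;
#'   use `Inf` to keep all converged fits).
#' @return A `curve_fit_3pl` (fields `b`, `c`, `e`, `rmse`, `n_points`,
#'   `degenerate`, and the fitted data) or a `curve_rejection` with a
#'   `reason` of `"min_points"`, `"fit_failed"` or `"rmse_gate"` (the latter
#'   retains the offending `rmse`). Test rejection with [is_rejected()].
#' @examples
#' x <- c(0.01, 0.1, 0.5, 1, 5, 20)
#' fit <- fit_3pl(x, curve_eval_3pl(1.2, 0.1, 0.5, x))
#' tidy(fit)
#' @export
fit_3pl <- function(concs, viabilities, min_points = 5, rmse_max = 0.3) {
  if (length(concs) != length(viabilities)) {
    abort("concs and viabilities must have the same length")
  }
  if (any(!is.finite(concs)) || any(concs <= 0)) {
    abort("all fit concentrations must be finite and strictly positive")
  }
  if (any(!is.finite(viabilities))) abort("viabilities must be finite")
  n <- length(concs)
  if (n < min_points) {
    return(structure(list(reason = "min_points", n_points = n),
                     class = "curve_rejection"))
  }
  make_fit <- function(b, c, e, degenerate = FALSE) {
    rmse <- sqrt(mean((curve_eval_3pl(b, c, e, concs) - viabilities)^2))
    structure(list(b = b, c = c, e = e, rmse = rmse, n_points = n,
                   degenerate = degenerate, concs = concs,
                   viabilities = viabilities),
              class = "curve_fit_3pl")
  }
  if (sd(viabilities) < 1e-9) {
    fit <- make_fit(1, clamp(mean(viabilities), 0, 1), geometric_mean(concs),
                    degenerate = TRUE)
    return(fit)
  }
  lx <- log(concs)
  starts <- list(
    c(b = 1, c = min(viabilities), e = geometric_mean(concs)),
    c(b = 1, c = 0, e = geometric_mean(concs)),
    c(b = 2, c = min(viabilities) / 2, e = exp(median(lx)))
  )
  residual <- function(p) curve_eval_3pl(p[1], p[2], exp(p[3]), concs) - viabilities
  best <- NULL
  for (s in starts) {
    # e is optimized on the log scale for conditioning
    sol <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = c(s[["b"]], s[["c"]], log(s[["e"]])),
        lower = c(1e-6, 0, log(1e-12)),
        upper = c(1e3, 1, log(1e12)),
        fn = residual,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
      )),
      error = function(e) NULL
    )
    if (!is.null(sol) && sol$info %in% 1:4) {
      rss <- sum(sol$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(par = sol$par, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(reason = "fit_failed", n_points = n),
                     class = "curve_rejection"))
  }
  out <- make_fit(best$par[1], best$par[2], exp(best$par[3]))
  if (out$rmse > rmse_max) {
    return(structure(list(reason = "rmse_gate", rmse = out$rmse, n_points = n,
                          fit = out),
                     class = "curve_rejection"))
  }
  out
}

#' @rdname fit_3pl
#' @param x Object to test.
#' @export
is_rejected <- function(x) inherits(x, "curve_rejection")

# raw 3PL evaluation (exported: useful to build synthetic curves)
#' Evaluate the three-parameter logistic function
#'
#' @param b,c,e Curve parameters (slope, lower asymptote, inflection
#'   concentration).
#' @param x Concentrations, micromolar; `x = 0` returns the limit value 1.
#' @return Viability values.
#' @export
curve_eval_3pl <- function(b, c, e, x) {
  out <- c + (1 - c) / (1 + exp(b * (log(x) - log(e))))
  out[x == 0] <- 1
  out
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit A `curve_fit_3pl`.
#' @param x Concentrations, micromolar (0 returns the limit value 1).
#' @return Predicted viabilities.
#' @export
curve_eval <- function(fit, x) {
  stopifnot(inherits(fit, "curve_fit_3pl"))
  if (any(!is.finite(x)) || any(x < 0)) abort("concentrations must be finite and >= 0")
  curve_eval_3pl(fit$b, fit$c, fit$e, x)
}

#' Invert a dose-response curve at an inhibition level
#'
#' Returns the concentration at which the curve reaches a relative
#' inhibition of `inhibition_level` percent, i.e. crosses the target
#' viability `v* = (100 - inhibition_level) / 100`. The IC50 is
#' `ic_level(fit, 50)`; the IC75 and IC90 (which cross viability 0.75 and
#' 0.90) are `ic_level(fit, 25)` and `ic_level(fit, 10)`. The closed form is
#' `x = e * (((1 - c) / (v* - c)) - 1)^(1/b)`; when the asymptote `c >= v*`
#' the curve never reaches the level and `NA` is returned.
#'
#' @param fit A `curve_fit_3pl`.
#' @param inhibition_level Inhibition percentage in (0, 100); 50 gives the
#'   IC50.
#' @return Concentration in micromolar, or `NA` when undefined.
#' @export
ic_level <- function(fit, inhibition_level = 50) {
  stopifnot(inherits(fit, "curve_fit_3pl"))
  if (inhibition_level <= 0 || inhibition_level >= 100) {
    abort("inhibition_level must lie strictly between 0 and 100")
  }
  v_star <- (100 - inhibition_level) / 100
  if (fit$c >= v_star) return(NA_real_)
  gap <- (1 - fit$c) / (v_star - fit$c) - 1
  fit$e * gap^(1 / fit$b)
}

#' CMax viability of a monotherapy
#'
#' The relative viability read off the fitted dose-response curve at the
#' drug's CMax, the peak plasma concentration after the highest clinically
#' recommended dose. Because CMax is fixed per drug, the measure is
#' comparable across drugs. When the CMax exceeds the highest screened
#' concentration the value is an extrapolation of the fitted curve, flagged
#' via the `"extrapolated"` attribute.
#'
#' @param fit A `curve_fit_3pl`.
#' @param cmax CMax concentration, micromolar, > 0.
#' @param max_screened Highest screened concentration; defaults to the
#'   maximum concentration used in the fit.
#' @return Viability in \[0, 1\] with logical attribute `extrapolated`.
#' @export
cmax_viability <- function(fit, cmax, max_screened = NULL) {
  stopifnot(inherits(fit, "curve_fit_3pl"))
  if (!is.finite(cmax) || cmax <= 0) abort("cmax must be finite and positive")
  max_screened <- max_screened %||% max(fit$concs)
  out <- curve_eval(fit, cmax)
  attr(out, "extrapolated") <- cmax > max_screened
  out
}

#' Assemble a dose-response matrix for one cell line and drug pair
#'
#' Builds the viability grid over the screened concentrations of the two
#' drugs, augmented with a zero-dose margin on each axis: the (0, 0) corner
#' is the untreated control (viability 1), monotherapy entries of each drug
#' fill its zero margin, and combination entries fill the interior. Grid
#' cells without a measurement are `NA` and flagged in the `missing` matrix.
#' Drug orientation is canonical (lexicographically smaller drug on the
#' rows).
#'
#' @param entries Screen-table rows for a single cell line and a single
#'   unordered drug pair, including that pair's combination entries and
#'   (optionally) each drug's monotherapy entries, on the raw micromolar
#'   scale.
#' @param inhibition Optional replacement inhibition vector aligned with
#'   `entries` (e.g. model predictions); defaults to the observed column.
#' @return A `dose_response_matrix` with `row_concs`, `col_concs` (sorted,
#'   starting at 0), the `viability` matrix, the `missing` flag matrix and
#'   identifiers.
#' @export
assemble_matrix <- function(entries, inhibition = NULL) {
  if (conc_scale(entries) != "raw_uM") {
    abort("assemble_matrix needs raw micromolar concentrations")
  }
  if (nrow(entries) == 0) abort("no entries supplied")
  inhibition <- inhibition %||% entries$inhibition
  if (length(inhibition) != nrow(entries)) {
    abort("inhibition vector must align with entries")
  }
  cell <- unique(entries$cell_line)
  if (length(cell) != 1) abort("entries must belong to a single cell line")
  cp <- canonicalize_pair(entries$drug_row, entries$drug_col,
                          entries$conc_row, entries$conc_col)
  comb <- !is.na(cp$drug_b)
  if (!any(comb)) abort("entries contain no combination measurements")
  pair <- unique(cp[comb, c("drug_a", "drug_b")])
  if (nrow(pair) != 1) abort("entries must cover a single drug pair")
  drug_a <- pair$drug_a; drug_b <- pair$drug_b
  mono_a <- !comb & cp$drug_a == drug_a
  mono_b <- !comb & cp$drug_a == drug_b
  if (!all(comb | mono_a | mono_b)) {
    abort("entries contain monotherapies of drugs outside the pair")
  }

  row_concs <- sort(unique(c(0, cp$conc_a[comb | mono_a])))
  col_concs <- sort(unique(c(0, cp$conc_b[comb], cp$conc_a[mono_b])))
  v <- matrix(NA_real_, length(row_concs), length(col_concs),
              dimnames = list(conc_key(row_concs), conc_key(col_concs)))
  viab <- inhibition_to_viability(inhibition)

  place <- function(i, j, value, what) {
    if (!is.na(v[i, j]) && abs(v[i, j] - value) > 1e-9) {
      abort(paste0("conflicting duplicate measurement at ", what,
                   " — average replicates before assembling matrices"))
    }
    v[i, j] <<- value
  }
  ri <- match(conc_key(cp$conc_a), rownames(v))
  ci <- match(conc_key(cp$conc_b), colnames(v))
  mono_b_ci <- match(conc_key(cp$conc_a), colnames(v))
  for (k in seq_len(nrow(entries))) {
    if (comb[k]) {
      place(ri[k], ci[k], viab[k], "interior cell")
    } else if (mono_a[k]) {
      place(ri[k], 1L, viab[k], "row margin")
    } else {
      place(1L, mono_b_ci[k], viab[k], "column margin")
    }
  }
  v[1, 1] <- 1  # untreated control
  structure(list(row_concs = row_concs, col_concs = col_concs,
                 viability = v, missing = is.na(v),
                 cell_line = cell, drug_row = drug_a, drug_col = drug_b),
            class = "dose_response_matrix")
}

#' @export
print.dose_response_matrix <- function(x, ...) {
  cat("Dose-response matrix: ", x$cell_line, ", ", x$drug_row, " x ",
      x$drug_col, " (", length(x$row_concs), " x ", length(x$col_concs),
      " doses, ", sum(x$missing), " missing)\n", sep = "")
  invisible(x)
}

#' Combination CMax viability
#'
#' The minimum relative viability attainable within the clinically bounded
#' concentration box \[0, CMax_A\] x \[0, CMax_B\]: each axis is divided into
#' `grid_n` equally spaced concentrations from 0 to the drug's CMax
#' (inclusive), the viability at each of the `grid_n^2` lattice points is
#' estimated by bilinear interpolation of the dose-response matrix, and the
#' minimum is returned. Taking the minimum over the whole box (rather than
#' the viability at the CMax corner) captures synergy windows at
#' sub-CMax concentrations.
#'
#' Matrix-based measures never extrapolate: a CMax beyond the screened range
#' is clamped to the maximum screened concentration when `clamp = TRUE`
#' (flagged via attribute `clamped`) and raises an error otherwise.
#'
#' @param matrix A [assemble_matrix()] result with no missing cells inside
#'   the evaluation box.
#' @param cmax_a,cmax_b CMax concentration of the row/column drug,
#'   micromolar.
#' @param grid_n Lattice points per axis (default 100, i.e. 10000
#'   combinations).
#' @param clamp Clamp CMax values beyond the screened range?
#' @return Minimum viability in \[0, 1\], with logical attribute `clamped`.
#' @export
combination_cmax_viability <- function(matrix, cmax_a, cmax_b, grid_n = 100,
                                       clamp = TRUE) {
  stopifnot(inherits(matrix, "dose_response_matrix"))
  if (cmax_a <= 0 || cmax_b <= 0) abort("CMax concentrations must be positive")
  max_a <- max(matrix$row_concs); max_b <- max(matrix$col_concs)
  clamped <- cmax_a > max_a || cmax_b > max_b
  if (clamped && !clamp) {
    abort("CMax exceeds the screened concentration range and clamping is disabled")
  }
  box_a <- min(cmax_a, max_a); box_b <- min(cmax_b, max_b)
  # every grid corner bracketing the box must be measured
  need_r <- matrix$row_concs <= box_a
  if (any(!need_r)) need_r[which(!need_r)[1]] <- TRUE
  need_c <- matrix$col_concs <= box_b
  if (any(!need_c)) need_c[which(!need_c)[1]] <- TRUE
  if (any(matrix$missing[need_r, need_c])) {
    abort("dose-response matrix has missing cells inside the CMax box")
  }
  xa <- seq(0, box_a, length.out = grid_n)
  xb <- seq(0, box_b, length.out = grid_n)
  # interp2 treats x along columns, y along rows
  vals <- pracma::interp2(x = matrix$col_concs, y = matrix$row_concs,
                          Z = matrix$viability,
                          xp = rep(xb, each = grid_n), yp = rep(xa, grid_n),
                          method = "linear")
  out <- min(vals)
  attr(out, "clamped") <- clamped
  out
}

#' Summarize curve-fit quality
#'
#' @param fits List of [fit_3pl()] results; accepted fits and RMSE-gate
#'   rejections both contribute their RMSE, other rejections are counted but
#'   excluded.
#' @param threshold RMSE quality threshold (default 0.3).
#' @return One-row tibble with `n_fits`, `n_rejected`, `mean_rmse` and
#'   `frac_below_threshold`; `n_fits = 0` yields an all-`NA` summary row.
#' @export
curve_rmse_report <- function(fits, threshold = 0.3) {
  if (length(fits) == 0) abort("no fits supplied")
  rmses <- purrr::map_dbl(fits, function(f) {
    if (inherits(f, "curve_fit_3pl")) return(f$rmse)
    if (is_rejected(f) && !is.null(f$rmse)) return(f$rmse)
    NA_real_
  })
  n_rej <- sum(purrr::map_lgl(fits, is_rejected))
  rmses <- rmses[!is.na(rmses)]
  if (length(rmses) == 0) {
    return(tibble::tibble(n_fits = 0L, n_rejected = n_rej,
                          mean_rmse = NA_real_, frac_below_threshold = NA_real_))
  }
  tibble::tibble(n_fits = length(rmses), n_rejected = n_rej,
                 mean_rmse = mean(rmses),
                 frac_below_threshold = mean(rmses < threshold))
}

#' @method tidy curve_fit_3pl
#' @export
tidy.curve_fit_3pl <- function(x, ...) {
  tibble::tibble(term = c("b", "c", "e"),
                 estimate = c(x$b, x$c, x$e))
}

#' @method glance curve_fit_3pl
#' @export
glance.curve_fit_3pl <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, n_points = x$n_points, degenerate = x$degenerate)
}

#' @export
print.curve_fit_3pl <- function(x, ...) {
  cat(sprintf("3PL fit: b=%.4g c=%.4g e=%.4g (rmse %.4g, %d points%s)\n",
              x$b, x$c, x$e, x$rmse, x$n_points,
              if (x$degenerate) ", degenerate-flat" else ""))
  invisible(x)
}

#' @export
print.curve_rejection <- function(x, ...) {
  cat("3PL fit rejected:", x$reason,
      if (!is.null(x$rmse)) sprintf("(rmse %.3f)", x$rmse) else "", "\n")
  invisible(x)
}

#' Reconstruct sensitivity measures for every treatment of a screen
#'
#' The measure-reconstruction pipeline: converts inhibitions (observed, or
#' model predictions aligned with the table) to viabilities, fits a 3PL
#' curve per cell line and drug from the monotherapy entries, and assembles
#' a dose-response matrix per cell line and drug pair. From these it derives
#' IC50/IC75/IC90 and CMax viability per monotherapy, and the combination
#' CMax viability per drug pair (for pairs whose CMax box is fully
#' measured). Only drugs present in `cmax_table` receive CMax-based
#' measures.
#'
#' @param table Replicate-averaged screen table on the raw micromolar scale
#'   (use `preprocess_screen(..., log1p_concs = FALSE)`).
#' @param cmax_table Data frame with columns `drug` and `cmax` (micromolar).
#' @param inhibition Optional inhibition vector aligned with `table` rows
#'   (e.g. model predictions mapped back to entries); defaults to the
#'   observed values.
#' @param ic_levels Viability percentages defining the IC measures (default
#'   50, 75, 90: the IC50/IC75/IC90 cross viability 0.5/0.75/0.90, i.e.
#'   inhibition 50/25/10 percent).
#' @param grid_n Lattice resolution for the combination CMax viability.
#' @param rmse_max RMSE gate for curve fits.
#' @return A long tibble of sensitivity records: `cell_line`, `treatment`,
#'   `type` (`"mono"`/`"combination"`), `measure`, `value` (`NA` when
#'   undefined), and `flag` (extrapolated/clamped/rejection notes).
#' @export
reconstruct_measures <- function(table, cmax_table, inhibition = NULL,
                                 ic_levels = c(50, 75, 90), grid_n = 100,
                                 rmse_max = 0.3) {
  if (conc_scale(table) != "raw_uM") {
    abort("reconstruct_measures needs raw micromolar concentrations")
  }
  tbl <- tibble::as_tibble(table)
  tbl$..inh <- inhibition %||% tbl$inhibition
  cmax_map <- setNames(cmax_table$cmax, cmax_table$drug)

  mono <- dplyr::filter(tbl, is.na(.data$drug_col))
  mono_groups <- dplyr::group_split(dplyr::group_by(mono, .data$cell_line, .data$drug_row))
  mono_records <- purrr::map_dfr(mono_groups, function(g) {
    fit <- fit_3pl(g$conc_row, inhibition_to_viability(g$..inh), rmse_max = rmse_max)
    base <- tibble::tibble(cell_line = g$cell_line[1], treatment = g$drug_row[1],
                           type = "mono")
    if (is_rejected(fit)) {
      return(dplyr::mutate(base, measure = "fit", value = NA_real_, flag = fit$reason))
    }
    recs <- purrr::map_dfr(ic_levels, function(lv) {
      dplyr::mutate(base, measure = paste0("ic", lv),
                    value = ic_level(fit, 100 - lv),
                    flag = NA_character_)
    })
    cm <- cmax_map[g$drug_row[1]]
    if (!is.na(cm)) {
      cv <- cmax_viability(fit, cm)
      recs <- dplyr::bind_rows(recs, dplyr::mutate(
        base, measure = "cmax_viability", value = as.numeric(cv),
        flag = if (attr(cv, "extrapolated")) "extrapolated" else NA_character_))
    }
    recs
  })

  comb <- dplyr::filter(tbl, !is.na(.data$drug_col))
  comb$..pair_a <- canonicalize_pair(comb$drug_row, comb$drug_col, 0, 0)$drug_a
  comb$..pair_b <- canonicalize_pair(comb$drug_row, comb$drug_col, 0, 0)$drug_b
  comb_groups <- dplyr::group_split(
    dplyr::group_by(comb, .data$cell_line, .data$..pair_a, .data$..pair_b))
  comb_records <- purrr::map_dfr(comb_groups, function(g) {
    ca <- cmax_map[g$..pair_a[1]]; cb <- cmax_map[g$..pair_b[1]]
    base <- tibble::tibble(cell_line = g$cell_line[1],
                           treatment = paste(g$..pair_a[1], g$..pair_b[1], sep = " + "),
                           type = "combination")
    if (is.na(ca) || is.na(cb)) return(dplyr::slice(base, 0L))
    margins <- dplyr::filter(mono, .data$cell_line == g$cell_line[1],
                             .data$drug_row %in% c(g$..pair_a[1], g$..pair_b[1]))
    entries <- dplyr::bind_rows(g[names(mono)], margins)
    m <- assemble_matrix(set_conc_scale(entries, "raw_uM"),
                         inhibition = entries$..inh)
    val <- tryCatch(combination_cmax_viability(m, ca, cb, grid_n = grid_n),
                    error = function(e) NULL)
    if (is.null(val)) {
      return(dplyr::mutate(base, measure = "combination_cmax_viability",
                           value = NA_real_, flag = "incomplete_matrix"))
    }
    dplyr::mutate(base, measure = "combination_cmax_viability",
                  value = as.numeric(val),
                  flag = if (attr(val, "clamped")) "clamped" else NA_character_)
  })
  dplyr::bind_rows(mono_records, comb_records)
}
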