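# Shared fixtures: built in code, deterministic given explicit seeds.

# small synthetic world for fast end-to-end tests
tiny_world <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_cells = 12, n_drugs = 6, n_combinations = 8, latent_dim = 4,
         n_genes = 80, doses_per_drug = 5, replicates = 1, noise_sd = 7,
         synergy_fraction = 0.25, seed = seed),
    list(...)
  )
  generate_world(do.call(synthetic_world_config, args))
}

# a screen table from raw columns (raw micromolar scale)
screen_tbl <- function(cell, dr, dc, cr, cc, inh) {
  tbl <- tibble::tibble(cell_line = cell, drug_row = dr, drug_col = dc,
                        conc_row = cr, conc_col = cc, inhibition = inh)
  attr(tbl, "conc_scale") <- "raw_uM"
  tbl
}

# construct a dose_response_matrix object directly (test fixture)
make_drm <- function(row_concs, col_concs, viability,
                     cell = "CL1", drug_a = "A", drug_b = "B") {
  structure(list(row_concs = row_concs, col_concs = col_concs,
                 viability = viability, missing = is.na(viability),
                 cell_line = cell, drug_row = drug_a, drug_col = drug_b),
            class = "dose_response_matrix")
}

# independent bilinear interpolation oracle (no pracma): min over an
# n x n lattice on [0, cmax_a] x [0, cmax_b], clamped to the grid range
bilinear_min_oracle <- function(m, cmax_a, cmax_b, n) {
  rc <- m$row_concs; cc <- m$col_concs; Z <- m$viability
  xa <- seq(0, min(cmax_a, max(rc)), length.out = n)
  xb <- seq(0, min(cmax_b, max(cc)), length.out = n)
  i <- pmin(findInterval(xa, rc), length(rc) - 1L)
  j <- pmin(findInterval(xb, cc), length(cc) - 1L)
  u <- (xa - rc[i]) / (rc[i + 1L] - rc[i])
  v <- (xb - cc[j]) / (cc[j + 1L] - cc[j])
  best <- Inf
  for (q in seq_along(xb)) {
    z <- (1 - u) * (1 - v[q]) * Z[cbind(i, j[q])] +
      u * (1 - v[q]) * Z[cbind(i + 1L, j[q])] +
      (1 - u) * v[q] * Z[cbind(i, j[q] + 1L)] +
      u * v[q] * Z[cbind(i + 1L, j[q] + 1L)]
    best <- min(best, min(z))
  }
  best
}

# grid-resolution error bound: largest viability jump between adjacent cells
adjacent_cell_bound <- function(m) {
  z <- m$viability
  max(abs(diff(z)), abs(t(diff(t(z)))))
}

# bisection oracle for inverting a fitted curve at target viability v_star
bisect_ic <- function(fit, v_star, lo = 1e-12, hi = 1e12, tol = 1e-12) {
  f <- function(x) curve_eval(fit, x) - v_star
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# random valid dose-response matrix with measured (0,0) = 1
random_drm <- function(nr = 5, nc = 4) {
  rc <- c(0, sort(runif(nr - 1, 0.1, 10)))
  cc <- c(0, sort(runif(nc - 1, 0.1, 10)))
  z <- matrix(runif(nr * nc), nr, nc)
  z[1, 1] <- 1
  make_drm(rc, cc, z)
}
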