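#' Configure a synthetic combination-screen world
#'
#' Defines the study conditions for a generated screen: monotherapy
#' responses follow a three-parameter logistic curve per cell line and drug
#' whose potency depends on the cell's latent state, combinations follow
#' Bliss-style independence (product of monotherapy viabilities) with an
#' optional localized synergy window, and replicate noise on the inhibition
#' scale has standard deviation `noise_sd` (default 7 inhibition units, the
#' scale of replicate disagreement in large public combination screens).
#'
#' @param n_cells,n_drugs Number of cell lines and drugs.
#' @param n_combinations Number of unordered drug pairs screened in
#'   combination (every pair is screened on every cell line).
#' @param latent_dim Dimension of the latent cell state driving both
#'   expression and drug potency.
#' @param n_genes Number of genes in the expression matrix.
#' @param doses_per_drug Doses per drug, half-log-spaced around the drug's
#'   prior median potency; at least 5 so monotherapy curves are fittable.
#' @param replicates Technical replicates per measurement.
#' @param noise_sd Replicate noise standard deviation, inhibition units.
#' @param synergy_fraction Fraction of combination pairs given a synergy
#'   window (a localized dip of the viability surface below independence).
#' @param cmax_quantile Position of each drug's CMax within its screened
#'   log-concentration range (0 = lowest dose, 1 = highest).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_cells = 40, n_drugs = 12, n_combinations = 30,
                                   latent_dim = 5, n_genes = 300,
                                   doses_per_drug = 5, replicates = 1,
                                   noise_sd = 7, synergy_fraction = 0.25,
                                   cmax_quantile = 0.75, seed = 1) {
  if (doses_per_drug < 5) abort("doses_per_drug must be at least 5 (fittable curves)")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (n_combinations > choose(n_drugs, 2)) {
    abort("n_combinations exceeds the number of available drug pairs")
  }
  if (cmax_quantile < 0 || cmax_quantile > 1) abort("cmax_quantile must lie in [0, 1]")
  structure(list(n_cells = n_cells, n_drugs = n_drugs,
                 n_combinations = n_combinations, latent_dim = latent_dim,
                 n_genes = n_genes, doses_per_drug = doses_per_drug,
                 replicates = replicates, noise_sd = noise_sd,
                 synergy_fraction = synergy_fraction,
                 cmax_quantile = cmax_quantile, seed = as.integer(seed)),
            class = "synthetic_world_config")
}

# localized synergy window: Gaussian dip on the log-concentration plane;
# evaluates to 1 (no interaction) on the zero-dose margins
interaction_modifier <- function(conc_a, conc_b, amp, center_a, center_b, sigma) {
  la <- suppressWarnings(log(conc_a)); lb <- suppressWarnings(log(conc_b))
  bump <- exp(-((la - center_a)^2 + (lb - center_b)^2) / (2 * sigma^2))
  bump[conc_a == 0 | conc_b == 0] <- 0
  1 - amp * bump
}

#' Generate a synthetic screen world with known ground truth
#'
#' Draws a latent state per cell line and an effect vector per drug
#' (a linear readout of the drug's fingerprint, so fingerprint-based models
#' can learn potency); the inflection concentration of each (cell, drug)
#' curve is `exp(mu_drug + <cell latent, drug effect>)`, making cell-blind
#' generalization learnable from expression. Expression is the latent state
#' mapped through random gene loadings plus noise. Combination viability is
#' the product of the monotherapy viabilities, times a localized synergy
#' dip for the configured fraction of pairs. Inhibition is
#' `100 * (1 - viability)` plus Gaussian noise, clipped to \[-200, 200\]
#' (clipping after noise, so extreme noise settings exercise the quality
#' filter).
#'
#' @param cfg A [synthetic_world_config()].
#' @return A `synthetic_world` list: `screen` (raw-scale screen table),
#'   `expression` (genes x cells), `fingerprints`, `descriptors`, `targets`,
#'   `cmax` tables, `ground_truth` (true curve parameters, combination
#'   interactions, latent states) and `config`.
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_world_config"))
  withr::with_seed(derive_seed(cfg$seed, 100L), {
    cells <- sprintf("CL%03d", seq_len(cfg$n_cells))
    drugs <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))

    latent <- matrix(rnorm(cfg$n_cells * cfg$latent_dim), cfg$n_cells,
                     dimnames = list(cells, NULL))
    loadings <- matrix(rnorm(cfg$n_genes * cfg$latent_dim), cfg$n_genes)
    expression <- loadings %*% t(latent) +
      matrix(rnorm(cfg$n_genes * cfg$n_cells, sd = 0.3), cfg$n_genes)
    dimnames(expression) <- list(genes, cells)

    # fingerprints; drug potency effect is a linear readout of the bits
    n_bits <- 32L
    fp <- matrix(rbinom(cfg$n_drugs * n_bits, 1, 0.35), cfg$n_drugs,
                 dimnames = list(drugs, sprintf("bit%02d", seq_len(n_bits))))
    readout <- matrix(rnorm(n_bits * cfg$latent_dim, sd = 1 / sqrt(n_bits)), n_bits)
    effect <- scale(fp %*% readout, center = TRUE, scale = FALSE)
    delta <- latent %*% t(effect)           # cells x drugs log-potency shifts
    sdd <- sd(delta)
    if (sdd > 0) { effect <- effect * (0.7 / sdd); delta <- delta * (0.7 / sdd) }

    mu <- rnorm(cfg$n_drugs, mean = 0, sd = 0.8)       # log uM median potency
    slope <- runif(cfg$n_drugs, 0.8, 2)
    asymptote <- runif(cfg$n_drugs, 0, 0.3)
    e_true <- exp(sweep(delta, 2, mu, "+"))            # cells x drugs
    dimnames(e_true) <- list(cells, drugs)

    dose_grid <- lapply(seq_len(cfg$n_drugs), function(d) {
      exp(mu[d]) * 10^seq(-1, 1, length.out = cfg$doses_per_drug)
    })
    names(dose_grid) <- drugs
    cmax <- purrr::map_dbl(dose_grid, function(g) {
      exp(log(min(g)) + cfg$cmax_quantile * (log(max(g)) - log(min(g))))
    })

    # numeric descriptors: fingerprint readouts plus noise, and one
    # deliberately constant column to exercise variance filtering downstream
    n_desc <- 16L
    desc_map <- matrix(rnorm(n_bits * n_desc), n_bits)
    desc <- fp %*% desc_map + matrix(rnorm(cfg$n_drugs * n_desc, sd = 0.1), cfg$n_drugs)
    colnames(desc) <- sprintf("prop%02d", seq_len(n_desc))
    desc <- cbind(desc, prop_const = 1)

    targets <- purrr::map_dfr(seq_len(cfg$n_drugs), function(d) {
      tibble::tibble(drug = drugs[d],
                     target = sample(sprintf("T%02d", 1:20), sample(1:4, 1)))
    })

    mono_viab <- function(cell_i, drug_i, conc) {
      curve_eval_3pl(slope[drug_i], asymptote[drug_i],
                     e_true[cbind(cell_i, drug_i)], conc)
    }

    mono <- tidyr::crossing(cell_line = cells, drug = drugs,
                            dose_idx = seq_len(cfg$doses_per_drug),
                            replicate = seq_len(cfg$replicates))
    mono$conc <- purrr::map2_dbl(mono$drug, mono$dose_idx,
                                 ~ dose_grid[[.x]][.y])
    mono$viab <- mono_viab(match(mono$cell_line, cells),
                           match(mono$drug, drugs), mono$conc)

    all_pairs <- utils::combn(drugs, 2)
    pair_idx <- sort(sample(ncol(all_pairs), cfg$n_combinations))
    n_syn <- round(cfg$synergy_fraction * cfg$n_combinations)
    syn_flags <- sample(rep(c(TRUE, FALSE),
                            c(n_syn, cfg$n_combinations - n_syn)))
    combos <- purrr::map_dfr(seq_along(pair_idx), function(i) {
      da <- all_pairs[1, pair_idx[i]]; db <- all_pairs[2, pair_idx[i]]
      ga <- dose_grid[[da]]; gb <- dose_grid[[db]]
      tibble::tibble(
        drug_a = da, drug_b = db, synergy = syn_flags[i],
        amp = if (syn_flags[i]) runif(1, 0.25, 0.5) else 0,
        center_a = runif(1, quantile(log(ga), 0.3), quantile(log(ga), 0.7)),
        center_b = runif(1, quantile(log(gb), 0.3), quantile(log(gb), 0.7)),
        sigma = runif(1, 0.4, 0.8)
      )
    })

    comb <- tidyr::crossing(pair = seq_len(cfg$n_combinations),
                            cell_line = cells,
                            ia = seq_len(cfg$doses_per_drug),
                            ib = seq_len(cfg$doses_per_drug),
                            replicate = seq_len(cfg$replicates))
    comb$drug_a <- combos$drug_a[comb$pair]
    comb$drug_b <- combos$drug_b[comb$pair]
    comb$conc_a <- purrr::map2_dbl(comb$drug_a, comb$ia, ~ dose_grid[[.x]][.y])
    comb$conc_b <- purrr::map2_dbl(comb$drug_b, comb$ib, ~ dose_grid[[.x]][.y])
    ci <- match(comb$cell_line, cells)
    va <- mono_viab(ci, match(comb$drug_a, drugs), comb$conc_a)
    vb <- mono_viab(ci, match(comb$drug_b, drugs), comb$conc_b)
    mod <- interaction_modifier(comb$conc_a, comb$conc_b,
                                combos$amp[comb$pair],
                                combos$center_a[comb$pair],
                                combos$center_b[comb$pair],
                                combos$sigma[comb$pair])
    comb$viab <- pmax(va * vb * mod, 0)

    screen <- dplyr::bind_rows(
      tibble::tibble(cell_line = mono$cell_line, drug_row = mono$drug,
                     drug_col = NA_character_, conc_row = mono$conc,
                     conc_col = 0, viab = mono$viab),
      tibble::tibble(cell_line = comb$cell_line, drug_row = comb$drug_a,
                     drug_col = comb$drug_b, conc_row = comb$conc_a,
                     conc_col = comb$conc_b, viab = comb$viab)
    )
    screen$inhibition <- clamp(
      100 * (1 - screen$viab) + rnorm(nrow(screen), sd = cfg$noise_sd),
      -200, 200)
    screen$viab <- NULL
    screen <- set_conc_scale(screen, "raw_uM")

    ground_truth <- structure(list(
      curves = tidyr::crossing(cell_line = cells, drug = drugs) |>
        dplyr::mutate(b = slope[match(.data$drug, drugs)],
                      c = asymptote[match(.data$drug, drugs)],
                      e = e_true[cbind(match(.data$cell_line, cells),
                                       match(.data$drug, drugs))]),
      combos = combos,
      dose_grid = dose_grid,
      cell_latent = latent,
      drug_effect = effect
    ), class = "ground_truth")

    structure(list(
      screen = screen,
      expression = expression,
      fingerprints = tibble::as_tibble(cbind(data.frame(drug = drugs), fp)),
      descriptors = tibble::as_tibble(cbind(data.frame(drug = drugs), desc)),
      targets = targets,
      cmax = tibble::tibble(drug = drugs, cmax = unname(cmax)),
      ground_truth = ground_truth,
      config = cfg
    ), class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic screen world:", x$config$n_cells, "cells,",
      x$config$n_drugs, "drugs,", x$config$n_combinations, "combinations,",
      nrow(x$screen), "screen entries\n")
  invisible(x)
}

#' Analytic sensitivity measures from the generator's ground truth
#'
#' Computes, from the true curve parameters rather than from generated
#' data: the IC50 and the CMax viability per (cell line, drug), and the
#' combination CMax viability per (cell line, drug pair) by dense
#' evaluation of the true viability surface over the CMax box. These are
#' the recovery targets the full measurement pipeline is validated against.
#'
#' @param world A [generate_world()] result.
#' @param dense_n Grid points per axis for the dense surface minimum.
#' @return A long tibble of sensitivity records matching the shape of
#'   [reconstruct_measures()] output (`cell_line`, `treatment`, `type`,
#'   `measure`, `value`).
#' @export
ground_truth_measures <- function(world, dense_n = 201) {
  stopifnot(inherits(world, "synthetic_world"))
  gt <- world$ground_truth
  cmax_map <- setNames(world$cmax$cmax, world$cmax$drug)

  mono <- gt$curves
  v_star <- 0.5
  gap <- (1 - mono$c) / (v_star - mono$c) - 1
  ic50 <- unname(ifelse(mono$c >= v_star, NA_real_, mono$e * gap^(1 / mono$b)))
  cm <- unname(cmax_map[mono$drug])
  cv <- curve_eval_3pl(mono$b, mono$c, mono$e, cm)
  mono_records <- dplyr::bind_rows(
    tibble::tibble(cell_line = mono$cell_line, treatment = mono$drug,
                   type = "mono", measure = "ic50", value = ic50),
    tibble::tibble(cell_line = mono$cell_line, treatment = mono$drug,
                   type = "mono", measure = "cmax_viability", value = cv)
  )

  cells <- rownames(gt$cell_latent)
  curve_lookup <- gt$curves
  key <- paste(curve_lookup$cell_line, curve_lookup$drug)
  comb_records <- purrr::map_dfr(seq_len(nrow(gt$combos)), function(i) {
    cb <- gt$combos[i, ]
    xa <- seq(0, cmax_map[cb$drug_a], length.out = dense_n)
    xb <- seq(0, cmax_map[cb$drug_b], length.out = dense_n)
    purrr::map_dfr(cells, function(cl) {
      pa <- curve_lookup[match(paste(cl, cb$drug_a), key), ]
      pb <- curve_lookup[match(paste(cl, cb$drug_b), key), ]
      va <- curve_eval_3pl(pa$b, pa$c, pa$e, xa)
      vb <- curve_eval_3pl(pb$b, pb$c, pb$e, xb)
      mod <- interaction_modifier(rep(xa, length(xb)), rep(xb, each = length(xa)),
                                  cb$amp, cb$center_a, cb$center_b, cb$sigma)
      surface <- as.vector(outer(va, vb)) * mod
      tibble::tibble(cell_line = cl,
                     treatment = paste(cb$drug_a, cb$drug_b, sep = " + "),
                     type = "combination",
                     measure = "combination_cmax_viability",
                     value = max(min(surface), 0))
    })
  })
  dplyr::bind_rows(mono_records, comb_records)
}

#' Write a synthetic world's tables to a directory
#'
#' Emits the screen table, expression matrix, drug feature tables and CMax
#' table as plain-text files in the dialects the package readers consume.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_screen_table(world$screen, file.path(dir, "screen.tsv"))
  expr <- tibble::as_tibble(world$expression, rownames = "gene")
  readr::write_csv(expr, file.path(dir, "expression.csv"), progress = FALSE)
  readr::write_csv(world$fingerprints, file.path(dir, "fingerprints.csv"), progress = FALSE)
  readr::write_csv(world$descriptors, file.path(dir, "descriptors.csv"), progress = FALSE)
  readr::write_csv(world$targets, file.path(dir, "targets.csv"), progress = FALSE)
  readr::write_csv(world$cmax, file.path(dir, "cmax.csv"), progress = FALSE)
  invisible(dir)
}
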