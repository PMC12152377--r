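#' Specify a train/test split
#'
#' @param mode `"cell_blind"` holds out entire cell lines (train and test
#'   cell-line sets are disjoint, mimicking prediction for a new patient);
#'   `"random_entry"` splits at the entry level while keeping the duplicated
#'   AB/BA representations of one treatment entry on the same side.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed controlling the split.
#' @param fold_count Number of cross-validation folds (default 5).
#' @return A `split_spec`.
#' @export
split_spec <- function(mode = c("cell_blind", "random_entry"),
                       test_fraction = 0.2, seed = 1, fold_count = 5) {
  mode <- match.arg(mode)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must lie strictly between 0 and 1")
  }
  if (fold_count < 2) abort("fold_count must be at least 2")
  structure(list(mode = mode, test_fraction = test_fraction,
                 seed = as.integer(seed), fold_count = as.integer(fold_count)),
            class = "split_spec")
}

#' Split a screen table into training and test partitions
#'
#' Cell-blind mode samples `test_fraction` of the cell lines and assigns all
#' their entries to the test side, leaving train/test cell-line sets
#' disjoint. Random-entry mode samples canonical entry keys, so the AB/BA
#' duplicates of one treatment entry always land on the same side. The split
#' is deterministic given the seed carried in `spec`.
#'
#' @param table A screen table.
#' @param spec A [split_spec()].
#' @return A `screen_split`: list with screen tables `train` and `test`
#'   (concentration scale preserved) and, for cell-blind splits,
#'   `train_cells`/`test_cells`.
#' @export
make_split <- function(table, spec) {
  stopifnot(inherits(spec, "split_spec"))
  scale <- conc_scale(table)
  if (spec$mode == "cell_blind") {
    cells <- sort(unique(table$cell_line))
    if (length(cells) < 2) abort("cell-blind splitting needs at least 2 cell lines")
    n_test <- max(1L, round(spec$test_fraction * length(cells)))
    if (n_test >= length(cells)) n_test <- length(cells) - 1L
    test_cells <- withr::with_seed(derive_seed(spec$seed, 1L),
                                   sort(sample(cells, n_test)))
    train_cells <- setdiff(cells, test_cells)
    out <- list(
      train = set_conc_scale(dplyr::filter(table, .data$cell_line %in% train_cells), scale),
      test = set_conc_scale(dplyr::filter(table, .data$cell_line %in% test_cells), scale),
      train_cells = train_cells, test_cells = test_cells
    )
  } else {
    keys <- canonical_key(table)
    uniq <- unique(keys)
    n_test <- max(1L, round(spec$test_fraction * length(uniq)))
    if (n_test >= length(uniq)) n_test <- length(uniq) - 1L
    test_keys <- withr::with_seed(derive_seed(spec$seed, 2L), sample(uniq, n_test))
    out <- list(
      train = set_conc_scale(table[!(keys %in% test_keys), , drop = FALSE], scale),
      test = set_conc_scale(table[keys %in% test_keys, , drop = FALSE], scale)
    )
  }
  structure(c(out, list(spec = spec)), class = "screen_split")
}

#' @export
print.screen_split <- function(x, ...) {
  cat("Screen split (", x$spec$mode, "): ", nrow(x$train), " train / ",
      nrow(x$test), " test entries\n", sep = "")
  invisible(x)
}

default_grid <- function(algorithm) {
  switch(algorithm,
    random_forest = list(num_trees = 500, mtry_frac = NA, min_node_size = c(1, 5)),
    elastic_net = list(alpha = c(0.1, 0.5, 0.9), lambda = 10^seq(-3, 1, length.out = 5)),
    neural_network = list(size = c(8, 32), decay = 0.1, maxit = 200),
    list()
  )
}

#' Specify a regression backend
#'
#' All backends share one contract: fit on an encoded training dataset,
#' predict inhibition for an encoded test dataset. `mean_baseline` always
#' predicts the training-target mean; `per_treatment_baseline` predicts the
#' training mean inhibition of the drug (monotherapies) or of the drug
#' combination, falling back to the global mean for treatments unseen in
#' training.
#'
#' @param algorithm One of `"random_forest"`, `"elastic_net"`,
#'   `"neural_network"`, `"mean_baseline"`, `"per_treatment_baseline"`.
#' @param grid Named list of hyperparameter candidate vectors; defaults are
#'   small desk-scale grids (random forest: 500 trees, sqrt features per
#'   split, min node size 1 or 5; elastic net: mixing 0.1/0.5/0.9 by a log
#'   penalty grid; network: one hidden layer of 8 or 32 units with weight
#'   decay).
#' @param selected Named list fixing hyperparameters, bypassing
#'   cross-validation. Single-candidate grid entries are auto-selected.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(algorithm = c("random_forest", "elastic_net", "neural_network",
                                         "mean_baseline", "per_treatment_baseline"),
                           grid = NULL, selected = NULL) {
  algorithm <- match.arg(algorithm)
  grid <- grid %||% default_grid(algorithm)
  if (is.null(selected) && length(grid) > 0 && all(lengths(grid) == 1)) {
    selected <- lapply(grid, `[[`, 1)
  }
  structure(list(algorithm = algorithm, grid = grid, selected = selected,
                 cv_results = NULL),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  cat("Regressor spec:", x$algorithm, "\n")
  if (!is.null(x$selected)) {
    cat("  selected:", paste(names(x$selected), unlist(x$selected),
                             sep = "=", collapse = ", "), "\n")
  } else if (length(x$grid) > 0) {
    cat("  grid of", nrow(expand.grid(x$grid)), "candidates (unselected)\n")
  }
  invisible(x)
}

is_baseline <- function(reg) reg$algorithm %in% c("mean_baseline", "per_treatment_baseline")

# per-sample treatment key from provenance (internal)
provenance_treatment <- function(prov) treatment_id(prov$drug_row, prov$drug_col)

#' Fit a regressor and predict test inhibitions
#'
#' @param reg A [regressor_spec()] with `selected` hyperparameters (baselines
#'   need none).
#' @param train,test `encoded_dataset` objects from [build_dataset()].
#' @param seed Integer seed for stochastic backends.
#' @return Numeric vector of predicted inhibitions, one per test sample. For
#'   `per_treatment_baseline` the number of unseen-treatment fallbacks is
#'   attached as attribute `n_fallback`.
#' @export
fit_predict <- function(reg, train, test, seed = 1) {
  stopifnot(inherits(reg, "regressor_spec"),
            inherits(train, "encoded_dataset"), inherits(test, "encoded_dataset"))
  if (!is_baseline(reg) && is.null(reg$selected)) {
    abort("regressor has no selected hyperparameters; run cross_validate() or fix `selected`")
  }
  n_test <- nrow(test$x)
  hp <- reg$selected
  preds <- switch(reg$algorithm,
    mean_baseline = rep(mean(train$y), n_test),
    per_treatment_baseline = {
      tr_key <- provenance_treatment(train$provenance)
      te_key <- provenance_treatment(test$provenance)
      means <- tapply(train$y, tr_key, mean)
      p <- unname(means[te_key])
      n_fb <- sum(is.na(p))
      p[is.na(p)] <- mean(train$y)
      attr(p, "n_fallback") <- n_fb
      p
    },
    random_forest = {
      mtry <- if (is.null(hp$mtry_frac) || is.na(hp$mtry_frac)) {
        max(1L, floor(sqrt(ncol(train$x))))
      } else max(1L, floor(hp$mtry_frac * ncol(train$x)))
      fit <- ranger::ranger(x = train$x, y = train$y,
                            num.trees = hp$num_trees %||% 500,
                            mtry = mtry,
                            min.node.size = hp$min_node_size %||% 5,
                            seed = derive_seed(seed, 3L), num.threads = 1)
      predict(fit, data = test$x, num.threads = 1)$predictions
    },
    elastic_net = {
      fit <- glmnet::glmnet(train$x, train$y, alpha = hp$alpha %||% 0.5,
                            lambda = hp$lambda %||% 0.01)
      as.numeric(predict(fit, newx = test$x, s = hp$lambda %||% 0.01))
    },
    neural_network = {
      mu <- colMeans(train$x)
      sg <- apply(train$x, 2, sd); sg[sg == 0 | !is.finite(sg)] <- 1
      xs <- sweep(sweep(train$x, 2, mu), 2, sg, "/")
      ys_mu <- mean(train$y); ys_sd <- max(sd(train$y), 1e-8)
      fit <- withr::with_seed(derive_seed(seed, 4L),
        nnet::nnet(xs, (train$y - ys_mu) / ys_sd,
                   size = hp$size %||% 16, decay = hp$decay %||% 0.1,
                   maxit = hp$maxit %||% 200, linout = TRUE, trace = FALSE,
                   MaxNWts = 200000))
      xt <- sweep(sweep(test$x, 2, mu), 2, sg, "/")
      as.numeric(predict(fit, xt)) * ys_sd + ys_mu
    }
  )
  if (!all(is.finite(preds))) abort("regressor produced non-finite predictions")
  preds
}

#' Select hyperparameters by cell-blind cross-validation
#'
#' Partitions the training cell lines into `spec$fold_count` disjoint folds.
#' For each hyperparameter candidate and each fold, the cell feature model is
#' refit on that fold's training cells only (held-out fold cells never touch
#' the PCA), datasets are encoded, the model is fit and the fold mean
#' absolute error (MAE) recorded. The candidate with the smallest mean MAE
#' across folds wins; ties are broken by grid order.
#'
#' @param table Preprocessed training screen table (log1p scale).
#' @param expression Genes x cells expression matrix.
#' @param spec A [split_spec()] supplying seed and `fold_count`.
#' @param reg A [regressor_spec()] with a candidate grid.
#' @param cfg A [drug_encoding_config()].
#' @param n_components Number of cell principal components.
#' @param duplicate Duplicate AB/BA combination samples (order-dependent
#'   settings only)?
#' @return The regressor spec with `selected` filled in and a `cv_results`
#'   tibble (one row per candidate x fold, with `mae`).
#' @export
cross_validate <- function(table, expression, spec, reg, cfg,
                           n_components, duplicate = FALSE) {
  stopifnot(inherits(spec, "split_spec"), inherits(reg, "regressor_spec"))
  candidates <- expand.grid(reg$grid, stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) abort("hyperparameter grid is empty")
  cells <- sort(unique(table$cell_line))
  if (length(cells) < spec$fold_count) {
    abort("fewer training cell lines than cross-validation folds")
  }
  fold_of <- withr::with_seed(derive_seed(spec$seed, 5L), {
    shuffled <- sample(cells)
    setNames(rep_len(seq_len(spec$fold_count), length(cells)),
             shuffled)
  })
  scale <- conc_scale(table)
  fold_data <- lapply(seq_len(spec$fold_count), function(f) {
    tr_cells <- names(fold_of)[fold_of != f]
    te_cells <- names(fold_of)[fold_of == f]
    tr_tbl <- set_conc_scale(dplyr::filter(table, .data$cell_line %in% tr_cells), scale)
    te_tbl <- set_conc_scale(dplyr::filter(table, .data$cell_line %in% te_cells), scale)
    if (nrow(tr_tbl) == 0 || nrow(te_tbl) == 0) {
      abort(paste0("cross-validation fold ", f, " has no samples"))
    }
    # per-fold PCA refit: feature space never sees held-out fold cells
    cm <- fit_cell_features(expression, tr_cells,
                            min(n_components, length(tr_cells)))
    list(train = build_dataset(tr_tbl, cm, cfg, expression, duplicate = duplicate),
         test = build_dataset(te_tbl, cm, cfg, expression, duplicate = duplicate))
  })
  results <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- as.list(candidates[i, , drop = FALSE])
    reg_i <- reg; reg_i$selected <- cand
    purrr::map_dfr(seq_len(spec$fold_count), function(f) {
      preds <- fit_predict(reg_i, fold_data[[f]]$train, fold_data[[f]]$test,
                           seed = derive_seed(spec$seed, 10L + f))
      dplyr::bind_cols(tibble::as_tibble(cand),
                       tibble::tibble(candidate = i, fold = f,
                                      mae = mean(abs(preds - fold_data[[f]]$test$y))))
    })
  })
  mean_mae <- tapply(results$mae, results$candidate, mean)
  winner <- as.integer(names(mean_mae)[which.min(mean_mae)])  # ties: grid order
  reg$selected <- as.list(candidates[winner, , drop = FALSE])
  reg$cv_results <- results
  reg
}

#' @method tidy regressor_spec
#' @export
tidy.regressor_spec <- function(x, ...) {
  if (is.null(x$cv_results)) {
    return(tibble::tibble(term = names(x$selected),
                          value = as.character(unlist(x$selected))))
  }
  x$cv_results
}

#' @method glance regressor_spec
#' @export
glance.regressor_spec <- function(x, ...) {
  out <- tibble::tibble(algorithm = x$algorithm)
  if (!is.null(x$cv_results)) {
    out$cv_mae <- min(tapply(x$cv_results$mae, x$cv_results$candidate, mean))
  }
  if (!is.null(x$selected)) {
    out$selected <- paste(names(x$selected), unlist(x$selected),
                          sep = "=", collapse = ", ")
  }
  out
}
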