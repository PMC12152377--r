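test_that("cell-blind splits hold out whole cell lines, deterministically", {
  w <- tiny_world(seed = 5, n_cells = 10)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  sp <- make_split(pp, split_spec("cell_blind", test_fraction = 0.2, seed = 9))
  expect_length(sp$test_cells, 2)
  expect_length(sp$train_cells, 8)
  expect_length(intersect(unique(sp$train$cell_line), unique(sp$test$cell_line)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(pp))

  sp2 <- make_split(pp, split_spec("cell_blind", test_fraction = 0.2, seed = 9))
  expect_identical(sp$test_cells, sp2$test_cells)
  sp3 <- make_split(pp, split_spec("cell_blind", test_fraction = 0.2, seed = 10))
  expect_false(identical(sp$test_cells, sp3$test_cells))

  expect_error(split_spec("cell_blind", test_fraction = 1.2), "test_fraction")
})

test_that("random-entry splits keep duplicated AB/BA samples on one side", {
  w <- tiny_world(seed = 5)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  sp <- make_split(pp, split_spec("random_entry", test_fraction = 0.25, seed = 3))
  cm <- fit_cell_features(w$expression, colnames(w$expression), 5)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  tr <- build_dataset(sp$train, cm, cfg, w$expression, duplicate = TRUE)
  te <- build_dataset(sp$test, cm, cfg, w$expression, duplicate = TRUE)
  expect_length(intersect(tr$provenance$entry_key, te$provenance$entry_key), 0)
  # test cell lines may overlap training cell lines in this mode
  expect_gt(length(intersect(unique(sp$train$cell_line),
                             unique(sp$test$cell_line))), 0)
})

test_that("baseline predictions follow their definitions", {
  w <- tiny_world(seed = 5)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 4)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  ds <- build_dataset(pp, cm, cfg, w$expression)
  tr <- combosens:::subset_dataset(ds, 1:200)
  te <- combosens:::subset_dataset(ds, 201:260)

  pm <- fit_predict(regressor_spec("mean_baseline"), tr, te)
  expect_equal(pm, rep(mean(tr$y), 60))

  pt <- fit_predict(regressor_spec("per_treatment_baseline"), tr, te)
  key_tr <- combosens:::provenance_treatment(tr$provenance)
  key_te <- combosens:::provenance_treatment(te$provenance)
  seen <- key_te %in% key_tr
  if (any(seen)) {
    i <- which(seen)[1]
    expect_equal(pt[i], mean(tr$y[key_tr == key_te[i]]))
  }
  if (any(!seen)) {
    expect_equal(as.numeric(unique(pt[!seen])), mean(tr$y))
  }
})

test_that("a random forest fits noiseless feature-determined targets closely", {
  w <- tiny_world(seed = 17, noise_sd = 0)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 4)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  ds <- build_dataset(pp, cm, cfg, w$expression)
  reg <- regressor_spec("random_forest",
                        grid = list(num_trees = 200, mtry_frac = 0.5, min_node_size = 1))
  preds <- fit_predict(reg, ds, ds, seed = 2)
  train_mae <- mean(abs(preds - ds$y))
  base_mae <- mean(abs(mean(ds$y) - ds$y))
  expect_lt(train_mae, 0.25 * base_mae)
})

test_that("cross-validation partitions cells into disjoint folds and selects by MAE", {
  w <- tiny_world(seed = 23, n_cells = 10)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  sspec <- split_spec("cell_blind", seed = 4, fold_count = 5)

  # single candidate: selected, with per-fold MAEs reported
  reg1 <- regressor_spec("elastic_net", grid = list(alpha = 0.5, lambda = 0.01))
  cv1 <- cross_validate(pp, w$expression, sspec, reg1, cfg, n_components = 4)
  expect_equal(cv1$selected$alpha, 0.5)
  expect_equal(nrow(cv1$cv_results), 5)
  expect_true(all(is.finite(cv1$cv_results$mae)))

  # all five folds over the 10 cells were evaluated
  expect_setequal(unique(cv1$cv_results$fold), 1:5)

  # a near-constant model (huge penalty) loses to a fitting one on signal data
  reg2 <- regressor_spec("elastic_net", grid = list(alpha = 0.5, lambda = c(1e6, 0.01)))
  cv2 <- cross_validate(pp, w$expression, sspec, reg2, cfg, n_components = 4)
  expect_equal(cv2$selected$lambda, 0.01)
  expect_equal(glance(cv2)$cv_mae,
               min(tapply(cv2$cv_results$mae, cv2$cv_results$candidate, mean)))
})

test_that("a trained forest beats both baselines on a cell-blind synthetic split", {
  w <- tiny_world(seed = 29, n_cells = 14)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  sp <- make_split(pp, split_spec("cell_blind", seed = 6))
  cm <- fit_cell_features(w$expression, sp$train_cells, 5)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  tr <- build_dataset(sp$train, cm, cfg, w$expression, duplicate = TRUE)
  te <- build_dataset(sp$test, cm, cfg, w$expression, duplicate = TRUE)
  reg <- regressor_spec("random_forest",
                        grid = list(num_trees = 150, mtry_frac = NA, min_node_size = 5))
  mae <- function(p) mean(abs(p - te$y))
  m_rf <- mae(fit_predict(reg, tr, te, seed = 1))
  m_mean <- mae(fit_predict(regressor_spec("mean_baseline"), tr, te))
  m_treat <- mae(fit_predict(regressor_spec("per_treatment_baseline"), tr, te))
  expect_lt(m_rf, m_mean)
  expect_lt(m_rf, m_treat)
})
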