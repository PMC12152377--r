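test_that("cell feature model centers on training cells only", {
  set.seed(42)
  expr <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("G%02d", 1:50), sprintf("CL%d", 1:8)))
  train <- sprintf("CL%d", 1:6)
  cm <- fit_cell_features(expr, train, 4)
  expect_equal(cm$gene_means, rowMeans(expr[, train]))
  # means do not change when test columns change
  expr2 <- expr
  expr2[, 7:8] <- expr2[, 7:8] + 100
  cm2 <- fit_cell_features(expr2, train, 4)
  expect_equal(cm$gene_means, cm2$gene_means)
  expect_equal(as.numeric(project_cells(cm2, expr2, "CL7")),
               as.numeric(project_cells(cm, expr, "CL7")) +
                 100 * as.numeric(colSums(cm$component_loadings)))

  # duplicate columns project identically
  expr3 <- expr
  expr3[, "CL2"] <- expr3[, "CL1"]
  cm3 <- fit_cell_features(expr3, train, 3)
  sc <- project_cells(cm3, expr3, c("CL1", "CL2"))
  expect_equal(sc[1, ], sc[2, ])

  expect_error(fit_cell_features(expr, train, 7), "n_components")
})

test_that("low-rank expression is captured by the leading components", {
  w <- tiny_world(seed = 7, n_genes = 120, latent_dim = 3)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 6)
  var_explained <- cumsum(cm$sdev^2) / sum(cm$sdev^2)
  expect_gte(var_explained[3], 0.95)
})

make_cfgs <- function(w) {
  drugs <- sort(unique(w$screen$drug_row))
  list(
    onehot = drug_encoding_config("onehot", drugs = drugs),
    onehottar = drug_encoding_config("onehottar", drugs = drugs,
                                     targets = w$targets, min_target_degree = 1),
    maccs = drug_encoding_config("maccs", fingerprints = w$fingerprints),
    physchem = drug_encoding_config("physchem", descriptors = w$descriptors)
  )
}

test_that("encodings have the documented block structure and lengths", {
  w <- tiny_world(seed = 13)
  cfgs <- make_cfgs(w)
  n_fp <- ncol(cfgs$maccs$fingerprint_matrix)
  n_pc <- ncol(cfgs$physchem$descriptor_matrix)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 5)

  combo <- pp[!is.na(pp$drug_col), ][1, ]
  mono <- pp[is.na(pp$drug_col), ][1, ]
  combo <- combosens:::set_conc_scale(combo, "log1p")
  mono <- combosens:::set_conc_scale(mono, "log1p")

  enc <- encode_entry(combo, cm, cfgs$maccs, w$expression)
  expect_length(enc$drug_features, 2 * n_fp + 2)
  expect_length(encode_entry(combo, cm, cfgs$physchem, w$expression)$drug_features,
                2 * n_pc + 2)
  expect_length(encode_entry(combo, cm, cfgs$onehot, w$expression)$drug_features, 6)
  expect_length(enc$cell_features, 5)

  # monotherapy zeroes the second fingerprint block and its concentration
  encm <- encode_entry(mono, cm, cfgs$maccs, w$expression)
  second <- encm$drug_features[(n_fp + 2):(2 * n_fp + 2)]
  expect_true(all(second == 0))

  # the deliberately constant descriptor column was dropped
  expect_false("prop_const" %in% colnames(cfgs$physchem$descriptor_matrix))

  expect_error(
    encode_entry(dplyr::mutate(combo, drug_row = "NOPE"), cm, cfgs$onehot, w$expression),
    "NOPE")
})

test_that("one-hot concentration features count the dosed drugs", {
  w <- tiny_world(seed = 13)
  cfgs <- make_cfgs(w)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 5)
  ds <- build_dataset(pp, cm, cfgs$onehot, w$expression)
  drug_block <- ds$x[, grepl("^drug_", colnames(ds$x)), drop = FALSE]
  n_dosed <- rowSums(drug_block > 0)
  expect_equal(n_dosed, ifelse(is.na(ds$provenance$drug_col), 1, 2))
})

test_that("target features count how many entry drugs hit each molecule", {
  targets <- tibble::tibble(drug = c("A", "B", "B"), target = c("m1", "m1", "m2"))
  cfg <- drug_encoding_config("onehottar", drugs = c("A", "B"),
                              targets = targets, min_target_degree = 1)
  tbl <- screen_tbl("CL1", "A", "B", log1p(1), log1p(2), 10)
  attr(tbl, "conc_scale") <- "log1p"
  expr <- matrix(rnorm(10 * 2), 10, 2,
                 dimnames = list(sprintf("G%d", 1:10), c("CL1", "CL2")))
  cm <- fit_cell_features(expr, c("CL1", "CL2"), 1)
  enc <- encode_entry(tbl, cm, cfg, expr)
  expect_equal(unname(enc$drug_features["target_m1"]), 2)
  expect_equal(unname(enc$drug_features["target_m2"]), 1)

  # degree filter: m2 targeted by one drug only
  cfg5 <- drug_encoding_config("onehottar", drugs = c("A", "B"),
                               targets = targets, min_target_degree = 2)
  expect_identical(cfg5$target_index, "m1")
})

test_that("AB and BA encodings are block swaps with identical cell features", {
  w <- tiny_world(seed = 13)
  cfg <- drug_encoding_config("maccs", fingerprints = w$fingerprints)
  n_fp <- ncol(cfg$fingerprint_matrix)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 5)
  combo <- combosens:::set_conc_scale(pp[!is.na(pp$drug_col), ][3, ], "log1p")
  ab <- encode_entry(combo, cm, cfg, w$expression, order = "AB")
  ba <- encode_entry(combo, cm, cfg, w$expression, order = "BA")
  b1 <- seq_len(n_fp + 1); b2 <- (n_fp + 2):(2 * n_fp + 2)
  expect_equal(unname(ab$drug_features[b1]), unname(ba$drug_features[b2]))
  expect_equal(unname(ab$drug_features[b2]), unname(ba$drug_features[b1]))
  expect_equal(ab$cell_features, ba$cell_features)
  expect_equal(ab$target, ba$target)
})

test_that("dataset duplication doubles combinations only, for order-bound settings", {
  w <- tiny_world(seed = 13)
  cfgs <- make_cfgs(w)
  pp <- preprocess_screen(w$screen, drug_min_entries = 1)
  cm <- fit_cell_features(w$expression, colnames(w$expression), 5)
  n_combo <- sum(!is.na(pp$drug_col)); n_mono <- sum(is.na(pp$drug_col))

  dup <- build_dataset(pp, cm, cfgs$maccs, w$expression, duplicate = TRUE)
  expect_equal(nrow(dup$x), 2 * n_combo + n_mono)
  nodup <- build_dataset(pp, cm, cfgs$maccs, w$expression, duplicate = FALSE)
  expect_equal(nrow(nodup$x), n_combo + n_mono)

  expect_warning(
    oh <- build_dataset(pp, cm, cfgs$onehot, w$expression, duplicate = TRUE),
    "order-free")
  expect_equal(nrow(oh$x), n_combo + n_mono)

  # duplicated pairs share target values and keys
  dupes <- dup$provenance[dup$provenance$order == "BA", ]
  m <- match(dupes$entry_key, dup$provenance$entry_key)
  expect_equal(dup$y[m], dup$y[dup$provenance$order == "BA"])

  # raw-scale tables are refused
  expect_error(build_dataset(w$screen, cm, cfgs$maccs, w$expression), "log1p")
})
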