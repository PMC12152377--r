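#' Fit principal-component cell-line features
#'
#' Runs a PCA on the gene-expression profiles of the training cell lines only
#' (centering, no per-gene scaling: the expression input is expected to be
#' already normalized) and keeps the first `n_components` components. The
#' model can then project any cell line, including held-out ones, using the
#' training-cell gene means — test cells never influence the feature space.
#'
#' @param expression Numeric matrix, genes x cell lines, with gene row names
#'   and cell-line column names.
#' @param training_cells Character vector of training cell-line identifiers
#'   (must be columns of `expression`).
#' @param n_components Number of components to keep; large corpora
#'   conventionally use 300, desk-scale screens proportionally fewer. Must
#'   not exceed `min(length(training_cells), nrow(expression))`.
#' @return A `cell_feature_model` with orthonormal loadings (genes x
#'   `n_components`), the training-cell gene means, and the training cell ids.
#' @export
fit_cell_features <- function(expression, training_cells, n_components) {
  if (!all(training_cells %in% colnames(expression))) {
    abort("training_cells contains cell lines absent from the expression matrix")
  }
  if (n_components > min(length(training_cells), nrow(expression))) {
    abort(paste0("n_components (", n_components, ") exceeds min(n training cells, n genes) = ",
                 min(length(training_cells), nrow(expression))))
  }
  train <- expression[, training_cells, drop = FALSE]
  pca <- prcomp(t(train), center = TRUE, scale. = FALSE, rank. = n_components)
  structure(
    list(
      training_cell_ids = training_cells,
      component_loadings = pca$rotation[, seq_len(n_components), drop = FALSE],
      gene_means = pca$center,
      sdev = pca$sdev,
      n_components = n_components
    ),
    class = "cell_feature_model"
  )
}

#' Project cell lines into the fitted component space
#'
#' @param model A `cell_feature_model` from [fit_cell_features()].
#' @param expression Genes x cells expression matrix covering the cells to
#'   project (gene set must match the fitted model).
#' @param cells Cells to project; defaults to all columns.
#' @return Numeric matrix, cells x components.
#' @export
project_cells <- function(model, expression, cells = colnames(expression)) {
  stopifnot(inherits(model, "cell_feature_model"))
  if (!all(rownames(model$component_loadings) %in% rownames(expression))) {
    abort("expression matrix does not cover the genes of the fitted model")
  }
  x <- t(expression[rownames(model$component_loadings), cells, drop = FALSE])
  sweep(x, 2, model$gene_means) %*% model$component_loadings
}

#' @export
print.cell_feature_model <- function(x, ...) {
  cat("Cell feature model:", x$n_components, "components fitted on",
      length(x$training_cell_ids), "training cell lines,",
      nrow(x$component_loadings), "genes\n")
  invisible(x)
}

#' Configure a drug/concentration encoding
#'
#' Four encodings of the treatment (drugs + concentrations) are supported:
#' \describe{
#'   \item{`onehot`}{One feature per drug in `drugs`; a drug present in the
#'     entry carries its log1p-scaled concentration, all others 0.}
#'   \item{`onehottar`}{The `onehot` block plus one count feature per target
#'     molecule targeted by at least `min_target_degree` of the drugs; each
#'     target feature counts how many drugs of the entry target it (0-2).}
#'   \item{`maccs`}{Two binary fingerprint blocks, each followed by that
#'     drug's concentration; for monotherapies the second block and its
#'     concentration are zero.}
#'   \item{`physchem`}{Like `maccs` with numeric physico-chemical descriptor
#'     blocks.}
#' }
#' Fingerprint/descriptor columns that show no variation across the
#' configured drugs are dropped, so block lengths are data-dependent.
#'
#' @param setting One of `"onehot"`, `"onehottar"`, `"maccs"`, `"physchem"`.
#' @param drugs Ordered drug index (required for `onehot`/`onehottar`).
#' @param targets Drug-to-target mapping, a data frame with columns `drug`
#'   and `target` (required for `onehottar`).
#' @param fingerprints Data frame with a `drug` column and binary fingerprint
#'   columns (required for `maccs`).
#' @param descriptors Data frame with a `drug` column and numeric descriptor
#'   columns (required for `physchem`).
#' @param min_target_degree Minimum number of configured drugs that must
#'   target a molecule for it to become a feature (default 5).
#' @return A `drug_encoding_config`.
#' @export
drug_encoding_config <- function(setting = c("onehot", "onehottar", "maccs", "physchem"),
                                 drugs = NULL, targets = NULL,
                                 fingerprints = NULL, descriptors = NULL,
                                 min_target_degree = 5) {
  setting <- match.arg(setting)
  cfg <- list(setting = setting, min_target_degree = min_target_degree)

  feature_matrix <- function(df, what) {
    if (is.null(df)) abort(paste0("setting '", setting, "' requires a ", what, " table"))
    if (!"drug" %in% names(df)) abort(paste0(what, " table needs a 'drug' key column"))
    m <- as.matrix(df[setdiff(names(df), "drug")])
    storage.mode(m) <- "double"
    rownames(m) <- df$drug
    keep <- apply(m, 2, function(col) length(unique(col)) > 1)
    if (!any(keep)) abort(paste0("all ", what, " columns are constant"))
    m[, keep, drop = FALSE]
  }

  if (setting %in% c("onehot", "onehottar")) {
    if (is.null(drugs)) abort("onehot encodings require an ordered drug index")
    cfg$drug_index <- drugs
  }
  if (setting == "onehottar") {
    if (is.null(targets)) abort("setting 'onehottar' requires a drug-target table")
    tar <- dplyr::filter(tibble::as_tibble(targets), .data$drug %in% drugs)
    degree <- table(unique(tar)[["target"]])
    cfg$target_index <- sort(names(degree)[degree >= min_target_degree])
    cfg$target_map <- unique(tar)
  }
  if (setting == "maccs") cfg$fingerprint_matrix <- feature_matrix(fingerprints, "fingerprint")
  if (setting == "physchem") cfg$descriptor_matrix <- feature_matrix(descriptors, "descriptor")
  structure(cfg, class = "drug_encoding_config")
}

# length of the drug-feature block for a config
drug_block_length <- function(cfg) {
  switch(cfg$setting,
    onehot = length(cfg$drug_index),
    onehottar = length(cfg$drug_index) + length(cfg$target_index),
    maccs = 2L * ncol(cfg$fingerprint_matrix) + 2L,
    physchem = 2L * ncol(cfg$descriptor_matrix) + 2L
  )
}

#' @export
print.drug_encoding_config <- function(x, ...) {
  cat("Drug encoding config: setting '", x$setting, "', ",
      drug_block_length(x), " drug features\n", sep = "")
  invisible(x)
}

# drug feature rows for a vector of entries (internal, vectorized)
encode_drug_block <- function(table, cfg, order = "AB") {
  n <- nrow(table)
  known <- function(d) {
    d <- d[!is.na(d)]
    pool <- switch(cfg$setting,
      onehot = , onehottar = cfg$drug_index,
      maccs = rownames(cfg$fingerprint_matrix),
      physchem = rownames(cfg$descriptor_matrix))
    bad <- setdiff(unique(d), pool)
    if (length(bad) > 0) {
      abort(paste0("cannot encode unknown drug(s): ", paste(bad, collapse = ", ")))
    }
  }
  known(table$drug_row); known(table$drug_col)

  if (cfg$setting %in% c("onehot", "onehottar")) {
    m <- matrix(0, n, length(cfg$drug_index),
                dimnames = list(NULL, paste0("drug_", cfg$drug_index)))
    m[cbind(seq_len(n), match(table$drug_row, cfg$drug_index))] <- table$conc_row
    has2 <- which(!is.na(table$drug_col))
    m[cbind(has2, match(table$drug_col[has2], cfg$drug_index))] <- table$conc_col[has2]
    if (cfg$setting == "onehottar") {
      tmap <- matrix(0, length(cfg$drug_index), length(cfg$target_index),
                     dimnames = list(cfg$drug_index, cfg$target_index))
      tm <- dplyr::filter(cfg$target_map, .data$target %in% cfg$target_index)
      tmap[cbind(match(tm$drug, cfg$drug_index), match(tm$target, cfg$target_index))] <- 1
      present <- matrix(0, n, length(cfg$drug_index))
      present[cbind(seq_len(n), match(table$drug_row, cfg$drug_index))] <- 1
      present[cbind(has2, match(table$drug_col[has2], cfg$drug_index))] <-
        present[cbind(has2, match(table$drug_col[has2], cfg$drug_index))] + 1
      counts <- present %*% tmap
      colnames(counts) <- paste0("target_", cfg$target_index)
      m <- cbind(m, counts)
    }
    return(m)
  }

  # feature-block settings: [block1 | conc1 | block2 | conc2]
  fm <- if (cfg$setting == "maccs") cfg$fingerprint_matrix else cfg$descriptor_matrix
  L <- ncol(fm)
  first_drug <- table$drug_row; first_conc <- table$conc_row
  second_drug <- table$drug_col; second_conc <- table$conc_col
  if (order == "BA") {
    comb <- !is.na(table$drug_col)
    first_drug[comb] <- table$drug_col[comb]; first_conc[comb] <- table$conc_col[comb]
    second_drug[comb] <- table$drug_row[comb]; second_conc[comb] <- table$conc_row[comb]
  }
  block1 <- fm[match(first_drug, rownames(fm)), , drop = FALSE]
  block2 <- matrix(0, n, L)
  has2 <- !is.na(second_drug)
  block2[has2, ] <- fm[match(second_drug[has2], rownames(fm)), , drop = FALSE]
  second_conc[!has2] <- 0
  m <- cbind(block1, first_conc, block2, second_conc)
  colnames(m) <- c(paste0("d1_", colnames(fm)), "conc1",
                   paste0("d2_", colnames(fm)), "conc2")
  rownames(m) <- NULL
  m
}

#' Encode a single screen entry
#'
#' Builds the model-ready feature vector for one entry: the cell line's
#' principal-component scores followed by the drug/concentration block of the
#' configured setting. `onehot`/`onehottar` encodings are independent of drug
#' order; `maccs`/`physchem` place the drug blocks in the requested `order`
#' with each concentration adjacent to its drug block.
#'
#' @param entry One-row screen table (log1p concentration scale).
#' @param cell_model A fitted [fit_cell_features()] model.
#' @param cfg A [drug_encoding_config()].
#' @param expression Genes x cells expression matrix covering the entry's
#'   cell line.
#' @param order `"AB"` keeps the entry's drug orientation, `"BA"` swaps the
#'   two drug blocks (combination entries only).
#' @return A list with `cell_features`, `drug_features`, `target` (the
#'   inhibition) and `provenance`.
#' @export
encode_entry <- function(entry, cell_model, cfg, expression, order = c("AB", "BA")) {
  order <- match.arg(order)
  if (nrow(entry) != 1) abort("encode_entry expects exactly one entry")
  if (conc_scale(entry) != "log1p") {
    abort("entries must be log1p-scaled before encoding (run preprocess_screen)")
  }
  list(
    cell_features = drop(project_cells(cell_model, expression, entry$cell_line)),
    drug_features = drop(encode_drug_block(entry, cfg, order)),
    target = entry$inhibition,
    provenance = tibble::tibble(entry_key = canonical_key(entry), order = order)
  )
}

#' Build a model-ready dataset from a preprocessed screen
#'
#' Encodes every entry of `table` as cell principal components plus the
#' configured drug/concentration block. For the order-dependent `maccs` and
#' `physchem` settings with `duplicate = TRUE`, every combination entry is
#' included twice — once per drug order (AB and BA) — with the same target,
#' so a trained model learns order-robust predictions; monotherapies are
#' never duplicated. The order-free `onehot`/`onehottar` settings ignore
#' `duplicate` with a warning.
#'
#' @inheritParams encode_entry
#' @param table Preprocessed screen table (log1p scale).
#' @param duplicate Include both drug orders of each combination entry?
#' @return An `encoded_dataset`: a list with feature matrix `x`, target
#'   vector `y` and a `provenance` tibble (entry key, drug pair,
#'   concentrations and order flag per sample, in deterministic order).
#' @export
build_dataset <- function(table, cell_model, cfg, expression, duplicate = FALSE) {
  if (conc_scale(table) != "log1p") {
    abort("table must be log1p-scaled before encoding (run preprocess_screen)")
  }
  order_free <- cfg$setting %in% c("onehot", "onehottar")
  if (duplicate && order_free) {
    warn("duplicate = TRUE has no effect for order-free encodings; building single samples")
    duplicate <- FALSE
  }
  cells <- unique(table$cell_line)
  scores <- project_cells(cell_model, expression, cells)
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))

  make_x <- function(tbl, order) {
    cbind(scores[match(tbl$cell_line, cells), , drop = FALSE],
          encode_drug_block(tbl, cfg, order))
  }
  prov <- function(tbl, order) {
    tibble::tibble(entry_key = canonical_key(tbl), cell_line = tbl$cell_line,
                   drug_row = tbl$drug_row, drug_col = tbl$drug_col,
                   conc_row = tbl$conc_row, conc_col = tbl$conc_col,
                   order = order)
  }
  x <- make_x(table, "AB")
  provenance <- prov(table, "AB")
  y <- table$inhibition
  if (duplicate) {
    comb <- dplyr::filter(tibble::as_tibble(table), !is.na(.data$drug_col))
    if (nrow(comb) > 0) {
      x <- rbind(x, make_x(comb, "BA"))
      provenance <- dplyr::bind_rows(provenance, prov(comb, "BA"))
      y <- c(y, comb$inhibition)
    }
  }
  rownames(x) <- NULL
  structure(list(x = x, y = y, provenance = provenance, setting = cfg$setting),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("Encoded dataset ('", x$setting, "'): ", nrow(x$x), " samples x ",
      ncol(x$x), " features\n", sep = "")
  invisible(x)
}

# subset an encoded dataset by sample index (internal)
subset_dataset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                 provenance = ds$provenance[idx, , drop = FALSE],
                 setting = ds$setting),
            class = "encoded_dataset")
}
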