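#' Read a combination-screen table
#'
#' Reads a DrugComb-style screen export with one row per dose-response
#' measurement. The required columns are `cell_line`, `drug_row`, `drug_col`,
#' `conc_row`, `conc_col` (micromolar) and `inhibition` (relative inhibition,
#' percent-like). Monotherapies carry an absent second drug, encoded by any of
#' the `null_tokens` in `drug_col` with `conc_col = 0`.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` uses a comma, anything else a tab).
#' @param null_tokens Character values of `drug_col` interpreted as "no second
#'   drug". `NA` is always accepted.
#' @return A screen table: a [tibble::tibble()] with the six columns above
#'   (`drug_col` is `NA` for monotherapies) in file order, flagged as being on
#'   the raw micromolar concentration scale.
#' @seealso [preprocess_screen()], [write_screen_table()]
#' @export
read_screen_table <- function(path, delim = NULL, null_tokens = c("NULL", "", "NA")) {
  if (!file.exists(path)) {
    abort(paste0("screen table file does not exist: ", path))
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
  required <- c("cell_line", "drug_row", "drug_col", "conc_row", "conc_col", "inhibition")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("screen table is missing required column(s): ", paste(missing, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      # +1 for the header line
      abort(paste0("unparseable numeric value '", x[bad[1]], "' in column '", col,
                   "' at line ", bad[1] + 1L))
    }
    out
  }
  tbl <- tibble::tibble(
    cell_line = raw$cell_line,
    drug_row = raw$drug_row,
    drug_col = ifelse(raw$drug_col %in% null_tokens | is.na(raw$drug_col), NA_character_, raw$drug_col),
    conc_row = parse_num(raw$conc_row, "conc_row"),
    conc_col = parse_num(raw$conc_col, "conc_col"),
    inhibition = parse_num(raw$inhibition, "inhibition")
  )
  if (anyNA(tbl$inhibition) || anyNA(tbl$conc_row) || anyNA(tbl$conc_col)) {
    abort("screen table contains missing concentration or inhibition values")
  }
  set_conc_scale(tbl, "raw_uM")
}

#' Write a screen table
#'
#' Inverse of [read_screen_table()]: monotherapies are emitted with the
#' literal token `NULL` in `drug_col`. Integer-valued numeric fields
#' round-trip bit-stably.
#'
#' @param table A screen table.
#' @param path Output path; `.csv` extension selects comma separation,
#'   anything else tab separation.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(table, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- dplyr::mutate(table, drug_col = ifelse(is.na(.data$drug_col), "NULL", .data$drug_col))
  readr::write_delim(out, path, delim = delim, na = "NULL", progress = FALSE)
  invisible(path)
}

#' Preprocess a raw combination screen
#'
#' Applies, in order: (1) drop quality-flagged entries with inhibition
#' outside \[-200, 200\]; (2) drop entries where every tested concentration is
#' zero; (3) drop entries whose cell line has no expression profile; (4) merge
#' same-drug "combinations" into monotherapies by summing the two
#' concentrations; (5) rewrite two-drug entries where exactly one
#' concentration is positive as monotherapies of the dosed drug; (6) average
#' inhibition over replicates sharing the same cell line, unordered drug pair
#' and concentration pair; (7) log1p-transform both concentration columns;
#' (8) keep only drugs with at least `drug_min_entries` remaining entries.
#'
#' Replicate detection canonicalizes drug pairs lexicographically, with each
#' concentration following its drug. The drug-count filter is applied once,
#' after all other steps, and is not iterated.
#'
#' @param table A screen table on the raw micromolar scale.
#' @param cells_with_expression Character vector of cell-line identifiers with
#'   an expression profile; entries for other cell lines are dropped. `NULL`
#'   keeps all cell lines.
#' @param drug_min_entries Minimum number of post-filter entries a drug needs
#'   to be retained (large screens conventionally use 10000; pick a value
#'   matched to the screen size).
#' @param log1p_concs Apply the log1p transform (step 7)? Disable to obtain a
#'   replicate-averaged table that stays on the micromolar scale, e.g. for
#'   dose-response reconstruction.
#' @return A new preprocessed screen table; the input is unchanged. The
#'   concentration-scale flag records whether log1p was applied.
#' @examples
#' tbl <- tibble::tibble(
#'   cell_line = "CL1", drug_row = "A", drug_col = c("A", NA),
#'   conc_row = c(1, 2), conc_col = c(2, 0), inhibition = c(30, 250)
#' )
#' preprocess_screen(tbl, drug_min_entries = 1)
#' @export
preprocess_screen <- function(table, cells_with_expression = NULL,
                              drug_min_entries = 10000, log1p_concs = TRUE) {
  if (conc_scale(table) == "log1p") {
    abort("screen table is already log1p-scaled; refusing to normalize twice")
  }
  tbl <- tibble::as_tibble(table)

  # (1) quality filter on inhibition
  tbl <- dplyr::filter(tbl, .data$inhibition >= -200, .data$inhibition <= 200)
  # (2) all-zero concentrations carry no treatment
  tbl <- dplyr::filter(tbl, !(.data$conc_row == 0 & .data$conc_col == 0))
  # (3) restrict to cell lines with molecular features
  if (!is.null(cells_with_expression)) {
    tbl <- dplyr::filter(tbl, .data$cell_line %in% cells_with_expression)
  }
  # (4) same drug on both axes: a monotherapy at the summed concentration
  same <- !is.na(tbl$drug_col) & tbl$drug_col == tbl$drug_row
  tbl$conc_row[same] <- tbl$conc_row[same] + tbl$conc_col[same]
  tbl$conc_col[same] <- 0
  tbl$drug_col[same] <- NA_character_
  # (5) two drugs but only one dosed: a monotherapy of the dosed drug
  only_col <- !is.na(tbl$drug_col) & tbl$conc_row == 0 & tbl$conc_col > 0
  tbl$drug_row[only_col] <- tbl$drug_col[only_col]
  tbl$conc_row[only_col] <- tbl$conc_col[only_col]
  only_row <- !is.na(tbl$drug_col) & tbl$conc_col == 0 & tbl$conc_row > 0
  tbl$drug_col[only_col | only_row] <- NA_character_
  tbl$conc_col[only_col | only_row] <- 0
  # (6) replicate averaging over the canonical key
  cp <- canonicalize_pair(tbl$drug_row, tbl$drug_col, tbl$conc_row, tbl$conc_col)
  tbl <- dplyr::bind_cols(tbl["cell_line"], cp, tbl["inhibition"])
  tbl <- dplyr::summarise(
    dplyr::group_by(tbl, .data$cell_line, .data$drug_a, .data$drug_b,
                    .data$conc_a, .data$conc_b),
    inhibition = mean(.data$inhibition), .groups = "drop"
  )
  tbl <- tibble::tibble(
    cell_line = tbl$cell_line,
    drug_row = tbl$drug_a, drug_col = tbl$drug_b,
    conc_row = tbl$conc_a, conc_col = tbl$conc_b,
    inhibition = tbl$inhibition
  )
  # (7) log1p-normalize concentrations
  if (log1p_concs) {
    tbl$conc_row <- log1p(tbl$conc_row)
    tbl$conc_col <- log1p(tbl$conc_col)
  }
  # (8) drop sparsely screened drugs (applied once, not iterated)
  drug_counts <- table(c(tbl$drug_row, tbl$drug_col[!is.na(tbl$drug_col)]))
  keep <- names(drug_counts)[drug_counts >= drug_min_entries]
  tbl <- dplyr::filter(tbl, .data$drug_row %in% keep,
                       is.na(.data$drug_col) | .data$drug_col %in% keep)
  set_conc_scale(tbl, if (log1p_concs) "log1p" else "raw_uM")
}

#' Summarize replicate noise in a raw screen
#'
#' For every canonical key (cell line, unordered drug pair, concentration
#' pair) measured at least twice, computes the sample standard deviation of
#' the replicate inhibitions, and summarizes those standard deviations across
#' keys. Run this before replicate averaging.
#'
#' @param table A screen table that still contains replicates.
#' @return A one-row tibble with `mean_sd`, `median_sd` and
#'   `n_replicated_keys`. When no key has replicates the summary values are
#'   `NA` and `n_replicated_keys` is 0.
#' @export
replicate_noise_summary <- function(table) {
  key <- canonical_key(table)
  sds <- tapply(table$inhibition, key, function(x) if (length(x) >= 2) sd(x) else NA_real_)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) {
    return(tibble::tibble(mean_sd = NA_real_, median_sd = NA_real_, n_replicated_keys = 0L))
  }
  tibble::tibble(mean_sd = mean(sds), median_sd = median(sds),
                 n_replicated_keys = length(sds))
}
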