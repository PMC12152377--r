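#' @importFrom rlang %||% .data abort warn
#' @importFrom stats cor median prcomp predict quantile rbinom rnorm runif sd setNames wilcox.test
#' @importFrom utils head
NULL

# concentration scale flag carried on screen tables ("raw_uM" or "log1p")
conc_scale <- function(table) attr(table, "conc_scale") %||% "raw_uM"

set_conc_scale <- function(table, scale) {
  stopifnot(scale %in% c("raw_uM", "log1p"))
  attr(table, "conc_scale") <- scale
  table
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

geometric_mean <- function(x) exp(mean(log(x)))

# numeric-stable key component for concentrations (replicate matching on floats)
conc_key <- function(x) formatC(x, digits = 10, format = "g")

# Canonical treatment orientation: unordered drug pair sorted lexicographically,
# concentrations following their drugs. Monotherapies keep drug_a = drug_row.
canonicalize_pair <- function(drug_row, drug_col, conc_row, conc_col) {
  mono <- is.na(drug_col)
  swap <- !mono & drug_col < drug_row
  tibble::tibble(
    drug_a = ifelse(swap, drug_col, drug_row),
    drug_b = ifelse(swap, drug_row, drug_col),
    conc_a = ifelse(swap, conc_col, conc_row),
    conc_b = ifelse(swap, conc_row, conc_col)
  )
}

# canonical replicate key: cell + unordered pair + concentration pair
canonical_key <- function(table) {
  cp <- canonicalize_pair(table$drug_row, table$drug_col, table$conc_row, table$conc_col)
  paste(table$cell_line,
        cp$drug_a, ifelse(is.na(cp$drug_b), "NULL", cp$drug_b),
        conc_key(cp$conc_a), conc_key(cp$conc_b),
        sep = "|")
}

# treatment identifier: drug name for monotherapy, "A + B" (sorted) for combos
treatment_id <- function(drug_row, drug_col) {
  cp <- canonicalize_pair(drug_row, drug_col, 0, 0)
  ifelse(is.na(cp$drug_b), cp$drug_a, paste(cp$drug_a, cp$drug_b, sep = " + "))
}

# derive a stream-specific 32-bit seed from a pipeline seed
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483647L
}
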