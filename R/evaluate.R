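#' Summarize prediction errors, overall or by group
#'
#' Computes MAE, Pearson correlation (PCC) and R-squared between actual and
#' predicted inhibitions. Grouped summaries guard against the inflation of
#' overall correlations by between-treatment mean differences: because some
#' drugs/combinations have systematically higher inhibitions than others,
#' even constant per-treatment predictions achieve an overall PCC above 0,
#' while carrying no within-treatment signal. `per_drug` restricts to
#' monotherapies grouped by drug, `per_combination` to combinations grouped
#' by unordered pair, and `per_interval` stratifies by the actual inhibition
#' using half-open intervals `(lo, hi]`.
#'
#' Groups with fewer than two distinct actual values have an undefined PCC
#' (`NA`, not 0); macro-averages are taken over defined groups and report
#' the number of exclusions.
#'
#' @param data Tibble with columns `actual` and `predicted`, plus `drug_row`
#'   and `drug_col` for the treatment groupings.
#' @param grouping `"none"`, `"per_drug"`, `"per_combination"` or
#'   `"per_interval"`.
#' @param interval_edges Breakpoints for `per_interval` (default -25, 0, 25,
#'   50, 75, 100).
#' @return An `error_summary`: a tibble with one row per group (`group`,
#'   `n`, `mae`, `pcc`, `r2`) plus attributes `overall` (same metrics on the
#'   ungrouped data) and `macro` (means across defined groups with
#'   `n_undefined_pcc`). Retrieve them with [glance()].
#' @export
summarize_errors <- function(data,
                             grouping = c("none", "per_drug", "per_combination", "per_interval"),
                             interval_edges = c(-25, 0, 25, 50, 75, 100)) {
  grouping <- match.arg(grouping)
  if (nrow(data) == 0) abort("no samples to summarize")
  if (!all(c("actual", "predicted") %in% names(data))) {
    abort("data needs 'actual' and 'predicted' columns")
  }
  metrics <- function(a, p) {
    pcc <- if (length(unique(a)) >= 2 && length(unique(p)) >= 2) cor(a, p) else NA_real_
    sst <- sum((a - mean(a))^2)
    r2 <- if (sst > 0) 1 - sum((a - p)^2) / sst else NA_real_
    tibble::tibble(n = length(a), mae = mean(abs(a - p)), pcc = pcc, r2 = r2)
  }
  df <- tibble::as_tibble(data)
  df$group <- switch(grouping,
    none = "all",
    per_drug = ifelse(is.na(df$drug_col), df$drug_row, NA_character_),
    per_combination = ifelse(is.na(df$drug_col), NA_character_,
                             treatment_id(df$drug_row, df$drug_col)),
    per_interval = as.character(cut(df$actual, breaks = interval_edges))
  )
  df <- dplyr::filter(df, !is.na(.data$group))
  if (nrow(df) == 0) abort(paste0("no samples fall under grouping '", grouping, "'"))
  by_group <- purrr::map_dfr(split(df, df$group), function(g) {
    dplyr::bind_cols(tibble::tibble(group = g$group[1]),
                     metrics(g$actual, g$predicted))
  })
  by_group <- dplyr::arrange(by_group, .data$group)
  overall <- metrics(df$actual, df$predicted)
  defined <- !is.na(by_group$pcc)
  macro <- tibble::tibble(
    mean_mae = mean(by_group$mae),
    mean_pcc = if (any(defined)) mean(by_group$pcc[defined]) else NA_real_,
    mean_r2 = mean(by_group$r2, na.rm = TRUE),
    n_groups = nrow(by_group),
    n_undefined_pcc = sum(!defined)
  )
  structure(by_group, class = c("error_summary", class(by_group)),
            overall = overall, macro = macro, grouping = grouping)
}

#' @method glance error_summary
#' @export
glance.error_summary <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::rename_with(attr(x, "overall"), ~ paste0("overall_", .x)),
    attr(x, "macro")
  )
}

#' @method tidy error_summary
#' @export
tidy.error_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Agreement between order-swapped duplicate predictions
#'
#' For order-dependent encodings, every combination treatment appears twice
#' in the test data (drug orders AB and BA). An order-robust model should
#' predict both representations identically; this measures the Pearson
#' correlation and the mean absolute difference between the paired
#' predictions.
#'
#' @param predictions Tibble with columns `entry_key`, `order` (`"AB"` or
#'   `"BA"`) and `prediction`; every key must appear once per order.
#' @return One-row tibble with `pcc` (`NA` when either side is constant),
#'   `mean_abs_difference` and `n_pairs`.
#' @export
duplicate_agreement <- function(predictions) {
  need <- c("entry_key", "order", "prediction")
  if (!all(need %in% names(predictions))) {
    abort("predictions needs columns entry_key, order, prediction")
  }
  wide <- tidyr::pivot_wider(predictions[need], names_from = "order",
                             values_from = "prediction")
  if (!all(c("AB", "BA") %in% names(wide)) || anyNA(wide$AB) || anyNA(wide$BA)) {
    bad <- wide$entry_key[!stats::complete.cases(wide)]
    abort(paste0("unpaired entries (missing AB or BA prediction): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  pcc <- if (sd(wide$AB) > 0 && sd(wide$BA) > 0) cor(wide$AB, wide$BA) else NA_real_
  tibble::tibble(pcc = pcc,
                 mean_abs_difference = mean(abs(wide$AB - wide$BA)),
                 n_pairs = nrow(wide))
}

# signed-rank Z statistic and effect size (zeros dropped, ties averaged)
signed_rank_effect <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(r = 0, n = 0))
  rk <- rank(abs(d))
  w <- sum(sign(d) * rk)
  sigma <- sqrt(sum(rk^2))
  z <- if (sigma > 0) w / sigma else 0
  list(r = z / sqrt(n), n = n)
}

#' Pairwise comparison of prediction approaches
#'
#' Performs a paired Wilcoxon signed-rank test on the per-sample absolute
#' errors of every unordered pair of approaches, on identically keyed test
#' samples. P-values are Bonferroni-adjusted by multiplying with the number
#' of tests (capped at 1): `n` approaches yield `n (n - 1) / 2` tests. The
#' effect size `r` is the standardized signed-rank statistic divided by the
#' square root of the number of non-zero pairs; its magnitude measures
#' strength, and its sign the direction (positive when the first approach
#' of the pair has larger errors). Zero differences are dropped before
#' ranking.
#'
#' @param error_sets Named list of per-sample absolute-error vectors, all
#'   the same length and sample order.
#' @return Tibble with one row per approach pair: `approach_a`,
#'   `approach_b`, `p_raw`, `p_adjusted`, `r`, `n_tests`.
#' @export
compare_approaches <- function(error_sets) {
  if (is.null(names(error_sets)) || any(names(error_sets) == "")) {
    abort("error_sets must be a named list")
  }
  lens <- lengths(error_sets)
  if (length(unique(lens)) != 1) {
    abort("error vectors are not key-aligned (differing lengths)")
  }
  nms <- names(error_sets)
  pairs <- utils::combn(nms, 2)
  n_tests <- ncol(pairs)
  purrr::map_dfr(seq_len(n_tests), function(i) {
    a <- error_sets[[pairs[1, i]]]; b <- error_sets[[pairs[2, i]]]
    d <- a - b
    p <- if (all(d == 0)) 1 else suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    eff <- signed_rank_effect(d)
    tibble::tibble(approach_a = pairs[1, i], approach_b = pairs[2, i],
                   p_raw = p, p_adjusted = min(1, p * n_tests),
                   r = eff$r, n_tests = n_tests)
  })
}
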