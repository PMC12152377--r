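#' Rank treatments for one cell line by (combination) CMax viability
#'
#' Orders treatments from most to least effective, i.e. ascending by
#' viability (smaller CMax viability = stronger maximal clinically feasible
#' effect). Ties are broken lexicographically by treatment identifier, so
#' rankings are deterministic. Records with an undefined viability are
#' excluded and counted.
#'
#' @param records Tibble of sensitivity records for a single cell line with
#'   columns `treatment`, `type` (`"mono"`/`"combination"`) and `value`
#'   (viability in \[0, 1\]), e.g. the CMax-viability rows of
#'   [reconstruct_measures()].
#' @param scope `"mono_only"` ranks monotherapies, `"mono_plus_combo"`
#'   merges mono- and combination treatments into one list.
#' @return A `treatment_ranking` tibble (`treatment`, `type`, `viability`,
#'   `rank`), ascending by viability, with attribute `n_excluded`.
#' @export
build_ranking <- function(records, scope = c("mono_only", "mono_plus_combo")) {
  scope <- match.arg(scope)
  need <- c("treatment", "type", "value")
  if (!all(need %in% names(records))) {
    abort("records needs columns treatment, type, value")
  }
  df <- tibble::as_tibble(records)[, need]
  if (scope == "mono_only") df <- dplyr::filter(df, .data$type == "mono")
  n_before <- nrow(df)
  df <- dplyr::filter(df, !is.na(.data$value))
  if (anyDuplicated(df$treatment) > 0) {
    abort("duplicate treatment identifiers in ranking records")
  }
  df <- dplyr::arrange(df, .data$value, .data$treatment)
  out <- tibble::tibble(treatment = df$treatment, type = df$type,
                        viability = df$value, rank = seq_len(nrow(df)))
  structure(out, class = c("treatment_ranking", class(out)),
            scope = scope, n_excluded = n_before - nrow(df))
}

#' Score a predicted treatment ranking against the actual one
#'
#' Compares two rankings over the same treatment set with: the Spearman
#' correlation (SCC) between actual and predicted viabilities (1-based
#' average ranks for ties); the overlap between the top-`k` treatments of
#' both rankings for each cutoff in `ks`; the rank of the actually most
#' effective treatment within the predicted ranking and vice versa
#' (average-rank for ties); and the viability gap, i.e. how much worse (in
#' actual viability) the predicted-best treatment is than the actual best —
#' 0 when the recommendation is optimal, and never negative.
#'
#' @param actual,predicted `treatment_ranking` objects over the same
#'   treatments ([build_ranking()]).
#' @param ks Top-k cutoffs (default 5 and 10).
#' @return One-row tibble: `scc`, one `overlap_k<k>` column per cutoff,
#'   `rank_of_actual_best_in_predicted`, `rank_of_predicted_best_in_actual`,
#'   `viability_gap`, `n_treatments`.
#' @export
score_rankings <- function(actual, predicted, ks = c(5, 10)) {
  stopifnot(inherits(actual, "treatment_ranking"),
            inherits(predicted, "treatment_ranking"))
  extra_a <- setdiff(actual$treatment, predicted$treatment)
  extra_p <- setdiff(predicted$treatment, actual$treatment)
  if (length(extra_a) + length(extra_p) > 0) {
    abort(paste0("rankings cover different treatment sets; only in actual: {",
                 paste(head(extra_a, 5), collapse = ", "),
                 "}, only in predicted: {",
                 paste(head(extra_p, 5), collapse = ", "), "}"))
  }
  m <- match(actual$treatment, predicted$treatment)
  av <- actual$viability
  pv <- predicted$viability[m]
  scc <- if (length(av) >= 2) suppressWarnings(cor(av, pv, method = "spearman")) else NA_real_

  overlaps <- purrr::map_dbl(ks, function(k) {
    k <- min(k, nrow(actual))
    length(intersect(actual$treatment[seq_len(k)], predicted$treatment[seq_len(k)]))
  })
  # average ranks on the viability scale (ties share a rank)
  pred_ranks <- rank(pv)   # aligned with actual$treatment order
  act_ranks <- rank(av)
  best_actual <- 1L                       # actual ranking is sorted
  best_pred_tr <- predicted$treatment[1]
  i_bp <- match(best_pred_tr, actual$treatment)
  out <- tibble::tibble(
    scc = scc,
    rank_of_actual_best_in_predicted = pred_ranks[best_actual],
    rank_of_predicted_best_in_actual = act_ranks[i_bp],
    viability_gap = av[i_bp] - min(av),
    n_treatments = nrow(actual)
  )
  for (i in seq_along(ks)) out[[paste0("overlap_k", ks[i])]] <- overlaps[i]
  out
}
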