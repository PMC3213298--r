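#' Confusion counts between predicted and true label tracks
#'
#' Positions where either track is `"?"`/`NA` are excluded pairwise.
#' Accepts character tracks (`"0"`/`"1"`/`"?"`) or 0/1 numeric vectors.
#'
#' @param predicted,actual Equal-length label tracks.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  p <- as_binary_track(predicted)
  a <- as_binary_track(actual)
  if (length(p) != length(a)) {
    abort("label tracks have different lengths", class = "homint_domain_error")
  }
  ok <- !is.na(p) & !is.na(a)
  tibble(
    tp = sum(p[ok] == 1 & a[ok] == 1),
    fp = sum(p[ok] == 1 & a[ok] == 0),
    tn = sum(p[ok] == 0 & a[ok] == 0),
    fn = sum(p[ok] == 0 & a[ok] == 1)
  )
}

as_binary_track <- function(x) {
  if (is.character(x)) {
    out <- suppressWarnings(as.integer(x))
    out[!x %in% c("0", "1")] <- NA_integer_
    return(out)
  }
  as.integer(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`; specificity in the
#' precision sense used throughout this package, `TP/(TP+FP)` — not the
#' true-negative rate; accuracy `(TP+TN)/total`; and the Matthews
#' correlation coefficient. A metric whose denominator is zero is undefined
#' and reported as `NA` (summaries exclude and count these rather than
#' substituting zeros).
#'
#' @param counts Tibble with columns `tp`, `fp`, `tn`, `fn` (one row per
#'   protein, or a single pooled row).
#' @return `counts` with `sensitivity`, `specificity`, `accuracy`, `cc`
#'   appended.
#' @export
classification_metrics <- function(counts) {
  with_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(counts,
    sensitivity = with_na(.data$tp, .data$tp + .data$fn),
    specificity = with_na(.data$tp, .data$tp + .data$fp),
    accuracy = with_na(.data$tp + .data$tn, .data$tp + .data$fp + .data$tn + .data$fn),
    cc = mcc(.data$tp, .data$fp, .data$tn, .data$fn)
  )
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, `NA` when any
#' marginal is zero. Computed in floating point so large pooled counts do
#' not overflow.
#'
#' @param tp,fp,tn,fn Count vectors.
#' @return Numeric vector in `[-1, 1]` (or `NA`).
#' @export
mcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(den2 > 0, (tp * tn - fp * fn) / sqrt(den2), NA_real_)
}

#' Overall performance, protein-based and residue-based
#'
#' Protein-based overall measures are unweighted means over proteins of
#' each per-protein metric, excluding proteins for which that metric is
#' undefined (the number excluded is reported per metric). Residue-based
#' measures pool the confusion counts over all proteins first, so large
#' proteins weigh more. The two families answer different questions — how
#' well a given *protein* is predicted on average versus how well a given
#' *residue* is labelled — and differ whenever protein sizes or
#' difficulties differ.
#'
#' @param counts Tibble of per-protein confusion counts (`tp`, `fp`, `tn`,
#'   `fn`; any id columns are preserved in neither output).
#' @return Tibble with rows `basis = "protein"` and `basis = "residue"`,
#'   the four metrics, `n_proteins`, and per-metric `n_undefined_*`
#'   counts (protein basis only).
#' @export
summarize_performance <- function(counts) {
  per <- classification_metrics(counts)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "cc")
  protein <- tibble(basis = "protein", n_proteins = nrow(per))
  for (m in metric_cols) {
    protein[[m]] <- mean(per[[m]], na.rm = TRUE)
    protein[[paste0("n_undefined_", m)]] <- sum(is.na(per[[m]]))
  }
  pooled <- classification_metrics(tibble(
    tp = sum(counts$tp), fp = sum(counts$fp),
    tn = sum(counts$tn), fn = sum(counts$fn)
  ))
  residue <- dplyr::mutate(
    dplyr::select(pooled, dplyr::all_of(metric_cols)),
    basis = "residue", n_proteins = nrow(per)
  )
  dplyr::bind_rows(protein, residue) |>
    dplyr::select(dplyr::all_of(c("basis", "n_proteins", metric_cols)),
                  dplyr::everything())
}

#' Interface conservation score between two label tracks
#'
#' The Matthews correlation between interface labels transferred from a
#' template (or predicted) and a query's true labels; `"?"` positions are
#' excluded pairwise. This is the quantity the linear ranking models
#' approximate from alignment statistics.
#'
#' @param predicted,actual Equal-length label tracks
#'   (`"0"`/`"1"`/`"?"` or 0/1/NA).
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
ic_score <- function(predicted, actual) {
  classification_metrics(confusion_counts(predicted, actual))$cc
}

#' Precision-recall sweep over the vote-score threshold
#'
#' Majority-vote predictors emit a small set of distinct vote scores, so
#' the sweep evaluates exactly the thresholds present in the data: at
#' threshold `t` a residue is called an interface when its vote score is
#' `>= t`. Overall sensitivity and specificity (precision) at each
#' threshold follow the chosen basis of [summarize_performance()].
#'
#' @param scores Tibble with columns `protein_id`, `vote_score` (NA for
#'   positions without votes, which are counted as negatives), and `truth`
#'   (0/1 or `"0"`/`"1"`/`"?"`).
#' @param basis `"protein"` or `"residue"`.
#' @return Tibble `threshold`, `sensitivity`, `specificity`, ordered by
#'   increasing threshold.
#' @export
pr_sweep <- function(scores, basis = c("protein", "residue")) {
  basis <- match.arg(basis)
  thresholds <- sort(unique(scores$vote_score[!is.na(scores$vote_score)]))
  purrr::map_dfr(thresholds, function(t) pr_at_threshold(scores, t, basis))
}

#' @rdname pr_sweep
#' @param threshold Vote-score threshold applied as `vote_score >= threshold`.
#' @export
pr_at_threshold <- function(scores, threshold, basis = c("protein", "residue")) {
  basis <- match.arg(basis)
  truth <- as_binary_track(scores$truth)
  keep <- !is.na(truth)
  scores <- scores[keep, , drop = FALSE]
  truth <- truth[keep]
  call <- as.integer(!is.na(scores$vote_score) & scores$vote_score >= threshold)
  counts <- tibble(protein_id = scores$protein_id, call = call, truth = truth) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      tp = sum(.data$call == 1 & .data$truth == 1),
      fp = sum(.data$call == 1 & .data$truth == 0),
      tn = sum(.data$call == 0 & .data$truth == 0),
      fn = sum(.data$call == 0 & .data$truth == 1),
      .groups = "drop"
    )
  row <- summarize_performance(dplyr::select(counts, -"protein_id"))
  row <- row[row$basis == basis, , drop = FALSE]
  tibble(threshold = threshold, sensitivity = row$sensitivity,
         specificity = row$specificity)
}

#' Evaluate a set of predictions against truth tracks
#'
#' Convenience wrapper: computes per-protein confusion counts from tidied
#' predictions and a truth label table, then the overall summaries.
#'
#' @param predictions Tibble as from stacking [tidy()] prediction tables
#'   (`query_id`, `pos`, `call`).
#' @param truth Label tibble (`chain`, `pos`, `label`) with `chain`
#'   matching `query_id`.
#' @return List with `per_protein` (counts + metrics) and `overall`
#'   (protein- and residue-based rows).
#' @export
evaluate_predictions <- function(predictions, truth) {
  per <- predictions |>
    dplyr::inner_join(dplyr::rename(truth, query_id = "chain"),
                      by = c("query_id", "pos")) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::group_modify(function(d, key) {
      confusion_counts(as.character(d$call), d$label)
    }) |>
    dplyr::ungroup()
  list(
    per_protein = classification_metrics(per),
    overall = summarize_performance(dplyr::select(per, -"query_id"))
  )
}
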