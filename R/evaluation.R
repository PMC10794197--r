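# Scoring of extracted records against gold annotations: three-clause
# true-positive definition, precision/recall/F-score, and accumulative
# convergence curves averaged over random accumulating orders.

value_equal <- function(a, b, tol = 1e-9) {
  if (length(a) != length(b)) return(FALSE)
  all(abs(a - b) <= tol * pmax(1, abs(a), abs(b)))
}

compound_overlaps <- function(a, b) {
  an <- tolower(normalize_name(c(a$names %||% character(0),
                                 a$labels %||% character(0))))
  bn <- tolower(normalize_name(c(b$names %||% character(0),
                                 b$labels %||% character(0))))
  length(intersect(an[nzchar(an)], bn[nzchar(bn)])) > 0
}

record_matches <- function(extracted, gold, tol = 1e-9) {
  # (i) correct property with both the value and the unit (compared on the
  #     standardized scale, which ties value and unit together)
  if (!identical(extracted$property_id, gold$property_id)) return(FALSE)
  if (!value_equal(extracted$standard_value, gold$standard_value, tol)) return(FALSE)
  # (ii) correct compound name or label
  if (is.null(extracted$compound) || is.null(gold$compound)) return(FALSE)
  if (!compound_overlaps(extracted$compound, gold$compound)) return(FALSE)
  # (iii) correct temperature for delayed-lifetime records
  if (identical(extracted$property_id, "tau_d")) {
    te <- extracted$extra$temperature
    tg <- gold$extra$temperature
    if (is.null(te) != is.null(tg)) return(FALSE)
    if (!is.null(te) && !value_equal(te, tg, tol)) return(FALSE)
  }
  TRUE
}

#' Match extracted records against gold records
#'
#' Greedy one-to-one matching per document, in document order. A pair
#' matches iff (i) the property, value and unit agree (exact equality of
#' standardized values, relative tolerance 1e-9), (ii) a compound name or
#' label agrees, and (iii) for delayed-lifetime records the temperature
#' agrees. Unmatched extracted records are false positives; unmatched gold
#' records are false negatives.
#'
#' @param extracted,gold Lists of records carrying `provenance$doc_id`.
#' @return List with `tp`, `fp`, `fn` counts, `labels` (logical per
#'   extracted record: matched), `gold_hit` (logical per gold record), and
#'   `per_property` count table.
#' @export
match_records <- function(extracted, gold) {
  doc_of <- function(r) r$provenance$doc_id %||% ""
  gold_used <- rep(FALSE, length(gold))
  labels <- rep(FALSE, length(extracted))
  gold_docs <- vapply(gold, doc_of, character(1))
  for (i in seq_along(extracted)) {
    e <- extracted[[i]]
    cand <- which(!gold_used & gold_docs == doc_of(e))
    for (j in cand) {
      if (record_matches(e, gold[[j]])) {
        gold_used[j] <- TRUE
        labels[i] <- TRUE
        break
      }
    }
  }
  props <- c("lambda_em", "plqy", "delta_e_st", "tau_d")
  per_property <- lapply(setNames(props, props), function(p) {
    ei <- vapply(extracted, function(r) identical(r$property_id, p), logical(1))
    gi <- vapply(gold, function(r) identical(r$property_id, p), logical(1))
    c(tp = sum(labels[ei]), fp = sum(!labels[ei]), fn = sum(!gold_used[gi]))
  })
  list(
    tp = sum(labels), fp = sum(!labels), fn = sum(!gold_used),
    labels = labels, gold_hit = gold_used, per_property = per_property
  )
}

#' Precision, recall and F-score from confusion counts
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F = 2PR/(P+R); a zero denominator yields
#' 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named list `(precision, recall, f_score)`.
#' @export
compute_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_score <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f_score = f_score)
}

#' Accumulative convergence curves over random accumulating orders
#'
#' For each of `n_orders` random permutations of the per-record outcome
#' labels, computes the cumulative metric after k records; the final point
#' of every curve equals the overall metric regardless of the permutation.
#' The mean curve across orders is returned alongside the individual curves.
#'
#' @param labels Logical vector: per extracted record TP (for precision
#'   curves) or per gold record hit (for recall curves).
#' @param n_orders Number of random accumulating orders (default 5).
#' @param seed Integer seed making the permutations reproducible.
#' @return List with `curves` (list of numeric vectors), `mean_curve`,
#'   `final` (overall metric), `n_orders`.
#' @export
accumulative_curves <- function(labels, n_orders = 5, seed = 1) {
  if (n_orders < 1) stop("n_orders must be >= 1")
  labels <- as.logical(labels)
  n <- length(labels)
  curves <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_orders), function(o) {
      perm <- sample.int(n)
      cumsum(labels[perm]) / seq_len(n)
    })
  })
  mean_curve <- if (n > 0) Reduce(`+`, curves) / n_orders else numeric(0)
  list(
    curves = curves, mean_curve = mean_curve,
    final = if (n > 0) mean(labels) else 0,
    n_orders = n_orders
  )
}

#' Evaluate extracted records against a gold file
#'
#' @param extracted List of records (or path readable by [read_records()]).
#' @param gold List of gold records (or a JSON path).
#' @param n_orders,seed Passed to [accumulative_curves()].
#' @return A `tadf_evaluation_report`: counts, metrics, per-property
#'   breakdown, precision and recall convergence curves.
#' @export
evaluate_records <- function(extracted, gold, n_orders = 5, seed = 1) {
  if (is.character(extracted)) extracted <- read_records(extracted, "json")
  if (is.character(gold)) gold <- read_records(gold, "json")
  m <- match_records(extracted, gold)
  metrics <- compute_metrics(m$tp, m$fp, m$fn)
  per_property <- lapply(m$per_property, function(cts) {
    c(as.list(cts), compute_metrics(cts[["tp"]], cts[["fp"]], cts[["fn"]]))
  })
  structure(
    c(list(tp = m$tp, fp = m$fp, fn = m$fn), metrics,
      list(
        per_property = per_property,
        precision_curves = accumulative_curves(m$labels, n_orders, seed),
        recall_curves = accumulative_curves(m$gold_hit, n_orders, seed + 1),
        n_orders = n_orders
      )),
    class = "tadf_evaluation_report"
  )
}

#' @export
print.tadf_evaluation_report <- function(x, ...) {
  cat(sprintf("<tadf_evaluation_report> TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Mean precision over property-wise values
#'
#' Returns both the simple (unweighted) mean and the record-count-weighted
#' mean of per-property precisions, both in percent.
#'
#' @param precisions Numeric vector of per-property precisions in percent.
#' @param n_records Record counts per property (weights).
#' @return Named list `(simple, weighted)`.
#' @export
mean_precision <- function(precisions, n_records) {
  list(simple = mean(precisions),
       weighted = sum(precisions * n_records) / sum(n_records))
}
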