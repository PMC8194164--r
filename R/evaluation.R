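#' @title Retrieval evaluation
#' @description Performance measures for target prediction: top-N success
#'   rate, per-query precision/recall/F1 at N, decoy (presumed-inactive)
#'   evaluation, and pooled-percentage aggregation of per-class count
#'   tables. A prediction is correct when the predicted target name matches
#'   any known target of the query (case-insensitive, whitespace
#'   normalized).
#' @name evaluation
NULL

.norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

# ranked target names (deduplicated records kept in rank order) for one
# query result data.frame
.ranked_names <- function(res) {
  res <- res[!is.na(res$rank), , drop = FALSE]
  res <- res[order(res$rank), , drop = FALSE]
  res$target_name
}

#' Top-N success rate over a query set
#'
#' Fraction of queries with at least one record in the top `n` whose target
#' name is among the query's true targets. Queries missing from `truth` are
#' excluded with a warning.
#'
#' @param results Named list of ranked prediction data.frames (one per
#'   query, as from [predict_batch()]).
#' @param truth Named list: query id -> character vector of true target
#'   names (multi-target compounds list several).
#' @param n Rank threshold (e.g. 1, 5, 10).
#' @return Success rate in \[0, 1\].
#' @export
success_rate <- function(results, truth, n) {
  stopifnot(n >= 1L)
  ids <- names(results)
  known <- ids %in% names(truth)
  if (!all(known)) {
    warning(sum(!known), " quer(ies) without ground truth excluded")
    ids <- ids[known]
  }
  if (!length(ids)) stop("no evaluable queries")
  hits <- vapply(ids, function(id) {
    ranked <- .norm_name(.ranked_names(results[[id]]))
    any(utils::head(ranked, n) %in% .norm_name(truth[[id]]))
  }, logical(1))
  mean(hits)
}

#' Per-query precision, recall and F1 at rank N
#'
#' Taking the top `n` records as predicted positives and all true targets as
#' actual positives: TP = distinct true target names matched within the top
#' `n` (duplicate PDB entries of one target name count once); recall =
#' TP / |truth|; precision = TP / min(n, records returned) so short result
#' lists keep precision bounded by 1; F1 = 2PR/(P+R), 0 when P + R = 0.
#' Queries with zero returned records score (0, 0, 0) and are flagged.
#'
#' @inheritParams success_rate
#' @return List with per-query data.frame `per_query` (columns `query_id`,
#'   `tp`, `precision`, `recall`, `f1`, `flagged`) and unweighted means
#'   `precision`, `recall`, `f1`.
#' @export
prf_at_n <- function(results, truth, n) {
  stopifnot(n >= 1L)
  ids <- names(results)
  known <- ids %in% names(truth)
  if (!all(known)) {
    warning(sum(!known), " quer(ies) without ground truth excluded")
    ids <- ids[known]
  }
  per <- lapply(ids, function(id) {
    ranked <- .norm_name(.ranked_names(results[[id]]))
    tr <- unique(.norm_name(truth[[id]]))
    if (!length(tr)) stop("empty truth set for query ", id)
    top <- utils::head(ranked, n)
    tp <- length(intersect(unique(top), tr))
    denom <- min(n, length(ranked))
    if (denom == 0L) {
      return(data.frame(query_id = id, tp = 0L, precision = 0, recall = 0,
                        f1 = 0, flagged = TRUE, stringsAsFactors = FALSE))
    }
    precision <- tp / denom
    recall <- tp / length(tr)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(query_id = id, tp = tp, precision = precision,
               recall = recall, f1 = f1, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_query = per,
       precision = mean(per$precision),
       recall = mean(per$recall),
       f1 = mean(per$f1))
}

#' Full evaluation report for a query set
#'
#' Per-query rank of the first true target plus aggregate success rates at
#' N in \{1, 5, 10\} and mean precision/recall/F1 at N = 10.
#'
#' @inheritParams success_rate
#' @param ns Rank thresholds for success rates.
#' @param prf_n Rank threshold for the precision/recall/F1 averages.
#' @return Object of class `evaluation_report`.
#' @export
evaluation_report <- function(results, truth, ns = c(1L, 5L, 10L),
                              prf_n = 10L) {
  first_rank <- vapply(names(results), function(id) {
    if (!id %in% names(truth)) return(NA_integer_)
    ranked <- .norm_name(.ranked_names(results[[id]]))
    hit <- which(ranked %in% .norm_name(truth[[id]]))
    if (length(hit)) as.integer(hit[1]) else NA_integer_
  }, integer(1))
  success <- vapply(ns, function(n) success_rate(results, truth, n), numeric(1))
  prf <- prf_at_n(results, truth, prf_n)
  structure(list(
    first_true_rank = first_rank,
    success = stats::setNames(success, paste0("top", ns)),
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    prf_n = prf_n, per_query = prf$per_query),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Target prediction evaluation\n")
  cat("  success rates:",
      paste(sprintf("%s = %.3f", names(x$success), x$success),
            collapse = ", "), "\n")
  cat(sprintf("  mean (top %d): precision %.3f, recall %.3f, F1 %.3f\n",
              x$prf_n, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Decoy (negative-compound) evaluation
#'
#' For each intended target, counts how many of its decoys rank that target
#' within the top 1 / 5 / 10 of their prediction lists. The fail percentage
#' -- decoys whose intended target does NOT appear in the top 10 -- is the
#' headline number: high is good for presumed-inactive molecules.
#' Percentages are rounded to the nearest integer.
#'
#' @param decoy_results Named list of ranked prediction data.frames, one
#'   per decoy.
#' @param intended_target Named character vector: decoy id -> intended
#'   target name.
#' @return Object of class `decoy_report`: data.frame with per-target
#'   counts `n`, `top1`, `top5`, `top10`, `fail` and percentages
#'   `top10_pct`, `fail_pct`.
#' @export
decoy_evaluate <- function(decoy_results, intended_target) {
  ids <- names(decoy_results)
  stopifnot(all(ids %in% names(intended_target)))
  per_target <- split(ids, unname(intended_target[ids]))
  rows <- lapply(names(per_target), function(tn) {
    dids <- per_target[[tn]]
    rank_of <- vapply(dids, function(id) {
      ranked <- .norm_name(.ranked_names(decoy_results[[id]]))
      hit <- which(ranked %in% .norm_name(tn))
      if (length(hit)) hit[1] else Inf
    }, numeric(1))
    n <- length(dids)
    top10 <- sum(rank_of <= 10)
    data.frame(intended_target = tn, n = n,
               top1 = sum(rank_of <= 1), top5 = sum(rank_of <= 5),
               top10 = top10, fail = n - top10,
               top10_pct = round(100 * top10 / n),
               fail_pct = round(100 * (n - top10) / n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("decoy_report", "data.frame"))
}

#' Pool per-class top-N hit counts into overall percentages
#'
#' Column-wise totals of per-class hit/fail counts and pooled percentages
#' over the union of ligands, rounded to the nearest integer -- the
#' arithmetic behind "Total" and "(%)" rows of benchmark comparison tables.
#'
#' @param counts data.frame with column `n` (ligands per class) and one or
#'   more hit-count columns (e.g. `top1`, `top10`, `fail`).
#' @return List with `totals` (named sums including `n`) and `percent`
#'   (named integer percentages of each count column over total `n`).
#' @export
#' @examples
#' aggregate_table(data.frame(n = c(19, 19, 18, 16, 5),
#'                            top10 = c(19, 18, 13, 16, 0)))
aggregate_table <- function(counts) {
  stopifnot(is.data.frame(counts), "n" %in% names(counts))
  count_cols <- setdiff(names(counts), c("n", "class", "intended_target"))
  count_cols <- count_cols[vapply(counts[count_cols], is.numeric, logical(1))]
  if (!length(count_cols)) stop("no count columns to aggregate")
  for (cc in count_cols) {
    if (any(counts[[cc]] > counts$n | counts[[cc]] < 0)) {
      stop("inconsistent counts in column '", cc, "' (outside [0, n])")
    }
  }
  n_total <- sum(counts$n)
  totals <- c(n = n_total, vapply(counts[count_cols], sum, numeric(1)))
  percent <- vapply(counts[count_cols],
                    function(v) round(100 * sum(v) / n_total), numeric(1))
  list(totals = totals, percent = percent)
}
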